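# Shared test helpers: micro-ontologies and independent graph oracles.

# A tiny ontology built from an edge specification like
#   c("a IS_A b", "x CONJUGATE_BASE_OF y")
micro_ontology <- function(edge_spec, extra_nodes = character()) {
  parts <- strsplit(edge_spec, " ")
  edges <- data.frame(source = vapply(parts, `[[`, "", 1),
                      kind = vapply(parts, `[[`, "", 2),
                      target = vapply(parts, `[[`, "", 3),
                      stringsAsFactors = FALSE)
  ids <- unique(c(edges$source, edges$target, extra_nodes))
  onto_graph(data.frame(id = ids, name = ids, is_obsolete = FALSE,
                        stringsAsFactors = FALSE), edges)
}

# Independent transitive-closure oracle over IS_A edges (direction "up"
# follows child -> parent). Returns data.frame(id, depth) like ancestors().
reach_oracle <- function(graph, id, direction = "up", max_steps = Inf) {
  is_a <- graph$edges[graph$edges$kind == "IS_A", , drop = FALSE]
  step <- if (direction == "up") {
    function(v) is_a$target[is_a$source %in% v]
  } else {
    function(v) is_a$source[is_a$target %in% v]
  }
  out <- data.frame(id = character(), depth = integer(), stringsAsFactors = FALSE)
  frontier <- id
  seen <- id
  d <- 0
  while (length(frontier) > 0 && d < max_steps) {
    d <- d + 1
    frontier <- setdiff(unique(step(frontier)), seen)
    if (length(frontier) == 0) break
    seen <- c(seen, frontier)
    out <- rbind(out, data.frame(id = frontier, depth = d, stringsAsFactors = FALSE))
  }
  out
}

# Exhaustive simple-path enumeration on a compound graph; returns the
# minimal total node weight (endpoints included) between a and b, or Inf.
enum_lightest <- function(graph, a, b) {
  best <- Inf
  walk <- function(node, seen, total) {
    if (node == b) {
      best <<- min(best, total)
      return(invisible())
    }
    for (nb in graph$adj[[node]]) {
      if (nb %in% seen) next
      walk(nb, c(seen, nb), total + graph$weight[[nb]])
    }
    invisible()
  }
  walk(a, a, graph$weight[[a]])
  best
}

# Minimal hop count between a and b by BFS (uniform-weight reference).
bfs_hops <- function(graph, a, b) {
  if (a == b) return(0)
  frontier <- a; seen <- a; d <- 0
  while (length(frontier) > 0) {
    d <- d + 1
    frontier <- setdiff(unique(unlist(graph$adj[frontier], use.names = FALSE)), seen)
    if (b %in% frontier) return(d)
    seen <- c(seen, frontier)
  }
  Inf
}

fig2_paths <- function() {
  fx <- fig2_fixture()
  ontology_paths(fx$ontology, "CHEBI:36021",
                 c("CHEBI:30823", "CHEBI:28868", "CHEBI:7896"))
}

extdata <- function(...) {
  system.file("extdata", ..., package = "chebimap", mustWork = TRUE)
}
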