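#' Build the bipartite compound graph of a network
#'
#' Undirected bipartite graph with one node per unique compound (base id)
#' and one node per reaction; a compound is linked to every reaction it
#' participates in (as substrate or product, in any compartment copy).
#' Reaction direction is ignored. Listed side compounds (ubiquitous
#' cofactors such as ATP or water, whose high degree distorts path search)
#' are removed before degrees are computed. Every node is weighted by its
#' squared degree, the weight used by [lightest_path()].
#'
#' @param network a `metabolic_network`.
#' @param side_compounds optional character vector of base ids to drop;
#'   unknown ids raise a warning and are ignored.
#' @return object of class `compound_graph`: list with `nodes`, `type`
#'   (`"metabolite"`/`"reaction"`), `adj` (named adjacency list), `weight`
#'   (named numeric, degree squared), `edges` (two-column data.frame).
#' @export
build_compound_graph <- function(network, side_compounds = NULL) {
  met <- network$metabolites
  base_of <- stats::setNames(met$base_id, met$species_id)
  if (!is.null(side_compounds)) {
    missing <- setdiff(side_compounds, met$base_id)
    if (length(missing) > 0) {
      warning("side compound(s) not in network, ignored: ",
              paste(missing, collapse = ", "))
    }
  }
  drop <- side_compounds %||% character()
  from <- character(); to <- character()
  for (r in network$reactions) {
    parts <- unique(base_of[c(r$substrates$species_id, r$products$species_id)])
    parts <- setdiff(parts, drop)
    if (length(parts) == 0) next
    from <- c(from, rep(r$reaction_id, length(parts)))
    to <- c(to, parts)
  }
  edges <- unique(data.frame(from = from, to = to, stringsAsFactors = FALSE))
  mets <- setdiff(unique(met$base_id), drop)
  rxns <- unique(edges$from)
  nodes <- c(mets, rxns)
  type <- stats::setNames(c(rep("metabolite", length(mets)),
                            rep("reaction", length(rxns))), nodes)
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  both <- rbind(edges, data.frame(from = edges$to, to = edges$from,
                                  stringsAsFactors = FALSE))
  got <- split(both$to, factor(both$from, levels = nodes))
  adj[names(got)] <- lapply(got, function(v) sort(unique(v)))
  deg <- vapply(adj, length, integer(1))
  structure(list(nodes = nodes, type = type, adj = adj,
                 weight = stats::setNames(as.numeric(deg)^2, nodes),
                 edges = edges),
            class = "compound_graph")
}

#' @export
print.compound_graph <- function(x, ...) {
  cat(sprintf("Compound graph: %d metabolites, %d reactions, %d edges\n",
              sum(x$type == "metabolite"), sum(x$type == "reaction"),
              nrow(x$edges)))
  invisible(x)
}

#' Lightest path between two nodes under squared-degree weights
#'
#' Returns the path minimizing the cumulated node weight (sum of squared
#' degrees over all path nodes, endpoints included), the heuristic that
#' steers paths away from hub currency metabolites. Ties on total weight
#' are broken toward fewer hops, then toward smaller node labels, so
#' results are deterministic. Implemented as Dijkstra with
#' the standard node-to-edge weight transformation.
#'
#' @param graph a `compound_graph`.
#' @param a,b node ids.
#' @return list with `path` (character vector, `NULL` when disconnected),
#'   `weight` (total, `Inf` when disconnected), `connected` (logical).
#' @export
lightest_path <- function(graph, a, b) {
  if (!(a %in% graph$nodes)) stop("unknown node: ", a)
  if (!(b %in% graph$nodes)) stop("unknown node: ", b)
  w <- graph$weight
  if (a == b) return(list(path = a, weight = unname(w[[a]]), connected = TRUE))
  # dist = total node weight from a up to and including the key node
  dist <- stats::setNames(rep(Inf, length(graph$nodes)), graph$nodes)
  hops <- dist
  prev <- stats::setNames(rep(NA_character_, length(graph$nodes)), graph$nodes)
  dist[[a]] <- w[[a]]; hops[[a]] <- 0
  done <- stats::setNames(rep(FALSE, length(graph$nodes)), graph$nodes)
  repeat {
    open <- which(!done & is.finite(dist))
    if (length(open) == 0) break
    ord <- open[order(dist[open], hops[open], names(dist)[open])]
    u <- names(dist)[ord[1]]
    if (u == b) break
    done[[u]] <- TRUE
    for (v in graph$adj[[u]]) {
      if (done[[v]]) next
      nd <- dist[[u]] + w[[v]]
      nh <- hops[[u]] + 1
      better <- nd < dist[[v]] || (nd == dist[[v]] && nh < hops[[v]]) ||
        (nd == dist[[v]] && nh == hops[[v]] && !is.na(prev[[v]]) && u < prev[[v]])
      if (better) {
        dist[[v]] <- nd; hops[[v]] <- nh; prev[[v]] <- u
      }
    }
  }
  if (!is.finite(dist[[b]])) {
    return(list(path = NULL, weight = Inf, connected = FALSE))
  }
  path <- b
  while (path[1] != a) path <- c(prev[[path[1]]], path)
  list(path = path, weight = unname(dist[[b]]), connected = TRUE)
}

#' Extract the subnetwork connecting a set of mapped metabolites
#'
#' Union, over all unordered pairs of mapped compounds, of the lightest
#' paths between them on the bipartite compound graph. Reaction nodes on
#' the paths become the subnetwork's reactions; metabolite nodes (and the
#' mapped compounds themselves) its metabolites. Pairs with no connecting
#' path are reported, not dropped.
#'
#' @param network the source `metabolic_network`.
#' @param graph the `compound_graph` built from it.
#' @param mapped character vector of mapped base ids; ids absent from the
#'   graph are reported in `absent` and skipped.
#' @return object of class `subnetwork`: list with `metabolite_ids`,
#'   `reaction_ids`, `source_pairs` (data.frame: `from`, `to`, `weight`,
#'   `connected`), `mapped`, `absent`.
#' @export
extract_subnetwork <- function(network, graph, mapped) {
  mapped <- unique(mapped)
  absent <- setdiff(mapped, graph$nodes[graph$type == "metabolite"])
  if (length(absent) > 0) {
    warning("mapped id(s) not in compound graph, skipped: ",
            paste(absent, collapse = ", "))
  }
  mapped <- sort(setdiff(mapped, absent))
  mets <- character(); rxns <- character()
  pairs <- data.frame(from = character(), to = character(), weight = numeric(),
                      connected = logical(), stringsAsFactors = FALSE)
  if (length(mapped) < 2) {
    warning("fewer than 2 mapped nodes; returning the mapped nodes only")
    mets <- mapped
  } else {
    for (i in seq_len(length(mapped) - 1)) {
      for (j in seq(i + 1, length(mapped))) {
        lp <- lightest_path(graph, mapped[i], mapped[j])
        pairs <- rbind(pairs, data.frame(
          from = mapped[i], to = mapped[j], weight = lp$weight,
          connected = lp$connected, stringsAsFactors = FALSE))
        if (lp$connected) {
          on_path <- lp$path
          mets <- c(mets, on_path[graph$type[on_path] == "metabolite"])
          rxns <- c(rxns, on_path[graph$type[on_path] == "reaction"])
        }
      }
    }
    mets <- c(mets, mapped)
  }
  structure(list(metabolite_ids = sort(unique(mets)),
                 reaction_ids = sort(unique(rxns)),
                 source_pairs = pairs, mapped = mapped, absent = absent),
            class = "subnetwork")
}

#' @export
print.subnetwork <- function(x, ...) {
  cat(sprintf("Subnetwork: %d metabolites, %d reactions (from %d mapped compounds)\n",
              length(x$metabolite_ids), length(x$reaction_ids), length(x$mapped)))
  if (nrow(x$source_pairs) > 0 && any(!x$source_pairs$connected)) {
    cat("  disconnected pairs:", sum(!x$source_pairs$connected), "\n")
  }
  invisible(x)
}

#' Export a subnetwork
#'
#' Writes the subnetwork as an SBML subset of the source model and/or as an
#' undirected edge-list TSV (`from`, `to` compound-graph edges restricted
#' to the subnetwork).
#'
#' @param sub a `subnetwork`.
#' @param network the source `metabolic_network`.
#' @param graph the `compound_graph` used for extraction.
#' @param sbml_path,edges_path output paths (either may be `NULL` to skip).
#' @return invisible list of written paths.
#' @export
write_subnetwork <- function(sub, network, graph, sbml_path = NULL,
                             edges_path = NULL) {
  written <- list()
  if (!is.null(edges_path)) {
    keep <- graph$edges$from %in% sub$reaction_ids &
      graph$edges$to %in% sub$metabolite_ids
    utils::write.table(graph$edges[keep, , drop = FALSE], edges_path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    written$edges <- edges_path
  }
  if (!is.null(sbml_path)) {
    met <- network$metabolites
    # keep all species of retained reactions so the SBML subset is valid
    rx_species <- unique(unlist(lapply(network$reactions[sub$reaction_ids],
      function(r) c(r$substrates$species_id, r$products$species_id)),
      use.names = FALSE))
    keep_sp <- union(met$species_id[met$base_id %in% sub$metabolite_ids], rx_species)
    write_sbml(network, sbml_path, species_ids = keep_sp,
               reaction_ids = sub$reaction_ids)
    written$sbml <- sbml_path
  }
  invisible(written)
}
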