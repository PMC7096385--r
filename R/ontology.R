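EDGE_KINDS <- c("IS_A", "CONJUGATE_BASE_OF", "CONJUGATE_ACID_OF", "TAUTOMER_OF")
FUNCTIONAL_KINDS <- c("CONJUGATE_BASE_OF", "CONJUGATE_ACID_OF", "TAUTOMER_OF")

#' Canonicalize a ChEBI identifier
#'
#' Accepts the common spellings found in datasets and SBML annotations
#' (`"CHEBI:30823"`, `"chebi:30823"`, `"CHEBI_30823"`, `"30823"`, and digit
#' groups containing thousands separators such as `"CHEBI:36,021"`) and
#' returns the canonical `"CHEBI:<digits>"` form. Values with no digits
#' return `NA`.
#'
#' @param x character vector of raw identifiers.
#' @return character vector of canonical ids (`NA` where unparseable).
#' @export
#' @examples
#' canonical_chebi(c("chebi:30823", "36,021", "CHEBI_35366", "n/a"))
canonical_chebi <- function(x) {
  x <- trimws(as.character(x))
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x) & nzchar(x)
  digits <- gsub("[ ,]", "", x[ok])
  digits <- sub("^(?i)chebi[:_]?\\s*", "", digits, perl = TRUE)
  good <- grepl("^[0-9]+$", digits)
  out[ok][good] <- paste0("CHEBI:", digits[good])
  out
}

#' Construct a chemical-entity ontology graph
#'
#' The ontology is a directed acyclic graph of chemical entities: `IS_A`
#' edges run child to parent and define the hierarchy, while
#' `CONJUGATE_BASE_OF`, `CONJUGATE_ACID_OF` and `TAUTOMER_OF` edges link
#' functional variants of the same compound and are traversed in both
#' directions. The `IS_A` subgraph is verified acyclic at construction.
#'
#' @param nodes data.frame with columns `id`, `name` and optionally
#'   `is_obsolete` (logical).
#' @param edges data.frame with columns `source`, `kind`, `target`; rows with
#'   unrecognized kinds are dropped with a warning.
#' @param synonyms optional named list mapping id to a character vector of
#'   synonyms.
#' @param alt_ids optional named character vector remapping secondary ids to
#'   primary ids (applied when ids are looked up).
#' @return an object of class `onto_graph`.
#' @export
onto_graph <- function(nodes, edges, synonyms = NULL, alt_ids = NULL) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(nodes) == 0) {
    nodes <- data.frame(id = character(), name = character(),
                        is_obsolete = logical(), stringsAsFactors = FALSE)
  }
  if (is.null(nodes$is_obsolete)) nodes$is_obsolete <- rep(FALSE, nrow(nodes))
  nodes$is_obsolete[is.na(nodes$is_obsolete)] <- FALSE
  if (anyDuplicated(nodes$id)) {
    stop("duplicate node ids: ", paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "))
  }
  if (nrow(edges) == 0) {
    edges <- data.frame(source = character(), kind = character(),
                        target = character(), stringsAsFactors = FALSE)
  }
  unknown <- !(edges$kind %in% EDGE_KINDS)
  n_dropped <- sum(unknown)
  if (n_dropped > 0) {
    warning(sprintf("dropped %d edge(s) of unknown kind: %s", n_dropped,
                    paste(unique(edges$kind[unknown]), collapse = ", ")))
    edges <- edges[!unknown, , drop = FALSE]
  }
  missing_ep <- setdiff(c(edges$source, edges$target), nodes$id)
  if (length(missing_ep) > 0) {
    stop("edge endpoint(s) absent from node table: ",
         paste(utils::head(missing_ep, 5), collapse = ", "))
  }

  is_a <- edges[edges$kind == "IS_A", , drop = FALSE]
  cyc <- .find_isa_cycle_member(nodes$id, is_a)
  if (!is.na(cyc)) stop("IS_A subgraph is cyclic (cycle through ", cyc, ")")

  parents <- split(is_a$target, factor(is_a$source, levels = nodes$id))
  children <- split(is_a$source, factor(is_a$target, levels = nodes$id))
  fun <- edges[edges$kind %in% FUNCTIONAL_KINDS, , drop = FALSE]
  # functional edges are symmetric for traversal: index both directions
  fun_both <- rbind(
    data.frame(from = fun$source, to = fun$target, kind = fun$kind, stringsAsFactors = FALSE),
    data.frame(from = fun$target, to = fun$source, kind = fun$kind, stringsAsFactors = FALSE))
  fun_both <- unique(fun_both)
  functional <- split(fun_both[, c("to", "kind")], factor(fun_both$from, levels = nodes$id))

  syn <- stats::setNames(vector("list", nrow(nodes)), nodes$id)
  if (!is.null(synonyms)) syn[names(synonyms)] <- synonyms

  structure(list(
    nodes = nodes, edges = edges, synonyms = syn,
    parents = lapply(parents, unique), children = lapply(children, unique),
    functional = functional,
    alt_ids = if (is.null(alt_ids)) character() else alt_ids,
    n_dropped_edges = n_dropped
  ), class = "onto_graph")
}

# Kahn's algorithm on the IS_A subgraph; returns NA if acyclic, else the id
# of one node on a cycle.
.find_isa_cycle_member <- function(ids, is_a) {
  if (nrow(is_a) == 0 || length(ids) == 0) return(NA_character_)
  outdeg <- table(factor(is_a$source, levels = ids))
  incoming <- split(is_a$source, factor(is_a$target, levels = ids))
  queue <- ids[outdeg == 0]
  removed <- 0L
  deg <- as.integer(outdeg)
  names(deg) <- ids
  while (length(queue) > 0) {
    v <- queue[[1]]; queue <- queue[-1]; removed <- removed + 1L
    for (u in incoming[[v]]) {
      deg[[u]] <- deg[[u]] - 1L
      if (deg[[u]] == 0L) queue <- c(queue, u)
    }
  }
  if (removed < length(ids)) names(deg)[deg > 0][1] else NA_character_
}

#' @export
print.onto_graph <- function(x, ...) {
  kinds <- table(factor(x$edges$kind, levels = EDGE_KINDS))
  cat(sprintf("Chemical-entity ontology graph: %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  cat(sprintf("  IS_A: %d  conjugate acid/base: %d  tautomer: %d  obsolete nodes: %d\n",
              kinds[["IS_A"]],
              kinds[["CONJUGATE_BASE_OF"]] + kinds[["CONJUGATE_ACID_OF"]],
              kinds[["TAUTOMER_OF"]], sum(x$nodes$is_obsolete)))
  invisible(x)
}

#' Load an ontology from OBO or TSV
#'
#' Two formats are supported. `"obo"` reads OBO 1.2/1.4 flat files
#' (`[Term]` stanzas with `is_a`, `relationship:
#' is_conjugate_base_of/is_conjugate_acid_of/is_tautomer_of`, `synonym`,
#' `alt_id` and `is_obsolete` lines). `"tsv"` reads the plain fixture
#' dialect: a directory containing `nodes.tsv` (columns `id`, `name`,
#' `synonyms` pipe-separated) and `edges.tsv` (columns `source`, `kind`,
#' `target`), both UTF-8 with a header row.
#'
#' @param path file path (OBO) or directory path (TSV dialect).
#' @param format `"obo"` or `"tsv"`.
#' @return an [onto_graph].
#' @export
load_ontology <- function(path, format = c("obo", "tsv")) {
  format <- match.arg(format)
  if (format == "obo") {
    if (!file.exists(path)) stop("cannot read ontology file: ", path)
    .parse_obo(path)
  } else {
    nf <- file.path(path, "nodes.tsv")
    ef <- file.path(path, "edges.tsv")
    if (!file.exists(nf) || !file.exists(ef)) {
      stop("TSV ontology requires nodes.tsv and edges.tsv under ", path)
    }
    nodes <- utils::read.delim(nf, stringsAsFactors = FALSE, colClasses = "character")
    edges <- utils::read.delim(ef, stringsAsFactors = FALSE, colClasses = "character")
    syn <- NULL
    if (!is.null(nodes$synonyms)) {
      syn <- lapply(strsplit(nodes$synonyms, "|", fixed = TRUE),
                    function(s) s[nzchar(s)])
      names(syn) <- nodes$id
      nodes$synonyms <- NULL
    }
    obs <- if (is.null(nodes$is_obsolete)) FALSE else tolower(nodes$is_obsolete) %in% c("true", "1")
    onto_graph(data.frame(id = nodes$id, name = nodes$name, is_obsolete = obs,
                          stringsAsFactors = FALSE),
               edges, synonyms = syn)
  }
}

.OBO_REL_MAP <- c(is_conjugate_base_of = "CONJUGATE_BASE_OF",
                  is_conjugate_acid_of = "CONJUGATE_ACID_OF",
                  is_tautomer_of = "TAUTOMER_OF")

.parse_obo <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  term_starts <- which(lines == "[Term]")
  stanza_starts <- grep("^\\[", lines)
  ids <- character(); nms <- character(); obs <- logical()
  syn <- list(); alt <- character()
  es <- character(); ek <- character(); et <- character()
  for (s in term_starts) {
    nxt <- stanza_starts[stanza_starts > s]
    end <- if (length(nxt)) nxt[1] - 1L else length(lines)
    block <- lines[(s + 1L):end]
    getv <- function(key) {
      v <- block[startsWith(block, paste0(key, ":"))]
      trimws(sub(paste0("^", key, ":"), "", v))
    }
    id <- getv("id")[1]
    if (is.na(id)) next
    ids <- c(ids, id)
    nm <- getv("name")[1]
    nms <- c(nms, if (is.na(nm)) "" else nm)
    obs <- c(obs, any(grepl("^is_obsolete:\\s*true", block)))
    sv <- getv("synonym")
    syn[[id]] <- sub('^"(.*)".*$', "\\1", sv)
    for (a in getv("alt_id")) alt[a] <- id
    for (p in getv("is_a")) {
      p <- trimws(sub("!.*$", "", p))
      es <- c(es, id); ek <- c(ek, "IS_A"); et <- c(et, p)
    }
    for (r in getv("relationship")) {
      r <- trimws(sub("!.*$", "", r))
      parts <- strsplit(r, "\\s+")[[1]]
      if (length(parts) >= 2 && parts[1] %in% names(.OBO_REL_MAP)) {
        es <- c(es, id); ek <- c(ek, .OBO_REL_MAP[[parts[1]]]); et <- c(et, parts[2])
      }
    }
  }
  edges <- data.frame(source = es, kind = ek, target = et, stringsAsFactors = FALSE)
  # tolerate dangling references to terms outside the file
  known <- c(edges$source, edges$target) %in% ids
  keep <- edges$source %in% ids & edges$target %in% ids
  onto_graph(data.frame(id = ids, name = nms, is_obsolete = obs, stringsAsFactors = FALSE),
             edges[keep, , drop = FALSE], synonyms = syn, alt_ids = alt)
}

# Resolve an id through the secondary-id remap table; error if absent.
resolve_id <- function(graph, id, arg = "id") {
  if (length(id) != 1 || is.na(id)) stop("invalid ", arg, ": ", id)
  if (id %in% names(graph$alt_ids)) id <- graph$alt_ids[[id]]
  if (!(id %in% graph$nodes$id)) {
    stop("unknown ontology id: ", id, call. = FALSE)
  }
  id
}

.bfs_isa <- function(graph, id, max_steps, direction = c("up", "down")) {
  direction <- match.arg(direction)
  adj <- if (direction == "up") graph$parents else graph$children
  out_id <- character(); out_depth <- integer()
  if (max_steps < 1) {
    return(data.frame(id = out_id, depth = out_depth, stringsAsFactors = FALSE))
  }
  visited <- id
  frontier <- id
  depth <- 0L
  while (length(frontier) > 0 && depth < max_steps) {
    depth <- depth + 1L
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, visited)
    if (length(nxt) == 0) break
    visited <- c(visited, nxt)
    out_id <- c(out_id, nxt); out_depth <- c(out_depth, rep(depth, length(nxt)))
    frontier <- nxt
  }
  data.frame(id = out_id, depth = out_depth, stringsAsFactors = FALSE)
}

#' Ancestors of an ontology node
#'
#' Nodes reachable by following 1..`max_up` `IS_A` edges child to parent
#' (i.e. toward more generic classes); `depth` is the minimal edge count.
#'
#' @param graph an [onto_graph].
#' @param id node identifier (secondary ids are remapped).
#' @param max_up maximum number of upward steps (`Inf` for the full closure).
#' @return data.frame with columns `id`, `depth`.
#' @export
ancestors <- function(graph, id, max_up = Inf) {
  stopifnot(max_up >= 0)
  .bfs_isa(graph, resolve_id(graph, id), max_up, "up")
}

#' Descendants of an ontology node
#'
#' Mirror of [ancestors()]: follows `IS_A` edges parent to child, toward
#' more specific species.
#'
#' @inheritParams ancestors
#' @param max_down maximum number of downward steps.
#' @return data.frame with columns `id`, `depth`.
#' @export
descendants <- function(graph, id, max_down = Inf) {
  stopifnot(max_down >= 0)
  .bfs_isa(graph, resolve_id(graph, id), max_down, "down")
}

#' Functional neighbors of an ontology node
#'
#' All nodes connected to `id` by one conjugate-acid/base or tautomer edge,
#' in either direction, each tagged with the edge kind.
#'
#' @inheritParams ancestors
#' @return data.frame with columns `id`, `kind`.
#' @export
functional_neighbors <- function(graph, id) {
  id <- resolve_id(graph, id)
  fn <- graph$functional[[id]]
  if (is.null(fn) || nrow(fn) == 0) {
    return(data.frame(id = character(), kind = character(), stringsAsFactors = FALSE))
  }
  data.frame(id = fn$to, kind = fn$kind, stringsAsFactors = FALSE)
}

# TRUE if character vector a is lexicographically smaller than b, comparing
# element-wise, shorter prefix wins.
.seq_less <- function(a, b) {
  n <- min(length(a), length(b))
  for (i in seq_len(n)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}

.match_path <- function(query, target, h_signed, ab, taut, seq, penalties) {
  mag <- abs(h_signed) + penalties[["acid_base"]] * ab + penalties[["tautomer"]] * taut
  structure(list(
    query = query, target = target,
    hierarchical_steps = as.integer(h_signed),
    acid_base_steps = as.integer(ab), tautomer_steps = as.integer(taut),
    node_sequence = seq,
    distance = if (h_signed < 0) -mag else mag
  ), class = "match_path")
}

#' @export
print.match_path <- function(x, ...) {
  cat(sprintf("%s -> %s  distance %+g  [%s]\n", x$query, x$target, x$distance,
              paste(x$node_sequence, collapse = " > ")))
  invisible(x)
}

#' Signed ontology paths from a query to a set of targets
#'
#' Searches grammar-legal paths from `query` to each target: an optional
#' functional step (conjugate acid/base or tautomer) at either endpoint,
#' around a monotone `IS_A` chain running entirely upward (toward generic
#' classes) or entirely downward (toward specific species). For each
#' reachable target the path of minimal absolute distance is returned, with
#'
#' \deqn{d = sign \times (|h| + 0.1\,a + 0.01\,t)}
#'
#' where `h` is the hierarchical step count (negative when descending),
#' `a` the number of acid/base steps and `t` the number of tautomer steps.
#' Purely functional paths (no hierarchical step) have positive distance.
#' Ties for one target are broken by the lexicographically smallest node
#' sequence. Obsolete nodes are never traversed or returned.
#'
#' @param graph an [onto_graph].
#' @param query query node id (must exist in the graph).
#' @param targets character vector of target ids; ids absent from the graph
#'   are skipped and reported in the `"skipped_targets"` attribute.
#' @param max_up,max_down bounds on hierarchical steps in each direction.
#' @param penalties named numeric vector with elements `acid_base` and
#'   `tautomer`; the per-edge distance increments.
#' @return list of `match_path` objects, sorted by |distance| then target
#'   id, with attribute `skipped_targets`.
#' @export
ontology_paths <- function(graph, query, targets, max_up = 20, max_down = 20,
                           penalties = c(acid_base = 0.1, tautomer = 0.01)) {
  if (max_up < 0 || max_down < 0) stop("max_up and max_down must be >= 0")
  query <- resolve_id(graph, query, "query")
  targets <- unique(targets)
  targets <- vapply(targets, function(t) {
    if (t %in% names(graph$alt_ids)) graph$alt_ids[[t]] else t
  }, character(1), USE.NAMES = FALSE)
  obsolete <- graph$nodes$id[graph$nodes$is_obsolete]
  known <- setdiff(intersect(targets, graph$nodes$id), obsolete)
  skipped <- setdiff(targets, known)

  best <- list() # target -> match_path
  consider <- function(target, h_signed, ab, taut, seq) {
    if (!(target %in% known)) return(invisible())
    cand <- .match_path(query, target, h_signed, ab, taut, seq, penalties)
    cur <- best[[target]]
    if (is.null(cur) || abs(cand$distance) < abs(cur$distance) ||
        (abs(cand$distance) == abs(cur$distance) &&
         .seq_less(cand$node_sequence, cur$node_sequence))) {
      best[[target]] <<- cand
    }
    invisible()
  }

  is_ok <- function(ids) ids[!(ids %in% obsolete)]
  fstep <- function(kind) if (kind == "TAUTOMER_OF") c(0L, 1L) else c(1L, 0L)

  starts <- list(list(node = query, ab = 0L, taut = 0L, seq = query))
  fq <- functional_neighbors(graph, query)
  for (i in seq_len(nrow(fq))) {
    if (fq$id[i] %in% obsolete) next
    st <- fstep(fq$kind[i])
    starts[[length(starts) + 1L]] <- list(node = fq$id[i], ab = st[1], taut = st[2],
                                          seq = c(query, fq$id[i]))
  }

  for (st in starts) {
    # endpoint candidates at hierarchical depth 0 (query itself, or after a
    # leading functional step), plus a trailing functional step
    consider(st$node, 0L, st$ab, st$taut, st$seq)
    fe <- functional_neighbors(graph, st$node)
    for (j in seq_len(nrow(fe))) {
      if (fe$id[j] %in% st$seq || fe$id[j] %in% obsolete) next
      en <- fstep(fe$kind[j])
      consider(fe$id[j], 0L, st$ab + en[1], st$taut + en[2], c(st$seq, fe$id[j]))
    }
    for (dir in c("up", "down")) {
      bound <- if (dir == "up") max_up else max_down
      if (bound < 1) next
      adj <- if (dir == "up") graph$parents else graph$children
      # layered BFS keeping, per node, the lexicographically smallest
      # sequence among minimal-depth paths
      frontier <- stats::setNames(list(st$seq), st$node)
      seen <- st$node
      depth <- 0L
      while (length(frontier) > 0 && depth < bound) {
        depth <- depth + 1L
        nxt <- list()
        for (node in names(frontier)) {
          for (p in is_ok(adj[[node]])) {
            if (p %in% seen) next
            cand_seq <- c(frontier[[node]], p)
            if (is.null(nxt[[p]]) || .seq_less(cand_seq, nxt[[p]])) nxt[[p]] <- cand_seq
          }
        }
        if (length(nxt) == 0) break
        seen <- c(seen, names(nxt))
        h <- if (dir == "down") -depth else depth
        for (node in names(nxt)) {
          sq <- nxt[[node]]
          consider(node, h, st$ab, st$taut, sq)
          fe <- functional_neighbors(graph, node)
          for (j in seq_len(nrow(fe))) {
            if (fe$id[j] %in% sq || fe$id[j] %in% obsolete) next
            en <- fstep(fe$kind[j])
            consider(fe$id[j], h, st$ab + en[1], st$taut + en[2], c(sq, fe$id[j]))
          }
        }
        frontier <- nxt
      }
    }
  }

  res <- if (length(best) == 0) list() else {
    unname(best[order(vapply(best, function(p) abs(p$distance), numeric(1)),
                      names(best))])
  }
  attr(res, "skipped_targets") <- skipped
  res
}
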