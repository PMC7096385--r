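#' Brute-force enumeration of grammar-legal ontology paths
#'
#' Independent reference implementation used to validate the production
#' matcher and to compute ground truth for planted fixtures. It performs an
#' exhaustive depth-first enumeration of simple paths over the raw edge
#' list, keeping only paths legal under the matching grammar — functional
#' (conjugate acid/base, tautomer) steps only adjacent to an endpoint, at
#' most one per endpoint, and all hierarchical steps in one direction — and
#' records, for every reachable node, the minimal-|distance| path. Intended
#' for small graphs (tens of nodes); complexity is exponential in the worst
#' case.
#'
#' @inheritParams ontology_paths
#' @return data.frame with one row per reachable node: `target`,
#'   `distance`, `hierarchical_steps`, `acid_base_steps`, `tautomer_steps`,
#'   `path` (node ids joined by `" > "`).
#' @export
enumerate_ontology_paths <- function(graph, query, max_up = 20, max_down = 20,
                                     penalties = c(acid_base = 0.1, tautomer = 0.01)) {
  query <- resolve_id(graph, query, "query")
  obsolete <- graph$nodes$id[graph$nodes$is_obsolete]
  best <- new.env(parent = emptyenv())

  note <- function(node, h, ab, taut, seq) {
    mag <- abs(h) + penalties[["acid_base"]] * ab + penalties[["tautomer"]] * taut
    d <- if (h < 0) -mag else mag
    cur <- get0(node, envir = best)
    if (is.null(cur) || mag < cur$mag ||
        (mag == cur$mag && .seq_less(seq, cur$seq))) {
      assign(node, list(mag = mag, d = d, h = h, ab = ab, taut = taut, seq = seq),
             envir = best)
    }
  }

  # phase: 0 = at query, 1 = after leading functional step, 2 = inside the
  # hierarchical chain, 3 = after trailing functional step (path must end)
  walk <- function(node, seq, phase, dir, nup, ndown, ab, taut) {
    note(node, if (dir == "down") -ndown else nup, ab, taut, seq)
    if (phase == 3) return(invisible())
    if (phase %in% c(0, 1) || phase == 2) {
      dirs <- if (phase == 2) dir else c("up", "down")
      for (dd in dirs) {
        adj <- if (dd == "up") graph$parents[[node]] else graph$children[[node]]
        bound_ok <- if (dd == "up") nup < max_up else ndown < max_down
        if (!bound_ok) next
        for (nb in adj) {
          if (nb %in% seq || nb %in% obsolete) next
          walk(nb, c(seq, nb), 2, dd,
               nup + (dd == "up"), ndown + (dd == "down"), ab, taut)
        }
      }
    }
    fn <- graph$functional[[node]]
    if (!is.null(fn)) {
      for (j in seq_len(nrow(fn))) {
        nb <- fn$to[j]
        if (nb %in% seq || nb %in% obsolete) next
        tt <- fn$kind[j] == "TAUTOMER_OF"
        walk(nb, c(seq, nb), if (phase == 0) 1 else 3, dir,
             nup, ndown, ab + !tt, taut + tt)
      }
    }
    invisible()
  }

  walk(query, query, 0, "none", 0L, 0L, 0L, 0L)

  hits <- ls(best)
  hits <- setdiff(hits, character(0))
  rows <- lapply(hits, function(n) {
    b <- best[[n]]
    data.frame(target = n, distance = b$d, hierarchical_steps = b$h,
               acid_base_steps = b$ab, tautomer_steps = b$taut,
               path = paste(b$seq, collapse = " > "), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(target = character(), distance = numeric(),
                      hierarchical_steps = integer(), acid_base_steps = integer(),
                      tautomer_steps = integer(), path = character(),
                      stringsAsFactors = FALSE)
  }
  out[order(abs(out$distance), out$target), , drop = FALSE]
}
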