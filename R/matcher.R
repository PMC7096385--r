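#' Normalize a compound name for exact matching
#'
#' Lower-cases, strips surrounding whitespace, collapses internal runs of
#' whitespace to single spaces and unifies Unicode dash variants (hyphen,
#' en/em dash, minus sign) to ASCII `"-"`. Idempotent.
#'
#' @param raw character vector of names.
#' @return normalized character vector.
#' @export
#' @examples
#' normalize_name("  14,15-DiHETE ")
normalize_name <- function(raw) {
  x <- tolower(enc2utf8(as.character(raw)))
  x <- gsub("[\u2010\u2011\u2012\u2013\u2014\u2015\u2212]", "-", x)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

#' Read a dataset of lipids/metabolites to map
#'
#' Accepts TSV (columns `id`, `name`, `chebi`, extra columns carried
#' through) or JSON (array of objects with the same keys). ChEBI ids are
#' canonicalized; an `id` column is synthesized from row numbers when
#' absent.
#'
#' @param path input file.
#' @param format `"tsv"`, `"json"`, or `"auto"` (by extension).
#' @return data.frame with columns `entry_id`, `name`, `chebi_id`, plus any
#'   extra columns.
#' @export
read_dataset <- function(path, format = c("auto", "tsv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) == "json") "json" else "tsv"
  }
  df <- if (format == "json") {
    as.data.frame(jsonlite::fromJSON(path), stringsAsFactors = FALSE)
  } else {
    utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  }
  as_dataset(df)
}

#' Coerce a data.frame to the dataset-entry contract
#'
#' @param df data.frame with columns `id` (or `entry_id`), `name`, and
#'   optionally `chebi` (or `chebi_id`).
#' @return data.frame with `entry_id`, `name`, `chebi_id` first.
#' @export
as_dataset <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  nm <- names(df)
  id_col <- intersect(c("entry_id", "id"), nm)[1]
  chebi_col <- intersect(c("chebi_id", "chebi"), nm)[1]
  entry_id <- if (!is.na(id_col)) as.character(df[[id_col]]) else
    sprintf("entry_%d", seq_len(nrow(df)))
  if (anyDuplicated(entry_id)) stop("duplicate dataset entry ids")
  if (is.null(df$name)) stop("dataset requires a 'name' column")
  chebi_raw <- if (!is.na(chebi_col)) as.character(df[[chebi_col]]) else
    rep(NA_character_, nrow(df))
  extra <- df[, setdiff(nm, c(id_col, chebi_col, "name")), drop = FALSE]
  out <- data.frame(entry_id = entry_id, name = as.character(df$name),
                    chebi_raw = chebi_raw,
                    chebi_id = canonical_chebi(chebi_raw),
                    stringsAsFactors = FALSE)
  cbind(out, extra)
}

.empty_results <- function() {
  data.frame(entry_id = character(), name = character(), chebi_id = character(),
             base_id = character(), network_name = character(),
             match_type = character(), distance = numeric(), path = character(),
             is_closest = logical(), stringsAsFactors = FALSE)
}

.result_rows <- function(entries, compounds, type, distance = 0,
                         path = NA_character_, is_closest = TRUE) {
  data.frame(entry_id = entries$entry_id, name = entries$name,
             chebi_id = entries$chebi_id, base_id = compounds$base_id,
             network_name = compounds$name, match_type = type,
             distance = distance, path = path, is_closest = is_closest,
             stringsAsFactors = FALSE)
}

#' Exact matching on normalized names
#'
#' A dataset entry matches a unique network compound when their normalized
#' names (or any network-declared synonym) coincide.
#'
#' @param dataset dataset data.frame (see [as_dataset()]).
#' @param network a `metabolic_network`.
#' @param synonyms optional named list: `base_id` -> character vector of
#'   synonyms (SBML carries few; degrades to primary-name comparison).
#' @return data.frame of match rows, distance 0, type `NAME_EXACT`.
#' @export
exact_name_match <- function(dataset, network, synonyms = NULL) {
  uc <- unique_compounds(network)
  if (nrow(dataset) == 0 || nrow(uc) == 0) return(.empty_results())
  keys <- lapply(seq_len(nrow(uc)), function(i) {
    unique(normalize_name(c(uc$name[i], synonyms[[uc$base_id[i]]])))
  })
  lut <- data.frame(key = unlist(keys),
                    row = rep(seq_len(nrow(uc)), lengths(keys)),
                    stringsAsFactors = FALSE)
  qk <- normalize_name(dataset$name)
  hit <- match(qk, lut$key)
  sel <- which(!is.na(hit))
  if (length(sel) == 0) return(.empty_results())
  .result_rows(dataset[sel, , drop = FALSE], uc[lut$row[hit[sel]], , drop = FALSE],
               "NAME_EXACT")
}

#' Exact matching on ChEBI identifiers
#'
#' A dataset entry matches every unique compound annotated with the same
#' canonical ChEBI id. Entries without a ChEBI id are skipped (tallied by
#' the pipeline); syntactically malformed ids raise a per-entry warning.
#'
#' @inheritParams exact_name_match
#' @return data.frame of match rows, distance 0, type `CHEBI_EXACT`.
#' @export
exact_chebi_match <- function(dataset, network) {
  uc <- unique_compounds(network)
  if (nrow(dataset) == 0 || nrow(uc) == 0) return(.empty_results())
  malformed <- !is.na(dataset$chebi_raw) & nzchar(trimws(dataset$chebi_raw)) &
    is.na(dataset$chebi_id)
  for (i in which(malformed)) {
    warning("entry ", dataset$entry_id[i], ": malformed ChEBI id '",
            dataset$chebi_raw[i], "', skipped")
  }
  rows <- .empty_results()
  for (i in which(!is.na(dataset$chebi_id))) {
    tgt <- which(uc$chebi_id == dataset$chebi_id[i])
    if (length(tgt) > 0) {
      rows <- rbind(rows, .result_rows(dataset[rep(i, length(tgt)), , drop = FALSE],
                                       uc[tgt, , drop = FALSE], "CHEBI_EXACT"))
    }
  }
  rows
}

#' Ontology-based matching
#'
#' For every dataset entry carrying a ChEBI id (by default, only entries
#' not already matched exactly), searches the ontology for network
#' compounds reachable under the path grammar of [ontology_paths()] and
#' reports each with its signed distance. All targets at the minimal
#' |distance| are flagged `is_closest`; when both signs occur at the
#' minimal |distance| the negative (more specific) targets take the flag.
#'
#' @inheritParams exact_name_match
#' @param graph an [onto_graph].
#' @param exclude_entries entry ids to skip (typically the exactly matched).
#' @param max_up,max_down,penalties forwarded to [ontology_paths()].
#' @return data.frame of match rows with type `ONTOLOGY`, plus attribute
#'   `"unknown_in_ontology"` listing entry ids whose ChEBI id is absent
#'   from the graph.
#' @export
ontology_match <- function(dataset, network, graph, exclude_entries = character(),
                           max_up = 20, max_down = 20,
                           penalties = c(acid_base = 0.1, tautomer = 0.01)) {
  uc <- unique_compounds(network)
  targets <- uc[!is.na(uc$chebi_id), , drop = FALSE]
  rows <- .empty_results()
  unknown <- character()
  todo <- which(!is.na(dataset$chebi_id) & !(dataset$entry_id %in% exclude_entries))
  for (i in todo) {
    q <- dataset$chebi_id[i]
    if (!(q %in% graph$nodes$id) && !(q %in% names(graph$alt_ids))) {
      unknown <- c(unknown, dataset$entry_id[i])
      next
    }
    paths <- ontology_paths(graph, q, unique(targets$chebi_id),
                            max_up = max_up, max_down = max_down,
                            penalties = penalties)
    if (length(paths) == 0) next
    dists <- vapply(paths, `[[`, numeric(1), "distance")
    min_mag <- min(abs(dists))
    closest <- abs(dists) == min_mag
    if (any(closest & dists < 0)) closest <- closest & dists < 0
    for (j in seq_along(paths)) {
      hit <- which(targets$chebi_id == paths[[j]]$target)
      rows <- rbind(rows, .result_rows(
        dataset[rep(i, length(hit)), , drop = FALSE],
        targets[hit, , drop = FALSE], "ONTOLOGY",
        distance = dists[j],
        path = paste(paths[[j]]$node_sequence, collapse = " > "),
        is_closest = closest[j]))
    }
  }
  attr(rows, "unknown_in_ontology") <- unknown
  rows
}

#' Run the full matching pipeline
#'
#' Exact-name pass, then exact-ChEBI pass, then ontology pass for entries
#' with a ChEBI id and no exact match. Returns all match rows together with
#' a summary: counts per match type, unmatched entries, and entries without
#' a ChEBI id (which never enter ontology matching).
#'
#' @inheritParams ontology_match
#' @param rematch_exact if `TRUE`, exactly matched entries are also sent
#'   through the ontology pass (default `FALSE`).
#' @return object of class `match_report`: list with `results` (data.frame)
#'   and `summary` (list).
#' @export
match_dataset <- function(dataset, network, graph, synonyms = NULL,
                          max_up = 20, max_down = 20,
                          penalties = c(acid_base = 0.1, tautomer = 0.01),
                          rematch_exact = FALSE) {
  dataset <- as_dataset(dataset)
  r_name <- exact_name_match(dataset, network, synonyms)
  r_chebi <- exact_chebi_match(dataset, network)
  exact_ids <- unique(c(r_name$entry_id, r_chebi$entry_id))
  r_onto <- ontology_match(dataset, network, graph,
                           exclude_entries = if (rematch_exact) character() else exact_ids,
                           max_up = max_up, max_down = max_down,
                           penalties = penalties)
  results <- rbind(r_name, r_chebi, as.data.frame(r_onto))
  results <- results[order(match(results$entry_id, dataset$entry_id),
                           match(results$match_type,
                                 c("NAME_EXACT", "CHEBI_EXACT", "ONTOLOGY")),
                           abs(results$distance), results$base_id), , drop = FALSE]
  rownames(results) <- NULL

  matched_ids <- unique(results$entry_id)
  no_chebi <- dataset$entry_id[is.na(dataset$chebi_id)]
  no_chebi <- setdiff(no_chebi, matched_ids)
  unmatched <- setdiff(dataset$entry_id, c(matched_ids, no_chebi))
  summary <- list(
    n_entries = nrow(dataset),
    name_exact = length(unique(r_name$entry_id)),
    chebi_exact = length(unique(r_chebi$entry_id)),
    ontology = length(unique(r_onto$entry_id)),
    matched = length(matched_ids),
    unmatched = length(unmatched),
    no_chebi = length(no_chebi),
    unknown_in_ontology = attr(r_onto, "unknown_in_ontology") %||% character())
  structure(list(results = results, summary = summary,
                 unmatched_ids = unmatched, no_chebi_ids = no_chebi),
            class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  s <- x$summary
  cat("Matching report\n")
  cat(sprintf("  entries: %d  matched: %d (name %d, ChEBI %d, ontology %d)\n",
              s$n_entries, s$matched, s$name_exact, s$chebi_exact, s$ontology))
  cat(sprintf("  unmatched: %d  without ChEBI id: %d\n", s$unmatched, s$no_chebi))
  if (length(s$unknown_in_ontology)) {
    cat("  ChEBI ids absent from ontology:",
        paste(s$unknown_in_ontology, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a match report to TSV or JSON
#'
#' The TSV carries one row per match with the summary as leading `#`
#' comment lines; JSON nests `summary` and `results`. Both round-trip
#' through [read_report()].
#'
#' @param report a `match_report`.
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  s <- report$summary
  if (format == "json") {
    jsonlite::write_json(list(summary = s, results = report$results), path,
                         auto_unbox = TRUE, digits = NA, na = "null")
    return(invisible(path))
  }
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  hdr <- sprintf("# %s: %s",
                 c("n_entries", "name_exact", "chebi_exact", "ontology",
                   "matched", "unmatched", "no_chebi"),
                 c(s$n_entries, s$name_exact, s$chebi_exact, s$ontology,
                   s$matched, s$unmatched, s$no_chebi))
  writeLines(hdr, con)
  utils::write.table(report$results, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read back a TSV or JSON match report
#'
#' @param path report path written by [write_report()].
#' @param format `"tsv"`, `"json"`, or `"auto"`.
#' @return list with `results` (data.frame) and `summary` (list).
#' @export
read_report <- function(path, format = c("auto", "tsv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) == "json") "json" else "tsv"
  }
  if (format == "json") {
    obj <- jsonlite::fromJSON(path)
    res <- as.data.frame(obj$results, stringsAsFactors = FALSE)
    if (nrow(res) == 0) res <- .empty_results()
    return(list(results = res, summary = as.list(obj$summary)))
  }
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- grep("^#", lines, value = TRUE)
  kv <- strsplit(sub("^#\\s*", "", hdr), ":\\s*")
  summary <- stats::setNames(lapply(kv, function(p) as.numeric(p[2])),
                             vapply(kv, `[[`, character(1), 1))
  body <- lines[!grepl("^#", lines)]
  res <- utils::read.delim(text = paste(body, collapse = "\n"),
                           stringsAsFactors = FALSE)
  if (nrow(res) > 0) {
    res$distance <- as.numeric(res$distance)
    res$is_closest <- as.logical(res$is_closest)
    res$path[res$path %in% c("", "NA")] <- NA_character_
    for (col in c("entry_id", "name", "chebi_id", "base_id", "network_name",
                  "match_type", "path")) res[[col]] <- as.character(res[[col]])
  } else {
    res <- .empty_results()
  }
  list(results = res, summary = summary)
}
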