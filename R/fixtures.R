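#' Construct a metabolic network in memory
#'
#' Programmatic constructor used by fixture generators and tests; the same
#' container [read_sbml()] produces.
#'
#' @param metabolites data.frame with `species_id`, `name`, `compartment`,
#'   `chebi_id` (`NA` allowed). `base_id` is derived from the compartment
#'   suffix convention unless supplied.
#' @param reactions list of lists with `reaction_id`, `substrates`,
#'   `products` (character vectors of species ids or data.frames with
#'   `species_id`, `stoichiometry`), optional `name`, `reversible`.
#' @return a `metabolic_network`.
#' @export
make_network <- function(metabolites, reactions = list()) {
  met <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  if (is.null(met$base_id)) {
    suf <- paste0("_", met$compartment)
    has <- !is.na(met$compartment) & endsWith(met$species_id, suf)
    met$base_id <- met$species_id
    met$base_id[has] <- substr(met$species_id[has], 1,
                               nchar(met$species_id[has]) - nchar(suf[has]))
  }
  if (is.null(met$chebi_id)) met$chebi_id <- NA_character_
  met$chebi_id <- canonical_chebi(met$chebi_id)
  met$n_chebi <- as.integer(!is.na(met$chebi_id))
  met <- met[, c("species_id", "base_id", "name", "compartment", "chebi_id",
                 "n_chebi")]
  side <- function(x) {
    if (is.data.frame(x)) return(x)
    data.frame(species_id = x, stoichiometry = rep(1, length(x)),
               stringsAsFactors = FALSE)
  }
  rx <- lapply(reactions, function(r) {
    list(reaction_id = r$reaction_id,
         name = r$name %||% r$reaction_id,
         reversible = r$reversible %||% TRUE,
         substrates = side(r$substrates), products = side(r$products),
         pathway = r$pathway %||% NA_character_)
  })
  names(rx) <- vapply(rx, `[[`, character(1), "reaction_id")
  chebi_all <- lapply(met$chebi_id, function(x) if (is.na(x)) character() else x)
  names(chebi_all) <- met$species_id
  structure(list(metabolites = met, chebi_all = chebi_all, reactions = rx,
                 provenance = list(path = "in-memory", level = NA, version = NA)),
            class = "metabolic_network")
}

#' The packaged worked-example fixture
#'
#' A small neighborhood of the ChEBI fatty-acid hierarchy around
#' octadec-9-enoic acid (CHEBI:36021), with its specific child oleic acid
#' (CHEBI:16196) and its conjugate base oleate (CHEBI:30823), a three-step
#' ancestor chain up to fatty acid (CHEBI:35366) with conjugate base
#' fatty acid anion (CHEBI:28868), and a hexadecanoate branch. The
#' companion mini-network annotates M_ocdcea with oleate and M_Rtotal with
#' fatty acid anion, so the dataset entry "C18:1 n-9" (CHEBI:36021)
#' matches M_ocdcea at distance -1.1 and M_Rtotal at +3.1.
#'
#' @return list with `ontology` ([onto_graph]), `network`
#'   (`metabolic_network`), `dataset` (one-row data.frame).
#' @export
fig2_fixture <- function() {
  nodes <- data.frame(
    id = c("CHEBI:36021", "CHEBI:16196", "CHEBI:30823", "CHEBI:25413",
           "CHEBI:27208", "CHEBI:35366", "CHEBI:28868", "CHEBI:15756",
           "CHEBI:7896"),
    name = c("octadec-9-enoic acid", "oleic acid", "oleate",
             "octadecenoic acid", "unsaturated fatty acid", "fatty acid",
             "fatty acid anion", "hexadecanoic acid", "hexadecanoate"),
    is_obsolete = FALSE, stringsAsFactors = FALSE)
  edges <- data.frame(
    source = c("CHEBI:16196", "CHEBI:36021", "CHEBI:25413", "CHEBI:27208",
               "CHEBI:15756", "CHEBI:30823", "CHEBI:28868", "CHEBI:7896"),
    kind = c("IS_A", "IS_A", "IS_A", "IS_A", "IS_A",
             "CONJUGATE_BASE_OF", "CONJUGATE_BASE_OF", "CONJUGATE_BASE_OF"),
    target = c("CHEBI:36021", "CHEBI:25413", "CHEBI:27208", "CHEBI:35366",
               "CHEBI:35366", "CHEBI:16196", "CHEBI:35366", "CHEBI:15756"),
    stringsAsFactors = FALSE)
  ontology <- onto_graph(nodes, edges,
                         synonyms = list("CHEBI:16196" = "octadec-9Z-enoic acid"))
  network <- make_network(
    data.frame(species_id = c("M_ocdcea_c", "M_Rtotal_c", "M_hdca_c"),
               name = c("Oleate", "Rtotal", "Hexadecanoate"),
               compartment = "c",
               chebi_id = c("CHEBI:30823", "CHEBI:28868", "CHEBI:7896"),
               stringsAsFactors = FALSE),
    list(list(reaction_id = "R_desat", substrates = "M_hdca_c",
              products = "M_ocdcea_c"),
         list(reaction_id = "R_pool", substrates = "M_ocdcea_c",
              products = "M_Rtotal_c")))
  dataset <- data.frame(id = "L1", name = "C18:1 n-9", chebi = "CHEBI:36021",
                        stringsAsFactors = FALSE)
  list(ontology = ontology, network = network, dataset = dataset)
}

#' Random ontology DAG generator
#'
#' Nodes are created in topological order; every node after the first gets
#' one `IS_A` parent among the earlier nodes (so the `IS_A` subgraph is a
#' connected DAG by construction) and a second parent with probability
#' `p_extra`. Functional edges (conjugate acid/base or tautomer) are added
#' between random node pairs with expected count `p_functional * n_nodes`.
#'
#' @param n_nodes number of nodes.
#' @param p_extra probability of a second IS_A parent.
#' @param p_functional expected functional edges per node.
#' @param seed integer seed; fixes all randomness.
#' @return an [onto_graph] with synthetic ids `CHEBI:900001...`.
#' @export
random_ontology <- function(n_nodes, p_extra = 0.2, p_functional = 0.15,
                            seed = 1) {
  stopifnot(n_nodes >= 1)
  set.seed(seed)
  ids <- sprintf("CHEBI:%d", 900000 + seq_len(n_nodes))
  nodes <- data.frame(id = ids, name = sprintf("compound %d", seq_len(n_nodes)),
                      is_obsolete = FALSE, stringsAsFactors = FALSE)
  src <- character(); knd <- character(); tgt <- character()
  for (i in seq_len(n_nodes)[-1]) {
    parents <- sample.int(i - 1, 1)
    if (stats::runif(1) < p_extra && i > 2) {
      parents <- unique(c(parents, sample.int(i - 1, 1)))
    }
    src <- c(src, rep(ids[i], length(parents)))
    knd <- c(knd, rep("IS_A", length(parents)))
    tgt <- c(tgt, ids[parents])
  }
  n_fun <- stats::rpois(1, p_functional * n_nodes)
  if (n_nodes >= 2 && n_fun > 0) {
    for (k in seq_len(n_fun)) {
      pair <- sample.int(n_nodes, 2)
      src <- c(src, ids[pair[1]])
      knd <- c(knd, sample(FUNCTIONAL_KINDS, 1))
      tgt <- c(tgt, ids[pair[2]])
    }
  }
  edges <- unique(data.frame(source = src, kind = knd, target = tgt,
                             stringsAsFactors = FALSE))
  onto_graph(nodes, edges)
}

#' Random planted matching fixture
#'
#' Generates a reproducible (ontology, network, dataset) triple whose
#' ground truth is computed at generation time by the independent
#' brute-force enumerator [enumerate_ontology_paths()], never by the
#' production matcher. The network annotates one unique compound per
#' chosen target node; the dataset holds one entry per chosen query node.
#'
#' @param n_nodes ontology size (`>= n_targets >= 1`).
#' @param n_targets number of network target compounds.
#' @param n_queries number of dataset entries.
#' @param max_planted_depth search bound used when computing truth.
#' @param p_functional expected functional edges per node (0 disables
#'   penalties, making all planted distances integers).
#' @param seed integer seed fixing all randomness.
#' @return list with `ontology`, `network`, `dataset`, and `truth` — a
#'   named list mapping entry id to a data.frame (`base_id`, `distance`).
#' @export
random_planted_triple <- function(n_nodes = 25, n_targets = 3, n_queries = 2,
                                  max_planted_depth = 20, p_functional = 0.15,
                                  seed = 1) {
  if (n_nodes < n_targets || n_targets < 1 || n_queries < 1) {
    stop("infeasible parameters: need n_nodes >= n_targets >= 1, n_queries >= 1")
  }
  ontology <- random_ontology(n_nodes, p_functional = p_functional, seed = seed)
  ids <- ontology$nodes$id
  target_ix <- sample.int(n_nodes, n_targets)
  query_ix <- sample.int(n_nodes, n_queries)
  base_ids <- sprintf("M_t%02d", seq_len(n_targets))
  network <- make_network(
    data.frame(species_id = paste0(base_ids, "_c"),
               name = sprintf("target %d", seq_len(n_targets)),
               compartment = "c", chebi_id = ids[target_ix],
               stringsAsFactors = FALSE))
  dataset <- data.frame(id = sprintf("Q%02d", seq_len(n_queries)),
                        name = sprintf("query compound %d", seq_len(n_queries)),
                        chebi = ids[query_ix], stringsAsFactors = FALSE)
  truth <- lapply(seq_len(n_queries), function(q) {
    oracle <- enumerate_ontology_paths(ontology, ids[query_ix[q]],
                                       max_up = max_planted_depth,
                                       max_down = max_planted_depth)
    hit <- oracle[oracle$target %in% ids[target_ix], , drop = FALSE]
    data.frame(base_id = base_ids[match(hit$target, ids[target_ix])],
               target = hit$target, distance = hit$distance,
               stringsAsFactors = FALSE)
  })
  names(truth) <- dataset$id
  list(ontology = ontology, network = network, dataset = dataset, truth = truth)
}

#' Random metabolic network generator
#'
#' Small random networks for graph-level tests: `n_rxns` reactions each
#' drawing 2--4 distinct random metabolites split into substrates and
#' products. With `n_compartments > 1`, each metabolite is duplicated
#' across compartments according to a recorded plan.
#'
#' @param n_mets number of distinct compounds.
#' @param n_rxns number of reactions.
#' @param n_compartments compartments to duplicate over (first compartment
#'   always present; others with probability 0.5).
#' @param seed integer seed.
#' @return a `metabolic_network` with attribute `"plan"` (data.frame
#'   `base_id`, `n_copies`).
#' @export
random_network <- function(n_mets = 8, n_rxns = 6, n_compartments = 1, seed = 1) {
  set.seed(seed)
  base <- sprintf("M_m%02d", seq_len(n_mets))
  comps <- letters[seq_len(n_compartments)]
  sp <- list()
  for (i in seq_len(n_mets)) {
    in_comp <- c(TRUE, stats::runif(n_compartments - 1) < 0.5)
    for (k in which(in_comp)) {
      sp[[length(sp) + 1]] <- data.frame(
        species_id = paste0(base[i], "_", comps[k]),
        name = sprintf("metabolite %d", i), compartment = comps[k],
        chebi_id = NA_character_, stringsAsFactors = FALSE)
    }
  }
  met <- do.call(rbind, sp)
  rx <- lapply(seq_len(n_rxns), function(r) {
    k <- sample(2:min(4, n_mets), 1)
    picks <- sample(met$species_id, k)
    n_sub <- sample.int(k - 1, 1)
    list(reaction_id = sprintf("R_r%02d", r),
         substrates = picks[seq_len(n_sub)], products = picks[-seq_len(n_sub)])
  })
  net <- make_network(met, rx)
  plan <- as.data.frame(table(net$metabolites$base_id), stringsAsFactors = FALSE)
  names(plan) <- c("base_id", "n_copies")
  attr(net, "plan") <- plan
  net
}

#' Serialize an ontology to the TSV dialect
#'
#' Writes `nodes.tsv` (`id`, `name`, `synonyms` pipe-separated,
#' `is_obsolete`) and `edges.tsv` (`source`, `kind`, `target`) under `dir`,
#' the format [load_ontology()] reads back.
#'
#' @param graph an [onto_graph].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_ontology_tsv <- function(graph, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  syn <- vapply(graph$nodes$id, function(id) {
    paste(graph$synonyms[[id]], collapse = "|")
  }, character(1))
  nodes <- data.frame(id = graph$nodes$id, name = graph$nodes$name,
                      synonyms = unname(syn),
                      is_obsolete = tolower(graph$nodes$is_obsolete),
                      stringsAsFactors = FALSE)
  utils::write.table(nodes, file.path(dir, "nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.table(graph$edges, file.path(dir, "edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(dir)
}

#' Serialize a dataset to TSV
#'
#' @param dataset data.frame with `id`/`entry_id`, `name`, `chebi` columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dataset_tsv <- function(dataset, path) {
  utils::write.table(dataset, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}
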