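toy_net <- function() {
  make_network(
    data.frame(species_id = paste0("M_", letters[1:3], "_c"),
               name = LETTERS[1:3], compartment = "c", chebi_id = NA),
    list(list(reaction_id = "R1", substrates = c("M_a_c", "M_b_c"),
              products = "M_c_c")))
}

test_that("the bipartite graph carries squared-degree weights", {
  g <- build_compound_graph(toy_net())
  expect_setequal(g$nodes, c("M_a", "M_b", "M_c", "R1"))
  expect_equal(unname(g$weight[["R1"]]), 9)
  expect_equal(unname(g$weight[["M_a"]]), 1)
})

test_that("removing a side compound lowers adjacent reaction degrees", {
  net <- make_network(
    data.frame(species_id = c("M_a_c", "M_h2o_c", "M_c_c"),
               name = c("A", "water", "C"), compartment = "c", chebi_id = NA),
    list(list(reaction_id = "R1", substrates = c("M_a_c", "M_h2o_c"),
              products = "M_c_c")))
  g <- build_compound_graph(net, side_compounds = "M_h2o")
  expect_false("M_h2o" %in% g$nodes)
  expect_equal(unname(g$weight[["R1"]]), 4)
  expect_warning(build_compound_graph(net, side_compounds = "M_ghost"),
                 "not in network")
})

test_that("degrees satisfy the handshake lemma on random networks", {
  for (seed in 1:6) {
    net <- random_network(n_mets = 9, n_rxns = 7, seed = seed)
    g <- build_compound_graph(net)
    expect_equal(sum(lengths(g$adj)), 2 * nrow(g$edges))
    expect_equal(unname(g$weight), unname(lengths(g$adj))^2)
  }
})

test_that("a node is its own lightest path", {
  g <- build_compound_graph(toy_net())
  lp <- lightest_path(g, "M_a", "M_a")
  expect_equal(lp$path, "M_a")
  expect_equal(lp$weight, g$weight[["M_a"]])
  expect_error(lightest_path(g, "M_a", "nope"), "unknown node")
})

test_that("the low-degree detour beats the hub route", {
  # hub reaction touches all five metabolites (degree 5); chain reactions
  # connect a to e in three low-degree hops
  net <- make_network(
    data.frame(species_id = paste0("M_", letters[1:5], "_c"),
               name = LETTERS[1:5], compartment = "c", chebi_id = NA),
    list(list(reaction_id = "R_hub", substrates = c("M_a_c", "M_b_c"),
              products = c("M_c_c", "M_d_c", "M_e_c")),
         list(reaction_id = "R1", substrates = "M_a_c", products = "M_c_c"),
         list(reaction_id = "R2", substrates = "M_c_c", products = "M_e_c")))
  g <- build_compound_graph(net)
  lp <- lightest_path(g, "M_a", "M_e")
  expect_false("R_hub" %in% lp$path)
  expect_equal(lp$weight, enum_lightest(g, "M_a", "M_e"))
})

test_that("lightest paths equal the exhaustive minimum on small random graphs", {
  for (seed in 1:12) {
    net <- random_network(n_mets = 3 + seed %% 4, n_rxns = 2 + seed %% 5,
                          seed = seed)
    g <- build_compound_graph(net)
    mets <- g$nodes[g$type == "metabolite"]
    for (a in mets) for (b in mets) {
      lp <- lightest_path(g, a, b)
      ref <- enum_lightest(g, a, b)
      if (is.finite(ref)) {
        expect_equal(lp$weight, ref)
        expect_equal(sum(g$weight[lp$path]), lp$weight)
      } else {
        expect_false(lp$connected)
      }
    }
  }
})

test_that("minimal weights agree with an independent igraph computation", {
  skip_if_not_installed("igraph")
  for (seed in 1:5) {
    net <- random_network(n_mets = 8, n_rxns = 8, seed = seed)
    g <- build_compound_graph(net)
    ig <- igraph::graph_from_data_frame(g$edges, directed = FALSE,
                                        vertices = g$nodes)
    ew <- (g$weight[g$edges$from] + g$weight[g$edges$to]) / 2
    d <- igraph::distances(ig, weights = ew)
    mets <- g$nodes[g$type == "metabolite"]
    for (a in mets) for (b in setdiff(mets, a)) {
      lp <- lightest_path(g, a, b)
      ref <- d[a, b] + (g$weight[[a]] + g$weight[[b]]) / 2
      if (lp$connected) expect_equal(lp$weight, unname(ref))
      else expect_false(is.finite(d[a, b]))
    }
  }
})

test_that("with uniform weights the lightest path is a minimum-hop path", {
  for (seed in 1:5) {
    net <- random_network(n_mets = 7, n_rxns = 7, seed = seed)
    g <- build_compound_graph(net)
    g$weight[] <- 1
    mets <- g$nodes[g$type == "metabolite"]
    for (a in mets) for (b in setdiff(mets, a)) {
      lp <- lightest_path(g, a, b)
      h <- bfs_hops(g, a, b)
      if (lp$connected) expect_equal(length(lp$path) - 1, h)
      else expect_equal(h, Inf)
    }
  }
})

test_that("two metabolites sharing one reaction extract just that reaction", {
  net <- toy_net()
  g <- build_compound_graph(net)
  sub <- extract_subnetwork(net, g, c("M_a", "M_c"))
  expect_setequal(sub$metabolite_ids, c("M_a", "M_c"))
  expect_equal(sub$reaction_ids, "R1")
  expect_true(all(sub$source_pairs$connected))
})

test_that("the extracted union equals the brute-force union of pairwise optima", {
  for (seed in 1:6) {
    net <- random_network(n_mets = 6, n_rxns = 6, seed = seed)
    g <- build_compound_graph(net)
    mets <- g$nodes[g$type == "metabolite"]
    set.seed(seed + 100)
    mapped <- sort(sample(mets, 3))
    sub <- extract_subnetwork(net, g, mapped)
    # reference union from the enumeration oracle weights
    for (i in 1:2) for (j in (i + 1):3) {
      lp <- lightest_path(g, mapped[i], mapped[j])
      ref <- enum_lightest(g, mapped[i], mapped[j])
      pr <- sub$source_pairs
      row <- pr[pr$from == mapped[i] & pr$to == mapped[j], ]
      expect_equal(row$weight, if (is.finite(ref)) ref else Inf)
      if (lp$connected) {
        expect_true(all(lp$path %in% c(sub$metabolite_ids, sub$reaction_ids)))
      }
    }
    # every retained id resolves in the source network
    expect_true(all(sub$reaction_ids %in% names(net$reactions)))
    expect_true(all(sub$metabolite_ids %in% net$metabolites$base_id))
  }
})

test_that("adding a mapped node never removes reactions from the union", {
  for (seed in 1:5) {
    net <- random_network(n_mets = 7, n_rxns = 7, seed = seed)
    g <- build_compound_graph(net)
    mets <- g$nodes[g$type == "metabolite"]
    set.seed(seed + 200)
    mapped <- sort(sample(mets, 3))
    s2 <- extract_subnetwork(net, g, mapped[1:2])
    s3 <- extract_subnetwork(net, g, mapped)
    expect_true(all(s2$reaction_ids %in% s3$reaction_ids))
  }
})

test_that("degenerate mapped sets warn and return the mapped nodes only", {
  net <- toy_net()
  g <- build_compound_graph(net)
  expect_warning(sub <- extract_subnetwork(net, g, "M_a"), "fewer than 2")
  expect_equal(sub$metabolite_ids, "M_a")
  expect_length(sub$reaction_ids, 0)
  expect_warning(expect_warning(
    extract_subnetwork(net, g, c("M_a", "M_zz")), "not in compound graph"))
})

test_that("subnetwork exports re-read as a consistent SBML subset", {
  net <- random_network(n_mets = 8, n_rxns = 8, seed = 3)
  g <- build_compound_graph(net)
  mets <- g$nodes[g$type == "metabolite"]
  sub <- extract_subnetwork(net, g, sort(mets[1:3]))
  sbml <- withr::local_tempfile(fileext = ".xml")
  edges <- withr::local_tempfile(fileext = ".tsv")
  write_subnetwork(sub, net, g, sbml_path = sbml, edges_path = edges)
  net2 <- read_sbml(sbml)
  expect_setequal(names(net2$reactions), sub$reaction_ids)
  el <- utils::read.delim(edges, stringsAsFactors = FALSE)
  expect_true(all(el$from %in% sub$reaction_ids))
})
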