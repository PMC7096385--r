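test_that("packaged fixture ontology loads from the TSV dialect", {
  g <- load_ontology(extdata("fig2_ontology"), "tsv")
  expect_s3_class(g, "onto_graph")
  expect_equal(g$nodes$name[g$nodes$id == "CHEBI:36021"], "octadec-9-enoic acid")
  expect_true("octadec-9Z-enoic acid" %in% g$synonyms[["CHEBI:16196"]])
  expect_equal(nrow(g$edges), 8)
})

test_that("empty node and edge tables give an empty graph without error", {
  g <- onto_graph(data.frame(id = character(), name = character()),
                  data.frame(source = character(), kind = character(),
                             target = character()))
  expect_equal(nrow(g$nodes), 0)
  expect_equal(nrow(g$edges), 0)
})

test_that("a random DAG survives a TSV round trip", {
  g <- random_ontology(100, seed = 42)
  dir <- withr::local_tempdir()
  write_ontology_tsv(g, dir)
  g2 <- load_ontology(dir, "tsv")
  expect_equal(sort(g2$nodes$id), sort(g$nodes$id))
  key <- function(x) sort(paste(x$edges$source, x$edges$kind, x$edges$target))
  expect_equal(key(g2), key(g))
})

test_that("unknown edge kinds are dropped with a warning; cycles are fatal", {
  nodes <- data.frame(id = c("a", "b"), name = c("a", "b"))
  expect_warning(
    g <- onto_graph(nodes, data.frame(source = c("a", "a"),
                                      kind = c("IS_A", "PART_OF"),
                                      target = c("b", "b"))),
    "unknown kind")
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$n_dropped_edges, 1)
  expect_error(
    onto_graph(nodes, data.frame(source = c("a", "b"), kind = "IS_A",
                                 target = c("b", "a"))),
    "cyclic")
  expect_error(load_ontology(tempfile("nope"), "obo"), "cannot read")
})

test_that("OBO stanzas parse: is_a, relationships, obsolete and alt_id", {
  obo <- c(
    "format-version: 1.2", "",
    "[Term]", "id: CHEBI:1", "name: parent acid", "",
    "[Term]", "id: CHEBI:2", "name: child acid", "alt_id: CHEBI:9",
    "synonym: \"kid acid\" EXACT []", "is_a: CHEBI:1 ! parent acid", "",
    "[Term]", "id: CHEBI:3", "name: child base",
    "relationship: is_conjugate_base_of CHEBI:2 ! child acid", "",
    "[Term]", "id: CHEBI:4", "name: gone", "is_obsolete: true",
    "is_a: CHEBI:1")
  path <- withr::local_tempfile(lines = obo, fileext = ".obo")
  g <- load_ontology(path, "obo")
  expect_equal(nrow(g$nodes), 4)
  expect_true(g$nodes$is_obsolete[g$nodes$id == "CHEBI:4"])
  expect_equal(g$synonyms[["CHEBI:2"]], "kid acid")
  expect_equal(ancestors(g, "CHEBI:2")$id, "CHEBI:1")
  # alt_id remap applies at lookup
  expect_equal(ancestors(g, "CHEBI:9")$id, "CHEBI:1")
  fn <- functional_neighbors(g, "CHEBI:2")
  expect_equal(fn$id, "CHEBI:3")
  expect_equal(fn$kind, "CONJUGATE_BASE_OF")
})

test_that("ancestors and descendants match a brute-force reachability oracle", {
  for (seed in 1:5) {
    g <- random_ontology(30, seed = seed)
    for (id in sample(g$nodes$id, 8)) {
      up <- ancestors(g, id)
      up_ref <- reach_oracle(g, id, "up")
      expect_equal(up[order(up$id), ], up_ref[order(up_ref$id), ],
                   ignore_attr = TRUE)
      dn <- descendants(g, id)
      dn_ref <- reach_oracle(g, id, "down")
      expect_equal(dn[order(dn$id), ], dn_ref[order(dn_ref$id), ],
                   ignore_attr = TRUE)
    }
  }
})

test_that("zero radius and leaves give empty sets; unknown ids error", {
  g <- fig2_fixture()$ontology
  expect_equal(nrow(ancestors(g, "CHEBI:36021", max_up = 0)), 0)
  expect_equal(nrow(descendants(g, "CHEBI:16196")), 0) # leaf
  expect_error(ancestors(g, "CHEBI:424242"), "unknown ontology id")
  expect_error(ontology_paths(g, "CHEBI:36021", "CHEBI:30823", max_up = -1),
               "must be >= 0")
})

test_that("fig2 lineage: ancestors climb to fatty acid, oleic acid is one down", {
  g <- fig2_fixture()$ontology
  up <- ancestors(g, "CHEBI:36021")
  expect_setequal(up$id, c("CHEBI:25413", "CHEBI:27208", "CHEBI:35366"))
  expect_equal(up$depth[up$id == "CHEBI:35366"], 3)
  dn <- descendants(g, "CHEBI:36021", max_down = 1)
  expect_equal(dn$id, "CHEBI:16196") # oleic acid
  fn <- functional_neighbors(g, "CHEBI:16196")
  expect_true("CHEBI:30823" %in% fn$id) # oleate
  expect_equal(fn$kind[fn$id == "CHEBI:30823"], "CONJUGATE_BASE_OF")
})

test_that("functional neighborhood is symmetric", {
  for (seed in 1:5) {
    g <- random_ontology(20, p_functional = 0.4, seed = seed)
    for (a in g$nodes$id) {
      for (b in functional_neighbors(g, a)$id) {
        expect_true(a %in% functional_neighbors(g, b)$id)
      }
    }
  }
})

test_that("query equal to a target yields the single zero-distance path", {
  g <- fig2_fixture()$ontology
  r <- ontology_paths(g, "CHEBI:36021", "CHEBI:36021")
  expect_length(r, 1)
  expect_identical(r[[1]]$distance, 0)
  expect_equal(r[[1]]$node_sequence, "CHEBI:36021")
  # and zero distance arises only for the query itself
  r2 <- ontology_paths(g, "CHEBI:36021",
                       setdiff(g$nodes$id, "CHEBI:36021"))
  expect_true(all(vapply(r2, `[[`, numeric(1), "distance") != 0))
})

test_that("absent targets are skipped and reported", {
  g <- fig2_fixture()$ontology
  r <- ontology_paths(g, "CHEBI:36021", c("CHEBI:30823", "CHEBI:555555"))
  expect_equal(attr(r, "skipped_targets"), "CHEBI:555555")
  expect_length(r, 1)
})

test_that("matcher distances equal exhaustive enumeration on random DAGs", {
  for (seed in 1:25) {
    g <- random_ontology(25, p_functional = 0.2, seed = seed)
    query <- sample(g$nodes$id, 1)
    targets <- sample(g$nodes$id, 6)
    got <- ontology_paths(g, query, targets)
    ref <- enumerate_ontology_paths(g, query)
    ref <- ref[ref$target %in% targets, , drop = FALSE]
    expect_equal(length(got), nrow(ref))
    for (p in got) {
      expect_equal(p$distance, ref$distance[ref$target == p$target])
    }
  }
})

test_that("penalty-free random DAG distances are signed BFS depths", {
  for (seed in 1:10) {
    g <- random_ontology(25, p_functional = 0, seed = seed)
    query <- sample(g$nodes$id, 1)
    r <- ontology_paths(g, query, g$nodes$id)
    up <- ancestors(g, query); dn <- descendants(g, query)
    for (p in r) {
      if (p$target == query) {
        expect_identical(p$distance, 0)
      } else if (p$distance > 0) {
        expect_equal(p$distance, up$depth[up$id == p$target])
      } else {
        expect_equal(p$distance, -dn$depth[dn$id == p$target])
      }
    }
  }
})

test_that("path invariants hold: sign, composition, sequence length", {
  for (seed in 1:10) {
    g <- random_ontology(25, p_functional = 0.3, seed = seed)
    query <- sample(g$nodes$id, 1)
    for (p in ontology_paths(g, query, g$nodes$id)) {
      mag <- abs(p$hierarchical_steps) + 0.1 * p$acid_base_steps +
        0.01 * p$tautomer_steps
      expect_equal(abs(p$distance), mag)
      expect_equal(sign(p$distance), if (p$hierarchical_steps < 0) -1 else
        if (mag == 0) 0 else 1)
      expect_length(p$node_sequence,
                    abs(p$hierarchical_steps) + p$acid_base_steps +
                      p$tautomer_steps + 1)
      # hierarchical legs are monotone: verify against the edge list
      seq <- p$node_sequence
      if (length(seq) > 1) {
        is_a <- g$edges[g$edges$kind == "IS_A", ]
        fun <- g$edges[g$edges$kind != "IS_A", ]
        for (k in seq_len(length(seq) - 1)) {
          a <- seq[k]; b <- seq[k + 1]
          up_edge <- any(is_a$source == a & is_a$target == b)
          dn_edge <- any(is_a$source == b & is_a$target == a)
          fn_edge <- any((fun$source == a & fun$target == b) |
                           (fun$source == b & fun$target == a))
          # steps that can only be hierarchical must follow the path's sign
          if (xor(up_edge, dn_edge) && !fn_edge) {
            expect_equal(up_edge, p$hierarchical_steps > 0)
          }
        }
      }
    }
  }
})

test_that("enlarging the search bounds never increases any minimal distance", {
  for (seed in 1:5) {
    g <- random_ontology(25, p_functional = 0.2, seed = seed)
    query <- sample(g$nodes$id, 1)
    targets <- g$nodes$id
    dist_at <- function(bound) {
      r <- ontology_paths(g, query, targets, max_up = bound, max_down = bound)
      stats::setNames(vapply(r, function(p) abs(p$distance), numeric(1)),
                      vapply(r, `[[`, character(1), "target"))
    }
    small <- dist_at(2); big <- dist_at(10)
    expect_true(all(names(small) %in% names(big)))
    expect_true(all(big[names(small)] <= small + 1e-12))
  }
})

test_that("each extra functional step adds exactly its increment", {
  g <- micro_ontology(c("acid IS_A parent", "base CONJUGATE_BASE_OF acid",
                        "taut TAUTOMER_OF base"))
  d <- function(t) ontology_paths(g, "acid", t)[[1]]$distance
  expect_equal(d("parent"), 1)
  expect_equal(d("base"), 0.1)
  expect_equal(d("taut"), 0.11)
})

test_that("obsolete nodes are never returned as endpoints", {
  g <- onto_graph(
    data.frame(id = c("a", "b", "c"), name = c("a", "b", "c"),
               is_obsolete = c(FALSE, TRUE, FALSE)),
    data.frame(source = c("a", "b"), kind = "IS_A", target = c("b", "c")))
  r <- ontology_paths(g, "a", c("b", "c"))
  expect_false("b" %in% vapply(r, `[[`, character(1), "target"))
})
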