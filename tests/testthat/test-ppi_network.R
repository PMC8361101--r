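test_that("PPI edge lists are symmetric, deduplicated, self-loop free", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "B\tA", "A\tA", "B\tC", "B\tC"), f)
  expect_warning(db <- load_ppi_database(f), "self-loop")
  expect_equal(nrow(db$edges), 2)
  expect_equal(db$edges$a, c("A", "B"))
  expect_equal(db$edges$b, c("B", "C"))
  expect_equal(db$proteins, c("A", "B", "C"))

  # optional interaction-type column survives
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB\tdirect interaction"), f2)
  db2 <- load_ppi_database(f2)
  expect_equal(db2$edges$type, "direct interaction")

  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "C\t"), f3)
  expect_error(load_ppi_database(f3), "line 2")
})

test_that("pathological networks follow the one-bridge rule", {
  db <- ppi_database(data.frame(a = c("A", "B", "C", "A"),
                                b = c("B", "C", "D", "E")))
  # direct edge between seeds
  net <- build_pathological_network(c("A", "B"), db)
  expect_equal(net$nodes, c("A", "B"))
  expect_equal(nrow(net$edges), 1)

  # B bridges seeds A and C; E touches only one seed and is excluded
  net2 <- build_pathological_network(c("A", "C"), db)
  expect_equal(net2$nodes, c("A", "B", "C"))
  expect_equal(edge_keys_for_test(net2$edges), c("A|B", "B|C"))

  # pendant additions allowed when the rule is relaxed
  net3 <- build_pathological_network(c("A", "C"), db, min_seed_neighbors = 1)
  expect_true("E" %in% net3$nodes)

  # seed absent from the database is kept as an isolated node
  net4 <- build_pathological_network("X", db)
  expect_equal(net4$nodes, "X")
  expect_equal(nrow(net4$edges), 0)

  # output independent of seed iteration order
  net5 <- build_pathological_network(c("C", "A"), db)
  expect_equal(net5$nodes, net2$nodes)
  expect_equal(net5$edges, net2$edges)

  expect_error(build_pathological_network(character(0), db), "empty")
})

test_that("betweenness matches hand values on canonical graphs", {
  path3 <- ppi_database(data.frame(a = c("A", "B"), b = c("B", "C")))
  net <- build_pathological_network(c("A", "B", "C"), path3)
  b <- betweenness_scores(net)
  expect_equal(b[["B"]], 1)
  expect_equal(b[["A"]], 0)

  star <- ppi_database(data.frame(a = "H", b = c("L1", "L2", "L3")))
  bs <- betweenness_scores(build_pathological_network(
    c("H", "L1", "L2", "L3"), star))
  expect_equal(bs[["H"]], 3)  # choose(3, 2) leaf pairs

  tri <- ppi_database(data.frame(a = c("A", "B", "C"), b = c("B", "C", "A")))
  bt <- betweenness_scores(build_pathological_network(c("A", "B", "C"), tri))
  expect_equal(unname(bt), c(0, 0, 0))
})

test_that("betweenness agrees with the path-enumeration oracle", {
  set.seed(2024)
  for (i in 1:150) {
    n <- sample(3:7, 1)
    adj <- random_adjacency(n, p_edge = runif(1, 0.3, 0.8))
    g <- adjacency_to_network(adj)
    expect_equal(unname(betweenness_scores(g)), oracle_betweenness(adj),
                 tolerance = 1e-10)
  }
})

test_that("tree betweenness sums to interior-geodesic pair count", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(4:7, 1)
    g <- igraph::sample_tree(n)
    igraph::V(g)$name <- sprintf("N%d", seq_len(n))
    adj <- as.matrix(igraph::as_adjacency_matrix(g))
    # in a tree each pair has a unique geodesic with (distance - 1)
    # interior nodes; total betweenness counts interior incidences
    d <- igraph::distances(g)
    n_interior <- sum(pmax(d[upper.tri(d)] - 1, 0))
    expect_equal(sum(betweenness_scores(g)), n_interior)
    expect_equal(unname(betweenness_scores(g)), oracle_betweenness(adj))
  }
})

test_that("hub selection rules behave as specified", {
  sc <- c(A = 0, B = 0, C = 0, D = 0, E = 12)
  # mean 2.4, sample sd 5.367 -> threshold 13.13 exceeds every score
  expect_equal(high_betweenness_nodes(sc, rule = "z", k = 2), character(0))
  expect_equal(high_betweenness_nodes(sc, rule = "positive"), "E")

  expect_equal(high_betweenness_nodes(c(A = 1, B = 1), rule = "z", k = 0),
               character(0))  # nothing exceeds the mean strictly
  expect_error(high_betweenness_nodes(c(A = 1), rule = "z"), "at least two")
  expect_error(high_betweenness_nodes(numeric(0)), "non-empty")

  sc2 <- c(A = 0, B = 0, C = 0, D = 0, E = 0, F = 0, G = 0, H = 0, I = 30)
  expect_equal(high_betweenness_nodes(sc2, rule = "z", k = 2), "I")
})

test_that("per-model hub sets OR-aggregate over timepoints, seeds only", {
  db <- ppi_database(data.frame(a = c("A", "B", "X", "Y"),
                                b = c("B", "C", "Y", "Z")))
  net1 <- build_pathological_network(c("A", "B", "C"), db, timepoint = 1)
  net3 <- build_pathological_network(c("X", "Z"), db, timepoint = 3)
  # net3: Y bridges X and Z but is not a seed, so it cannot be core-eligible
  high <- model_high_nodes(list(net1, net3), rule = "positive")
  expect_equal(high, "B")
  high_all <- model_high_nodes(list(net1, net3), rule = "positive",
                               seeds_only = FALSE)
  expect_equal(high_all, c("B", "Y"))
})
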