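test_that("bootstrap null matches forced and hypergeometric limits", {
  # both sets exhaust the universe: every draw overlaps completely
  null_full <- bootstrap_commonness_null(50, 50, 50, reps = 20, seed = 1)
  expect_true(all(null_full$samples == 100))

  # tiny sets in a huge universe almost never overlap
  null_tiny <- bootstrap_commonness_null(1e6, 5, 5, reps = 200, seed = 2)
  expect_gt(mean(null_tiny$samples == 0), 0.95)

  # raw overlap mean within 3 Monte-Carlo SEs of the hypergeometric mean
  null <- bootstrap_commonness_null(1965, 73, 62, reps = 4000, seed = 3)
  hyper_mean <- 62 * 73 / 1965
  hyper_var <- 62 * (73 / 1965) * (1 - 73 / 1965) * (1965 - 62) / (1965 - 1)
  mc_se <- sqrt(hyper_var / 4000)
  expect_lt(abs(mean(null$raw_overlap) - hyper_mean), 3 * mc_se)
  expect_lt(abs(var(null$raw_overlap) - hyper_var),
            3 * hyper_var * sqrt(2 / 4000))

  # reproducible from the seed
  null_b <- bootstrap_commonness_null(1965, 73, 62, reps = 4000, seed = 3)
  expect_identical(null$samples, null_b$samples)

  expect_error(bootstrap_commonness_null(10, 11, 5), "sizes")
})

test_that("truncated-normal fit recovers parameters away from the bounds", {
  set.seed(11)
  x <- rnorm(10000, 50, 5)
  x <- x[x > 0 & x < 100]  # effectively untruncated
  for (m in c("moments", "mle")) {
    fit <- fit_truncated_normal(x, method = m)
    expect_lt(abs(fit[["mean"]] - 50) / 50, 0.02)
    expect_lt(abs(fit[["sd"]] - 5) / 5, 0.02)
  }
  expect_error(fit_truncated_normal(rep(3, 10)), "distinct")
})

test_that("MLE fit corrects for mass piled against the bound", {
  set.seed(12)
  # half-normal: parent mean 0, observed only above the bound
  x <- abs(rnorm(5000, 0, 10))
  fit <- fit_truncated_normal(x, lower = 0, upper = 100, method = "mle")
  expect_lt(fit[["mean"]], mean(x))
})

test_that("z-score standardizes against the fitted null", {
  expect_equal(commonness_zscore(5, 5, 2), 0)
  expect_equal(commonness_zscore(7, 5, 2), 1)
  null <- bootstrap_commonness_null(200, 20, 20, reps = 500, seed = 4)
  z <- commonness_zscore(mean(null$samples), null)
  expect_lt(abs(z), 1)
  expect_error(commonness_zscore(5, 5, 0), "positive")
})

test_that("node and edge precision follow the validation-network denominator", {
  net <- function(nodes, edges) assemble_core_network(nodes, edges)
  A <- net(c("A", "B", "C"), data.frame(a = c("A", "B"), b = c("B", "C")))
  expect_equal(node_edge_precision(A, A), c(node = 100, edge = 100))

  B <- net(c("B", "C", "D"), data.frame(a = c("B", "C"), b = c("C", "D")))
  p <- node_edge_precision(A, B)
  expect_equal(p[["node"]], 100 * 2 / 3)
  expect_equal(p[["edge"]], 50)

  D <- net(c("X", "Y"), data.frame(a = "X", b = "Y"))
  expect_equal(unname(node_edge_precision(A, D)), c(0, 0))

  # adding correct nodes to the estimate never lowers precision
  A_plus <- list(nodes = c(A$nodes, "D"), edges = A$edges)
  expect_gte(node_edge_precision(A_plus, B)[["node"]],
             p[["node"]])

  empty <- net(character(0), data.frame(a = character(0), b = character(0)))
  expect_error(node_edge_precision(A, empty), "undefined")
})

test_that("correlation errors reproduce the hand example and MAE <= RMSE", {
  err <- correlation_errors(c(0.5, 0.2), c(0.6, 0.5))  # diffs 0.1, 0.3
  expect_equal(err[["mae"]], 0.2)
  expect_equal(err[["rmse"]], sqrt(0.05))
  expect_equal(correlation_errors(c(0.3, 0.8), c(0.3, 0.8))[["mae"]], 0)

  set.seed(21)
  for (i in 1:30) {
    c1 <- runif(sample(2:20, 1)); c2 <- runif(length(c1))
    e <- correlation_errors(c1, c2)
    expect_lte(e[["mae"]], e[["rmse"]] + 1e-12)
  }
})

test_that("replicate-split CV yields zero error for homogeneous replicates", {
  # identical replicates: any split gives identical group trajectories
  quant <- do.call(rbind, lapply(c(1, 3, 6), function(tp)
    rbind(make_quant("P1", "S1", "m1", tp, rep(1 + tp / 10, 3)),
          make_quant("P2", "S1", "m1", tp, rep(2 - tp / 10, 3)),
          make_quant("P3", "S1", "m1", tp, rep(1, 3)))))
  edges <- data.frame(a = c("P1", "P2"), b = c("P2", "P3"))
  cv <- correlation_error_cv(quant, edges)
  expect_equal(nrow(cv), 3)  # leave-one-replicate-out
  expect_equal(cv$mae, rep(0, 3))
  expect_equal(cv$rmse, rep(0, 3))
  expect_true(all(cv$n_edges == 2))

  # noisy replicates: errors positive and MAE <= RMSE per split
  set.seed(9)
  quant$disease_signal <- quant$disease_signal * exp(rnorm(nrow(quant), 0, 0.2))
  cv2 <- correlation_error_cv(quant, edges)
  expect_true(all(cv2$mae <= cv2$rmse + 1e-12))
  expect_true(all(cv2$mae > 0))
})

test_that("physical-interaction enrichment follows the printed arithmetic", {
  enr <- physical_interaction_enrichment(13, 79, 62724, 20395)
  expect_equal(round(enr$observed_ratio, 1), 16.5)
  expect_equal(round(enr$expected_ratio, 3), 0.015)
  # independent check of the tail against dhyper summation
  pop <- 20395^2
  p_direct <- sum(dhyper(13:79, 62724, pop - 62724, 79))
  expect_equal(enr$p_value / p_direct, 1, tolerance = 1e-10)

  expect_equal(physical_interaction_enrichment(0, 79, 100, 1000)$p_value, 1)

  # p non-increasing in the support count
  ps <- vapply(0:10, function(s)
    physical_interaction_enrichment(s, 20, 1000, 300,
                                    margin = "unordered")$p_value,
    numeric(1))
  expect_true(all(diff(ps) <= 1e-15))

  expect_error(physical_interaction_enrichment(5, 4, 10, 100), "supported")
})
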