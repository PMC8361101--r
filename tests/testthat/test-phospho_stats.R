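test_that("channel normalization equalizes totals and preserves proportions", {
  m <- matrix(c(50, 50, 150, 150), nrow = 2,
              dimnames = list(c("s1", "s2"), c("r1", "r2")))
  out <- normalize_channels(m)
  expect_equal(colSums(out), c(r1 = 200, r2 = 200))
  expect_equal(out[, "r1"], c(s1 = 100, s2 = 100))
  expect_equal(out[, "r2"], c(s1 = 100, s2 = 100))

  # already balanced input is untouched
  bal <- matrix(c(40, 60, 70, 30), nrow = 2)
  expect_equal(normalize_channels(bal), bal)

  # single site
  one <- matrix(c(10, 30), nrow = 1)
  expect_equal(as.numeric(normalize_channels(one)), c(20, 20))

  # random matrices: totals equal, within-column ratios preserved
  set.seed(42)
  for (i in 1:10) {
    x <- matrix(rexp(24) + 0.1, nrow = 6)
    y <- normalize_channels(x)
    expect_equal(colSums(y), rep(mean(colSums(x)), 4), ignore_attr = TRUE)
    expect_equal(sweep(y, 2, colSums(y), "/"), sweep(x, 2, colSums(x), "/"))
  }

  expect_error(normalize_channels(matrix(c(1, -1), 1)), "non-positive")
})

test_that("fragment aggregation is the geometric mean", {
  expect_equal(aggregate_fragment_intensities(c(5, 5, 5)), 5)
  expect_equal(aggregate_fragment_intensities(c(4, 9)), 6)
  expect_equal(aggregate_fragment_intensities(c(1, 8)), 2 * sqrt(2))
  expect_error(aggregate_fragment_intensities(numeric(0)), "non-empty")
  expect_error(aggregate_fragment_intensities(c(1, 0)), "positive")
})

test_that("log ratios map the unit ratio to zero in any base", {
  rec <- data.frame(disease_signal = c(100, 200, 25),
                    control_signal = c(100, 100, 100))
  out <- compute_log_ratios(rec, base = 2)
  expect_equal(out$log_ratio, c(0, 1, -2))
  out10 <- compute_log_ratios(rec, base = 10)
  expect_equal(out10$log_ratio, c(0, log10(2), log10(0.25)))
  expect_error(compute_log_ratios(
    data.frame(disease_signal = 0, control_signal = 1)), "non-positive")
})

test_that("welch_test matches the textbook formula oracle", {
  a <- c(1.0, 1.1, 0.9); b <- c(2.0, 2.1, 1.9)
  orc <- oracle_welch(a, b)
  expect_equal(orc$t, -sqrt(150), tolerance = 1e-12)  # -12.247
  expect_equal(orc$df, 4, tolerance = 1e-12)
  expect_equal(welch_test(a, b), orc$p, tolerance = 1e-12)

  expect_lt(welch_test(c(0, 0, 0, 0), c(10, 10, 10, 10.0001)), 1e-6)

  # identical nonconstant groups: t = 0, p = 1
  expect_equal(welch_test(c(1, 2, 3), c(1, 2, 3)), 1)
  # degenerate equal-constant convention
  expect_equal(welch_test(c(2, 2), c(2, 2)), 1)
  expect_error(welch_test(1, c(1, 2)), "at least two")

  # symmetry and general agreement with the oracle on random draws
  set.seed(7)
  for (i in 1:25) {
    x <- rnorm(sample(2:6, 1)); y <- rnorm(sample(2:6, 1), mean = runif(1))
    expect_equal(welch_test(x, y), oracle_welch(x, y)$p, tolerance = 1e-10)
    expect_equal(welch_test(x, y), welch_test(y, x))
  }
})

test_that("welch_test controls its type-I error", {
  # at n = 3 the Welch-Satterthwaite approximation is conservative (its
  # true size under equal variances is near 0.034): require control, not
  # exact nominal attainment
  set.seed(123)
  p3 <- vapply(seq_len(10000),
               function(i) welch_test(rnorm(3), rnorm(3)), numeric(1))
  expect_lt(mean(p3 < 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 10000))
  expect_gt(mean(p3 < 0.05), 0.02)
  # at moderate n the size reaches the nominal level
  set.seed(124)
  p30 <- vapply(seq_len(4000),
                function(i) welch_test(rnorm(30), rnorm(30)), numeric(1))
  expect_lt(abs(mean(p30 < 0.05) - 0.05), 0.012)
})

test_that("bh_adjust reproduces the step-up formula and its invariances", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.005, 0.01, 0.03, 0.04)),
               c(0.02, 0.02, 0.04, 0.04))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(99)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p))
    expect_true(all(q >= p))
    perm <- sample(seq_along(p))
    expect_equal(bh_adjust(p[perm])[order(perm)], q)
  }
})

test_that("changed-site selection uses strict thresholds in both modes", {
  res <- data.frame(protein_id = paste0("P", 1:4), site = "S1",
                    model_id = "m1", timepoint = 1,
                    mean_log_ratio = 0,
                    p_value = c(0.005, 0.01, 0.03, 0.04),
                    q_value = bh_adjust(c(0.005, 0.01, 0.03, 0.04)))
  expect_equal(nrow(select_changed_sites(res, mode = "q", alpha = 0.05)), 4)

  res2 <- data.frame(protein_id = c("A", "B"), site = "S1", model_id = "m",
                     timepoint = 1, mean_log_ratio = 0,
                     p_value = c(0.04, 0.6), q_value = c(0.08, 0.6))
  sel <- select_changed_sites(res2, mode = "p")
  expect_equal(sel$protein_id, "A")

  res3 <- data.frame(protein_id = "A", site = "S1", model_id = "m",
                     timepoint = 1, mean_log_ratio = 0,
                     p_value = 0.05, q_value = 0.05)
  expect_equal(nrow(select_changed_sites(res3, mode = "p")), 0)
  expect_error(select_changed_sites(res3, mode = "x"))
})

test_that("differential_phospho tests per analysis and flags consistently", {
  set.seed(5)
  quant <- rbind(
    make_quant("P1", "S1", "m1", 1, c(4.1, 3.9, 4.0)),   # strong change
    make_quant("P2", "S1", "m1", 1, c(1.05, 0.95, 1.0)), # null
    make_quant("P1", "S1", "m1", 3, c(1.0, 1.1, 0.9)))   # other analysis
  # give control replicates slight variation so both groups have variance
  quant$control_signal <- quant$control_signal * c(0.99, 1.0, 1.01)
  res <- differential_phospho(quant)
  expect_equal(nrow(res), 3)
  r11 <- res[res$protein_id == "P1" & res$timepoint == 1, ]
  expect_equal(r11$mean_log_ratio, mean(log2(c(4.1, 3.9, 4.0) /
                                               c(0.99, 1.0, 1.01))))
  expect_true(r11$sig_p)
  expect_true(all(res$q_value >= res$p_value))
  # q-values are adjusted within each model x timepoint family
  fam <- res[res$timepoint == 1, ]
  expect_equal(sort(fam$q_value), sort(bh_adjust(fam$p_value)))

  # one-sample mode agrees with a direct one-sample t-test on log ratios
  res1 <- differential_phospho(quant, mode = "one_sample")
  logr <- log2(c(1.05, 0.95, 1.0) / c(0.99, 1.0, 1.01))
  expect_equal(res1$p_value[res1$protein_id == "P2"],
               t.test(logr, mu = 0)$p.value)
})
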