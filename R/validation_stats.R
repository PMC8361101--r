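#' Bootstrap null distribution of core-network commonness
#'
#' Draws two uniform without-replacement protein subsets of the observed
#' core-set sizes from the detected-protein universe and records the
#' percentage node commonness (100 |A n B| / |A u B|) for each replicate,
#' then fits a truncated normal to the samples (see
#' [fit_truncated_normal()]). This is the null against which an observed
#' commonness is standardized: how much overlap two core sets of the given
#' sizes would share by detection alone.
#'
#' @param n_total Number of detected proteins (the sampling universe).
#' @param n_a,n_b Sizes of the two core node sets.
#' @param reps Number of bootstrap replicates (10,000 in the study design).
#' @param seed Integer seed; all draws come from one seeded generator.
#' @return Object of class `commonness_null` with elements `samples`
#'   (percent commonness per replicate), `raw_overlap` (intersection
#'   sizes), `fit_mean`, `fit_sd`, `fit_method`, and the call parameters.
#' @export
bootstrap_commonness_null <- function(n_total, n_a, n_b, reps = 10000L,
                                      seed = 1L) {
  if (n_a > n_total || n_b > n_total || n_a < 1L || n_b < 1L)
    stop("core set sizes must lie in [1, n_total]")
  if (reps < 1L) stop("reps must be >= 1")
  set.seed(seed)
  raw <- integer(reps)
  for (i in seq_len(reps)) {
    a <- sample.int(n_total, n_a)
    b <- sample.int(n_total, n_b)
    raw[i] <- length(intersect(a, b))
  }
  samples <- 100 * raw / (n_a + n_b - raw)
  fit <- tryCatch(fit_truncated_normal(samples, lower = 0, upper = 100),
                  error = function(e) {
                    out <- c(mean = NA_real_, sd = NA_real_)
                    attr(out, "method") <- "degenerate"
                    out
                  })
  structure(list(n_total = n_total, n_a = n_a, n_b = n_b, reps = reps,
                 seed = seed, raw_overlap = raw, samples = samples,
                 fit_mean = fit[["mean"]], fit_sd = fit[["sd"]],
                 fit_method = attr(fit, "method")),
            class = "commonness_null")
}

#' @export
print.commonness_null <- function(x, ...) {
  cat(sprintf(
    "Commonness null: %d reps, |universe|=%d, |A|=%d, |B|=%d\n  fitted mean %.3f%%, sd %.3f%% (%s)\n",
    x$reps, x$n_total, x$n_a, x$n_b, x$fit_mean, x$fit_sd, x$fit_method))
  invisible(x)
}

#' Fit a truncated normal to bounded percentage samples
#'
#' Estimates the location and scale of a normal distribution truncated to
#' `[lower, upper]` from samples on that interval. Samples lying exactly on
#' a bound are excluded before fitting: the commonness statistic is
#' discrete, and its atom at zero overlap is a boundary artifact that a
#' continuous truncated normal cannot represent (see the methods vignette).
#'
#' Two estimators are available. `"moments"` (default) takes the mean and
#' sample SD of the interior samples -- for data well inside the bounds this
#' is the ordinary normal fit, and on the discrete commonness null it
#' reproduces the observed location/scale robustly. `"mle"` maximizes the
#' truncated-normal likelihood of the interior samples, applying the full
#' truncation correction (fitted mean at or below the sample mean when mass
#' piles against the lower bound). Degenerate samples are rejected.
#'
#' @param samples Numeric vector, at least two distinct interior values.
#' @param lower,upper Truncation bounds, default `[0, 100]`.
#' @param method `"moments"` or `"mle"`.
#' @return Named numeric vector `c(mean = , sd = )` with attribute `method`.
#' @export
fit_truncated_normal <- function(samples, lower = 0, upper = 100,
                                 method = c("moments", "mle")) {
  method <- match.arg(method)
  if (any(samples < lower | samples > upper))
    stop("samples must lie within [lower, upper]")
  x <- samples[samples > lower & samples < upper]
  if (length(unique(x)) < 2L)
    stop("need at least two distinct interior samples")
  m <- mean(x)
  s <- stats::sd(x)
  if (method == "moments") {
    out <- c(mean = m, sd = s)
    attr(out, "method") <- "moments"
    return(out)
  }
  nll <- function(par) {
    mu <- par[1L]
    sg <- exp(par[2L])
    z <- stats::pnorm(upper, mu, sg) - stats::pnorm(lower, mu, sg)
    if (z <= 0) return(Inf)
    -sum(stats::dnorm(x, mu, sg, log = TRUE)) + length(x) * log(z)
  }
  fit <- stats::optim(c(m, log(s)), nll, method = "Nelder-Mead")
  if (fit$convergence != 0) {
    warning("truncated-normal MLE did not converge; falling back to moments")
    out <- c(mean = m, sd = s)
    attr(out, "method") <- "moments-fallback"
    return(out)
  }
  out <- c(mean = fit$par[1L], sd = exp(fit$par[2L]))
  attr(out, "method") <- "mle"
  out
}

#' Standardized rarity of an observed commonness
#'
#' @param observed Observed percentage commonness.
#' @param fit_mean,fit_sd Null parameters, e.g. from
#'   [bootstrap_commonness_null()]. A `commonness_null` object may be
#'   passed as `fit_mean`.
#' @return z-score (SD units above the null mean).
#' @export
commonness_zscore <- function(observed, fit_mean, fit_sd = NULL) {
  if (inherits(fit_mean, "commonness_null")) {
    fit_sd <- fit_mean$fit_sd
    fit_mean <- fit_mean$fit_mean
  }
  if (fit_sd <= 0) stop("fit_sd must be positive")
  (observed - fit_mean) / fit_sd
}

#' Hold-out / cross-validation precision of node and edge selection
#'
#' Precision of the estimated network against an independently derived
#' validation network: the percentage of the validation network's nodes
#' (edges) that the estimation also selected, 100 |shared| / |validation|.
#'
#' @param estimated,validation `core_network` objects (or lists with
#'   `nodes` and `edges` elements).
#' @return Named numeric vector `c(node = , edge = )`, percentages.
#' @export
node_edge_precision <- function(estimated, validation) {
  if (length(validation$nodes) == 0L)
    stop("validation network has no nodes; precision undefined")
  node <- 100 * length(intersect(estimated$nodes, validation$nodes)) /
    length(validation$nodes)
  ek_est <- edge_keys(canonical_edges(estimated$edges$a, estimated$edges$b))
  ek_val <- edge_keys(canonical_edges(validation$edges$a, validation$edges$b))
  edge <- if (length(ek_val) == 0L) NA_real_
          else 100 * length(intersect(ek_est, ek_val)) / length(ek_val)
  c(node = node, edge = edge)
}

#' MAE and RMSE between two sets of edge correlations
#'
#' Mean absolute error and root mean square error over the N edges with a
#' correlation defined in both groups:
#' MAE = sum |corr_g2 - corr_g1| / N, RMSE = sqrt(sum |.|^2 / N).
#'
#' @param corr_g1,corr_g2 Numeric vectors of per-edge correlations, aligned.
#' @return Named numeric vector `c(mae = , rmse = , n_edges = )`.
#' @export
correlation_errors <- function(corr_g1, corr_g2) {
  stopifnot(length(corr_g1) == length(corr_g2))
  keep <- is.finite(corr_g1) & is.finite(corr_g2)
  if (!any(keep)) stop("no edges with correlations defined in both groups")
  d <- abs(corr_g2[keep] - corr_g1[keep])
  c(mae = mean(d), rmse = sqrt(mean(d^2)), n_edges = sum(keep))
}

#' Replicate-split cross-validation of edge correlations
#'
#' Evaluates random variation among the replicate animals of one model:
#' replicates are split into two groups, per-edge cosine correlations are
#' recomputed from each group's mean ratio trajectories, and MAE/RMSE of
#' the correlations over the shared edges are reported per split. The
#' default splits are the leave-one-replicate-out partitions (g1 = one
#' animal, g2 = the rest), the only scheme consistent with a threefold
#' design at N = 3.
#'
#' @param records Quantification table for a single model.
#' @param edges Candidate edges (data frame `a`, `b`), typically that
#'   model's network edges.
#' @param splits Optional list of two-element lists of replicate IDs; by
#'   default all leave-one-out partitions of the observed replicates.
#' @param timepoints Timepoints of the trajectory vectors.
#' @return Data frame with one row per split: `split`, `mae`, `rmse`,
#'   `n_edges`; `mae <= rmse` on every row.
#' @export
correlation_error_cv <- function(records, edges, splits = NULL,
                                 timepoints = c(1, 3, 6)) {
  reps <- sort(unique(records$replicate))
  if (length(reps) < 2L) stop("need at least two replicates per model")
  if (is.null(splits))
    splits <- lapply(reps, function(r) list(g1 = r, g2 = setdiff(reps, r)))
  edge_corr <- function(sub) {
    vec <- trajectory_vectors(sub, timepoints = timepoints)
    sel <- correlated_edges_for_model(edges, vec, threshold = -Inf)
    stats::setNames(sel$r, edge_keys(sel))
  }
  out <- do.call(rbind, lapply(seq_along(splits), function(i) {
    sp <- splits[[i]]
    c1 <- edge_corr(records[records$replicate %in% sp$g1, , drop = FALSE])
    c2 <- edge_corr(records[records$replicate %in% sp$g2, , drop = FALSE])
    shared <- intersect(names(c1), names(c2))
    if (length(shared) == 0L)
      stop("no shared edges between replicate groups in split ", i)
    err <- correlation_errors(c1[shared], c2[shared])
    data.frame(split = i, mae = err[["mae"]], rmse = err[["rmse"]],
               n_edges = err[["n_edges"]])
  }))
  rownames(out) <- NULL
  out
}

#' Physical-interaction enrichment of core edges
#'
#' Compares the fraction of core edges supported by a physical-interaction
#' database against the database's background edge density, with a
#' one-sided Fisher exact test (hypergeometric upper tail) for drawing at
#' least `supported` annotated pairs among `total_edges` draws. The default
#' `"ordered"` margin uses the full n^2 protein-pair population, matching
#' the printed arithmetic of the reference analysis (62,724 / 20,395^2 =
#' 0.015%); `"unordered"` uses C(n, 2) pairs.
#'
#' @param supported Number of core edges with database support.
#' @param total_edges Number of core edges tested.
#' @param db_pairs Number of annotated interacting pairs in the database.
#' @param n_proteins Size of the protein universe of the database.
#' @param margin `"ordered"` (n^2 pairs, default) or `"unordered"`.
#' @return List: `observed_ratio` and `expected_ratio` (percent), `p_value`.
#' @export
physical_interaction_enrichment <- function(supported, total_edges,
                                            db_pairs, n_proteins,
                                            margin = c("ordered",
                                                       "unordered")) {
  margin <- match.arg(margin)
  if (supported < 0 || supported > total_edges || total_edges < 1L)
    stop("need 0 <= supported <= total_edges, total_edges >= 1")
  population <- if (margin == "ordered") n_proteins^2
                else choose(n_proteins, 2)
  if (db_pairs > population) stop("db_pairs exceeds the pair population")
  list(observed_ratio = 100 * supported / total_edges,
       expected_ratio = 100 * db_pairs / population,
       p_value = stats::phyper(supported - 1, db_pairs,
                               population - db_pairs, total_edges,
                               lower.tail = FALSE))
}
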