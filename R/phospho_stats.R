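#' Equalize total signal across quantification channels
#'
#' Applies the bias correction used for isobaric (iTRAQ-style) reporter
#' quantification: every channel (column) is rescaled so that all column
#' totals equal the grand mean of the original column totals. Within-column
#' proportions are preserved exactly, so disease/control ratios computed
#' after correction are unaffected by global loading differences.
#'
#' @param signal_table Numeric matrix of strictly positive intensities,
#'   sites in rows and channels (replicate signals) in columns.
#' @return Matrix of the same shape with equalized column totals.
#' @export
normalize_channels <- function(signal_table) {
  signal_table <- as.matrix(signal_table)
  if (nrow(signal_table) < 1L || ncol(signal_table) < 1L)
    stop("signal_table must contain at least one site and one channel")
  bad <- which(!is.finite(signal_table) | signal_table <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-positive or non-finite signal at row %d, column %d",
                 bad[1L, 1L], bad[1L, 2L]))
  totals <- colSums(signal_table)
  sweep(signal_table, 2L, mean(totals) / totals, `*`)
}

#' Aggregate fragment intensities into one peptide quantity
#'
#' The quantity of a phosphopeptide observed through several MS/MS fragments
#' is summarized as the geometric mean of the fragment intensities.
#'
#' @param fragment_signals Numeric vector of positive intensities.
#' @return The geometric mean (positive scalar).
#' @export
aggregate_fragment_intensities <- function(fragment_signals) {
  if (length(fragment_signals) == 0L)
    stop("fragment_signals must be non-empty")
  if (any(!is.finite(fragment_signals) | fragment_signals <= 0))
    stop("fragment_signals must be strictly positive")
  exp(mean(log(fragment_signals)))
}

#' Log disease/control ratios
#'
#' @param records Data frame with positive `disease_signal` and
#'   `control_signal` columns (see [read_quant_table()]).
#' @param base Logarithm base; phosphoproteome ratios are conventionally
#'   reported in log2.
#' @return `records` with a `log_ratio` column appended.
#' @export
compute_log_ratios <- function(records, base = 2) {
  stopifnot(is.data.frame(records),
            all(c("disease_signal", "control_signal") %in% names(records)))
  bad <- which(records$disease_signal <= 0 | records$control_signal <= 0)
  if (length(bad) > 0L)
    stop(sprintf("non-positive signal in record %d", bad[1L]))
  records$log_ratio <-
    log(records$disease_signal / records$control_signal, base = base)
  records
}

#' Welch's unequal-variance t-test
#'
#' Two-sided Welch test with Welch-Satterthwaite degrees of freedom, as used
#' to call a phosphosite changed between disease and control replicates
#' (N = 3 per group in the study design). When both groups are constant and
#' equal the p-value is 1 by convention.
#'
#' @param group_a,group_b Numeric vectors with at least two values each.
#' @return Two-sided p-value.
#' @export
welch_test <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("each group needs at least two values")
  va <- stats::var(group_a)
  vb <- stats::var(group_b)
  if (va == 0 && vb == 0) {
    # degenerate: no within-group variability at all
    return(if (mean(group_a) == mean(group_b)) 1 else 0)
  }
  stats::t.test(group_a, group_b, var.equal = FALSE)$p.value
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment; q-values are returned in the
#' input order and capped at 1.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.finite(p_values) | p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Per-analysis differential phosphorylation
#'
#' Runs the Welch test per phosphosite within every model x timepoint
#' analysis and adjusts for multiplicity within that analysis (each mass run
#' is one hypothesis family). Two testing modes are provided:
#' `"two_sample"` compares log disease signals against log control signals
#' across replicates; `"one_sample"` tests the per-replicate log ratios
#' against zero, matching a paired-channel reading of the isobaric design.
#'
#' @param records Quantification table (see [read_quant_table()]).
#' @param base Log base for `mean_log_ratio` (significance is
#'   base-invariant).
#' @param mode `"two_sample"` (default) or `"one_sample"`.
#' @param alpha Significance level for the `sig_p` / `sig_q` flags.
#' @return Data frame with one row per (protein, site, model, timepoint):
#'   `mean_log_ratio`, `p_value`, `q_value`, and strict-inequality flags
#'   `sig_p`, `sig_q`.
#' @export
differential_phospho <- function(records, base = 2,
                                 mode = c("two_sample", "one_sample"),
                                 alpha = 0.05) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(records))
  req <- c("protein_id", "site", "model_id", "timepoint", "replicate",
           "disease_signal", "control_signal")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols) > 0L)
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  if (any(records$disease_signal <= 0 | records$control_signal <= 0))
    stop("signals must be strictly positive")

  analysis <- interaction(records$model_id, records$timepoint, drop = TRUE)
  out <- do.call(rbind, lapply(split(records, analysis), function(blk) {
    per_site <- split(blk, interaction(blk$protein_id, blk$site, drop = TRUE))
    res <- lapply(per_site, function(s) {
      logr <- log(s$disease_signal / s$control_signal, base = base)
      p <- if (mode == "two_sample") {
        welch_test(log(s$disease_signal), log(s$control_signal))
      } else {
        if (length(logr) < 2L || stats::var(logr) == 0) {
          if (all(logr == 0)) 1 else 0
        } else {
          stats::t.test(logr, mu = 0)$p.value
        }
      }
      data.frame(protein_id = s$protein_id[1L], site = s$site[1L],
                 model_id = s$model_id[1L], timepoint = s$timepoint[1L],
                 mean_log_ratio = mean(logr), p_value = p,
                 stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, res)
    res$q_value <- bh_adjust(res$p_value)
    res
  }))
  rownames(out) <- NULL
  out$sig_p <- out$p_value < alpha
  out$sig_q <- out$q_value < alpha
  out
}

#' Select significantly changed sites
#'
#' @param results Output of [differential_phospho()].
#' @param mode `"p"` (Welch p-value) or `"q"` (BH-adjusted).
#' @param alpha Threshold; comparison is strict (`< alpha`).
#' @return Subset of `results` rows passing the threshold.
#' @export
select_changed_sites <- function(results, mode = c("p", "q"), alpha = 0.05) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(results))
  col <- if (mode == "p") "p_value" else "q_value"
  results[results[[col]] < alpha, , drop = FALSE]
}

#' Changed proteins per analysis
#'
#' Convenience split of [select_changed_sites()] output into the per-analysis
#' protein sets that seed the pathological networks.
#'
#' @param changed Data frame of selected sites.
#' @return Nested list: `proteins[[model_id]][[as.character(timepoint)]]` is
#'   a character vector of protein IDs.
#' @export
changed_proteins_by_analysis <- function(changed) {
  out <- list()
  if (nrow(changed) == 0L) return(out)
  for (m in unique(changed$model_id)) {
    blk <- changed[changed$model_id == m, , drop = FALSE]
    out[[m]] <- lapply(split(blk$protein_id, as.character(blk$timepoint)),
                       unique)
  }
  out
}
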