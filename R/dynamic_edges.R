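#' Chronological trajectory vectors of phosphosites
#'
#' Each phosphosite of one disease model is characterized by a 3D vector
#' whose components are the mean disease/control ratios over replicates at
#' the three ages (by default 1, 3 and 6 months, mapped to x, y, z). A site
#' missing any timepoint is flagged incomplete rather than imputed: three
#' points leave no room for principled imputation.
#'
#' @param records Quantification table for one or more models (columns as in
#'   [read_quant_table()]).
#' @param timepoints Ordered vector of expected timepoints (months).
#' @param log_space If `TRUE`, components are mean log2 ratios instead of
#'   raw ratios. Raw ratios are the default: they match how the vectors are
#'   defined in the underlying method, at the price of a systematically
#'   inflated cosine for all-positive vectors (hence the high 0.9 cutoff).
#' @return Data frame: `protein_id`, `site`, `model_id`, one column per
#'   timepoint (`x`, `y`, `z` for three), and `complete`.
#' @export
trajectory_vectors <- function(records, timepoints = c(1, 3, 6),
                               log_space = FALSE) {
  stopifnot(is.data.frame(records))
  if (any(records$disease_signal <= 0 | records$control_signal <= 0))
    stop("signals must be strictly positive")
  ratio <- records$disease_signal / records$control_signal
  if (log_space) ratio <- log2(ratio)
  key <- interaction(records$protein_id, records$site, records$model_id,
                     drop = TRUE)
  blocks <- split(data.frame(ratio = ratio, timepoint = records$timepoint,
                             protein_id = records$protein_id,
                             site = records$site,
                             model_id = records$model_id,
                             stringsAsFactors = FALSE), key)
  comp_names <- if (length(timepoints) == 3L) c("x", "y", "z")
                else paste0("t", timepoints)
  out <- lapply(blocks, function(blk) {
    means <- vapply(timepoints, function(tp) {
      v <- blk$ratio[blk$timepoint == tp]
      if (length(v) == 0L) NA_real_ else mean(v)
    }, numeric(1))
    row <- data.frame(protein_id = blk$protein_id[1L], site = blk$site[1L],
                      model_id = blk$model_id[1L], stringsAsFactors = FALSE)
    row[comp_names] <- as.list(means)
    row$complete <- !anyNA(means)
    row
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Cosine correlation of two trajectory vectors
#'
#' Absolute cosine of the angle between two vectors:
#' r = |v1 . v2| / (||v1|| ||v2||), so r is in \[0, 1\] and invariant to
#' rescaling either vector.
#'
#' @param v1,v2 Numeric vectors of equal length (3 components for the
#'   standard three-timepoint design), all finite, nonzero norm.
#' @return r in \[0, 1\].
#' @export
cosine_correlation <- function(v1, v2) {
  if (length(v1) != length(v2)) stop("vectors must have equal length")
  if (anyNA(v1) || anyNA(v2) || any(!is.finite(c(v1, v2))))
    stop("vectors must be complete and finite")
  n2 <- sum(v1^2) * sum(v2^2)
  if (n2 == 0) stop("zero-norm vector")
  abs(sum(v1 * v2)) / sqrt(n2)
}

#' Select highly correlated edges of a model's network
#'
#' An edge of the pathological network is "highly correlated" when some
#' phosphosite of one endpoint and some phosphosite of the other both have
#' complete trajectory vectors with cosine correlation at or above the
#' threshold (non-strict; r >= 0.9 by default). With several sites per
#' protein the edge correlation is the maximum over all cross-site pairs.
#' Candidate pairs are restricted to network edges; edges with no usable
#' vector pair are silently not selected.
#'
#' @param edges Candidate edges: a data frame with columns `a`, `b` (e.g.
#'   [model_union_edges()]), or a `pathological_network`.
#' @param vectors [trajectory_vectors()] output for the same model.
#' @param threshold Cosine cutoff, default 0.9.
#' @return Data frame `a`, `b`, `r` of selected edges.
#' @export
correlated_edges_for_model <- function(edges, vectors, threshold = 0.9) {
  if (inherits(edges, "pathological_network")) edges <- edges$edges
  stopifnot(is.data.frame(edges), all(c("a", "b") %in% names(edges)))
  comp <- setdiff(names(vectors),
                  c("protein_id", "site", "model_id", "complete"))
  usable <- vectors[vectors$complete, , drop = FALSE]
  vec_by_protein <- split(as.matrix(usable[comp]), usable$protein_id)
  nc <- length(comp)

  sel <- logical(nrow(edges))
  rmax <- rep(NA_real_, nrow(edges))
  for (i in seq_len(nrow(edges))) {
    va <- vec_by_protein[[edges$a[i]]]
    vb <- vec_by_protein[[edges$b[i]]]
    if (is.null(va) || is.null(vb)) next
    ma <- matrix(va, ncol = nc)
    mb <- matrix(vb, ncol = nc)
    best <- -Inf
    for (j in seq_len(nrow(ma))) for (l in seq_len(nrow(mb))) {
      n2 <- sum(ma[j, ]^2) * sum(mb[l, ]^2)
      if (n2 == 0) next
      best <- max(best, abs(sum(ma[j, ] * mb[l, ])) / sqrt(n2))
    }
    if (is.finite(best)) {
      rmax[i] <- best
      sel[i] <- best >= threshold
    }
  }
  out <- edges[sel, c("a", "b"), drop = FALSE]
  out$r <- rmax[sel]
  rownames(out) <- NULL
  out
}
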