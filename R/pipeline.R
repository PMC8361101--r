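#' Infer group core networks from a quantification table and PPI database
#'
#' Runs the full inference chain in memory: per-analysis differential
#' phosphorylation (Step 1), per-model-per-timepoint pathological networks
#' (Step 2), betweenness hub selection with OR-aggregation over timepoints
#' (Step 3), trajectory-vector cosine edge selection per model (Step 4),
#' and group core networks plus their common core (Steps 5-6).
#'
#' @param quant Quantification table (see [read_quant_table()]).
#' @param db A [ppi_database()].
#' @param groups Named character vector mapping every model in `quant` to a
#'   group label.
#' @param timepoints Timepoints of the trajectory design.
#' @param log_base Log base of the differential analysis.
#' @param sig_mode `"p"` or `"q"` site selection.
#' @param alpha Significance threshold (strict).
#' @param betweenness_rule `"positive"` (default here: group-level support
#'   filtering supplies specificity, the strict z-cut is for hub ranking) or
#'   `"z"`.
#' @param k SD multiplier for the `"z"` rule.
#' @param correlation_threshold Cosine cutoff for edge selection.
#' @param min_support Models per group required for core membership.
#' @param welch_mode Passed to [differential_phospho()].
#' @param normalize Apply per-analysis channel bias correction first.
#' @return List: `differential`, `high_sets`, `correlated_sets`,
#'   `networks` (nested model/timepoint), `group_cores` (one
#'   `core_network` per group), `common_core`, `commonness` (percent node
#'   commonness between the two group cores, `NA` if undefined), and
#'   `detection_counts` for the common core nodes.
#' @export
infer_core_networks <- function(quant, db, groups = default_model_groups(),
                                timepoints = c(1, 3, 6), log_base = 2,
                                sig_mode = c("p", "q"), alpha = 0.05,
                                betweenness_rule = c("positive", "z"),
                                k = 2, correlation_threshold = 0.9,
                                min_support = 2L,
                                welch_mode = c("two_sample", "one_sample"),
                                normalize = TRUE) {
  sig_mode <- match.arg(sig_mode)
  betweenness_rule <- match.arg(betweenness_rule)
  welch_mode <- match.arg(welch_mode)
  models <- unique(quant$model_id)
  unknown <- setdiff(models, names(groups))
  if (length(unknown) > 0L)
    stop("models without a group assignment: ",
         paste(unknown, collapse = ", "))
  groups <- groups[names(groups) %in% models]

  if (normalize) quant <- normalize_quant_table(quant)
  diff <- differential_phospho(quant, base = log_base, mode = welch_mode,
                               alpha = alpha)
  changed <- select_changed_sites(diff, mode = sig_mode, alpha = alpha)
  seeds_by <- changed_proteins_by_analysis(changed)

  networks <- list()
  high_sets <- list()
  correlated_sets <- list()
  for (m in names(groups)) {
    nets <- list()
    for (tp in names(seeds_by[[m]])) {
      seeds <- seeds_by[[m]][[tp]]
      if (length(seeds) == 0L) next
      nets[[tp]] <- build_pathological_network(seeds, db, model_id = m,
                                               timepoint = as.numeric(tp))
    }
    networks[[m]] <- nets
    high_sets[[m]] <- model_high_nodes(nets, rule = betweenness_rule, k = k)
    vecs <- trajectory_vectors(quant[quant$model_id == m, , drop = FALSE],
                               timepoints = timepoints)
    correlated_sets[[m]] <-
      correlated_edges_for_model(model_union_edges(nets), vecs,
                                 threshold = correlation_threshold)
  }

  group_labels <- unique(groups)
  sig_tier <- site_significance_tier(diff, alpha = alpha)
  group_cores <- list()
  for (g in group_labels) {
    in_g <- names(groups)[groups == g]
    nodes_g <- core_nodes(high_sets[in_g], groups, min_support)
    edges_g <- core_edges(correlated_sets[in_g], groups, min_support)
    group_cores[[g]] <- assemble_core_network(nodes_g, edges_g,
                                              group_label = g,
                                              node_meta = sig_tier)
  }
  nodes_c <- core_nodes(high_sets, groups, min_support)
  edges_c <- core_edges(correlated_sets, groups, min_support)
  common <- assemble_core_network(
    nodes_c, edges_c,
    group_label = paste(c(sort(group_labels), "common"), collapse = "-"),
    node_meta = sig_tier)

  comm <- if (length(group_labels) == 2L &&
              (length(group_cores[[1L]]$nodes) > 0L ||
               length(group_cores[[2L]]$nodes) > 0L)) {
    commonness(group_cores[[1L]], group_cores[[2L]])
  } else NA_real_

  detected_by_analysis <- lapply(
    split(quant$protein_id,
          interaction(quant$model_id, quant$timepoint, drop = TRUE)),
    unique)
  det <- detection_support_counts(detected_by_analysis, common$nodes)

  list(differential = diff, high_sets = high_sets,
       correlated_sets = correlated_sets, networks = networks,
       group_cores = group_cores, common_core = common,
       commonness = comm, detection_counts = det)
}

#' Per-analysis channel bias correction of a quantification table
#'
#' Applies [normalize_channels()] within every model x timepoint analysis,
#' treating each replicate's disease and control signal columns as separate
#' channels.
#'
#' @param quant Quantification table.
#' @return Table of the same shape with corrected signals.
#' @export
normalize_quant_table <- function(quant) {
  do.call(rbind, lapply(
    split(quant, interaction(quant$model_id, quant$timepoint, drop = TRUE)),
    function(blk) {
      site_key <- interaction(blk$protein_id, blk$site, drop = TRUE)
      sites <- levels(site_key)
      reps <- sort(unique(blk$replicate))
      dmat <- cmat <- matrix(NA_real_, length(sites), length(reps),
                             dimnames = list(sites, reps))
      ridx <- match(blk$replicate, reps)
      sidx <- match(as.character(site_key), sites)
      dmat[cbind(sidx, ridx)] <- blk$disease_signal
      cmat[cbind(sidx, ridx)] <- blk$control_signal
      full <- stats::complete.cases(dmat) & stats::complete.cases(cmat)
      if (sum(full) >= 1L && length(reps) >= 1L) {
        norm <- normalize_channels(cbind(dmat[full, , drop = FALSE],
                                         cmat[full, , drop = FALSE]))
        nd <- norm[, seq_along(reps), drop = FALSE]
        ncl <- norm[, length(reps) + seq_along(reps), drop = FALSE]
        hit <- full[sidx]
        pos <- cbind(match(as.character(site_key)[hit], sites[full]),
                     ridx[hit])
        blk$disease_signal[hit] <- nd[pos]
        blk$control_signal[hit] <- ncl[pos]
      }
      blk
    })) -> out
  rownames(out) <- NULL
  out
}

site_significance_tier <- function(diff, alpha = 0.05) {
  by_protein <- split(diff, diff$protein_id)
  out <- do.call(rbind, lapply(by_protein, function(blk) {
    data.frame(protein_id = blk$protein_id[1L],
               tier = if (any(blk$sig_q)) "q" else
                 if (any(blk$sig_p)) "p" else "none",
               n_sig_analyses = sum(blk$sig_p),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Run the full pipeline and persist every stage
#'
#' File-level orchestration of [infer_core_networks()] plus the validation
#' summary: reads the inputs, writes per-stage TSV tables, GraphML/SIF
#' exports of the core networks, and a machine-readable JSON summary, all
#' stamped with the configuration and seed.
#'
#' @param config Named list: `quant` (path or data frame), `ppi` (path or
#'   `ppi_database`), `out_dir`, `groups`, and optionally `timepoints`,
#'   `log_base`, `sig_mode`, `alpha`, `betweenness_rule`, `k`,
#'   `correlation_threshold`, `min_support`, `welch_mode`, `normalize`,
#'   `seed`, `bootstrap_reps`.
#' @return The [infer_core_networks()] result, invisibly, with a
#'   `validation` element appended.
#' @export
run_pipeline <- function(config) {
  defaults <- list(timepoints = c(1, 3, 6), log_base = 2, sig_mode = "p",
                   alpha = 0.05, betweenness_rule = "positive", k = 2,
                   correlation_threshold = 0.9, min_support = 2L,
                   welch_mode = "two_sample", normalize = TRUE,
                   seed = 1L, bootstrap_reps = 10000L)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  for (nm in c("quant", "ppi", "out_dir", "groups"))
    if (is.null(config[[nm]])) stop("config is missing '", nm, "'")

  quant <- if (is.character(config$quant)) read_quant_table(config$quant)
           else config$quant
  db <- if (is.character(config$ppi)) load_ppi_database(config$ppi)
        else config$ppi
  groups <- unlist(config$groups)
  unknown <- setdiff(unique(quant$model_id), names(groups))
  if (length(unknown) > 0L)
    stop("config error: models without a group assignment: ",
         paste(unknown, collapse = ", "))

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- infer_core_networks(
    quant, db, groups = groups, timepoints = config$timepoints,
    log_base = config$log_base, sig_mode = config$sig_mode,
    alpha = config$alpha, betweenness_rule = config$betweenness_rule,
    k = config$k, correlation_threshold = config$correlation_threshold,
    min_support = config$min_support, welch_mode = config$welch_mode,
    normalize = config$normalize)

  out <- function(...) file.path(config$out_dir, ...)
  write_tsv(res$differential, out("differential.tsv"))
  vec_all <- do.call(rbind, lapply(unique(quant$model_id), function(m)
    trajectory_vectors(quant[quant$model_id == m, , drop = FALSE],
                       timepoints = config$timepoints)))
  write_tsv(vec_all, out("trajectory_vectors.tsv"))
  corr_tab <- do.call(rbind, lapply(names(res$correlated_sets), function(m) {
    ed <- res$correlated_sets[[m]]
    if (nrow(ed) == 0L) return(NULL)
    cbind(model_id = m, ed)
  }))
  if (!is.null(corr_tab)) write_tsv(corr_tab, out("correlated_edges.tsv"))

  for (g in names(res$group_cores))
    export_core_network(res$group_cores[[g]],
                        out(sprintf("core_%s", gsub("[^A-Za-z0-9_.-]", "_", g))))
  export_core_network(res$common_core, out("core_common"))

  if (length(res$common_core$nodes) == 0L)
    warning("common core network is empty")

  validation <- NULL
  n_detected <- length(unique(quant$protein_id))
  gc <- res$group_cores
  if (length(gc) == 2L && length(gc[[1L]]$nodes) > 0L &&
      length(gc[[2L]]$nodes) > 0L) {
    null <- bootstrap_commonness_null(n_detected,
                                      length(gc[[1L]]$nodes),
                                      length(gc[[2L]]$nodes),
                                      reps = config$bootstrap_reps,
                                      seed = config$seed)
    validation <- list(
      commonness = res$commonness,
      null_fit_mean = null$fit_mean, null_fit_sd = null$fit_sd,
      commonness_z = commonness_zscore(res$commonness, null))
  }
  summary <- list(
    config = config[setdiff(names(config), c("quant", "ppi"))],
    n_detected_proteins = n_detected,
    n_analyses = length(unique(interaction(quant$model_id, quant$timepoint,
                                           drop = TRUE))),
    group_cores = lapply(res$group_cores, function(x)
      list(nodes = length(x$nodes), edges = nrow(x$edges))),
    common_core = list(nodes = length(res$common_core$nodes),
                       edges = nrow(res$common_core$edges)),
    detection_counts = as.list(res$detection_counts),
    validation = validation)
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  res$validation <- validation
  invisible(res)
}

#' Export a core network as GraphML, SIF and node/edge tables
#'
#' @param net A `core_network`.
#' @param prefix Output path prefix (writes `<prefix>.graphml`,
#'   `<prefix>.sif`, `<prefix>_nodes.tsv`, `<prefix>_edges.tsv`).
#' @return `prefix`, invisibly.
#' @export
export_core_network <- function(net, prefix) {
  stopifnot(inherits(net, "core_network"))
  node_tab <- data.frame(protein_id = net$nodes, stringsAsFactors = FALSE)
  if (!is.null(net$node_meta))
    node_tab <- merge(node_tab, net$node_meta, by = "protein_id",
                      all.x = TRUE, sort = TRUE)
  write_tsv(node_tab, paste0(prefix, "_nodes.tsv"))
  write_tsv(net$edges, paste0(prefix, "_edges.tsv"))
  write_sif(net$nodes, net$edges, paste0(prefix, ".sif"))
  if (length(net$nodes) > 0L) {
    g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                       vertices = node_tab)
    igraph::V(g)$group_label <- net$group_label
    igraph::write_graph(g, paste0(prefix, ".graphml"), format = "graphml")
  }
  invisible(prefix)
}

#' Core network of a single model
#'
#' The minimal single-model analogue of a group core, used for hold-out and
#' cross-validation comparisons: nodes high in that model (any timepoint)
#' connected by its highly correlated edges.
#'
#' @param high_nodes The model's hub set ([model_high_nodes()]).
#' @param correlated Edge data frame from [correlated_edges_for_model()].
#' @param label Network label.
#' @return A `core_network`.
#' @export
single_model_core_network <- function(high_nodes, correlated,
                                      label = "holdout") {
  assemble_core_network(high_nodes, correlated, group_label = label)
}
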