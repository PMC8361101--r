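#' Default model-to-group assignment of the emulated study
#'
#' Four FTLD knock-in genotypes and four AD transgenic genotypes, the
#' eight-model two-group design whose 8 models x 3 timepoints give 24
#' analyses.
#'
#' @return Named character vector mapping model ID to `"FTLD"` / `"AD"`.
#' @export
default_model_groups <- function() {
  c(PGRN_KI = "FTLD", TDP43_KI = "FTLD", VCP_KI = "FTLD", CHMP2B_KI = "FTLD",
    FAD5x_Tg = "AD", APP_Tg = "AD", PS1_Tg = "AD", PS2_Tg = "AD")
}

# Trajectory shape library, log2 scale, normalized to mean |log2 ratio| = 1
# so that effect_size scales directly to the mean absolute log2 ratio.
trajectory_profile_library <- function() {
  list(increase = c(-1.5, 0, 1.5),
       decrease = c(1.5, 0, -1.5),
       peak     = c(-0.75, 1.5, -0.75))
}

#' Generate a random PPI database
#'
#' @param n_proteins Number of proteins (named `P0001`, `P0002`, ...).
#' @param n_edges Number of undirected edges; must not exceed
#'   `choose(n_proteins, 2)`.
#' @param model `"erdos_renyi"` (uniform random graph) or `"scale_free"`
#'   (power-law degree fitness), the two standard topology families for PPI
#'   surrogates.
#' @param seed Integer seed; the same seed reproduces the same edge set.
#' @return A [ppi_database()].
#' @export
generate_ppi_database <- function(n_proteins, n_edges,
                                  model = c("erdos_renyi", "scale_free"),
                                  seed = 1L) {
  model <- match.arg(model)
  if (n_edges > choose(n_proteins, 2))
    stop(sprintf("n_edges (%d) exceeds the maximum %d for %d proteins",
                 n_edges, choose(n_proteins, 2), n_proteins))
  set.seed(seed)
  g <- if (model == "erdos_renyi") {
    igraph::sample_gnm(n_proteins, n_edges)
  } else {
    igraph::sample_fitness_pl(n_proteins, n_edges, exponent.out = 2.5)
  }
  names_ <- sprintf("P%04d", seq_len(n_proteins))
  el <- igraph::as_edgelist(g, names = FALSE)
  ppi_database(data.frame(a = names_[el[, 1L]], b = names_[el[, 2L]],
                          stringsAsFactors = FALSE))
}

#' Plant a correlated core module into a PPI database
#'
#' Chooses `n_core` proteins, partitions them into profile clusters (one
#' trajectory shape per cluster, drawn from a monotone-increase /
#' monotone-decrease / peak library), and wires each cluster as a cycle
#' plus random chords so every planted node lies on internal shortest
#' paths. The planted core edges of the ground truth are all database edges
#' joining two planted nodes that share a profile: cross-profile pairs have
#' cosine below the selection threshold by construction and are therefore
#' not part of the recoverable truth.
#'
#' @param db A [ppi_database()] to augment.
#' @param n_core Number of planted core proteins (default 30).
#' @param n_clusters Number of profile clusters (default 3, one per shape).
#' @param chords_per_cluster Extra within-cluster edges beyond the cycle.
#' @param effect_size Mean absolute log2 disease/control ratio of planted
#'   sites (default 1.5).
#' @param noise_sd Replicate-level log2 noise SD (default 0.2).
#' @param dropout_rate Per-(site, model, timepoint) detection dropout
#'   probability (default 0.05).
#' @param model_groups Model-to-group map (default [default_model_groups()]).
#' @param seed Integer seed.
#' @return List with the augmented `db` and `truth`, an object of class
#'   `synthetic_truth` (planted nodes/edges, per-site log2 trajectory
#'   profiles, noise and dropout settings).
#' @export
plant_core_module <- function(db, n_core = 30L, n_clusters = 3L,
                              chords_per_cluster = 2L, effect_size = 1.5,
                              noise_sd = 0.2, dropout_rate = 0.05,
                              model_groups = default_model_groups(),
                              seed = 1L) {
  stopifnot(inherits(db, "ppi_database"), n_core >= n_clusters * 3L)
  set.seed(seed)
  core <- sample(db$proteins, n_core)
  cluster <- rep(seq_len(n_clusters), length.out = n_core)
  shapes <- trajectory_profile_library()
  shape_of_cluster <- names(shapes)[rep(seq_along(shapes),
                                        length.out = n_clusters)]

  new_edges <- NULL
  for (cl in seq_len(n_clusters)) {
    members <- core[cluster == cl]
    ring <- c(members, members[1L])
    cyc <- canonical_edges(ring[-length(ring)], ring[-1L])
    chords <- NULL
    if (chords_per_cluster > 0L && length(members) >= 4L) {
      pairs <- utils::combn(members, 2L)
      cand <- canonical_edges(pairs[1L, ], pairs[2L, ])
      cand <- cand[!edge_keys(cand) %in% edge_keys(cyc), , drop = FALSE]
      chords <- cand[sample.int(nrow(cand),
                                min(chords_per_cluster, nrow(cand))), ,
                     drop = FALSE]
    }
    new_edges <- rbind(new_edges, cyc, chords)
  }
  ed <- db$edges[c("a", "b")]
  ed <- rbind(ed, new_edges)
  ed <- ed[!duplicated(edge_keys(ed)), , drop = FALSE]
  db2 <- ppi_database(ed)

  # truth edges: db edges between same-cluster (same-profile) planted nodes
  cl_of <- stats::setNames(cluster, core)
  both_core <- db2$edges$a %in% core & db2$edges$b %in% core
  same_cl <- both_core &
    cl_of[db2$edges$a] == cl_of[db2$edges$b]
  truth_edges <- db2$edges[which(same_cl), c("a", "b"), drop = FALSE]
  rownames(truth_edges) <- NULL

  profiles <- do.call(rbind, lapply(seq_len(n_core), function(i) {
    sh <- shapes[[shape_of_cluster[cluster[i]]]]
    data.frame(protein_id = core[i], site = "S1",
               cluster = cluster[i],
               profile = shape_of_cluster[cluster[i]],
               log2_t1 = effect_size * sh[1L],
               log2_t2 = effect_size * sh[2L],
               log2_t3 = effect_size * sh[3L],
               stringsAsFactors = FALSE)
  }))
  truth <- structure(list(planted_core_nodes = sort(core),
                          planted_core_edges = truth_edges,
                          trajectory_profiles = profiles,
                          model_groups = model_groups,
                          effect_size = effect_size, noise_sd = noise_sd,
                          dropout_rate = dropout_rate, seed = seed),
                     class = "synthetic_truth")
  list(db = db2, truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "Synthetic truth: %d planted nodes, %d planted edges, effect %.2f log2, noise sd %.2f, dropout %.2f\n",
    length(x$planted_core_nodes), nrow(x$planted_core_edges),
    x$effect_size, x$noise_sd, x$dropout_rate))
  invisible(x)
}

#' Generate a multi-model phosphoproteome quantification dataset
#'
#' Emulates the structure of the study data: for every model, timepoint and
#' replicate, each phosphosite gets a disease signal
#' `baseline * 2^(true log2 ratio + N(0, noise_sd))` against a fixed
#' control baseline. Background sites have true log2 ratio 0 at every
#' timepoint; planted core sites follow their cluster's trajectory profile,
#' identically across all models of both groups, so their pairwise cosine
#' correlations stay above the selection threshold in expectation.
#' Detection dropout removes a (site, model, timepoint) block independently
#' with probability `dropout_rate`.
#'
#' @param truth A `synthetic_truth` from [plant_core_module()].
#' @param db The matching [ppi_database()] (planted sites are attached to
#'   its proteins; background sites to proteins outside the planted core).
#' @param n_background_sites Number of unchanged background phosphosites
#'   (default 500).
#' @param timepoints Timepoints in months (default `c(1, 3, 6)`).
#' @param n_replicates Replicate animals per model and timepoint (default 3).
#' @param baseline Control signal intensity (arbitrary units).
#' @param seed Integer seed; identical seeds give identical tables.
#' @return Quantification data frame (columns as in [read_quant_table()]).
#' @export
generate_phospho_dataset <- function(truth, db, n_background_sites = 500L,
                                     timepoints = c(1, 3, 6),
                                     n_replicates = 3L, baseline = 1000,
                                     seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"), inherits(db, "ppi_database"))
  if (!all(truth$planted_core_nodes %in% db$proteins))
    stop("planted nodes must belong to the database protein universe")
  if (!all(edge_keys(truth$planted_core_edges) %in% edge_keys(db$edges)))
    stop("planted edges must belong to the database edge set")
  set.seed(seed)

  background_pool <- setdiff(db$proteins, truth$planted_core_nodes)
  bg_proteins <- sample(background_pool, n_background_sites, replace = TRUE)
  bg_sites <- paste0("S", stats::ave(seq_along(bg_proteins), bg_proteins,
                                     FUN = seq_along))

  prof <- truth$trajectory_profiles
  site_tab <- rbind(
    data.frame(protein_id = prof$protein_id, site = prof$site,
               log2_t1 = prof$log2_t1, log2_t2 = prof$log2_t2,
               log2_t3 = prof$log2_t3, stringsAsFactors = FALSE),
    data.frame(protein_id = bg_proteins, site = bg_sites,
               log2_t1 = 0, log2_t2 = 0, log2_t3 = 0,
               stringsAsFactors = FALSE))
  true_log2 <- as.matrix(site_tab[c("log2_t1", "log2_t2", "log2_t3")])
  n_sites <- nrow(site_tab)

  models <- names(truth$model_groups)
  out <- vector("list", length(models) * length(timepoints))
  idx <- 0L
  for (m in models) {
    for (ti in seq_along(timepoints)) {
      detected <- stats::runif(n_sites) >= truth$dropout_rate
      if (!any(detected)) next
      n_det <- sum(detected)
      blk <- site_tab[detected, c("protein_id", "site"), drop = FALSE]
      blk <- blk[rep(seq_len(n_det), each = n_replicates), , drop = FALSE]
      blk$model_id <- m
      blk$timepoint <- timepoints[ti]
      blk$replicate <- rep(seq_len(n_replicates), n_det)
      mu <- rep(true_log2[detected, ti], each = n_replicates)
      blk$disease_signal <-
        baseline * 2^(mu + stats::rnorm(n_det * n_replicates,
                                        sd = truth$noise_sd))
      blk$control_signal <- baseline
      idx <- idx + 1L
      out[[idx]] <- blk
    }
  }
  out <- do.call(rbind, out[seq_len(idx)])
  rownames(out) <- NULL
  out
}

#' Convenience wrapper: full synthetic study
#'
#' Generates a PPI database, plants the core module and simulates the
#' quantification table under the default study conditions (8 models in two
#' groups, 3 timepoints, 3 replicates, 500 background + 30 planted sites).
#'
#' @param n_proteins,n_edges PPI database size (defaults 800 / 2000).
#' @param n_core,n_background_sites Planted and background site counts.
#' @param effect_size,noise_sd,dropout_rate Generator parameters (see
#'   [plant_core_module()]).
#' @param model_groups Model-to-group map.
#' @param timepoints,n_replicates Study layout.
#' @param seed Integer seed controlling the whole simulation.
#' @return List: `quant`, `db`, `truth`.
#' @export
simulate_study <- function(n_proteins = 800L, n_edges = 2000L,
                           n_core = 30L, n_background_sites = 500L,
                           effect_size = 1.5, noise_sd = 0.2,
                           dropout_rate = 0.05,
                           model_groups = default_model_groups(),
                           timepoints = c(1, 3, 6), n_replicates = 3L,
                           seed = 1L) {
  db0 <- generate_ppi_database(n_proteins, n_edges, seed = seed)
  planted <- plant_core_module(db0, n_core = n_core,
                               effect_size = effect_size,
                               noise_sd = noise_sd,
                               dropout_rate = dropout_rate,
                               model_groups = model_groups,
                               seed = seed + 1L)
  quant <- generate_phospho_dataset(planted$truth, planted$db,
                                    n_background_sites = n_background_sites,
                                    timepoints = timepoints,
                                    n_replicates = n_replicates,
                                    seed = seed + 2L)
  list(quant = quant, db = planted$db, truth = planted$truth)
}

#' Precision and recall of an inferred core network against planted truth
#'
#' @param inferred A `core_network`.
#' @param truth A `synthetic_truth`.
#' @return List with `node_precision`, `node_recall`, `edge_precision`,
#'   `edge_recall`, `node_f1`, `edge_f1`. Precision is `NA` when the
#'   inferred set is empty; F1 is 0 then.
#' @export
evaluate_recovery <- function(inferred, truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (length(truth$planted_core_nodes) == 0L)
    stop("truth has no planted nodes")
  pr <- function(est, tru) {
    tp <- length(intersect(est, tru))
    precision <- if (length(est) == 0L) NA_real_ else tp / length(est)
    recall <- tp / length(tru)
    f1 <- if (length(est) == 0L || tp == 0L) 0
          else 2 * precision * recall / (precision + recall)
    list(precision = precision, recall = recall, f1 = f1)
  }
  n <- pr(inferred$nodes, truth$planted_core_nodes)
  e <- pr(edge_keys(canonical_edges(inferred$edges$a, inferred$edges$b)),
          edge_keys(truth$planted_core_edges))
  list(node_precision = n$precision, node_recall = n$recall,
       node_f1 = n$f1, edge_precision = e$precision,
       edge_recall = e$recall, edge_f1 = e$f1)
}
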