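support_counts_by_group <- function(member_sets, groups) {
  # member_sets: named list model -> character keys; groups: model -> group
  models <- names(member_sets)
  if (is.null(models) || !all(models %in% names(groups)))
    stop("every model must be assigned to a group")
  keys <- sort(unique(unlist(member_sets, use.names = FALSE)))
  out <- list()
  for (g in unique(groups[models])) {
    in_g <- models[groups[models] == g]
    hits <- matrix(vapply(in_g, function(m) keys %in% member_sets[[m]],
                          logical(length(keys))),
                   nrow = length(keys))
    out[[g]] <- stats::setNames(as.integer(rowSums(hits)), keys)
  }
  out
}

check_min_support <- function(min_support, groups, models) {
  if (is.null(models) || !all(models %in% names(groups)))
    stop("every model must be assigned to a group")
  gs <- unique(groups[models])
  ms <- if (length(min_support) == 1L && is.null(names(min_support)))
    stats::setNames(rep(as.integer(min_support), length(gs)), gs)
  else {
    if (!all(gs %in% names(min_support)))
      stop("min_support must cover every group")
    stats::setNames(as.integer(min_support[gs]), gs)
  }
  for (g in gs) {
    n_models <- sum(groups[models] == g)
    if (ms[[g]] > n_models)
      stop(sprintf("min_support (%d) exceeds the number of models in group %s (%d)",
                   ms[[g]], g, n_models))
  }
  ms
}

#' Select core nodes from per-model hub sets
#'
#' A protein is a core node when it is a high-betweenness node in at least
#' `min_support` models of *every* group supplied. Passing the models of a
#' single group yields that group's core nodes; passing both disease groups
#' yields the candidates for the common core (the "at least 2 FTLD and at
#' least 2 AD models" rule with the defaults).
#'
#' @param high_sets Named list, one character vector of hub proteins per
#'   model (see [model_high_nodes()]).
#' @param groups Named character vector mapping model ID to group label.
#' @param min_support Required number of supporting models, a single integer
#'   or a named per-group vector. Default 2.
#' @return Character vector of core node IDs (sorted).
#' @export
core_nodes <- function(high_sets, groups, min_support = 2L) {
  models <- names(high_sets)
  ms <- check_min_support(min_support, groups, models)
  counts <- support_counts_by_group(high_sets, groups)
  keys <- sort(unique(unlist(high_sets, use.names = FALSE)))
  keep <- rep(TRUE, length(keys))
  for (g in names(counts)) keep <- keep & counts[[g]][keys] >= ms[[g]]
  keys[keep]
}

#' Select core edges from per-model correlated edge sets
#'
#' Same support rule as [core_nodes()], applied to protein-level undirected
#' edges ("highly correlated" in at least `min_support` models of every
#' group).
#'
#' @param correlated_sets Named list, one edge data frame (`a`, `b`) per
#'   model (see [correlated_edges_for_model()]).
#' @param groups Named character vector mapping model ID to group label.
#' @param min_support As in [core_nodes()].
#' @return Data frame of core edges (`a`, `b`), canonical order.
#' @export
core_edges <- function(correlated_sets, groups, min_support = 2L) {
  key_sets <- lapply(correlated_sets, function(ed) {
    if (nrow(ed) == 0L) return(character(0))
    unique(edge_keys(canonical_edges(ed$a, ed$b)))
  })
  keys <- core_nodes(key_sets, groups, min_support)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  data.frame(a = vapply(parts, `[`, "", 1L),
             b = vapply(parts, `[`, "", 2L), stringsAsFactors = FALSE)
}

#' Assemble a core network from core nodes and core edges
#'
#' Keeps only core edges whose both endpoints are core nodes, then drops
#' core nodes left without any incident edge: only nodes connected by core
#' edges belong to the core network. The operation is idempotent and an
#' empty result is a valid outcome.
#'
#' @param nodes Character vector of core node IDs.
#' @param edges Data frame of core edges (`a`, `b`).
#' @param group_label Label such as `"AD"`, `"FTLD"` or `"AD-FTLD-common"`.
#' @param node_meta Optional data frame of per-node metadata (support
#'   counts, detection counts, significance tier), keyed by a `protein_id`
#'   column; rows are subset to the surviving nodes.
#' @return Object of class `core_network`: `group_label`, `nodes`, `edges`,
#'   `node_meta`.
#' @export
assemble_core_network <- function(nodes, edges, group_label = "core",
                                  node_meta = NULL) {
  nodes <- unique(as.character(nodes))
  edges <- canonical_edges(as.character(edges$a), as.character(edges$b))
  edges <- edges[edges$a %in% nodes & edges$b %in% nodes, , drop = FALSE]
  edges <- edges[!duplicated(edge_keys(edges)), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- sort(intersect(nodes, c(edges$a, edges$b)))
  if (!is.null(node_meta))
    node_meta <- node_meta[node_meta$protein_id %in% nodes, , drop = FALSE]
  structure(list(group_label = group_label, nodes = nodes, edges = edges,
                 node_meta = node_meta),
            class = "core_network")
}

#' @export
print.core_network <- function(x, ...) {
  cat(sprintf("Core network [%s]: %d nodes, %d edges\n",
              x$group_label, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

core_nodeset <- function(x) {
  if (inherits(x, "core_network")) x$nodes else unique(as.character(x))
}

#' Commonness of two core networks
#'
#' Percentage node overlap, 100 * |A intersect B| / |A union B|. The union
#' denominator is fixed by the worked arithmetic of the method: 43 shared
#' nodes out of core sets of 73 and 62 give 100 * 43 / 92 = 46.7%.
#'
#' @param net_a,net_b `core_network` objects or character node vectors.
#' @return Percentage in \[0, 100\].
#' @export
commonness <- function(net_a, net_b) {
  a <- core_nodeset(net_a)
  b <- core_nodeset(net_b)
  if (length(a) == 0L && length(b) == 0L)
    stop("commonness is undefined for two empty networks")
  100 * length(intersect(a, b)) / length(union(a, b))
}

#' Subtract one core network from another
#'
#' Nodes of A not present in B; edges of A with both endpoints surviving;
#' isolated nodes then dropped. Subtracting the common core from a group
#' core isolates that group's specific component.
#'
#' @param net_a,net_b `core_network` objects.
#' @return A `core_network` labelled `"<A> minus <B>"`.
#' @export
network_difference <- function(net_a, net_b) {
  stopifnot(inherits(net_a, "core_network"), inherits(net_b, "core_network"))
  keep <- setdiff(net_a$nodes, net_b$nodes)
  assemble_core_network(keep, net_a$edges,
                        group_label = paste(net_a$group_label, "minus",
                                            net_b$group_label),
                        node_meta = net_a$node_meta)
}

#' Detection support per node across analyses
#'
#' Counts, for each node, the number of analyses (model x timepoint mass
#' runs) in which the protein was detected at all, regardless of
#' significance.
#'
#' @param analyses List of character vectors, one detected-protein set per
#'   analysis.
#' @param nodes Character vector of node IDs.
#' @return Named integer vector over `nodes`.
#' @export
detection_support_counts <- function(analyses, nodes) {
  nodes <- as.character(nodes)
  if (length(nodes) == 0L) return(stats::setNames(integer(0), character(0)))
  hits <- matrix(vapply(analyses, function(s) nodes %in% s,
                        logical(length(nodes))),
                 nrow = length(nodes))
  stats::setNames(as.integer(rowSums(hits)), nodes)
}
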