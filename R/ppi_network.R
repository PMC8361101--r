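canonical_edges <- function(a, b) {
  data.frame(a = pmin(a, b), b = pmax(a, b), stringsAsFactors = FALSE)
}

edge_keys <- function(edges) paste(edges$a, edges$b, sep = "\r")

#' Construct a PPI database from an edge table
#'
#' Edges are undirected: pairs are stored in canonical order and
#' deduplicated; self-loops are dropped with a warning. Optional interaction
#' type labels (e.g. MINT interaction types) are kept per edge.
#'
#' @param edges Data frame whose first two columns are protein IDs; an
#'   optional third column carries an interaction type label.
#' @return Object of class `ppi_database` with elements `edges` (data frame
#'   `a`, `b`, optionally `type`) and `proteins` (character vector).
#' @export
ppi_database <- function(edges) {
  stopifnot(is.data.frame(edges), ncol(edges) >= 2L)
  a <- as.character(edges[[1L]])
  b <- as.character(edges[[2L]])
  loops <- a == b
  if (any(loops))
    warning(sprintf("dropped %d self-loop(s)", sum(loops)))
  ed <- canonical_edges(a[!loops], b[!loops])
  if (ncol(edges) >= 3L) ed$type <- as.character(edges[[3L]])[!loops]
  ed <- ed[!duplicated(edge_keys(ed)), , drop = FALSE]
  rownames(ed) <- NULL
  structure(list(edges = ed, proteins = sort(unique(c(ed$a, ed$b)))),
            class = "ppi_database")
}

#' Load a PPI database from a flat edge-list file
#'
#' Expects 2-3 tab-separated columns per line (`protein_a`, `protein_b`,
#' optional interaction type), `#` comments allowed, no header by default --
#' the layout of MINT/STRING-style exports.
#'
#' @param path File path.
#' @param header Whether the first line is a header row.
#' @return A [ppi_database()].
#' @export
load_ppi_database <- function(path, header = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = header, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L)
    stop("PPI edge list needs at least two columns: ", path)
  bad <- which(is.na(tab[[1L]]) | is.na(tab[[2L]]) |
                 tab[[1L]] == "" | tab[[2L]] == "")
  if (length(bad) > 0L)
    stop(sprintf("malformed edge at line %d of %s", bad[1L] + header, path))
  ppi_database(tab)
}

#' @export
print.ppi_database <- function(x, ...) {
  cat(sprintf("PPI database: %d proteins, %d undirected edges\n",
              length(x$proteins), nrow(x$edges)))
  invisible(x)
}

#' Build a pathological PPI subnetwork around changed proteins
#'
#' The network contains every seed (changed) protein found in the database,
#' every database edge between two seeds, and every non-seed protein that is
#' adjacent to at least `min_seed_neighbors` seeds, together with its edges
#' to those seeds -- i.e. at most one extra node may be interposed between
#' seeds, and only where it bridges them. Seeds absent from the database are
#' retained as isolated nodes so they stay visible downstream (they can never
#' score as hubs).
#'
#' @param seed_proteins Character vector of changed protein IDs.
#' @param db A [ppi_database()].
#' @param min_seed_neighbors Seed adjacency required of a bridge node;
#'   default 2 (a pendant addition adds no path information). Set to 1 for
#'   sensitivity analysis.
#' @param model_id,timepoint Optional labels carried as metadata.
#' @return Object of class `pathological_network`: `graph` (igraph), `seeds`,
#'   `nodes`, `edges`, plus the labels.
#' @export
build_pathological_network <- function(seed_proteins, db,
                                       min_seed_neighbors = 2L,
                                       model_id = NA_character_,
                                       timepoint = NA) {
  seeds <- sort(unique(as.character(seed_proteins)))
  if (length(seeds) == 0L) stop("seed set is empty")
  stopifnot(inherits(db, "ppi_database"))

  ed <- db$edges
  a_seed <- ed$a %in% seeds
  b_seed <- ed$b %in% seeds
  seed_seed <- ed[a_seed & b_seed, c("a", "b"), drop = FALSE]

  # bridge candidates: non-seed endpoint of a seed--non-seed edge
  half <- rbind(
    data.frame(seed = ed$a[a_seed & !b_seed], other = ed$b[a_seed & !b_seed],
               stringsAsFactors = FALSE),
    data.frame(seed = ed$b[b_seed & !a_seed], other = ed$a[b_seed & !a_seed],
               stringsAsFactors = FALSE))
  n_seed_nbrs <- table(half$other[!duplicated(half)])
  bridges <- names(n_seed_nbrs)[n_seed_nbrs >= min_seed_neighbors]
  bridge_edges <- canonical_edges(half$seed[half$other %in% bridges],
                                 half$other[half$other %in% bridges])

  edges <- rbind(seed_seed, bridge_edges)
  edges <- edges[!duplicated(edge_keys(edges)), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- sort(unique(c(seeds, edges$a, edges$b)))

  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  igraph::V(g)$seed <- nodes %in% seeds
  structure(list(graph = g, seeds = seeds, nodes = nodes, edges = edges,
                 model_id = model_id, timepoint = timepoint),
            class = "pathological_network")
}

#' @export
print.pathological_network <- function(x, ...) {
  cat(sprintf("Pathological network%s: %d nodes (%d seeds), %d edges\n",
              if (is.na(x$model_id)) "" else
                sprintf(" [%s, %s months]", x$model_id, x$timepoint),
              length(x$nodes), length(x$seeds), nrow(x$edges)))
  invisible(x)
}

#' Betweenness centrality of a pathological network
#'
#' Unnormalized shortest-path betweenness on the undirected, unweighted
#' graph; each unordered source-target pair is counted once and tied
#' geodesics share credit fractionally.
#'
#' @param net A [build_pathological_network()] result (or an igraph graph).
#' @return Named numeric vector, one score per node.
#' @export
betweenness_scores <- function(net) {
  g <- if (inherits(net, "pathological_network")) net$graph else net
  if (igraph::vcount(g) == 0L) return(stats::setNames(numeric(0), character(0)))
  b <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  stats::setNames(as.numeric(b), igraph::V(g)$name)
}

#' Select high-betweenness (hub) nodes
#'
#' Either every node with a positive score (`rule = "positive"`, the loose
#' condition) or nodes exceeding mean + k * SD of the scores within the same
#' network (`rule = "z"`; sample SD, denominator n - 1).
#'
#' @param scores Named numeric vector from [betweenness_scores()].
#' @param rule `"z"` or `"positive"`.
#' @param k SD multiplier for the `"z"` rule (field practice: 2 or 3).
#' @return Character vector of selected node names.
#' @export
high_betweenness_nodes <- function(scores, rule = c("z", "positive"), k = 2) {
  rule <- match.arg(rule)
  if (length(scores) == 0L) stop("scores must be non-empty")
  if (rule == "positive") return(names(scores)[scores > 0])
  if (length(scores) < 2L)
    stop("the z rule needs at least two scored nodes (SD undefined)")
  names(scores)[scores > mean(scores) + k * stats::sd(scores)]
}

#' Per-model hub set across timepoint networks
#'
#' A protein counts as "high" for a model if it is a high-betweenness node in
#' at least one of that model's timepoint networks (OR-aggregation over
#' time). By default only a network's seed (changed) proteins are eligible:
#' core-node candidates must themselves carry changed phosphosites, while
#' bridge nodes only contribute topology. The mean/SD for the `"z"` rule are
#' always taken over all scored nodes of the network.
#'
#' @param nets List of `pathological_network` objects for one model.
#' @param rule,k Passed to [high_betweenness_nodes()].
#' @param seeds_only Restrict eligibility to seed nodes (default `TRUE`).
#' @return Character vector of hub proteins for the model.
#' @export
model_high_nodes <- function(nets, rule = c("z", "positive"), k = 2,
                             seeds_only = TRUE) {
  rule <- match.arg(rule)
  high <- character(0)
  for (net in nets) {
    sc <- betweenness_scores(net)
    if (length(sc) == 0L) next
    if (rule == "z" && length(sc) < 2L) next
    h <- high_betweenness_nodes(sc, rule = rule, k = k)
    if (seeds_only) h <- intersect(h, net$seeds)
    high <- union(high, h)
  }
  sort(high)
}

#' Union of a model's timepoint network edges
#'
#' @param nets List of `pathological_network` objects.
#' @return Data frame of unique canonical edges (`a`, `b`).
#' @export
model_union_edges <- function(nets) {
  ed <- do.call(rbind, lapply(nets, function(n) n$edges))
  if (is.null(ed))
    return(data.frame(a = character(0), b = character(0),
                      stringsAsFactors = FALSE))
  ed <- ed[!duplicated(edge_keys(ed)), , drop = FALSE]
  rownames(ed) <- NULL
  ed
}
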