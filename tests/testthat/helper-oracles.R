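# Independent oracles used to check the package implementations.

# Textbook Welch statistic: t, Welch-Satterthwaite df, two-sided p from pt().
oracle_welch <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- var(a) / na; vb <- var(b) / nb
  t_stat <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  list(t = t_stat, df = df, p = 2 * pt(-abs(t_stat), df))
}

# BH step-up by the definitional formula: q_(i) = min_{j>=i} p_(j) m / j,
# capped at 1, returned in input order.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- p[ord] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  pmin(q_sorted, 1)[order(ord)]
}

# Betweenness by exhaustive simple-path enumeration (feasible for n <= 7):
# for every unordered pair, enumerate all simple paths by DFS, keep the
# shortest, and give each interior node fractional credit.
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  bw <- numeric(n)
  if (n < 3L) return(bw)
  all_paths <- function(s, t) {
    paths <- list()
    dfs <- function(v, visited, path) {
      if (v == t) {
        paths[[length(paths) + 1L]] <<- path
        return(invisible())
      }
      for (w in which(adj[v, ] == 1L)) {
        if (!visited[w]) dfs(w, `[<-`(visited, w, TRUE), c(path, w))
      }
    }
    start <- rep(FALSE, n)
    dfs(s, `[<-`(start, s, TRUE), s)
    paths
  }
  for (s in seq_len(n - 1L)) for (t in (s + 1L):n) {
    ps <- all_paths(s, t)
    if (length(ps) == 0L) next
    lens <- vapply(ps, length, integer(1))
    shortest <- ps[lens == min(lens)]
    for (p in shortest) {
      interior <- p[-c(1L, length(p))]
      bw[interior] <- bw[interior] + 1 / length(shortest)
    }
  }
  bw
}

# Random simple undirected graph as an adjacency matrix.
random_adjacency <- function(n, p_edge = 0.5) {
  adj <- matrix(0L, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (runif(1) < p_edge) adj[i, j] <- adj[j, i] <- 1L
  }
  adj
}

adjacency_to_network <- function(adj) {
  nodes <- sprintf("N%d", seq_len(nrow(adj)))
  idx <- which(upper.tri(adj) & adj == 1L, arr.ind = TRUE)
  edges <- data.frame(a = nodes[idx[, 1L]], b = nodes[idx[, 2L]],
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  g
}

# Tiny quant-table builder for targeted fixtures: one row per replicate.
make_quant <- function(protein, site, model, timepoint, ratios,
                       baseline = 100) {
  do.call(rbind, lapply(seq_along(ratios), function(i) {
    data.frame(protein_id = protein, site = site, model_id = model,
               timepoint = timepoint, replicate = i,
               disease_signal = baseline * ratios[i],
               control_signal = baseline, stringsAsFactors = FALSE)
  }))
}

edge_keys_for_test <- function(edges) paste(edges$a, edges$b, sep = "|")
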