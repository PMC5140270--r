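# Brute-force oracles, independent of the package implementation: plain
# adjacency matrices, hand-rolled BFS and definition-level statistics.

oracle_adjacency <- function(edge_table, nodes, directed = TRUE) {
  n <- length(nodes)
  A <- matrix(0L, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edge_table))) {
    A[edge_table$pre[i], edge_table$post[i]] <- 1L
    if (!directed) A[edge_table$post[i], edge_table$pre[i]] <- 1L
  }
  A
}

# all-pairs BFS hop distances on an adjacency matrix
oracle_bfs_all <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n, dimnames = dimnames(A))
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    frontier <- s
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (v in frontier) {
        for (w in which(A[v, ] > 0)) {
          if (is.infinite(dist[w])) {
            dist[w] <- dist[v] + 1
            nxt <- c(nxt, w)
          }
        }
      }
      frontier <- nxt
    }
    D[s, ] <- dist
  }
  D
}

# every Table-2-style statistic from first principles
oracle_network_stats <- function(edge_table, directed = TRUE) {
  nodes <- sort(unique(c(edge_table$pre, edge_table$post)))
  n <- length(nodes)
  A <- oracle_adjacency(edge_table, nodes, directed)
  loops <- sum(edge_table$pre == edge_table$post)
  U <- (A + t(A)) > 0
  diag(U) <- FALSE

  k <- rowSums(U)
  local_cc <- vapply(seq_len(n), function(v) {
    nb <- which(U[v, ])
    if (length(nb) < 2) return(0)
    sub <- U[nb, nb, drop = FALSE]
    sum(sub) / (length(nb) * (length(nb) - 1))
  }, numeric(1))
  Anl <- A
  diag(Anl) <- 0L
  D <- oracle_bfs_all(Anl)
  diag(D) <- Inf
  finite <- is.finite(D)
  ecc <- apply(D, 1, function(r) if (any(is.finite(r))) max(r[is.finite(r)]) else NA)
  # weak components by BFS on the symmetrised graph
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    frontier <- s
    comp[s] <- cid
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (v in frontier) {
        for (w in which(U[v, ] | A[v, ] > 0 | A[, v] > 0)) {
          if (is.na(comp[w])) {
            comp[w] <- cid
            nxt <- c(nxt, w)
          }
        }
      }
      frontier <- nxt
    }
  }
  simple_pairs <- sum(Anl > 0)
  dens_u <- sum(U) / (n * (n - 1))
  list(
    clustering_coefficient = if (n >= 3) mean(local_cc) else NA_real_,
    n_connected_components = max(comp),
    diameter = if (any(!is.na(ecc))) max(ecc, na.rm = TRUE) else NA_real_,
    radius = if (any(!is.na(ecc))) min(ecc, na.rm = TRUE) else NA_real_,
    n_shortest_paths = sum(finite),
    pct_pairs_with_shortest_path = 100 * sum(finite) / (n * (n - 1)),
    characteristic_path_length = if (any(finite)) mean(D[finite]) else NA_real_,
    avg_neighbors = mean(k),
    n_nodes = n,
    density = if (directed) simple_pairs / (n * (n - 1)) else dens_u,
    heterogeneity = sqrt(mean((k - mean(k))^2)) / mean(k),
    n_self_loops = loops,
    centralization = if (n > 2) (n / (n - 2)) * (max(k) / (n - 1) - dens_u) else NA_real_
  )
}

# exhaustive enumeration of all minimal-hop paths from any source to any
# sink, by depth-limited DFS after BFS gives the minimum
oracle_shortest_arcs <- function(edge_table, sources, sinks) {
  nodes <- sort(unique(c(edge_table$pre, edge_table$post)))
  sources <- intersect(sources, nodes)
  sinks <- intersect(sinks, nodes)
  if (length(sources) == 0 || length(sinks) == 0) {
    return(list(min_hops = NA, paths = list()))
  }
  A <- oracle_adjacency(edge_table, nodes, directed = TRUE)
  diag(A) <- 0L
  D <- oracle_bfs_all(A)
  d_sub <- D[sources, sinks, drop = FALSE]
  d_sub[d_sub == 0] <- Inf
  if (!any(is.finite(d_sub))) return(list(min_hops = NA, paths = list()))
  min_hops <- min(d_sub[is.finite(d_sub)])
  paths <- list()
  dfs <- function(path, depth) {
    v <- path[length(path)]
    if (depth == min_hops) {
      if (v %in% sinks) paths[[length(paths) + 1]] <<- path
      return(invisible())
    }
    for (w in nodes[A[v, ] > 0]) {
      if (!w %in% path) dfs(c(path, w), depth + 1)
    }
  }
  for (s in sources) dfs(s, 0)
  keep <- vapply(paths, function(p) length(p) == min_hops + 1, logical(1))
  list(min_hops = min_hops, paths = paths[keep])
}

random_edge_table <- function(n_nodes, n_edges, seed, allow_loops = TRUE,
                              kind = "chemical") {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  pre <- sample(nodes, n_edges, replace = TRUE)
  post <- sample(nodes, n_edges, replace = TRUE)
  if (!allow_loops) {
    while (any(pre == post)) {
      post[pre == post] <- sample(nodes, sum(pre == post), replace = TRUE)
    }
  }
  tibble::tibble(pre = pre, post = post, kind = kind,
                 n_contacts = 1L, total_sections = 3L,
                 cumulative_depth_um = round(stats::runif(n_edges, 0.06, 2), 3)) |>
    dplyr::distinct(pre, post, .keep_all = TRUE)
}
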