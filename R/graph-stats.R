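cns_regions <- c("BV", "neck", "MG", "CNC")

edge_table_graph <- function(edge_table, directed = TRUE) {
  nodes <- sort(unique(c(edge_table$pre, edge_table$post)))
  igraph::graph_from_data_frame(
    edge_table[, c("pre", "post")], directed = directed,
    vertices = data.frame(name = nodes)
  )
}

restrict_edges <- function(edge_table, roster, scope) {
  if (scope == "full") return(edge_table)
  keep_ids <- roster$cell_id[roster$region %in% cns_regions &
                               roster$is_neuron %in% TRUE]
  edge_table[edge_table$pre %in% keep_ids & edge_table$post %in% keep_ids, ,
             drop = FALSE]
}

#' Whole-network statistics
#'
#' The statistic suite conventionally reported for connectome graphs
#' (clustering coefficient, connected components, diameter, radius,
#' reachable-pair share, characteristic path length, average neighbours,
#' density, heterogeneity, centralization, self-loop count), under the
#' following documented conventions: shortest paths are unweighted hop
#' counts; the characteristic path length averages over ordered reachable
#' pairs of distinct nodes; components use weak connectivity; diameter and
#' radius are the max/min node eccentricities over reachable pairs;
#' clustering, average neighbours, heterogeneity and centralization are
#' computed on the undirected simple graph with self-loops removed, with
#' nodes of fewer than two neighbours contributing zero clustering;
#' heterogeneity is SD(degree)/mean(degree) and centralization is
#' `(n/(n-2)) * (max(k)/(n-1) - density)` on the undirected view.
#'
#' @param edge_table output of [build_edge_table()].
#' @param mode treat edges as `"directed"` (chemical) or `"undirected"`
#'   (gap junctions).
#' @param roster roster tibble; required for `scope = "cns_only"`.
#' @param scope `"full"` or `"cns_only"` (CNS neurons only, i.e. neurons
#'   of the brain vesicle, neck, motor ganglion and caudal nerve cord).
#' @param n_multi_edge_pairs optionally carry the [multi_edge_pairs()]
#'   count into the report (a depth-aggregated edge table no longer knows
#'   contact multiplicities).
#' @param directed_clustering also report a directed clustering variant
#'   (directed edges among undirected neighbours over `k*(k-1)`).
#' @return one-row tibble of class `network_stat_report`.
#' @export
network_stats <- function(edge_table, mode = c("directed", "undirected"),
                          roster = NULL, scope = c("full", "cns_only"),
                          n_multi_edge_pairs = NA_integer_,
                          directed_clustering = FALSE) {
  mode <- match.arg(mode)
  scope <- match.arg(scope)
  if (scope == "cns_only") {
    if (is.null(roster)) abort("scope = 'cns_only' requires a roster")
    edge_table <- restrict_edges(edge_table, roster, scope)
  }
  if (nrow(edge_table) == 0) abort("empty graph")
  directed <- mode == "directed"
  g <- edge_table_graph(edge_table, directed = directed)
  n <- igraph::vcount(g)
  n_loops <- sum(edge_table$pre == edge_table$post)

  # undirected simple view for neighbourhood statistics
  gu <- igraph::as_undirected(igraph::simplify(g, remove.loops = TRUE),
                              mode = "collapse")
  k <- igraph::degree(gu)
  clustering <- if (n < 3) NA_real_ else {
    loc <- igraph::transitivity(gu, type = "local", isolates = "zero")
    mean(loc)
  }

  d <- igraph::distances(g, mode = "out")
  diag(d) <- Inf                      # ordered pairs of distinct nodes
  finite <- is.finite(d)
  n_pairs <- if (directed) n * (n - 1) else n * (n - 1)
  n_reach <- sum(finite)
  cpl <- if (n_reach > 0) mean(d[finite]) else NA_real_
  ecc <- apply(d, 1, function(r) if (any(is.finite(r))) max(r[is.finite(r)]) else NA_real_)
  diameter <- if (any(!is.na(ecc))) max(ecc, na.rm = TRUE) else NA_real_
  radius <- if (any(!is.na(ecc))) min(ecc, na.rm = TRUE) else NA_real_

  dens_u <- sum(k) / 2 / (n * (n - 1) / 2)
  simple_pairs <- nrow(dplyr::distinct(
    edge_table[edge_table$pre != edge_table$post, c("pre", "post")]))
  density <- if (directed) simple_pairs / (n * (n - 1)) else dens_u
  heterogeneity <- if (mean(k) > 0) pop_sd(k) / mean(k) else NA_real_
  centralization <- if (n > 2) (n / (n - 2)) * (max(k) / (n - 1) - dens_u) else NA_real_

  out <- tibble::tibble(
    mode = mode, scope = scope,
    clustering_coefficient = clustering,
    n_connected_components = as.integer(igraph::count_components(g, mode = "weak")),
    diameter = diameter, radius = radius,
    n_shortest_paths = n_reach,
    pct_pairs_with_shortest_path = 100 * n_reach / n_pairs,
    characteristic_path_length = cpl,
    avg_neighbors = mean(k),
    n_nodes = n, density = density,
    heterogeneity = heterogeneity,
    n_self_loops = n_loops,
    n_multi_edge_pairs = n_multi_edge_pairs,
    centralization = centralization
  )
  if (directed_clustering) {
    out$clustering_coefficient_directed <- directed_local_clustering(edge_table)
  }
  class(out) <- c("network_stat_report", class(out))
  out
}

# mean over nodes of (directed edges among the node's undirected
# neighbours) / (k * (k - 1)); nodes with k < 2 contribute 0
directed_local_clustering <- function(edge_table) {
  et <- edge_table[edge_table$pre != edge_table$post, , drop = FALSE]
  nodes <- sort(unique(c(et$pre, et$post)))
  adj <- unique(paste0(et$pre, "\r", et$post))
  nb <- lapply(setNames(nodes, nodes), function(v) {
    setdiff(unique(c(et$post[et$pre == v], et$pre[et$post == v])), v)
  })
  vals <- vapply(nodes, function(v) {
    nbs <- nb[[v]]
    kk <- length(nbs)
    if (kk < 2) return(0)
    pairs <- expand.grid(a = nbs, b = nbs, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$a != pairs$b, ]
    sum(paste0(pairs$a, "\r", pairs$b) %in% adj) / (kk * (kk - 1))
  }, numeric(1))
  mean(vals)
}

#' Per-node degree table
#'
#' In-degree and out-degree count directed edge rows (self-loops once in
#' each); `n_neighbors` counts distinct adjacent cells ignoring direction
#' and excluding the node itself.
#'
#' @param edge_table output of [build_edge_table()].
#' @return tibble with `cell_id`, `in_degree`, `out_degree`,
#'   `n_neighbors`, `self_loop`.
#' @export
degree_table <- function(edge_table) {
  nodes <- sort(unique(c(edge_table$pre, edge_table$post)))
  outd <- table(factor(edge_table$pre, levels = nodes))
  ind <- table(factor(edge_table$post, levels = nodes))
  loops <- unique(edge_table$pre[edge_table$pre == edge_table$post])
  nb <- unname(vapply(nodes, function(v) {
    length(setdiff(unique(c(edge_table$post[edge_table$pre == v],
                            edge_table$pre[edge_table$post == v])), v))
  }, integer(1)))
  tibble::tibble(
    cell_id = nodes,
    in_degree = as.integer(ind), out_degree = as.integer(outd),
    n_neighbors = nb, self_loop = nodes %in% loops
  )
}

#' Ordered cell pairs connected by more than one distinct contact
#'
#' Counted on the raw contact list (before depth aggregation): the number
#' of ordered (pre, post) pairs -- canonical unordered pairs for gap
#' junctions -- joined by two or more separate annotated contacts.
#'
#' @inheritParams contact_rows
#' @return list with `count` and the per-pair `pairs` tibble.
#' @export
multi_edge_pairs <- function(x, kind = c("chemical", "gap"),
                             exclusions = character(), min_sections = 1L) {
  kind <- match.arg(kind)
  long <- contact_rows(x, kind, exclusions, min_sections)
  if (kind == "gap" && nrow(long) > 0) {
    a <- pmin(long$pre, long$post); b <- pmax(long$pre, long$post)
    long$pre <- a; long$post <- b
  }
  pairs <- long |>
    dplyr::distinct(.data$contact_id, .data$pre, .data$post) |>
    dplyr::count(.data$pre, .data$post, name = "n_contacts") |>
    dplyr::filter(.data$n_contacts >= 2)
  list(count = nrow(pairs), pairs = pairs)
}
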