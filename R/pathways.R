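#' Enumerate all minimal-hop sensory-to-motor arcs
#'
#' Finds the minimum number of synapses (directed edges) connecting any
#' source cell to any sink cell, and returns every arc achieving that
#' minimum -- ties are enumerated, never broken. Edge count, not
#' interneuron count, measures arc length, so a sensory cell connecting
#' through one interneuron to a motor neuron is a disynaptic (2-edge) arc.
#' Gap junctions are not searched unless they were folded into the edge
#' table as bidirectional edges by the caller.
#'
#' @param edge_table directed chemical edge table.
#' @param sources,sinks character vectors of cell ids (e.g. all cells of a
#'   sensory class, all motor neurons).
#' @param min_edge_depth drop edges with cumulative depth strictly below
#'   this threshold (um) before searching; default 0 keeps all.
#' @return list with `reachable` (logical), `min_hops`, and `arcs`: a list
#'   of tibbles, one per arc, each with `step`, `from`, `to`,
#'   `depth_um`.
#' @export
shortest_arcs <- function(edge_table, sources, sinks, min_edge_depth = 0) {
  et <- edge_table[edge_table$cumulative_depth_um >= min_edge_depth, ,
                   drop = FALSE]
  g <- edge_table_graph(et, directed = TRUE)
  nodes <- igraph::V(g)$name
  sources <- intersect(sources, nodes)
  sinks <- intersect(sinks, nodes)
  unreachable <- list(reachable = FALSE, min_hops = NA_integer_, arcs = list())
  if (length(sources) == 0 || length(sinks) == 0) return(unreachable)
  d <- igraph::distances(g, v = sources, to = sinks, mode = "out")
  # a zero-hop "arc" (a source that is itself a sink) is not a pathway
  d[d == 0] <- Inf
  if (!any(is.finite(d))) return(unreachable)
  min_hops <- min(d[is.finite(d)])
  depth_lookup <- setNames(et$cumulative_depth_um, paste0(et$pre, "\r", et$post))
  arcs <- list()
  for (s in sources) {
    hits <- sinks[d[s, sinks] == min_hops]
    if (length(hits) == 0) next
    ap <- igraph::all_shortest_paths(g, from = s, to = hits, mode = "out")
    for (p in ap$vpaths) {
      vs <- igraph::V(g)$name[as.integer(p)]
      if (length(vs) != min_hops + 1) next
      steps <- tibble::tibble(
        step = seq_len(min_hops),
        from = vs[-length(vs)], to = vs[-1]
      )
      steps$depth_um <- unname(depth_lookup[paste0(steps$from, "\r", steps$to)])
      arcs[[length(arcs) + 1]] <- steps
    }
  }
  list(reachable = TRUE, min_hops = as.integer(min_hops), arcs = arcs)
}

#' Condense an edge table to a class-level network
#'
#' Nodes become connectivity classes (`cell_type` codes); a class-to-class
#' edge weight is the summed cumulative depth of all member-to-member
#' edges, so total depth is conserved. Classes with no members present in
#' the edge table are absent. Restricting to a sensory modality keeps only
#' the classes reachable (downstream) from that modality's sensory
#' classes.
#'
#' @param edge_table directed chemical edge table.
#' @param roster roster tibble with `cell_type`.
#' @param modality optional: one of `names(modality_classes())`, or `NULL`
#'   for the full class-level condensation.
#' @param weak_threshold_um class-level edges with summed depth below this
#'   are flagged `weak` (rendered dashed in pathway summaries).
#' @return tibble with `pre_class`, `post_class`, `n_edges`,
#'   `cumulative_depth_um`, `weak`.
#' @export
modality_subnetwork <- function(edge_table, roster, modality = NULL,
                                weak_threshold_um = 0.1) {
  cls <- setNames(roster$cell_type, roster$cell_id)
  et <- edge_table[edge_table$pre %in% names(cls) &
                     edge_table$post %in% names(cls), , drop = FALSE]
  cond <- tibble::tibble(
    pre_class = unname(cls[et$pre]), post_class = unname(cls[et$post]),
    cumulative_depth_um = et$cumulative_depth_um
  ) |>
    dplyr::group_by(.data$pre_class, .data$post_class) |>
    dplyr::summarise(n_edges = dplyr::n(),
                     cumulative_depth_um = sum(.data$cumulative_depth_um),
                     .groups = "drop") |>
    dplyr::mutate(weak = .data$cumulative_depth_um < weak_threshold_um)
  if (is.null(modality)) return(cond)
  mod <- modality_classes()
  if (!modality %in% names(mod)) {
    abort(paste0("unknown modality '", modality, "' (known: ",
                 paste(names(mod), collapse = ", "), ")"))
  }
  seeds <- intersect(mod[[modality]], unique(c(cond$pre_class, cond$post_class)))
  if (length(seeds) == 0) return(cond[0, ])
  cg <- igraph::graph_from_data_frame(
    cond[, c("pre_class", "post_class")], directed = TRUE)
  reach <- unique(unlist(lapply(seeds, function(s) {
    igraph::V(cg)$name[!is.infinite(igraph::distances(cg, v = s, mode = "out"))]
  })))
  cond[cond$pre_class %in% reach & cond$post_class %in% reach, , drop = FALSE]
}

#' Sensory classes of each modality
#'
#' The four modalities used for pathway summaries: light (ocellus and
#' canal photoreceptors), gravity (antenna cells), coronet (putative
#' pressure sense) and PNS mechano/chemosensation.
#'
#' @return named list of `cell_type` code vectors.
#' @export
modality_classes <- function() {
  list(
    light = c("PR-I", "PR-II", "PR-III"),
    gravity = "antenna",
    coronet = "coronet",
    pns = c("RTEN", "ATENa", "ATENp", "DCEN", "BTN")
  )
}

#' Feed-forward triplet motifs across three classes
#'
#' Enumerates node triples (a, b, c) with a drawn from `a_class`, b from
#' `b_class`, c from `c_class`, such that the directed edges a->b, b->c
#' and the shortcut a->c all exist.
#'
#' @param edge_table directed edge table.
#' @param roster roster tibble.
#' @param a_class,b_class,c_class `cell_type` codes of the three layers.
#' @return list with `count` and `motifs` tibble (`a`, `b`, `c`).
#' @export
feedforward_triplets <- function(edge_table, roster, a_class, b_class, c_class) {
  members <- function(cl) roster$cell_id[roster$cell_type %in% cl]
  e <- dplyr::distinct(edge_table[, c("pre", "post")])
  ab <- e[e$pre %in% members(a_class) & e$post %in% members(b_class), ]
  bc <- e[e$pre %in% members(b_class) & e$post %in% members(c_class), ]
  ac <- e[e$pre %in% members(a_class) & e$post %in% members(c_class), ]
  names(ab) <- c("a", "b"); names(bc) <- c("b", "c"); names(ac) <- c("a", "c")
  motifs <- ab |>
    dplyr::inner_join(bc, by = "b", relationship = "many-to-many") |>
    dplyr::inner_join(ac, by = c("a", "c")) |>
    dplyr::filter(.data$a != .data$b, .data$b != .data$c, .data$a != .data$c) |>
    dplyr::arrange(.data$a, .data$b, .data$c)
  list(count = nrow(motifs), motifs = motifs)
}
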