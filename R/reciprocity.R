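neuron_edge_filter <- function(edge_table, roster, include_pseudo = FALSE,
                               drop_self = TRUE) {
  et <- edge_table
  if (drop_self) et <- et[et$pre != et$post, , drop = FALSE]
  if (!include_pseudo && !is.null(roster)) {
    neurons <- roster$cell_id[roster$is_neuron %in% TRUE]
    et <- et[et$pre %in% neurons & et$post %in% neurons, , drop = FALSE]
  }
  et
}

#' Proportion of connected neuron pairs that are reciprocally connected
#'
#' The denominator is the set of unordered neuron pairs joined by at least
#' one directed edge; the numerator the subset with edges in both
#' directions. Pairs involving exclusively postsynaptic pseudo-cells
#' (muscle, basal lamina) are excluded by default since they can never be
#' reciprocal; self-loops are always excluded.
#'
#' @param edge_table directed chemical edge table.
#' @param roster roster tibble used to restrict to neuron-neuron pairs;
#'   pass `NULL` (or `include_pseudo = TRUE`) to keep every node.
#' @param include_pseudo keep non-neuronal nodes in the pair set.
#' @return proportion in `[0, 1]`.
#' @export
reciprocity_proportion <- function(edge_table, roster = NULL,
                                   include_pseudo = is.null(roster)) {
  if (nrow(edge_table) == 0) abort("empty edge table")
  et <- neuron_edge_filter(edge_table, roster, include_pseudo)
  if (nrow(et) == 0) abort("no qualifying edges after filtering")
  a <- pmin(et$pre, et$post)
  b <- pmax(et$pre, et$post)
  fwd <- et$pre < et$post
  key <- paste0(a, "\r", b)
  has_fwd <- tapply(fwd, key, any)
  has_bwd <- tapply(!fwd, key, any)
  mean(has_fwd & has_bwd)
}

#' Pairwise reciprocity table
#'
#' One row per connected unordered pair. By convention the larger of the
#' two directional depths is reported as `d_forward`, so the extent
#' `d_forward / (d_forward + d_backward)` lies in `[0.5, 1]` for
#' reciprocal pairs and is exactly 1 for one-way pairs. The geometric mean
#' `sqrt(d_forward * d_backward)` is reported only for reciprocal pairs.
#'
#' @inheritParams reciprocity_proportion
#' @return tibble with `cell_a`, `cell_b` (lexicographic pair order),
#'   `d_forward`, `d_backward`, `extent`, `geometric_mean`, `reciprocal`.
#' @export
pair_reciprocity_table <- function(edge_table, roster = NULL,
                                   include_pseudo = is.null(roster)) {
  et <- neuron_edge_filter(edge_table, roster, include_pseudo)
  if (nrow(et) == 0) {
    return(tibble::tibble(cell_a = character(), cell_b = character(),
                          d_forward = double(), d_backward = double(),
                          extent = double(), geometric_mean = double(),
                          reciprocal = logical()))
  }
  et$cell_a <- pmin(et$pre, et$post)
  et$cell_b <- pmax(et$pre, et$post)
  et$dir_ab <- et$pre < et$post
  agg <- et |>
    dplyr::group_by(.data$cell_a, .data$cell_b) |>
    dplyr::summarise(
      d_ab = sum(.data$cumulative_depth_um[.data$dir_ab]),
      d_ba = sum(.data$cumulative_depth_um[!.data$dir_ab]),
      .groups = "drop"
    )
  d_fwd <- pmax(agg$d_ab, agg$d_ba)
  d_bwd <- pmin(agg$d_ab, agg$d_ba)
  reciprocal <- agg$d_ab > 0 & agg$d_ba > 0
  tibble::tibble(
    cell_a = agg$cell_a, cell_b = agg$cell_b,
    d_forward = d_fwd, d_backward = d_bwd,
    extent = d_fwd / (d_fwd + d_bwd),
    geometric_mean = ifelse(reciprocal, sqrt(d_fwd * d_bwd), NA_real_),
    reciprocal = reciprocal
  )
}
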