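#' Sided cell counts
#'
#' Tallies the roster per grouping variable and side (left / centre /
#' right), with marginal totals per region and overall, in the layout of
#' a sided cell-census table. Unassigned sides are reported in their own
#' column rather than folded into the counts.
#'
#' @param roster roster tibble with sides assigned.
#' @param grouping roster column to group by (default `"cell_type"`).
#' @param neurons_only count neurons only (default `TRUE`).
#' @return list with `by_group`, `by_region` and `total` tibbles, each
#'   with `left`, `centre`, `right`, `unassigned` columns.
#' @export
sided_counts <- function(roster, grouping = "cell_type", neurons_only = TRUE) {
  r <- roster
  if (neurons_only) r <- r[r$is_neuron %in% TRUE, , drop = FALSE]
  tally <- function(df, keys) {
    df |>
      dplyr::count(dplyr::across(dplyr::all_of(keys)), .data$side) |>
      tidyr::pivot_wider(names_from = "side", values_from = "n",
                         values_fill = 0L) |>
      (\(d) {
        for (col in c("left", "midline", "right", "unassigned")) {
          if (!col %in% names(d)) d[[col]] <- 0L
        }
        dplyr::rename(d, centre = "midline")[, c(keys, "left", "centre",
                                                 "right", "unassigned")]
      })()
  }
  r$all <- "all"
  list(
    by_group = tally(r, c("region", grouping)),
    by_region = tally(r, "region"),
    total = tally(r, "all")[, c("left", "centre", "right", "unassigned")]
  )
}

#' Neuromuscular left:right input ratio for a motor-neuron pair
#'
#' Pools the dorsal and medial muscle bands per side (the bands are
#' electrically coupled) and reports the left:right split of the pair's
#' neuromuscular input both by synapse number and by synaptic profile
#' (section) number, as percentage pairs rounded by largest remainder so
#' each pair sums to 100.
#'
#' @param x a [connectome()].
#' @param motor_neurons cell ids of the pair (e.g. `c("MN2L", "MN2R")`).
#' @param label group label for the output row.
#' @return one-row tibble (`label`, `left_count`, `right_count`,
#'   `left_sections`, `right_sections`, `left_pct_by_count`, ... ).
#' @export
nmj_lr_ratio <- function(x, motor_neurons, label = paste(motor_neurons,
                                                         collapse = "+")) {
  stopifnot(inherits(x, "connectome"))
  rows <- contact_rows(x, "chemical")
  roster <- x$cells
  muscle <- roster$cell_id[roster$cell_type == "muscle" | roster$region == "muscle"]
  nmj <- rows[rows$pre %in% motor_neurons & rows$post %in% muscle, , drop = FALSE]
  if (nrow(nmj) == 0) abort("motor-neuron pair has no neuromuscular junctions")
  side <- roster$side[match(nmj$post, roster$cell_id)]
  cnt <- c(left = sum(side == "left"), right = sum(side == "right"))
  sec <- c(left = sum(nmj$n_sections[side == "left"]),
           right = sum(nmj$n_sections[side == "right"]))
  pc <- unname(largest_remainder_pct(cnt))
  ps <- unname(largest_remainder_pct(sec))
  tibble::tibble(
    label = label,
    left_count = unname(cnt["left"]), right_count = unname(cnt["right"]),
    left_sections = unname(sec["left"]), right_sections = unname(sec["right"]),
    left_pct_by_count = pc[1], right_pct_by_count = pc[2],
    left_pct_by_sections = ps[1], right_pct_by_sections = ps[2]
  )
}

#' Laterality of relay-class output to a target region
#'
#' For each presynaptic connectivity class, the proportion of its output
#' (by synapse count and by cumulative depth) landing on left- versus
#' right-side targets of the given region -- the quantity behind
#' relay-to-motor-ganglion laterality summaries.
#'
#' @param edge_table directed chemical edge table.
#' @param roster roster tibble.
#' @param source_classes character vector of presynaptic `cell_type`
#'   codes; classes with no outgoing edges are dropped with a warning.
#' @param target_region region code of the targets (default `"MG"`).
#' @param target_neurons_only restrict targets to neurons.
#' @return tibble per class: depth and edge-count totals to left/right
#'   targets and the corresponding left percentages.
#' @export
relay_laterality <- function(edge_table, roster, source_classes,
                             target_region = "MG",
                             target_neurons_only = TRUE) {
  out <- lapply(source_classes, function(cls) {
    members <- roster$cell_id[roster$cell_type == cls]
    targets_ok <- roster$region == target_region &
      (!target_neurons_only | roster$is_neuron %in% TRUE)
    et <- edge_table[edge_table$pre %in% members, , drop = FALSE]
    tside <- roster$side[match(et$post, roster$cell_id)]
    keep <- targets_ok[match(et$post, roster$cell_id)] & tside %in% c("left", "right")
    et <- et[keep, , drop = FALSE]
    tside <- tside[keep]
    if (nrow(et) == 0) {
      warn(sprintf("class '%s' has no outgoing edges to region '%s'",
                   cls, target_region))
      return(NULL)
    }
    depth <- tapply(et$cumulative_depth_um, factor(tside, c("left", "right")),
                    sum, default = 0)
    cnt <- table(factor(tside, c("left", "right")))
    tibble::tibble(
      source_class = cls,
      left_depth_um = depth[["left"]], right_depth_um = depth[["right"]],
      left_edges = as.integer(cnt[["left"]]), right_edges = as.integer(cnt[["right"]]),
      pct_left_by_depth = 100 * depth[["left"]] / sum(depth),
      pct_left_by_edges = 100 * cnt[["left"]] / sum(cnt)
    )
  })
  dplyr::bind_rows(out)
}

#' Sort a connectivity matrix into left/right quadrants
#'
#' Permutes rows (presynaptic) into left, midline, right order and columns
#' (postsynaptic) into right, midline, left order, so the four corner
#' blocks are the left-to-right, left-to-left, right-to-right and
#' right-to-left quadrants, with midline cells separating them. Within
#' each side block the original (rostro-caudal input) order is preserved,
#' and the permutation conserves every entry.
#'
#' @param m square numeric matrix with cell-id dimnames.
#' @param roster roster tibble giving each label a side.
#' @return list with `matrix` (the permuted matrix) and `quadrants`
#'   (tibble of quadrant name and row/column index ranges).
#' @export
sort_matrix_by_side <- function(m, roster) {
  labels <- rownames(m)
  side <- roster$side[match(labels, roster$cell_id)]
  if (any(is.na(side) | side == "unassigned")) {
    bad <- labels[is.na(side) | side == "unassigned"]
    abort(paste0("labels without an assigned side: ", paste(bad, collapse = ", ")))
  }
  row_order <- c(which(side == "left"), which(side == "midline"),
                 which(side == "right"))
  col_order <- c(which(side == "right"), which(side == "midline"),
                 which(side == "left"))
  out <- m[row_order, col_order, drop = FALSE]
  nl <- sum(side == "left"); nm <- sum(side == "midline"); nr <- sum(side == "right")
  rng <- function(a, b) if (b < a) integer(0) else a:b
  quadrants <- tibble::tibble(
    quadrant = c("L->R", "L->L", "R->L", "R->R"),
    row_start = c(1, 1, nl + nm + 1, nl + nm + 1),
    row_end = c(nl, nl, nl + nm + nr, nl + nm + nr),
    col_start = c(1, nr + nm + 1, nr + nm + 1, 1),
    col_end = c(nr, nr + nm + nl, nr + nm + nl, nr)
  )
  list(matrix = out, quadrants = quadrants)
}

#' Left/right edge differences between homologous cell pairs
#'
#' Given a bijective mapping of left cells to their right homologues,
#' classifies every directed edge among the mapped cells as present on
#' both sides, left-only, or right-only, reporting the left/right weight
#' ratio for both-sides edges. The three sets partition all edges among
#' the cells considered.
#'
#' @param edge_table directed edge table.
#' @param homolog_pairs tibble with columns `left`, `right`.
#' @return list of class `side_diff_report` with tibbles `both_sides`,
#'   `left_only`, `right_only` (edges named by canonical pair labels).
#' @export
side_diff <- function(edge_table, homolog_pairs) {
  hp <- tibble::as_tibble(homolog_pairs)
  if (anyDuplicated(hp$left) || anyDuplicated(hp$right) ||
      length(intersect(hp$left, hp$right)) > 0) {
    abort("homolog mapping must be a bijection between disjoint left and right sets")
  }
  canon <- c(setNames(hp$left, hp$left), setNames(hp$left, hp$right))
  side_of <- c(setNames(rep("left", nrow(hp)), hp$left),
               setNames(rep("right", nrow(hp)), hp$right))
  cells <- names(canon)
  et <- edge_table[edge_table$pre %in% cells & edge_table$post %in% cells, ,
                   drop = FALSE]
  # an edge belongs to the side of its presynaptic cell; decussating
  # (cross-side) edges are tracked separately from ipsilateral ones so an
  # ipsilateral a->b never collides with a contralateral a->b
  contra <- ifelse(side_of[et$pre] == side_of[et$post], "ipsi", "contra")
  key <- paste0(canon[et$pre], "\r", canon[et$post], "\r", contra)
  sides <- side_of[et$pre]
  df <- tibble::tibble(key = key, side = sides,
                       weight = et$cumulative_depth_um)
  agg <- df |>
    dplyr::group_by(.data$key, .data$side) |>
    dplyr::summarise(weight = sum(.data$weight), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "side", values_from = "weight")
  for (col in c("left", "right")) if (!col %in% names(agg)) agg[[col]] <- NA_real_
  split_key <- do.call(rbind, strsplit(agg$key, "\r", fixed = TRUE))
  agg$pre_homolog <- split_key[, 1]
  agg$post_homolog <- split_key[, 2]
  agg$crossing <- split_key[, 3] == "contra"
  agg$key <- NULL
  both <- agg[!is.na(agg$left) & !is.na(agg$right), , drop = FALSE]
  both$weight_ratio_lr <- both$left / both$right
  structure(list(
    both_sides = both[, c("pre_homolog", "post_homolog", "crossing", "left",
                          "right", "weight_ratio_lr")],
    left_only = agg[!is.na(agg$left) & is.na(agg$right),
                    c("pre_homolog", "post_homolog", "crossing", "left")],
    right_only = agg[is.na(agg$left) & !is.na(agg$right),
                     c("pre_homolog", "post_homolog", "crossing", "right")]
  ), class = "side_diff_report")
}

#' @export
print.side_diff_report <- function(x, ...) {
  cat(sprintf("side-diff report: %d both-sides, %d left-only, %d right-only edge(s)\n",
              nrow(x$both_sides), nrow(x$left_only), nrow(x$right_only)))
  invisible(x)
}
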