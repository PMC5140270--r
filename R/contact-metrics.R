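dcv_classes <- c("dcv-small", "dcv-medium", "dcv-large")

#' Synapse- and gap-junction-level summary statistics
#'
#' Computes, separately for chemical synapses and putative gap junctions:
#' total contacts, total sections, mean sections per contact, number and
#' mean span of contacts seen in more than one section, and the
#' percentages of contacts that are unpolarized, polyadic (more than one
#' postsynaptic target) or carry dense-core vesicles. Percentages are
#' reported to one decimal (round half up); full precision is kept in the
#' `*_raw` columns.
#'
#' @param x a [connectome()].
#' @param exclusions optional target-exclusion keywords (see
#'   [contact_rows()]); a contact is dropped only if all of its targets are
#'   excluded.
#' @return list of class `contact_summary` with elements `by_kind` (one
#'   row per kind) and `per_neuron` (population mean/SD of presynaptic
#'   sites, received synapses and gap junctions per neuron).
#' @export
summarize_contacts <- function(x, exclusions = character()) {
  stopifnot(inherits(x, "connectome"))
  cts <- x$contacts
  if (length(exclusions) > 0) {
    keep <- vapply(seq_len(nrow(cts)), function(i) {
      rows <- x$cells[match(cts$post_targets[[i]], x$cells$cell_id), , drop = FALSE]
      !all(exclusion_mask(exclusions, rows))
    }, logical(1))
    cts <- cts[keep, , drop = FALSE]
  }
  if (nrow(cts) == 0) {
    warn("connectome has no contacts; summary is all zeros")
  }
  round1 <- function(p) floor(p * 10 + 0.5) / 10  # round half up, 1 decimal
  one_kind <- function(k) {
    sub <- cts[cts$kind == k, , drop = FALSE]
    n <- nrow(sub)
    tot_sec <- sum(sub$n_sections)
    over1 <- sub$n_sections > 1
    pct_unpol <- if (n > 0) 100 * sum(sub$unpolarized) / n else NA_real_
    pct_poly <- if (n > 0) 100 * sum(lengths(sub$post_targets) >= 2) / n else NA_real_
    has_dcv <- vapply(sub$vesicle_classes,
                      function(v) length(intersect(v, dcv_classes)) > 0, logical(1))
    pct_dcv <- if (n > 0) 100 * sum(has_dcv) / n else NA_real_
    tibble::tibble(
      kind = k,
      total_contacts = n,
      total_sections = tot_sec,
      mean_sections_per_contact = if (n > 0) tot_sec / n else NA_real_,
      contacts_over_1_section = sum(over1),
      mean_sections_over_1_section =
        if (any(over1)) sum(sub$n_sections[over1]) / sum(over1) else NA_real_,
      pct_unpolarized = round1(pct_unpol), pct_unpolarized_raw = pct_unpol,
      pct_polyadic = round1(pct_poly), pct_polyadic_raw = pct_poly,
      pct_dcv = round1(pct_dcv), pct_dcv_raw = pct_dcv
    )
  }
  per <- per_neuron_stats(x)
  structure(list(
    by_kind = dplyr::bind_rows(lapply(c("chemical", "gap"), one_kind)),
    per_neuron = per$population
  ), class = "contact_summary")
}

#' @export
print.contact_summary <- function(x, ...) {
  print(x$by_kind)
  print(x$per_neuron)
  invisible(x)
}

#' Distribution of synapse arity (monads, dyads, triads, ...)
#'
#' @param x a [connectome()].
#' @return list with `counts` (tibble of arity vs count over chemical
#'   contacts), `polyad_fraction` (contacts with >= 2 targets over all
#'   chemical contacts) and `dyad_share` (dyads over polyads; `NA` when
#'   there are no polyads).
#' @export
polyad_distribution <- function(x) {
  stopifnot(inherits(x, "connectome"))
  chem <- x$contacts[x$contacts$kind == "chemical", , drop = FALSE]
  arity <- lengths(chem$post_targets)
  tab <- table(arity)
  counts <- tibble::tibble(arity = as.integer(names(tab)),
                           n = as.integer(tab))
  n_poly <- sum(arity >= 2)
  list(
    counts = counts,
    polyad_fraction = if (nrow(chem) > 0) n_poly / nrow(chem) else NA_real_,
    dyad_share = if (n_poly > 0) sum(arity == 2) / n_poly else NA_real_
  )
}

#' Compartment-by-compartment distribution of synaptic contacts
#'
#' Fractions of annotated contact-target rows by presynaptic and
#' postsynaptic compartment (soma, axon, terminal, dendrite, ...). Rows
#' lacking an annotation on the requested end are tallied separately under
#' `unknown` and excluded from the denominator of the annotated fractions.
#'
#' @param x a [connectome()].
#' @param direction `"post"` (default; where contacts terminate), `"pre"`,
#'   or `"both"` for the full pre x post cross-table.
#' @return tibble of compartments and fractions (annotated rows sum to 1),
#'   plus an `n_unknown` attribute.
#' @export
compartment_distribution <- function(x, direction = c("post", "pre", "both")) {
  direction <- match.arg(direction)
  chem <- x$contacts[x$contacts$kind == "chemical", , drop = FALSE]
  arity <- lengths(chem$post_targets)
  pre <- rep(chem$pre_compartment, arity)
  post <- unlist(lapply(seq_len(nrow(chem)), function(i) {
    v <- chem$post_compartments[[i]]
    if (length(v) == arity[i]) v else rep(NA_character_, arity[i])
  }))
  df <- switch(direction,
    post = tibble::tibble(compartment = post),
    pre = tibble::tibble(compartment = pre),
    both = tibble::tibble(pre_compartment = pre, post_compartment = post)
  )
  known <- stats::complete.cases(df)
  out <- df[known, , drop = FALSE] |>
    dplyr::count(dplyr::across(dplyr::everything()), name = "n") |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::arrange(dplyr::desc(.data$n))
  attr(out, "n_unknown") <- sum(!known)
  out
}

#' Per-neuron synapse loads
#'
#' One row per neuron in the selected denominator set: number of
#' presynaptic sites (contacts where the neuron is presynaptic), received
#' synapses (contact-target rows where it is postsynaptic), gap-junction
#' contacts it participates in, and distinct in/out partner counts.
#' Population means use the population SD (divisor n) by default.
#'
#' @param x a [connectome()].
#' @param denominator `"active_cns"` (CNS neurons with >= 1 presynaptic
#'   site), `"cns_plus_btn"` (adds bipolar tail neurons) or `"all_neurons"`.
#' @param divisor_n logical; `FALSE` switches the SD to divisor n-1.
#' @return list with `per_cell` tibble and `population` summary tibble.
#' @export
per_neuron_stats <- function(x, denominator = c("active_cns", "cns_plus_btn",
                                                "all_neurons"),
                             divisor_n = TRUE) {
  stopifnot(inherits(x, "connectome"))
  denominator <- match.arg(denominator)
  cns_regions <- c("BV", "neck", "MG", "CNC")
  cells <- x$cells
  neurons <- cells$cell_id[which(cells$is_neuron)]
  chem <- contact_rows(x, "chemical")
  gap <- contact_rows(x, "gap")
  presyn <- table(x$contacts$pre_cell[x$contacts$kind == "chemical"])
  received <- table(chem$post)
  gap_touch <- table(c(gap$pre, gap$post))
  out_partners <- chem |> dplyr::distinct(.data$pre, .data$post) |>
    dplyr::count(.data$pre, name = "out_partners")
  in_partners <- chem |> dplyr::distinct(.data$pre, .data$post) |>
    dplyr::count(.data$post, name = "in_partners")
  depth_by_pre <- chem |> dplyr::group_by(.data$pre) |>
    dplyr::summarise(total_depth_um = sum(.data$depth_um), .groups = "drop")

  tab <- tibble::tibble(cell_id = neurons) |>
    dplyr::left_join(cells[, c("cell_id", "cell_type", "region", "side")], by = "cell_id") |>
    dplyr::mutate(
      n_presyn = as.integer(presyn[.data$cell_id]),
      n_received = as.integer(received[.data$cell_id]),
      n_gap = as.integer(gap_touch[.data$cell_id])
    ) |>
    dplyr::left_join(out_partners, by = c(cell_id = "pre")) |>
    dplyr::left_join(in_partners, by = c(cell_id = "post")) |>
    dplyr::left_join(depth_by_pre, by = c(cell_id = "pre")) |>
    dplyr::mutate(dplyr::across(
      c("n_presyn", "n_received", "n_gap", "out_partners", "in_partners"),
      ~ dplyr::coalesce(.x, 0L))) |>
    dplyr::mutate(total_depth_um = dplyr::coalesce(.data$total_depth_um, 0))

  in_cns <- tab$region %in% cns_regions
  sel <- switch(denominator,
    active_cns = in_cns & tab$n_presyn >= 1,
    cns_plus_btn = (in_cns & tab$n_presyn >= 1) | tab$cell_type == "BTN",
    all_neurons = rep(TRUE, nrow(tab))
  )
  sub <- tab[sel, , drop = FALSE]
  summ <- function(v, what) tibble::tibble(
    statistic = what, mean = mean(v), sd = pop_sd(v, divisor_n),
    min = if (length(v)) min(v) else NA_real_,
    max = if (length(v)) max(v) else NA_real_, n_neurons = length(v))
  population <- dplyr::bind_rows(
    summ(sub$n_presyn, "presynaptic_sites"),
    summ(sub$n_received, "received_synapses"),
    summ(sub$n_gap, "gap_junctions")
  )
  list(per_cell = tab, population = population, denominator = denominator)
}

#' Scaling of synapse load with contact depth and partner number
#'
#' Two fits over the per-neuron table: (i) total presynaptic depth vs
#' number of presynaptic sites, ordinary linear regression; (ii) number of
#' presynaptic sites S vs number of postsynaptic partners P as a power law
#' S = a * P^b, fitted by least squares on log-log values (rows with
#' non-positive S or P are excluded with a warning).
#'
#' @param per_cell per-cell tibble from [per_neuron_stats()].
#' @return list with `linear` (`slope`, `intercept`, `r_squared`) and
#'   `power` (`a`, `b`, `r_squared`, `n`).
#' @export
fit_scaling <- function(per_cell) {
  stopifnot(nrow(per_cell) >= 3)
  r2 <- function(fit, y) {
    res <- sum(stats::residuals(fit)^2)
    tot <- sum((y - mean(y))^2)
    if (tot == 0) return(NA_real_)
    1 - res / tot
  }
  lin <- stats::lm(total_depth_um ~ n_presyn, data = per_cell)
  linear <- list(
    slope = unname(stats::coef(lin)[2]),
    intercept = unname(stats::coef(lin)[1]),
    r_squared = r2(lin, per_cell$total_depth_um)
  )
  ok <- per_cell$n_presyn > 0 & per_cell$out_partners > 0
  if (any(!ok)) {
    warn(sprintf("%d neuron(s) with non-positive counts excluded from the power fit",
                 sum(!ok)))
  }
  sub <- per_cell[ok, , drop = FALSE]
  pw <- stats::lm(log(n_presyn) ~ log(out_partners), data = sub)
  power <- list(
    a = unname(exp(stats::coef(pw)[1])),
    b = unname(stats::coef(pw)[2]),
    r_squared = r2(pw, log(sub$n_presyn)),
    n = nrow(sub)
  )
  list(linear = linear, power = power)
}
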