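#' Section-thickness schedule of the serial EM series
#'
#' The reconstruction was cut as three consecutive runs of ultrathin
#' sections of different thickness along the anterior-posterior axis:
#' 3375 sections at 60 nm (brain vesicle through motor ganglion), 1360 at
#' 70 nm (anterior tail) and 2193 at 100 nm (posterior tail). Section
#' indices are 0-based; each zone is a closed interval of indices.
#'
#' @return A tibble with columns `start_section`, `end_section`,
#'   `thickness_nm`.
#' @export
default_thickness_schedule <- function() {
  tibble::tibble(
    start_section = c(0L, 3375L, 4735L),
    end_section   = c(3374L, 4734L, 6927L),
    thickness_nm  = c(60, 70, 100)
  )
}

blank_cells <- function() {
  tibble::tibble(
    cell_id = character(), cell_type = character(), region = character(),
    side = character(), nucleus_section = integer(),
    nucleus_x = double(), nucleus_y = double(),
    is_neuron = logical(), has_cilium = logical()
  )
}

blank_contacts <- function() {
  tibble::tibble(
    contact_id = character(), kind = character(), pre_cell = character(),
    post_targets = list(), first_section = integer(), n_sections = integer(),
    thickness_nm = list(), unpolarized = logical(), vesicle_classes = list(),
    pre_compartment = character(), post_compartments = list()
  )
}

#' Assemble a connectome object
#'
#' A connectome bundles the cell roster, the annotated contact list
#' (chemical synapses, including neuromuscular junctions, and putative gap
#' junctions) and the section-thickness schedule needed to convert section
#' spans into cumulative contact depth in micrometres.
#'
#' The contact table has one row per annotated contact. `post_targets` is a
#' list-column of ordered postsynaptic cell ids: a monad has one entry, a
#' dyad two, a triad three. Gap junctions always have exactly one partner
#' and are treated as unordered pairs downstream. `thickness_nm` optionally
#' carries explicit per-section thicknesses (nm); when an entry is `NULL`
#' the thickness is looked up in the schedule, so contacts straddling a
#' 60/70 or 70/100 nm boundary sum their true per-section values.
#'
#' @param cells tibble of cell records (`cell_id`, `cell_type`, `region`,
#'   `side`, `nucleus_section`, `nucleus_x`, `nucleus_y`, `is_neuron`,
#'   `has_cilium`). Missing optional columns are filled with `NA`.
#' @param contacts tibble of contact records (see Details).
#' @param thickness_schedule tibble mapping closed 0-based section-index
#'   ranges to nm thickness; defaults to [default_thickness_schedule()].
#' @param provenance free-form list of metadata.
#' @return An object of class `connectome`.
#' @export
connectome <- function(cells, contacts,
                       thickness_schedule = default_thickness_schedule(),
                       provenance = list()) {
  cells <- tibble::as_tibble(cells)
  contacts <- tibble::as_tibble(contacts)
  for (col in names(blank_cells())) {
    if (!col %in% names(cells)) cells[[col]] <- blank_cells()[[col]][NA_integer_][seq_len(nrow(cells))]
  }
  if (!"post_targets" %in% names(contacts) && "post_cell" %in% names(contacts)) {
    contacts$post_targets <- as.list(contacts$post_cell)
    contacts$post_cell <- NULL
  }
  defaults <- list(
    thickness_nm = vector("list", nrow(contacts)),
    unpolarized = FALSE,
    vesicle_classes = vector("list", nrow(contacts)),
    pre_compartment = NA_character_,
    post_compartments = vector("list", nrow(contacts))
  )
  for (col in names(defaults)) {
    if (!col %in% names(contacts)) contacts[[col]] <- defaults[[col]]
  }
  structure(
    list(cells = cells, contacts = contacts,
         thickness_schedule = tibble::as_tibble(thickness_schedule),
         provenance = provenance),
    class = "connectome"
  )
}

#' @export
print.connectome <- function(x, ...) {
  n_chem <- sum(x$contacts$kind == "chemical")
  n_gap <- sum(x$contacts$kind == "gap")
  cat(sprintf(
    "<connectome> %d cells (%d neurons), %d chemical contacts, %d gap contacts\n",
    nrow(x$cells), sum(x$cells$is_neuron, na.rm = TRUE), n_chem, n_gap))
  invisible(x)
}

#' Validate a connectome
#'
#' Reporting operation: never throws. Checks for dangling cell references,
#' zero-length section spans, polyadic gap-junction contacts, duplicate
#' cell ids, and contact spans that fall outside the thickness schedule.
#'
#' @param x a [connectome()].
#' @return tibble of findings (`finding`, `id`, `message`); zero rows iff
#'   the connectome is well-formed.
#' @export
validate_connectome <- function(x) {
  stopifnot(inherits(x, "connectome"))
  findings <- list()
  add <- function(finding, id, message) {
    findings[[length(findings) + 1]] <<-
      tibble::tibble(finding = finding, id = id, message = message)
  }
  dup <- unique(x$cells$cell_id[duplicated(x$cells$cell_id)])
  for (d in dup) add("duplicate_cell_id", d, sprintf("cell id '%s' occurs more than once", d))

  known <- x$cells$cell_id
  cts <- x$contacts
  if (nrow(cts) > 0) {
    for (i in seq_len(nrow(cts))) {
      refs <- c(cts$pre_cell[[i]], cts$post_targets[[i]])
      missing <- setdiff(refs, known)
      for (m in missing) {
        add("dangling_reference", cts$contact_id[[i]],
            sprintf("contact '%s' references unknown cell '%s'", cts$contact_id[[i]], m))
      }
      if (cts$n_sections[[i]] < 1) {
        add("zero_length_span", cts$contact_id[[i]],
            sprintf("contact '%s' has n_sections = %d", cts$contact_id[[i]], cts$n_sections[[i]]))
      }
      if (cts$kind[[i]] == "gap" && length(cts$post_targets[[i]]) > 1) {
        add("polyadic_gap", cts$contact_id[[i]],
            sprintf("gap contact '%s' has %d partners", cts$contact_id[[i]],
                    length(cts$post_targets[[i]])))
      }
      prof <- cts$thickness_nm[[i]]
      if (!is.null(prof) && length(prof) != cts$n_sections[[i]]) {
        add("thickness_profile_mismatch", cts$contact_id[[i]],
            sprintf("contact '%s': %d thickness values for %d sections",
                    cts$contact_id[[i]], length(prof), cts$n_sections[[i]]))
      }
    }
    # schedule coverage, only meaningful for positive spans w/o explicit profile
    sched <- x$thickness_schedule
    covered <- function(first, n) {
      if (n < 1) return(TRUE)
      len <- 0
      for (z in seq_len(nrow(sched))) {
        len <- len + max(0, min(first + n - 1, sched$end_section[z]) -
                           max(first, sched$start_section[z]) + 1)
      }
      len == n
    }
    for (i in seq_len(nrow(cts))) {
      if (is.null(cts$thickness_nm[[i]]) &&
          !covered(cts$first_section[[i]], cts$n_sections[[i]])) {
        add("span_outside_schedule", cts$contact_id[[i]],
            sprintf("contact '%s' spans sections outside the thickness schedule",
                    cts$contact_id[[i]]))
      }
    }
  }
  if (length(findings) == 0) {
    tibble::tibble(finding = character(), id = character(), message = character())
  } else {
    dplyr::bind_rows(findings)
  }
}

#' Cumulative depth of each contact, in micrometres
#'
#' The anatomical synaptic-strength proxy: the number of serial sections a
#' contact spans multiplied by the section thickness, i.e. the sum of
#' per-section thickness over the closed span
#' `[first_section, first_section + n_sections - 1]`, divided by 1000 to
#' give micrometres. Contacts with an explicit per-section thickness
#' profile use it; others are resolved against the schedule.
#'
#' @param x a [connectome()], or a contact tibble.
#' @param schedule thickness schedule (only needed when `x` is a tibble).
#' @return numeric vector, one strictly positive depth (um) per contact.
#' @export
contact_depth <- function(x, schedule = NULL) {
  if (inherits(x, "connectome")) {
    schedule <- x$thickness_schedule
    contacts <- x$contacts
  } else {
    contacts <- x
    if (is.null(schedule)) schedule <- default_thickness_schedule()
  }
  n <- nrow(contacts)
  if (n == 0) return(numeric(0))
  depth_nm <- numeric(n)
  first <- contacts$first_section
  nsec <- contacts$n_sections
  last <- first + nsec - 1L
  explicit <- !vapply(contacts$thickness_nm, is.null, logical(1))
  if (any(explicit)) {
    depth_nm[explicit] <- vapply(contacts$thickness_nm[explicit], sum, numeric(1))
  }
  idx <- which(!explicit)
  if (length(idx) > 0) {
    cov <- integer(n)
    for (z in seq_len(nrow(schedule))) {
      ov <- pmax(0L, pmin(last[idx], schedule$end_section[z]) -
                      pmax(first[idx], schedule$start_section[z]) + 1L)
      depth_nm[idx] <- depth_nm[idx] + ov * schedule$thickness_nm[z]
      cov[idx] <- cov[idx] + ov
    }
    bad <- idx[cov[idx] != nsec[idx]]
    if (length(bad) > 0) {
      i <- bad[1]
      abort(sprintf(
        "contact '%s': span [%d, %d] includes section indices not covered by the thickness schedule",
        contacts$contact_id[[i]], first[i], last[i]))
    }
  }
  depth_nm / 1000
}

#' Assign left/right/midline side from nucleus position
#'
#' Applies the sidedness rule used for the roster: a midline drawn through
#' the neural canal classifies nuclei strictly left of the line as `left`,
#' strictly right as `right`, and nuclei intersected by the line (within
#' `nucleus_radius` pixels of it) as `midline`. Cells without a recorded
#' nucleus position are returned `unassigned` with a warning.
#'
#' @param cells roster tibble with `nucleus_section`, `nucleus_x` columns.
#' @param midline the midline x-coordinate: a single number, a function of
#'   section index, or a tibble with columns `section`, `x`.
#' @param nucleus_radius half-width (pixels) within which a nucleus is
#'   considered intersected by the midline.
#' @return the roster with its `side` column replaced.
#' @export
assign_side <- function(cells, midline, nucleus_radius = 0) {
  mx_at <- if (is.function(midline)) {
    midline
  } else if (is.data.frame(midline)) {
    lookup <- setNames(midline$x, midline$section)
    function(s) unname(lookup[as.character(s)])
  } else {
    force(midline)
    function(s) rep(midline, length(s))
  }
  no_pos <- is.na(cells$nucleus_x) | is.na(cells$nucleus_section)
  if (any(no_pos)) {
    warn(sprintf("%d cell(s) lack a nucleus position; side set to 'unassigned'",
                 sum(no_pos)))
  }
  mx <- rep(NA_real_, nrow(cells))
  ok <- !no_pos
  mx[ok] <- mx_at(cells$nucleus_section[ok])
  side <- rep("unassigned", nrow(cells))
  dx <- cells$nucleus_x - mx
  side[ok & abs(dx) <= nucleus_radius] <- "midline"
  side[ok & dx < -nucleus_radius] <- "left"
  side[ok & dx > nucleus_radius] <- "right"
  cells$side <- side
  cells
}

#' Expand contacts to one row per postsynaptic target
#'
#' Polyadic chemical synapses (dyads, triads) contribute their full section
#' span and depth to every postsynaptic target, mirroring how all
#' connections of a dyad or triad are plotted in the connectivity matrix.
#'
#' @param x a [connectome()].
#' @param kind `"chemical"` or `"gap"`.
#' @param min_sections drop contacts spanning fewer sections (the `>1
#'   section` reliability filter is `min_sections = 2`).
#' @param exclusions character subset of `c("bm","Ep","Mu","space")`:
#'   drop target rows onto the basal lamina, ependymal cells, muscle, or
#'   an unresolved postsynaptic space.
#' @param expand_unpolarized if `TRUE`, unpolarized chemical contacts also
#'   contribute a reversed row (both cells carry presynaptic vesicles); by
#'   default they count once in their annotated direction.
#' @return tibble with one row per (contact, post target), carrying
#'   `depth_um`.
#' @export
contact_rows <- function(x, kind = c("chemical", "gap"),
                         exclusions = character(), min_sections = 1L,
                         expand_unpolarized = FALSE) {
  stopifnot(inherits(x, "connectome"))
  kind <- match.arg(kind)
  cts <- x$contacts[x$contacts$kind == kind, , drop = FALSE]
  cts <- cts[cts$n_sections >= min_sections, , drop = FALSE]
  if (nrow(cts) == 0) {
    return(tibble::tibble(contact_id = character(), pre = character(),
                          post = character(), post_rank = integer(),
                          n_sections = integer(), depth_um = double()))
  }
  depth <- contact_depth(cts, x$thickness_schedule)
  arity <- lengths(cts$post_targets)
  long <- tibble::tibble(
    contact_id = rep(cts$contact_id, arity),
    pre = rep(cts$pre_cell, arity),
    post = unlist(cts$post_targets),
    post_rank = unlist(lapply(arity, seq_len)),
    n_sections = rep(cts$n_sections, arity),
    depth_um = rep(depth, arity)
  )
  if (expand_unpolarized && kind == "chemical" && any(cts$unpolarized)) {
    rev_rows <- long[rep(cts$unpolarized, arity), , drop = FALSE]
    tmp <- rev_rows$pre
    rev_rows$pre <- rev_rows$post
    rev_rows$post <- tmp
    rev_rows$contact_id <- paste0(rev_rows$contact_id, ":rev")
    long <- dplyr::bind_rows(long, rev_rows)
  }
  if (length(exclusions) > 0) {
    roster_rows <- x$cells[match(long$post, x$cells$cell_id), , drop = FALSE]
    long <- long[!exclusion_mask(exclusions, roster_rows), , drop = FALSE]
  }
  long
}

#' Build the weighted edge table
#'
#' Aggregates surviving contact rows into one directed row per ordered
#' (pre, post) cell pair (chemical) or one row per canonical unordered pair
#' (gap junctions; the lexicographically smaller cell id is stored first).
#' Each polyadic contact contributes its full section count and depth to
#' every post target. Exclusions and the minimum-section filter are applied
#' before aggregation.
#'
#' @inheritParams contact_rows
#' @return tibble with columns `pre`, `post`, `kind`, `n_contacts`,
#'   `total_sections`, `cumulative_depth_um`.
#' @export
build_edge_table <- function(x, kind = c("chemical", "gap"),
                             exclusions = character(), min_sections = 1L,
                             expand_unpolarized = FALSE) {
  kind <- match.arg(kind)
  long <- contact_rows(x, kind, exclusions, min_sections, expand_unpolarized)
  if (kind == "gap" && nrow(long) > 0) {
    a <- pmin(long$pre, long$post)
    b <- pmax(long$pre, long$post)
    long$pre <- a
    long$post <- b
  }
  out <- long |>
    dplyr::group_by(.data$pre, .data$post) |>
    dplyr::summarise(
      n_contacts = dplyr::n(),
      total_sections = sum(.data$n_sections),
      cumulative_depth_um = sum(.data$depth_um),
      .groups = "drop"
    ) |>
    dplyr::mutate(kind = kind, .after = "post") |>
    dplyr::arrange(.data$pre, .data$post)
  out
}
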