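#' Read and write contact annotation tables
#'
#' The on-disk contact table is a flat CSV with one row per postsynaptic
#' target of each contact (so a dyad occupies two rows sharing a
#' `contact_id`, ordered by `post_rank`). Columns:
#' `contact_id,kind,pre_cell,post_cell,post_rank,first_section,n_sections,`
#' `thickness_profile,unpolarized,vesicle_classes,pre_compartment,post_compartment`.
#' `thickness_profile` is empty (resolve against the schedule), a single nm
#' value, or semicolon-joined per-section nm values; `vesicle_classes` is
#' semicolon-joined.
#'
#' @param path file path.
#' @return `read_contacts()` returns a contact tibble suitable for
#'   [connectome()]; malformed rows raise an error naming the line number.
#' @export
read_contacts <- function(path) {
  spec <- list(
    contact_id = readr::col_character(), kind = readr::col_character(),
    pre_cell = readr::col_character(), post_cell = readr::col_character(),
    post_rank = readr::col_integer(), first_section = readr::col_integer(),
    n_sections = readr::col_integer(), thickness_profile = readr::col_character(),
    unpolarized = readr::col_logical(), vesicle_classes = readr::col_character(),
    pre_compartment = readr::col_character(), post_compartment = readr::col_character()
  )
  header <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(),
                                  progress = FALSE, show_col_types = FALSE))
  raw <- readr::read_csv(
    path, col_types = do.call(readr::cols, spec[intersect(names(spec), header)]),
    progress = FALSE, show_col_types = FALSE)
  mandatory <- c("contact_id", "kind", "pre_cell", "post_cell", "post_rank",
                 "first_section", "n_sections")
  missing <- setdiff(mandatory, names(raw))
  if (length(missing) > 0) {
    abort(paste0("contact file lacks mandatory column(s): ",
                 paste(missing, collapse = ", ")))
  }
  optional <- c(thickness_profile = NA_character_, vesicle_classes = NA_character_,
                pre_compartment = NA_character_, post_compartment = NA_character_)
  for (col in names(optional)) {
    if (!col %in% names(raw)) raw[[col]] <- optional[[col]]
  }
  if (!"unpolarized" %in% names(raw)) raw$unpolarized <- FALSE
  bad <- which(is.na(raw$n_sections) | raw$n_sections < 1)
  if (length(bad) > 0) {
    abort(sprintf("invalid n_sections at line %d of %s (header is line 1)",
                  bad[1] + 1L, path))
  }
  parse_profile <- function(s, n) {
    if (is.na(s) || s == "") return(NULL)
    v <- as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
    if (length(v) == 1) v <- rep(v, n)
    v
  }
  split_semi <- function(s) {
    if (is.na(s) || s == "") character(0) else strsplit(s, ";", fixed = TRUE)[[1]]
  }
  ord <- order(match(raw$contact_id, unique(raw$contact_id)), raw$post_rank)
  raw <- raw[ord, , drop = FALSE]
  grp <- factor(raw$contact_id, levels = unique(raw$contact_id))
  sizes <- tabulate(grp)
  rank_ok <- raw$post_rank == sequence(sizes)
  if (any(!rank_ok)) {
    bad <- which(!rank_ok)[1]
    abort(sprintf("inconsistent polyad ranks for contact '%s' (line %d)",
                  raw$contact_id[[bad]], ord[bad] + 1L))
  }
  head_row <- !duplicated(grp)
  first <- raw[head_row, , drop = FALSE]
  tibble::tibble(
    contact_id = first$contact_id, kind = first$kind,
    pre_cell = first$pre_cell,
    post_targets = unname(split(raw$post_cell, grp)),
    first_section = first$first_section, n_sections = first$n_sections,
    thickness_nm = unname(Map(parse_profile, first$thickness_profile,
                              first$n_sections)),
    unpolarized = !is.na(first$unpolarized) & first$unpolarized,
    vesicle_classes = unname(lapply(first$vesicle_classes, split_semi)),
    pre_compartment = first$pre_compartment,
    post_compartments = unname(split(raw$post_compartment, grp))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_contacts
#' @param x a [connectome()] or a contact tibble.
#' @export
write_contacts <- function(x, path) {
  contacts <- if (inherits(x, "connectome")) x$contacts else x
  arity <- lengths(contacts$post_targets)
  fmt_profile <- function(p) {
    if (is.null(p)) "" else paste(format(p, trim = TRUE, scientific = FALSE),
                                  collapse = ";")
  }
  flat <- tibble::tibble(
    contact_id = rep(contacts$contact_id, arity),
    kind = rep(contacts$kind, arity),
    pre_cell = rep(contacts$pre_cell, arity),
    post_cell = unlist(contacts$post_targets),
    post_rank = unlist(lapply(arity, seq_len)),
    first_section = rep(contacts$first_section, arity),
    n_sections = rep(contacts$n_sections, arity),
    thickness_profile = rep(vapply(contacts$thickness_nm, fmt_profile, character(1)), arity),
    unpolarized = rep(contacts$unpolarized, arity),
    vesicle_classes = rep(vapply(contacts$vesicle_classes,
                                 function(v) paste(v, collapse = ";"), character(1)), arity),
    pre_compartment = rep(contacts$pre_compartment, arity),
    post_compartment = {
      pc <- contacts$post_compartments
      unlist(lapply(seq_along(pc), function(i) {
        v <- pc[[i]]
        if (length(v) == arity[i]) v else rep(NA_character_, arity[i])
      }))
    }
  )
  readr::write_csv(flat, path, progress = FALSE)
  invisible(path)
}

#' Read and write cell rosters
#'
#' CSV schema: `cell_id,cell_type,region,side,nucleus_section,nucleus_x,`
#' `nucleus_y,is_neuron,has_cilium`.
#'
#' @param path file path.
#' @return a roster tibble.
#' @export
read_roster <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    cell_id = readr::col_character(), cell_type = readr::col_character(),
    region = readr::col_character(), side = readr::col_character(),
    nucleus_section = readr::col_integer(), nucleus_x = readr::col_double(),
    nucleus_y = readr::col_double(), is_neuron = readr::col_logical(),
    has_cilium = readr::col_logical()
  ), progress = FALSE)
}

#' @rdname read_roster
#' @param cells roster tibble.
#' @export
write_roster <- function(cells, path) {
  readr::write_csv(cells, path, progress = FALSE)
  invisible(path)
}

#' Read and write a thickness schedule
#'
#' YAML (or JSON, which is a YAML subset) list of records with fields
#' `start_section`, `end_section`, `thickness_nm`.
#'
#' @param path file path.
#' @return a thickness-schedule tibble.
#' @export
read_thickness_schedule <- function(path) {
  raw <- yaml::read_yaml(path)
  dplyr::bind_rows(lapply(raw, tibble::as_tibble))
}

#' @rdname read_thickness_schedule
#' @param schedule thickness-schedule tibble.
#' @export
write_thickness_schedule <- function(schedule, path) {
  recs <- lapply(seq_len(nrow(schedule)), function(i) as.list(schedule[i, ]))
  yaml::write_yaml(recs, path)
  invisible(path)
}

#' Write an edge table as a square connectivity matrix
#'
#' Rows are presynaptic cells, columns postsynaptic cells, entries the
#' cumulative depth of contact in micrometres. With `pool_muscle = TRUE`
#' the dorsal and medial muscle-band columns are summed into one pooled
#' column per side (`muscle-L`, `muscle-R`), as in the published matrix
#' where the two bands are electrically coupled. Output is deterministic:
#' fixed label order, 6 significant digits.
#'
#' @param edge_table output of [build_edge_table()].
#' @param roster roster tibble (defines the label set and muscle sides).
#' @param path output CSV path.
#' @param pool_muscle pool dorsal+medial muscle columns per side.
#' @param labels optional explicit label order; default: roster order.
#' @export
write_matrix <- function(edge_table, roster, path, pool_muscle = FALSE,
                         labels = NULL) {
  if (is.null(labels)) labels <- roster$cell_id
  if (anyDuplicated(labels)) abort("duplicate labels in matrix")
  m <- matrix(0, nrow = length(labels), ncol = length(labels),
              dimnames = list(labels, labels))
  keep <- edge_table$pre %in% labels & edge_table$post %in% labels
  et <- edge_table[keep, , drop = FALSE]
  m[cbind(et$pre, et$post)] <- et$cumulative_depth_um
  if (pool_muscle) {
    is_mus <- roster$cell_type == "muscle" | roster$region == "muscle"
    for (s in c("left", "right")) {
      ids <- roster$cell_id[is_mus & roster$side == s]
      ids <- intersect(ids, colnames(m))
      if (length(ids) > 0) {
        pooled <- rowSums(m[, ids, drop = FALSE])
        newname <- if (s == "left") "muscle-L" else "muscle-R"
        m <- m[!rownames(m) %in% ids, !colnames(m) %in% ids, drop = FALSE]
        m <- cbind(m, pooled[rownames(m)])
        colnames(m)[ncol(m)] <- newname
        m <- rbind(m, 0)
        rownames(m)[nrow(m)] <- newname
      }
    }
  }
  df <- tibble::as_tibble(signif(m, 6), rownames = "cell_id")
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Read a connectivity matrix into an edge table
#'
#' Zero entries produce no edge rows. The matrix must be square with
#' unique row/column labels in matching order.
#'
#' @param path CSV written by [write_matrix()] (or a converted deposited
#'   matrix with the same shape).
#' @param kind edge kind to stamp on the rows.
#' @return edge-table tibble (`pre`, `post`, `kind`, `cumulative_depth_um`;
#'   contact counts and section totals are not recoverable from a matrix
#'   and are returned `NA`).
#' @export
read_matrix <- function(path, kind = "chemical") {
  df <- readr::read_csv(path, col_types = readr::cols(
    cell_id = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  labels <- df$cell_id
  m <- as.matrix(df[, -1, drop = FALSE])
  if (nrow(m) != ncol(m)) abort("matrix is not square")
  if (anyDuplicated(labels) || anyDuplicated(colnames(m))) {
    abort("duplicate matrix labels")
  }
  if (!identical(labels, colnames(m))) {
    if (!setequal(labels, colnames(m))) abort("row and column labels differ")
    m <- m[, labels, drop = FALSE]
  }
  rownames(m) <- labels
  nz <- which(m != 0, arr.ind = TRUE)
  tibble::tibble(
    pre = labels[nz[, 1]], post = colnames(m)[nz[, 2]], kind = kind,
    n_contacts = NA_integer_, total_sections = NA_integer_,
    cumulative_depth_um = m[nz]
  ) |> dplyr::arrange(.data$pre, .data$post)
}

#' Export an edge table as GraphML
#'
#' Nodes carry `cell_type`, `region` and `side`; edges carry `kind`,
#' `n_contacts` and `cumulative_depth_um`. Gap-junction tables are written
#' as undirected graphs, chemical tables as directed.
#'
#' @param edge_table output of [build_edge_table()].
#' @param roster roster tibble supplying node attributes.
#' @param path output path.
#' @export
export_graphml <- function(edge_table, roster, path) {
  directed <- !all(edge_table$kind == "gap")
  esc <- function(x) {
    x <- ifelse(is.na(x), "", x)
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  nodes <- sort(unique(c(edge_table$pre, edge_table$post)))
  idx <- match(nodes, roster$cell_id)
  node_xml <- sprintf(
    paste0('<node id="%s"><data key="d0">%s</data>',
           '<data key="d1">%s</data><data key="d2">%s</data></node>'),
    esc(nodes), esc(roster$cell_type[idx]), esc(roster$region[idx]),
    esc(roster$side[idx]))
  edge_xml <- sprintf(
    paste0('<edge source="%s" target="%s"><data key="d3">%s</data>',
           '<data key="d4">%d</data><data key="d5">%s</data></edge>'),
    esc(edge_table$pre), esc(edge_table$post), esc(edge_table$kind),
    edge_table$n_contacts,
    vapply(edge_table$cumulative_depth_um, format, character(1), digits = 6))
  keys <- c(
    '<key id="d0" for="node" attr.name="cell_type" attr.type="string"/>',
    '<key id="d1" for="node" attr.name="region" attr.type="string"/>',
    '<key id="d2" for="node" attr.name="side" attr.type="string"/>',
    '<key id="d3" for="edge" attr.name="kind" attr.type="string"/>',
    '<key id="d4" for="edge" attr.name="n_contacts" attr.type="int"/>',
    '<key id="d5" for="edge" attr.name="cumulative_depth_um" attr.type="double"/>')
  txt <- paste0(
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    paste(keys, collapse = ""),
    sprintf('<graph id="G" edgedefault="%s">',
            if (directed) "directed" else "undirected"),
    paste(node_xml, collapse = ""), paste(edge_xml, collapse = ""),
    "</graph></graphml>")
  doc <- xml2::read_xml(txt)   # parse once: guarantees well-formed output
  xml2::write_xml(doc, path)
  invisible(path)
}
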