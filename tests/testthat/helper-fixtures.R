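# tiny in-code fixtures shared across test files

toy_roster <- function() {
  tibble::tibble(
    cell_id = c("A", "B", "C", "mu1", "bl", "ep"),
    cell_type = c("prRN", "MGIN", "MN", "muscle", "basal-lamina", "ependymal"),
    region = c("BV", "MG", "MG", "muscle", "other", "BV"),
    side = c("left", "left", "right", "left", "midline", "right"),
    nucleus_section = c(5L, 5L, 5L, NA, NA, 5L),
    nucleus_x = c(300, 350, 700, NA, NA, 650),
    nucleus_y = 500,
    is_neuron = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    has_cilium = NA
  )
}

toy_contact <- function(id, pre, posts, kind = "chemical", first = 10L,
                        n_sec = 3L, thickness = NULL, unpol = FALSE,
                        ves = character(0), pre_cmp = "axon",
                        post_cmps = NULL) {
  tibble::tibble(
    contact_id = id, kind = kind, pre_cell = pre, post_targets = list(posts),
    first_section = first, n_sections = n_sec,
    thickness_nm = list(thickness), unpolarized = unpol,
    vesicle_classes = list(ves), pre_compartment = pre_cmp,
    post_compartments = list(post_cmps %||% rep("axon", length(posts)))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

toy_connectome <- function(contacts = NULL) {
  contacts <- contacts %||% dplyr::bind_rows(
    toy_contact("c1", "A", "B"),
    toy_contact("c2", "B", "C", n_sec = 2L)
  )
  cionaconn::connectome(toy_roster(), contacts)
}

flat_schedule <- function(thickness = 60, n = 10000L) {
  tibble::tibble(start_section = 0L, end_section = n, thickness_nm = thickness)
}

# a small random connectome exercising polyads and both kinds
random_small_connectome <- function(seed, n_cells = 12, n_contacts = 60) {
  set.seed(seed)
  ids <- sprintf("cell%02d", seq_len(n_cells))
  roster <- tibble::tibble(
    cell_id = ids, cell_type = "BVIN", region = "BV",
    side = sample(c("left", "right", "midline"), n_cells, replace = TRUE),
    nucleus_section = 10L, nucleus_x = 500, nucleus_y = 500,
    is_neuron = TRUE, has_cilium = NA
  )
  contacts <- dplyr::bind_rows(lapply(seq_len(n_contacts), function(i) {
    pre <- sample(ids, 1)
    arity <- sample(1:3, 1, prob = c(0.8, 0.15, 0.05))
    posts <- sample(setdiff(ids, pre), arity)
    kind <- if (stats::runif(1) < 0.25) "gap" else "chemical"
    if (kind == "gap") posts <- posts[1]
    toy_contact(sprintf("r%03d", i), pre, posts, kind = kind,
                first = sample(0:50, 1), n_sec = sample(1:8, 1),
                unpol = kind == "chemical" && stats::runif(1) < 0.1,
                ves = if (stats::runif(1) < 0.2) c("small-lucent", "dcv-medium")
                      else "small-lucent")
  }))
  cionaconn::connectome(roster, contacts, flat_schedule())
}
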