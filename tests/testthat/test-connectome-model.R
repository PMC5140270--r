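test_that("validation reports nothing on a well-formed toy and finds defects", {
  expect_identical(nrow(validate_connectome(toy_connectome())), 0L)

  bad <- toy_connectome(dplyr::bind_rows(
    toy_contact("c1", "A", "X"),                      # dangling post
    toy_contact("c2", "A", c("B", "C"), kind = "gap") # polyadic gap
  ))
  rep <- validate_connectome(bad)
  expect_identical(sum(rep$finding == "dangling_reference"), 1L)
  expect_identical(sum(rep$finding == "polyadic_gap"), 1L)

  zero <- toy_connectome(toy_contact("c1", "A", "B", n_sec = 0L))
  expect_true("zero_length_span" %in% validate_connectome(zero)$finding)
})

test_that("sidedness rule: strict left/right, midline on intersection", {
  cells <- toy_roster()[1:3, ]
  cells$nucleus_x <- c(500, 490, 510)   # on line, 10 px left, 10 px right
  out <- assign_side(cells, midline = 500, nucleus_radius = 2)
  expect_identical(out$side, c("midline", "left", "right"))

  cells$nucleus_x <- c(NA, 490, 510)
  expect_warning(out2 <- assign_side(cells, 500), "unassigned")
  expect_identical(out2$side[1], "unassigned")
})

test_that("assign_side is exhaustive and mutually exclusive", {
  set.seed(4)
  n <- 200
  cells <- tibble::tibble(
    cell_id = sprintf("c%03d", 1:n), cell_type = "BVIN", region = "BV",
    side = "unassigned",
    nucleus_section = sample(c(NA, 0:100), n, replace = TRUE),
    nucleus_x = ifelse(runif(n) < 0.05, NA, runif(n, 0, 1000)),
    nucleus_y = 500, is_neuron = TRUE, has_cilium = NA
  )
  out <- suppressWarnings(assign_side(cells, 500, nucleus_radius = 5))
  expect_true(all(out$side %in% c("left", "right", "midline", "unassigned")))
  no_pos <- is.na(cells$nucleus_x) | is.na(cells$nucleus_section)
  expect_identical(out$side == "unassigned", no_pos)
  ok <- !no_pos
  expect_identical(out$side[ok] == "left", cells$nucleus_x[ok] < 495)
  expect_identical(out$side[ok] == "right", cells$nucleus_x[ok] > 505)
})

test_that("sided roster reproduces the published CNS totals 88/15/75", {
  roster <- default_roster()
  # positions consistent with the declared sides, then re-derive sides
  set.seed(9)
  off <- runif(nrow(roster), 10, 200)
  roster$nucleus_section <- 100L
  roster$nucleus_x <- 500 + ifelse(roster$side == "left", -off,
                                   ifelse(roster$side == "right", off, 0))
  rederived <- assign_side(roster, 500)
  cns <- rederived[rederived$region %in% c("BV", "neck", "MG", "CNC") &
                     rederived$is_neuron, ]
  counts <- table(cns$side)
  expect_identical(as.integer(counts[c("left", "midline", "right")]),
                   c(88L, 15L, 75L))
})

test_that("contact depth multiplies span by per-section thickness", {
  conn <- toy_connectome(dplyr::bind_rows(
    toy_contact("c1", "A", "B", n_sec = 1L),
    toy_contact("c2", "A", "B", n_sec = 5L, thickness = rep(70, 5)),
    toy_contact("c3", "A", "C", n_sec = 29L)
  ))
  d <- contact_depth(conn)
  # brute-force per-section loop for the 29-section maximum span
  brute <- sum(vapply(0:28, function(s) 60, numeric(1))) / 1000
  expect_equal(d, c(0.06, 0.35, brute))
  expect_equal(brute, 1.74)
})

test_that("depth sums true per-section values across thickness boundaries", {
  sched <- default_thickness_schedule()
  conn <- connectome(toy_roster(),
                     toy_contact("c1", "A", "B", first = 3370L, n_sec = 10L),
                     sched)
  # sections 3370..3379: five at 60 nm, five at 70 nm
  brute <- sum(vapply(3370:3379, function(s) {
    z <- sched[sched$start_section <= s & sched$end_section >= s, ]
    z$thickness_nm
  }, numeric(1))) / 1000
  expect_equal(contact_depth(conn), brute)
  expect_equal(brute, 0.65)
})

test_that("depth is additive over a partition of the span", {
  sched <- default_thickness_schedule()
  set.seed(11)
  for (i in 1:20) {
    first <- sample(0:6800, 1)
    n_sec <- sample(1:60, 1)
    n_sec <- min(n_sec, 6927 - first + 1)
    cut <- sample(seq_len(n_sec), 1)
    whole <- toy_contact("w", "A", "B", first = first, n_sec = n_sec)
    left <- toy_contact("l", "A", "B", first = first, n_sec = cut)
    parts <- if (cut < n_sec) {
      dplyr::bind_rows(left, toy_contact("r", "A", "B",
                                         first = first + cut,
                                         n_sec = n_sec - cut))
    } else left
    expect_equal(sum(contact_depth(parts, sched)),
                 contact_depth(whole, sched))
  }
})

test_that("spans outside the schedule raise an error naming the contact", {
  conn <- connectome(toy_roster(),
                     toy_contact("cX", "A", "B", first = 6920L, n_sec = 20L))
  expect_error(contact_depth(conn), "cX")
})

test_that("dyads contribute full depth to every post target", {
  conn <- toy_connectome(toy_contact("d1", "A", c("B", "C")))
  et <- build_edge_table(conn, "chemical")
  expect_identical(nrow(et), 2L)
  expect_equal(et$cumulative_depth_um, c(0.18, 0.18))
  expect_identical(et$total_sections, c(3L, 3L))
  expect_identical(sort(et$post), c("B", "C"))

  # adding a 1-section contact then filtering at 2 sections leaves rows as-is
  conn2 <- toy_connectome(dplyr::bind_rows(
    toy_contact("d1", "A", c("B", "C")),
    toy_contact("s1", "A", "B", n_sec = 1L)
  ))
  et2 <- build_edge_table(conn2, "chemical", min_sections = 2)
  expect_equal(et2, et)
})

test_that("edge-table depth conserves total contact depth times arity", {
  for (seed in 1:5) {
    conn <- random_small_connectome(seed)
    et <- build_edge_table(conn, "chemical")
    chem <- conn$contacts[conn$contacts$kind == "chemical", ]
    expected <- sum(contact_depth(chem, conn$thickness_schedule) *
                      lengths(chem$post_targets))
    expect_equal(sum(et$cumulative_depth_um), expected)

    # dropping one target from every dyad removes exactly those depths
    is_dyad <- lengths(chem$post_targets) == 2
    trimmed <- chem
    trimmed$post_targets[is_dyad] <-
      lapply(trimmed$post_targets[is_dyad], function(p) p[1])
    conn_tr <- connectome(conn$cells, dplyr::bind_rows(
      trimmed, conn$contacts[conn$contacts$kind == "gap", ]),
      conn$thickness_schedule)
    et_tr <- build_edge_table(conn_tr, "chemical")
    drop_depth <- sum(contact_depth(chem[is_dyad, ], conn$thickness_schedule))
    expect_equal(sum(et$cumulative_depth_um) - sum(et_tr$cumulative_depth_um),
                 drop_depth)
  }
})

test_that("gap edges use canonical unordered pairs", {
  conn <- toy_connectome(dplyr::bind_rows(
    toy_contact("g1", "B", "A", kind = "gap"),
    toy_contact("g2", "A", "B", kind = "gap")
  ))
  et <- build_edge_table(conn, "gap")
  expect_identical(nrow(et), 1L)
  expect_identical(et$pre, "A")
  expect_identical(et$n_contacts, 2L)
})

test_that("exclusion keywords drop the right targets and reject unknowns", {
  conn <- toy_connectome(dplyr::bind_rows(
    toy_contact("c1", "A", "B"),
    toy_contact("c2", "A", "mu1"),
    toy_contact("c3", "A", "bl"),
    toy_contact("c4", "A", "ep"),
    toy_contact("c5", "A", c("B", "bl"))   # dyad: neuron kept, bl dropped
  ))
  et <- build_edge_table(conn, "chemical",
                         exclusions = c("bm", "Ep", "Mu"))
  expect_identical(sort(unique(et$post)), "B")
  expect_identical(sum(et$n_contacts), 2L)
  expect_error(build_edge_table(conn, "chemical", exclusions = "bogus"),
               "unknown exclusion")
})

test_that("unpolarized contacts count once unless expansion is requested", {
  conn <- toy_connectome(toy_contact("u1", "A", "B", unpol = TRUE))
  et1 <- build_edge_table(conn, "chemical")
  expect_identical(nrow(et1), 1L)
  et2 <- build_edge_table(conn, "chemical", expand_unpolarized = TRUE)
  expect_identical(nrow(et2), 2L)
  expect_setequal(et2$pre, c("A", "B"))
})
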