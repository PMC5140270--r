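test_that("sided counts tally a toy roster and match a brute tally", {
  roster <- tibble::tibble(
    cell_id = c("a", "b", "c", "d"), cell_type = "BVIN", region = "BV",
    side = c("left", "left", "right", "midline"),
    nucleus_section = 1L, nucleus_x = 1, nucleus_y = 1,
    is_neuron = TRUE, has_cilium = NA)
  sc <- sided_counts(roster)
  expect_equal(unname(unlist(sc$total[, c("left", "centre", "right")])),
               c(2L, 1L, 1L))

  set.seed(61)
  big <- tibble::tibble(
    cell_id = sprintf("n%03d", 1:120),
    cell_type = sample(c("MN", "MGIN", "BVIN"), 120, replace = TRUE),
    region = sample(c("BV", "MG"), 120, replace = TRUE),
    side = sample(c("left", "right", "midline", "unassigned"), 120,
                  replace = TRUE),
    nucleus_section = 1L, nucleus_x = 1, nucleus_y = 1,
    is_neuron = TRUE, has_cilium = NA)
  sc2 <- sided_counts(big)
  tal <- table(big$side)
  expect_identical(sc2$total$left, as.integer(tal[["left"]]))
  expect_identical(sc2$total$unassigned, as.integer(tal[["unassigned"]]))
  expect_identical(sum(unlist(sc2$total)), 120L)
})

test_that("default roster reproduces the published census margins", {
  roster <- default_roster()
  sc <- sided_counts(roster[roster$region %in% c("BV", "neck", "MG", "CNC"), ])
  expect_equal(unname(unlist(sc$total[, c("left", "centre", "right")])),
               c(88L, 15L, 75L))
  by_region <- sc$by_region
  bv <- by_region[by_region$region == "BV", ]
  expect_equal(unname(unlist(bv[, c("left", "centre", "right")])),
               c(72L, 14L, 57L))
})

test_that("NMJ left:right ratios: symmetric toy, brute-force percentages", {
  roster <- default_roster()
  mk_nmj <- function(n_left, n_right, spans_l = 3L, spans_r = 3L) {
    dplyr::bind_rows(
      lapply(seq_len(n_left), function(i) {
        toy_contact(sprintf("L%03d", i), "MN1L", "mus-dorsal-L",
                    n_sec = spans_l)
      }),
      lapply(seq_len(n_right), function(i) {
        toy_contact(sprintf("R%03d", i), "MN1R", "mus-dorsal-R",
                    n_sec = spans_r)
      })
    )
  }
  conn <- connectome(roster, mk_nmj(10, 10))
  r <- nmj_lr_ratio(conn, c("MN1L", "MN1R"))
  expect_equal(c(r$left_pct_by_count, r$right_pct_by_count), c(50, 50))
  expect_equal(c(r$left_pct_by_sections, r$right_pct_by_sections), c(50, 50))

  set.seed(71)
  nl <- sample(5:50, 1); nr <- sample(5:50, 1)
  conn2 <- connectome(roster, mk_nmj(nl, nr, spans_l = 4L, spans_r = 2L))
  r2 <- nmj_lr_ratio(conn2, c("MN1L", "MN1R"))
  expect_equal(r2$left_pct_by_count + r2$right_pct_by_count, 100)
  expect_lte(abs(r2$left_pct_by_count - 100 * nl / (nl + nr)), 1)
  expect_equal(r2$left_sections, 4 * nl)
  expect_error(nmj_lr_ratio(connectome(roster, mk_nmj(1, 1)[0, ]),
                            c("MN2L", "MN2R")),
               "no neuromuscular junctions")
})

test_that("largest-remainder percentages always sum to the whole", {
  expect_equal(sum(largest_remainder_pct(c(1, 2))), 100)
  expect_equal(largest_remainder_pct(c(46, 54)), c(46, 54))
  set.seed(72)
  for (i in 1:25) {
    counts <- sample(1:500, sample(2:5, 1), replace = TRUE)
    pct <- largest_remainder_pct(counts)
    expect_equal(sum(pct), 100)
    expect_true(all(abs(pct - 100 * counts / sum(counts)) <= 1))
  }
})

test_that("relay laterality: all-left class, random classes vs brute force", {
  roster <- default_roster()
  mg_left <- roster$cell_id[roster$region == "MG" & roster$side == "left"][1:2]
  et <- tibble::tibble(pre = roster$cell_id[roster$cell_type == "prRN"][1:2],
                       post = mg_left, kind = "chemical", n_contacts = 1L,
                       total_sections = 3L, cumulative_depth_um = c(0.2, 0.4))
  rl <- relay_laterality(et, roster, "prRN")
  expect_equal(rl$pct_left_by_depth, 100)
  expect_equal(rl$pct_left_by_edges, 100)

  set.seed(73)
  mg <- roster$cell_id[roster$region == "MG" & roster$is_neuron &
                         roster$side %in% c("left", "right")]
  pre <- sample(roster$cell_id[roster$cell_type == "antRN"], 30, replace = TRUE)
  post <- sample(mg, 30, replace = TRUE)
  et2 <- tibble::tibble(pre = pre, post = post, kind = "chemical",
                        n_contacts = 1L, total_sections = 3L,
                        cumulative_depth_um = round(runif(30, 0.06, 1), 3)) |>
    dplyr::distinct(pre, post, .keep_all = TRUE)
  rl2 <- relay_laterality(et2, roster, "antRN")
  sides <- roster$side[match(et2$post, roster$cell_id)]
  expect_equal(rl2$pct_left_by_depth,
               100 * sum(et2$cumulative_depth_um[sides == "left"]) /
                 sum(et2$cumulative_depth_um))
  expect_equal(rl2$left_edges + rl2$right_edges, nrow(et2))
  expect_warning(relay_laterality(et2, roster, c("antRN", "coronet")),
                 "coronet")
})

test_that("side-sorted matrix: block order, conservation, quadrant sums", {
  roster <- tibble::tibble(
    cell_id = c("l1", "l2", "r1", "r2"), cell_type = "BVIN", region = "BV",
    side = c("left", "left", "right", "right"),
    nucleus_section = 1L, nucleus_x = 1, nucleus_y = 1,
    is_neuron = TRUE, has_cilium = NA)
  m <- matrix(1:16, 4, 4, dimnames = list(roster$cell_id, roster$cell_id))
  sorted <- sort_matrix_by_side(m, roster)
  # rows left-first, columns right-first: top-left block is L -> R
  expect_identical(rownames(sorted$matrix), c("l1", "l2", "r1", "r2"))
  expect_identical(colnames(sorted$matrix), c("r1", "r2", "l1", "l2"))
  expect_equal(sum(sorted$matrix), sum(m))
  q <- sorted$quadrants
  lr <- q[q$quadrant == "L->R", ]
  expect_equal(sum(sorted$matrix[lr$row_start:lr$row_end,
                                 lr$col_start:lr$col_end]),
               sum(m[c("l1", "l2"), c("r1", "r2")]))

  # applying the sort twice gives the same ordering (stable permutation)
  twice <- sort_matrix_by_side(sorted$matrix, roster)
  expect_identical(rownames(twice$matrix), rownames(sorted$matrix))

  # random matrix with midline cells: quadrant sums partition brute-force
  set.seed(81)
  ids <- sprintf("c%02d", 1:9)
  roster2 <- tibble::tibble(
    cell_id = ids, cell_type = "BVIN", region = "BV",
    side = sample(c("left", "right", "midline"), 9, replace = TRUE),
    nucleus_section = 1L, nucleus_x = 1, nucleus_y = 1,
    is_neuron = TRUE, has_cilium = NA)
  m2 <- matrix(runif(81), 9, 9, dimnames = list(ids, ids))
  s2 <- sort_matrix_by_side(m2, roster2)
  expect_equal(sum(s2$matrix), sum(m2))
  for (i in seq_len(nrow(s2$quadrants))) {
    qq <- s2$quadrants[i, ]
    pre_side <- if (startsWith(qq$quadrant, "L")) "left" else "right"
    post_side <- if (endsWith(qq$quadrant, "L")) "left" else "right"
    brute <- sum(m2[roster2$cell_id[roster2$side == pre_side],
                    roster2$cell_id[roster2$side == post_side]])
    got <- if (qq$row_end >= qq$row_start && qq$col_end >= qq$col_start) {
      sum(s2$matrix[qq$row_start:qq$row_end, qq$col_start:qq$col_end,
                    drop = FALSE])
    } else 0
    expect_equal(got, brute, info = qq$quadrant)
  }

  roster_bad <- dplyr::mutate(roster, side = replace(side, 1, "unassigned"))
  expect_error(sort_matrix_by_side(m, roster_bad), "l1")
})

test_that("side-diff: mirror symmetry, single asymmetric edge, brute force", {
  mirror <- cionaconn:::mirror_fixture()
  et <- build_edge_table(mirror$connectome, "chemical")
  rep0 <- side_diff(et, mirror$homologs)
  expect_identical(nrow(rep0$left_only), 0L)
  expect_identical(nrow(rep0$right_only), 0L)
  expect_identical(nrow(rep0$both_sides), 3L)
  expect_equal(rep0$both_sides$weight_ratio_lr, rep(1, 3))

  # one extra left edge -> exactly one left-only entry
  extra <- toy_contact("x1", "senA-L", "mnA-L")
  conn2 <- connectome(mirror$connectome$cells,
                      dplyr::bind_rows(mirror$connectome$contacts, extra))
  rep1 <- side_diff(build_edge_table(conn2, "chemical"), mirror$homologs)
  expect_identical(nrow(rep1$left_only), 1L)
  expect_identical(rep1$left_only$pre_homolog, "senA-L")

  # non-bijective mapping errors
  bad <- dplyr::bind_rows(mirror$homologs,
                          tibble::tibble(left = "senA-L", right = "inA-R"))
  expect_error(side_diff(et, bad), "bijection")

  # random paired networks classified identically by direct set comparison
  set.seed(91)
  left_ids <- sprintf("L%02d", 1:6)
  right_ids <- sprintf("R%02d", 1:6)
  hp <- tibble::tibble(left = left_ids, right = right_ids)
  rnd_pairs <- function(ids, n) {
    p <- expand.grid(pre = ids, post = ids, stringsAsFactors = FALSE)
    p <- p[p$pre != p$post, ]
    p[sample(nrow(p), n), ]
  }
  le <- rnd_pairs(left_ids, 10)
  re <- rnd_pairs(right_ids, 10)
  et_r <- tibble::tibble(
    pre = c(le$pre, re$pre), post = c(le$post, re$post),
    kind = "chemical", n_contacts = 1L, total_sections = 2L,
    cumulative_depth_um = runif(20, 0.06, 1))
  rep_r <- side_diff(et_r, hp)
  canon <- setNames(c(left_ids, left_ids), c(left_ids, right_ids))
  lkeys <- paste0(canon[le$pre], ">", canon[le$post])
  rkeys <- paste0(canon[re$pre], ">", canon[re$post])
  expect_identical(nrow(rep_r$both_sides), length(intersect(lkeys, rkeys)))
  expect_identical(nrow(rep_r$left_only), length(setdiff(lkeys, rkeys)))
  expect_identical(nrow(rep_r$right_only), length(setdiff(rkeys, lkeys)))
})

test_that("graph unioned with its mirrored copy has no one-sided edges", {
  set.seed(92)
  left_ids <- sprintf("L%02d", 1:5)
  right_ids <- sprintf("R%02d", 1:5)
  hp <- tibble::tibble(left = left_ids, right = right_ids)
  p <- expand.grid(pre = left_ids, post = left_ids, stringsAsFactors = FALSE)
  p <- p[p$pre != p$post, ]
  p <- p[sample(nrow(p), 8), ]
  mirror_map <- setNames(right_ids, left_ids)
  et <- tibble::tibble(
    pre = c(p$pre, unname(mirror_map[p$pre])),
    post = c(p$post, unname(mirror_map[p$post])),
    kind = "chemical", n_contacts = 1L, total_sections = 2L,
    cumulative_depth_um = rep(runif(8, 0.06, 1), 2))
  rep <- side_diff(et, hp)
  expect_identical(nrow(rep$left_only), 0L)
  expect_identical(nrow(rep$right_only), 0L)
})
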