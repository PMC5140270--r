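test_that("summary ratios satisfy their defining identities", {
  for (seed in c(2, 5)) {
    conn <- random_small_connectome(seed, n_contacts = 80)
    s <- summarize_contacts(conn)$by_kind
    for (i in seq_len(nrow(s))) {
      if (s$total_contacts[i] > 0) {
        expect_equal(s$mean_sections_per_contact[i],
                     s$total_sections[i] / s$total_contacts[i])
      }
    }
    expect_true(all(s$pct_unpolarized >= 0 & s$pct_unpolarized <= 100,
                    na.rm = TRUE))
    # filtering at two sections never increases any count
    filt <- conn
    filt$contacts <- filt$contacts[filt$contacts$n_sections >= 2, ]
    s2 <- summarize_contacts(filt)$by_kind
    expect_true(all(s2$total_contacts <= s$total_contacts))
    expect_true(all(s2$total_sections <= s$total_sections))
  }
})

test_that("empty connectome warns and reports zeros", {
  empty <- connectome(toy_roster(), toy_connectome()$contacts[0, ])
  expect_warning(s <- summarize_contacts(empty), "no contacts")
  expect_identical(s$by_kind$total_contacts, c(0L, 0L))
})

test_that("polyad distribution: shares match construction and brute tally", {
  # 93 dyads + 7 triads -> dyad share 93%
  cts <- dplyr::bind_rows(
    lapply(1:93, function(i) toy_contact(sprintf("d%02d", i), "A", c("B", "C"))),
    lapply(1:7, function(i) toy_contact(sprintf("t%02d", i), "A", c("B", "C", "mu1")))
  )
  pd <- polyad_distribution(toy_connectome(cts))
  expect_equal(pd$dyad_share, 0.93)
  expect_equal(pd$polyad_fraction, 1)

  # monads only: fraction 0, share absent
  mon <- dplyr::bind_rows(lapply(1:10, function(i) {
    toy_contact(sprintf("m%02d", i), "A", "B")
  }))
  pd0 <- polyad_distribution(toy_connectome(mon))
  expect_equal(pd0$polyad_fraction, 0)
  expect_true(is.na(pd0$dyad_share))

  # random arities equal an independent tally
  set.seed(31)
  arities <- sample(1:4, 200, replace = TRUE, prob = c(0.7, 0.2, 0.07, 0.03))
  posts <- lapply(arities, function(a) sprintf("p%02d", seq_len(a) + 1))
  cts_r <- dplyr::bind_rows(lapply(seq_along(posts), function(i) {
    toy_contact(sprintf("r%03d", i), "p01", posts[[i]])
  }))
  roster <- tibble::tibble(
    cell_id = sprintf("p%02d", 1:6), cell_type = "BVIN", region = "BV",
    side = "left", nucleus_section = 1L, nucleus_x = 400, nucleus_y = 500,
    is_neuron = TRUE, has_cilium = NA)
  pd_r <- polyad_distribution(connectome(roster, cts_r))
  expect_equal(pd_r$polyad_fraction, mean(arities >= 2))
  expect_equal(pd_r$dyad_share, sum(arities == 2) / sum(arities >= 2))
  expect_identical(sum(pd_r$counts$n), 200L)
})

test_that("compartment fractions sum to one and match construction", {
  all_axon <- dplyr::bind_rows(lapply(1:5, function(i) {
    toy_contact(sprintf("a%d", i), "A", "B")
  }))
  cd <- compartment_distribution(toy_connectome(all_axon))
  expect_identical(nrow(cd), 1L)
  expect_equal(cd$fraction, 1)

  # constructed 68 of 100 onto axon or terminal
  posts <- c(rep("axon", 44), rep("terminal", 24), rep("soma", 20),
             rep("dendrite", 12))
  cts <- dplyr::bind_rows(lapply(seq_along(posts), function(i) {
    toy_contact(sprintf("k%03d", i), "A", "B", post_cmps = posts[i])
  }))
  cd2 <- compartment_distribution(toy_connectome(cts))
  expect_equal(sum(cd2$fraction), 1)
  at <- sum(cd2$fraction[cd2$compartment %in% c("axon", "terminal")])
  expect_equal(at, 0.68)

  # random annotations equal a direct tally
  set.seed(13)
  pool <- c("axon", "terminal", "soma", "dendrite")
  rand <- sample(pool, 150, replace = TRUE)
  cts_r <- dplyr::bind_rows(lapply(seq_along(rand), function(i) {
    toy_contact(sprintf("q%03d", i), "A", "B", post_cmps = rand[i])
  }))
  cd3 <- compartment_distribution(toy_connectome(cts_r))
  tallied <- as.data.frame(table(rand) / length(rand))
  for (i in seq_len(nrow(cd3))) {
    expect_equal(cd3$fraction[i],
                 tallied$Freq[tallied$rand == cd3$compartment[i]])
  }
})

test_that("per-neuron statistics match a two-pass oracle", {
  one <- toy_connectome(dplyr::bind_rows(lapply(1:3, function(i) {
    toy_contact(sprintf("s%d", i), "B", "C")
  })))
  p1 <- per_neuron_stats(one)
  row <- p1$population[p1$population$statistic == "presynaptic_sites", ]
  expect_equal(row$mean, 3)
  expect_equal(row$sd, 0)
  expect_identical(row$n_neurons, 1L)   # only B has presynaptic sites

  # the published range endpoints, constructed: two neurons with 1 and 430
  big <- dplyr::bind_rows(
    toy_contact("x1", "A", "C"),
    lapply(1:430, function(i) toy_contact(sprintf("y%03d", i), "B", "C"))
  )
  p2 <- per_neuron_stats(toy_connectome(big))
  row2 <- p2$population[p2$population$statistic == "presynaptic_sites", ]
  expect_equal(c(row2$min, row2$max), c(1, 430))

  # random data against an independent mean/SD computation
  conn <- random_small_connectome(17, n_contacts = 100)
  p3 <- per_neuron_stats(conn, denominator = "all_neurons", divisor_n = TRUE)
  presyn_oracle <- vapply(conn$cells$cell_id, function(id) {
    sum(conn$contacts$pre_cell == id & conn$contacts$kind == "chemical")
  }, numeric(1))
  row3 <- p3$population[p3$population$statistic == "presynaptic_sites", ]
  expect_equal(row3$mean, mean(presyn_oracle))
  expect_equal(row3$sd, sqrt(mean((presyn_oracle - mean(presyn_oracle))^2)))
  # received synapses count every dyad target separately
  recv_oracle <- vapply(conn$cells$cell_id, function(id) {
    sum(unlist(conn$contacts$post_targets[conn$contacts$kind == "chemical"]) == id)
  }, numeric(1))
  row4 <- p3$population[p3$population$statistic == "received_synapses", ]
  expect_equal(row4$mean, mean(recv_oracle))
})

test_that("scaling fits recover exact and noisy generating laws", {
  # exact line: depth = 2 * synapse count
  tab <- tibble::tibble(n_presyn = 1:20, out_partners = 1:20,
                        total_depth_um = 2 * (1:20))
  fs <- fit_scaling(tab)
  expect_equal(fs$linear$slope, 2)
  expect_equal(fs$linear$r_squared, 1)

  # exact power law S = 3 * P^1.5
  tab2 <- tibble::tibble(out_partners = 1:20,
                         n_presyn = 3 * (1:20)^1.5,
                         total_depth_um = 1)
  fs2 <- fit_scaling(tab2)
  expect_equal(fs2$power$b, 1.5, tolerance = 1e-9)
  expect_equal(fs2$power$a, 3, tolerance = 1e-9)
  expect_equal(fs2$power$r_squared, 1)

  # parameter recovery at n = 150 with multiplicative noise, fixed seed
  set.seed(101)
  P <- sample(1:40, 150, replace = TRUE)
  S <- pmax(1, round(4.5 * P^0.8 * exp(rnorm(150, 0, 0.2))))
  tab3 <- tibble::tibble(n_presyn = S, out_partners = P,
                         total_depth_um = S * 0.21)
  fs3 <- fit_scaling(tab3)
  expect_lt(abs(fs3$power$b - 0.8), 0.1)

  # invariant to row order
  perm <- tab3[sample(nrow(tab3)), ]
  expect_equal(fit_scaling(perm)$power$b, fs3$power$b)

  # non-positive rows are excluded with a warning
  tab4 <- dplyr::bind_rows(tab3, tibble::tibble(
    n_presyn = 0, out_partners = 0, total_depth_um = 0))
  expect_warning(fs4 <- fit_scaling(tab4), "excluded")
  expect_equal(fs4$power$b, fs3$power$b)
})
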