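test_that("connectivity index is passes per contact, bounded by [0, 1]", {
  s <- tibble::tibble(match_id = "M1", team_id = c("A", "B"),
                      condition = "wR", n_p = c(25L, 0L), n_c = c(50L, 12L))
  ci <- connectivity_index(s)
  expect_equal(ci$C, c(0.5, 0))

  s$n_c[1] <- 0L
  expect_error(connectivity_index(s), "no ball contact",
               class = "teamsync_undefined_statistic_error")
})

test_that("connectivity equals the possession-level tally of a simulated match", {
  set.seed(21)
  sim <- simulate_match(match_sim_config("male16"), "M1", wr_position = 1)
  poss <- sim$possessions
  ci <- connectivity_index(summarize_thirds(poss))
  for (i in seq_len(nrow(ci))) {
    sub <- poss[poss$team_id == ci$team_id[i] &
                  poss$condition == ci$condition[i], ]
    expect_equal(ci$C[i], sum(sub$n_passes) / sum(sub$n_contacts))
  }
  expect_true(all(ci$C >= 0 & ci$C <= 1))
})

test_that("relative connectivity is the fractional change against the wR third", {
  expect_equal(relative_connectivity(0.55, 0.50), 0.1)
  expect_equal(relative_connectivity(0.5, 0.5), 0)
  expect_equal(relative_connectivity(0.46, 0.50), -0.08)
  expect_error(relative_connectivity(0.5, 0),
               class = "teamsync_undefined_normalization_error")
  # invariant under common rescaling of both connectivities
  for (a in c(0.5, 1.7, 3)) {
    expect_equal(relative_connectivity(a * 0.42, a * 0.35),
                 relative_connectivity(0.42, 0.35))
  }
})

test_that("relative connectivity table drops team-matches with zero wR connectivity", {
  s <- tibble::tibble(
    match_id = rep("M1", 6),
    team_id = rep(c("A", "B"), each = 3),
    condition = rep(c("wR", "Sy", "nS"), 2),
    n_p = c(10L, 12L, 9L, 0L, 5L, 5L),
    n_c = c(20L, 20L, 20L, 10L, 10L, 10L)
  )
  expect_warning(rc <- relative_connectivity_table(s), "zero wR")
  expect_equal(unique(rc$team_id), "A")
  expect_equal(rc$value[rc$condition == "Sy"], 0.2)
  expect_equal(rc$value[rc$condition == "nS"], -0.1)
})

test_that("sequence-length filters keep the right possessions and nest monotonically", {
  poss <- make_possessions(c(0, 2, 4, 6), c(2, 4, 6, 8))
  expect_equal(filter_possessions(poss, "max", 3)$n_passes, c(0L, 2L))
  expect_equal(filter_possessions(poss, "min", 0), poss)
  expect_equal(filter_possessions(poss, "none"), poss)

  set.seed(3)
  sim <- simulate_match(match_sim_config("male16"), "M1", 2)
  big <- sim$possessions
  expect_equal(filter_possessions(big, "min", 6),
               big[big$n_passes >= 6, ])
  for (b in 0:5) {
    lo <- filter_possessions(big, "max", b)
    hi <- filter_possessions(big, "max", b + 1)
    expect_true(nrow(dplyr::anti_join(lo, hi, by = names(lo))) == 0)
    lo_min <- filter_possessions(big, "min", b + 1)
    hi_min <- filter_possessions(big, "min", b)
    expect_true(nrow(dplyr::anti_join(lo_min, hi_min, by = names(lo))) == 0)
  }
  expect_error(filter_possessions(poss, "min", -1),
               class = "teamsync_argument_error")
})

test_that("condition contrast returns the exact rank p and the medians", {
  expect_equal(condition_contrast(c(1, 2, 3), c(4, 5, 6))$p_value, 0.1)
  same <- c(0.1, -0.2, 0.05, 0)
  expect_equal(condition_contrast(same, same)$p_value, 1)
  res <- condition_contrast(c(1, 2, 3), c(4, 5, 6), test = "t")
  expect_lt(res$p_value, 0.05)
  expect_equal(res$median_Sy, 2)
  expect_equal(res$median_nS, 5)
  expect_error(condition_contrast(1, c(1, 2)),
               class = "teamsync_insufficient_data_error")
})

test_that("an unfiltered sweep row reproduces the plain contrast", {
  set.seed(9)
  sim <- simulate_experiment(match_sim_config("male16", n_matches = 4,
                                              wr_position_counts = c(2, 1, 1)),
                             seed = 9)
  sw <- sweep_sequence_lengths(sim$possessions, 0, "min")
  rc <- relative_connectivity_table(sim$third_summaries)
  direct <- condition_contrast(rc$value[rc$condition == "Sy"],
                               rc$value[rc$condition == "nS"])
  expect_equal(sw$p_rank, direct$p_value)
  expect_equal(sw$median_Sy, direct$median_Sy)
  expect_equal(sw$median_nS, direct$median_nS)
})

test_that("a pass-success effect confined to long sequences sharpens under a min-length filter", {
  # handcrafted team-matches: short possessions noisy but exchangeable
  # across conditions, long possessions more pass-rich under Sy than nS
  set.seed(606)
  rand_short <- function() sample(0:2, 24, replace = TRUE)
  poss <- dplyr::bind_rows(lapply(1:10, function(i) {
    make_team_match(
      sprintf("M%02d", i), sprintf("T%02d", i),
      list(wR = c(rand_short(), rep(4, 4)),
           Sy = c(rand_short(), rep(6, 4)),
           nS = c(rand_short(), rep(4, 4)))
    )
  }))
  sw <- sweep_sequence_lengths(poss, c(0, 3), "min")
  expect_lt(sw$p_rank[sw$bound == 3], sw$p_rank[sw$bound == 0])
})

test_that("sweep rows degrade to NA when the filtered sample collapses", {
  poss <- make_team_match("M1", "T1",
                          list(wR = c(0, 1), Sy = c(0, 1), nS = c(0, 1)))
  expect_message(
    sw <- sweep_sequence_lengths(poss, c(0, 5), "min"),
    "no possessions retained|no team-match|collapsed"
  )
  expect_true(is.na(sw$p_rank[sw$bound == 5]))
})
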