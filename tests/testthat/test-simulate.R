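test_that("match simulation is deterministic under a fixed seed", {
  cfg <- match_sim_config("male16")
  a <- simulate_experiment(cfg, seed = 123)
  b <- simulate_experiment(cfg, seed = 123)
  expect_identical(a$possessions, b$possessions)
  expect_identical(a$schedule, b$schedule)
  c <- simulate_experiment(cfg, seed = 124)
  expect_false(identical(a$possessions, c$possessions))

  sa <- simulate_stroop(stroop_sim_config(), seed = 9)
  sb <- simulate_stroop(stroop_sim_config(), seed = 9)
  expect_identical(sa$trials, sb$trials)
})

test_that("generated tables satisfy every structural invariant of the data model", {
  sim <- simulate_experiment(match_sim_config("male16"), seed = 2)
  expect_silent(validate_possessions(sim$possessions))
  s <- sim$third_summaries
  # 16 matches x 2 teams, one third per condition each
  expect_equal(nrow(s), 16 * 2 * 3)
  per_team <- dplyr::count(s, match_id, team_id)
  expect_true(all(per_team$n == 3))
  sched <- sim$schedule
  per_cond <- dplyr::count(sched, team_id, condition)
  expect_true(all(per_cond$n == 1))
  # in every stimulated third one team hears Sy while the other hears nS
  ras <- sched[sched$condition != "wR", ]
  per_third <- tapply(ras$condition, list(ras$match_id, ras$third),
                      function(x) length(unique(x)))
  expect_true(all(is.na(per_third) | per_third == 2))
  expect_silent(validate_stroop_trials(simulate_stroop(
    stroop_sim_config(group_sizes = stroop_group_sizes()[1:3, ]),
    seed = 3)$trials))
})

test_that("unstimulated thirds are placed per the configured position counts", {
  sim <- simulate_experiment(match_sim_config("male16"), seed = 5)
  wr <- sim$schedule[sim$schedule$condition == "wR", ]
  wr_one <- wr[!duplicated(wr$match_id), ]
  expect_equal(as.integer(table(factor(wr_one$third, levels = 1:3))),
               c(6L, 6L, 4L))
  sim_f <- simulate_experiment(match_sim_config("female14"), seed = 5)
  wr_f <- sim_f$schedule[sim_f$schedule$condition == "wR", ]
  expect_equal(as.integer(table(factor(wr_f$third[!duplicated(wr_f$match_id)],
                                       levels = 1:3))),
               c(5L, 5L, 4L))
  expect_error(match_sim_config("male16", wr_position_counts = c(6, 6, 5)),
               class = "teamsync_config_error")
})

test_that("the nS tempo assignment covers the five per-player tempi", {
  sim <- simulate_match(match_sim_config("male16"), "M1", 1)
  expect_equal(sort(unique(sim$tempi$tempo_bpm)),
               c(119, 133, 147, 154, 161))
  per_team <- tapply(sim$tempi$tempo_bpm, sim$tempi$team_id,
                     function(x) length(unique(x)))
  expect_true(all(per_team == 5))
})

test_that("connectivity of a long simulation converges to the pass-success probability", {
  # under the geometric possession chain, E[passes per possession] = q/(1-q)
  # and C = n_p/n_c -> q
  cfg <- match_sim_config("male16", n_matches = 40,
                          wr_position_counts = c(14, 13, 13),
                          effect_sy = 0, effect_ns = 0)
  sim <- simulate_experiment(cfg, seed = 77)
  s <- sim$third_summaries
  q <- cfg$base_pass_success
  C_all <- sum(s$n_p) / sum(s$n_c)
  expect_lt(abs(C_all - q), 0.01)
  mean_passes <- sum(s$n_p) / sum(s$n_possessions)
  expect_lt(abs(mean_passes - q / (1 - q)), 0.1)
})

test_that("ground truth records the analytic relative connectivity of the injected effects", {
  cfg <- match_sim_config("male16")
  sim <- simulate_experiment(cfg, seed = 1)
  expect_equal(unname(sim$ground_truth$expected_relative_connectivity),
               c(0.04, -0.08))
  null_cfg <- match_sim_config("female14")
  expect_equal(unname(simulate_experiment(null_cfg, seed = 1)$
                        ground_truth$expected_relative_connectivity),
               c(0, 0))
})

test_that("probabilities pushed outside [0,1] by effects are clipped with a warning", {
  expect_warning(match_sim_config("male16", base_pass_success = 0.9,
                                  effect_sy = 0.2),
                 "clipped")
})

test_that("stroop generator reproduces its own median ground truth", {
  cfg <- stroop_sim_config(group_sizes = tibble::tibble(
    gender = "male", phase = "not_applicable", tempo_bpm = 140, n = 200L))
  sim <- simulate_stroop(cfg, seed = 42)
  sel <- select_trials(sim$trials)
  truth <- sim$ground_truth$groups$true_median
  expect_equal(truth,
               (1 - 0.065) * (0.2 + exp(log(1.3) + 0.10)))
  expect_lt(abs(median(sel$rt_s) - truth) / truth, 0.02)
  # music-block effect applies only in block 2
  base_blocks <- sim$trials[sim$trials$block != 2 & !sim$trials$congruent &
                              sim$trials$run == "stroop", ]
  expect_lt(abs(median(base_blocks$rt_s) - truth / (1 - 0.065)) /
              truth, 0.02)
})

test_that("ground-truth report pairs injected and recovered values and flags mismatches", {
  truth <- tibble::tibble(condition = c("Sy", "nS"), truth = c(0.04, -0.08))
  est <- tibble::tibble(condition = c("Sy", "nS"),
                        estimate = c(0.035, -0.074))
  rep <- ground_truth_report(truth, est)
  expect_equal(rep$error, c(-0.005, 0.006), tolerance = 1e-12)
  expect_equal(nrow(ground_truth_report(truth[1, ], est[1, ])), 1)
  expect_error(
    ground_truth_report(truth,
                        tibble::tibble(condition = "wR", estimate = 0)),
    class = "teamsync_pairing_error"
  )
})

test_that("recovered relative-connectivity medians track swept injected effects monotonically", {
  effects <- c(-0.06, 0, 0.06)
  meds <- vapply(seq_along(effects), function(i) {
    cfg <- match_sim_config("male16", effect_sy = effects[i], effect_ns = 0)
    sim <- simulate_experiment(cfg, seed = 500 + i)
    rc <- relative_connectivity_table(sim$third_summaries)
    median(rc$value[rc$condition == "Sy"])
  }, numeric(1))
  expect_true(all(diff(meds) > 0))
})

test_that("a null simulation recovers effects within error of zero", {
  sim <- simulate_experiment(match_sim_config("female14"), seed = 11)
  rc <- relative_connectivity_table(sim$third_summaries)
  est <- tibble::tibble(
    condition = c("Sy", "nS"),
    estimate = c(median(rc$value[rc$condition == "Sy"]),
                 median(rc$value[rc$condition == "nS"]))
  )
  truth <- tibble::tibble(condition = c("Sy", "nS"), truth = c(0, 0))
  rep <- ground_truth_report(truth, est)
  # median of 28 team-match ratios: sampling SD about 0.015
  expect_true(all(abs(rep$error) < 0.06))
})

test_that("the null preset never over-rejects: contrasts and scoring probabilities are conservative", {
  # the Sy and nS relative-connectivity values of a team-match share the
  # same wR denominator, so the two-sample contrast is conservative under
  # the null; the scoring point probability is conservative by construction
  cfg <- match_sim_config("female14")
  n_rep <- 200
  reject_contrast <- logical(n_rep)
  small_P <- logical(n_rep)
  exact_null_prob <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    sim <- simulate_experiment(cfg, seed = 900000 + i)
    rc <- relative_connectivity_table(sim$third_summaries)
    reject_contrast[i] <- condition_contrast(
      rc$value[rc$condition == "Sy"],
      rc$value[rc$condition == "nS"])$p_value <= 0.05
    sw <- scoring_sweep(sim$third_summaries, 1)
    small_P[i] <- sw$P[sw$cond_a == "Sy"] <= 0.05
    # exact null probability of the event {point probability <= 0.05}
    # given this replicate's number of non-tied comparisons: the point
    # probability is not a tail p-value, so this can exceed 0.05
    n_i <- sw$k_a[sw$cond_a == "Sy"] + sw$k_b[sw$cond_a == "Sy"]
    pk <- binomial_probability(n_i - 0:n_i, 0:n_i)
    exact_null_prob[i] <- sum(pk[pk <= 0.05])
  }
  mc_error <- 3 * sqrt(0.05 * 0.95 / n_rep)
  expect_lte(mean(reject_contrast), 0.05 + mc_error)
  se_mix <- sqrt(sum(exact_null_prob * (1 - exact_null_prob))) / n_rep
  expect_lt(abs(mean(small_P) - mean(exact_null_prob)), 3 * se_mix)
})
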