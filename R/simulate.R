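## Seeded generators emulating the statistical structure of both
## experiments with known ground truth.
##
## Match model: within a possession, after each ball contact a pass succeeds
## with probability q (condition dependent); the possession continues on
## success and ends on failure, so the number of passes per possession is
## geometric with success parameter q and n_contacts = n_passes + 1. Summed
## over a third, the connectivity index C = n_p/n_c then converges to q,
## which maps the generator's single behavioural parameter directly onto
## the statistic under study. A goal at possession end becomes more likely
## with the length of the preceding pass sequence (long-distance shots were
## not allowed in the exercise, so scoring requires build-up).

clip01 <- function(p, what) {
  if (any(p < 0) || any(p > 1)) {
    rlang::warn(sprintf("%s clipped into [0, 1]", what))
    p <- pmin(pmax(p, 0), 1)
  }
  p
}

#' Configuration of the match simulator
#'
#' Presets encode the study conditions: `"male16"` (16 matches, thirds
#' without stimulation placed 6/6/4 at beginning/middle/end, pass-success
#' effects chosen so the analytic relative connectivity is +4% under Sy and
#' -8% under nS) and `"female14"` (14 matches, 5/5/4, zero effects).
#'
#' @param preset `"male16"` or `"female14"`.
#' @param n_matches Number of matches.
#' @param players_per_team Players per team (default 5).
#' @param third_minutes Minutes per third (default 10).
#' @param possession_rate Ball possessions per team per minute (default 6;
#'   a small-sided possession exercise changes possession every few
#'   seconds).
#' @param base_pass_success Per-contact pass success probability without
#'   stimulation (default 0.65).
#' @param effect_sy,effect_ns Additive change of the pass-success
#'   probability under the Sy / nS condition. The analytic relative
#'   connectivity of a condition is `effect / base_pass_success`.
#' @param goal_prob_by_passes Goal probability at possession end, indexed
#'   by the number of passes (last element reused for longer sequences);
#'   rises to a plateau.
#' @param wr_position_counts Length-3 counts of matches with the
#'   unstimulated third at the beginning / middle / end; must sum to
#'   `n_matches`.
#' @param ns_tempi Per-player tempi (bpm) of the non-synchronous condition.
#' @return A list of class `match_sim_config`.
#' @export
match_sim_config <- function(preset = c("male16", "female14"),
                             n_matches = NULL,
                             players_per_team = 5,
                             third_minutes = 10,
                             possession_rate = 6,
                             base_pass_success = 0.65,
                             effect_sy = NULL,
                             effect_ns = NULL,
                             goal_prob_by_passes = c(0.005, 0.02, 0.045,
                                                     0.07, 0.09),
                             wr_position_counts = NULL,
                             ns_tempi = NS_TEMPI) {
  preset <- match.arg(preset)
  defaults <- switch(preset,
    male16 = list(n_matches = 16L, wr = c(6L, 6L, 4L),
                  e_sy = 0.04 * base_pass_success,
                  e_ns = -0.08 * base_pass_success),
    female14 = list(n_matches = 14L, wr = c(5L, 5L, 4L), e_sy = 0, e_ns = 0)
  )
  n_matches <- if (is.null(n_matches)) defaults$n_matches else as.integer(n_matches)
  effect_sy <- if (is.null(effect_sy)) defaults$e_sy else effect_sy
  effect_ns <- if (is.null(effect_ns)) defaults$e_ns else effect_ns
  wr_position_counts <- if (is.null(wr_position_counts)) {
    # rescale the preset's pattern when n_matches is overridden
    if (n_matches == defaults$n_matches) defaults$wr else {
      base <- floor(n_matches / 3)
      c(base + (n_matches %% 3 >= 1), base + (n_matches %% 3 >= 2), base)
    }
  } else as.integer(wr_position_counts)
  if (n_matches < 1) {
    ts_error("n_matches must be >= 1", "teamsync_config_error")
  }
  if (length(wr_position_counts) != 3 ||
      sum(wr_position_counts) != n_matches) {
    ts_error("wr_position_counts must be 3 counts summing to n_matches",
             "teamsync_config_error")
  }
  if (possession_rate <= 0 || third_minutes <= 0) {
    ts_error("possession_rate and third_minutes must be positive",
             "teamsync_config_error")
  }
  if (base_pass_success <= 0 || base_pass_success >= 1) {
    ts_error("base_pass_success must lie in (0, 1)", "teamsync_config_error")
  }
  if (length(ns_tempi) != players_per_team) {
    ts_error("ns_tempi must list one tempo per player", "teamsync_config_error")
  }
  q <- clip01(base_pass_success + c(wR = 0, Sy = effect_sy, nS = effect_ns),
              "pass-success probabilities")
  gp <- clip01(goal_prob_by_passes, "goal probabilities")
  structure(
    list(
      preset = preset, n_matches = n_matches,
      players_per_team = players_per_team, third_minutes = third_minutes,
      possession_rate = possession_rate,
      base_pass_success = base_pass_success,
      effect_sy = effect_sy, effect_ns = effect_ns,
      pass_success = q, goal_prob_by_passes = gp,
      wr_position_counts = wr_position_counts, ns_tempi = ns_tempi
    ),
    class = "match_sim_config"
  )
}

team_third_possessions <- function(config, match_id, team_id, condition,
                                   offset) {
  q <- config$pass_success[[condition]]
  n_poss <- stats::rpois(1, config$possession_rate * config$third_minutes)
  if (n_poss == 0) {
    return(NULL)
  }
  n_passes <- stats::rgeom(n_poss, 1 - q)
  gp <- config$goal_prob_by_passes
  goal_p <- gp[pmin(n_passes, length(gp) - 1) + 1]
  list(
    match_id = rep(match_id, n_poss),
    team_id = rep(team_id, n_poss),
    condition = rep(condition, n_poss),
    order_index = offset + 2L * (seq_len(n_poss) - 1L),
    n_passes = n_passes,
    n_contacts = n_passes + 1L,
    goal = stats::rbinom(n_poss, 1, goal_p) == 1
  )
}

#' Simulate one match
#'
#' Generates the three 10-minute thirds of a match: the condition schedule
#' (the unstimulated third at the given position; in the two stimulated
#' thirds one team plays under Sy while the other plays under nS, and vice
#' versa), alternating team possessions with geometric pass chains, and the
#' per-player tempo assignment of the nS thirds.
#'
#' @param config A [match_sim_config()].
#' @param match_id Identifier for the match.
#' @param wr_position Position (1..3) of the third without stimulation;
#'   drawn uniformly when missing.
#' @return A list with `possessions` (a valid possession tibble),
#'   `schedule` (match_id, third, team_id, condition), and `tempi`
#'   (match_id, team_id, player, tempo_bpm for the nS thirds).
#' @export
simulate_match <- function(config, match_id, wr_position = NULL) {
  stopifnot(inherits(config, "match_sim_config"))
  if (is.null(wr_position)) {
    wr_position <- sample.int(3, 1)
  }
  teams <- paste0(match_id, "_T", 1:2)
  ras_thirds <- setdiff(1:3, wr_position)
  # coin flip: which team hears the synchronous rhythm first
  first_sy <- sample(1:2, 1)
  cond_t1 <- character(3)
  cond_t2 <- character(3)
  cond_t1[wr_position] <- "wR"
  cond_t2[wr_position] <- "wR"
  cond_t1[ras_thirds] <- if (first_sy == 1) c("Sy", "nS") else c("nS", "Sy")
  cond_t2[ras_thirds] <- if (first_sy == 1) c("nS", "Sy") else c("Sy", "nS")
  schedule <- tibble::tibble(
    match_id = match_id,
    third = rep(1:3, each = 2),
    team_id = rep(teams, 3),
    condition = as.vector(rbind(cond_t1, cond_t2))
  )
  parts <- vector("list", 6)
  k <- 0
  for (third in 1:3) {
    for (i in 1:2) {
      k <- k + 1
      parts[[k]] <- team_third_possessions(
        config, match_id, teams[i],
        if (i == 1) cond_t1[third] else cond_t2[third],
        offset = i - 1L
      )
    }
  }
  parts <- parts[!vapply(parts, is.null, logical(1))]
  possessions <- tibble::as_tibble(
    lapply(setNames(POSSESSION_COLS, POSSESSION_COLS), function(col) {
      do.call(c, lapply(parts, `[[`, col))
    })
  )
  tempi <- tibble::tibble(
    match_id = match_id,
    team_id = rep(teams, each = config$players_per_team),
    player = rep(seq_len(config$players_per_team), 2),
    tempo_bpm = rep(config$ns_tempi, 2)
  )
  list(possessions = possessions, schedule = schedule, tempi = tempi)
}

#' Simulate a full match experiment
#'
#' Places the unstimulated third per the configured beginning/middle/end
#' counts (in randomized order), simulates every match, and records the
#' generator's ground truth for parameter-recovery studies.
#'
#' @param config A [match_sim_config()].
#' @param seed Integer seed; when given, output is fully reproducible.
#' @return A list of class `teamsync_experiment` with `possessions`,
#'   `schedule`, `tempi`, `third_summaries`, and `ground_truth` (injected
#'   effects, condition-wise pass-success probabilities, and the analytic
#'   relative connectivity `effect / base` per condition).
#' @export
simulate_experiment <- function(config = match_sim_config(), seed = NULL) {
  stopifnot(inherits(config, "match_sim_config"))
  if (!is.null(seed)) {
    set.seed(seed)
  }
  wr_positions <- sample(rep(1:3, times = config$wr_position_counts))
  ids <- sprintf("M%02d", seq_len(config$n_matches))
  sims <- lapply(seq_len(config$n_matches), function(i) {
    simulate_match(config, ids[i], wr_positions[i])
  })
  possessions <- dplyr::bind_rows(lapply(sims, `[[`, "possessions"))
  structure(
    list(
      possessions = possessions,
      schedule = dplyr::bind_rows(lapply(sims, `[[`, "schedule")),
      tempi = dplyr::bind_rows(lapply(sims, `[[`, "tempi")),
      third_summaries = summarize_thirds(possessions,
                                         config$third_minutes),
      ground_truth = list(
        preset = config$preset,
        seed = seed,
        pass_success = config$pass_success,
        expected_relative_connectivity = c(
          Sy = config$effect_sy / config$base_pass_success,
          nS = config$effect_ns / config$base_pass_success
        ),
        config = config
      )
    ),
    class = "teamsync_experiment"
  )
}

#' Table of participant counts per tempo group
#'
#' Default group sizes of the Stroop emulation: 20 male participants per
#' tempo; female participants stratified by menstrual-cycle phase with
#' per-(phase, tempo) counts 10/10/10 (menstrual), 2/2/5 (folicular),
#' 4/6/3 (ovulatory), 8/7/8 (luteal) at 100/140/180 bpm.
#'
#' @return A tibble `gender`, `phase`, `tempo_bpm`, `n`.
#' @export
stroop_group_sizes <- function() {
  dplyr::bind_rows(
    tibble::tibble(gender = "male", phase = "not_applicable",
                   tempo_bpm = STROOP_TEMPI, n = 20L),
    tibble::tibble(gender = "female", phase = "menstrual",
                   tempo_bpm = STROOP_TEMPI, n = c(10L, 10L, 10L)),
    tibble::tibble(gender = "female", phase = "folicular",
                   tempo_bpm = STROOP_TEMPI, n = c(2L, 2L, 5L)),
    tibble::tibble(gender = "female", phase = "ovulatory",
                   tempo_bpm = STROOP_TEMPI, n = c(4L, 6L, 3L)),
    tibble::tibble(gender = "female", phase = "luteal",
                   tempo_bpm = STROOP_TEMPI, n = c(8L, 7L, 8L))
  )
}

#' Configuration of the Stroop simulator
#'
#' Reaction times follow a shifted lognormal,
#' `rt = m * (shift + exp(N(meanlog + delta, sdlog)))`, where `delta` is the
#' Stroop-interference increment applied to incongruent trials of the
#' stroop run, and the multiplicative factor `m = 1 + median_shift` applies
#' in block 2 only (the music block) according to the participant's tempo
#' group. The true block-2 incongruent-stroop median of a group is thus
#' `(1 + median_shift) * (shift + exp(meanlog + delta))`.
#'
#' @param group_sizes Participant counts per (gender, phase, tempo) cell;
#'   defaults to [stroop_group_sizes()].
#' @param trials_per_run Trials per run (default 48: 24 congruent and 24
#'   incongruent, randomized).
#' @param rt_shift Shift of the lognormal, seconds (default 0.2).
#' @param rt_meanlog Meanlog (default `log(1.3)`, i.e. baseline median
#'   1.5 s).
#' @param rt_sdlog Sdlog (default 0.35).
#' @param interference_delta Meanlog increment on incongruent stroop-run
#'   trials (default 0.10).
#' @param tempo_effects Tibble `gender`, `tempo_bpm`, `median_shift` of
#'   multiplicative median shifts in the music block; defaults to the male
#'   preference reported for 140 bpm, a -6.5% shift, and zero elsewhere.
#' @return A list of class `stroop_sim_config`.
#' @export
stroop_sim_config <- function(group_sizes = stroop_group_sizes(),
                              trials_per_run = 48L,
                              rt_shift = 0.2,
                              rt_meanlog = log(1.3),
                              rt_sdlog = 0.35,
                              interference_delta = 0.10,
                              tempo_effects = NULL) {
  if (is.null(tempo_effects)) {
    tempo_effects <- tibble::tibble(
      gender = rep(GENDERS, each = 3),
      tempo_bpm = rep(STROOP_TEMPI, 2),
      median_shift = c(0, -0.065, 0, 0, 0, 0)
    )
  }
  group_sizes <- tibble::as_tibble(group_sizes)
  stopifnot(all(c("gender", "phase", "tempo_bpm", "n") %in%
                  names(group_sizes)))
  if (any(group_sizes$n < 0)) {
    ts_error("group sizes must be >= 0", "teamsync_config_error")
  }
  if (trials_per_run < 2 || trials_per_run %% 2 != 0) {
    ts_error("trials_per_run must be a positive even count",
             "teamsync_config_error")
  }
  if (rt_shift < 0 || rt_sdlog <= 0) {
    ts_error("rt_shift must be >= 0 and rt_sdlog > 0",
             "teamsync_config_error")
  }
  structure(
    list(group_sizes = group_sizes, trials_per_run = as.integer(trials_per_run),
         rt_shift = rt_shift, rt_meanlog = rt_meanlog, rt_sdlog = rt_sdlog,
         interference_delta = interference_delta,
         tempo_effects = tibble::as_tibble(tempo_effects)),
    class = "stroop_sim_config"
  )
}

#' Simulate a Stroop experiment
#'
#' Per participant: an assigned tempo, 3 blocks of 2 runs (neutral, stroop)
#' of `trials_per_run` trials each, half congruent and half incongruent in
#' randomized order; reaction times from the shifted lognormal with the
#' tempo effect applied in block 2.
#'
#' @param config A [stroop_sim_config()].
#' @param seed Integer seed for full reproducibility.
#' @return A list of class `teamsync_stroop_sim` with `trials` (a valid
#'   Stroop trial tibble) and `ground_truth` (per-group true block-2
#'   incongruent medians and the injected shifts).
#' @export
simulate_stroop <- function(config = stroop_sim_config(), seed = NULL) {
  stopifnot(inherits(config, "stroop_sim_config"))
  if (!is.null(seed)) {
    set.seed(seed)
  }
  gs <- config$group_sizes[config$group_sizes$n > 0, ]
  participants <- tibble::tibble(
    gender = rep(gs$gender, gs$n),
    phase = rep(gs$phase, gs$n),
    tempo_assigned = rep(gs$tempo_bpm, gs$n)
  )
  participants$participant_id <- sprintf("P%03d", seq_len(nrow(participants)))
  n_part <- nrow(participants)
  tpr <- config$trials_per_run
  half <- tpr %/% 2
  rows_per_part <- 3L * 2L * tpr
  n_rows <- n_part * rows_per_part

  idx <- rep(seq_len(n_part), each = rows_per_part)
  block <- rep(rep(1:3, each = 2L * tpr), n_part)
  run <- rep(rep(rep(RUNS, each = tpr), 3), n_part)
  # randomized congruency order within every run
  n_runs <- n_part * 6L
  congruent <- as.vector(
    apply(matrix(stats::runif(n_runs * tpr), nrow = tpr), 2,
          function(u) rank(u, ties.method = "first") <= half)
  )
  shift_tbl <- dplyr::left_join(
    participants, config$tempo_effects,
    by = c("gender", tempo_assigned = "tempo_bpm")
  )
  shift_tbl$median_shift[is.na(shift_tbl$median_shift)] <- 0
  m <- ifelse(block == 2, 1 + shift_tbl$median_shift[idx], 1)
  delta <- ifelse(run == "stroop" & !congruent, config$interference_delta, 0)
  rt <- m * (config$rt_shift +
               exp(stats::rnorm(n_rows, config$rt_meanlog + delta,
                                config$rt_sdlog)))
  trials <- tibble::tibble(
    participant_id = participants$participant_id[idx],
    gender = participants$gender[idx],
    phase = participants$phase[idx],
    tempo_bpm = ifelse(block == 2, participants$tempo_assigned[idx],
                       NA_integer_),
    block = block,
    run = run,
    congruent = congruent,
    rt_s = rt
  )
  truth <- dplyr::left_join(gs, config$tempo_effects,
                            by = c("gender", "tempo_bpm"))
  truth$median_shift[is.na(truth$median_shift)] <- 0
  truth$true_median <- (1 + truth$median_shift) *
    (config$rt_shift + exp(config$rt_meanlog + config$interference_delta))
  structure(
    list(trials = trials,
         ground_truth = list(seed = seed, groups = truth, config = config)),
    class = "teamsync_stroop_sim"
  )
}

#' Compare injected generator parameters with recovered estimates
#'
#' @param truth A tibble holding the generator's injected values in a
#'   `truth` column plus key columns identifying each quantity (e.g.
#'   `quantity`, or `condition`, or `gender` + `tempo_bpm`).
#' @param estimates A tibble holding the pipeline's recovered values in an
#'   `estimate` column plus the same key columns; an optional `mc_se`
#'   column carries Monte-Carlo error bars.
#' @return The joined recovery table with an `error = estimate - truth`
#'   column. Raises a pairing error when any quantity of either side is
#'   unmatched.
#' @export
ground_truth_report <- function(truth, estimates) {
  truth <- tibble::as_tibble(truth)
  estimates <- tibble::as_tibble(estimates)
  stopifnot("truth" %in% names(truth), "estimate" %in% names(estimates))
  keys <- intersect(setdiff(names(truth), "truth"),
                    setdiff(names(estimates), c("estimate", "mc_se")))
  if (length(keys) == 0) {
    ts_error("no shared key columns to pair on", "teamsync_pairing_error")
  }
  joined <- dplyr::full_join(truth, estimates, by = keys)
  if (anyNA(joined$truth) || anyNA(joined$estimate)) {
    ts_error("unpaired quantities between ground truth and estimates",
             "teamsync_pairing_error")
  }
  dplyr::mutate(joined, error = .data$estimate - .data$truth)
}
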