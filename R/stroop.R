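## Reaction-time analysis of the color-word matching Stroop task: selection
## of incongruent trials from the music block, empirical CDFs, medians with
## distribution-free 95% confidence intervals, and pairwise tempo contrasts
## within gender or menstrual-phase strata.

#' Select trials for the tempo analysis
#'
#' The default analysis selection is the incongruent trials of the stroop
#' run in block 2 (the only block performed under music), where interference
#' between word and color probes the attention level.
#'
#' @param trials A validated Stroop trial table.
#' @param block Block number(s) to retain (default 2).
#' @param run Run label(s) to retain (default `"stroop"`).
#' @param congruent Congruency value(s) to retain (default `FALSE`,
#'   incongruent only).
#' @return The selected subset; raises an insufficient-data error if the
#'   selection is empty.
#' @export
select_trials <- function(trials, block = 2, run = "stroop",
                          congruent = FALSE) {
  trials <- validate_stroop_trials(trials)
  out <- trials |>
    dplyr::filter(.data$block %in% !!block,
                  .data$run %in% !!run,
                  .data$congruent %in% !!congruent)
  if (nrow(out) == 0) {
    ts_error(
      sprintf("selection (block %s, run %s, congruent %s) retains no trials",
              paste(block, collapse = "/"), paste(run, collapse = "/"),
              paste(congruent, collapse = "/")),
      "teamsync_insufficient_data_error"
    )
  }
  out
}

#' Empirical cumulative distribution of reaction times
#'
#' Right-continuous step function, evaluable at arbitrary points; at its own
#' sorted sample points it attains k/n exactly.
#'
#' @param rts Nonempty numeric vector of reaction times (seconds).
#' @return A function of class `ecdf`.
#' @export
rt_ecdf <- function(rts) {
  rts <- as.numeric(rts)
  if (length(rts) == 0 || anyNA(rts)) {
    ts_error("rts must be nonempty and free of missing values",
             "teamsync_argument_error")
  }
  stats::ecdf(rts)
}

#' Sample median with a distribution-free confidence interval
#'
#' Order-statistic interval `[X_(l), X_(u)]` with symmetric ranks
#' `l = j + 1`, `u = n - j` determined from the Binomial(n, 1/2)
#' distribution of the number of observations below the median. With
#' `rank_rule = "closest"` (default) `j` is chosen so that the exact
#' coverage `1 - 2 P(B <= j)` is closest to `level`; with `"conservative"`,
#' the largest `j` with coverage at least `level`. A bootstrap percentile
#' interval is available as an alternative method.
#'
#' @param rts Numeric sample, `n >= 6` (the smallest n with a proper
#'   distribution-free 95% interval).
#' @param level Confidence level (default 0.95).
#' @param method `"order_statistic"` (default) or `"bootstrap"`.
#' @param rank_rule `"closest"` or `"conservative"` (order-statistic method
#'   only).
#' @param n_boot Bootstrap replicates for `method = "bootstrap"`.
#' @return A one-row tibble: `n`, `median`, `ci_low`, `ci_high`, `coverage`
#'   (exact coverage of the order-statistic interval; `NA` for bootstrap).
#' @examples
#' median_ci(1:9)  # median 5, interval [2, 8]
#' @export
median_ci <- function(rts, level = 0.95,
                      method = c("order_statistic", "bootstrap"),
                      rank_rule = c("closest", "conservative"),
                      n_boot = 2000) {
  method <- match.arg(method)
  rank_rule <- match.arg(rank_rule)
  rts <- as.numeric(rts)
  n <- length(rts)
  if (n < 6 || anyNA(rts)) {
    ts_error("need n >= 6 non-missing values for a 95% median interval",
             "teamsync_insufficient_data_error")
  }
  m <- stats::median(rts)
  if (method == "bootstrap") {
    boot <- vapply(seq_len(n_boot),
                   function(i) stats::median(rts[sample.int(n, n, TRUE)]),
                   numeric(1))
    qs <- stats::quantile(boot, c((1 - level) / 2, (1 + level) / 2),
                          names = FALSE, type = 1)
    return(tibble::tibble(n = n, median = m, ci_low = qs[1], ci_high = qs[2],
                          coverage = NA_real_))
  }
  js <- 0:floor((n - 1) / 2)
  covs <- 1 - 2 * stats::pbinom(js, n, 0.5)
  j <- if (rank_rule == "closest") {
    js[which.min(abs(covs - level))]
  } else {
    cand <- js[covs >= level]
    if (length(cand) == 0) {
      ts_error("no order-statistic interval attains the requested level",
               "teamsync_insufficient_data_error")
    }
    max(cand)
  }
  xs <- sort(rts)
  tibble::tibble(
    n = n, median = m,
    ci_low = xs[j + 1], ci_high = xs[n - j],
    coverage = 1 - 2 * stats::pbinom(j, n, 0.5)
  )
}

#' Per-group reaction-time summaries and pairwise tempo comparisons
#'
#' Within one stratum (e.g. the male participants, or one menstrual-cycle
#' phase), compares the reaction-time distributions of the three tempo
#' groups by pairwise two-sided Mann-Whitney-Wilcoxon tests, and summarizes
#' each group by its median with 95% confidence interval.
#'
#' @param trials Trials of one stratum, already reduced to the analysis
#'   selection (see [select_trials()]); must contain at least 2 tempo
#'   groups.
#' @param pool `"trials"` pools all trials of a group (the cumulative
#'   distributions are trial-level; default); `"participants"` reduces each
#'   participant to their median reaction time first.
#' @param ... Passed on to [mann_whitney()].
#' @return A list with `summaries` (one row per tempo: `tempo_bpm`, `n`,
#'   `median`, `ci_low`, `ci_high`) and `pairwise` (one row per tempo pair:
#'   `tempo_a`, `tempo_b`, `statistic`, `p_value`, `method`, `n_x`, `n_y`).
#' @export
tempo_comparison <- function(trials, pool = c("trials", "participants"),
                             ...) {
  pool <- match.arg(pool)
  trials <- tibble::as_tibble(trials)
  if (nrow(trials) == 0) {
    ts_error("no trials supplied", "teamsync_insufficient_data_error")
  }
  samples <- if (pool == "trials") {
    split(trials$rt_s, trials$tempo_bpm)
  } else {
    per_part <- trials |>
      dplyr::group_by(.data$tempo_bpm, .data$participant_id) |>
      dplyr::summarise(rt_s = stats::median(.data$rt_s), .groups = "drop")
    split(per_part$rt_s, per_part$tempo_bpm)
  }
  if (length(samples) < 2) {
    ts_error("need at least 2 tempo groups to compare",
             "teamsync_insufficient_data_error")
  }
  summaries <- dplyr::bind_rows(lapply(names(samples), function(tp) {
    ci <- median_ci(samples[[tp]])
    tibble::tibble(tempo_bpm = as.numeric(tp), n = ci$n, median = ci$median,
                   ci_low = ci$ci_low, ci_high = ci$ci_high)
  }))
  combos <- utils::combn(names(samples), 2)
  pairwise <- dplyr::bind_rows(lapply(seq_len(ncol(combos)), function(i) {
    a <- combos[1, i]
    b <- combos[2, i]
    res <- mann_whitney(samples[[a]], samples[[b]], ...)
    dplyr::bind_cols(
      tibble::tibble(tempo_a = as.numeric(a), tempo_b = as.numeric(b)), res
    )
  }))
  list(summaries = summaries, pairwise = pairwise)
}

#' Split female trials by menstrual-cycle phase
#'
#' Phase labels come from the input table (assigned by forward-counting in
#' the emulated design). The partition over the four phases is exhaustive
#' and disjoint for female trials.
#'
#' @param trials A validated Stroop trial table.
#' @return A named list of trial tibbles (`menstrual`, `folicular`,
#'   `ovulatory`, `luteal`).
#' @export
stratify_by_phase <- function(trials) {
  trials <- validate_stroop_trials(trials)
  fem <- dplyr::filter(trials, .data$gender == "female")
  bad <- fem$phase == "not_applicable"
  if (any(bad)) {
    ts_error(sprintf(
      "female trial row(s) without a menstrual-cycle phase: %s",
      paste(utils::head(which(bad), 5), collapse = ", ")),
      "teamsync_validation_error")
  }
  phases <- setdiff(PHASES, "not_applicable")
  setNames(lapply(phases, function(p) fem[fem$phase == p, ]), phases)
}

#' Participant counts per (gender/phase, tempo) cell
#'
#' @param trials A validated Stroop trial table.
#' @return A tibble `gender`, `phase`, `tempo_bpm`, `n_participants`,
#'   counting distinct participants per cell (tempo taken from block 2).
#' @export
participant_counts <- function(trials) {
  trials <- validate_stroop_trials(trials)
  trials |>
    dplyr::filter(.data$block == 2) |>
    dplyr::distinct(.data$participant_id, .data$gender, .data$phase,
                    .data$tempo_bpm) |>
    dplyr::count(.data$gender, .data$phase, .data$tempo_bpm,
                 name = "n_participants")
}
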