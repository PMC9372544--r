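## The team connectivity index and its condition contrasts.
##
## Connectivity operationalizes generalized synchronization in team play:
## for one team in one 10-minute third, C = n_p / n_c, the number of
## completed passes per ball contact. Relative connectivity normalizes a
## team-match's value under acoustic stimulation to its own third without
## stimulation, removing absolute team strength.

#' Connectivity index of a third
#'
#' `C = n_p / n_c` per (match, team, condition) cell: passes per ball
#' contact, a dimensionless ratio in \[0, 1\] (one-touch play, where the
#' reception simultaneously is the pass, attains the upper bound).
#'
#' @param summaries A third-summary table (see [summarize_thirds()]), or any
#'   table with `match_id`, `team_id`, `condition`, `n_p`, `n_c`.
#' @return A tibble `match_id`, `team_id`, `condition`, `C`.
#' @export
connectivity_index <- function(summaries) {
  summaries <- tibble::as_tibble(summaries)
  if (any(summaries$n_c == 0)) {
    bad <- which(summaries$n_c == 0)
    ts_error(
      sprintf("connectivity undefined: no ball contact recorded in third(s) %s",
              paste(utils::head(paste(summaries$match_id[bad],
                                      summaries$team_id[bad],
                                      summaries$condition[bad], sep = "/"), 5),
                    collapse = ", ")),
      "teamsync_undefined_statistic_error"
    )
  }
  dplyr::transmute(
    summaries,
    match_id = .data$match_id,
    team_id = .data$team_id,
    condition = .data$condition,
    C = .data$n_p / .data$n_c
  )
}

#' Relative connectivity with respect to the unstimulated third
#'
#' `(C_cond - C_wR) / C_wR`: the fractional change of a team-match's
#' connectivity under a stimulated condition compared to its own third
#' without rhythmic stimulation. An estimate of 0.1 connotes a 10% increase.
#'
#' @param c_cond Connectivity under the stimulated (Sy or nS) condition.
#' @param c_wr Connectivity of the same team-match without stimulation;
#'   must be positive for the normalization to be defined.
#' @return `(c_cond - c_wr) / c_wr`, vectorized.
#' @examples
#' relative_connectivity(0.55, 0.50)  # 0.1, a 10% increase
#' @export
relative_connectivity <- function(c_cond, c_wr) {
  if (any(is.na(c_wr)) || any(c_wr <= 0)) {
    ts_error("normalization undefined: C_wR must be > 0",
             "teamsync_undefined_normalization_error")
  }
  (c_cond - c_wr) / c_wr
}

#' Relative connectivity table of an experiment
#'
#' Joins each team-match's Sy and nS connectivity with its wR value and
#' computes relative connectivity. Team-matches whose wR third has zero
#' connectivity cannot be normalized; they are dropped with a warning.
#'
#' @inheritParams connectivity_index
#' @return A tibble `match_id`, `team_id`, `condition` (Sy/nS), `value`.
#' @export
relative_connectivity_table <- function(summaries) {
  conn <- connectivity_index(summaries)
  wr <- conn |>
    dplyr::filter(.data$condition == "wR") |>
    dplyr::select("match_id", "team_id", C_wR = "C")
  ras <- conn |>
    dplyr::filter(.data$condition %in% CRAS_CONDITIONS) |>
    dplyr::inner_join(wr, by = c("match_id", "team_id"))
  degenerate <- ras$C_wR <= 0
  if (any(degenerate)) {
    rlang::warn(sprintf(
      "dropping %d team-match value(s) with zero wR connectivity: %s",
      sum(degenerate),
      paste(utils::head(unique(paste(ras$match_id[degenerate],
                                     ras$team_id[degenerate], sep = "/")), 5),
            collapse = ", ")))
    ras <- ras[!degenerate, ]
  }
  dplyr::transmute(
    ras,
    match_id = .data$match_id,
    team_id = .data$team_id,
    condition = .data$condition,
    value = (.data$C - .data$C_wR) / .data$C_wR
  )
}

#' Filter possessions by pass-sequence length
#'
#' The length of a pass sequence is the number of completed passes in a
#' possession (a possession without any pass has length 0). `mode = "min"`
#' keeps possessions with at least `bound` passes, `mode = "max"` those with
#' at most `bound`; bounds are inclusive. Downstream counts and connectivity
#' are then recomputed from the retained subset only.
#'
#' @param possessions A validated possession table.
#' @param mode `"none"`, `"min"`, or `"max"`.
#' @param bound Integer bound on the number of passes, `>= 0`.
#' @return The filtered possession table (possibly empty).
#' @export
filter_possessions <- function(possessions, mode = c("none", "min", "max"),
                               bound = 0) {
  mode <- match.arg(mode)
  if (mode != "none" &&
      (!is.numeric(bound) || length(bound) != 1 || is.na(bound) ||
       bound < 0 || bound != trunc(bound))) {
    ts_error("bound must be a single integer >= 0", "teamsync_argument_error")
  }
  possessions <- tibble::as_tibble(possessions)
  switch(mode,
    none = possessions,
    min = possessions[possessions$n_passes >= bound, ],
    max = possessions[possessions$n_passes <= bound, ]
  )
}

#' Contrast relative connectivity between the Sy and nS conditions
#'
#' Two-sided test of the hypothesis that the Sy and nS relative-connectivity
#' samples stem from the same distribution, plus the sample medians. The rank
#' test ([mann_whitney()]) is the default; the pooled-variance t test is the
#' parametric counterpart.
#'
#' @param values_sy,values_ns Numeric samples of relative connectivity
#'   values, one per team-match, each of size >= 2.
#' @param test `"rank"` or `"t"`.
#' @param ... Passed on to [mann_whitney()].
#' @return A one-row tibble: `n_Sy`, `n_nS`, `median_Sy`, `median_nS`,
#'   `statistic`, `p_value`, `method`.
#' @export
condition_contrast <- function(values_sy, values_ns, test = c("rank", "t"),
                               ...) {
  test <- match.arg(test)
  if (length(values_sy) < 2 || length(values_ns) < 2) {
    ts_error("need at least 2 values per condition for a contrast",
             "teamsync_insufficient_data_error")
  }
  res <- switch(test,
    rank = mann_whitney(values_sy, values_ns, ...),
    t = two_sample_t(values_sy, values_ns)
  )
  tibble::tibble(
    n_Sy = length(values_sy),
    n_nS = length(values_ns),
    median_Sy = stats::median(values_sy),
    median_nS = stats::median(values_ns),
    statistic = res$statistic,
    p_value = res$p_value,
    method = res$method
  )
}

rc_samples <- function(summaries, unit = c("team_match", "match_mean")) {
  unit <- match.arg(unit)
  rc <- relative_connectivity_table(summaries)
  if (unit == "match_mean") {
    rc <- rc |>
      dplyr::group_by(.data$match_id, .data$condition) |>
      dplyr::summarise(value = mean(.data$value), .groups = "drop")
  }
  list(
    Sy = rc$value[rc$condition == "Sy"],
    nS = rc$value[rc$condition == "nS"]
  )
}

#' Sweep condition contrasts over pass-sequence-length bounds
#'
#' Recomputes the full connectivity pipeline (filter possessions, aggregate
#' thirds, normalize to wR, contrast Sy vs nS) for each sequence-length
#' bound, reproducing the layout of the minimal/maximal-length sweep panels:
#' medians per condition plus rank-test and t-test p-values per bound.
#'
#' Team-matches whose filtered wR third retains no contact (or zero
#' connectivity) drop out of that bound's sample with a warning rather than
#' being imputed. Bounds whose samples collapse below 2 values per condition
#' yield `NA` test results with a message.
#'
#' @param possessions A validated possession table.
#' @param bounds Ordered integer vector of bounds.
#' @param mode `"min"` or `"max"` (see [filter_possessions()]).
#' @param unit Sampling unit: `"team_match"` pools both teams of a match
#'   (one Sy and one nS value per team-match, the default), `"match_mean"`
#'   averages the two teams of a match first.
#' @return A tibble with one row per bound: `bound`, `mode`, `n_Sy`, `n_nS`,
#'   `median_Sy`, `median_nS`, `p_rank`, `p_t`.
#' @export
sweep_sequence_lengths <- function(possessions, bounds, mode = c("min", "max"),
                                   unit = c("team_match", "match_mean")) {
  mode <- match.arg(mode)
  unit <- match.arg(unit)
  if (length(bounds) < 1) {
    ts_error("bounds must be a nonempty vector", "teamsync_argument_error")
  }
  possessions <- validate_possessions(possessions)
  rows <- lapply(bounds, function(b) {
    sub <- filter_possessions(possessions, mode, b)
    empty_row <- tibble::tibble(
      bound = b, mode = mode, n_Sy = 0L, n_nS = 0L,
      median_Sy = NA_real_, median_nS = NA_real_,
      p_rank = NA_real_, p_t = NA_real_
    )
    if (nrow(sub) == 0) {
      rlang::inform(sprintf("bound %d (%s): no possessions retained", b, mode))
      return(empty_row)
    }
    summ <- summarize_thirds(sub)
    # a summary row disappears entirely when a third retains no possession;
    # keep only team-matches with all three conditions and positive wR C
    complete <- summ |>
      dplyr::count(.data$match_id, .data$team_id) |>
      dplyr::filter(.data$n == 3)
    summ <- dplyr::semi_join(summ, complete, by = c("match_id", "team_id"))
    dropped <- nrow(complete) == 0
    if (dropped) {
      rlang::inform(sprintf(
        "bound %d (%s): no team-match retains all three conditions", b, mode))
      return(empty_row)
    }
    samples <- withCallingHandlers(
      rc_samples(summ, unit),
      warning = function(w) {
        rlang::inform(sprintf("bound %d (%s): %s", b, mode,
                              conditionMessage(w)))
        rlang::cnd_muffle(w)
      }
    )
    if (length(samples$Sy) < 2 || length(samples$nS) < 2) {
      rlang::inform(sprintf(
        "bound %d (%s): sample collapsed below 2 values per condition",
        b, mode))
      return(dplyr::mutate(empty_row,
                           n_Sy = length(samples$Sy),
                           n_nS = length(samples$nS)))
    }
    rank_res <- condition_contrast(samples$Sy, samples$nS, test = "rank")
    t_res <- tryCatch(
      condition_contrast(samples$Sy, samples$nS, test = "t"),
      teamsync_degenerate_error = function(e) NULL
    )
    tibble::tibble(
      bound = b, mode = mode,
      n_Sy = rank_res$n_Sy, n_nS = rank_res$n_nS,
      median_Sy = rank_res$median_Sy, median_nS = rank_res$median_nS,
      p_rank = rank_res$p_value,
      p_t = if (is.null(t_res)) NA_real_ else t_res$p_value
    )
  })
  dplyr::bind_rows(rows)
}
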