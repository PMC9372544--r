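## Condition-wise scoring-difference counts and their exact binomial
## probability. For each team-match the goals scored under two conditions
## are compared; the team-match counts in favor of whichever condition
## out-scored the other by at least D goals. Under the null that either
## direction is equally likely, the probability of the observed (k_A, k_B)
## split is the binomial point probability
##   P = C(k_A + k_B, k_B) * p_A^k_A * p_B^k_B .

#' Count scoring differences in favor of each condition
#'
#' For every team-match (a team within one match), compares the goals scored
#' in the `cond_a` third with those in the `cond_b` third. `k_a` counts
#' team-matches where `cond_a` out-scored `cond_b` by at least `D` goals,
#' `k_b` the reverse; team-matches with |difference| < D contribute to
#' neither count. Goals are compared per third without duration
#' normalization (thirds are equally long).
#'
#' @param summaries A third-summary table (see [summarize_thirds()]); every
#'   team-match must have exactly one third per compared condition.
#' @param cond_a,cond_b Condition labels from `wR`, `Sy`, `nS`.
#' @param D Scoring-difference threshold, integer >= 1.
#' @return A one-row tibble: `cond_a`, `cond_b`, `D`, `k_a`, `k_b`.
#' @export
scoring_difference_counts <- function(summaries, cond_a, cond_b, D = 1) {
  if (!is.numeric(D) || length(D) != 1 || is.na(D) || D < 1 ||
      D != trunc(D)) {
    ts_error("D must be a single integer >= 1", "teamsync_argument_error")
  }
  stopifnot(cond_a %in% CONDITIONS, cond_b %in% CONDITIONS)
  summaries <- tibble::as_tibble(summaries)
  wide <- summaries |>
    dplyr::filter(.data$condition %in% c(cond_a, cond_b)) |>
    dplyr::select("match_id", "team_id", "condition", "goals") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "goals")
  for (cond in c(cond_a, cond_b)) {
    if (!cond %in% names(wide) || anyNA(wide[[cond]])) {
      missing_tm <- if (!cond %in% names(wide)) {
        paste(wide$match_id, wide$team_id, sep = "/")
      } else {
        paste(wide$match_id[is.na(wide[[cond]])],
              wide$team_id[is.na(wide[[cond]])], sep = "/")
      }
      ts_error(
        sprintf("team-match(es) %s lack a %s third",
                paste(utils::head(missing_tm, 5), collapse = ", "), cond),
        "teamsync_validation_error"
      )
    }
  }
  diff <- wide[[cond_a]] - wide[[cond_b]]
  tibble::tibble(
    cond_a = cond_a, cond_b = cond_b, D = as.integer(D),
    k_a = sum(diff >= D), k_b = sum(-diff >= D)
  )
}

#' Binomial probability of an observed favor split
#'
#' Point probability of observing exactly `k_a` team-matches in favor of one
#' condition and `k_b` in favor of the other, under the null hypothesis that
#' scoring differences between conditions appear with probabilities `p_a`
#' and `p_b`:
#' \deqn{P = \binom{k_a + k_b}{k_b} p_a^{k_a} p_b^{k_b}.}
#' With the default `p_a = p_b = 0.5` this is symmetric in `(k_a, k_b)` and
#' sums to 1 over all splits of `k_a + k_b`. `tail = TRUE` instead returns
#' the one-sided tail sum over splits at least as extreme in the direction
#' of `k_b` (a conventional sign test; an extension beyond the point
#' probability).
#'
#' @param k_a,k_b Nonnegative integer counts (vectorized).
#' @param p_a,p_b Null favor probabilities in (0, 1).
#' @param tail If `TRUE`, return `P(X >= k_b)` for
#'   `X ~ Binomial(k_a + k_b, p_b)` instead of the point probability.
#' @return Numeric probability in (0, 1].
#' @examples
#' binomial_probability(6, 20)   # 0.003431 at 4 significant figures
#' binomial_probability(1, 7)    # 0.03125
#' @export
binomial_probability <- function(k_a, k_b, p_a = 0.5, p_b = 0.5,
                                 tail = FALSE) {
  if (any(is.na(k_a)) || any(is.na(k_b)) || any(k_a < 0) || any(k_b < 0) ||
      any(k_a != trunc(k_a)) || any(k_b != trunc(k_b))) {
    ts_error("k_a and k_b must be nonnegative integers",
             "teamsync_argument_error")
  }
  if (any(p_a <= 0) || any(p_a >= 1) || any(p_b <= 0) || any(p_b >= 1)) {
    ts_error("p_a and p_b must lie in (0, 1)", "teamsync_argument_error")
  }
  if (tail) {
    # one-sided upper tail in the direction of k_b (requires p_a + p_b = 1
    # for the usual sign-test reading; evaluated with p_b as success prob)
    return(stats::pbinom(k_b - 1, k_a + k_b, p_b, lower.tail = FALSE))
  }
  choose(k_a + k_b, k_b) * p_a^k_a * p_b^k_b
}

#' Sweep scoring-difference comparisons over thresholds and condition pairs
#'
#' Rows for the three condition pairs (wR vs Sy, wR vs nS, Sy vs nS) at each
#' threshold `D`, with favor counts and binomial probability.
#'
#' @inheritParams scoring_difference_counts
#' @param D_values Nonempty vector of integer thresholds.
#' @param p_a,p_b Null favor probabilities (see [binomial_probability()]).
#' @return A tibble `cond_a`, `cond_b`, `D`, `k_a`, `k_b`, `P`.
#' @export
scoring_sweep <- function(summaries, D_values = 1:4, p_a = 0.5, p_b = 0.5) {
  if (length(D_values) < 1) {
    ts_error("D_values must be nonempty", "teamsync_argument_error")
  }
  pairs <- list(c("wR", "Sy"), c("wR", "nS"), c("Sy", "nS"))
  rows <- lapply(pairs, function(pr) {
    dplyr::bind_rows(lapply(D_values, function(D) {
      scoring_difference_counts(summaries, pr[1], pr[2], D)
    }))
  })
  out <- dplyr::bind_rows(rows)
  dplyr::mutate(out, P = binomial_probability(.data$k_a, .data$k_b, p_a, p_b))
}

#' Paired t test on per-team-match goal counts
#'
#' Parametric counterpart of the binomial favor statistic: pairs the goals
#' of the same team-match under two conditions and applies the standard
#' paired t test (two-sided).
#'
#' @inheritParams scoring_difference_counts
#' @return A one-row tibble with `statistic` (t), `p_value`, `method`
#'   (`t_paired`), `n_x`, `n_y` (both the number of pairs).
#' @export
paired_scoring_t <- function(summaries, cond_a, cond_b) {
  stopifnot(cond_a %in% CONDITIONS, cond_b %in% CONDITIONS)
  summaries <- tibble::as_tibble(summaries)
  wide <- summaries |>
    dplyr::filter(.data$condition %in% c(cond_a, cond_b)) |>
    dplyr::select("match_id", "team_id", "condition", "goals") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "goals") |>
    tidyr::drop_na()
  if (nrow(wide) < 2) {
    ts_error("need at least 2 complete pairs", "teamsync_insufficient_data_error")
  }
  d <- wide[[cond_a]] - wide[[cond_b]]
  if (stats::var(d) == 0) {
    ts_error("all paired differences are equal: t statistic degenerate",
             "teamsync_degenerate_error")
  }
  ht <- stats::t.test(wide[[cond_a]], wide[[cond_b]], paired = TRUE)
  new_test_result(unname(ht$statistic), ht$p.value, "t_paired",
                  nrow(wide), nrow(wide))
}
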