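## Two-sample hypothesis-test machinery shared by the match and Stroop
## analyses: an exact Mann-Whitney-Wilcoxon rank test with midrank tie
## handling (complete enumeration of group assignments, seeded Monte-Carlo
## permutation fallback, tie-corrected normal approximation), and thin
## wrappers for the parametric counterparts.

new_test_result <- function(statistic, p_value, method, n_x, n_y) {
  tibble::tibble(
    statistic = statistic,
    p_value = min(max(p_value, .Machine$double.xmin), 1),
    method = method,
    n_x = n_x,
    n_y = n_y
  )
}

#' Mann-Whitney-Wilcoxon rank test
#'
#' Two-sided two-sample rank test for the hypothesis that `x` and `y` stem
#' from the same distribution. Ties receive midranks. The p-value is the
#' permutation probability, under random assignment of the pooled values to
#' the two groups, of a rank sum at least as far from its null mean as the
#' observed one:
#' \deqn{p = P(|W - \mu_W| \ge |w_{obs} - \mu_W|), \quad
#'       \mu_W = n_x (n_x + n_y + 1)/2.}
#'
#' Method selection (`method = "auto"`): complete enumeration of all
#' `choose(n_x + n_y, n_x)` group assignments when that count is at most
#' `exact_limit`; otherwise, a seeded Monte-Carlo permutation estimate for
#' moderate pooled sizes (`n_x + n_y <= mc_max_n`); otherwise the normal
#' approximation with tie-corrected variance and continuity correction.
#'
#' @param x,y Numeric samples, each nonempty.
#' @param method `"auto"`, `"exact"`, `"montecarlo"`, or `"normal"`.
#' @param exact_limit Maximum number of assignments enumerated exactly.
#' @param mc_max_n Largest pooled sample size for which the Monte-Carlo
#'   fallback (rather than the normal approximation) is used under `"auto"`.
#' @param n_perm Number of Monte-Carlo permutations.
#' @return A one-row tibble with `statistic` (the U statistic of `x`),
#'   `p_value`, `method` (`rank_exact`, `rank_montecarlo`, or `rank_normal`),
#'   `n_x`, `n_y`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))  # exact two-sided p = 0.1
#' @export
mann_whitney <- function(x, y,
                         method = c("auto", "exact", "montecarlo", "normal"),
                         exact_limit = 1e6, mc_max_n = 30, n_perm = 1e4) {
  method <- match.arg(method)
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) < 1 || length(y) < 1 || anyNA(x) || anyNA(y)) {
    ts_error("both samples must be nonempty and free of missing values",
             "teamsync_argument_error")
  }
  n_x <- length(x)
  n_y <- length(y)
  n <- n_x + n_y
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n_x)])
  mu <- n_x * (n + 1) / 2
  u_obs <- w_obs - n_x * (n_x + 1) / 2
  d_obs <- abs(w_obs - mu)
  eps <- 1e-9

  if (method == "auto") {
    method <- if (choose(n, n_x) <= exact_limit) "exact"
              else if (n <= mc_max_n) "montecarlo"
              else "normal"
  }

  if (method == "exact") {
    if (choose(n, n_x) > exact_limit) {
      ts_error("exact enumeration infeasible for these sample sizes",
               "teamsync_argument_error")
    }
    idx <- utils::combn(n, n_x)
    sums <- colSums(matrix(r[idx], nrow = n_x))
    p <- mean(abs(sums - mu) >= d_obs - eps)
    return(new_test_result(u_obs, p, "rank_exact", n_x, n_y))
  }

  if (method == "montecarlo") {
    extreme <- sum(vapply(
      seq_len(n_perm),
      function(i) abs(sum(r[sample.int(n, n_x)]) - mu) >= d_obs - eps,
      logical(1)
    ))
    # add-one estimate keeps p in (0, 1]
    p <- (1 + extreme) / (1 + n_perm)
    return(new_test_result(u_obs, p, "rank_montecarlo", n_x, n_y))
  }

  # normal approximation, tie-corrected variance, continuity correction
  tie_tab <- table(r)
  tie_term <- sum(tie_tab^3 - tie_tab)
  v <- n_x * n_y / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (v <= 0) {
    # all pooled values identical: no evidence against the null
    return(new_test_result(u_obs, 1, "rank_normal", n_x, n_y))
  }
  z <- (d_obs - 0.5) / sqrt(v)
  p <- 2 * stats::pnorm(-max(z, 0))
  new_test_result(u_obs, p, "rank_normal", n_x, n_y)
}

#' Two-sample Student t test (pooled variance)
#'
#' Parametric counterpart of [mann_whitney()] used for the corroborating
#' re-analysis of relative connectivity values. Wraps
#' [stats::t.test()] with `var.equal = TRUE` and a two-sided alternative.
#'
#' @param x,y Numeric samples with at least 2 observations each.
#' @return A one-row tibble with `statistic` (t), `p_value`, `method`
#'   (`t_two_sample`), `n_x`, `n_y`.
#' @export
two_sample_t <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) < 2 || length(y) < 2 || anyNA(x) || anyNA(y)) {
    ts_error("both samples need >= 2 non-missing observations",
             "teamsync_argument_error")
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    ts_error("zero pooled variance: t statistic undefined",
             "teamsync_degenerate_error")
  }
  ht <- stats::t.test(x, y, var.equal = TRUE)
  new_test_result(unname(ht$statistic), ht$p.value, "t_two_sample",
                  length(x), length(y))
}

#' Tabulate p-values against the 5% and 1% reference levels
#'
#' @param results A tibble of test results (any table with a `p_value`
#'   column), e.g. stacked rows from [mann_whitney()] or a sweep table.
#' @return The input with columns `log10_p`, `sig_05`, `sig_01` appended.
#' @seealso [plot_p_value_panel()]
#' @export
p_value_panel <- function(results) {
  results <- tibble::as_tibble(results)
  if (nrow(results) == 0 || !"p_value" %in% names(results)) {
    ts_error("results must be a nonempty table with a p_value column",
             "teamsync_argument_error")
  }
  dplyr::mutate(
    results,
    log10_p = log10(.data$p_value),
    sig_05 = .data$p_value <= 0.05,
    sig_01 = .data$p_value <= 0.01
  )
}

#' Plot p-values on a logarithmic scale with 5% and 1% reference lines
#'
#' @param results A table with a `p_value` column and an `x` aesthetic
#'   column named by `x`.
#' @param x Name of the column mapped to the abscissa (e.g. the
#'   sequence-length bound of a sweep).
#' @return A ggplot object.
#' @export
plot_p_value_panel <- function(results, x = "bound") {
  panel <- p_value_panel(results)
  ggplot2::ggplot(panel,
                  ggplot2::aes(x = .data[[x]], y = .data$p_value)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = c(0.05, 0.01), linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(y = "p-value (log scale)")
}
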