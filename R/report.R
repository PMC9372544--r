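## End-to-end report generation: composes the module operations into the
## three match-analysis tables (condition-wise counts with playing-time
## normalization, the sequence-length sweep of relative-connectivity
## contrasts, the scoring-difference sweep) and the Stroop report (per-group
## medians with confidence intervals, pairwise tempo p-value matrices, CDF
## data). Every report cell comes from a module operation; this layer only
## arranges and writes them.

write_report_csv <- function(x, out_dir, name) {
  readr::write_csv(x, file.path(out_dir, name), progress = FALSE)
}

run_metadata <- function(config_args, seed = NULL) {
  list(
    package = "teamsync",
    version = as.character(utils::packageVersion("teamsync")),
    seed = seed,
    config_hash = rlang::hash(config_args)
  )
}

#' Run the full match analysis
#'
#' @param possessions A validated possession table (or a path to a
#'   possession CSV).
#' @param out_dir Output directory for the CSV report bundle; created if
#'   missing. `NULL` (default) skips writing.
#' @param min_bounds,max_bounds Bounds for the minimal / maximal
#'   pass-sequence-length sweeps.
#' @param D_values Scoring-difference thresholds.
#' @param unit Sampling unit of the connectivity contrast (see
#'   [sweep_sequence_lengths()]).
#' @param seed Optional seed recorded in the run metadata (the analysis
#'   itself is deterministic).
#' @return A list with `counts` (per-condition totals incl. N0 and
#'   per-minute rates), `sweep_min`, `sweep_max`, `scoring`, and `metadata`;
#'   written as `counts.csv`, `connectivity_sweep.csv`, `scoring_sweep.csv`,
#'   `run_metadata.json` when `out_dir` is given. Reruns with identical
#'   input and configuration produce byte-identical files.
#' @export
run_soccer_analysis <- function(possessions, out_dir = NULL,
                                min_bounds = 0:7, max_bounds = 1:8,
                                D_values = 1:4,
                                unit = c("team_match", "match_mean"),
                                seed = NULL) {
  unit <- match.arg(unit)
  if (is.character(possessions) && length(possessions) == 1) {
    possessions <- read_possession_table(possessions)
  }
  possessions <- validate_possessions(possessions)
  summaries <- summarize_thirds(possessions)
  counts <- summaries |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      n_team_thirds = dplyr::n(),
      n_p = sum(.data$n_p), n_c = sum(.data$n_c),
      goals = sum(.data$goals), N0 = sum(.data$N0),
      total_min = sum(.data$duration_min),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      passes_per_min = .data$n_p / .data$total_min,
      goals_per_min = .data$goals / .data$total_min,
      N0_per_min = .data$N0 / .data$total_min
    )
  sweep_min <- sweep_sequence_lengths(possessions, min_bounds, "min", unit)
  sweep_max <- sweep_sequence_lengths(possessions, max_bounds, "max", unit)
  scoring <- scoring_sweep(summaries, D_values)
  metadata <- run_metadata(
    list(min_bounds = min_bounds, max_bounds = max_bounds,
         D_values = D_values, unit = unit),
    seed
  )
  out <- list(counts = counts, sweep_min = sweep_min, sweep_max = sweep_max,
              scoring = scoring, metadata = metadata)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_report_csv(counts, out_dir, "counts.csv")
    write_report_csv(dplyr::bind_rows(sweep_min, sweep_max), out_dir,
                     "connectivity_sweep.csv")
    write_report_csv(scoring, out_dir, "scoring_sweep.csv")
    jsonlite::write_json(metadata, file.path(out_dir, "run_metadata.json"),
                         auto_unbox = TRUE, null = "null", pretty = TRUE)
  }
  invisible(out)
}

stratum_report <- function(trials, stratum_label, pool, skipped) {
  res <- tryCatch(
    tempo_comparison(trials, pool = pool),
    teamsync_insufficient_data_error = function(e) e
  )
  if (inherits(res, "error")) {
    return(list(
      summaries = NULL, pairwise = NULL,
      skipped = dplyr::bind_rows(skipped, tibble::tibble(
        stratum = stratum_label, reason = conditionMessage(res)))
    ))
  }
  list(
    summaries = dplyr::mutate(res$summaries, stratum = stratum_label,
                              .before = 1),
    pairwise = dplyr::mutate(res$pairwise, stratum = stratum_label,
                             .before = 1),
    skipped = skipped
  )
}

#' Run the full Stroop analysis
#'
#' Selects the incongruent trials of the stroop run in the music block,
#' then reports per-gender and per-menstrual-phase tempo-group summaries
#' (median, 95% CI), pairwise tempo rank-test matrices, and ECDF data.
#' Strata whose groups are too small are reported in `skipped` while the
#' analysis continues for the remaining strata.
#'
#' @param trials A validated Stroop trial table (or a path to a Stroop
#'   CSV).
#' @param out_dir Output directory; `NULL` (default) skips writing.
#' @param pool Pooling level of the tempo comparison (see
#'   [tempo_comparison()]).
#' @param seed Optional seed recorded in the run metadata.
#' @return A list with `summaries`, `pairwise`, `cdf` (one `(stratum,
#'   tempo_bpm, rt_s, F)` row per distinct reaction time), `skipped`, and
#'   `metadata`.
#' @export
run_stroop_analysis <- function(trials, out_dir = NULL,
                                pool = c("trials", "participants"),
                                seed = NULL) {
  pool <- match.arg(pool)
  if (is.character(trials) && length(trials) == 1) {
    trials <- read_stroop_table(trials)
  }
  selected <- select_trials(trials)
  skipped <- tibble::tibble(stratum = character(), reason = character())
  strata <- list()
  for (g in GENDERS) {
    strata[[g]] <- selected[selected$gender == g, ]
  }
  for (p in names(stratify_by_phase(selected))) {
    strata[[paste0("female_", p)]] <-
      selected[selected$gender == "female" & selected$phase == p, ]
  }
  summaries <- list()
  pairwise <- list()
  cdf <- list()
  for (label in names(strata)) {
    tr <- strata[[label]]
    if (nrow(tr) == 0) {
      skipped <- dplyr::bind_rows(skipped, tibble::tibble(
        stratum = label, reason = "no trials"))
      next
    }
    sr <- stratum_report(tr, label, pool, skipped)
    skipped <- sr$skipped
    summaries[[label]] <- sr$summaries
    pairwise[[label]] <- sr$pairwise
    cdf[[label]] <- tr |>
      dplyr::group_by(.data$tempo_bpm) |>
      dplyr::reframe(rt_s = sort(unique(.data$rt_s)),
                     F = rt_ecdf(.data$rt_s)(sort(unique(.data$rt_s)))) |>
      dplyr::mutate(stratum = label, .before = 1)
  }
  out <- list(
    summaries = dplyr::bind_rows(summaries),
    pairwise = dplyr::bind_rows(pairwise),
    cdf = dplyr::bind_rows(cdf),
    skipped = skipped,
    metadata = run_metadata(list(pool = pool), seed)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_report_csv(out$summaries, out_dir, "stroop_group_summaries.csv")
    write_report_csv(out$pairwise, out_dir, "stroop_pairwise_tests.csv")
    write_report_csv(out$cdf, out_dir, "stroop_cdf.csv")
    write_report_csv(out$skipped, out_dir, "stroop_skipped.csv")
    jsonlite::write_json(out$metadata,
                         file.path(out_dir, "run_metadata.json"),
                         auto_unbox = TRUE, null = "null", pretty = TRUE)
  }
  invisible(out)
}
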