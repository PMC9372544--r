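## Possession-level match events and Stroop trials: tibble-based domain
## types, CSV dialects, and structural validation.

POSSESSION_COLS <- c(
  "match_id", "team_id", "condition", "order_index",
  "n_passes", "n_contacts", "goal"
)

STROOP_COLS <- c(
  "participant_id", "gender", "phase", "tempo_bpm",
  "block", "run", "congruent", "rt_s"
)

#' Validate a possession-level event table
#'
#' A possession is one uninterrupted spell of ball control by one team and is
#' the atomic unit of the match analysis. Each row carries the counts of
#' completed passes and ball contacts during the possession and whether it
#' ended with a goal. Structural invariants: at least one contact per
#' possession, and no more passes than contacts (every pass is initiated by a
#' contact; a possession where every contact is a pass is legal one-touch
#' play).
#'
#' @param possessions A data frame with columns `match_id`, `team_id`,
#'   `condition` (one of `"wR"`, `"Sy"`, `"nS"`), `order_index`, `n_passes`,
#'   `n_contacts`, `goal` (logical or 0/1).
#' @return The validated table as a tibble, invisibly unchanged apart from
#'   `goal` being coerced to logical.
#' @export
validate_possessions <- function(possessions) {
  possessions <- tibble::as_tibble(possessions)
  missing <- setdiff(POSSESSION_COLS, names(possessions))
  if (length(missing) > 0) {
    ts_error(
      paste0("possession table is missing column(s): ",
             paste(missing, collapse = ", ")),
      "teamsync_format_error"
    )
  }
  bad_cond <- !possessions$condition %in% CONDITIONS
  if (any(bad_cond)) {
    ts_error(
      sprintf("unknown condition label %s in row(s) %s (expected wR, Sy, nS)",
              paste(unique(possessions$condition[bad_cond]), collapse = ", "),
              paste(utils::head(which(bad_cond), 5), collapse = ", ")),
      "teamsync_validation_error"
    )
  }
  check_count <- function(x, name, minimum = 0) {
    bad <- is.na(x) | x < minimum | x != trunc(x)
    if (any(bad)) {
      ts_error(
        sprintf("column %s must hold integer counts >= %d; bad row(s): %s",
                name, minimum,
                paste(utils::head(which(bad), 5), collapse = ", ")),
        "teamsync_validation_error"
      )
    }
  }
  check_count(possessions$n_passes, "n_passes", 0)
  check_count(possessions$n_contacts, "n_contacts", 1)
  check_count(possessions$order_index, "order_index", 0)
  over <- possessions$n_passes > possessions$n_contacts
  if (any(over)) {
    ts_error(
      sprintf("n_passes > n_contacts in row(s): %s",
              paste(utils::head(which(over), 5), collapse = ", ")),
      "teamsync_validation_error"
    )
  }
  if (!is.logical(possessions$goal)) {
    bad <- !possessions$goal %in% c(0, 1)
    if (any(bad)) {
      ts_error(
        sprintf("goal must be logical or 0/1; bad row(s): %s",
                paste(utils::head(which(bad), 5), collapse = ", ")),
        "teamsync_validation_error"
      )
    }
    possessions$goal <- as.logical(possessions$goal)
  }
  possessions
}

#' Read a possession-level event table from CSV
#'
#' The dialect is UTF-8, comma separated, `.` decimal separator, mandatory
#' header row, with columns
#' `match_id,team_id,condition,order_index,n_passes,n_contacts,goal`
#' (`condition` in `wR`/`Sy`/`nS`, `goal` in 0/1). A machine-readable schema
#' ships in `system.file("extdata", "possession_schema.json", package =
#' "teamsync")`.
#'
#' @param path Path to the CSV file.
#' @return A validated tibble of possessions, row order preserved.
#' @export
read_possession_table <- function(path) {
  if (!file.exists(path)) {
    ts_error(paste0("file not found: ", path), "teamsync_format_error")
  }
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      match_id = readr::col_character(),
      team_id = readr::col_character(),
      condition = readr::col_character(),
      order_index = readr::col_integer(),
      n_passes = readr::col_integer(),
      n_contacts = readr::col_integer(),
      goal = readr::col_integer(),
      .default = readr::col_guess()
    ),
    progress = FALSE, show_col_types = FALSE
  )
  validate_possessions(raw)
}

#' Write a possession table in the canonical CSV dialect
#'
#' Canonical column order and integer formatting, so that write-then-read is
#' an identity and rewriting an unmodified file is byte-identical.
#'
#' @param possessions A validated possession table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_possession_table <- function(possessions, path) {
  possessions <- validate_possessions(possessions)
  out <- possessions[, POSSESSION_COLS]
  out$goal <- as.integer(out$goal)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Validate a Stroop trial table
#'
#' One row per timed response of the color-word matching Stroop task.
#' Reaction times are positive seconds. Music (and hence a tempo) is present
#' only in block 2, and each participant hears a single tempo throughout, to
#' exclude memory effects.
#'
#' @param trials A data frame with columns `participant_id`, `gender`
#'   (`male`/`female`), `phase` (`menstrual`, `folicular`, `ovulatory`,
#'   `luteal`, or `not_applicable`), `tempo_bpm` (100/140/180, `NA` outside
#'   block 2), `block` (1..3), `run` (`neutral`/`stroop`), `congruent`
#'   (logical or 0/1), `rt_s` (seconds).
#' @return The validated tibble, `congruent` coerced to logical.
#' @export
validate_stroop_trials <- function(trials) {
  trials <- tibble::as_tibble(trials)
  missing <- setdiff(STROOP_COLS, names(trials))
  if (length(missing) > 0) {
    ts_error(
      paste0("stroop table is missing column(s): ",
             paste(missing, collapse = ", ")),
      "teamsync_format_error"
    )
  }
  bad_rows <- function(bad) paste(utils::head(which(bad), 5), collapse = ", ")
  if (any(bad <- !trials$gender %in% GENDERS)) {
    ts_error(sprintf("unknown gender label in row(s): %s", bad_rows(bad)),
             "teamsync_validation_error")
  }
  if (any(bad <- is.na(trials$phase) | !trials$phase %in% PHASES)) {
    ts_error(sprintf("unknown phase label in row(s): %s", bad_rows(bad)),
             "teamsync_validation_error")
  }
  if (any(bad <- !trials$block %in% 1:3)) {
    ts_error(sprintf("block must be 1, 2 or 3; bad row(s): %s", bad_rows(bad)),
             "teamsync_validation_error")
  }
  if (any(bad <- !trials$run %in% RUNS)) {
    ts_error(sprintf("run must be neutral or stroop; bad row(s): %s",
                     bad_rows(bad)),
             "teamsync_validation_error")
  }
  if (any(bad <- is.na(trials$rt_s) | trials$rt_s <= 0)) {
    ts_error(sprintf("rt_s must be > 0; bad row(s): %s", bad_rows(bad)),
             "teamsync_validation_error")
  }
  in2 <- trials$block == 2
  if (any(bad <- in2 & !trials$tempo_bpm %in% STROOP_TEMPI)) {
    ts_error(sprintf(
      "tempo_bpm must be one of 100, 140, 180 in block 2; bad row(s): %s",
      bad_rows(bad)), "teamsync_validation_error")
  }
  if (any(bad <- !in2 & !is.na(trials$tempo_bpm))) {
    ts_error(sprintf(
      "tempo_bpm must be empty outside block 2 (no music); bad row(s): %s",
      bad_rows(bad)), "teamsync_validation_error")
  }
  n_tempi <- tapply(trials$tempo_bpm[in2], trials$participant_id[in2],
                    function(x) length(unique(x)))
  if (any(n_tempi > 1)) {
    ts_error(sprintf(
      "participant(s) %s carry more than one tempo (one tempo per participant)",
      paste(utils::head(names(n_tempi)[n_tempi > 1], 5), collapse = ", ")),
      "teamsync_validation_error")
  }
  if (!is.logical(trials$congruent)) {
    if (any(bad <- !trials$congruent %in% c(0, 1))) {
      ts_error(sprintf("congruent must be logical or 0/1; bad row(s): %s",
                       bad_rows(bad)),
               "teamsync_validation_error")
    }
    trials$congruent <- as.logical(trials$congruent)
  }
  trials
}

#' Read a Stroop trial table from CSV
#'
#' Dialect: UTF-8, comma separated, header row, columns
#' `participant_id,gender,phase,tempo_bpm,block,run,congruent,rt_s`.
#' Schema in `system.file("extdata", "stroop_schema.json", package =
#' "teamsync")`.
#'
#' @inheritParams read_possession_table
#' @return A validated tibble of trials.
#' @export
read_stroop_table <- function(path) {
  if (!file.exists(path)) {
    ts_error(paste0("file not found: ", path), "teamsync_format_error")
  }
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      gender = readr::col_character(),
      phase = readr::col_character(),
      tempo_bpm = readr::col_integer(),
      block = readr::col_integer(),
      run = readr::col_character(),
      congruent = readr::col_integer(),
      rt_s = readr::col_double(),
      .default = readr::col_guess()
    ),
    progress = FALSE, show_col_types = FALSE
  )
  validate_stroop_trials(raw)
}

#' Write a Stroop trial table in the canonical CSV dialect
#'
#' @param trials A validated Stroop trial table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stroop_table <- function(trials, path) {
  trials <- validate_stroop_trials(trials)
  out <- trials[, STROOP_COLS]
  out$congruent <- as.integer(out$congruent)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Aggregate possessions into per-third summaries
#'
#' One row per (match, team, condition): total passes `n_p`, total contacts
#' `n_c`, goals, the number of possessions without any pass `N0` (an
#' indicator of team segregation), and the possession count. Each team plays
#' each condition in exactly one 10-minute third, so a (match, team,
#' condition) cell identifies a third.
#'
#' @param possessions A validated possession table.
#' @param duration_min Length of one third in minutes (default 10).
#' @return A tibble with columns `match_id`, `team_id`, `condition`, `n_p`,
#'   `n_c`, `goals`, `N0`, `n_possessions`, `duration_min`. Empty input gives
#'   an empty tibble.
#' @export
summarize_thirds <- function(possessions, duration_min = 10) {
  possessions <- validate_possessions(possessions)
  possessions |>
    dplyr::group_by(.data$match_id, .data$team_id, .data$condition) |>
    dplyr::summarise(
      n_p = sum(.data$n_passes),
      n_c = sum(.data$n_contacts),
      goals = sum(.data$goal),
      N0 = sum(.data$n_passes == 0),
      n_possessions = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(duration_min = duration_min)
}

#' Convert per-third counts to per-minute rates
#'
#' Playing-time normalization for comparisons between groups with different
#' match counts (e.g. 16 male vs 14 female matches).
#'
#' @param summaries A third-summary table (see [summarize_thirds()]).
#' @param total_minutes Total playing time the counts accumulate over; must
#'   be positive.
#' @return The input with `n_p`, `n_c`, `goals`, `N0` replaced by per-minute
#'   rates.
#' @export
rate_normalize <- function(summaries, total_minutes) {
  if (!is.numeric(total_minutes) || length(total_minutes) != 1 ||
      is.na(total_minutes) || total_minutes <= 0) {
    ts_error("total_minutes must be a single positive number",
             "teamsync_argument_error")
  }
  dplyr::mutate(
    tibble::as_tibble(summaries),
    dplyr::across(dplyr::any_of(c("n_p", "n_c", "goals", "N0")),
                  ~ .x / total_minutes)
  )
}
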