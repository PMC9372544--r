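# Builders for small in-code fixtures and independent test oracles.

make_possessions <- function(n_passes, n_contacts = n_passes + 1,
                             goal = FALSE, match_id = "M1", team_id = "T1",
                             condition = "wR") {
  n <- length(n_passes)
  tibble::tibble(
    match_id = rep_len(match_id, n),
    team_id = rep_len(team_id, n),
    condition = rep_len(condition, n),
    order_index = seq_len(n) - 1L,
    n_passes = as.integer(n_passes),
    n_contacts = as.integer(rep_len(n_contacts, n)),
    goal = rep_len(goal, n)
  )
}

# one team-match with given pass counts per condition third
make_team_match <- function(match_id, team_id, passes_by_cond,
                            goals_by_cond = NULL) {
  dplyr::bind_rows(lapply(names(passes_by_cond), function(cond) {
    np <- passes_by_cond[[cond]]
    g <- rep(FALSE, length(np))
    if (!is.null(goals_by_cond) && goals_by_cond[[cond]] > 0) {
      g[seq_len(goals_by_cond[[cond]])] <- TRUE
    }
    make_possessions(np, np + 1L, goal = g, match_id = match_id,
                     team_id = team_id, condition = cond)
  }))
}

# goals-only third summary table (for scoring statistics)
make_goal_summaries <- function(goals_a, goals_b, cond_a = "wR",
                                cond_b = "Sy") {
  n <- length(goals_a)
  ids <- sprintf("TM%02d", seq_len(n))
  tibble::tibble(
    match_id = rep(ids, 2),
    team_id = rep(ids, 2),
    condition = rep(c(cond_a, cond_b), each = n),
    n_p = 0L, n_c = 1L,
    goals = c(goals_a, goals_b),
    N0 = 0L, n_possessions = 1L, duration_min = 10
  )
}

# independent complete-enumeration oracle for the two-sided rank test:
# enumerates group assignments as bit masks (a different route than the
# package's combn enumeration)
oracle_rank_p <- function(x, y) {
  nx <- length(x)
  n <- nx + length(y)
  stopifnot(n <= 20)
  r <- rank(c(x, y))
  mu <- nx * (n + 1) / 2
  d_obs <- abs(sum(r[seq_len(nx)]) - mu)
  bits <- matrix(as.integer(intToBits(0:(2^n - 1))),
                 nrow = 32)[seq_len(n), , drop = FALSE]
  keep <- colSums(bits) == nx
  sums <- colSums(bits[, keep, drop = FALSE] * r)
  mean(abs(sums - mu) >= d_obs - 1e-9)
}

# popcount of 0 .. 2^n - 1, built by doubling (independent of choose())
popcounts <- function(n) {
  pc <- 0L
  for (i in seq_len(n)) {
    pc <- c(pc, pc + 1L)
  }
  pc
}
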