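# teamsync

Statistical pipeline for a two-part question from movement science: does a
collectively displayed rhythmic acoustic stimulus improve interpersonal
coordination in team play, and does its tempo modulate attention?

The experimental design it serves: small-sided (5-a-side) soccer matches of
three 10-minute thirds, one played without rhythm (`wR`), one with a rhythm
delivered synchronously at 140 bpm to all teammates (`Sy`), and one with
the same rhythm at a different tempo per player (`nS`, 119–161 bpm); and a
color-word matching Stroop task performed under the same rhythm at 100,
140, or 180 bpm, with reaction times on incongruent trials measuring the
attention level.

## The statistics at its core

* **Connectivity index** of a team in one third: `C = n_p / n_c`, passes
  per ball contact — an operationalization of generalized synchronization
  in team play. Condition effects are measured by **relative
  connectivity**, `(C_cond − C_wR) / C_wR`, which removes absolute team
  strength; samples of these values (one per team-match per condition) are
  compared with a two-sided Mann-Whitney-Wilcoxon rank test, optionally
  stratified by pass-sequence length.
* **Scoring differences**: for each team-match, the team-matches where one
  condition out-scored the other by at least `D` goals are counted as
  `(k_A, k_B)`, and the probability of that split under an equal-chance
  null is the exact binomial point probability
  `P = C(k_A+k_B, k_B) · p_A^k_A · p_B^k_B` with `p_A = p_B = 1/2`.
* **Reaction-time analysis**: empirical CDFs, medians with
  distribution-free order-statistic 95% confidence intervals, and pairwise
  rank tests between tempo groups, within gender and menstrual-cycle-phase
  strata.
* An exact **Mann-Whitney-Wilcoxon** implementation (midrank ties, complete
  enumeration up to 10^6 assignments, seeded Monte-Carlo fallback,
  tie-corrected normal approximation) backs all contrasts.
* Seeded **synthetic generators** emulate both experiments (geometric
  pass-chain possession model; shifted-lognormal reaction times) with known
  ground truth, so every stage is verifiable by parameter recovery without
  the original data.

## Worked example

Simulate the 16-match cohort with its study-condition effects (+4% Sy,
−8% nS analytic relative connectivity), then run the condition contrast:

```r
library(teamsync)

sim <- simulate_experiment(match_sim_config("male16"), seed = 1)
rc  <- relative_connectivity_table(sim$third_summaries)
condition_contrast(rc$value[rc$condition == "Sy"],
                   rc$value[rc$condition == "nS"])
#> # A tibble: 1 × 7
#>    n_Sy  n_nS median_Sy median_nS statistic     p_value method
#>   <int> <int>     <dbl>     <dbl>     <dbl>       <dbl> <chr>
#> 1    32    32    0.0396   -0.0913       879 0.000000861 rank_normal
```

The 32 team-matches recover the injected effects (median +4.0% under Sy,
−9.1% under nS) and the rank test cleanly separates the two stimulated
conditions. Scoring differences and their binomial point probabilities:

```r
scoring_sweep(sim$third_summaries, D_values = 1:3)
#> # A tibble: 9 × 6
#>   cond_a cond_b     D   k_a   k_b     P
#>   <chr>  <chr>  <int> <int> <int> <dbl>
#> 1 wR     Sy         1    13    13 0.155
#> 2 wR     Sy         2     5     7 0.193
#> # ... 7 more rows

binomial_probability(6, 20)   # the reference 6-vs-20 favor split
#> [1] 0.003430694
```

At one simulated cohort the goal statistic is noisy (P ≈ 0.13 for Sy vs nS
at D = 1 here); the 6-vs-20 split evaluates to 0.003431 at four
significant figures. The Stroop side, at the study's male group sizes
(20 participants × 24 incongruent trials per tempo) with the −6.5% shift
at 140 bpm:

```r
stroop <- simulate_stroop(stroop_sim_config(), seed = 1)
male   <- select_trials(stroop$trials) |> dplyr::filter(gender == "male")
tempo_comparison(male)$summaries
#> # A tibble: 3 × 5
#>   tempo_bpm     n median ci_low ci_high
#>       <dbl> <int>  <dbl>  <dbl>   <dbl>
#> 1       100   480   1.70   1.64    1.74
#> 2       140   480   1.55   1.49    1.59
#> 3       180   480   1.62   1.57    1.68
```

The 140 bpm group's median reaction time is about 0.1 s below the others,
and the pairwise rank tests flag 140-vs-100 (p ≈ 9e-5) and 140-vs-180
(p ≈ 0.004) while 100-vs-180 stays non-significant (p ≈ 0.3).

`run_soccer_analysis()` / `run_stroop_analysis()` compose these stages
into CSV report bundles; `inst/cli/teamsync.R` wraps them for shell use.

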