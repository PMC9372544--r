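---
title: "Quantifying rhythm-driven interpersonal coordination: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying rhythm-driven interpersonal coordination: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
library(teamsync)
```

teamsync analyses a two-part experimental design: small-sided soccer
matches played under three acoustic conditions, and a color-word matching
Stroop task performed under rhythms of different tempi. This vignette
documents the statistical models, the tunable parameters, the synthetic
generators, and the design choices that were genuinely open — the things a
maintainer would want to know before trusting or changing a default.

## The match analysis

### Design

Teams of 5 play 30-minute matches divided into three 10-minute thirds. One
third is played without rhythmic stimulation (`wR`); in the other two, a
rhythm is delivered over headphones to all players — synchronously at 140
bpm to one team (`Sy`) while the other team hears the same rhythm at one
tempo per player, 119/133/147/154/161 bpm (`nS`), and vice versa in the
other stimulated third. Every team therefore experiences each condition
exactly once per match, and the *team-match* (one team within one match) is
the unit on which conditions are compared. The emulated cohorts are 16
matches (male, `wR` third placed at beginning/middle/end in 6/6/4 matches)
and 14 matches (female, 5/5/4).

### Connectivity

Effective team play in this exercise means fast, precise passing with few
ball contacts per player. The connectivity of a team in one third is

$$C = n_p / n_c,$$

passes per ball contact, a dimensionless ratio in $[0, 1]$ (one-touch play,
where the reception simultaneously is the pass, attains the bound). To
remove the absolute strength of the randomly constituted teams, each
stimulated third is normalized to the same team-match's unstimulated third:

$$C_{rel} = (C^{cond} - C^{wR}) / C^{wR},$$

so 0.1 means a 10% improvement over playing without rhythm. The Sy-vs-nS
contrast compares the two samples of $C_{rel}$ values (one per team-match
per condition) with a two-sided Mann-Whitney-Wilcoxon rank test; the
pooled-variance two-sample t test is provided as the parametric
counterpart. Pass-sequence-length stratification (`filter_possessions()`,
`sweep_sequence_lengths()`) recomputes the whole pipeline on possessions
with at least / at most a given number of passes; bounds are inclusive, and
length 0 is a possession without any pass (the `N0` segregation indicator
counts these).

Choices worth knowing:

* **Unit of analysis.** Each team-match contributes one Sy and one nS
  value, pooled across matches (`unit = "team_match"`). Averaging the two
  teams of a match first (`unit = "match_mean"`) is exposed because the
  design does not force either reading; pooling is the more granular and is
  the default.
* **Degenerate thirds.** A filtered third with no remaining contact, or a
  wR third with $C = 0$, cannot be normalized; the team-match is dropped
  from that bound's sample with a message rather than imputed.
* **A caveat the tests quantify.** The Sy and nS values of a team-match
  share the same wR denominator, so the two samples are positively
  correlated and the two-sample null contrast is *conservative*: under a
  zero-effect simulation its rejection rate at the nominal 5% level is
  well below 5% (the property suite asserts the one-sided bound; the
  simulated rate is under 1%). Detected effects are therefore, if
  anything, understated; users should not interpret a non-significant
  contrast at nominal 5% as a calibrated 5% test.

### Scoring differences

For a condition pair and threshold $D \ge 1$, each team-match is counted in
favor of whichever condition out-scored the other by at least $D$ goals
(ties count for neither side). Under the null that either direction is
equally likely, the probability of an observed split $(k_A, k_B)$ is the
binomial point probability

$$P = \binom{k_A + k_B}{k_B}\, p_A^{k_A}\, p_B^{k_B}, \qquad
  p_A = p_B = 1/2 .$$

This is deliberately the *point* probability of the observed split, not a
tail sum — it is the quantity the analysis is built around, and
`binomial_probability(6, 20)` reproduces the reference value 0.003431. A
conventional one-sided sign-test tail is available behind `tail = TRUE` as
an extension. Two properties matter for interpretation: the point
probabilities over all splits of $n = k_A + k_B$ sum to 1 and are symmetric
at $p = 1/2$; but the event $\{P \le \alpha\}$ is **not** a calibrated
$\alpha$-level event (with $n = 26$ its null probability is about 0.17).
The test suite checks the point probability against exhaustive enumeration
of the $2^n$ favor sequences and checks the observed frequency of
$\{P \le 0.05\}$ under a null simulation against its exact binomial value.
Goals are compared per third without duration normalization (thirds are
equally long); cross-cohort count comparisons use per-minute rates
(`rate_normalize()`), which removes the different match counts of the two
cohorts.

### Rank-test machinery

`mann_whitney()` uses midranks for ties and defines the two-sided p-value
as the permutation probability of a rank sum at least as far from its null
mean as observed. Method selection: complete enumeration of all
$\binom{n_x+n_y}{n_x}$ assignments when that count is at most $10^6$
(exactness at the sample sizes of the sweeps); a seeded Monte-Carlo
permutation estimate (add-one corrected so $p > 0$) for pooled sizes up to
30 where enumeration is infeasible; otherwise the normal approximation with
tie-corrected variance and a 0.5 continuity correction. For tie-free data
the exact path agrees with `wilcox.test(exact = TRUE)`; with ties it agrees
with complete enumeration by construction (both verified in the suite, the
latter against an independent bitmask enumeration). No multiple-testing
correction is applied across sweep bounds — each bound reports its raw p —
since the sweep is a sensitivity display, not a family of confirmatory
tests.

## The Stroop analysis

Participants perform 3 blocks of two 48-trial runs (neutral, stroop; 24
congruent and 24 incongruent trials each, randomized). Only block 2 is
performed under music, at one tempo per participant (100, 140, or 180
bpm). The analysis selection is the incongruent trials of the stroop run
in block 2; blocks 1 and 3 stay in the data model for baseline contrasts.
Group structure: 20 male participants per tempo; female participants
stratified by menstrual-cycle phase (menstrual 10/10/10, folicular 2/2/5,
ovulatory 4/6/3, luteal 8/7/8 at 100/140/180 bpm), phase labels assigned
upstream by forward-counting and taken as given.

Per group the package reports the empirical CDF, the median, and a
distribution-free 95% confidence interval from symmetric order-statistic
ranks: with $B \sim \mathrm{Binomial}(n, 1/2)$, the interval
$[X_{(j+1)}, X_{(n-j)}]$ has exact coverage $1 - 2P(B \le j)$. The default
rank rule picks $j$ with exact coverage *closest* to the nominal level;
at the emulated group sizes (48–480 trials) this keeps true coverage
within roughly 94–96%, whereas the conservative rule (largest interval
with coverage $\ge$ 95%, available via `rank_rule = "conservative"`)
overshoots to 97% at the smallest cells. A bootstrap percentile interval
is available as an alternative method. Pairwise tempo contrasts use the
same rank test as the match analysis.

Pooling is trial-level by default (the cumulative distributions are
trial-level distributions); `pool = "participants"` reduces each
participant to their median first and is the right choice whenever
participant heterogeneity dominates. No reaction-time trimming is applied
by default.

## The synthetic generators

The generators exist to make every pipeline stage verifiable by parameter
recovery with known ground truth; their defaults encode the emulated study
conditions.

**Match generator.** Possessions arrive per team-third as
$\mathrm{Poisson}(\text{rate} \times \text{minutes})$ with a default rate
of 6 possessions per team per minute — in a 5-a-side possession exercise
on a small pitch, possession changes every few seconds. Within a
possession, each contact's pass succeeds with probability $q$; the
possession ends at the first failure, so passes per possession are
geometric, $n_c = n_p + 1$, and the third-level connectivity converges to
$q$ — the generator's single behavioural parameter *is* the statistic
under study, which makes the analytic expectation of relative
connectivity simply $\mathit{effect}/q_{base}$. Defaults: $q_{base} =
0.65$; Sy effect $+0.04\,q_{base}$ and nS effect $-0.08\,q_{base}$ (the
reported male effect magnitudes used as generator inputs, giving analytic
relative connectivity $+0.04$ and $-0.08$); goal probability at possession
end rising with the pass count to a plateau
(0.005/0.02/0.045/0.07/0.09 at 0/1/2/3/4+ passes), reflecting that
long-distance shots were not allowed, so scoring requires build-up.

What the generator does **not** emulate: heterogeneous team strength
(irrelevant by construction, since relative connectivity removes it),
within-match coupling between the two teams (one team's possession ends
the other's), defensive pressure varying with pass count, fatigue across
thirds, and any dependence of possession counts on condition. Passing
tests therefore show that the pipeline recovers effects of the assumed
possession process, not that real match data satisfy that process.

**Stroop generator.** Reaction times are shifted lognormal,
$rt = m(s + e^{N(\mu + \delta, \sigma)})$ with defaults $s = 0.2$ s,
$e^\mu = 1.3$ s, $\sigma = 0.35$ (baseline median 1.5 s, the scale on
which a 0.1 s shift is about 6.5%), interference increment $\delta = 0.10$
on incongruent stroop-run trials, and the multiplicative factor $m$
applied only in block 2 per the participant's tempo group (default: male
140 bpm $-6.5\%$; all other cells 0). The group's true block-2 incongruent
median is $m(s + e^{\mu + \delta})$, which the coverage and recovery
studies use as ground truth. Trials are i.i.d. within a group — there is
no participant random effect, consistent with the trial-pooled default
unit; with participant heterogeneity the trial-pooled tests would be
anticonservative, which is exactly when `pool = "participants"` should be
used instead.

## Numerical choices and degenerate inputs

* Exact enumeration cutoff $10^6$ assignments; Monte-Carlo window up to
  pooled $n = 30$ with $10^4$ permutations by default; normal
  approximation beyond, whose agreement with the exact tie-free
  distribution is regression-tested at $n = 15 + 15$ (within 0.01).
* Rank-sum comparisons use an absolute tolerance of $10^{-9}$ when
  counting assignments as extreme, so midrank arithmetic cannot flip a
  strict inequality.
* p-values are clamped into $(0, 1]$; a pooled sample with zero rank
  variance (all values identical) returns $p = 1$.
* Zero-contact thirds raise an undefined-statistic error; zero wR
  connectivity drops the team-match from relative samples with a warning;
  all-equal paired goal differences raise a degenerate-variance error
  rather than returning $t = \mathrm{NaN}$.
* Effect-shifted probabilities outside $[0, 1]$ are clipped with a
  warning at configuration time.
* Binomial point probabilities are computed from `choose()` and powers of
  $1/2$, which are exact in double precision throughout the study's count
  range (the normalization identity holds to $10^{-12}$ up to $n = 25$).

## Problem sizes of the verification studies

The calibration and recovery studies in the test suite run at sizes chosen
to bound their Monte-Carlo error while staying desk-scale: 1000 null
replicates of the 14-match cohort for contrast calibration; 50 replicates
of a 200-match cohort (plus 200 replicates at 16 matches) for effect
recovery; 500 replicates at the male group sizes for the tempo-shift power
study and 200 for null uniformity; 1000 replicates per group size for
median-interval coverage. Convergence at 200 matches is judged against the
recovered median's own Monte-Carlo spread, below which the
median-of-ratios bias (order $1/n_{poss}$, about 0.002 here) is not
resolvable.

## Known limitations

* The conservative null behaviour of the Sy-vs-nS contrast (shared wR
  denominator) is inherent to the normalization, not fixable by the test
  choice; a paired statistic on $C^{Sy} - C^{nS}$ would be calibrated but
  is a different analysis than the one implemented here.
* The point-probability scoring statistic is descriptive of the observed
  split; it is not a size-$\alpha$ test (see above).
* Possession boundaries, contact-counting conventions and phase
  assignment are upstream annotation concerns; the tables are taken as
  ground truth, and the data model only enforces $n_p \le n_c$.
* Connectivity compares conditions within team-matches only; it is not a
  graph-theoretic pass network and carries no player-level information.
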