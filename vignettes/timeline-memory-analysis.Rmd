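---
title: "Analyzing boundary-segmented timeline memory experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing boundary-segmented timeline memory experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(timelinr)
library(dplyr)
```

## The task and its measurements

`timelinr` analyzes serial-position timeline memory experiments in which a
participant encodes a sequence of 72 pictures segmented into 9 color
contexts of 8 items (the frame color changes after every eighth picture,
creating an event boundary), and later places probed items on a 1–72
timeline. Each participant completes three such sessions, one per
within-subject stimulation condition (sham, slow-theta 3 Hz, fast-theta
8 Hz), with the six possible condition orders counterbalanced across
participants. The timeline task probes the 1st (boundary), 3rd, 5th, and
7th item of every context — 36 probes per session.

Two dependent variables are computed per probe:

* **temporal accuracy** — the absolute placement error `|rated − actual|`,
  in position units (lower is better);
* **temporal bias** — the signed error `rated − actual` (negative =
  placed earlier than actual, i.e. temporal compression).

For every subject, condition, and position class (boundary vs
non-boundary), trials are averaged into a *subject cell*; the cells are the
unit of all inference.

## The chance-level null

Timeline placements have a position-dependent chance level: a random
responder makes larger absolute errors at the ends of the scale than in the
middle. The package implements the null in two equivalent ways:

* `simulate_chance()` draws `n_series` uniformly random permutations of
  `1..72` as simulated response series and averages per-position absolute
  and signed errors across series.
* `exact_chance()` uses the closed form: the marginal of a uniform random
  permutation at any slot is uniform on `1..N`, so the expected absolute
  error at position `p` is `(p(p−1)/2 + (N−p)(N−p+1)/2)/N`, the expected
  signed error is `(N+1)/2 − p`, and the grand mean absolute error is
  `(N² − 1)/(3N)` — for `N = 72`, `5183/216 ≈ 23.995`, which rounds to 24.

Because permutations and independent uniform draws share the same
per-position marginal, the exact oracle is valid for the permutation null;
the permutation structure additionally forces the grand signed error of
*every* series to be exactly zero (a permutation preserves the multiset of
positions).

```{r chance}
mc <- simulate_chance(n_series = 10000, n_positions = 72, seed = 1)
glance(mc)
exact_chance(72)$abs_error[c(1, 36)]
```

`compare_to_chance()` mirrors the empirical-vs-chance procedure: per
subject, the difference between the chance curve and the empirical error at
each probed position is averaged over retained trials, and the subject
means are tested against zero per condition with one-sample t-tests
(df = n − 1). Bias is compared against the per-position chance signed error
rather than the grand zero, mirroring the accuracy procedure; the grand
means average all 72 positions with equal weight, while subject comparisons
use only the probed positions.

## The generative simulator

Because the study's raw data live in an external repository, the package
ships a generative stand-in with the statistical structure the analysis
assumes. Rated positions follow a linear compression model per condition
`c`:

```
rated = round(clip(actual + b_subj + a_c + s_c * (wcp − 1) + ε, 1, 72)),
ε ~ Normal(0, σ_c),  b_subj ~ Normal(0, subject_sd)
```

where `wcp` is the within-context position, `a_c` the condition's bias
intercept, and `s_c` its slope in distance from the boundary (negative
slope = compression growing away from the boundary). Linearity in boundary
distance is the simplest structure consistent with a boundary-vs-pooled
non-boundary contrast. Rated positions are rounded to whole numbers and
clipped to the scale endpoints, mirroring the response device. Encoding
response times carry a boundary slowing effect (default +0.15 s) inside
the 2.5 s response window, with a 1% missing-response rate (missing
responses are dropped from RT analyses). Timeline response times are
lognormal with a 2% default rate of out-of-range outliers (uniform on
[0.1, 0.5) ∪ (15, 30] s), which feed the exclusion rules. A configurable
fraction of subjects are degenerate same-location responders who repeat
their previous rating with probability 0.53.

Default bias/noise values are calibrated so default 24-subject cohorts land
near the canonical group-level cell means of the task — pooled accuracy
about 17 (sham) and 15 (slow theta); pooled bias about −2.9 (sham) and
−0.7 (fast theta) — *after* clipping and rounding attenuation. The raw
linear parameters are therefore larger in magnitude than the attenuated
landing points. No test asserts the landing points themselves; tests assert
recovery of configured parameters and sign/order properties.

What the simulator does **not** emulate: edge pile-up of responses beyond
what Gaussian-plus-clip produces, response granularity effects, serial
dependencies in non-degenerate responders, and any oscillatory mechanism —
the generator is phenomenological. Passing tests therefore validate the
analysis machinery and its calibration on data with these properties, not
the neuroscientific claims themselves.

```{r cohort}
cohort <- simulate_cohort(design_spec(n_participants = 6), seed = 1)
cohort
```

### Parameter recovery

`recover_bias_params()` fits per-subject least squares of trial bias on
boundary distance and averages coefficients across subjects. Recovery is
assessed in a moderate-noise regime (noise SD 5) restricted to interior
serial positions 17–56, where the linear model is observed without
censoring; at the default noise levels the scale edges censor the model and
least squares estimates the clipped process instead of the generating
parameters — a property of the scale, not a bug in the estimator.

## Exclusions, degenerate responders, aggregation

* Timeline trials with response times **strictly** below 0.5 s or above
  15 s are excluded; boundary values are retained. On default cohorts with
  outlier rate 0.022 this discards about 2.2% of trials.
* A subject whose modal rated position accounts for ≥ 50% of trials is
  flagged as a same-location responder and (optionally) dropped.
* The non-boundary cell averages the per-position means of positions 3, 5,
  and 7 with equal weight, so unequal exclusions cannot re-weight
  positions. `granularity = "four_position"` keeps the four probed
  positions separate for the supplementary 3 × 4 analyses.
* The robust re-analysis replaces trial-level means with two-sided trimmed
  means; the trim fraction defaults to 0.2 per tail and is configurable. At
  trim 0 the robust chain reproduces the raw chain exactly.

## Inference chain

`rm_anova()` fits the univariate (subject-stratified) within-subject
ANOVA: each within effect is tested against its own subject-by-effect
interaction, so a 3 × 2 design with 24 subjects reports df (2, 46) for the
condition effect and (1, 23) for the position effect — the convention the
task's analyses use. Partial eta squared is
`SS_effect / (SS_effect + SS_error)`. Sphericity is assumed by default;
`sphericity_correction = "greenhouse_geisser"` rescales dfs by the Box
epsilon estimated from the subject-cell covariance. Effects with zero
effect variance are reported as F = 0, p = 1 rather than NaN, which makes
the end-to-end identity-generator null well defined.

A note on the encoding response-time analysis: the package fits the 3 × 8
(condition × encoding position) univariate model, under which the position
effect for 24 subjects carries df (7, 161). Published reports of this
design sometimes print multivariate-flavored dfs for the 8-level position
effect; the package deliberately implements the univariate model whose df
convention matches the main 3 × 2 analyses, and documents the discrepancy
here rather than matching it.

`pairwise_posthoc()` runs paired t-tests for all level pairs on
subject-level values pooled over position classes, with Cohen's d for
paired differences (`mean(diff)/sd(diff)`, sample sd) and the
Bonferroni-corrected alpha `0.05/3 ≈ 0.0167` for three condition
comparisons.

`diff_correlation()` correlates, across subjects, the stimulation-induced
change in accuracy with the change in bias (each relative to sham);
`compare_condition_correlations()` then compares the two condition-wise
correlations with a z-test for non-overlapping dependent correlations: the
Fisher-transformed difference scaled by the Pearson–Filon covariance term
estimated from the six pairwise correlations among the four difference
scores. When cross-correlations are unavailable the statistic falls back to
the independent-samples Fisher z with a warning; with zero
cross-correlations the two coincide
(`z = (atanh r₁ − atanh r₂) / sqrt(2/(n−3))`).

`covariate_anova()` enters one mean-centered between-subject covariate
(sham identification, or stimulation order coded 1..6 as a linear term)
with its interactions with the within factors. `sham_identification_test()`
uses the exact binomial tail against chance level 1/3 — the package's
deliberate choice of test for a binary identification count; both one- and
two-sided p-values are reported.

`power_rm_anova()` searches the smallest n whose noncentral-F tail beyond
the central critical value reaches the target power, with noncentrality
`f²·n·m·ε/(1−ρ)`. The assumed repeated-measures correlation ρ is exposed
(default 0.5) because power for within designs is undefined without it.

```{r power}
power_rm_anova(f = 0.30, alpha = 0.05, target_power = 0.8, m = 3, rho = 0.5)
```

## The pipeline

`run_pipeline()` chains everything with one master seed fanned out into
per-stage child seeds, so stages are independently reproducible. With an
output directory it writes the dataset CSVs, the chance curve, the subject
cells (raw and trimmed), a JSON result bundle, and a Markdown report with
eight analysis blocks (encoding RT, chance, accuracy, bias, robust,
correlations, identification, order). Stage failures abort with the stage
name; completed outputs are preserved. Configurations can be read from
YAML via `read_run_config()`.

```{r pipeline, eval = FALSE}
bundle <- run_pipeline(run_config(seed = 1, out_dir = "run1"))
tidy(bundle$anova_accuracy)
```

## Numerical and design choices

* Positions are 1-based everywhere; no 0-based index crosses a function
  boundary.
* Frame colors come from a fixed built-in palette of 27 maximally spaced
  RGB triples (the 3 × 3 × 3 grid over channel values {0, 128, 255});
  any palette of distinct colors can be substituted.
* Probe order within the timeline task is uniformly shuffled (seeded);
  the original task's probe order is not documented, and no analysis here
  depends on it except the degenerate responder's sticking behavior.
* Degenerate-subject flagging operates per subject across all sessions;
  the modal-share threshold (0.5) is the documented flagging rule.
* Ties and degenerate statistics are reported, not hidden: zero-variance
  paired differences give t = 0/d = 0 (all-zero case) or an explicit
  degenerate flag; constant difference vectors give an undefined r with a
  warning; a constant covariate is an error at the function level and a
  "not estimable" entry in the pipeline report.
* Monte-Carlo problem sizes used by the test suite: 10,000 chance series;
  1000 cohorts for the type-I calibration and boundary-effect averages;
  500 cohorts for the effect-detection checks; 200 subjects for parameter
  recovery. These sizes give Monte-Carlo standard errors comfortably below
  the asserted tolerances.

## Known limitations

* The simulator's Gaussian-plus-clip response model is one of several
  plausible forms; empirical rated-position distributions (granularity,
  edge pile-up) may differ.
* The univariate ANOVA assumes sphericity by default; for the 8-level
  encoding-position factor the Greenhouse–Geisser flag is advisable.
* Trial-level mixed-effects models and Bayesian re-analyses are out of
  scope; the analysis aggregates to subject cells throughout.
* The exact-binomial identification test is a deliberate substitution of a
  well-defined exact procedure for an ambiguous named test; its p-value is
  not expected to reproduce any particular published value.
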