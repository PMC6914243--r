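---
title: "Methods: trial-based cost-effectiveness analysis with blendcea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trial-based cost-effectiveness analysis with blendcea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blendcea)
```

## The problem

blendcea implements a complete trial-based health-economic evaluation for a
two-arm psychotherapy trial (blended care versus standard care for
depression in specialized mental health services) with assessments at
baseline and three follow-ups (weeks 10, 20, 30). The pipeline covers:

1. derivation of clinical and utility outcomes from raw assessments,
2. costing of self-reported resource use from two analytic perspectives,
3. baseline-adjusted mixed-model estimation of incremental costs and
   effects,
4. Monte Carlo propagation to ICERs, cost-effectiveness planes and
   acceptability curves (CEACs), and
5. a sample-size simulation for CEAC stability.

Because patient-level data from such trials are generally not deposited,
the package ships a synthetic trial generator whose defaults encode the
published summary structure of a pilot trial of this design. Every
downstream stage is exercised and tested against that generator.

## Clinical outcomes

**Reliable change.** The reliable change index divides the change score
(follow-up minus baseline, on the 0–84 depression self-report scale) by the
standard error of the difference scores. We use the published constant
`se_diff = 4.78` rather than recomputing it from a baseline SD and
reliability: recomputation gives 4.76–4.80 depending on which printed SD
one starts from, and a fixed constant is reproducible. Treatment response
is `RCI < -1.96` (strict; the boundary value is non-response), remission
additionally requires a follow-up score strictly below 13, so remission
always implies response. Boundary conventions follow the printed
definitions exactly.

**Completers.** A patient is a treatment completer at 14 or more total
sessions — the smallest integer covering 75% of the 18-session protocol.
(The source material is internally inconsistent about whether the protocol
baseline is 18 or 19 sessions; we follow the explicit "75% of 18" formula,
which yields 14.)

**QALYs.** Cumulative quality-adjusted life-years are the trapezoid
integral of the piecewise-linear interpolation of EQ-5D utilities over
time, divided by 365.25/7 weeks per year. Missing interior utilities are
skipped, so interpolation spans the gap; values are never extrapolated
beyond the last observed utility. Severity classes use configurable
cutpoints (defaults 13/25/38/48, the instrument's published severity
index) — these are configuration, not constants, because the analysis does
not depend on them.

## Costing

Resource-use counts over each 4-week recall window are multiplied by unit
prices; medication items additionally carry a fixed dispensing fee
(default €6 per prescription). Therapist feedback on online sessions is
costed at 30 minutes of therapist time per message. The shipped unit-cost
table is **illustrative only**: the real reference-year values live in a
national costing manual and must be supplied by the user
(`read_unit_costs()`).

**Cumulative costs.** The published description says only "linear
interpolation". We convert each window cost to a per-week rate
(window/4) and integrate the piecewise-linear rate curve — this reproduces
a constant-cost patient exactly (window €400 → €100/week → €3000 over 30
weeks) and handles missing interior windows by interpolating the rate
across the gap, consistent with the mixed models' missing-at-random
stance (no zero-imputation). Two alternatives are exposed behind flags:
`method = "window_scale"` multiplies each follow-up window by gap/4 (2.5
for 10-week gaps) and sums; `anchor_baseline = FALSE` treats the baseline
window as a pre-treatment reference and carries the first follow-up rate
back to week 0. Whether the original analysis anchored at the baseline
window is not stated; anchoring is the default here.

**Delivery costs.** Face-to-face sessions are costed at a per-session
price and feedback messages via the therapist rate; both accrue linearly
over the study period in the cumulative series. Online sessions carry no
platform cost (hosting costs are explicitly unavailable and out of scope).

**Perspectives.** Societal = direct medical + direct nonmedical +
indirect nonmedical (conservation is asserted to 1e-9 in the tests);
provider = direct medical only. Sensitivity variants drop inpatient items
(rare, costly, potentially influential) or keep only
absenteeism/presenteeism costs. Productivity losses are costed
human-capital style (hours × price); no friction-cost correction is
applied because none is described.

## Mixed models

Continuous outcomes use linear mixed models with a patient random
intercept, restricted maximum likelihood, categorical time, and a baseline
covariate when specified; follow-up rows only are modeled, and partially
observed patients contribute their observed rows (no imputation or
listwise deletion). Binary longitudinal outcomes use logistic models; the
random intercept is omitted by default because all patients enter in the
same state (a current depressive episode), mirroring the published model
choice.

For the cost-effectiveness framework, time is dropped: cumulative cost and
the effect are regressed on group (with the relevant baseline), giving one
incremental cost ΔC and one incremental effect ΔE across all follow-ups.
Binary effects use a **linear risk-difference mixed model** — that is the
estimand the ICER needs — with a logistic alternative exposed for
completeness (a different estimand, never used for ICERs).

Engineering choices: the optimizer runs with derivative checks off for
speed; a failed fit is retried with bobyqa; if the random-intercept model
is degenerate (zero residual variance on noise-free synthetic data, or a
non-positive-definite covariance), the fit falls back to a fixed-effects
model and says so in `fit_meta$fallback_lm`. Non-convergence is flagged,
never silent. Wald 95% intervals use ±1.96·SE.

## Monte Carlo uncertainty

The published analysis ran "5000 probabilistic Monte Carlo simulations,
running all mixed models simultaneously", which does not pin down the
mechanism. The default here is a **patient-level cluster bootstrap**:
resample patients with replacement within arm and refit both CEA models on
each replicate. This preserves the within-patient correlation between
costs and effects, which a per-coefficient normal draw destroys; the
parametric alternative (`method = "parametric"`) is provided and labeled
as ignoring that correlation. Replicates whose fits fail outright are
redrawn up to 10 times and then dropped with a count; more than 1% drops
aborts the run.

ICERs are reported with their quadrant (a bare ratio is sign-ambiguous);
ΔE = 0 yields an undefined ICER rather than an infinity. Plane quadrant
conventions are fixed and documented: ΔE > 0 is east, ΔC > 0 is north,
with ties going west/south — measure-zero events for continuous draws.
The CEAC is the fraction of draws with strictly positive net monetary
benefit λ·ΔE − ΔC (ties count against cost-effectiveness, the
conservative choice). Percentile intervals over the draws are the default
uncertainty intervals; Wald intervals are also emitted, since the original
report does not say which was used.

## The synthetic world

The generator's defaults state one fixed world; they were chosen from the
published summary tables and are not tuned afterwards:

* arms of 53 and 49 patients; assessments at weeks 0/10/20/30;
* baseline severity 45.2 (SD 12.1) vs 41.5 (SD 11.6) — the baseline
  imbalance is part of the world;
* follow-up scores = baseline + cumulative time effect (defaults −11.4,
  −14.4, −17.6, the observed full-sample declines) + arm effect (default
  +2, the reported adjusted group coefficient) + patient-level deviation
  (SD 6) + visit noise (SD 9), clamped to [0, 84] then rounded;
* utilities = 1.06 − 0.015·score + noise (SD 0.25), clamped to the
  national-tariff range [−0.33, 1]. No severity–utility link is published;
  a negative link is required for realistic joint behavior, and these
  values reproduce the published arm means (≈0.36/0.46) and SDs (≈0.3);
* window costs per category are gamma draws (means ≈ €450/€250/€710,
  matching the baseline cost table's standard-arm order of magnitude) plus
  a Bernoulli inpatient event (p = 0.02, €5000) for the "rare and costly
  events" skew, converted to resource-use counts through the default
  price table so costing reproduces the configured euro amounts;
* session counts from truncated normals matching the published adherence
  means (blended ≈ 10 face-to-face + 9.6 online + 8.4 feedback; standard
  ≈ 13.3 face-to-face);
* per-visit missingness is logistic in age (centered at 40) and
  employment, defaults qlogis(0.30) intercept, −0.04/year, −0.7 for
  employment — younger and unemployed patients drop out more, at roughly
  the observed rates. Dropout is non-monotone by default (patients may
  return, as in the observed per-wave counts); a monotone mode exists.

The between-assessment correlation of scores and costs is not published;
the score random-intercept SD (6) is a stated guess, and window costs are
independent across windows within patient. A green test therefore
establishes internal correctness of the pipeline on a plausible world —
not reproduction of the real trial's tables, which would require the
undeposited patient-level data.

## CEAC stability (sample-size simulation)

`ceac_stability()` follows the population-parameter design of the original
power analysis: for each per-arm n between 10 and 500 (the default grid
includes the design point n = 75), trials are simulated from fixed per-arm
cost (gamma) and effect (Bernoulli) distributions, each trial's CEAC is
computed from the normal approximation of (ΔC, ΔE), and the across-trial
SD of the acceptability probability is reported per ceiling. This is a
deliberate simplification — the original procedure simulated from
population-level estimates, not from a full patient-level generator — and
keeps the n-sweep fast enough to run in tests. Default population values
(costs ≈ €12,400/€8,500 with large SDs, response 0.65/0.60) are of the
order of the published 30-week cumulative costs and response rates.

## Pipeline determinism and limitations

All randomness in `run_pipeline()` flows from one root seed via fixed
per-stage offsets, so identical config + seed gives byte-identical CSVs.
Stage caching keyed on content hashes was considered and dropped: no
hashing facility for in-memory objects is available in the dependency
budget, and recomputation is cheap at this scale.

Known limitations: no multiple imputation or random slopes; no value-of-
information or budget-impact analysis; no discounting (the horizon is
under a year); the default unit-cost table is illustrative, not the
national manual; and the generator does not emulate item-level
questionnaire responses, tariff scoring, or serial correlation in costs.
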