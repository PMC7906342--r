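---
title: "Methods: microsimulation cost-effectiveness of reflex-test prostate cancer screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microsimulation cost-effectiveness of reflex-test prostate cancer screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prostacea)
```

## The problem

PSA screening for prostate cancer reduces disease-specific mortality but
generates many unnecessary biopsies, overdiagnoses and costs, because an
elevated PSA is a poor discriminator between benign prostates, indolent
Gleason 6 cancers and the Gleason ≥ 7 cancers that drive mortality.
Multi-marker *reflex* tests such as the Stockholm3 model (S3M) are applied
only when an initial PSA exceeds a low reflex threshold α (1, 1.5 or
2 ng/mL) and aim to keep the sensitivity of the PSA ≥ 3 ng/mL rule for
Gleason ≥ 7 cancers while referring fewer benign and Gleason 6 prostates to
biopsy.

`prostacea` implements a lifetime societal cost-effectiveness analysis of
five strategies — no screening, quadrennial PSA screening at ages 55–69, and
quadrennial screening with a reflex test at α ∈ {1, 1.5, 2} — over a
stochastic natural-history microsimulation. The registry-calibrated
parameters behind the published analysis of this design are not public, so
the package ships a *synthetic* scenario bundle (`default_scenario()`): the
publicly printed quantities (unit costs, thresholds, reflex-test
characteristics, discounting) are pinned verbatim, everything else is a
documented stand-in flagged in `metadata$synthetic`. Absolute event rates
and ICERs from the synthetic bundle are therefore illustrative; the
reproducible surface is the arithmetic, the mechanisms, and the qualitative
orderings.

## Natural-history model

Men enter disease-free at age 35. A man's latent history is generated by
competing-risks composition of:

* **Onset** with a piecewise-constant, age-increasing hazard; at onset a
  Gleason grade (6 / 7 / 8+) is drawn once and never changes.
* **Extent progression** localised → advanced T-stage → metastatic, with
  per-grade exponential hazards, giving the 3 × 3 grid of nine possible
  diagnosis states.
* **Clinical diagnosis** with a hazard depending on the current
  (grade × extent) state.
* **Other-cause death** from a life table converted to piecewise-constant
  hazards (continuous event times, no discretisation artefacts). The
  shipped default is a Gompertz table (`gen_lifetable()`).
* **Prostate-cancer survival**: an exponential time drawn per
  (grade × extent *at detection*), but *anchored at the — possibly
  counterfactual — clinical diagnosis age*. A screen-detected man keeps the
  same survival quantile but is re-indexed to the (weakly better) state at
  detection, so earlier detection helps only through stage shift and
  lead-time bias is removed by construction.

The latent clinical diagnosis age is retained even when it falls after
other-cause death: it is exactly what defines overdiagnosis (screen
detection in a man whose clinical diagnosis would never have happened in
his lifetime) and what anchors post-detection survival.

**PSA growth.** log PSA is linear with person-level random effects:
`b0 + b1 (age − 35) + b2 max(0, age − onset)` plus fresh Gaussian
measurement noise per determination. The published model this emulates
extends an American (FHCRC-style) growth model but prints no formula, so
the log-linear form with a post-onset slope change is this package's design
choice. The default effects were set once to match population screening
epidemiology — roughly 15–25 % of men aged 55–70 above 3 ng/mL, intra-
individual coefficient of variation about 25 % — which also reproduces the
reference analysis's qualitative biopsy-reduction magnitudes. They are
configuration values, not estimates.

## Reflex-test characteristics

For state *D* ∈ {benign, GS 6, GS ≥ 7} and reflex threshold α, the
*relative positive fraction*

r(α|D) = Pr(reflex+ | D, α ≤ PSA < 10) / Pr(3 ≤ PSA < 10 | D, α ≤ PSA < 10)

generalises relative true/false-positive fractions to three states; 1 − r
is the relative change in biopsies for that state. `estimate_rpf()`
computes the windowed count ratio from paired trial-like data
(`gen_trial_dataset()` generates such data with controllable targets), with
a bootstrap CI over men.

Inside the simulator the reflex test is realised as a per-state PSA
threshold τ(α|D) chosen so that
Pr(PSA ≥ τ | D, window) = r(α|D) · Pr(3 ≤ PSA < 10 | D, window)
(`calibrate_tau()` on the cohort's own screen-age PSA distribution,
`build_reference_sample()`). Positivity is then a deterministic threshold
on the modelled PSA — men below τ are reflex-negative. Conventions:
ties break by "≥" everywhere; with an empirical sample τ is the smallest
sample value achieving the target count (rounded to the nearest attainable
count); r = 1 gives τ = 3 exactly, making the reflex pathway identical to
the PSA pathway; a survival function input is solved by bisection to 1e-6.
τ is monotone non-increasing in r, which makes lifetime biopsies ordered
S3M(2) ≤ S3M(1.5) ≤ S3M(1) ≤ PSA under common random numbers.

## Screening pathways

Screens happen at 55, 59, 63, 67 (start 55, every 4 years while ≤ 69 — the
ERSPC-style reading of "quadrennial 55–69"). PSA arm: biopsy referral at
PSA ≥ 3. Reflex arm: direct referral at PSA ≥ 10; reflex evaluation for
α ≤ PSA < 10 with positivity PSA ≥ τ(α|state). Referred men are biopsied
with probability `biopsy_compliance` (0.9 in the synthetic bundle; 1.0 in
idealised test configurations); a biopsy reveals the latent state
(sensitivity 1 by default and configurable — detection differences are
already encoded in the test characteristics). Men test-positive but
biopsy-negative at their final scheduled screen receive one follow-up
retest two years later (the published design states post-70 follow-up for
exactly this group without a schedule; one retest at 71 is this package's
choice, configurable via `post70_followup`). Symptomatic diagnoses incur
on average two diagnostic biopsies. Treatment (active surveillance /
prostatectomy / radiation) is assigned from a configurable grade-specific
table for non-metastatic diagnoses; metastatic disease moves directly to
advanced-disease management.

All per-man randomness (event quantiles, screen-age measurement noise,
compliance, treatment assignment) is drawn with the cohort, man-major under
a single seed. Consequences: strategies compared on one cohort share random
numbers (paired comparisons, and the r ≡ 1 equivalence is exact, not
statistical), and the first *m* men of any cohort are identical for every
cohort size n ≥ m.

## Economics

**QALYs** (`accumulate_qalys()`): the life course from 35 to death is
partitioned into intervals; each contributes
∫ norm(age) · multiplier · (1 + rate)^−(age − 35) by yearly-resolution
quadrature. Overlapping states take the *minimum* multiplier (a common
convention; the source is silent). Transient states (screening episode,
biopsy episode, diagnosis phase, treatment, post-treatment) carry
durations; advanced disease runs to death and the terminal state covers
the last six months before prostate-cancer death. The shipped utility
values are synthetic stand-ins in the style of published screening models
(the exact table behind the reference analysis is not public).

**Costs** (`accumulate_costs()`): each event contributes its unit cost,
tagged screening / diagnosis / treatment / advanced disease, discounted at
the event age; phase costs (advanced disease, terminal care) are lump sums
at phase entry. Printed values are stored verbatim: PSA test €58 (its
printed components 30 + 4 + 26 are internally inconsistent with the total
and are kept as metadata only), reflex visit €255 with €196 assay, biopsy
episode €560, advanced-disease treatment €41,683, €0.0851/SEK. Productivity
losses follow the human-capital approach — hours lost × age-specific salary
— capped at a configurable retirement age (65; the approach is known to
discriminate against older ages, hence the cap and its off switch).
Discounting is annual compounding (1 + r)^−t at 3 %/year from the
configurable reference age 35 (model entry; the source states the rate but
not the reference).

## Comparative statistics

`summarize_strategy()` scales events to a 10,000-man cohort and averages
costs per man (undiscounted and discounted). `compare_strategies()` gives
field-wise differences and percent changes plus ICERs per perspective
(direct = health sector, societal) with quadrant-aware labels
(`icer()`): dominant, dominated, undefined at ΔQALY = 0, and an explicit
south-west flag because a bare ratio is ambiguous there.
`frontier()` removes dominated then extended-dominated strategies until the
incremental ICER sequence is non-decreasing (ties in both coordinates keep
the first name alphabetically); it is tested against a brute-force
net-benefit oracle. `nbhw_category()` applies the Swedish bands
(low < €8,300 ≤ moderate < €41,600 ≤ high < €83,300 ≤ very high,
lower-inclusive).

## Sensitivity analyses

One-way axes (`oneway_sensitivity()`) perturb a single input — reflex-test
unit cost, discount rate 0–5 %, reflex performance at its CI bounds,
utility decrements ±20 %, biopsy cost €330–880, all costs ±20 % — under
common random numbers; axes touching only prices or utilities re-price the
same simulated runs, the reflex-performance axis recalibrates τ and re-runs
the pathway on the same cohort. Values outside the documented ranges warn
and proceed.

The probabilistic analysis (`uncertainty_spec()`, `sample_uncertainty()`,
`run_probabilistic()`) draws natural-history rates as independent
truncated normals around base values (the calibrated posterior covariance
is unpublished, so the bundle ships a diagonal stand-in), reflex r-values
as normals with sd (CI width)/3.92 truncated at 0, the biopsy episode cost
as a log-normal with 2.5/97.5 quantiles at 330/880 (sdlog ≈ 0.2502, median
≈ €538.9, implied mean ≈ €556, consistent with the stated €560), and other
costs and utility decrements as ±20 % triangular multipliers. Infeasible
draws are resampled and counted. One cohort random-number stream is reused
across draws so parameter uncertainty, not Monte-Carlo noise, dominates at
a few hundred draws. `ceac()` reports, per willingness-to-pay λ, the
fraction of draws in which a strategy has strictly higher net monetary
benefit λ·ΔQALY − ΔCost than the reference (pairwise versus PSA screening
by default; the multi-way "probability best" variant is a deliberate
non-feature of the default output).

## What the synthetic generator does and does not emulate

`gen_trial_dataset()` reproduces the *estimand structure* of a paired
screen-positive trial: per-state right-skewed PSA, and reflex positivity
placed so the windowed ratio equals the target r (all records at PSA ≥ 3
positive when r = 1, excess positivity below 3 for r > 1, impossible
targets rejected). It does not model the underlying biomarkers, SNPs or
the 10 % risk cut-off, correlation between repeat visits, or verification
bias. `default_scenario()` similarly emulates magnitudes and mechanisms,
not the Stockholm registries: passing tests demonstrate correct arithmetic
and mechanism, not that the shipped rates describe any real population.

## Numerical choices and problem sizes

Event times are continuous; piecewise-constant hazards are inverted
analytically, and the verification oracle (`expected_counts_oracle()`)
integrates the competing-risks equations with exact within-step
exponential transitions (stable for near-instantaneous rates) on a 0.01–
0.02-year grid. QALY quadrature is yearly with exact fractional end-years.
The test suite exercises cohorts of 10⁵ men for oracle agreement and
ordering checks, 2 × 10⁵ trial records for estimand recovery, and smaller
cohorts (10³–2 × 10⁴) for properties; the analysis scripts use 5 × 10⁴ men
for the main run and 60 draws × 5 × 10³ men for the probabilistic step.
These sizes give Monte-Carlo errors well inside the tolerances asserted.

## Known limitations

* Absolute rates, QALY totals and ICERs from the synthetic bundle are not
  calibrated to any registry and should not be quoted as estimates.
* Grade is fixed at onset (no Gleason progression), biopsy sensitivity
  defaults to perfect, and urologist discretion (ultrasound, DRE, volume)
  is absorbed into a single compliance probability.
* No MRI pathways, no budget-impact analysis, no friction-cost alternative
  to the human-capital approach, and no value-of-information analysis.
* Prostate-cancer survival is exponential per (grade × extent) state;
  richer parametric families would need only a new quantile function but
  are not shipped.
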