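# prostacea

Microsimulation cost-effectiveness analysis of prostate-cancer screening
with a reflex biomarker test, in R.

## The problem

PSA screening reduces prostate-cancer mortality but produces large numbers
of unnecessary biopsies, overdiagnosed indolent cancers and costs. Reflex
tests in the Stockholm3 (S3M) style are applied only when an initial PSA
exceeds a low threshold α (1, 1.5 or 2 ng/mL) and aim to keep the
sensitivity of the classic PSA ≥ 3 ng/mL biopsy-referral rule for
Gleason ≥ 7 cancers while referring fewer benign prostates and Gleason 6
cancers. Whether the extra test cost buys enough avoided harm is a
cost-effectiveness question over a man's remaining lifetime, which this
package answers by microsimulation for five strategies: no screening,
quadrennial PSA screening at ages 55–69, and quadrennial screening with a
reflex test at each α.

It is written for health-economic and screening-methods researchers who
want a tested, fully synthetic, reproducible re-implementation of this
analysis pipeline: the registry-calibrated natural-history parameters
behind the published analysis of this design are not public, so the
shipped scenario pins every publicly printed value verbatim (unit costs,
thresholds, test characteristics, discounting) and documents synthetic
stand-ins for the rest.

## The model in brief

* **Natural history** — from age 35: onset with age-increasing hazard and
  a fixed Gleason grade; progression localised → advanced T-stage →
  metastatic; clinical diagnosis with state-dependent hazard; other-cause
  death from a life table; prostate-cancer survival drawn per
  (grade × extent at detection) but anchored at the possibly
  counterfactual clinical-diagnosis age, so screen detection helps only
  through stage shift (no lead-time bias). Log-PSA grows linearly with a
  post-onset slope change and person-level random effects.
* **Reflex-test characteristics** — the relative positive fraction
  r(α|D) = Pr(reflex+ | D, α ≤ PSA < 10) / Pr(3 ≤ PSA < 10 | D, α ≤ PSA < 10)
  per state D ∈ {benign, GS 6, GS ≥ 7} (1 − r is the relative change in
  biopsies). Inside the simulator the reflex test is a per-state PSA
  threshold τ(α|D) solving
  Pr(PSA ≥ τ | D, window) = r(α|D) · Pr(3 ≤ PSA < 10 | D, window).
* **Economics** — QALYs as age-specific population norms times state
  multipliers integrated over the life course; event-based costs
  (screening, diagnostic work-up, treatment, advanced disease) plus
  human-capital productivity losses; 3 %/year discounting.
* **Comparative statistics** — per-10,000-men summaries, differences and
  percent changes, ICERs (ΔCost/ΔQALY) with dominance markers, the
  efficiency frontier with extended dominance, Swedish NBHW cost-per-QALY
  bands, one-way sensitivity analyses and probabilistic sensitivity
  analysis with cost-effectiveness acceptability curves.

See `vignettes/screening-cea-methods.Rmd` for the full account.

## Worked example

```r
library(prostacea)
sc  <- default_scenario(seed = 1)
res <- run_all_strategies(sc, n = 50000)
```

With the shipped synthetic scenario this prints (per 10,000 men;
`analysis/03_strategies.R` output):

```
 strategy screening_tests biopsies diagnosed overdiagnosed pc_deaths
     none               0     4148      2074             0       762
      psa           38016    13136      2284           210       669
    s3m_1           37227     9195      2266           192       675
  s3m_1.5           37157     8846      2263           189       678
    s3m_2           37108     8498      2257           183       680

Efficiency frontier (discounted societal):
 strategy cost  qaly              label icer_frontier
     none 1958 21.71          efficient            NA
    s3m_2 2639 21.72          efficient        124053
      psa 2655 21.72          dominated            NA
  s3m_1.5 2712 21.72 extended_dominated            NA
    s3m_1 2791 21.72          efficient        603203
```

Reading: PSA screening increases diagnoses (+210 per 10,000, all of the
excess overdiagnosed) and cuts prostate-cancer deaths (−93 per 10,000);
the reflex strategies avoid roughly a third of lifetime biopsies
(13,136 → 8,498 at α = 2) at higher screening cost; on the discounted
societal plane the 2 ng/mL reflex strategy sits on the efficiency frontier
and PSA-alone is dominated — the qualitative pattern of the published
analysis this emulates. Absolute numbers are synthetic-scenario outputs,
not estimates for any real population.

The numbered scripts under `analysis/` run the full workflow: scenario
bundle (`01`), trial generation, relative-positive-fraction estimation and
τ calibration (`02`), the main five-strategy run (`03`), and one-way plus
probabilistic sensitivity analyses (`04`), writing tables under
`results/`.

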