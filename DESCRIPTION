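Package: prostacea
Title: Microsimulation Cost-Effectiveness Analysis of Prostate Cancer
    Screening with a Reflex Biomarker Test
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates individual prostate-cancer natural histories
    (onset, Gleason grade, stage progression, clinical diagnosis,
    disease-specific and other-cause death, and longitudinal PSA
    growth) and evaluates screening strategies built on the PSA test
    and on a reflex biomarker test characterised by relative positive
    fractions, in the style of the Stockholm3 reflex design.  Provides
    quality-adjusted survival and societal cost accounting with
    discounting, incremental cost-effectiveness ratios, efficiency
    frontiers with extended dominance, one-way sensitivity analyses
    and probabilistic sensitivity analysis with cost-effectiveness
    acceptability curves.  Registry-calibrated natural-history
    parameters are not public, so the package ships a documented
    synthetic scenario bundle and a paired-design trial-data generator
    with controllable relative positive fractions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
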