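Package: lipedex
Title: DXA Body-Composition Indices and Diagnostic Thresholds for Lipedema
Version: 1.0.0
Authors@R:
    person("Lipedex", "Developers", email = "lipedex@example.org",
           role = c("aut", "cre"))
Description: Tools for the diagnostic work-up of lipedema from dual-energy
    X-ray absorptiometry (DXA) regional body composition. Computes the
    27-index panel of regional fat- and lean-mass distribution indices
    (FM/FMI, FM/total FM, LM/LMI, LM/total LM for six regions, trunk/legs
    and android/gynoid ratios, ALMI), performs age- and BMI-tolerance
    case-control matching, runs the normality-routed comparison battery
    with Bonferroni control, derives diagnostic thresholds by ROC analysis
    with Youden-index optimal cutoffs and DeLong confidence intervals, and
    encodes the clinical-plus-DXA diagnostic decision rule. Includes a
    calibrated synthetic cohort generator so the full pipeline can be
    exercised without patient-level data, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
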