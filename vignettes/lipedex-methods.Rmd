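---
title: "Methods: DXA fat-distribution indices for lipedema diagnosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DXA fat-distribution indices for lipedema diagnosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipedex)
```

## The model and its assumptions

Lipedema redistributes fat toward the legs while largely sparing the
trunk, lean tissue and bone. The package operationalizes this as a panel
of 27 regional distribution indices computed from a DXA body-composition
record: for each of six regions (legs, arms, legs+arms, trunk, android,
gynoid), regional fat mass divided by the fat mass index
(FMI = total FM/height², so the entry equals the regional share times
height²) and divided by total FM; the trunk/legs FM ratio; the
android/gynoid ratio of regional percent fat; the twelve analogous
lean-mass indices; and ALMI = (leg LM + arm LM)/height². The count of 27
is load-bearing: it is the denominator of the Bonferroni threshold
(0.05/27 ≈ 0.00185), so the panel membership is frozen in
`panel_index_info()` and asserted by tests.

The diagnostic claim being evaluated is deliberately asymmetric: the leg
FM/total FM index is a *rule-out* tool. The decision rule
(`apply_diagnostic_algorithm()`) confirms the diagnosis only from fully
met clinical criteria; when the clinical picture is doubtful, an index
below the cutoff (default 0.383) makes lipedema unlikely, and an index at
or above it sends the patient to multidisciplinary review. DXA never
overrides met criteria and never rules the disease *in*.

Assumptions inherited by every downstream result:

* regional masses arrive pre-partitioned by the scanner; the android and
  gynoid region geometry is metadata, not re-derived (the gynoid region
  intentionally overlaps legs and trunk, so regional masses are not
  additive across android/gynoid);
* adult women only (age ≥ 18, BMI ≥ 18 kg/m²); BMI below the study range
  is an error, not a bin;
* two-group tests are routed by a Shapiro-Wilk normality gate at
  α = 0.05 per group — parametric only when *both* groups pass.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| matching ratio | 2 | controls/case | reference design (74:148) |
| age tolerance | 3 | years | the "±3" caliper, inclusive |
| BMI tolerance | 3 | kg/m² | idem |
| Bonferroni α | 0.05 | — | family-wise level over 27 tests |
| normality α | 0.05 | — | Shapiro-Wilk routing gate |
| min group size | 5 | subjects | type/stage strata with fewer are excluded (the reference analysis dropped groups of 3 and 2, kept 11 and 14) |
| rule-out cutoff | 0.383 | fraction | the reported leg-share cutoff; the 0.384 variant printed elsewhere in the same source is selectable and always recorded in output metadata |
| DeLong CI level | 0.95 | — | conventional |

## What the synthetic generator emulates — and what it does not

No public patient-level dataset exists (data are available on request
only), so the generator is a first-class, tested module that emulates the
*statistical structure* the analysis assumes:

* **Per WHO BMI class and group:** age, BMI and FMI are truncated
  Gaussians with the published class means/SDs (BMI truncated to its
  class interval; class III capped at 70 kg/m² as a physical ceiling).
  The case class mix is 13/26/20/5/10 of 74, apportioned by largest
  remainder.
* **Shares, not masses, are calibrated.** Regional fat is reconstructed
  from directly drawn shares of total FM — legs, arms and gynoid from
  group-specific Gaussians (cases 0.451 ± 0.050, 0.106 ± 0.016,
  0.194 ± 0.018; controls 0.354 ± 0.055, 0.107 ± 0.013, 0.177 ± 0.023),
  head fixed at 0.02, trunk as the remainder, android as a drawn fraction
  of trunk fat (cases 0.155 ± 0.03, controls 0.167 ± 0.03, back-solved
  from the printed android and trunk shares per group). Lean mass is
  decomposed analogously. Draws are truncated at ±4 SD (floored at
  physical limits), which distorts the first two moments by far less than
  printed precision; configurations whose share draws push the trunk
  share to zero in more than 1% of attempts are rejected as
  miscalibrated.
* **Heights are not reported** in the source summaries; back-solving the
  absolute index rows (e.g. leg FM/FMI 1.237 = 0.451 × height²) gives a
  mean height of ~1.66 m, used with SD 0.065 m as a realistic value for
  adult European women. Chosen once; not revisited.
* **Lean mass is sampled from its own LMI distribution** (cases
  15.87 ± 2.84, controls 16.44 ± 2.30 kg/m², back-solved from the printed
  ALMI 7.65/7.66 and appendicular LM shares) rather than forced through
  weight = FM + LM + bone. The printed group summaries are not mass-
  consistent under that closure (it would imply a bone compartment about
  twice physiological), and DXA-scanned mass differs from scale weight in
  practice. Scale weight remains BMI × height².
* **Matched recruitment.** The default control pool is generated the way
  the study enrolled controls: for each case, `anchor_ratio` (default 4,
  the full pool multiplier) controls with age/BMI within the matching
  calipers (uniform ±2 offsets). This guarantees the pool spans the case
  age/BMI ranges so the deterministic greedy matcher is feasible; with
  fewer anchors per case, a neighbouring case can steal an age-outlier's
  only eligible controls. Control body-composition parameters are
  untouched by anchoring.
* **Type and stage** are multinomial with the exact count frequencies
  3/11/29/31/0 (types I–V) and 14/39/19/2 (stages 1–4) out of 74; the
  rounded percentages (19/53/26/3) sum to 101% and are not used.

What it does **not** emulate: scanner noise and calibration drift,
operator adjustment of regions of interest, non-Gaussian shapes of the
real index distributions, and any correlation between regional shares
(legs/arms/gynoid draws are independent within a subject). Consequently a
green test establishes that the *pipeline* recovers what the generator
encodes — group separations, AUCs, matching structure — but not the
empirical cutoff of the real cohort: under the Gaussian world the
Youden-optimal leg-share cutoff lands near 0.38–0.40 rather than exactly
0.383/0.384, and the skewed control tail that produced the reported
trunk/legs specificity of 0.93 is absent. These quantities are checked
qualitatively (signs, orderings), never numerically. One consequence of
drawing limb shares independently is that the legs+arms share variance is
slightly larger than printed (0.053 vs 0.047 for cases), so the empirical
legs+arms AUC sits marginally below the closed-form value computed from
the printed SDs.

## Numerical choices

* **ROC thresholds** are the midpoints between consecutive distinct
  pooled score values plus ∓∞ sentinels, so every achievable confusion
  matrix appears exactly once; the curve spans (0,0) and (1,1) in
  (1−specificity, sensitivity) space. Orientation is auto-selected by
  comparing group means so the AUC is ≥ 0.5 and is always recorded
  (trunk/legs runs lower-is-case).
* **AUC** is the trapezoid, provably identical to the normalized
  Mann-Whitney U with ties half-counted; the test suite enforces equality
  to 1e-12 against a brute-force pairwise oracle on 1,000 random
  instances.
* **Youden tie-breaks**: maximal J, then higher sensitivity (rule-out
  use-case), then the lower cutoff on the reported scale. J values that
  differ only by floating-point path (< 1e-12) are treated as tied.
* **Confidence intervals** use the DeLong placement-variance estimator
  with a Wald interval truncated to [0, 1]; the method in the source
  analysis is unnamed, so this choice is isolated in `auc_ci_delong()`
  and swappable. Coverage is verified by simulation (95% ± 3% at study
  size).
* **Mann-Whitney exactness** follows R's `wilcox.test` defaults (exact
  for small tie-free samples, normal approximation with tie correction
  otherwise); the Shapiro-Wilk gate is applied to an evenly spaced
  subsample of 5,000 sorted values when n exceeds the test's limit.
* **Android/gynoid percent fat**: the denominator convention is not
  stated in the source; the default is fat/(fat+lean+bone) — the
  scanner's region-percent-fat dialect, with regional bone taken from
  optional columns and treated as 0 when absent — and fat/(fat+lean) is
  available via `ag_denominator = "tissue"`.
* **Greedy matching** (not optimal bipartite matching): the study
  "group-matched" without stating an algorithm; greedy
  nearest-neighbour without replacement with normalized L1 ranking and
  id tie-breaks is deterministic, transparent, order-invariant, and
  feasible by construction at the default pool. Optimal-cost matching is
  a noted extension, not implemented.
* **Degenerate inputs** fail loudly: all-identical scores, zero leg fat
  (trunk/legs undefined), zero variance in correlations, BMI < 18, cases
  without type/stage — each with the offending record or index named.

## Decisions on genuinely open points

* Individual matching with tolerances is implemented as the stricter
  reading of "group-matched"; the looser frequency-matching reading
  would not pin per-pair calipers.
* Correlation routing (Pearson vs Spearman) follows the normality of the
  index values only — stages are ordinal and would fail any normality
  test, yet the reference analysis used Pearson for some rows.
* Tukey HSD is attached only after a significant ANOVA; no post hoc is
  added after Kruskal-Wallis.
* The 0.383 cutoff is the default (it appears in the decision-algorithm
  context); 0.384 is reachable by argument and surfaced in metadata.

## Known limitations

* The generator's independence assumptions understate real covariance
  between regional shares; empirical SDs of derived sums (legs+arms) are
  therefore approximate.
* The gynoid region's overlap bookkeeping is not mass-conserving — by
  design, mirroring the scanner's region definitions.
* Greedy matching is not guaranteed optimal; it is guaranteed
  deterministic and, at the default generator, feasible.
* Sensitivity/specificity at the empirical cutoff of the real cohort are
  not reproducible from summary statistics alone; only their qualitative
  pattern is testable here.
* Male reference data, pediatric ranges and longitudinal change are out
  of scope.
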