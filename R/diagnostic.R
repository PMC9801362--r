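# Clinical criteria, the type/stage taxonomy, and the DXA-assisted
# diagnostic decision rule. DXA is a rule-out aid only: it never overrides
# fully met clinical criteria, and an index at or above the cutoff sends
# the patient to multidisciplinary review rather than confirming disease.

#' Construct the six clinical diagnostic criteria
#'
#' All six criteria must be explicitly set (`TRUE`/`FALSE`, no defaults, no
#' `NA`): (i) disproportionate, bilateral and symmetric limb fat sparing
#' hands and feet; (ii) no or limited influence of weight loss on fat
#' distribution; (iii) limb pain, tenderness and easy bruising;
#' (iv) increased touch sensitivity or limb fatigue; (v) minimal or no
#' pitting edema; (vi) no relief of discomfort with limb elevation.
#'
#' @param disproportionate_limb_fat,weight_loss_resistant,pain_tenderness_bruising,touch_sensitivity_fatigue,minimal_pitting_edema,no_relief_with_elevation
#'   Logical scalars.
#' @return Object of class `"clinical_criteria"`.
#' @export
clinical_criteria <- function(disproportionate_limb_fat,
                              weight_loss_resistant,
                              pain_tenderness_bruising,
                              touch_sensitivity_fatigue,
                              minimal_pitting_edema,
                              no_relief_with_elevation) {
  vals <- list(
    disproportionate_limb_fat = disproportionate_limb_fat,
    weight_loss_resistant = weight_loss_resistant,
    pain_tenderness_bruising = pain_tenderness_bruising,
    touch_sensitivity_fatigue = touch_sensitivity_fatigue,
    minimal_pitting_edema = minimal_pitting_edema,
    no_relief_with_elevation = no_relief_with_elevation
  )
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.logical(v) || length(v) != 1 || is.na(v)) {
      stop("criterion '", nm, "' must be set to TRUE or FALSE")
    }
  }
  structure(vals, class = "clinical_criteria")
}

#' Are all six clinical criteria met?
#'
#' The clinical diagnosis is retained only when every criterion holds
#' (strict conjunction).
#'
#' @param criteria A [clinical_criteria()] object.
#' @return Logical scalar.
#' @export
criteria_met <- function(criteria) {
  stopifnot(inherits(criteria, "clinical_criteria"))
  all(unlist(criteria))
}

#' Apply the DXA-assisted diagnostic algorithm
#'
#' Decision rule: if all six clinical criteria are met, the diagnosis is
#' `"confirmed"` (DXA concordance is noted but never overrides the
#' clinic). If the clinical picture is doubtful or incomplete, the leg
#' FM/total FM index arbitrates: below the cutoff the disease is
#' `"ruled_out_unlikely"`; at or above the cutoff the verdict is
#' `"indeterminate_review"` (multidisciplinary review) — the index is a
#' rule-out tool, not a rule-in test.
#'
#' The default cutoff is 0.383; the 0.384 variant reported elsewhere in
#' the source study is available via `cutoff` and the choice is recorded
#' in the output metadata.
#'
#' @param criteria A [clinical_criteria()] object.
#' @param leg_share Leg FM / total FM, in (0, 1).
#' @param cutoff Rule-out cutoff (default 0.383).
#' @return Object of class `"lipedema_diagnosis"`: `verdict`, `leg_share`,
#'   `cutoff`, `criteria_met`, `dxa_concordant`, `cutoff_note`.
#' @examples
#' c_all <- clinical_criteria(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE)
#' apply_diagnostic_algorithm(c_all, 0.45)$verdict   # "confirmed"
#' @export
apply_diagnostic_algorithm <- function(criteria, leg_share, cutoff = 0.383) {
  stopifnot(inherits(criteria, "clinical_criteria"))
  if (!is.numeric(leg_share) || length(leg_share) != 1 ||
      is.na(leg_share) || leg_share <= 0 || leg_share >= 1) {
    stop("leg_share must be a single value in (0, 1)")
  }
  met <- criteria_met(criteria)
  verdict <- if (met) {
    "confirmed"
  } else if (leg_share < cutoff) {
    "ruled_out_unlikely"
  } else {
    "indeterminate_review"
  }
  structure(
    list(verdict = verdict,
         leg_share = leg_share,
         cutoff = cutoff,
         criteria_met = met,
         dxa_concordant = leg_share >= cutoff,
         cutoff_note = paste0(
           "cutoff variants 0.383/0.384 coexist in the source material; ",
           "this run used ", format(cutoff))),
    class = "lipedema_diagnosis"
  )
}

#' @export
print.lipedema_diagnosis <- function(x, ...) {
  cat("Lipedema diagnosis: ", x$verdict,
      " (leg FM/total FM = ", format(x$leg_share),
      ", cutoff = ", format(x$cutoff),
      ", clinical criteria ", if (x$criteria_met) "met" else "not met",
      ")\n", sep = "")
  invisible(x)
}

#' Classify lipedema type from the fat-distribution pattern
#'
#' Arm involvement defines type IV regardless of the lower-limb pattern;
#' otherwise: fat around hips and buttocks is type I, hips to knees type
#' II, hips to ankle with the typical "cuff sign" type III, and calf-only
#' fat type V.
#'
#' @param distribution One of `"hips_buttocks"`, `"hips_knees"`,
#'   `"hips_ankle_cuff"`, `"calf_only"`.
#' @param arm_involvement Logical.
#' @return `"I"` to `"V"`.
#' @export
classify_type <- function(distribution = c("hips_buttocks", "hips_knees",
                                           "hips_ankle_cuff", "calf_only"),
                          arm_involvement = FALSE) {
  distribution <- match.arg(distribution)
  if (!is.logical(arm_involvement) || length(arm_involvement) != 1 ||
      is.na(arm_involvement)) {
    stop("arm_involvement must be TRUE or FALSE")
  }
  if (arm_involvement) return("IV")
  switch(distribution,
         hips_buttocks = "I",
         hips_knees = "II",
         hips_ankle_cuff = "III",
         calf_only = "V")
}

#' Classify lipedema stage from skin morphology and lymphedema
#'
#' Concomitant lymphedema defines stage 4 regardless of skin morphology;
#' otherwise: smooth skin over a thickened hypodermis is stage 1, skin
#' indented over palpable pearl-sized nodules ("orange peel") stage 2, and
#' folds and divots over larger deforming fat masses stage 3.
#'
#' @param skin One of `"smooth_thickened"`, `"orange_peel_nodules"`,
#'   `"folds_divots"`.
#' @param lymphedema Logical.
#' @return Integer stage 1-4.
#' @export
classify_stage <- function(skin = c("smooth_thickened", "orange_peel_nodules",
                                    "folds_divots"),
                           lymphedema = FALSE) {
  skin <- match.arg(skin)
  if (!is.logical(lymphedema) || length(lymphedema) != 1 || is.na(lymphedema)) {
    stop("lymphedema must be TRUE or FALSE")
  }
  if (lymphedema) return(4L)
  switch(skin,
         smooth_thickened = 1L,
         orange_peel_nodules = 2L,
         folds_divots = 3L)
}
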