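# The 27-index panel of regional fat/lean mass distribution indices, plus
# BMI/FMI/LMI/ALMI/BMD helpers. Masses are kept in kg internally; BMD
# converts kg -> g at the boundary.

.regions6 <- c("legs", "arms", "legs_arms", "trunk", "android", "gynoid")

#' Names and categories of the 27-index panel
#'
#' The panel comprises, for six regions (legs, arms, legs+arms, trunk,
#' android, gynoid): regional FM divided by FMI (kg/\[kg/m\eqn{^2}\]) and by
#' total FM (fraction); the trunk/legs and android/gynoid fat ratios; the
#' analogous six LM/LMI and six LM/total LM indices; and ALMI
#' (kg/m\eqn{^2}). Exactly 27 entries — the multiple-testing denominator
#' for the Bonferroni threshold. BMI, FMI, LMI and total-body BMD are
#' carried alongside the panel but are not panel members.
#'
#' @return `panel_index_names()`: character vector of the 27 panel column
#'   names. `panel_index_info()`: data frame with columns `name` and
#'   `category` (`"fm"`, `"lm"` or `"almi"`).
#' @export
panel_index_names <- function() panel_index_info()$name

#' @rdname panel_index_names
#' @export
panel_index_info <- function() {
  data.frame(
    name = c(paste0("fm_fmi_", .regions6), paste0("fm_share_", .regions6),
             "trunk_legs_fm_ratio", "android_gynoid_fm_ratio",
             paste0("lm_lmi_", .regions6), paste0("lm_share_", .regions6),
             "almi"),
    category = c(rep("fm", 14), rep("lm", 12), "almi"),
    stringsAsFactors = FALSE
  )
}

#' Body mass index
#'
#' Weight divided by height squared.
#'
#' @param weight_kg Body weight in kg (> 0).
#' @param height_m Height in m (> 0).
#' @return BMI in kg/m\eqn{^2}.
#' @examples
#' compute_bmi(81, 1.80)  # 25
#' @export
compute_bmi <- function(weight_kg, height_m) {
  if (any(weight_kg <= 0)) stop("weight must be > 0")
  if (any(height_m <= 0)) stop("height must be > 0")
  weight_kg / height_m^2
}

#' Classify BMI into WHO classes
#'
#' Half-open intervals over the adult study range: \[18, 25) normal weight,
#' \[25, 30) overweight, \[30, 35) obesity class I, \[35, 40) class II,
#' \[40, Inf) class III. BMI below 18 is outside the study range and raises
#' an error rather than being silently binned.
#'
#' @param bmi BMI values in kg/m\eqn{^2} (>= 18).
#' @return Character vector of [who_bmi_classes()] labels.
#' @examples
#' classify_bmi(c(22.4, 24.95, 30))
#' @export
classify_bmi <- function(bmi) {
  if (any(is.na(bmi))) stop("BMI must not be NA")
  if (any(bmi < 18)) {
    stop("BMI out of study range (< 18 kg/m2): ",
         paste(signif(bmi[bmi < 18], 4), collapse = ", "))
  }
  who_bmi_classes()[findInterval(bmi, .who_breaks)]
}

#' Fat and lean mass indices
#'
#' FMI = total fat mass / height\eqn{^2}; LMI = total lean mass /
#' height\eqn{^2}.
#'
#' @param records Participant data frame (see [read_participants()]).
#' @return Numeric vector, kg/m\eqn{^2}.
#' @export
compute_fmi <- function(records) {
  validate_participants(records)
  records$fm_total / records$height_m^2
}

#' @rdname compute_fmi
#' @export
compute_lmi <- function(records) {
  validate_participants(records)
  records$lm_total / records$height_m^2
}

#' Appendicular lean mass index
#'
#' (leg LM + arm LM) / height\eqn{^2}; a sarcopenia surrogate and the 27th
#' panel entry.
#'
#' @param leg_lm,arm_lm Lean masses in kg (>= 0).
#' @param height_m Height in m (> 0).
#' @return ALMI in kg/m\eqn{^2}.
#' @examples
#' compute_almi(14, 4, 1.60)  # 7.03125
#' @export
compute_almi <- function(leg_lm, arm_lm, height_m) {
  if (any(leg_lm < 0) || any(arm_lm < 0)) stop("lean masses must be >= 0")
  if (any(height_m <= 0)) stop("height must be > 0")
  (leg_lm + arm_lm) / height_m^2
}

#' Total-body bone mineral density
#'
#' Bone mineral content (total body excluding head, kg) converted to grams
#' and divided by the projected bone area (cm\eqn{^2}).
#'
#' @param bone_mass_kg Bone mineral content in kg (>= 0).
#' @param bone_area_cm2 Projected bone area in cm\eqn{^2} (> 0).
#' @return BMD in g/cm\eqn{^2}.
#' @examples
#' compute_total_bmd(2.4, 2000)  # 1.2
#' @export
compute_total_bmd <- function(bone_mass_kg, bone_area_cm2) {
  if (any(bone_mass_kg < 0)) stop("bone mass must be >= 0")
  if (any(bone_area_cm2 <= 0)) stop("bone area must be > 0")
  bone_mass_kg * 1000 / bone_area_cm2
}

#' Validate a participant table
#'
#' Enforces the record invariants: required columns present; height, weight,
#' total FM and total LM strictly positive; age >= 18; every regional mass
#' >= 0 and no larger than its body total; type/stage present if and only if
#' the participant is a case. Errors name the offending row ids.
#'
#' @param records Participant data frame.
#' @param require_bone Also require the bone columns (default `TRUE`).
#' @return `records`, invisibly, if valid.
#' @export
validate_participants <- function(records, require_bone = TRUE) {
  need <- setdiff(.participant_columns, c("bm_android", "bm_gynoid"))
  if (!require_bone) need <- setdiff(need, c("bone_mass_total", "bone_area_cm2"))
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("participant table is missing columns: ", paste(miss, collapse = ", "))
  }
  if (nrow(records) == 0) stop("participant table is empty")
  bad_row <- function(cond, what) {
    if (any(cond, na.rm = TRUE) || anyNA(cond)) {
      ids <- records$id[which(cond | is.na(cond))]
      stop("invalid participant record(s) [", what, "]: ",
           paste(head(ids, 5), collapse = ", "))
    }
  }
  bad_row(!records$group %in% c("case", "control"), "group")
  bad_row(records$height_m <= 0, "height_m <= 0")
  bad_row(records$weight_kg <= 0, "weight_kg <= 0")
  bad_row(records$age < 18, "age < 18")
  bad_row(records$fm_total <= 0, "fm_total <= 0")
  bad_row(records$lm_total <= 0, "lm_total <= 0")
  for (p in c("fm", "lm")) {
    tot <- records[[paste0(p, "_total")]]
    for (r in c("legs", "arms", "trunk", "android", "gynoid", "head")) {
      v <- records[[paste0(p, "_", r)]]
      bad_row(v < 0, paste0(p, "_", r, " < 0"))
      bad_row(v > tot * (1 + 1e-9), paste0(p, "_", r, " > ", p, "_total"))
    }
  }
  if (require_bone) {
    bad_row(records$bone_mass_total < 0, "bone_mass_total < 0")
    bad_row(records$bone_area_cm2 <= 0, "bone_area_cm2 <= 0")
  }
  is_case <- records$group == "case"
  bad_row(is_case & (is.na(records$type) | is.na(records$stage)),
          "case without type/stage")
  bad_row(!is_case & (!is.na(records$type) | !is.na(records$stage)),
          "control with type/stage")
  invisible(records)
}

#' Compute the 27-index panel for each participant
#'
#' For each record: regional FM/total FM shares and FM/FMI values (the
#' latter equal share times height squared, by definition of FMI), the
#' trunk/legs FM ratio, the android/gynoid ratio of regional fat
#' percentages, the analogous lean-mass indices, and ALMI. BMI, FMI, LMI
#' and total-body BMD are appended as non-panel extras, together with id,
#' group, WHO BMI class, and (for cases) type and stage.
#'
#' The android/gynoid "fat percentage" denominator is configurable:
#' `"tissue_bone"` (default) uses fat/(fat + lean + bone), the scanner's
#' region-percent-fat convention, taking regional bone from the optional
#' `bm_android`/`bm_gynoid` columns (treated as 0 when absent);
#' `"tissue"` uses fat/(fat + lean).
#'
#' @param records Participant data frame.
#' @param ag_denominator Dialect for the android/gynoid fat percentages.
#' @return Data frame with one row per participant: `id`, `group`,
#'   `bmi_class`, the 27 panel columns of [panel_index_names()], then
#'   `bmi`, `fmi`, `lmi`, `bmd`, `type`, `stage`.
#' @examples
#' coh <- generate_cohort(default_config(), n_cases = 5, seed = 1)
#' panel <- compute_index_panel(coh)
#' panel[1, c("fm_share_legs", "trunk_legs_fm_ratio", "almi")]
#' @export
compute_index_panel <- function(records,
                                ag_denominator = c("tissue_bone", "tissue")) {
  validate_participants(records)
  ag_denominator <- match.arg(ag_denominator)
  h2 <- records$height_m^2
  if (any(records$fm_legs <= 0)) {
    stop("trunk_legs_fm_ratio undefined: leg FM is zero for record(s) ",
         paste(head(records$id[records$fm_legs <= 0], 5), collapse = ", "))
  }
  bm_a <- if ("bm_android" %in% names(records)) records$bm_android else 0
  bm_g <- if ("bm_gynoid" %in% names(records)) records$bm_gynoid else 0
  if (ag_denominator == "tissue") {
    bm_a <- 0
    bm_g <- 0
  }
  pf_android <- records$fm_android /
    (records$fm_android + records$lm_android + bm_a)
  pf_gynoid <- records$fm_gynoid /
    (records$fm_gynoid + records$lm_gynoid + bm_g)
  if (any(pf_gynoid <= 0)) {
    stop("android_gynoid_fm_ratio undefined: gynoid fat percentage is zero ",
         "for record(s) ",
         paste(head(records$id[pf_gynoid <= 0], 5), collapse = ", "))
  }

  out <- data.frame(id = records$id, group = records$group,
                    stringsAsFactors = FALSE)
  out$bmi_class <- classify_bmi(compute_bmi(records$weight_kg,
                                            records$height_m))
  for (p in c("fm", "lm")) {
    share_name <- function(r) paste0(p, "_share_", r)
    abs_name <- function(r) paste0(p, if (p == "fm") "_fmi_" else "_lmi_", r)
    tot <- records[[paste0(p, "_total")]]
    for (r in setdiff(.regions6, "legs_arms")) {
      sh <- records[[paste0(p, "_", r)]] / tot
      out[[share_name(r)]] <- sh
      out[[abs_name(r)]] <- sh * h2
    }
    # combined entry is the exact sum of the per-region entries
    out[[share_name("legs_arms")]] <-
      out[[share_name("legs")]] + out[[share_name("arms")]]
    out[[abs_name("legs_arms")]] <-
      out[[abs_name("legs")]] + out[[abs_name("arms")]]
  }
  out$trunk_legs_fm_ratio <- records$fm_trunk / records$fm_legs
  out$android_gynoid_fm_ratio <- pf_android / pf_gynoid
  out$almi <- compute_almi(records$lm_legs, records$lm_arms, records$height_m)

  out$bmi <- compute_bmi(records$weight_kg, records$height_m)
  out$fmi <- records$fm_total / h2
  out$lmi <- records$lm_total / h2
  out$bmd <- compute_total_bmd(records$bone_mass_total, records$bone_area_cm2)
  out$type <- records$type
  out$stage <- records$stage
  out[, c("id", "group", "bmi_class", panel_index_names(),
          "bmi", "fmi", "lmi", "bmd", "type", "stage")]
}
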