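# 1:k case-control matching under age and BMI tolerances.
#
# Greedy nearest-neighbour without replacement: cases are processed in
# ascending id order; candidate controls are ranked by the normalized L1
# distance |d age|/age_tol + |d BMI|/bmi_tol with ties broken by control id.
# Deterministic and invariant to pool row order.

#' Match controls to cases under age and BMI tolerances
#'
#' Selects `ratio` controls per case such that every matched pair satisfies
#' |age difference| <= `age_tol` and |BMI difference| <= `bmi_tol`
#' (tolerances inclusive, as the study's "+/- 3" phrasing implies). No
#' control is used twice. If some case runs out of eligible controls, the
#' error names that case.
#'
#' @param cases,pool Participant data frames ([read_participants()] schema).
#' @param ratio Controls per case (default 2).
#' @param age_tol Age tolerance in years (default 3).
#' @param bmi_tol BMI tolerance in kg/m\eqn{^2} (default 3).
#' @return An object of class `"matched_cohort"`: list with `cases`,
#'   `controls` (the selected pool rows), `assignment` (named list mapping
#'   case id to its control ids), `ratio`, `age_tol`, `bmi_tol`.
#' @examples
#' coh <- generate_cohort(default_config(), n_cases = 10, seed = 1)
#' m <- match_controls(coh[coh$group == "case", ],
#'                     coh[coh$group == "control", ])
#' nrow(m$controls)  # 20
#' @export
match_controls <- function(cases, pool, ratio = 2, age_tol = 3, bmi_tol = 3) {
  validate_participants(cases)
  validate_participants(pool)
  if (ratio < 1) stop("ratio must be >= 1")
  if (age_tol <= 0 || bmi_tol <= 0) stop("tolerances must be > 0")
  if (!all(cases$group == "case")) stop("'cases' must contain only cases")
  if (!all(pool$group == "control")) stop("'pool' must contain only controls")
  if (nrow(pool) < ratio * nrow(cases)) {
    stop("control pool too small: ", nrow(pool), " controls for ",
         nrow(cases), " cases at ratio ", ratio)
  }
  if (anyDuplicated(pool$id)) stop("duplicate control ids in pool")
  if (anyDuplicated(cases$id)) stop("duplicate case ids")

  cases <- cases[order(cases$id), ]
  pool <- pool[order(pool$id), ]
  case_bmi <- compute_bmi(cases$weight_kg, cases$height_m)
  pool_bmi <- compute_bmi(pool$weight_kg, pool$height_m)
  used <- logical(nrow(pool))
  assignment <- setNames(vector("list", nrow(cases)), cases$id)

  for (i in seq_len(nrow(cases))) {
    d_age <- abs(pool$age - cases$age[i])
    d_bmi <- abs(pool_bmi - case_bmi[i])
    elig <- which(!used & d_age <= age_tol & d_bmi <= bmi_tol)
    if (length(elig) < ratio) {
      stop("matching infeasible for case '", cases$id[i], "': ",
           length(elig), " eligible control(s) remaining, ", ratio,
           " required (age_tol = ", age_tol, ", bmi_tol = ", bmi_tol, ")")
    }
    dist <- d_age[elig] / age_tol + d_bmi[elig] / bmi_tol
    pick <- elig[order(dist, pool$id[elig])][seq_len(ratio)]
    used[pick] <- TRUE
    assignment[[i]] <- pool$id[pick]
  }

  controls <- pool[pool$id %in% unlist(assignment), ]
  rownames(controls) <- NULL
  structure(
    list(cases = cases, controls = controls, assignment = assignment,
         ratio = ratio, age_tol = age_tol, bmi_tol = bmi_tol),
    class = "matched_cohort"
  )
}

#' @export
print.matched_cohort <- function(x, ...) {
  cat("Matched cohort: ", nrow(x$cases), " cases, ", nrow(x$controls),
      " controls (1:", x$ratio, ", age +/-", x$age_tol,
      " y, BMI +/-", x$bmi_tol, " kg/m2)\n", sep = "")
  invisible(x)
}

#' Combine a matched cohort into one participant table
#'
#' @param matched A `"matched_cohort"` object.
#' @return Data frame of cases followed by matched controls.
#' @export
cohort_table <- function(matched) {
  stopifnot(inherits(matched, "matched_cohort"))
  out <- rbind(matched$cases, matched$controls)
  rownames(out) <- NULL
  out
}

#' Summarize a matched cohort by WHO BMI class
#'
#' Produces the familiar baseline table: for the overall cohort and each
#' WHO BMI class, participant counts and percentages plus age, BMI and FMI
#' mean (SD) per group, with the between-group test p-value (normality-
#' routed, see [compare_two_groups()]) appended where both groups have at
#' least 3 participants. Empty class cells are reported with n = 0, not
#' dropped.
#'
#' @param matched A `"matched_cohort"` object.
#' @return Data frame with one row per stratum (overall first).
#' @export
summarize_cohort <- function(matched) {
  stopifnot(inherits(matched, "matched_cohort"))
  tab <- cohort_table(matched)
  if (nrow(tab) == 0) stop("empty cohort")
  bmi <- compute_bmi(tab$weight_kg, tab$height_m)
  fmi <- tab$fm_total / tab$height_m^2
  cls <- classify_bmi(bmi)
  strata <- c("all", who_bmi_classes())
  rows <- lapply(strata, function(s) {
    in_s <- if (s == "all") rep(TRUE, nrow(tab)) else cls == s
    ca <- in_s & tab$group == "case"
    co <- in_s & tab$group == "control"
    msd <- function(v, sel) {
      if (sum(sel) == 0) c(NA_real_, NA_real_) else c(mean(v[sel]), sd(v[sel]))
    }
    pval <- function(v) {
      if (sum(ca) >= 3 && sum(co) >= 3) {
        compare_two_groups(v[ca], v[co])$p
      } else {
        NA_real_
      }
    }
    data.frame(
      stratum = s,
      n = sum(in_s),
      pct = 100 * sum(in_s) / nrow(tab),
      n_case = sum(ca), n_control = sum(co),
      age_case_mean = msd(tab$age, ca)[1], age_case_sd = msd(tab$age, ca)[2],
      age_control_mean = msd(tab$age, co)[1],
      age_control_sd = msd(tab$age, co)[2],
      age_p = pval(tab$age),
      bmi_case_mean = msd(bmi, ca)[1], bmi_case_sd = msd(bmi, ca)[2],
      bmi_control_mean = msd(bmi, co)[1], bmi_control_sd = msd(bmi, co)[2],
      bmi_p = pval(bmi),
      fmi_case_mean = msd(fmi, ca)[1], fmi_case_sd = msd(fmi, ca)[2],
      fmi_control_mean = msd(fmi, co)[1], fmi_control_sd = msd(fmi, co)[2],
      fmi_p = pval(fmi),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
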