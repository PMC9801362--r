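# Synthetic cohort generator.
#
# Shares, not raw masses, are the calibration targets: regional fat (lean)
# masses are reconstructed from directly drawn shares of the body total,
# because the published group summaries parameterize the shares. Draws come
# from Gaussians truncated at +/- trunc_k SDs (floored at physical limits),
# which leaves the first two moments undistorted at printed precision.

.participant_columns <- c(
  "id", "group", "age", "height_m", "weight_kg",
  "fm_legs", "fm_arms", "fm_trunk", "fm_android", "fm_gynoid", "fm_head",
  "fm_total",
  "lm_legs", "lm_arms", "lm_trunk", "lm_android", "lm_gynoid", "lm_head",
  "lm_total",
  "bone_mass_total", "bone_area_cm2", "bm_android", "bm_gynoid",
  "type", "stage"
)

.draw_share <- function(n, p, k, lower_floor = 1e-3, upper_cap = 0.98) {
  rnorm_trunc(n, p[1], p[2],
              lower = max(lower_floor, p[1] - k * p[2]),
              upper = min(upper_cap, p[1] + k * p[2]))
}

# Draw legs/arms shares jointly with rejection so trunk share
# (1 - legs - arms - head) stays positive. Errors out if more than 1% of
# attempts are rejected (signals a miscalibrated configuration).
.draw_limb_shares <- function(n, sh, k) {
  legs <- .draw_share(n, sh$legs, k)
  arms <- .draw_share(n, sh$arms, k)
  trunk <- 1 - legs - arms - sh$head
  attempts <- n
  rejected <- 0L
  iter <- 0L
  while (any(bad <- trunk <= 0)) {
    nb <- sum(bad)
    rejected <- rejected + nb
    attempts <- attempts + nb
    legs[bad] <- .draw_share(nb, sh$legs, k)
    arms[bad] <- .draw_share(nb, sh$arms, k)
    trunk <- 1 - legs - arms - sh$head
    iter <- iter + 1L
    if ((attempts >= 200 && rejected / attempts > 0.01) || iter > 1000L) {
      stop("generator miscalibrated: trunk share <= 0 in more than 1% of ",
           "share draws (", rejected, "/", attempts, " rejected)")
    }
  }
  if (attempts >= 200 && rejected / attempts > 0.01) {
    stop("generator miscalibrated: trunk share <= 0 in more than 1% of ",
         "share draws (", rejected, "/", attempts, " rejected)")
  }
  list(legs = legs, arms = arms, trunk = trunk)
}

# Core record generator operating on per-record age/BMI/class vectors.
.gen_records <- function(cfg, group, age, bmi, class, ids) {
  g <- cfg[[group]]
  n <- length(age)
  k <- cfg$trunc_k
  ct <- g$classes
  idx <- match(class, ct$class)
  if (anyNA(idx)) stop("unknown BMI class: ", paste(unique(class[is.na(idx)]),
                                                   collapse = ", "))
  height <- rnorm_trunc(n, g$height[1], g$height[2],
                        lower = max(1.40, g$height[1] - k * g$height[2]),
                        upper = g$height[1] + k * g$height[2])
  weight <- bmi * height^2

  fmi <- rnorm_trunc(n, ct$fmi_mean[idx], ct$fmi_sd[idx],
                     lower = pmax(2, ct$fmi_mean[idx] - k * ct$fmi_sd[idx]),
                     upper = ct$fmi_mean[idx] + k * ct$fmi_sd[idx])
  fm_total <- fmi * height^2
  fsh <- .draw_limb_shares(n, g$fm, k)
  fm_legs <- fsh$legs * fm_total
  fm_arms <- fsh$arms * fm_total
  fm_trunk <- fsh$trunk * fm_total
  fm_head <- g$fm$head * fm_total
  fm_android <- .draw_share(n, g$fm$android_of_trunk, k) * fm_trunk
  fm_gynoid <- .draw_share(n, g$fm$gynoid, k) * fm_total

  lmi <- rnorm_trunc(n, g$lmi[1], g$lmi[2],
                     lower = max(8, g$lmi[1] - k * g$lmi[2]),
                     upper = g$lmi[1] + k * g$lmi[2])
  lm_total <- lmi * height^2
  lsh <- .draw_limb_shares(n, g$lm, k)
  lm_legs <- lsh$legs * lm_total
  lm_arms <- lsh$arms * lm_total
  lm_trunk <- lsh$trunk * lm_total
  lm_head <- g$lm$head * lm_total
  lm_android <- .draw_share(n, g$lm$android_of_trunk, k) * lm_trunk
  lm_gynoid <- .draw_share(n, g$lm$gynoid, k) * lm_total

  bone_total <- g$bone_frac * weight  # total-body bone mass excluding head
  bmd <- rnorm_trunc(n, g$bmd[1], g$bmd[2],
                     lower = max(0.7, g$bmd[1] - k * g$bmd[2]),
                     upper = g$bmd[1] + k * g$bmd[2])
  bone_area <- bone_total * 1000 / bmd  # cm^2, from g/cm^2 density
  bm_android <- bone_total * lm_android / lm_total
  bm_gynoid <- bone_total * lm_gynoid / lm_total

  if (group == "case") {
    type <- c("I", "II", "III", "IV", "V")[
      sample.int(5, n, replace = TRUE, prob = cfg$case$type_probs)]
    stage <- sample.int(4, n, replace = TRUE, prob = cfg$case$stage_probs)
  } else {
    type <- rep(NA_character_, n)
    stage <- rep(NA_integer_, n)
  }

  data.frame(
    id = ids, group = group, age = age, height_m = height, weight_kg = weight,
    fm_legs = fm_legs, fm_arms = fm_arms, fm_trunk = fm_trunk,
    fm_android = fm_android, fm_gynoid = fm_gynoid, fm_head = fm_head,
    fm_total = fm_total,
    lm_legs = lm_legs, lm_arms = lm_arms, lm_trunk = lm_trunk,
    lm_android = lm_android, lm_gynoid = lm_gynoid, lm_head = lm_head,
    lm_total = lm_total,
    bone_mass_total = bone_total, bone_area_cm2 = bone_area,
    bm_android = bm_android, bm_gynoid = bm_gynoid,
    type = type, stage = stage,
    stringsAsFactors = FALSE
  )
}

#' Generate synthetic participant records for one group and BMI class
#'
#' Draws `n` records from the configured distributions: age and BMI from the
#' per-class truncated Gaussians, height from the group height distribution,
#' total fat mass via the per-class FMI distribution, regional fat masses by
#' decomposing total FM into drawn shares (legs, arms, fixed head; trunk as
#' the remainder; android as a drawn fraction of trunk FM; gynoid as its own
#' share of total FM, overlapping legs and trunk by construction, as in the
#' scanner's region definitions), lean masses analogously via the group LMI
#' distribution, and bone mass as a configured fraction of body weight.
#' Cases additionally carry a sampled lipedema type (I-V) and stage (1-4).
#'
#' Randomness comes from R's global RNG stream; use [generate_cohort()] (or
#' `set.seed()`) for reproducible draws.
#'
#' @param config A [default_config()]-shaped configuration.
#' @param group `"case"` or `"control"`.
#' @param bmi_class One of [who_bmi_classes()].
#' @param n Number of records.
#' @param id_prefix Prefix for generated participant ids.
#' @param id_start First integer suffix for ids.
#' @return A data frame with one row per participant (see
#'   [read_participants()] for the column schema).
#' @export
generate_participants <- function(config, group = c("case", "control"),
                                  bmi_class, n = 1,
                                  id_prefix = NULL, id_start = 1L) {
  validate_config(config)
  group <- match.arg(group)
  bmi_class <- match.arg(bmi_class, who_bmi_classes())
  if (n < 1) stop("n must be >= 1")
  if (is.null(id_prefix)) id_prefix <- if (group == "case") "case-" else "ctrl-"
  g <- config[[group]]
  k <- config$trunc_k
  ct <- g$classes[g$classes$class == bmi_class, ]
  age <- rnorm_trunc(n, ct$age_mean, ct$age_sd,
                     lower = max(18, ct$age_mean - k * ct$age_sd),
                     upper = ct$age_mean + k * ct$age_sd)
  bmi <- rnorm_trunc(n, ct$bmi_mean, ct$bmi_sd,
                     lower = max(ct$bmi_min, ct$bmi_mean - k * ct$bmi_sd),
                     upper = min(ct$bmi_max, ct$bmi_mean + k * ct$bmi_sd))
  ids <- sprintf("%s%05d", id_prefix, seq.int(id_start, length.out = n))
  .gen_records(config, group, age, bmi, rep(bmi_class, n), ids)
}

#' @rdname generate_participants
#' @export
generate_participant <- function(config, group = c("case", "control"),
                                 bmi_class, id_prefix = NULL, id_start = 1L) {
  generate_participants(config, group, bmi_class, n = 1,
                        id_prefix = id_prefix, id_start = id_start)
}

#' Generate a full synthetic case-control cohort
#'
#' Generates `n_cases` case records with the configured BMI-class mix
#' (13/26/20/5/10 proportions by default, apportioned by largest remainder)
#' plus `pool_multiplier * n_cases` control records. The control pool
#' emulates matched recruitment: for every case, `anchor_ratio` controls are
#' generated with age and BMI within the matching calipers (uniform
#' `+/- anchor_jitter` offsets, clamped to the study range), and the
#' remainder of the pool is drawn from the per-class control distributions.
#' This guarantees the pool spans the case age/BMI ranges so downstream 1:2
#' matching is feasible.
#'
#' Fixing `seed` makes the cohort fully reproducible record-for-record.
#'
#' @param config A [default_config()]-shaped configuration.
#' @param n_cases Number of cases (>= 1); the study size is 74.
#' @param seed Integer seed; falls back to `config$seed`; `NULL` leaves the
#'   RNG stream untouched.
#' @return A data frame of `n_cases + pool_multiplier * n_cases` participant
#'   rows, cases first.
#' @examples
#' coh <- generate_cohort(default_config(), n_cases = 10, seed = 1)
#' table(coh$group)
#' @export
generate_cohort <- function(config, n_cases = 74, seed = NULL) {
  validate_config(config)
  if (n_cases < 1) stop("n_cases must be >= 1")
  if (is.null(seed)) seed <- config$seed
  if (!is.null(seed)) set.seed(seed)

  cls <- who_bmi_classes()
  case_counts <- largest_remainder(n_cases, config$class_mix)
  cases <- NULL
  start <- 1L
  for (i in seq_along(cls)) {
    if (case_counts[i] == 0) next
    cases <- rbind(cases, generate_participants(
      config, "case", cls[i], case_counts[i], id_start = start))
    start <- start + case_counts[i]
  }
  cases <- cases[order(cases$id), ]
  rownames(cases) <- NULL

  # Anchored controls: age/BMI within the matching calipers of each case.
  r <- config$anchor_ratio
  jit <- config$anchor_jitter
  na <- r * n_cases
  case_age <- rep(cases$age, each = r)
  case_bmi <- rep(cases$weight_kg / cases$height_m^2, each = r)
  a_age <- pmax(18, case_age + runif(na, -jit, jit))
  a_bmi <- pmin(70, pmax(18, case_bmi + runif(na, -jit, jit)))
  a_class <- classify_bmi(a_bmi)
  a_ids <- sprintf("ctrl-%05d", seq_len(na))
  anchors <- .gen_records(config, "control", a_age, a_bmi, a_class, a_ids)

  # Filler controls from the per-class control distributions.
  n_fill <- config$pool_multiplier * n_cases - na
  pool <- anchors
  if (n_fill > 0) {
    fill_counts <- largest_remainder(n_fill, config$class_mix)
    start <- na + 1L
    for (i in seq_along(cls)) {
      if (fill_counts[i] == 0) next
      pool <- rbind(pool, generate_participants(
        config, "control", cls[i], fill_counts[i], id_start = start))
      start <- start + fill_counts[i]
    }
  }
  pool <- pool[order(pool$id), ]
  rownames(pool) <- NULL

  out <- rbind(cases, pool)
  rownames(out) <- NULL
  out
}
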