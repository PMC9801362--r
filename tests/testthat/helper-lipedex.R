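# Fixtures are built in code; oracles here are deliberately brute-force and
# independent of the implementation paths they check.

# One fully specified participant record. Defaults form a consistent
# normal-ish adult female control; the fat compartment matches the worked
# arithmetic example used across the body-composition tests.
make_record <- function(id = "p001", group = "control", age = 40,
                        height_m = 1.60,
                        fm_legs = 18, fm_arms = 4.24, fm_trunk = 16.96,
                        fm_android = 2.6, fm_gynoid = 7.6, fm_head = 0.8,
                        fm_total = 40,
                        lm_legs = 14, lm_arms = 4, lm_trunk = 20,
                        lm_android = 3, lm_gynoid = 6.3, lm_head = 4,
                        lm_total = 42,
                        bone_mass_total = 2.4, bone_area_cm2 = 2000,
                        bm_android = 0.2, bm_gynoid = 0.35,
                        weight_kg = NULL,
                        type = NA_character_, stage = NA_integer_) {
  if (is.null(weight_kg)) weight_kg <- fm_total + lm_total + bone_mass_total
  data.frame(id = id, group = group, age = age, height_m = height_m,
             weight_kg = weight_kg,
             fm_legs = fm_legs, fm_arms = fm_arms, fm_trunk = fm_trunk,
             fm_android = fm_android, fm_gynoid = fm_gynoid,
             fm_head = fm_head, fm_total = fm_total,
             lm_legs = lm_legs, lm_arms = lm_arms, lm_trunk = lm_trunk,
             lm_android = lm_android, lm_gynoid = lm_gynoid,
             lm_head = lm_head, lm_total = lm_total,
             bone_mass_total = bone_mass_total,
             bone_area_cm2 = bone_area_cm2,
             bm_android = bm_android, bm_gynoid = bm_gynoid,
             type = type, stage = stage, stringsAsFactors = FALSE)
}

# A record pinned to a given age and BMI (for matching tests).
make_covariate_record <- function(id, group, age, bmi, height_m = 1.60) {
  make_record(id = id, group = group, age = age, height_m = height_m,
              weight_kg = bmi * height_m^2,
              type = if (group == "case") "III" else NA_character_,
              stage = if (group == "case") 2L else NA_integer_)
}

# Mann-Whitney U oracle by exhaustive pairwise comparison, ties = 1/2.
brute_force_u <- function(x, y) {
  u <- 0
  for (xi in x) u <- u + sum(xi > y) + 0.5 * sum(xi == y)
  u / (length(x) * length(y))
}

# Confusion-matrix oracle at one threshold (higher-is-case orientation).
brute_force_point <- function(x, y, thr) {
  c(sens = mean(x >= thr), spec = mean(y < thr))
}

# Youden oracle: exhaustive scan over every midpoint threshold and the
# sentinels, on the original score scale. Ties broken by higher
# sensitivity, then lower cutoff (the reported convention).
brute_force_youden <- function(x, y,
                               orientation = c("higher_is_case",
                                               "lower_is_case")) {
  orientation <- match.arg(orientation)
  v <- sort(unique(c(x, y)))
  thr <- c(-Inf, (v[-length(v)] + v[-1]) / 2, Inf)
  best <- c(j = -Inf, cutoff = NA, sens = NA, spec = NA)
  for (t in thr) {
    if (orientation == "higher_is_case") {
      sens <- mean(x >= t)
      spec <- mean(y < t)
    } else {
      sens <- mean(x <= t)
      spec <- mean(y > t)
    }
    j <- sens + spec - 1
    if (j > best["j"] + 1e-12 ||
        (abs(j - best["j"]) <= 1e-12 && sens > best["sens"] + 1e-12)) {
      best <- c(j = j, cutoff = t, sens = sens, spec = spec)
    }
  }
  best
}

# Exhaustive feasibility check for 1:ratio matching without replacement on
# tiny instances (recursive search over eligible control subsets).
brute_force_feasible <- function(case_age, case_bmi, pool_age, pool_bmi,
                                 ratio, age_tol = 3, bmi_tol = 3) {
  n <- length(case_age)
  elig <- lapply(seq_len(n), function(i) {
    which(abs(pool_age - case_age[i]) <= age_tol &
            abs(pool_bmi - case_bmi[i]) <= bmi_tol)
  })
  recurse <- function(i, used) {
    if (i > n) return(TRUE)
    avail <- setdiff(elig[[i]], used)
    if (length(avail) < ratio) return(FALSE)
    for (combo in utils::combn(avail, ratio, simplify = FALSE)) {
      if (recurse(i + 1, c(used, combo))) return(TRUE)
    }
    FALSE
  }
  recurse(1, integer(0))
}
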