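test_that("default configuration carries the published calibration targets", {
  cfg <- default_config()
  expect_equal(cfg$case$fm$legs[["mean"]], 0.451)
  expect_equal(cfg$case$fm$legs[["sd"]], 0.050)
  expect_equal(cfg$control$fm$legs[["mean"]], 0.354)
  expect_equal(cfg$control$fm$legs[["sd"]], 0.055)
  expect_equal(sum(cfg$case$type_probs), 1.0)
  expect_equal(sum(cfg$case$stage_probs), 1.0)
  expect_equal(cfg$case$type_probs, c(3, 11, 29, 31, 0) / 74)
  expect_gte(cfg$pool_multiplier, cfg$anchor_ratio)
})

test_that("invalid configurations are rejected with the field named", {
  cfg <- default_config()
  cfg$case$fm$legs[["mean"]] <- 1.2
  expect_error(validate_config(cfg), "legs")
  cfg <- default_config()
  cfg$case$type_probs <- c(0.5, 0.5, 0.5, 0, 0)
  expect_error(validate_config(cfg), "type_probs")
  cfg <- default_config()
  cfg$pool_multiplier <- 1
  expect_error(validate_config(cfg), "pool_multiplier")
  cfg <- default_config()
  cfg$case$fm$legs <- c(mean = 0.70, sd = 0.05)
  cfg$case$fm$arms <- c(mean = 0.35, sd = 0.05)
  expect_error(validate_config(cfg), "head \\+ legs \\+ arms")
})

test_that("miscalibrated share draws trigger the trunk-positivity rejection", {
  cfg <- default_config()
  # means pass the static check but draws frequently push trunk <= 0
  cfg$case$fm$legs <- c(mean = 0.60, sd = 0.15)
  cfg$case$fm$arms <- c(mean = 0.30, sd = 0.10)
  set.seed(5)
  expect_error(generate_participants(cfg, "case", "overweight", n = 500),
               "miscalibrated")
})

test_that("generated records respect their BMI class and share accounting", {
  set.seed(7)
  rec <- generate_participant(default_config(), "control", "normal_weight")
  bmi <- rec$weight_kg / rec$height_m^2
  expect_gte(bmi, 18.0)
  expect_lt(bmi, 25.0)
  expect_identical(rec$group, "control")
  expect_true(is.na(rec$type) && is.na(rec$stage))

  set.seed(8)
  batch <- generate_participants(default_config(), "case", "obesity_I",
                                 n = 400)
  share_sum <- (batch$fm_legs + batch$fm_arms + batch$fm_trunk +
                  batch$fm_head) / batch$fm_total
  expect_equal(share_sum, rep(1, 400), tolerance = 1e-9)
  mass_cols <- grep("^(fm|lm)_", names(batch), value = TRUE)
  expect_true(all(as.matrix(batch[mass_cols]) > 0))
  expect_true(all(batch$type %in% c("I", "II", "III", "IV")))
  expect_true(all(batch$stage %in% 1:4))
  expect_silent(validate_participants(batch))
})

test_that("degenerate share SD yields the exact configured share", {
  cfg <- default_config()
  cfg$case$fm$arms <- c(mean = 0.1, sd = 0)
  set.seed(9)
  batch <- generate_participants(cfg, "case", "overweight", n = 50)
  expect_equal(batch$fm_arms / batch$fm_total, rep(0.1, 50),
               tolerance = 1e-12)
})

test_that("generator recovers configured share moments within 3 SE at n = 10^4", {
  cfg <- default_config()
  n <- 10000
  set.seed(2024)
  for (grp in c("case", "control")) {
    batch <- generate_participants(cfg, grp, "overweight", n = n)
    checks <- list(
      list("fm_legs", cfg[[grp]]$fm$legs),
      list("fm_arms", cfg[[grp]]$fm$arms),
      list("fm_gynoid", cfg[[grp]]$fm$gynoid),
      list("lm_legs", cfg[[grp]]$lm$legs),
      list("lm_gynoid", cfg[[grp]]$lm$gynoid)
    )
    for (ch in checks) {
      col <- ch[[1]]
      mu <- as.numeric(ch[[2]])
      tot <- if (startsWith(col, "fm")) batch$fm_total else batch$lm_total
      sh <- batch[[col]] / tot
      se_mean <- mu[2] / sqrt(n)
      se_sd <- mu[2] / sqrt(2 * n)
      expect_lt(abs(mean(sh) - mu[1]), 3 * se_mean,
                label = paste(grp, col, "mean"))
      expect_lt(abs(sd(sh) - mu[2]), 3 * se_sd,
                label = paste(grp, col, "sd"))
    }
  }
})

test_that("per-class FMI calibration reaches the published class means", {
  set.seed(31)
  batch <- generate_participants(default_config(), "case", "normal_weight",
                                 n = 4000)
  fmi <- batch$fm_total / batch$height_m^2
  expect_lt(abs(mean(fmi) - 8.06), 3 * 1.25 / sqrt(4000))
})

test_that("type and stage frequencies recover the configured multinomial", {
  cfg <- default_config()
  n <- 10000
  set.seed(99)
  batch <- generate_participants(cfg, "case", "overweight", n = n)
  stage_freq <- tabulate(batch$stage, nbins = 4) / n
  for (k in 1:4) {
    p <- cfg$case$stage_probs[k]
    expect_lt(abs(stage_freq[k] - p), 3 * sqrt(p * (1 - p) / n),
              label = paste("stage", k))
  }
  type_freq <- table(factor(batch$type, levels = c("I", "II", "III", "IV", "V")))
  for (k in 1:5) {
    p <- cfg$case$type_probs[k]
    expect_lt(abs(type_freq[k] / n - p), 3 * sqrt(p * (1 - p) / n) + 1e-12,
              label = paste("type", k))
  }
})

test_that("cohort generation meets its count contract and is reproducible", {
  cfg <- default_config()
  coh1 <- generate_cohort(cfg, n_cases = 74, seed = 42)
  expect_equal(sum(coh1$group == "case"), 74)
  expect_gte(sum(coh1$group == "control"), 296)
  cls <- classify_bmi(coh1$weight_kg[coh1$group == "case"] /
                        coh1$height_m[coh1$group == "case"]^2)
  expect_equal(as.vector(table(factor(cls, levels = who_bmi_classes()))),
               c(13, 26, 20, 5, 10))

  coh2 <- generate_cohort(cfg, n_cases = 74, seed = 42)
  expect_identical(coh1, coh2)
  coh3 <- generate_cohort(cfg, n_cases = 74, seed = 43)
  expect_false(identical(coh1, coh3))
})

test_that("configuration round-trips through JSON", {
  cfg <- default_config(seed = 7)
  path <- withr::local_tempfile(fileext = ".json")
  write_config(cfg, path)
  back <- read_config(path)
  expect_equal(back$case$fm$legs, cfg$case$fm$legs)
  expect_equal(back$control$classes, cfg$control$classes)
  expect_equal(back$case$stage_probs, cfg$case$stage_probs)
  expect_equal(back$pool_multiplier, cfg$pool_multiplier)
  # and the round-tripped config drives the generator identically
  a <- generate_cohort(cfg, n_cases = 5, seed = 3)
  b <- generate_cohort(back, n_cases = 5, seed = 3)
  expect_identical(a, b)
})
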