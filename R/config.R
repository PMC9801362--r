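#' WHO BMI class labels used throughout the package
#'
#' Five classes over the adult study range (BMI >= 18 kg/m\eqn{^2}):
#' normal weight \[18, 25), overweight \[25, 30), obesity class I \[30, 35),
#' class II \[35, 40), class III \[40, Inf). Intervals are half-open on the
#' right, as the printed ranges (e.g. "25-29.9") imply.
#'
#' @return Character vector of the five class labels, in ascending BMI order.
#' @export
who_bmi_classes <- function() {
  c("normal_weight", "overweight", "obesity_I", "obesity_II", "obesity_III")
}

.who_breaks <- c(18, 25, 30, 35, 40, Inf)

.group_class_table <- function(group) {
  cls <- who_bmi_classes()
  if (group == "case") {
    data.frame(
      class = cls,
      age_mean = c(31, 40, 42, 45, 45),
      age_sd   = c(9, 9, 14, 14, 13),
      bmi_mean = c(23.2, 27.2, 32.0, 35.7, 49.1),
      bmi_sd   = c(1.5, 1.5, 1.2, 0.7, 11.3),
      bmi_min  = c(18, 25, 30, 35, 40),
      bmi_max  = c(25, 30, 35, 40, 70),
      fmi_mean = c(8.06, 11.27, 14.86, 16.99, 23.63),
      fmi_sd   = c(1.25, 1.63, 1.21, 1.24, 1.27),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(
      class = cls,
      age_mean = c(36, 41, 44, 42, 39),
      age_sd   = c(10, 11, 14, 8, 6),
      bmi_mean = c(22.4, 27.4, 31.9, 36.4, 44.1),
      bmi_sd   = c(1.4, 1.4, 1.4, 1.0, 4.8),
      bmi_min  = c(18, 25, 30, 35, 40),
      bmi_max  = c(25, 30, 35, 40, 70),
      fmi_mean = c(7.26, 10.95, 14.00, 17.37, 22.53),
      fmi_sd   = c(1.33, 1.51, 1.18, 1.30, 1.30),
      stringsAsFactors = FALSE
    )
  }
}

#' Default synthetic-cohort generator configuration
#'
#' Returns the generator parameterization calibrated to the published
#' case-control group summaries: per WHO BMI class, age, BMI and fat mass
#' index (FMI) mean/SD per group; per group, the regional fat- and lean-mass
#' share distributions (legs, arms, gynoid as shares of the body total; head
#' fixed; trunk as the remainder; android as a fraction of trunk mass), the
#' lean mass index (LMI) distribution, bone mass fraction and bone mineral
#' density (BMD); and, for cases, the lipedema type (I-V) and stage (1-4)
#' frequencies.
#'
#' Key calibration targets (group mean (SD)): leg FM/total FM 0.451 (0.050)
#' in cases vs 0.354 (0.055) in controls; arm share 0.106 (0.016) vs
#' 0.107 (0.013); gynoid share 0.194 (0.018) vs 0.177 (0.023); type
#' frequencies 3/11/29/31/0 out of 74, stage frequencies 14/39/19/2 out
#' of 74. Head FM share is fixed at 0.02 (not reported; chosen so that
#' legs + arms + trunk account for ~0.98 of total FM). Height is
#' N(1.66, 0.065) m (back-solved from the absolute-index rows).
#'
#' @param pool_multiplier Controls generated per case (default 4, so that
#'   1:2 matching at the default tolerances is always feasible).
#' @param seed Optional integer stored in the config; [generate_cohort()]
#'   uses it when no explicit seed is passed.
#' @return A list of class `"lipedex_config"`; see [validate_config()] for
#'   the invariants it satisfies.
#' @examples
#' cfg <- default_config()
#' cfg$case$fm$legs   # c(mean = 0.451, sd = 0.050)
#' @export
default_config <- function(pool_multiplier = 4, seed = NULL) {
  cfg <- list(
    case = list(
      classes = .group_class_table("case"),
      height = c(mean = 1.66, sd = 0.065),
      fm = list(
        legs = c(mean = 0.451, sd = 0.050),
        arms = c(mean = 0.106, sd = 0.016),
        gynoid = c(mean = 0.194, sd = 0.018),
        head = 0.02,
        android_of_trunk = c(mean = 0.155, sd = 0.03)
      ),
      lm = list(
        legs = c(mean = 0.378, sd = 0.052),
        arms = c(mean = 0.104, sd = 0.017),
        gynoid = c(mean = 0.155, sd = 0.029),
        head = 0.057,
        android_of_trunk = c(mean = 0.150, sd = 0.02)
      ),
      lmi = c(mean = 15.87, sd = 2.84),
      bone_frac = 0.03,
      bmd = c(mean = 1.12, sd = 0.08),
      type_probs = c(3, 11, 29, 31, 0) / 74,
      stage_probs = c(14, 39, 19, 2) / 74
    ),
    control = list(
      classes = .group_class_table("control"),
      height = c(mean = 1.66, sd = 0.065),
      fm = list(
        legs = c(mean = 0.354, sd = 0.055),
        arms = c(mean = 0.107, sd = 0.013),
        gynoid = c(mean = 0.177, sd = 0.023),
        head = 0.02,
        android_of_trunk = c(mean = 0.167, sd = 0.03)
      ),
      lm = list(
        legs = c(mean = 0.357, sd = 0.018),
        arms = c(mean = 0.109, sd = 0.009),
        gynoid = c(mean = 0.154, sd = 0.009),
        head = 0.071,
        android_of_trunk = c(mean = 0.151, sd = 0.01)
      ),
      lmi = c(mean = 16.44, sd = 2.30),
      bone_frac = 0.03,
      bmd = c(mean = 1.12, sd = 0.08)
    ),
    # case BMI-class mix: 13/26/20/5/10 of 74
    class_mix = c(13, 26, 20, 5, 10) / 74,
    pool_multiplier = pool_multiplier,
    anchor_ratio = 4,     # in-caliper controls generated per case; the
                          # default pool is recruited-to-match (two spare
                          # anchors above the 1:2 ratio, so greedy matching
                          # cannot be starved by neighbour steals)
    anchor_jitter = 2.0,  # uniform age/BMI offset half-width for anchors
    trunc_k = 4,          # truncation half-width of share draws, in SDs
    seed = seed
  )
  class(cfg) <- "lipedex_config"
  validate_config(cfg)
  cfg
}

.check_share <- function(p, what) {
  if (length(p) < 2 || is.na(p[1]) || is.na(p[2]))
    stop("config: ", what, " must be c(mean, sd)")
  if (p[1] <= 0 || p[1] >= 1) stop("config: ", what, " mean must be in (0,1)")
  if (p[2] < 0) stop("config: ", what, " sd must be >= 0")
  invisible(TRUE)
}

#' Validate a generator configuration
#'
#' Checks the structural invariants of a [default_config()]-shaped object:
#' positive SDs, share means in (0,1) with head + legs + arms < 1, type and
#' stage probabilities summing to 1, and pool multiplier at least the anchor
#' (matching) ratio. Called by every generator entry point; errors are
#' raised with the offending field named.
#'
#' @param cfg A `"lipedex_config"` object.
#' @return `cfg`, invisibly, if valid.
#' @export
validate_config <- function(cfg) {
  for (g in c("case", "control")) {
    gg <- cfg[[g]]
    if (is.null(gg)) stop("config: missing group '", g, "'")
    ct <- gg$classes
    need <- c("class", "age_mean", "age_sd", "bmi_mean", "bmi_sd",
              "bmi_min", "bmi_max", "fmi_mean", "fmi_sd")
    if (!all(need %in% names(ct))) stop("config: incomplete class table for ", g)
    if (any(ct$age_sd <= 0) || any(ct$bmi_sd <= 0) || any(ct$fmi_sd <= 0))
      stop("config: class-table SDs must be > 0 (group ", g, ")")
    for (tissue in c("fm", "lm")) {
      sh <- gg[[tissue]]
      .check_share(sh$legs, paste(g, tissue, "legs"))
      .check_share(sh$arms, paste(g, tissue, "arms"))
      .check_share(sh$gynoid, paste(g, tissue, "gynoid"))
      .check_share(sh$android_of_trunk, paste(g, tissue, "android_of_trunk"))
      if (sh$head <= 0 || sh$head >= 1)
        stop("config: head share must be in (0,1) (", g, " ", tissue, ")")
      if (sh$head + sh$legs[1] + sh$arms[1] >= 1)
        stop("config: head + legs + arms share means must be < 1 (",
             g, " ", tissue, ")")
    }
    if (gg$lmi[2] <= 0) stop("config: lmi sd must be > 0 (", g, ")")
    if (gg$bone_frac <= 0 || gg$bone_frac >= 1)
      stop("config: bone_frac must be in (0,1) (", g, ")")
  }
  tp <- cfg$case$type_probs
  sp <- cfg$case$stage_probs
  if (length(tp) != 5 || abs(sum(tp) - 1) > 1e-8)
    stop("config: type_probs must have length 5 and sum to 1")
  if (length(sp) != 4 || abs(sum(sp) - 1) > 1e-8)
    stop("config: stage_probs must have length 4 and sum to 1")
  if (any(tp < 0) || any(sp < 0))
    stop("config: type/stage probabilities must be >= 0")
  if (length(cfg$class_mix) != 5 || abs(sum(cfg$class_mix) - 1) > 1e-8)
    stop("config: class_mix must have length 5 and sum to 1")
  if (cfg$pool_multiplier < cfg$anchor_ratio)
    stop("config: pool_multiplier must be >= anchor_ratio")
  if (cfg$trunc_k <= 0) stop("config: trunc_k must be > 0")
  invisible(cfg)
}

#' Read / write a generator configuration as JSON
#'
#' The configuration round-trips through JSON: `read_config(write_config(x))`
#' reproduces every numeric parameter exactly (full double precision is
#' written).
#'
#' @param cfg A `"lipedex_config"` object.
#' @param path File path of the JSON configuration.
#' @return `write_config` returns `path` invisibly; `read_config` returns a
#'   validated `"lipedex_config"` object.
#' @export
write_config <- function(cfg, path) {
  validate_config(cfg)
  jsonlite::write_json(unclass(cfg), path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns", null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  ms <- function(v) setNames(as.numeric(unlist(v))[1:2], c("mean", "sd"))
  for (g in c("case", "control")) {
    raw[[g]]$classes <- as.data.frame(raw[[g]]$classes)
    for (tissue in c("fm", "lm")) {
      for (f in c("legs", "arms", "gynoid", "android_of_trunk")) {
        raw[[g]][[tissue]][[f]] <- ms(raw[[g]][[tissue]][[f]])
      }
    }
    raw[[g]]$height <- ms(raw[[g]]$height)
    raw[[g]]$lmi <- ms(raw[[g]]$lmi)
    raw[[g]]$bmd <- ms(raw[[g]]$bmd)
  }
  cfg <- raw
  class(cfg) <- "lipedex_config"
  validate_config(cfg)
  cfg
}
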