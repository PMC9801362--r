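# The comparison battery: normality-routed two-group and multi-group tests
# across the 27-index panel, Bonferroni control over n = 27 tests, and the
# index-vs-stage correlation analysis.

#' Shapiro-Wilk normality assessment
#'
#' Routing test behind every parametric/non-parametric choice in the
#' battery. A sample is called non-normal when the Shapiro-Wilk p-value
#' falls below `alpha`. Constant samples are degenerate and reported as
#' non-normal. Samples larger than 5000 (the test's limit) are assessed on
#' a deterministic evenly spaced subsample of 5000 sorted values.
#'
#' @param x Numeric sample (n >= 3 after NA removal).
#' @param alpha Significance level for the routing decision (default 0.05).
#' @return List with `normal` (logical), `p` (Shapiro-Wilk p-value, NA when
#'   degenerate) and `degenerate`.
#' @export
assess_normality <- function(x, alpha = 0.05) {
  x <- x[!is.na(x)]
  if (length(x) < 3) stop("assess_normality: need at least 3 observations")
  if (sd(x) == 0) {
    return(list(normal = FALSE, p = NA_real_, degenerate = TRUE))
  }
  if (length(x) > 5000) {
    x <- sort(x)[round(seq(1, length(x), length.out = 5000))]
  }
  p <- shapiro.test(x)$p.value
  list(normal = p >= alpha, p = p, degenerate = FALSE)
}

#' Bonferroni-adjusted significance threshold
#'
#' `alpha / n_tests`; with the study's alpha = 0.05 over the 27-index panel
#' this is 0.05/27 = 0.00185 (to printed precision).
#'
#' @param alpha Family-wise level in (0, 1).
#' @param n_tests Number of tests (>= 1).
#' @return The per-test threshold.
#' @examples
#' bonferroni_threshold(0.05, 27)
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests = 1) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)")
  if (n_tests < 1) stop("n_tests must be >= 1")
  alpha / n_tests
}

#' Two-group comparison with normality routing
#'
#' Runs Student's t test (equal-variance, as in classic clinical practice)
#' when both groups pass [assess_normality()], otherwise the Mann-Whitney
#' (Wilcoxon rank-sum) test; R's `wilcox.test` defaults govern exactness
#' (exact for small tie-free samples, normal approximation with tie
#' correction otherwise). Two-tailed throughout.
#'
#' @param x,y Numeric samples (each n >= 3).
#' @param alpha Family-wise level.
#' @param n_tests Bonferroni denominator used for the significance flag.
#' @param label Optional index name recorded in the result.
#' @return One-row data frame: `index`, `n_case`, `n_control`, `mean_case`,
#'   `sd_case`, `mean_control`, `sd_control`, `test` (`"t"` or
#'   `"mann_whitney"`), `statistic`, `p`, `significant`.
#' @export
compare_two_groups <- function(x, y, alpha = 0.05, n_tests = 1,
                               label = NA_character_) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 3 || length(y) < 3) {
    stop("compare_two_groups: need at least 3 observations per group")
  }
  nx <- assess_normality(x, alpha = 0.05)
  ny <- assess_normality(y, alpha = 0.05)
  if (nx$degenerate && ny$degenerate && identical(unique(x), unique(y))) {
    # both constant at the same value: no difference, but no valid test
    res <- list(test = "degenerate", statistic = NA_real_, p = 1)
  } else if (nx$normal && ny$normal) {
    tt <- t.test(x, y, var.equal = TRUE)
    res <- list(test = "t", statistic = unname(tt$statistic), p = tt$p.value)
  } else {
    wt <- suppressWarnings(wilcox.test(x, y))
    res <- list(test = "mann_whitney", statistic = unname(wt$statistic),
                p = wt$p.value)
  }
  thr <- bonferroni_threshold(alpha, n_tests)
  data.frame(
    index = label, n_case = length(x), n_control = length(y),
    mean_case = mean(x), sd_case = sd(x),
    mean_control = mean(y), sd_control = sd(y),
    test = res$test, statistic = res$statistic, p = res$p,
    significant = res$p < thr,
    stringsAsFactors = FALSE
  )
}

#' Multi-group comparison with normality routing and small-group exclusion
#'
#' Groups smaller than `min_group_size` are excluded before testing
#' (mirroring the study's exclusion of a type with 3 and a stage with 2
#' participants). With at least 3 eligible groups, runs one-way ANOVA when
#' every group passes [assess_normality()] (Tukey HSD post hoc is attached
#' when the ANOVA is significant at `alpha`), otherwise Kruskal-Wallis (no
#' post hoc; only Tukey is part of the battery).
#'
#' @param values Numeric response.
#' @param groups Group labels, same length as `values`.
#' @param alpha Family-wise level.
#' @param n_tests Bonferroni denominator for the significance flag.
#' @param min_group_size Minimum group size retained (default 5).
#' @param label Optional index name.
#' @return List with `index`, `test` (`"anova"` or `"kruskal_wallis"`),
#'   `statistic`, `p`, `significant`, `groups` (per-group n, mean, sd),
#'   `excluded` (labels of dropped groups) and `posthoc` (Tukey table or
#'   `NULL`).
#' @export
compare_multi_groups <- function(values, groups, alpha = 0.05, n_tests = 1,
                                 min_group_size = 5, label = NA_character_) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- as.character(groups[keep])
  cnt <- table(groups)
  excluded <- names(cnt)[cnt < min_group_size]
  keep <- !groups %in% excluded
  values <- values[keep]
  groups <- groups[keep]
  cnt <- table(groups)
  if (length(cnt) < 3) {
    stop("compare_multi_groups: fewer than 3 eligible groups after ",
         "excluding groups smaller than ", min_group_size)
  }
  normal <- all(vapply(split(values, groups),
                       function(v) assess_normality(v, 0.05)$normal, TRUE))
  g <- factor(groups)
  posthoc <- NULL
  if (normal) {
    fit <- aov(values ~ g)
    s <- summary(fit)[[1]]
    stat <- s[["F value"]][1]
    p <- s[["Pr(>F)"]][1]
    test <- "anova"
    if (p < alpha) {
      tk <- TukeyHSD(fit)$g
      posthoc <- data.frame(
        comparison = rownames(tk), diff = tk[, "diff"],
        p_adj = tk[, "p adj"], significant = tk[, "p adj"] < alpha,
        row.names = NULL, stringsAsFactors = FALSE
      )
    }
  } else {
    kt <- kruskal.test(values, g)
    stat <- unname(kt$statistic)
    p <- kt$p.value
    test <- "kruskal_wallis"
  }
  summ <- aggregate(values, list(group = groups),
                    function(v) c(n = length(v), mean = mean(v), sd = sd(v)))
  summ <- data.frame(group = summ$group, n = summ$x[, "n"],
                     mean = summ$x[, "mean"], sd = summ$x[, "sd"],
                     stringsAsFactors = FALSE)
  list(index = label, test = test, statistic = stat, p = p,
       significant = p < bonferroni_threshold(alpha, n_tests),
       groups = summ, excluded = excluded, posthoc = posthoc)
}

#' Correlation between an index and lipedema stage
#'
#' Pearson correlation when the index values pass [assess_normality()],
#' Spearman otherwise (stage is ordinal; routing follows the index
#' distribution). Two-tailed p; r-squared reported alongside r.
#'
#' @param values Numeric index values.
#' @param stages Ordinal stages, paired with `values`.
#' @param alpha Family-wise level.
#' @param n_tests Bonferroni denominator for the significance flag.
#' @param label Optional index name.
#' @return One-row data frame: `index`, `method`, `r`, `r2`, `p`,
#'   `significant`.
#' @export
correlate_index_with_stage <- function(values, stages, alpha = 0.05,
                                       n_tests = 1, label = NA_character_) {
  keep <- !is.na(values) & !is.na(stages)
  values <- values[keep]
  stages <- as.numeric(stages[keep])
  if (length(values) < 3) stop("need at least 3 paired observations")
  if (sd(values) == 0 || sd(stages) == 0) {
    stop("correlation undefined: zero variance in values or stages")
  }
  method <- if (assess_normality(values, 0.05)$normal) "pearson" else "spearman"
  ct <- suppressWarnings(cor.test(values, stages, method = method,
                                  exact = FALSE))
  r <- unname(ct$estimate)
  data.frame(index = label, method = method, r = r, r2 = r^2, p = ct$p.value,
             significant = ct$p.value < bonferroni_threshold(alpha, n_tests),
             stringsAsFactors = FALSE)
}

#' Run the 27-index comparison battery on a matched cohort
#'
#' Computes the index panel for all participants and compares cases against
#' controls index by index with [compare_two_groups()], flagging
#' significance at the Bonferroni threshold alpha/27. Per-index errors are
#' caught and reported in the output; the battery continues.
#'
#' Stratified variants: `stratify = "bmi_class"` reruns the two-group
#' battery within each WHO BMI class (classes with fewer than 3 cases or
#' controls are skipped); `stratify = "type"` or `"stage"` compares the
#' index across lipedema types/stages among cases with
#' [compare_multi_groups()] and its small-group exclusion.
#'
#' @param matched A `"matched_cohort"` object.
#' @param alpha Family-wise level (default 0.05).
#' @param stratify `NULL`, `"bmi_class"`, `"type"` or `"stage"`.
#' @param min_group_size Exclusion threshold for type/stage strata.
#' @return For the unstratified battery: a 27-row data frame (one row per
#'   panel index) with attribute `"threshold"`. For `"bmi_class"`: a named
#'   list of such data frames. For `"type"`/`"stage"`: a data frame of
#'   per-index multi-group results.
#' @export
run_comparison_battery <- function(matched, alpha = 0.05, stratify = NULL,
                                   min_group_size = 5) {
  stopifnot(inherits(matched, "matched_cohort"))
  if (nrow(matched$cases) == 0 || nrow(matched$controls) == 0) {
    stop("empty cohort")
  }
  idx <- panel_index_names()
  n_tests <- length(idx)
  panel <- compute_index_panel(cohort_table(matched))
  is_case <- panel$group == "case"

  two_group_battery <- function(sel) {
    rows <- lapply(idx, function(nm) {
      tryCatch(
        compare_two_groups(panel[[nm]][sel & is_case],
                           panel[[nm]][sel & !is_case],
                           alpha = alpha, n_tests = n_tests, label = nm),
        error = function(e) {
          data.frame(index = nm, n_case = sum(sel & is_case),
                     n_control = sum(sel & !is_case),
                     mean_case = NA_real_, sd_case = NA_real_,
                     mean_control = NA_real_, sd_control = NA_real_,
                     test = paste("error:", conditionMessage(e)),
                     statistic = NA_real_, p = NA_real_, significant = NA,
                     stringsAsFactors = FALSE)
        }
      )
    })
    out <- do.call(rbind, rows)
    attr(out, "threshold") <- bonferroni_threshold(alpha, n_tests)
    out
  }

  if (is.null(stratify)) {
    return(two_group_battery(rep(TRUE, nrow(panel))))
  }
  stratify <- match.arg(stratify, c("bmi_class", "type", "stage"))
  if (stratify == "bmi_class") {
    out <- list()
    for (cl in who_bmi_classes()) {
      sel <- panel$bmi_class == cl
      if (sum(sel & is_case) >= 3 && sum(sel & !is_case) >= 3) {
        out[[cl]] <- two_group_battery(sel)
      }
    }
    return(out)
  }
  # type / stage: multi-group comparison among cases
  lab <- panel[[stratify]][is_case]
  rows <- lapply(idx, function(nm) {
    res <- tryCatch(
      compare_multi_groups(panel[[nm]][is_case], lab, alpha = alpha,
                           n_tests = n_tests,
                           min_group_size = min_group_size, label = nm),
      error = function(e) list(index = nm, test = paste("error:",
                                                        conditionMessage(e)),
                               statistic = NA_real_, p = NA_real_,
                               significant = NA, excluded = character(0))
    )
    data.frame(index = nm, test = res$test, statistic = res$statistic,
               p = res$p, significant = res$significant,
               excluded = paste(res$excluded, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "threshold") <- bonferroni_threshold(alpha, n_tests)
  out
}

#' Correlation battery between FM distribution indices and stage
#'
#' Runs [correlate_index_with_stage()] for every fat-mass panel index over
#' the cases of a matched cohort, at the Bonferroni threshold over the full
#' 27-index panel.
#'
#' @param matched A `"matched_cohort"` object.
#' @param alpha Family-wise level.
#' @return Data frame with one row per FM index.
#' @export
run_correlation_battery <- function(matched, alpha = 0.05) {
  stopifnot(inherits(matched, "matched_cohort"))
  panel <- compute_index_panel(matched$cases)
  info <- panel_index_info()
  idx <- info$name[info$category == "fm"]
  n_tests <- nrow(info)
  rows <- lapply(idx, function(nm) {
    correlate_index_with_stage(panel[[nm]], panel$stage, alpha = alpha,
                               n_tests = n_tests, label = nm)
  })
  out <- do.call(rbind, rows)
  attr(out, "threshold") <- bonferroni_threshold(alpha, n_tests)
  out
}
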