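# Trial-level descriptive and inferential statistics: remission
# classification at the SPDQ cut-off, uncorrected 2x2 Pearson chi-square
# tests of remission proportions, Welch's t test for engagement, and
# prompt-completion engagement rates.

#' Classify remission from a severity score
#'
#' Remission is defined by a severity score strictly below the cut-off
#' (default 12.13 on the SPDQ, the cut-off with high specificity against
#' a SAD diagnosis).
#'
#' @param spdq_score Nonnegative severity score(s); `NA` allowed.
#' @param cutoff Remission cut-off (default 12.13).
#' @return Integer vector: 1 = remitted, 0 = not remitted, `NA` preserved.
#' @export
#' @examples
#' classify_remission(c(12.12, 12.13, 0))
classify_remission <- function(spdq_score, cutoff = SPDQ_REMISSION_CUTOFF) {
  assert_that(all(spdq_score >= 0, na.rm = TRUE),
              "severity scores must be nonnegative")
  as.integer(spdq_score < cutoff)
}

#' Pearson chi-square test for a 2x2 table
#'
#' Uncorrected (no Yates continuity correction) Pearson chi-square on one
#' degree of freedom, via the closed form
#' `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`. A table with a zero marginal
#' has no association to test; the statistic is defined as 0 with a
#' warning.
#'
#' @param table 2x2 matrix of nonnegative counts, or the count `a` with
#'   `b`, `c`, `d` given separately. Rows are groups (or time points),
#'   columns remitted vs not.
#' @param b,c,d Remaining counts when `table` is scalar.
#' @return List with `statistic`, `df` (always 1), and `p_value`.
#' @export
#' @examples
#' pearson_chi_square(c(0, 96), c(15, 81))$statistic  # 16.27
pearson_chi_square <- function(table, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(table)) {
    counts <- as.numeric(t(table))
  } else if (!is.null(b) && is.null(c)) {
    counts <- c(table, b)  # two row vectors
  } else if (!is.null(d)) {
    counts <- c(table, b, c, d)
  } else {
    counts <- as.numeric(table)
  }
  assert_that(length(counts) == 4, "a 2x2 table requires four counts")
  assert_that(all(counts >= 0), "counts must be nonnegative")
  a <- counts[1]; b <- counts[2]; c <- counts[3]; d <- counts[4]
  n <- a + b + c + d
  assert_that(n >= 1, "total count must be >= 1")
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  if (denom == 0) {
    warning("zero marginal total; chi-square statistic defined as 0")
    return(list(statistic = 0, df = 1L, p_value = 1))
  }
  stat <- n * (a * d - b * c)^2 / denom
  list(statistic = stat, df = 1L,
       p_value = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Welch's two-sample t test
#'
#' Welch's unequal-variances t statistic with Welch-Satterthwaite degrees
#' of freedom, from either raw vectors or summary statistics.
#'
#' @param x,y Numeric vectors, or lists `list(mean=, sd=, n=)` of summary
#'   statistics.
#' @return List with `statistic`, `df`, and `p_value` (two-sided).
#' @export
#' @examples
#' welch_t_test(list(mean = 85.3, sd = 16.8, n = 96),
#'              list(mean = 85.1, sd = 18.7, n = 95))$df  # ~186.5
welch_t_test <- function(x, y) {
  summarize <- function(v) {
    if (is.list(v)) {
      assert_that(all(c("mean", "sd", "n") %in% names(v)),
                  "summary input needs mean, sd and n")
      v
    } else {
      v <- v[!is.na(v)]
      list(mean = mean(v), sd = sd(v), n = length(v))
    }
  }
  s1 <- summarize(x); s2 <- summarize(y)
  assert_that(s1$n >= 2 && s2$n >= 2, "each group needs n >= 2")
  assert_that(s1$sd > 0 || s2$sd > 0, "at least one group must vary")
  v1 <- s1$sd^2 / s1$n
  v2 <- s2$sd^2 / s2$n
  t_stat <- (s1$mean - s2$mean) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (s1$n - 1) + v2^2 / (s2$n - 1))
  list(statistic = t_stat, df = df,
       p_value = 2 * pt(-abs(t_stat), df))
}

#' Engagement rate from prompt completion
#'
#' @param prompts_completed Integer count(s) of completed prompts, out of
#'   `total` (default 70: five prompts per day over 14 days).
#' @param total Total prompts delivered.
#' @return Percentage completed.
#' @export
#' @examples
#' engagement_rate(56)  # 80, the active-participation threshold
engagement_rate <- function(prompts_completed, total = 70L) {
  assert_that(all(prompts_completed >= 0 & prompts_completed <= total,
                  na.rm = TRUE),
              sprintf("prompt counts must lie in [0, %d]", total))
  100 * prompts_completed / total
}

#' Remission and engagement summary for a trial dataset
#'
#' Reproduces the trial-level results block: per-arm remission counts and
#' rates at both waves (complete cases on the wave's severity score),
#' within-group chi-square tests against the zero-remission baseline
#' (eligibility requires active disorder at entry), the between-group
#' chi-square at each wave, and the Welch comparison of engagement rates.
#'
#' @param data A `trial_dataset`.
#' @param cutoff Remission cut-off.
#' @return List of class `remission_report`.
#' @export
remission_report <- function(data, cutoff = SPDQ_REMISSION_CUTOFF) {
  arms <- list(treatment = data$arm == 1, control = data$arm == 0)
  out <- list(cutoff = cutoff, time_points = list())
  for (tp in c("post", "1mfu")) {
    score <- data[[paste0("spdq_", tp)]]
    rem <- classify_remission(score, cutoff)
    cells <- lapply(arms, function(sel) {
      r <- rem[sel & !is.na(rem)]
      list(n = length(r), remitted = sum(r), rate = 100 * mean(r))
    })
    within <- lapply(cells, function(cl)
      pearson_chi_square(c(0, cl$n), c(cl$remitted, cl$n - cl$remitted)))
    between <- pearson_chi_square(
      c(cells$treatment$remitted,
        cells$treatment$n - cells$treatment$remitted),
      c(cells$control$remitted, cells$control$n - cells$control$remitted))
    out$time_points[[tp]] <- list(arms = cells, within = within,
                                  between = between)
  }
  if ("prompts_completed" %in% names(data)) {
    er <- engagement_rate(data$prompts_completed)
    out$engagement <- list(
      treatment = list(mean = mean(er[arms$treatment], na.rm = TRUE),
                       sd = sd(er[arms$treatment], na.rm = TRUE)),
      control = list(mean = mean(er[arms$control], na.rm = TRUE),
                     sd = sd(er[arms$control], na.rm = TRUE)),
      welch = welch_t_test(er[arms$treatment], er[arms$control]))
  }
  class(out) <- "remission_report"
  out
}

#' @export
print.remission_report <- function(x, ...) {
  cat("<remission_report> cutoff <", x$cutoff, "\n")
  for (tp in names(x$time_points)) {
    b <- x$time_points[[tp]]
    cat(sprintf(
      "  %s: treatment %d/%d (%.1f%%), control %d/%d (%.1f%%), between chi2=%.2f (p=%.3f)\n",
      tp, b$arms$treatment$remitted, b$arms$treatment$n,
      b$arms$treatment$rate, b$arms$control$remitted, b$arms$control$n,
      b$arms$control$rate, b$between$statistic, b$between$p_value))
  }
  invisible(x)
}
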