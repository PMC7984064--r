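# Group comparisons and summary tables in the reporting style used for
# microscopy quantifications: mean +/- SD per condition plus a two-sided
# Mann-Whitney U or t-test against a control.

#' Compare two samples with a Mann-Whitney U or t-test
#'
#' Two-sided by default. The Mann-Whitney U test uses the exact null
#' distribution for small untied samples and a mid-rank normal
#' approximation in the presence of ties; `t_equal_var` is the classical
#' Student test, `t_welch` the unequal-variance variant.
#'
#' @param a,b numeric samples (each n >= 1; n >= 2 for t-tests).
#' @param test `"mann_whitney"`, `"t_equal_var"` or `"t_welch"`.
#' @param star_thresholds decreasing p-value cut-offs mapped to `*`, `**`,
#'   `***`; significance-star conventions differ between venues, so the
#'   mapping is explicit and configurable rather than fixed.
#' @return One-row data.frame: sample sizes, means, SDs, test name,
#'   statistic, two-sided `p`, `stars`, and `flag` (non-empty for degenerate
#'   inputs handled by convention).
#' @export
compare_groups <- function(a, b,
                           test = c("mann_whitney", "t_equal_var", "t_welch"),
                           star_thresholds = c(0.05, 0.01, 0.001)) {
  test <- match.arg(test)
  a <- as.numeric(a); b <- as.numeric(b)
  stopifnot(length(a) >= 1L, length(b) >= 1L)
  flag <- ""
  if (test == "mann_whitney") {
    ht <- suppressWarnings(stats::wilcox.test(a, b, exact = NULL, correct = TRUE))
    stat <- unname(ht$statistic)  # U of the first sample
    p <- ht$p.value
    test_name <- "Mann-Whitney U"
  } else {
    stopifnot(length(a) >= 2L, length(b) >= 2L)
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      # degenerate: no variance at all; equal means are indistinguishable
      if (mean(a) == mean(b)) {
        stat <- 0; p <- 1; flag <- "zero variance, equal means: p = 1 by convention"
      } else {
        stat <- Inf; p <- 0; flag <- "zero variance, different means"
      }
      test_name <- if (test == "t_equal_var") "Student t" else "Welch t"
    } else {
      ht <- stats::t.test(a, b, var.equal = (test == "t_equal_var"))
      stat <- unname(ht$statistic)
      p <- ht$p.value
      test_name <- if (test == "t_equal_var") "Student t" else "Welch t"
    }
  }
  stars <- paste(rep("*", sum(p < star_thresholds)), collapse = "")
  if (stars == "") stars <- "ns"
  data.frame(n_a = length(a), n_b = length(b),
             mean_a = mean(a), mean_b = mean(b),
             sd_a = if (length(a) > 1) stats::sd(a) else 0,
             sd_b = if (length(b) > 1) stats::sd(b) else 0,
             test = test_name, statistic = stat, p = p, stars = stars,
             flag = flag)
}

#' Summarise a long table of measurements by condition
#'
#' One row per condition with n, mean and SD, plus the comparison of each
#' condition against a declared control.
#'
#' @param records data.frame with columns `condition` and `value`.
#' @param control the condition label to compare the others against.
#' @param test passed to [compare_groups()].
#' @param star_thresholds passed to [compare_groups()].
#' @return data.frame: `condition`, `n`, `mean`, `sd`, `p_vs_control`,
#'   `stars`, `flag` (`single observation` when SD is reported as 0 for
#'   n = 1).
#' @export
summarize_conditions <- function(records, control,
                                 test = "mann_whitney",
                                 star_thresholds = c(0.05, 0.01, 0.001)) {
  stopifnot(all(c("condition", "value") %in% names(records)))
  conds <- unique(as.character(records$condition))
  if (!control %in% conds) stop(sprintf("unknown control label '%s'", control))
  ctrl_vals <- records$value[records$condition == control]
  rows <- lapply(conds, function(cn) {
    v <- records$value[records$condition == cn]
    out <- data.frame(condition = cn, n = length(v), mean = mean(v),
                      sd = if (length(v) > 1) stats::sd(v) else 0,
                      p_vs_control = NA_real_, stars = "", flag = "")
    if (length(v) == 1L) out$flag <- "single observation"
    if (cn != control) {
      cmp <- compare_groups(ctrl_vals, v, test = test,
                            star_thresholds = star_thresholds)
      out$p_vs_control <- cmp$p
      out$stars <- cmp$stars
      if (nzchar(cmp$flag)) out$flag <- paste0(out$flag,
                                               if (nzchar(out$flag)) "; " else "",
                                               cmp$flag)
    }
    out
  })
  do.call(rbind, rows)
}
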