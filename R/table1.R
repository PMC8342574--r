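#' Chi-square test for a 2x2 table with Yates continuity correction
#'
#' Thin wrapper around [stats::chisq.test()] with the continuity
#' correction on by default: the statistic is
#' `sum((|O - E| - 0.5)^2 / E)` with the correction capped so cells where
#' `|O - E| < 0.5` contribute zero, referred to chi-square with 1 df. The
#' correction is appropriate for the modest cell counts of cohort
#' characteristic tables and never increases the statistic.
#'
#' @param table A 2x2 matrix of nonnegative counts (rows = groups,
#'   columns = outcome levels).
#' @param correct Apply the Yates correction (default `TRUE`).
#' @return List with `statistic`, `df` and `p_value`.
#' @examples
#' chi2_yates(matrix(c(168, 48, 76, 40), 2))
#' @export
chi2_yates <- function(table, correct = TRUE) {
  table <- as.matrix(table)
  stopifnot(nrow(table) == 2L, ncol(table) == 2L, all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("undefined test: a margin of the 2x2 table is zero")
  ct <- stats::chisq.test(table, correct = correct)
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value))
}

#' Welch two-sample t-test from group summaries
#'
#' The unequal-variance t-test computed from per-group mean, standard
#' deviation and sample size (the form published cohort tables provide):
#' `t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)` with Welch-Satterthwaite
#' degrees of freedom and a two-sided p-value.
#'
#' @param mean1,sd1,n1 Summary of group 1.
#' @param mean2,sd2,n2 Summary of group 2.
#' @return List with `t`, `df` and `p_value`. When both standard
#'   deviations are zero and the means are equal the test is degenerate;
#'   `t = 0`, `p = 1` by convention.
#' @examples
#' welch_t(26.84, 6.74, 212, 30.95, 7.02, 77)
#' @export
welch_t <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2L, n2 >= 2L, sd1 >= 0, sd2 >= 0)
  se2 <- sd1^2 / n1 + sd2^2 / n2
  if (se2 == 0) {
    if (mean1 == mean2) return(list(t = 0, df = NA_real_, p_value = 1))
    stop("zero variance in both groups with unequal means")
  }
  t <- (mean1 - mean2) / sqrt(se2)
  df <- se2^2 / ((sd1^2 / n1)^2 / (n1 - 1L) + (sd2^2 / n2)^2 / (n2 - 1L))
  list(t = t, df = df, p_value = 2 * stats::pt(-abs(t), df))
}

#' Cohort characteristics by ancestry
#'
#' Summarizes a twin cohort's metadata per ancestry stratum in the style
#' of a clinical Table 1: counts with percentages for categorical
#' variables, min / median (IQR) / mean (sd) / max with missingness for
#' continuous ones, plus between-ancestry tests — Yates-corrected
#' chi-square for 2x2 categorical contrasts (levels beyond yes/no, such as
#' "not_sure", and missing values are excluded from the test) and the
#' Welch t-test for continuous variables.
#'
#' @param records Metadata data frame (see [read_metadata()]).
#' @param ancestry_levels The two strata to compare (first = reference).
#' @param continuous,categorical Column names to summarize when present.
#' @return An object of class `cohort_summary`: list with `continuous`
#'   and `categorical` data frames and `n` per stratum.
#' @export
summarize_cohort <- function(records,
                             ancestry_levels = c("European", "African"),
                             continuous = c("age", "bmi", "ph"),
                             categorical = c("zygosity",
                                             "bacterial_vaginosis",
                                             "current_smoking")) {
  records <- validate_metadata(records)
  records <- records[records$ancestry %in% ancestry_levels, , drop = FALSE]
  g <- factor(records$ancestry, levels = ancestry_levels)
  n_strat <- table(g)

  cont <- lapply(intersect(continuous, names(records)), function(v) {
    x <- as.numeric(records[[v]])
    per <- lapply(ancestry_levels, function(a) {
      xa <- x[g == a]
      ok <- xa[!is.na(xa)]
      data.frame(variable = v, ancestry = a, n = length(ok),
                 missing = sum(is.na(xa)),
                 min = if (length(ok)) min(ok) else NA_real_,
                 q1 = if (length(ok)) unname(stats::quantile(ok, 0.25)) else NA_real_,
                 median = if (length(ok)) stats::median(ok) else NA_real_,
                 q3 = if (length(ok)) unname(stats::quantile(ok, 0.75)) else NA_real_,
                 mean = if (length(ok)) mean(ok) else NA_real_,
                 sd = if (length(ok) > 1L) stats::sd(ok) else NA_real_,
                 max = if (length(ok)) max(ok) else NA_real_,
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, per)
    tst <- if (all(tab$n >= 2L))
      welch_t(tab$mean[1L], tab$sd[1L], tab$n[1L],
              tab$mean[2L], tab$sd[2L], tab$n[2L])
    else list(t = NA_real_, df = NA_real_, p_value = NA_real_)
    tab$t <- tst$t
    tab$p_value <- tst$p_value
    tab
  })

  cat_tabs <- lapply(intersect(categorical, names(records)), function(v) {
    x <- records[[v]]
    binary_levels <- if (v == "zygosity") c("MZ", "DZ") else c("no", "yes")
    keep <- !is.na(x) & x %in% binary_levels
    ct <- table(g[keep], factor(x[keep], levels = binary_levels))
    tst <- if (all(rowSums(ct) > 0) && all(colSums(ct) > 0))
      chi2_yates(ct)
    else list(statistic = NA_real_, p_value = NA_real_)
    data.frame(variable = v,
               ancestry = rep(ancestry_levels, each = 2L),
               level = rep(binary_levels, times = 2L),
               count = as.vector(t(ct)),
               chisq = tst$statistic, p_value = tst$p_value,
               stringsAsFactors = FALSE)
  })

  out <- list(continuous = do.call(rbind, cont),
              categorical = do.call(rbind, cat_tabs),
              n = as.vector(n_strat), ancestry_levels = ancestry_levels)
  class(out) <- "cohort_summary"
  out
}

#' @export
print.cohort_summary <- function(x, digits = 3, ...) {
  cat(sprintf("Cohort summary: %s\n",
              paste(sprintf("%s N = %d", x$ancestry_levels, x$n),
                    collapse = ", ")))
  if (!is.null(x$continuous)) {
    cat("\nContinuous variables:\n")
    print(format(x$continuous, digits = digits), row.names = FALSE)
  }
  if (!is.null(x$categorical)) {
    cat("\nCategorical variables:\n")
    print(format(x$categorical, digits = digits), row.names = FALSE)
  }
  invisible(x)
}
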