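# Statistical tests used for the GUV binding assays: Student's unpaired
# t-test (pooled variance, as cited; Welch behind a flag), one-way ANOVA,
# and mean/SD/SEM summaries.

stat_result <- function(test, statistic, df, p_value, tails) {
  if (!is.na(p_value)) stopifnot(p_value >= 0, p_value <= 1)
  structure(list(test = test, statistic = statistic, df = df,
                 p_value = p_value, tails = as.integer(tails)),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g, df = %s, p = %.6g (%d-tailed)\n",
              x$test, x$statistic,
              paste(signif(x$df, 6), collapse = ", "), x$p_value, x$tails))
  invisible(x)
}

#' Student's unpaired two-sample t-test
#'
#' Pooled-variance two-sample t-test with `df = n1 + n2 - 2`, two-tailed by
#' default. When the pooled variance is zero and the means are equal the
#' two-tailed p-value is 1 by convention (0.5 one-tailed, t = 0); zero
#' pooled variance with different means gives p = 0. Set
#' `var_equal = FALSE` for the Welch variant.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @param tails 1 or 2 (default 2; the one-tailed alternative is
#'   `mean(x) > mean(y)`).
#' @param var_equal pooled variance (default `TRUE`).
#' @return object of class `stat_result` with `test`, `statistic`, `df`,
#'   `p_value`, `tails`.
#' @export
unpaired_t_test <- function(x, y, tails = 2L, var_equal = TRUE) {
  stopifnot(length(x) >= 2L, length(y) >= 2L, tails %in% 1:2)
  name <- if (var_equal) "two-sample Student t" else "Welch t"
  if (sd(x) == 0 && sd(y) == 0) {
    df <- length(x) + length(y) - 2L
    if (mean(x) == mean(y))
      return(stat_result(name, 0, df, if (tails == 2L) 1 else 0.5, tails))
    return(stat_result(name, sign(mean(x) - mean(y)) * Inf, df, 0, tails))
  }
  tt <- stats::t.test(x, y, var.equal = var_equal,
                      alternative = if (tails == 2L) "two.sided"
                                    else "greater")
  stat_result(name, unname(tt$statistic), unname(tt$parameter),
              tt$p.value, tails)
}

#' One-way analysis of variance
#'
#' Classic fixed-effects one-way ANOVA: `F = MS_between / MS_within` with
#' `k - 1` and `N - k` degrees of freedom. When all values are identical,
#' F = 0 and p = 1 by convention.
#'
#' @param groups list of >= 2 numeric vectors, each of length >= 2.
#' @return object of class `stat_result` (`df` holds `c(df1, df2)`).
#' @export
one_way_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L,
            all(vapply(groups, length, integer(1L)) >= 2L))
  values <- unlist(groups)
  df1 <- length(groups) - 1L
  df2 <- length(values) - length(groups)
  if (sd(values) == 0)
    return(stat_result("one-way ANOVA", 0, c(df1, df2), 1, 2L))
  g <- factor(rep(seq_along(groups), lengths(groups)))
  ow <- stats::oneway.test(values ~ g, var.equal = TRUE)
  stat_result("one-way ANOVA", unname(ow$statistic),
              unname(ow$parameter), ow$p.value, 2L)
}

#' Mean, sample SD and standard error of the mean
#'
#' @param values numeric vector with `n >= 2`.
#' @return list with `mean`, `sd` (n - 1 denominator), `sem` (SD/sqrt(n)),
#'   `n`.
#' @export
mean_sd_sem <- function(values) {
  n <- length(values)
  if (n < 2L) stopf("SD/SEM undefined for n < 2")
  s <- sd(values)
  list(mean = mean(values), sd = s, sem = s / sqrt(n), n = n)
}
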