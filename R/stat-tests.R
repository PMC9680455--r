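#' Single-factor (one-way) ANOVA
#'
#' Classic fixed-effects one-way analysis of variance, computed from sums of
#' squares: `F = MS_between / MS_within` on `(k - 1, N - k)` degrees of
#' freedom with an upper-tail p-value, matching the spreadsheet
#' "ANOVA: single factor" convention.
#'
#' @param groups List of `>= 2` numeric vectors, each of length `>= 2`.
#' @return A `test_result` list: `statistic`, `p_value`, `df` (length 2),
#'   `test_name`.
#' @examples
#' anova_single_factor(list(c(1, 2, 3), c(2, 3, 4)))$statistic  # 1.5
#' @export
anova_single_factor <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("anova_single_factor: need a list of >= 2 groups", call. = FALSE)
  n_i <- vapply(groups, length, integer(1))
  if (any(n_i < 2))
    stop("anova_single_factor: every group needs >= 2 values", call. = FALSE)
  all_x <- unlist(groups)
  N <- length(all_x)
  k <- length(groups)
  grand <- mean(all_x)
  means <- vapply(groups, mean, numeric(1))
  ssb <- sum(n_i * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- k - 1L
  df2 <- N - k
  if (ssw == 0 && ssb == 0)
    stop("anova_single_factor: undefined F (no variance within or between)",
         call. = FALSE)
  f <- (ssb / df1) / (ssw / df2)
  structure(list(statistic = f,
                 p_value = stats::pf(f, df1, df2, lower.tail = FALSE),
                 df = c(df1, df2),
                 test_name = "ANOVA single factor"),
            class = "test_result")
}

#' Paired two-sample t-test for means
#'
#' `t = mean(d) / (sd(d) / sqrt(n))` on the paired differences
#' `d = a - b`, `df = n - 1`, two-sided p-value from the exact t
#' distribution.
#'
#' @param a,b Numeric vectors of equal length `>= 2`.
#' @return A `test_result` list: `statistic`, `p_value`, `df`, `test_name`.
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b))
    stop("paired_t_test: samples must have equal length", call. = FALSE)
  n <- length(a)
  if (n < 2) stop("paired_t_test: need n >= 2 pairs", call. = FALSE)
  d <- a - b
  sd_d <- stats::sd(d)
  if (sd_d == 0)
    stop("paired_t_test: zero variance of differences (degenerate)",
         call. = FALSE)
  t_stat <- mean(d) / (sd_d / sqrt(n))
  structure(list(statistic = t_stat,
                 p_value = 2 * stats::pt(abs(t_stat), n - 1, lower.tail = FALSE),
                 df = n - 1L,
                 test_name = "t-test: paired two sample for means"),
            class = "test_result")
}
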