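#' One-way analysis of variance
#'
#' Standard fixed-effects decomposition over two or more groups:
#' between-group and within-group sums of squares, mean squares
#' (`MS = SS / df`), `F = MS_between / MS_within`, the upper-tail
#' p-value, and the F-critical value at `alpha`.
#'
#' @param data A data frame with a value column and a group column, or a
#'   list of numeric vectors (one per group).
#' @param value,group Column names when `data` is a data frame
#'   (defaults `"value"` and `"group"`).
#' @param alpha Significance level for F-critical (default 0.05).
#' @return An object of class `mech_anova`; see [tidy()] for the
#'   Source-of-Variation table and [glance()] for a one-row summary.
#' @export
#' @examples
#' one_way_anova(list(a = c(1, 2, 3), b = c(2, 3, 4)))
one_way_anova <- function(data, value = "value", group = "group",
                          alpha = 0.05) {
  if (is.data.frame(data)) {
    groups <- split(data[[value]], data[[group]])
  } else {
    groups <- data
  }
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (length(groups) < 2L || any(lengths(groups) < 2L)) {
    stop_phagemech("need >= 2 groups with >= 2 values each",
                   "phagemech_bad_groups")
  }
  all_x <- unlist(groups, use.names = FALSE)
  gm <- mean(all_x)
  n_i <- lengths(groups)
  m_i <- vapply(groups, mean, numeric(1))
  ss_between <- sum(n_i * (m_i - gm)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2),
                          numeric(1)))
  anova_from_sums(ss_between, length(groups) - 1L,
                  ss_within, sum(n_i) - length(groups), alpha = alpha)
}

#' Complete an ANOVA table from sums of squares
#'
#' Reconstructs the full one-way ANOVA table (MS, F-ratio, p-value,
#' F-critical) from the four printed quantities alone, without raw
#' data.
#'
#' @param ss_between,ss_within Sums of squares.
#' @param df_between,df_within Degrees of freedom (positive integers).
#' @param alpha Significance level for F-critical (default 0.05).
#' @return An object of class `mech_anova`.
#' @export
#' @examples
#' # the two-genome cyclizability comparison, from its printed sums
#' a <- anova_from_sums(17.288, 1, 1823.138, 45197)
#' glance(a)
anova_from_sums <- function(ss_between, df_between, ss_within, df_within,
                            alpha = 0.05) {
  stopifnot(df_between >= 1, df_within >= 1)
  ms_between <- ss_between / df_between
  ms_within <- ss_within / df_within
  f_ratio <- if (ss_between <= 0) 0 else ms_between / ms_within
  structure(
    list(
      ss_between = ss_between, ss_within = ss_within,
      ss_total = ss_between + ss_within,
      df_between = as.integer(df_between), df_within = as.integer(df_within),
      df_total = as.integer(df_between + df_within),
      ms_between = ms_between, ms_within = ms_within,
      f_ratio = f_ratio,
      p_value = pf(f_ratio, df_between, df_within, lower.tail = FALSE),
      f_critical = f_critical(df_between, df_within, alpha),
      alpha = alpha
    ),
    class = "mech_anova"
  )
}

#' Upper-alpha quantile of the F distribution
#'
#' @param df1,df2 Numerator and denominator degrees of freedom.
#' @param alpha Significance level in `(0, 1)`.
#' @return The critical F value.
#' @export
#' @examples
#' f_critical(1, 45197, 0.05)
f_critical <- function(df1, df2, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) {
    stop_phagemech("alpha must lie in (0, 1)", "phagemech_bad_alpha")
  }
  stopifnot(df1 >= 1, df2 >= 1)
  qf(1 - alpha, df1, df2)
}

#' @method tidy mech_anova
#' @export
tidy.mech_anova <- function(x, ...) {
  tibble(
    source = c("Between Groups", "Within Groups", "Total"),
    ss = c(x$ss_between, x$ss_within, x$ss_total),
    df = c(x$df_between, x$df_within, x$df_total),
    ms = c(x$ms_between, x$ms_within, NA_real_),
    f_ratio = c(x$f_ratio, NA_real_, NA_real_),
    p_value = c(x$p_value, NA_real_, NA_real_),
    f_critical = c(x$f_critical, NA_real_, NA_real_)
  )
}

#' @method glance mech_anova
#' @export
glance.mech_anova <- function(x, ...) {
  tibble(f_ratio = x$f_ratio, p_value = x$p_value,
         f_critical = x$f_critical, df_between = x$df_between,
         df_within = x$df_within, alpha = x$alpha)
}

#' @export
print.mech_anova <- function(x, ...) {
  cat("One-way ANOVA\n")
  print(tidy.mech_anova(x))
  invisible(x)
}

#' Mann-Whitney U test
#'
#' Rank-sum two-sample test, two-sided. `U` counts, over all
#' `n1 * n2` cross-pairs, the pairs where the first sample's value
#' exceeds the second's (ties count one half), so `U + U' = n1 * n2`.
#' In `"auto"` mode the p-value is exact (full enumeration of the null
#' rank distribution) when `n1 * n2 <= 400` and no ties are present,
#' and a normal approximation with tie correction and 0.5 continuity
#' correction otherwise.
#'
#' @param sample_a,sample_b Numeric vectors (non-empty).
#' @param mode `"auto"`, `"exact"` or `"approx"`.
#' @return An object of class `mech_mwu` with elements `u_statistic`,
#'   `u_prime`, `p_value`, `method` and `tie_correction_applied`.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
mann_whitney_u <- function(sample_a, sample_b,
                           mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  sample_a <- sample_a[!is.na(sample_a)]
  sample_b <- sample_b[!is.na(sample_b)]
  n1 <- length(sample_a); n2 <- length(sample_b)
  if (n1 == 0L || n2 == 0L) {
    stop_phagemech("both samples must be non-empty", "phagemech_empty_sample")
  }
  r <- rank(c(sample_a, sample_b))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(c(sample_a, sample_b)) > 0L
  use_exact <- switch(mode,
    exact = TRUE,
    approx = FALSE,
    auto = (n1 * n2 <= 400) && !has_ties
  )
  if (use_exact && has_ties) {
    stop_phagemech("exact p-value unavailable with ties",
                   "phagemech_exact_ties")
  }
  if (use_exact) {
    # null distribution of U by enumeration (distribution-counting DP)
    p <- min(1, 2 * min(pwilcox(u, n1, n2),
                        pwilcox(n1 * n2 - u, n1, n2)))
    method <- "exact"
    tie_corr <- FALSE
  } else {
    mu <- n1 * n2 / 2
    nt <- n1 + n2
    ties <- table(c(sample_a, sample_b))
    tie_term <- sum(ties^3 - ties) / (nt * (nt - 1))
    sigma2 <- (n1 * n2 / 12) * ((nt + 1) - tie_term)
    if (sigma2 <= 0) {
      # all values identical: U is exactly its null mean
      p <- 1
    } else {
      z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
      p <- 2 * stats::pnorm(z, lower.tail = FALSE)
      p <- min(1, max(p, .Machine$double.xmin))
    }
    method <- "normal-approximation"
    tie_corr <- has_ties
  }
  structure(
    list(u_statistic = u, u_prime = n1 * n2 - u, n1 = n1, n2 = n2,
         p_value = p, method = method, tie_correction_applied = tie_corr),
    class = "mech_mwu"
  )
}

#' @method tidy mech_mwu
#' @export
tidy.mech_mwu <- function(x, ...) {
  tibble(u_statistic = x$u_statistic, u_prime = x$u_prime,
         p_value = x$p_value, method = x$method,
         tie_correction_applied = x$tie_correction_applied,
         n1 = x$n1, n2 = x$n2)
}

#' @method glance mech_mwu
#' @export
glance.mech_mwu <- function(x, ...) tidy.mech_mwu(x, ...)

#' @export
print.mech_mwu <- function(x, ...) {
  cat("Mann-Whitney U test (two-sided, ", x$method, ")\n", sep = "")
  cat("U =", x$u_statistic, " U' =", x$u_prime, " p =",
      format(x$p_value), "\n")
  invisible(x)
}

#' Tukey boxplot summary
#'
#' Quartiles by linear interpolation of order statistics
#' (`quantile` type 7); whiskers reach the most extreme values within
#' `1.5 * IQR` of the quartiles; values beyond the whiskers are listed
#' as outliers.
#'
#' @param values Numeric vector with at least 4 non-missing values.
#' @return A list of class `boxplot_stats` with `median`, `q1`, `q3`,
#'   `iqr`, `whisker_low`, `whisker_high` and `outliers`.
#' @export
#' @examples
#' boxplot_stats(c(1:8, 100))
boxplot_stats <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 4L) {
    stop_phagemech("need at least 4 values for boxplot statistics",
                   "phagemech_too_short")
  }
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[3] + 1.5 * iqr
  inside <- values[values >= lo & values <= hi]
  structure(
    list(median = q[2], q1 = q[1], q3 = q[3], iqr = iqr,
         whisker_low = min(inside), whisker_high = max(inside),
         outliers = sort(values[values < lo | values > hi])),
    class = "boxplot_stats"
  )
}

#' @method tidy boxplot_stats
#' @export
tidy.boxplot_stats <- function(x, ...) {
  tibble(median = x$median, q1 = x$q1, q3 = x$q3, iqr = x$iqr,
         whisker_low = x$whisker_low, whisker_high = x$whisker_high,
         n_outliers = length(x$outliers))
}
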