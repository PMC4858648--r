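#' Pooled-variance two-sample t-test on raw samples
#'
#' Two-sided Student's t-test for the equality of means assuming equal
#' variances (df = n_a + n_b - 2), the test used for the per-feature
#' group comparisons. Delegates to [stats::t.test()] with
#' `var.equal = TRUE` and repackages the result with the group summaries.
#'
#' @param sample_a,sample_b numeric vectors, each of length >= 2.
#' @return A list with `t_stat`, `df`, `p_value`, `group_means`,
#'   `group_sds`, `group_ns`, `degenerate`.
#' @export
ttest_pooled <- function(sample_a, sample_b) {
  if (length(sample_a) < 2L || length(sample_b) < 2L)
    stop("each sample needs n >= 2", call. = FALSE)
  ms <- c(mean(sample_a), mean(sample_b))
  sds <- c(stats::sd(sample_a), stats::sd(sample_b))
  ns <- c(length(sample_a), length(sample_b))
  if (all(sds == 0)) {
    # zero pooled variance: t undefined unless the means agree too
    if (ms[1] == ms[2])
      return(list(t_stat = 0, df = sum(ns) - 2, p_value = 1,
                  group_means = ms, group_sds = sds, group_ns = ns,
                  degenerate = FALSE))
    return(list(t_stat = Inf * sign(ms[1] - ms[2]), df = sum(ns) - 2,
                p_value = 0, group_means = ms, group_sds = sds,
                group_ns = ns, degenerate = TRUE))
  }
  tt <- stats::t.test(sample_a, sample_b, var.equal = TRUE)
  list(t_stat = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, group_means = ms, group_sds = sds,
       group_ns = ns, degenerate = FALSE)
}

#' Pooled-variance two-sample t-test from summary statistics
#'
#' Computes the same test as [ttest_pooled()] from group means, standard
#' deviations and sizes only, so printed per-group summaries can be
#' re-tested without the raw data.
#'
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b group summaries; `n >= 2`,
#'   `sd >= 0`.
#' @return Same shape as [ttest_pooled()].
#' @export
ttest_from_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  if (n_a < 2L || n_b < 2L) stop("each group needs n >= 2", call. = FALSE)
  if (sd_a < 0 || sd_b < 0) stop("standard deviations must be >= 0", call. = FALSE)
  df <- n_a + n_b - 2
  sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / df
  if (sp2 == 0) {
    if (mean_a == mean_b)
      return(list(t_stat = 0, df = df, p_value = 1,
                  group_means = c(mean_a, mean_b), group_sds = c(sd_a, sd_b),
                  group_ns = c(n_a, n_b), degenerate = FALSE))
    return(list(t_stat = Inf * sign(mean_a - mean_b), df = df, p_value = 0,
                group_means = c(mean_a, mean_b), group_sds = c(sd_a, sd_b),
                group_ns = c(n_a, n_b), degenerate = TRUE))
  }
  t <- (mean_a - mean_b) / sqrt(sp2 * (1 / n_a + 1 / n_b))
  list(t_stat = t, df = df, p_value = 2 * stats::pt(-abs(t), df),
       group_means = c(mean_a, mean_b), group_sds = c(sd_a, sd_b),
       group_ns = c(n_a, n_b), degenerate = FALSE)
}

#' Per-feature univariate group comparison table
#'
#' Computes, for each texture feature, the per-class mean and SD and the
#' pooled two-sample t-test p-value comparing expected vs non-expected
#' ROIs. The 20 p-values are reported uncorrected for multiplicity.
#'
#' @param table a feature table (see [extract_feature_table()] /
#'   [generate_feature_table()]) with a `label` column.
#' @param features feature columns to test; default all 20.
#' @return data.frame: `feature`, `mean_e`, `sd_e`, `mean_ne`, `sd_ne`,
#'   `t_stat`, `p_value`.
#' @export
univariate_table <- function(table, features = texture_feature_names) {
  stopifnot(all(features %in% names(table)), "label" %in% names(table))
  e <- table[table$label == "E", , drop = FALSE]
  ne <- table[table$label == "NE", , drop = FALSE]
  rows <- lapply(features, function(f) {
    tt <- ttest_pooled(e[[f]], ne[[f]])
    data.frame(feature = f,
               mean_e = tt$group_means[1], sd_e = tt$group_sds[1],
               mean_ne = tt$group_means[2], sd_ne = tt$group_sds[2],
               t_stat = tt$t_stat, p_value = tt$p_value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pearson correlation matrix of selected features
#'
#' @param table a feature table.
#' @param features feature columns; default all 20.
#' @return Correlation matrix with unit diagonal; entries involving a
#'   zero-variance feature are NA and the affected features are listed in
#'   attribute `zero_variance`.
#' @export
feature_correlations <- function(table, features = texture_feature_names) {
  stopifnot(all(features %in% names(table)))
  X <- as.matrix(table[features])
  sds <- apply(X, 2, stats::sd)
  flat <- names(sds)[sds == 0]
  R <- suppressWarnings(stats::cor(X))
  diag(R) <- 1
  attr(R, "zero_variance") <- flat
  R
}

#' Power of the pooled two-sample t-test across sample sizes
#'
#' Exact power via the noncentral t distribution: with n subjects per
#' group, effect `delta` and common SD `sd`, the noncentrality is
#' delta/sd * sqrt(n/2) and power is the two-sided rejection probability
#' at level `alpha` with 2n - 2 degrees of freedom. A zero effect returns
#' power exactly alpha.
#'
#' @param delta raw mean difference.
#' @param sd common standard deviation (> 0).
#' @param alpha significance level in (0, 1); default 0.05.
#' @param n_per_group integer vector of per-group sample sizes (>= 2).
#' @return data.frame with `n_per_group`, `n_total`, `power`.
#' @export
power_curve <- function(delta, sd, alpha = 0.05, n_per_group = c(5, 10, 20, 50, 100)) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("`alpha` must lie strictly in (0, 1)", call. = FALSE)
  if (sd <= 0) stop("`sd` must be > 0", call. = FALSE)
  n_per_group <- as.integer(n_per_group)
  if (any(n_per_group < 2L)) stop("need n >= 2 per group", call. = FALSE)
  pw <- vapply(n_per_group, function(n) {
    df <- 2 * n - 2
    ncp <- abs(delta) / sd * sqrt(n / 2)
    tcrit <- stats::qt(1 - alpha / 2, df)
    stats::pt(-tcrit, df, ncp) + stats::pt(tcrit, df, ncp, lower.tail = FALSE)
  }, numeric(1))
  data.frame(n_per_group = n_per_group, n_total = 2L * n_per_group, power = pw)
}
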