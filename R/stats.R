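#' Normality-gated two-group comparison
#'
#' Runs Shapiro-Wilk on each sample; if either rejects normality at
#' `alpha_normality`, a two-sided Mann-Whitney U (Wilcoxon rank-sum) test is
#' reported, otherwise a two-sided independent-samples t-test. The chosen
#' test is recorded so every table row can state which was used.
#'
#' @param values_a,values_b Numeric samples (n >= 3 each; NAs dropped).
#' @param alpha_normality Normality gate level (default 0.05).
#' @return Data frame of class `stat_result`: `test_name`, `statistic`,
#'   `p_value`, `effect` (mean difference a - b), `effect_direction`,
#'   `n_a`, `n_b`, and the two Shapiro p-values.
#' @export
compare_groups <- function(values_a, values_b, alpha_normality = 0.05) {
  a <- values_a[is.finite(values_a)]
  b <- values_b[is.finite(values_b)]
  if (length(a) < 3 || length(b) < 3)
    stop("each sample must contain at least 3 finite values")
  sw_a <- stats::shapiro.test(a)$p.value
  sw_b <- stats::shapiro.test(b)$p.value
  nonparam <- sw_a < alpha_normality || sw_b < alpha_normality
  if (nonparam) {
    ht <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
    test_name <- "mann-whitney-u"
  } else {
    ht <- stats::t.test(a, b, var.equal = FALSE)
    test_name <- "t-test"
  }
  eff <- mean(a) - mean(b)
  out <- data.frame(test_name = test_name,
                    statistic = unname(ht$statistic),
                    p_value = ht$p.value,
                    effect = eff,
                    effect_direction = if (eff > 0) "a>b" else if (eff < 0)
                      "a<b" else "a=b",
                    n_a = length(a), n_b = length(b),
                    shapiro_p_a = sw_a, shapiro_p_b = sw_b)
  class(out) <- c("stat_result", class(out))
  out
}

#' Spearman rank correlation
#'
#' Rank correlation with midrank tie handling and a two-sided p-value
#' (asymptotic, matching the large-sample treatment of tied pipelines).
#'
#' @param x,y Paired numeric vectors (pairs with any NA dropped; n >= 4).
#' @return Data frame of class `stat_result` with `rho`, `p_value`,
#'   `n_pairs`.
#' @export
spearman_corr <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4) stop("need at least 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: rank correlation undefined")
  ht <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  out <- data.frame(test_name = "spearman",
                    rho = unname(ht$estimate),
                    p_value = ht$p.value,
                    n_pairs = length(x))
  class(out) <- c("stat_result", class(out))
  out
}

#' Power of the two-sided two-sample t-test
#'
#' Computed from the noncentral t distribution: with `n` per group and
#' standardized effect `d`, the noncentrality is `d * sqrt(n / 2)` on
#' `2n - 2` degrees of freedom.
#'
#' @param n_per_group Sample size per group (>= 2).
#' @param effect_size_d Standardized mean difference (Cohen's d, >= 0).
#' @param alpha Two-sided type-I error rate (default 0.05).
#' @return Power in [0, 1].
#' @export
power_two_sample <- function(n_per_group, effect_size_d, alpha = 0.05) {
  if (n_per_group < 2) stop("n_per_group must be >= 2")
  if (effect_size_d < 0) stop("effect size must be >= 0")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  df <- 2 * n_per_group - 2
  ncp <- effect_size_d * sqrt(n_per_group / 2)
  qcrit <- stats::qt(1 - alpha / 2, df)
  stats::pt(-qcrit, df, ncp) + (1 - stats::pt(qcrit, df, ncp))
}
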