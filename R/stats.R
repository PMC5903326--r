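# Chance-level and comparison statistics.

#' Practical level of chance
#'
#' Upper confidence bound of a random classifier's accuracy with a finite
#' number of evaluated decisions, using the adjusted proportion
#' `p~ = (k + 2) / (n + 4)` and its normal-quantile interval:
#' `100 * (p~ + z_{1 - alpha/2} * sqrt(p~ (1 - p~) / (n + 4)))`.
#' A %CA above this bound is better than chance at level `alpha`. At the
#' study scale (120 trials per class pooled over both classes, n = 240) the
#' bound is 56.27%; it decreases towards 50% as n grows.
#'
#' @param n Total number of evaluated decisions (both classes pooled).
#' @param k Expected number correct under random classification
#'   (default `n / 2`).
#' @param alpha Significance level.
#' @return The bound as a percentage.
#' @export
#' @examples
#' practical_chance_level(n = 240)
practical_chance_level <- function(n = 240, k = n / 2, alpha = 0.05) {
  if (n < 1 || alpha <= 0 || alpha >= 1) abort("need n >= 1 and 0 < alpha < 1")
  p <- (k + 2) / (n + 4)
  z <- qnorm(1 - alpha / 2)
  100 * (p + z * sqrt(p * (1 - p) / (n + 4)))
}

#' Compare two sets of fold-level accuracies
#'
#' Two-sided Mann-Whitney U (Wilcoxon rank-sum) test, as used to compare the
#' filter-bank + swarm pipeline with the broadband CSP baseline over the 100
#' cross-validation %CA values.
#'
#' @param ca_a,ca_b Numeric accuracy samples.
#' @param alpha Significance level.
#' @return One-row tibble: `u_statistic`, `p_value`, `significant`.
#' @export
compare_methods <- function(ca_a, ca_b, alpha = 0.05) {
  if (!length(ca_a) || !length(ca_b)) abort("both samples must be non-empty")
  wt <- suppressWarnings(wilcox.test(ca_a, ca_b, exact = FALSE))
  tibble::tibble(
    u_statistic = unname(wt$statistic),
    p_value = wt$p.value,
    significant = wt$p.value < alpha
  )
}

#' Lilliefors-corrected Kolmogorov-Smirnov normality check
#'
#' @param x Numeric sample, `n >= 4`.
#' @return One-row tibble: `statistic`, `p_value` (`NA` with a warning for a
#'   constant sample, where the test is degenerate).
#' @export
normality_check <- function(x) {
  if (length(x) < 4) abort("normality check needs n >= 4")
  if (stats::sd(x) == 0) {
    warn("constant sample: normality test degenerate")
    return(tibble::tibble(statistic = NA_real_, p_value = NA_real_))
  }
  lt <- nortest::lillie.test(x)
  tibble::tibble(statistic = unname(lt$statistic), p_value = lt$p.value)
}

#' Paired comparison of offline and online accuracies
#'
#' Thin paired t-test utility for per-subject offline vs online %CA.
#'
#' @param offline,online Equal-length per-subject accuracy vectors.
#' @param alpha Significance level.
#' @return One-row tibble: `t_statistic`, `df`, `p_value`, `significant`,
#'   `mean_difference`.
#' @export
compare_offline_online <- function(offline, online, alpha = 0.05) {
  if (length(offline) != length(online)) abort("paired samples must have equal length")
  tt <- t.test(offline, online, paired = TRUE)
  tibble::tibble(
    t_statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    significant = tt$p.value < alpha,
    mean_difference = unname(tt$estimate)
  )
}
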