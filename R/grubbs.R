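#' Grubbs outlier test for one designated datum against a control ensemble
#'
#' Pools the test value with its `N - 1` controls and computes the Grubbs
#' statistic `G = |test - mean| / sd` (sd over all `N` values, `N - 1`
#' denominator). `G` is compared against the critical value
#' `G_crit(N, a) = ((N - 1)/sqrt(N)) * sqrt(t^2 / (N - 2 + t^2))`, where `t`
#' is an upper quantile of the t distribution on `N - 2` degrees of freedom.
#'
#' With the defaults (`twoSided = TRUE`, `bonferroni = FALSE`) the t quantile
#' is taken at `alpha/2`, which makes the test exact at level `alpha` for a
#' *designated* datum — here, the real-genome bin count, which is fixed in
#' advance rather than selected as the most extreme of the pooled values.
#' `bonferroni = TRUE` divides the quantile level by `N` in addition, giving
#' the classic tabulated Grubbs critical values for the maximum-outlier test;
#' `twoSided = FALSE` gives the corresponding one-sided forms. The direction
#' (enrichment when the test count exceeds the pooled mean, deficiency when
#' below) is reported separately from the significance level.
#'
#' @param testCount the designated test value (real-genome bin count).
#' @param controlCounts numeric vector of >= 3 control values.
#' @param alphas significance levels to try, most lenient first after
#'   sorting; the reported level is the smallest alpha at which `G` exceeds
#'   the critical value.
#' @param twoSided use the `alpha/2` quantile (size-`alpha` test on
#'   `|deviation|`).
#' @param bonferroni additionally divide the quantile level by `N` (classic
#'   max-outlier Grubbs critical values).
#' @return one-row `data.frame` with columns `g` (the Grubbs statistic,
#'   0 when the pooled sd is 0), `direction` (`"enrichment"`,
#'   `"deficiency"` or `"none"`) and `pLevel` (smallest significant alpha,
#'   `NA` when not significant).
#' @examples
#' grubbsCall(10, rep(0, 100))   # G = 9.9504, enrichment at alpha = 0.001
#' @export
grubbsCall <- function(testCount, controlCounts, alphas = c(0.01, 0.001),
                       twoSided = TRUE, bonferroni = FALSE) {
  if (length(controlCounts) < 3L) stop("need at least 3 control values")
  x <- c(testCount, controlCounts)
  n <- length(x)
  m <- mean(x)
  s <- sd(x)
  if (s == 0) {
    return(data.frame(g = 0, direction = "none", pLevel = NA_real_,
                      stringsAsFactors = FALSE))
  }
  g <- abs(testCount - m) / s
  alphas <- sort(alphas, decreasing = TRUE)
  sig <- alphas[g > grubbsCritical(n, alphas, twoSided = twoSided,
                                   bonferroni = bonferroni)]
  level <- if (length(sig)) min(sig) else NA_real_
  direction <- if (is.na(level)) "none"
               else if (testCount > m) "enrichment" else "deficiency"
  data.frame(g = g, direction = direction, pLevel = level,
             stringsAsFactors = FALSE)
}

#' @rdname grubbsCall
#' @param n pooled sample size (controls + 1).
#' @param alpha significance level(s).
#' @export
grubbsCritical <- function(n, alpha, twoSided = TRUE, bonferroni = FALSE) {
  if (n < 3L) stop("Grubbs critical values need n >= 3")
  a <- alpha
  if (twoSided) a <- a / 2
  if (bonferroni) a <- a / n
  t <- qt(1 - a, df = n - 2)
  ((n - 1) / sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))
}
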