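# Distribution summaries and model comparisons.

#' Summarise a sensitivity distribution
#'
#' Quantiles use linear interpolation of the empirical CDF (R's default
#' type-7 estimator). The 90\% data range is the distance between the 5th
#' and 95th percentiles and serves as the variability measure; the notch
#' interval of the median is `median +- 1.57 IQR / sqrt(n)`.
#'
#' @param values numeric sample (n >= 2).
#' @return a [DistributionSummary-class].
#' @examples
#' summarizeDistribution(1:5)
#' @export
summarizeDistribution <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2) stop("at least two values are required")
  q <- unname(quantile(values, c(0.05, 0.25, 0.5, 0.75, 0.95), type = 7))
  iqr <- q[4] - q[2]
  notch <- 1.57 * iqr / sqrt(n)
  new("DistributionSummary", n = n, median = q[3], q1 = q[2], q3 = q[4],
      iqr = iqr, p5 = q[1], p95 = q[5], range90 = q[5] - q[1],
      medianCI = c(q[3] - notch, q[3] + notch))
}

setMethod("show", "DistributionSummary", function(object) {
  cat(sprintf(
    "DistributionSummary (n = %d)\n  median %.4g [notch %.4g, %.4g]\n",
    as.integer(object@n), object@median, object@medianCI[1],
    object@medianCI[2]))
  cat(sprintf("  IQR %.4g (q1 %.4g, q3 %.4g)\n", object@iqr, object@q1,
              object@q3))
  cat(sprintf("  90%% range %.4g (p5 %.4g, p95 %.4g)\n", object@range90,
              object@p5, object@p95))
  invisible(NULL)
})

#' Compare two sensitivity distributions
#'
#' Two-sided Mann-Whitney-U (Wilcoxon rank-sum) test; exact for small
#' tie-free samples, normal approximation with tie and continuity correction
#' otherwise.
#'
#' @param a,b numeric samples.
#' @return the two-sided p-value.
#' @export
compareDistributions <- function(a, b) {
  if (!length(a) || !length(b)) stop("both samples must be nonempty")
  wilcox.test(a, b, alternative = "two.sided", exact = NULL)$p.value
}

#' Fold change between two distribution summaries
#'
#' @param a,b [DistributionSummary-class] objects.
#' @param statistic `"median"`, `"range90"`, or `"iqr"`.
#' @return the ratio of the chosen statistic, `a / b`.
#' @export
foldChange <- function(a, b, statistic = c("median", "range90", "iqr")) {
  statistic <- match.arg(statistic)
  num <- slot(a, statistic)
  den <- slot(b, statistic)
  if (den == 0) stop("denominator statistic is zero")
  num / den
}
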