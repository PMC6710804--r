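#' Paired t-test for device differences
#'
#' Standard paired t on the differences `comparator - reference`. When the
#' differences have zero variance, the test is degenerate: the p-value is
#' defined as 1 when the mean difference is also 0, otherwise an error is
#' raised.
#'
#' @param reference,comparator Paired numeric vectors (length >= 2);
#'   differences are taken as `comparator - reference`.
#' @return List with `t`, `df`, `p_value`, `mean_difference`.
#' @export
paired_t <- function(reference, comparator) {
  if (length(reference) != length(comparator)) stop("paired_t: unequal pair lengths")
  if (length(reference) < 2) stop("paired_t: need at least 2 pairs")
  d <- comparator - reference
  if (sd(d) == 0) {
    if (mean(d) == 0)
      return(list(t = 0, df = length(d) - 1, p_value = 1, mean_difference = 0))
    stop("paired_t: zero variance of differences with nonzero mean")
  }
  tt <- t.test(comparator, reference, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_difference = unname(tt$estimate))
}

#' Bland-Altman agreement analysis
#'
#' Differences are `comparator - reference` (for device comparisons the
#' comparator plays the second-device role so reported differences follow
#' the "comparator minus reference" convention). 95% limits of agreement
#' use the 1.96 multiplier exactly; the CI of the mean difference uses the
#' small-sample t quantile.
#'
#' @inheritParams paired_t
#' @return An `agreement_report`: `n`, `mean_difference`, `sd_difference`,
#'   `loa_lower`, `loa_upper`, `ci_mean_difference` (length-2),
#'   `t_statistic`, `p_value`, `icc`, and `data` (pair means/differences,
#'   for plotting).
#' @export
bland_altman <- function(reference, comparator) {
  if (length(reference) != length(comparator)) stop("bland_altman: unequal pair lengths")
  n <- length(reference)
  if (n < 2) stop("bland_altman: need at least 2 pairs")
  d <- comparator - reference
  m <- mean(d)
  s <- sd(d)
  tt <- tryCatch(paired_t(reference, comparator),
                 error = function(e) list(t = NA_real_, p_value = NA_real_))
  icc <- tryCatch({
    icc_oneway(repeatability_study(data.frame(
      subject = rep(seq_len(n), 2), observer = "device",
      replicate = rep(1:2, each = n), parameter = "x",
      value = c(reference, comparator))), "x")
  }, error = function(e) NA_real_)
  structure(list(n = n, mean_difference = m, sd_difference = s,
                 loa_lower = m - 1.96 * s, loa_upper = m + 1.96 * s,
                 ci_mean_difference = m + c(-1, 1) * qt(0.975, n - 1) * s / sqrt(n),
                 t_statistic = tt$t, p_value = tt$p_value, icc = icc,
                 data = data.frame(mean = (reference + comparator) / 2,
                                   difference = d)),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> n = %d pairs\n", x$n))
  cat(sprintf("  mean difference %.4f +/- %.4f | 95%% LoA (%.3f, %.3f)\n",
              x$mean_difference, x$sd_difference, x$loa_lower, x$loa_upper))
  cat(sprintf("  95%% CI of mean (%.4f, %.4f) | paired t = %.3f, p = %.4g | ICC %.3f\n",
              x$ci_mean_difference[1], x$ci_mean_difference[2],
              x$t_statistic, x$p_value, x$icc))
  invisible(x)
}

#' Bland-Altman plot
#'
#' Scatter of per-pair differences against per-pair means with the mean
#' difference and the 95% limits of agreement drawn as horizontal lines.
#'
#' @param report An [bland_altman()] report.
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
bland_altman_plot <- function(report, title = NULL) {
  stopifnot(inherits(report, "agreement_report"))
  ggplot2::ggplot(report$data, ggplot2::aes(x = mean, y = difference)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = report$mean_difference, colour = "blue") +
    ggplot2::geom_hline(yintercept = c(report$loa_lower, report$loa_upper),
                        colour = "red", linetype = "dashed") +
    ggplot2::labs(x = "Mean of paired measurements",
                  y = "Difference (comparator - reference)",
                  title = title) +
    ggplot2::theme_minimal()
}
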