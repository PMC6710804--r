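#' Construct/validate a long-format repeatability study table
#'
#' @param df Data frame with columns `subject`, `observer`, `replicate`,
#'   `parameter`, `value` and optionally `unit`.
#' @return The validated data frame with class `repeatability_study`.
#' @export
repeatability_study <- function(df) {
  need <- c("subject", "observer", "replicate", "parameter", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("repeatability_study: missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!is.numeric(df$value)) stop("repeatability_study: 'value' must be numeric")
  if (!"unit" %in% names(df)) df$unit <- NA_character_
  class(df) <- unique(c("repeatability_study", class(df)))
  df
}

# One-way ANOVA components with subject as the grouping factor.
# Returns MSB, MSW, n_subjects, k (harmonic-mean replicates), grand mean, sd.
anova_components <- function(study, parameter, observer = NULL) {
  d <- study[study$parameter == parameter, , drop = FALSE]
  if (!is.null(observer)) d <- d[d$observer == observer, , drop = FALSE]
  if (nrow(d) == 0) stop("no measurements for parameter '", parameter, "'")
  n_i <- table(d$subject)
  if (length(n_i) < 2) stop("within_subject_sd/ICC need at least 2 subjects")
  if (sum(n_i) - length(n_i) < 1)
    stop("within-subject variance undefined: every subject has a single replicate")
  fit <- aov(value ~ factor(subject), data = d)
  sm <- summary(fit)[[1]]
  list(msb = sm[["Mean Sq"]][1], msw = sm[["Mean Sq"]][2],
       n_subjects = length(n_i),
       k = length(n_i) / sum(1 / as.numeric(n_i)),  # harmonic mean
       mean = mean(d$value), sd = sd(d$value))
}

#' Within-subject standard deviation (Sw)
#'
#' Square root of the residual mean square of the one-way ANOVA with subject
#' as the factor: the pooled SD of replicate measurements on the same eye.
#'
#' @param study A [repeatability_study()] table.
#' @param parameter Parameter name to analyse (e.g. `"axl"`).
#' @param observer Optional observer id to restrict to (intraobserver
#'   repeatability); `NULL` pools all rows.
#' @return Sw in the parameter's units.
#' @export
within_subject_sd <- function(study, parameter, observer = NULL) {
  sqrt(anova_components(study, parameter, observer)$msw)
}

#' Test-retest repeatability
#'
#' `TRT = 2.77 * Sw`: the interval within which 95% of differences between
#' two repeated measurements are expected to lie (2.77 is 1.96 * sqrt(2)).
#'
#' @param sw Within-subject SD (>= 0).
#' @return TRT in the same units.
#' @export
trt <- function(sw) {
  if (any(sw < 0)) stop("trt: sw must be >= 0")
  2.77 * sw
}

#' Within-subject coefficient of variation
#'
#' `CoV = 100 * Sw / mean`, in percent.
#'
#' @param sw Within-subject SD.
#' @param mean Mean of the measurements (> 0).
#' @return CoV in percent.
#' @export
cov_percent <- function(sw, mean) {
  if (any(mean <= 0)) stop("cov_percent: mean must be > 0")
  100 * sw / mean
}

#' One-way random-effects single-measure ICC
#'
#' `ICC(1,1) = (MSB - MSW) / (MSB + (k - 1) * MSW)` from the one-way ANOVA
#' over subjects, with `k` the (harmonic-mean, for unbalanced designs)
#' number of replicates per subject. Consistent with the one-way model
#' underlying [within_subject_sd()].
#'
#' @inheritParams within_subject_sd
#' @return ICC in `[-1, 1]`.
#' @export
icc_oneway <- function(study, parameter, observer = NULL) {
  a <- anova_components(study, parameter, observer)
  if (a$msb <= .Machine$double.eps && a$msw <= .Machine$double.eps)
    stop("icc_oneway: total variance is zero, ICC undefined")
  (a$msb - a$msw) / (a$msb + (a$k - 1) * a$msw)
}

#' Precision report: mean, Sw, TRT, CoV and ICC
#'
#' The full repeatability panel for one parameter (one table row of a
#' repeatability analysis): mean +/- SD of all measurements, within-subject
#' SD, test-retest repeatability, coefficient of variation and one-way ICC.
#'
#' @inheritParams within_subject_sd
#' @return An object of class `precision_report` with fields `parameter`,
#'   `observer`, `n_subjects`, `k_replicates`, `mean`, `sd`, `sw`, `trt`,
#'   `cov_percent`, `icc`, `unit`.
#' @export
precision_report <- function(study, parameter, observer = NULL) {
  a <- anova_components(study, parameter, observer)
  sw <- sqrt(a$msw)
  unit <- unique(study$unit[study$parameter == parameter])
  structure(list(parameter = parameter, observer = observer,
                 n_subjects = a$n_subjects, k_replicates = a$k,
                 mean = a$mean, sd = a$sd, sw = sw, trt = trt(sw),
                 cov_percent = cov_percent(sw, a$mean),
                 icc = icc_oneway(study, parameter, observer),
                 unit = unit[!is.na(unit)][1] %||% NA_character_),
            class = "precision_report")
}

#' @export
print.precision_report <- function(x, ...) {
  cat(sprintf("<precision_report> %s%s (n=%d, k=%.2g)\n", x$parameter,
              if (!is.null(x$observer)) paste0(", observer ", x$observer) else "",
              x$n_subjects, x$k_replicates))
  cat(sprintf("  mean %.2f +/- %.2f %s | Sw %.4g | TRT %.4g | CoV %.2f%% | ICC %.3f\n",
              x$mean, x$sd, x$unit %||% "", x$sw, x$trt, x$cov_percent, x$icc))
  invisible(x)
}

#' Interobserver study from first readings
#'
#' Reshapes a repeatability table for interobserver reproducibility: keeps
#' only each observer's first reading per subject and treats observers as
#' the replicate dimension.
#'
#' @param study A [repeatability_study()] table.
#' @return A `repeatability_study` where `replicate` indexes observers.
#' @export
first_readings_study <- function(study) {
  keep <- do.call(rbind, lapply(split(study, list(study$subject, study$observer,
                                                  study$parameter), drop = TRUE),
                                function(g) g[which.min(g$replicate), , drop = FALSE]))
  keep$replicate <- match(keep$observer, sort(unique(keep$observer)))
  keep$observer <- "pooled"
  rownames(keep) <- NULL
  repeatability_study(keep)
}
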