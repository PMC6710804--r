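# Cohort parameter distributions (means / between-subject SD) and the
# replicate measurement-noise scale of the instrument. Healthy values match
# a 50-eye repeatability cohort; cataract values a 115-eye surgical cohort.
cohort_defaults <- function(cohort = c("healthy", "cataract")) {
  cohort <- match.arg(cohort)
  if (cohort == "healthy") {
    list(means = c(axl = 23.93, acd = 3.59, lt = 4.02, cct = 555.44),
         between_sd = c(axl = 0.80, acd = 0.28, lt = 0.22, cct = 26.56),
         within_sd = c(axl = 0.01, acd = 0.01, lt = 0.02, cct = 2.0),
         opacity = NULL)
  } else {
    list(means = c(axl = 23.81, acd = 3.10, lt = 4.64, cct = 546.5),
         between_sd = c(axl = 1.89, acd = 0.41, lt = 0.35, cct = 33.1),
         within_sd = c(axl = 0.01, acd = 0.01, lt = 0.02, cct = 2.0),
         opacity = list(attenuation_range = c(0.3, 0.95)))
  }
}

#' Define a synthetic study protocol
#'
#' Describes a repeatability or device-agreement study on a synthetic
#' cohort: how many eyes, observers and replicates, which cohort parameter
#' distributions to draw ground truth from, and the per-replicate
#' measurement noise (which models a full measurement including realignment
#' between replicates).
#'
#' @param n_subjects Number of eyes.
#' @param observers Number of observers.
#' @param replicates Replicates per observer per eye.
#' @param cohort `"healthy"` or `"cataract"` (sets default means/SDs).
#' @param means,between_sd Named per-parameter cohort mean and
#'   between-subject SD (`axl`, `acd`, `lt` in mm; `cct` in um). Defaults
#'   from `cohort`.
#' @param within_sd Named per-parameter SD of a complete replicate
#'   measurement (includes realignment); same units.
#' @param mode `"gaussian"` draws replicate values as truth + Gaussian
#'   noise at `within_sd` (the measurement-level model); `"simulate"` runs
#'   the full [measure_biometry()] pipeline per replicate (slow, for small
#'   cohorts).
#' @param parameters Parameters to record.
#' @param realign_between_replicates Kept in the manifest; in `gaussian`
#'   mode realignment is what `within_sd` models, in `simulate` mode each
#'   replicate re-seeds the jitter.
#' @param seed Integer seed for the whole study.
#' @return An object of class `study_protocol`.
#' @export
study_protocol <- function(n_subjects = 50, observers = 2, replicates = 3,
                           cohort = "healthy", means = NULL, between_sd = NULL,
                           within_sd = NULL, mode = c("gaussian", "simulate"),
                           parameters = c("axl", "acd", "lt", "cct"),
                           realign_between_replicates = TRUE, seed = 1L) {
  if (replicates < 1) stop("study_protocol: replicates must be >= 1")
  if (n_subjects < 2) stop("study_protocol: need at least 2 subjects")
  defs <- cohort_defaults(cohort)
  structure(list(n_subjects = n_subjects, observers = observers,
                 replicates = replicates, cohort = cohort,
                 means = utils::modifyList(as.list(defs$means), as.list(means %||% list())),
                 between_sd = utils::modifyList(as.list(defs$between_sd),
                                                as.list(between_sd %||% list())),
                 within_sd = utils::modifyList(as.list(defs$within_sd),
                                               as.list(within_sd %||% list())),
                 opacity = defs$opacity, mode = match.arg(mode),
                 parameters = parameters,
                 realign_between_replicates = realign_between_replicates,
                 seed = as.integer(seed)),
            class = "study_protocol")
}

# Draw per-subject ground-truth parameters, resampling the rare draws that
# violate anatomy (ACD + LT must leave room for cornea and vitreous).
draw_cohort_truth <- function(protocol) {
  n <- protocol$n_subjects
  draw_one <- function(p) rnorm(n, protocol$means[[p]], protocol$between_sd[[p]])
  tr <- data.frame(subject = seq_len(n), axl = draw_one("axl"),
                   acd = draw_one("acd"), lt = draw_one("lt"),
                   cct = draw_one("cct"))
  bad <- function(tr) tr$cct / 1000 >= tr$acd - 0.5 | tr$acd + tr$lt >= tr$axl - 5 |
    tr$cct < 300 | tr$acd < 1.2 | tr$lt < 2
  for (it in 1:100) {
    b <- which(bad(tr))
    if (!length(b)) break
    for (p in c("axl", "acd", "lt", "cct"))
      tr[[p]][b] <- rnorm(length(b), protocol$means[[p]], protocol$between_sd[[p]])
  }
  if (!is.null(protocol$opacity)) {
    tr$opacity_attenuation <- runif(n, protocol$opacity$attenuation_range[1],
                                    protocol$opacity$attenuation_range[2])
  }
  tr
}

phantom_from_truth <- function(row, config = sim_config()) {
  spec <- healthy_eye_spec(axl_mm = row$axl, acd_mm = row$acd, lt_mm = row$lt,
                           cct_um = row$cct, indices = config$indices)
  if (!is.null(row$opacity_attenuation) && !is.na(row$opacity_attenuation)) {
    spec$pathology$opacity_attenuation <- row$opacity_attenuation
    spec$pathology$opacity_position_mm <- row$acd + 0.8 * row$lt  # posterior lens
    spec$pathology$opacity_lateral_extent_mm <- 2
  }
  build_phantom(spec)
}

measure_replicate <- function(truth_row, protocol, config) {
  if (protocol$mode == "gaussian") {
    vapply(protocol$parameters, function(p)
      truth_row[[p]] + rnorm(1, 0, protocol$within_sd[[p]]), numeric(1))
  } else {
    res <- measure_biometry(phantom_from_truth(truth_row, config), config)
    vapply(protocol$parameters, function(p) res$parameters[[p]]$mean, numeric(1))
  }
}

#' Run a synthetic repeatability/reproducibility study
#'
#' Simulates the full repeated-measurement design (subjects x observers x
#' replicates, realignment between replicates) on a synthetic cohort and
#' computes the precision panel: intraobserver reports per observer and
#' parameter, and interobserver reports from each observer's first readings.
#'
#' @param protocol A [study_protocol()].
#' @param config A [sim_config()] (used by `mode = "simulate"`).
#' @param out_dir Optional directory; when given, writes
#'   `measurements.csv`, `precision.json` and `manifest.json`.
#' @return List with `study` (the long measurement table), `intraobserver`
#'   (nested list observer -> parameter -> `precision_report`),
#'   `interobserver` (parameter -> `precision_report`), and `protocol`.
#' @export
run_repeatability_study <- function(protocol, config = sim_config(),
                                    out_dir = NULL) {
  stopifnot(inherits(protocol, "study_protocol"))
  run <- function() {
    truth <- draw_cohort_truth(protocol)
    rows <- list()
    for (obs in seq_len(protocol$observers)) {
      for (rep in seq_len(protocol$replicates)) {
        for (i in seq_len(nrow(truth))) {
          vals <- measure_replicate(truth[i, ], protocol, config)
          rows[[length(rows) + 1L]] <- data.frame(
            subject = truth$subject[i], observer = obs, replicate = rep,
            parameter = protocol$parameters, value = unname(vals),
            unit = unname(PARAM_UNITS[protocol$parameters]))
        }
      }
    }
    study <- repeatability_study(do.call(rbind, rows))
    intra <- lapply(seq_len(protocol$observers), function(obs)
      setNames(lapply(protocol$parameters, function(p)
        precision_report(study, p, observer = obs)), protocol$parameters))
    names(intra) <- paste0("observer_", seq_len(protocol$observers))
    inter <- if (protocol$observers >= 2) {
      fr <- first_readings_study(study)
      setNames(lapply(protocol$parameters, function(p) precision_report(fr, p)),
               protocol$parameters)
    } else NULL
    list(study = study, intraobserver = intra, interobserver = inter,
         truth = truth, protocol = protocol)
  }
  result <- withr::with_seed(protocol$seed, run())
  if (!is.null(out_dir)) write_repeatability_outputs(result, out_dir)
  result
}

#' Run a synthetic two-device agreement study
#'
#' Each synthetic eye is measured once by the study device and once by a
#' comparator sharing the same ground truth but with its own measurement
#' noise and optional fixed bias. Differences follow the
#' comparator-minus-reference convention.
#'
#' @param protocol A [study_protocol()] (`observers`/`replicates` are not
#'   used; one pair per eye).
#' @param device_b List with named vectors `within_sd` (comparator noise
#'   SD per parameter) and `bias` (fixed offset per parameter, default 0).
#' @param config A [sim_config()] (for `mode = "simulate"` reference
#'   measurements).
#' @param out_dir Optional output directory (`pairs.csv`,
#'   `agreement.json`, `manifest.json`).
#' @return List with `pairs` (long table), `reports` (parameter ->
#'   `agreement_report`), `protocol`.
#' @export
run_agreement_study <- function(protocol,
                                device_b = list(within_sd = c(axl = 0.010, acd = 0.010,
                                                              lt = 0.020, cct = 2.0),
                                                bias = c(axl = 0, acd = 0, lt = 0, cct = 0)),
                                config = sim_config(), out_dir = NULL) {
  stopifnot(inherits(protocol, "study_protocol"))
  bias <- device_b$bias %||% c(axl = 0, acd = 0, lt = 0, cct = 0)
  run <- function() {
    truth <- draw_cohort_truth(protocol)
    pairs <- do.call(rbind, lapply(seq_len(nrow(truth)), function(i) {
      a <- measure_replicate(truth[i, ], protocol, config)
      b <- vapply(protocol$parameters, function(p)
        truth[[p]][i] + bias[[p]] + rnorm(1, 0, device_b$within_sd[[p]]), numeric(1))
      data.frame(subject = truth$subject[i], parameter = protocol$parameters,
                 device_a = unname(a), device_b = unname(b),
                 unit = unname(PARAM_UNITS[protocol$parameters]))
    }))
    reports <- setNames(lapply(protocol$parameters, function(p) {
      d <- pairs[pairs$parameter == p, ]
      bland_altman(d$device_a, d$device_b)
    }), protocol$parameters)
    list(pairs = pairs, reports = reports, truth = truth, protocol = protocol)
  }
  result <- withr::with_seed(protocol$seed, run())
  if (!is.null(out_dir)) write_agreement_outputs(result, out_dir)
  result
}
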