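#' Convert an optical span to a geometric distance
#'
#' Divides an optical path length by the effective group index of the media
#' it traverses: `n_eff = sum(fraction_i * index_i)` with geometric
#' fractions. Exact inverse of [optical_path()] when the true per-segment
#' fractions are supplied.
#'
#' @param optical_mm Optical span (> 0).
#' @param media_weights Data frame or list with elements/columns
#'   `group_index` (>= 1) and `fraction` (summing to 1).
#' @return Geometric distance in mm.
#' @export
optical_to_geometric <- function(optical_mm, media_weights) {
  if (!is.finite(optical_mm) || optical_mm <= 0)
    stop("optical_to_geometric: optical span must be positive")
  w <- as.data.frame(media_weights)
  if (any(w$group_index < 1)) stop("optical_to_geometric: indices must be >= 1")
  if (abs(sum(w$fraction) - 1) > 1e-8)
    stop("optical_to_geometric: fractions must sum to 1")
  optical_mm / sum(w$fraction * w$group_index)
}

#' Glass-block accuracy check
#'
#' Bookkeeping of the instrument accuracy verification against a reference
#' N-BK7 glass block: the device displays optical path scaled by the
#' averaged eye index (`device value = optical / n_eye`); rescaling that
#' value by `n_eye / n_glass` yields the true glass thickness, which is
#' compared to the coordinate-machine reference.
#'
#' @param measured_optical_mm Raw optical thickness measured through the
#'   block (group-index-weighted path).
#' @param n_eye Averaged whole-eye group index applied by the device.
#' @param n_glass Group refractive index of N-BK7 at the device wavelength.
#' @param reference_mm Reference thickness of the block.
#' @return A `calibration_record` list: `measured_optical_mm`, `n_eye`,
#'   `n_glass`, `device_value_mm`, `corrected_thickness_mm`,
#'   `reference_thickness_mm`, `accuracy_delta_mm` (corrected - reference).
#' @export
glass_block_check <- function(measured_optical_mm, n_eye = 1.3549,
                              n_glass = 1.527, reference_mm) {
  if (n_eye <= 1 || n_glass <= 1) stop("glass_block_check: indices must be > 1")
  device_value <- measured_optical_mm / n_eye
  corrected <- device_value * n_eye / n_glass
  structure(list(measured_optical_mm = measured_optical_mm,
                 n_eye = n_eye, n_glass = n_glass,
                 device_value_mm = device_value,
                 corrected_thickness_mm = corrected,
                 reference_thickness_mm = reference_mm,
                 accuracy_delta_mm = corrected - reference_mm),
            class = "calibration_record")
}

#' @export
print.calibration_record <- function(x, ...) {
  cat(sprintf("<calibration_record> corrected %.4f mm vs reference %.4f mm (delta %+.4f mm)\n",
              x$corrected_thickness_mm, x$reference_thickness_mm, x$accuracy_delta_mm))
  invisible(x)
}

#' Robust outlier rejection for a shot series
#'
#' Modified z-score rule: a shot is rejected when
#' `|value - median| / (1.4826 * MAD) > threshold`. With zero MAD nothing is
#' rejected. If fewer than `min_retained` shots survive, a classed
#' measurement-failure error (`boct_measurement_failure`) is signalled.
#'
#' @param values Numeric vector of shot values (length >= 3).
#' @param threshold Modified z-score threshold.
#' @param min_retained Minimum number of surviving shots.
#' @return List with `kept` (values), `rejected` (indices into `values`).
#' @export
reject_outliers <- function(values, threshold = 2.5, min_retained = 5) {
  if (length(values) < 3) stop("reject_outliers: need at least 3 values")
  m <- median(values)
  s <- mad(values)  # 1.4826 * median absolute deviation
  rejected <- if (s > 0) which(abs(values - m) / s > threshold) else integer(0)
  kept <- if (length(rejected)) values[-rejected] else values
  if (length(kept) < min_retained) {
    stop(structure(class = c("boct_measurement_failure", "error", "condition"),
                   list(message = sprintf(
                     "measurement failure: only %d of %d shots retained (minimum %d)",
                     length(kept), length(values), min_retained),
                     call = sys.call(-1))))
  }
  list(kept = kept, rejected = rejected)
}

# Compose the four parameter spans from one boundary set and convert them
# to geometric units. Returns list(values = c(axl, acd, lt [mm], cct [um]),
# valid = logical per parameter, manual = any manual boundary used).
compose_spans <- function(bset, config) {
  d <- setNames(bset$depth_mm, bset$boundary)[BOUNDARIES]
  conf <- setNames(bset$confidence, bset$boundary)[BOUNDARIES]
  src <- setNames(bset$source, bset$boundary)[BOUNDARIES]
  usable <- !is.na(d) & (conf >= config$conf_floor | src == "manual")
  idx <- config$indices

  seg <- c(cornea = unname(d["cornea_back"] - d["cornea_front"]),
           aqueous = unname(d["lens_front"] - d["cornea_back"]),
           lens = unname(d["lens_back"] - d["lens_front"]),
           vitreous = unname(d["retina_post"] - d["lens_back"]))
  geom <- seg / idx[names(seg)]

  need <- list(cct = c("cornea_front", "cornea_back"),
               acd = c("cornea_front", "cornea_back", "lens_front"),
               lt = c("lens_front", "lens_back"),
               axl = BOUNDARIES)
  valid <- vapply(need, function(b) all(usable[b]), logical(1))

  axl <- if (config$device_mode)
    unname(d["retina_post"] - d["cornea_front"]) / config$n_eye
  else
    sum(geom)
  values <- c(axl = axl,
              acd = unname(geom["cornea"] + geom["aqueous"]),
              lt = unname(geom["lens"]),
              cct = unname(geom["cornea"]) * 1000)
  list(values = values, valid = valid,
       manual = any(src[!is.na(d)] == "manual"))
}

PARAMS <- c("axl", "acd", "lt", "cct")
PARAM_UNITS <- c(axl = "mm", acd = "mm", lt = "mm", cct = "um")

#' Biometry from segmented (possibly manually corrected) boundary sets
#'
#' Composes AXL, ACD, LT and CCT from a list of per-shot boundary sets,
#' applies per-orientation outlier rejection, pools the surviving shots and
#' converts optical spans to geometric units with the configured group
#' indices (per segment, or the single averaged eye index for AXL in device
#' mode).
#'
#' @param bsets List of `boundary_set` objects.
#' @param orientations Character vector parallel to `bsets`
#'   (`"horizontal"`/`"vertical"`).
#' @param config A [sim_config()].
#' @return A `biometry_result`; see [measure_biometry()].
#' @export
biometry_from_boundaries <- function(bsets, orientations, config = sim_config()) {
  stopifnot(length(bsets) == length(orientations))
  shots <- lapply(bsets, compose_spans, config = config)
  manual <- any(vapply(shots, `[[`, logical(1), "manual"))
  n_total <- length(bsets)
  per_param <- lapply(PARAMS, function(p) {
    kept_all <- numeric(0)
    n_rej_rule <- 0L
    ori_ok <- logical(0)
    for (o in unique(orientations)) {
      in_o <- which(orientations == o)
      vals <- vapply(shots[in_o], function(s)
        if (s$valid[[p]]) s$values[[p]] else NA_real_, numeric(1))
      vals <- vals[!is.na(vals)]
      min_keep <- min(config$min_retained, max(1L, ceiling(length(in_o) / 2)))
      res <- tryCatch(
        if (length(vals) >= 3) reject_outliers(vals, config$outlier_threshold, min_keep)
        else if (length(vals) >= min_keep) list(kept = vals, rejected = integer(0))
        else stop(structure(class = c("boct_measurement_failure", "error", "condition"),
                            list(message = "too few valid shots", call = NULL))),
        boct_measurement_failure = function(e) NULL)
      ori_ok <- c(ori_ok, !is.null(res))
      if (!is.null(res)) {
        kept_all <- c(kept_all, res$kept)
        n_rej_rule <- n_rej_rule + length(res$rejected)
      }
    }
    if (!any(ori_ok) || length(kept_all) == 0) {
      list(mean = NA_real_, sd = NA_real_, n_used = 0L, n_rejected = n_total,
           status = "failed")
    } else {
      list(mean = mean(kept_all),
           sd = if (length(kept_all) > 1) sd(kept_all) else 0,
           n_used = length(kept_all),
           n_rejected = n_total - length(kept_all),
           status = if (manual) "manual_corrected" else "ok")
    }
  })
  names(per_param) <- PARAMS
  structure(list(parameters = per_param, n_shots = n_total, units = PARAM_UNITS,
                 status = if (any(vapply(per_param, `[[`, character(1), "status") == "failed"))
                   "failed" else if (manual) "manual_corrected" else "ok"),
            class = "biometry_result")
}

#' Measure ocular biometry on a phantom
#'
#' The full measurement protocol of the simulated device: `n_shots`
#' acquisitions per orientation (horizontal and vertical), automatic
#' boundary segmentation per shot, per-orientation robust outlier rejection,
#' pooling, and optical-to-geometric conversion. Deterministic given `seed`.
#'
#' @param phantom An `eye_phantom`.
#' @param config A [sim_config()].
#' @param n_shots Shots per orientation (default 10).
#' @param seed Optional integer seed.
#' @param keep_scans If `TRUE`, attach the shots and boundary sets to the
#'   result (for inspection or manual correction).
#' @return A `biometry_result`: per parameter mean, SD, `n_used`,
#'   `n_rejected` (`n_used + n_rejected` = shots attempted) and status
#'   (`ok` / `manual_corrected` / `failed`; failed parameters carry no
#'   value). AXL/ACD/LT in mm, CCT in um.
#' @export
measure_biometry <- function(phantom, config = sim_config(), n_shots = 10,
                             seed = NULL, keep_scans = FALSE) {
  run <- function() {
    shots <- lapply(seq_len(n_shots), function(i) acquire_measurement(phantom, config))
    bsets <- list(); orients <- character(0)
    for (s in shots) for (o in c("horizontal", "vertical")) {
      bsets[[length(bsets) + 1L]] <- segment_shot(s, o, config)
      orients <- c(orients, o)
    }
    res <- biometry_from_boundaries(bsets, orients, config)
    if (keep_scans) {
      res$shots <- shots
      res$boundary_sets <- bsets
      res$orientations <- orients
    }
    res
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @export
print.biometry_result <- function(x, ...) {
  cat("<biometry_result> status:", x$status, "\n")
  for (p in PARAMS) {
    e <- x$parameters[[p]]
    if (e$status == "failed") {
      cat(sprintf("  %-3s : measurement failed (%d/%d shots rejected)\n",
                  toupper(p), e$n_rejected, e$n_used + e$n_rejected))
    } else {
      fmt <- if (p == "cct") "  %-3s : %7.2f +/- %.2f %s  (n=%d, rejected=%d)%s\n"
             else "  %-3s : %7.2f +/- %.3f %s  (n=%d, rejected=%d)%s\n"
      cat(sprintf(fmt, toupper(p), e$mean, e$sd, x$units[[p]], e$n_used,
                  e$n_rejected, if (e$status == "manual_corrected") " [manual]" else ""))
    }
  }
  invisible(x)
}
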