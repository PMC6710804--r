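# Per-A-scan peak detection: adaptive threshold (median + k*MAD of the
# envelope) with a relative-prominence floor, sub-pixel refinement by
# 3-point parabolic interpolation. Returns data.frame(pos_px, height) with
# pos_px on the 0-based pixel axis (depth = gate + pos_px * pixel).
find_ascan_peaks <- function(env, config) {
  thr <- median(env) + config$detect_k_mad * mad(env)
  floor_h <- config$prominence_frac * max(env)
  minh <- max(thr, floor_h)
  dist <- max(2L, round(config$axial_resolution_um / config$axial_pixel_um))
  pk <- pracma::findpeaks(env, minpeakheight = minh, minpeakdistance = dist)
  if (is.null(pk)) return(list(peaks = data.frame(pos_px = numeric(0), height = numeric(0)),
                               threshold = thr))
  idx <- pk[, 2]
  delta <- numeric(length(idx))
  interior <- idx > 1 & idx < length(env)
  if (any(interior)) {
    i <- idx[interior]
    y0 <- env[i - 1]; y1 <- env[i]; y2 <- env[i + 1]
    den <- y0 - 2 * y1 + y2
    delta[interior] <- ifelse(abs(den) > .Machine$double.eps,
                              0.5 * (y0 - y2) / den, 0)
  }
  ord <- order(idx)
  list(peaks = data.frame(pos_px = (idx - 1 + pmax(pmin(delta, 0.5), -0.5))[ord],
                          height = pk[ord, 1]),
       threshold = thr)
}

# Assign detected peaks to the role's boundaries (order-statistics policy):
# window 1: the two dominant peaks, anterior = cornea_front;
# window 2: shallowest peak = lens_front;
# window 3: deepest strong peak = lens_back;
# window 4: deepest strong peak = retina_post (RPE).
assign_peaks <- function(peaks, role, config) {
  out <- list()
  if (nrow(peaks) == 0) return(out)
  strong <- peaks[peaks$height >= config$strong_frac * max(peaks$height), , drop = FALSE]
  if (role == 1L) {
    if (nrow(peaks) >= 2) {
      dom <- peaks[order(-peaks$height)[1:2], ]
      dom <- dom[order(dom$pos_px), ]
      out$cornea_front <- dom[1, ]
      out$cornea_back <- dom[2, ]
    }
  } else if (role == 2L) {
    out$lens_front <- peaks[which.min(peaks$pos_px), ]
  } else if (role == 3L) {
    out$lens_back <- strong[which.max(strong$pos_px), ]
  } else if (role == 4L) {
    out$retina_post <- strong[which.max(strong$pos_px), ]
  }
  out
}

empty_boundary_row <- function(boundary) {
  data.frame(boundary = boundary, depth_mm = NA_real_, confidence = 0,
             source = "auto", quality = NA_real_, stringsAsFactors = FALSE)
}

role_boundaries <- function(role) {
  switch(role, `1` = c("cornea_front", "cornea_back"), `2` = "lens_front",
         `3` = "lens_back", `4` = "retina_post")
}

#' Detect anatomical boundaries in one measurement window
#'
#' Runs peak detection on every A-scan within the central lateral span,
#' assigns peaks to the window role's boundaries and pools positions across
#' A-scans by median. Pixel positions are converted to optical depth on the
#' common apex reference via the window's gate offset. A boundary detected in
#' fewer than half of the central A-scans is reported absent with confidence
#' 0 (the quality flag that calls for manual correction).
#'
#' @param window A `bscan_window` from [acquire_window()].
#' @param config A [sim_config()].
#' @return A `boundary_set` data.frame (rows = this role's boundaries) with
#'   columns `boundary`, `depth_mm` (optical, apex-referenced), `confidence`
#'   in `[0, 1]`, `source` (`"auto"`), `quality` (window signal quality, the
#'   median peak-to-threshold ratio).
#' @export
detect_boundaries <- function(window, config = sim_config()) {
  stopifnot(inherits(window, "bscan_window"))
  central <- which(abs(window$lateral_mm) <= config$central_span_mm / 2)
  per_scan <- lapply(central, function(j) {
    det <- find_ascan_peaks(window$ascans[, j], config)
    list(assign = assign_peaks(det$peaks, window$role, config),
         threshold = det$threshold)
  })
  thr_med <- median(vapply(per_scan, `[[`, numeric(1), "threshold"))
  rows <- lapply(role_boundaries(as.character(window$role)), function(b) {
    hits <- do.call(rbind, lapply(per_scan, function(s) s$assign[[b]]))
    if (is.null(hits) || nrow(hits) < length(central) / 2) return(empty_boundary_row(b))
    pos <- median(hits$pos_px)
    height <- median(hits$height)
    snr <- height / thr_med
    data.frame(boundary = b,
               depth_mm = window$gate_offset_mm + pos * window$pixel_um / 1000,
               confidence = max(0, min(1, (snr - 1) / 4)),
               source = "auto", quality = snr, stringsAsFactors = FALSE)
  })
  bset <- do.call(rbind, rows)
  class(bset) <- c("boundary_set", "data.frame")
  bset
}

#' Segment a full shot into a complete boundary set
#'
#' Applies [detect_boundaries()] to the four windows of one orientation and
#' stacks the results into the five-boundary set used by the biometry engine.
#'
#' @param shot A `boct_shot` from [acquire_measurement()].
#' @param orientation `"horizontal"` or `"vertical"`.
#' @param config A [sim_config()].
#' @return A `boundary_set` data.frame with one row per anatomical boundary;
#'   boundaries from failed windows are present with `NA` depth.
#' @export
segment_shot <- function(shot, orientation = "horizontal", config = sim_config()) {
  stopifnot(inherits(shot, "boct_shot"))
  orientation <- match.arg(orientation, c("horizontal", "vertical"))
  rows <- lapply(1:4, function(role) {
    w <- shot$windows[[orientation]][[role]]
    if (is.null(w)) {
      do.call(rbind, lapply(role_boundaries(as.character(role)), empty_boundary_row))
    } else {
      detect_boundaries(w, config)
    }
  })
  bset <- do.call(rbind, rows)
  rownames(bset) <- NULL
  class(bset) <- c("boundary_set", "data.frame")
  validate_boundary_set(bset, allow_na = TRUE)
  bset
}

validate_boundary_set <- function(bset, allow_na = FALSE) {
  if (!all(bset$boundary %in% BOUNDARIES))
    stop("boundary_set: unknown boundary id")
  d <- bset$depth_mm[match(BOUNDARIES, bset$boundary)]
  present <- !is.na(d)
  if (!allow_na && !all(present)) stop("boundary_set: missing boundary depth")
  dp <- d[present]
  if (length(dp) > 1 && any(diff(dp) <= 0))
    stop("boundary_set: depths must be strictly increasing in anatomical order")
  invisible(bset)
}

#' Manually correct boundary positions
#'
#' Mirrors the clinician's manual-correction workflow: edited boundaries are
#' replaced, marked `source = "manual"` with confidence 1, and the whole set
#' is re-validated. The edit is all-or-nothing: any anatomical-ordering
#' violation rejects the entire edit map.
#'
#' @param bset A `boundary_set`.
#' @param edits Named numeric vector, boundary id -> optical depth (mm,
#'   apex-referenced), e.g. `c(retina_post = 31.95)`.
#' @return The corrected `boundary_set`; downstream biometry recomputed from
#'   it reflects the edits.
#' @export
apply_manual_override <- function(bset, edits) {
  stopifnot(inherits(bset, "boundary_set"))
  if (length(edits) == 0) return(bset)
  if (is.null(names(edits)) || !all(names(edits) %in% BOUNDARIES))
    stop("apply_manual_override: edits must be named by boundary id")
  out <- bset
  for (b in names(edits)) {
    i <- match(b, out$boundary)
    if (is.na(i)) stop("apply_manual_override: boundary not in set: ", b)
    out$depth_mm[i] <- unname(edits[[b]])
    out$confidence[i] <- 1
    out$source[i] <- "manual"
  }
  validate_boundary_set(out, allow_na = TRUE)
  out
}

#' @export
print.boundary_set <- function(x, ...) {
  cat("<boundary_set> (optical mm, apex-referenced)\n")
  print.data.frame(x, digits = 5, row.names = FALSE)
  invisible(x)
}
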