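#' Simulator configuration
#'
#' Bundles the acquisition geometry and noise model of the simulated
#' spectral-domain OCT biometer, together with the segmentation and
#' measurement-series parameters used downstream.
#'
#' All depths on the A-scan axis are *optical* millimetres (group-index
#' weighted path), referenced to the anterior corneal apex. A window's
#' `gate_offset` is the optical depth of its first pixel; it may be negative,
#' which places the zero-delay line above the cornea (how window 1 keeps the
#' corneal surfaces away from the DC bin).
#'
#' @param center_wavelength_nm Source centre wavelength (informational).
#' @param spectral_samples Spectrometer samples per A-scan; the usable depth
#'   range is `spectral_samples / 2` pixels.
#' @param axial_pixel_um Axial pixel pitch on the reconstructed A-scan.
#' @param axial_resolution_um Nominal axial resolution (FWHM) in tissue;
#'   must be >= `axial_pixel_um`.
#' @param window_width_mm,window_depth_mm Lateral and axial extent of each
#'   measurement window.
#' @param rolloff_6db_mm Depth (within a window) at which spectrometer
#'   sensitivity roll-off halves the signal amplitude.
#' @param noise_floor Additive envelope noise level relative to a
#'   unit-reflectivity peak.
#' @param speckle_contrast Strength of the multiplicative Rayleigh-like
#'   speckle applied to the envelope (0 disables).
#' @param lateral_samples A-scans per B-scan window.
#' @param gate_margin_mm Clearance the gate solver keeps between a target
#'   boundary and the window edges.
#' @param jitter_sd_um SD of the per-window axial alignment jitter drawn for
#'   every shot (models residual eye/instrument motion between C-gate moves).
#' @param detect_k_mad Peak threshold: median + k * MAD of the envelope.
#' @param prominence_frac Peaks must additionally exceed this fraction of the
#'   window's envelope maximum (suppresses Hann sidelobes on noiseless data).
#' @param strong_frac "Strong peak" gate for last-peak assignment (windows 3
#'   and 4), as a fraction of the tallest detected peak.
#' @param central_span_mm Lateral span over which per-A-scan detections are
#'   pooled by median.
#' @param conf_floor Minimum boundary confidence for a detection to enter
#'   the biometry composition automatically.
#' @param indices Per-medium group indices used for optical-to-geometric
#'   conversion (the device's assumed indices; defaults match the phantom).
#' @param n_eye Averaged whole-eye group index, used for AXL when
#'   `device_mode = TRUE` and for the glass-block check.
#' @param device_mode If `TRUE`, convert the AXL span with the single
#'   averaged index `n_eye` instead of per-segment indices.
#' @param outlier_threshold Modified z-score threshold of the shot-series
#'   outlier rule.
#' @param min_retained Minimum surviving shots per orientation for a
#'   parameter, out of the default series of 10.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(center_wavelength_nm = 840,
                       spectral_samples = 2048,
                       axial_pixel_um = 2.4,
                       axial_resolution_um = 5,
                       window_width_mm = 3,
                       window_depth_mm = 2.5,
                       rolloff_6db_mm = 1.8,
                       noise_floor = 0.01,
                       speckle_contrast = 0.15,
                       lateral_samples = 25,
                       gate_margin_mm = 0.3,
                       jitter_sd_um = 5,
                       detect_k_mad = 6,
                       prominence_frac = 0.1,
                       strong_frac = 0.25,
                       central_span_mm = 1,
                       conf_floor = 0.2,
                       indices = default_indices(),
                       n_eye = 1.3549,
                       device_mode = FALSE,
                       outlier_threshold = 2.5,
                       min_retained = 5) {
  if (axial_pixel_um > axial_resolution_um)
    stop("sim_config: axial_pixel_um must not exceed axial_resolution_um")
  if (spectral_samples < 64 || spectral_samples %% 2 != 0)
    stop("sim_config: spectral_samples must be an even count >= 64")
  if (window_depth_mm <= 0 || window_width_mm <= 0)
    stop("sim_config: window dimensions must be positive")
  if (any(indices[MEDIA_NAMES] < 1) || any(is.na(indices[MEDIA_NAMES])))
    stop("sim_config: indices must name all four media with values >= 1")
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

# usable A-scan length in pixels (limited by window depth and by the
# spectrometer's Nyquist depth)
n_axial_pixels <- function(config) {
  min(floor(config$window_depth_mm * 1000 / config$axial_pixel_um),
      config$spectral_samples %/% 2L)
}

# ---- reflector model -------------------------------------------------------

# All specular reflectors of a phantom at one lateral position:
# data.frame(id, optical_mm, amplitude), pathology applied.
phantom_reflectors <- function(phantom, lateral_pos_mm = 0) {
  opt <- boundary_optical_depths(phantom)
  n_vit <- phantom$media$group_index[4]
  ret <- phantom$retina
  ids <- c("cornea_front", "cornea_back", "lens_front", "lens_back")
  depths <- unname(opt[ids])
  amps <- phantom$media$reflectivity

  rpe_opt <- unname(opt["retina_post"]) - n_vit * ret$rpe_elevation_um / 1000
  rpe_amp <- ret$rpe_reflectivity
  if (ret$detachment_height_um > 0) {
    # detached neurosensory retina: extra reflector anterior to the RPE,
    # sub-retinal fluid scatters roughly half of the RPE signal away
    ids <- c(ids, "retina_detached")
    depths <- c(depths, rpe_opt - n_vit * ret$detachment_height_um / 1000)
    amps <- c(amps, 0.5 * rpe_amp)
    rpe_amp <- 0.5 * rpe_amp
  }
  ids <- c(ids, "retina_post")
  depths <- c(depths, rpe_opt)
  amps <- c(amps, rpe_amp)
  if (ret$rpe_elevation_um > 0 || ret$bruch_offset_um > 0) {
    ids <- c(ids, "bruch")
    depths <- c(depths, unname(opt["retina_post"]) + n_vit * ret$bruch_offset_um / 1000)
    amps <- c(amps, ret$bruch_reflectivity)
  }

  pa <- phantom$pathology
  if (!is.na(pa$opacity_position_mm) && pa$opacity_attenuation > 0 &&
      abs(lateral_pos_mm) <= pa$opacity_lateral_extent_mm / 2) {
    op_opt <- geometric_to_optical_depth(phantom, pa$opacity_position_mm)
    # strictly posterior; a reflector at the opacity plane itself (e.g. the
    # posterior capsule under a subcapsular opacity) is not shaded
    shaded <- depths > op_opt + 1e-9
    amps[shaded] <- amps[shaded] * (1 - pa$opacity_attenuation)
  }
  data.frame(id = ids, optical_mm = depths, amplitude = amps,
             stringsAsFactors = FALSE)
}

rolloff_factor <- function(dz_mm, config) {
  0.5^((dz_mm / config$rolloff_6db_mm)^2)
}

# ---- spectral synthesis and reconstruction ---------------------------------

#' Simulate one raw spectral fringe
#'
#' Each reflector within reach of the window contributes a cosine fringe
#' whose frequency is proportional to its optical depth below the gate and
#' whose amplitude is reflectivity x opacity shadowing x sensitivity
#' roll-off; Gaussian spectral noise is added on top. Reflectors above the
#' gate or beyond the window depth are out of reach.
#'
#' @param phantom An `eye_phantom`.
#' @param lateral_pos_mm Lateral position of the A-scan within the window.
#' @param gate_offset_mm Optical depth of the window's first pixel
#'   (apex-referenced; may be negative).
#' @param config A [sim_config()].
#' @param axial_shift_mm Rigid axial displacement of the eye for this shot
#'   (alignment jitter), applied to every reflector.
#' @return Numeric vector of length `spectral_samples`. Uses the current RNG
#'   stream; seed at the acquisition level for reproducibility.
#' @export
simulate_spectrum <- function(phantom, lateral_pos_mm, gate_offset_mm, config,
                              axial_shift_mm = 0) {
  N <- config$spectral_samples
  n_z <- n_axial_pixels(config)
  refl <- phantom_reflectors(phantom, lateral_pos_mm)
  dz <- refl$optical_mm + axial_shift_mm - gate_offset_mm
  keep <- dz > 0 & dz < n_z * config$axial_pixel_um / 1000 & refl$amplitude > 0
  s <- numeric(N)
  if (any(keep)) {
    amp <- refl$amplitude[keep] * rolloff_factor(dz[keep], config)
    f_bin <- dz[keep] * 1000 / config$axial_pixel_um
    k <- 0:(N - 1L)
    s <- as.vector(cos(2 * pi * outer(k / N, f_bin)) %*% amp)
  }
  if (config$noise_floor > 0)
    s <- s + rnorm(N, sd = config$noise_floor * sqrt(N / 6))
  s
}

hann_window <- function(N) 0.5 * (1 - cos(2 * pi * (0:(N - 1L)) / (N - 1L)))

# Hann-apodized magnitude FFT of one or more spectra (columns), cropped to
# the usable depth range and normalized so a unit-amplitude fringe gives a
# unit-height peak.
reconstruct_envelope <- function(spectra, config) {
  spectra <- as.matrix(spectra)
  N <- nrow(spectra)
  if (N != config$spectral_samples)
    stop("reconstruct_ascan: spectrum length must equal spectral_samples")
  w <- hann_window(N)
  env <- Mod(mvfft(spectra * w)) * (2 / sum(w))
  env[seq_len(n_axial_pixels(config)), , drop = FALSE]
}

#' Reconstruct an A-scan from a raw spectrum
#'
#' Hann apodization, Fourier transform, magnitude envelope, cropped to the
#' window depth. Deterministic given its input.
#'
#' @param spectrum Raw fringe vector from [simulate_spectrum()].
#' @param config A [sim_config()].
#' @param gate_offset_mm Gate offset to record on the A-scan.
#' @return An object of class `ascan`: list with `amplitudes` (non-negative
#'   envelope per axial pixel), `gate_offset_mm`, `pixel_um`.
#' @export
reconstruct_ascan <- function(spectrum, config, gate_offset_mm = 0) {
  env <- reconstruct_envelope(matrix(spectrum, ncol = 1), config)[, 1]
  structure(list(amplitudes = env, gate_offset_mm = gate_offset_mm,
                 pixel_um = config$axial_pixel_um),
            class = "ascan")
}

# ---- window acquisition ----------------------------------------------------

# target boundaries (nominal optical depths) per window role
window_targets <- function(phantom, role) {
  opt <- boundary_optical_depths(phantom)
  switch(role,
    `1` = opt[c("cornea_front", "cornea_back")],
    `2` = opt["lens_front"],
    `3` = opt["lens_back"],
    `4` = opt["retina_post"],
    stop("role must be 1, 2, 3 or 4")
  )
}

# Choose the C-gate offset so the role's target boundaries sit inside the
# window with gate_margin clearance at both ends.
solve_gate_offset <- function(phantom, role, config) {
  tg <- window_targets(phantom, as.character(role))
  usable <- n_axial_pixels(config) * config$axial_pixel_um / 1000
  span <- max(tg) - min(tg)
  if (span > usable - 2 * config$gate_margin_mm)
    stop(sprintf(
      "acquisition error: window %d target span %.3f mm cannot fit the %.3f mm window",
      role, span, usable))
  min(tg) - config$gate_margin_mm
}

#' Acquire one B-scan measurement window
#'
#' Places the C-gate for the requested window role (1 cornea, 2 anterior
#' lens, 3 posterior lens, 4 retina), synthesizes the lateral stack of
#' A-scans across the 3 mm span, reconstructs envelopes and applies speckle.
#'
#' @param phantom An `eye_phantom`.
#' @param role Window role, 1-4.
#' @param orientation `"horizontal"` or `"vertical"`.
#' @param config A [sim_config()].
#' @param seed Optional integer; when given the acquisition is wrapped in
#'   [withr::with_seed()] and is bit-reproducible.
#' @param gate_offset_mm Optional explicit gate offset overriding the solver.
#' @param axial_shift_mm Rigid axial jitter for this shot.
#' @return Object of class `bscan_window`: `role`, `orientation`,
#'   `gate_offset_mm`, `pixel_um`, `lateral_mm`, and `ascans` (matrix, axial
#'   pixels x lateral positions).
#' @export
acquire_window <- function(phantom, role, orientation = "horizontal",
                           config = sim_config(), seed = NULL,
                           gate_offset_mm = NULL, axial_shift_mm = 0) {
  if (!role %in% 1:4) stop("acquire_window: role must be in 1..4")
  orientation <- match.arg(orientation, c("horizontal", "vertical"))
  run <- function() {
    gate <- gate_offset_mm %||% solve_gate_offset(phantom, role, config)
    lat <- seq(-config$window_width_mm / 2, config$window_width_mm / 2,
               length.out = config$lateral_samples)
    spectra <- vapply(lat, function(x)
      simulate_spectrum(phantom, x, gate, config, axial_shift_mm),
      numeric(config$spectral_samples))
    env <- reconstruct_envelope(spectra, config)
    if (config$speckle_contrast > 0) {
      # Rayleigh-like multiplicative speckle, mean-one
      r <- matrix(sqrt(rnorm(length(env))^2 + rnorm(length(env))^2) / sqrt(pi / 2),
                  nrow = nrow(env))
      env <- env * (1 - config$speckle_contrast + config$speckle_contrast * r)
    }
    structure(list(role = as.integer(role), orientation = orientation,
                   gate_offset_mm = gate, pixel_um = config$axial_pixel_um,
                   lateral_mm = lat, ascans = env),
              class = "bscan_window")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @export
print.bscan_window <- function(x, ...) {
  cat(sprintf("<bscan_window> role %d (%s), gate %.3f mm, %d x %d px\n",
              x$role, x$orientation, x$gate_offset_mm,
              nrow(x$ascans), ncol(x$ascans)))
  invisible(x)
}

#' Acquire one complete biometry shot
#'
#' One shot images all four window roles in both orientations (8 windows).
#' Each window receives an independent axial alignment jitter
#' `N(0, jitter_sd_um)`, recorded in the result so ground truth remains
#' recoverable. A window whose gate cannot be solved is flagged failed; the
#' remaining windows are preserved.
#'
#' @param phantom An `eye_phantom`.
#' @param config A [sim_config()].
#' @param seed Optional integer seed for the whole shot.
#' @return Object of class `boct_shot`: `windows` (nested list
#'   `[[orientation]][[role]]`), `jitter` (data.frame with `role`,
#'   `orientation`, `jitter_um`), `failed` (logical data.frame rows for
#'   windows that could not be acquired), `ok` (TRUE when all 8 succeeded).
#' @export
acquire_measurement <- function(phantom, config = sim_config(), seed = NULL) {
  run <- function() {
    grid <- expand.grid(role = 1:4,
                        orientation = c("horizontal", "vertical"),
                        stringsAsFactors = FALSE)
    grid$jitter_um <- rnorm(nrow(grid), sd = config$jitter_sd_um)
    windows <- list(horizontal = vector("list", 4), vertical = vector("list", 4))
    failed <- logical(nrow(grid))
    msg <- character(nrow(grid))
    for (i in seq_len(nrow(grid))) {
      res <- tryCatch(
        acquire_window(phantom, grid$role[i], grid$orientation[i], config,
                       axial_shift_mm = grid$jitter_um[i] / 1000),
        error = function(e) e)
      if (inherits(res, "error")) {
        failed[i] <- TRUE
        msg[i] <- conditionMessage(res)
      } else {
        windows[[grid$orientation[i]]][[grid$role[i]]] <- res
      }
    }
    structure(list(windows = windows,
                   jitter = cbind(grid, failed = failed, message = msg),
                   ok = !any(failed)),
              class = "boct_shot")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @export
print.boct_shot <- function(x, ...) {
  cat(sprintf("<boct_shot> %d/8 windows acquired\n", sum(!x$jitter$failed)))
  invisible(x)
}
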