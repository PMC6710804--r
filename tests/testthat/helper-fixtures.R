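# Shared fixtures: configs and phantoms built in code.

# default acquisition settings with all stochastic terms switched off
noiseless_config <- function(...) {
  sim_config(noise_floor = 0, speckle_contrast = 0, jitter_sd_um = 0, ...)
}

# phantom with every interface dark (no reflectors at all)
dark_phantom <- function() {
  spec <- healthy_eye_spec()
  spec$media$reflectivity <- rep(0, 4)
  spec$retina$rpe_reflectivity <- 0
  spec$retina$bruch_reflectivity <- 0
  build_phantom(spec)
}

# healthy phantom scaled to a target axial length, other dimensions at the
# population mean scaled proportionally within anatomy
phantom_with_axl <- function(axl_mm) {
  s <- axl_mm / 23.93
  build_phantom(healthy_eye_spec(axl_mm = axl_mm, acd_mm = 3.59 * s,
                                 lt_mm = 4.02 * s, cct_um = 555.44))
}

# dense posterior subcapsular opacity sitting on the posterior lens capsule:
# shadows only the retina
posterior_capsule_opacity_phantom <- function(attenuation = 0.97) {
  spec <- healthy_eye_spec()
  lens_back <- 0.55544 + 3.03456 + 4.02
  spec$pathology <- list(opacity_position_mm = lens_back,
                         opacity_attenuation = attenuation,
                         opacity_lateral_extent_mm = Inf)
  build_phantom(spec)
}

# optical depth of a boundary including retina offsets, from phantom truth
truth_optical_depths <- function(phantom) {
  c(cornea_front = 0,
    cornea_back = optical_path(phantom, "cornea_front", "cornea_back"),
    lens_front = optical_path(phantom, "cornea_front", "lens_front"),
    lens_back = optical_path(phantom, "cornea_front", "lens_back"),
    retina_post = optical_path(phantom, "cornea_front", "retina_post") -
      phantom$media$group_index[4] * phantom$retina$rpe_elevation_um / 1000)
}

# geometric media fractions of a full-eye span, for optical_to_geometric
axl_media_weights <- function(phantom) {
  th <- phantom$media$thickness_mm
  data.frame(group_index = phantom$media$group_index, fraction = th / sum(th))
}
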