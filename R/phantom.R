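# Anatomical boundary ids, anterior -> posterior. `retina_post` is the RPE
# (the posterior reflector used as the AXL endpoint in optical biometry).
BOUNDARIES <- c("cornea_front", "cornea_back", "lens_front", "lens_back", "retina_post")

MEDIA_NAMES <- c("cornea", "aqueous", "lens", "vitreous")

#' Default group refractive indices at 840 nm
#'
#' Per-medium group indices used both by the phantom (to place reflectors on
#' the optical depth axis) and by the biometry engine (to convert measured
#' optical spans back to geometric distances). Values are standard
#' optical-biometry literature figures; the averaged whole-eye index
#' `n_eye = 1.3549` is used when the engine runs in single-index device mode.
#'
#' @return Named numeric vector with elements `cornea`, `aqueous`, `lens`,
#'   `vitreous`.
#' @export
default_indices <- function() {
  c(cornea = 1.387, aqueous = 1.342, lens = 1.408, vitreous = 1.341)
}

#' Phantom specification for a mean healthy adult eye
#'
#' Layer thicknesses reproduce a population-mean healthy eye:
#' AXL 23.93 mm, ACD 3.59 mm (anterior cornea to anterior lens), LT 4.02 mm,
#' CCT 555.44 um. Interface reflectivities are relative amplitudes of the
#' specular boundaries; the RPE is the brightest posterior reflector and
#' Bruch's membrane a much weaker one just behind it.
#'
#' @param axl_mm,acd_mm,lt_mm,cct_um Target geometric dimensions. The aqueous
#'   and vitreous thicknesses are derived so the four dimensions close exactly
#'   (`AXL = CCT + aqueous + LT + vitreous`).
#' @param indices Named group refractive indices (see [default_indices()]).
#' @return A phantom spec list accepted by [build_phantom()].
#' @export
healthy_eye_spec <- function(axl_mm = 23.93, acd_mm = 3.59, lt_mm = 4.02,
                             cct_um = 555.44, indices = default_indices()) {
  cct_mm <- cct_um / 1000
  list(
    media = data.frame(
      name = MEDIA_NAMES,
      thickness_mm = c(cct_mm, acd_mm - cct_mm, lt_mm, axl_mm - acd_mm - lt_mm),
      group_index = unname(indices[MEDIA_NAMES]),
      # reflectivity of the medium's *anterior* interface:
      # cornea front, cornea back, lens front, lens back
      reflectivity = c(0.80, 0.30, 0.35, 0.35)
    ),
    retina = list(
      bruch_offset_um = 0, rpe_elevation_um = 0, detachment_height_um = 0,
      rpe_reflectivity = 0.55, bruch_reflectivity = 0.12
    ),
    pathology = list(
      opacity_position_mm = NA_real_, opacity_attenuation = 0,
      opacity_lateral_extent_mm = Inf
    )
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a validated layered eye phantom
#'
#' The phantom is the ground-truth object for the whole pipeline: an ordered
#' stack of four ocular media (cornea, aqueous, lens, vitreous), a retina
#' model (RPE depth, Bruch's membrane offset, RPE elevation, retinal
#' detachment height) and an optional lens-opacity pathology that shadows all
#' reflectors posterior to it.
#'
#' @param spec A spec list as returned by [healthy_eye_spec()] or read from
#'   JSON with [read_phantom_spec()]. Missing retina/pathology entries take
#'   the healthy defaults.
#' @return An object of class `eye_phantom`.
#' @seealso [geometric_dimensions()], [optical_path()]
#' @export
build_phantom <- function(spec = healthy_eye_spec()) {
  base <- healthy_eye_spec()
  media <- spec$media
  if (is.null(media)) stop("phantom spec field 'media' is missing")
  media <- as.data.frame(media)
  need <- c("name", "thickness_mm", "group_index", "reflectivity")
  miss <- setdiff(need, names(media))
  if (length(miss)) stop("phantom spec media missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(media) != 4L || !identical(as.character(media$name), MEDIA_NAMES))
    stop("phantom spec field 'media': exactly 4 media required in order ",
         paste(MEDIA_NAMES, collapse = ", "))
  for (i in seq_len(4L)) {
    if (!is.finite(media$thickness_mm[i]) || media$thickness_mm[i] <= 0)
      stop(sprintf("phantom spec field 'media$thickness_mm[%s]': must be > 0", media$name[i]))
    if (media$group_index[i] < 1 || media$group_index[i] > 2)
      stop(sprintf("phantom spec field 'media$group_index[%s]': must lie in [1, 2]", media$name[i]))
    if (media$reflectivity[i] < 0 || media$reflectivity[i] > 1)
      stop(sprintf("phantom spec field 'media$reflectivity[%s]': must lie in [0, 1]", media$name[i]))
  }

  compact <- function(x) x[!vapply(x, is.null, logical(1))]
  retina <- utils::modifyList(base$retina, compact(spec$retina %||% list()))
  for (f in c("bruch_offset_um", "rpe_elevation_um", "detachment_height_um")) {
    if (retina[[f]] < 0) stop(sprintf("phantom spec field 'retina$%s': must be >= 0", f))
  }
  for (f in c("rpe_reflectivity", "bruch_reflectivity")) {
    if (retina[[f]] < 0 || retina[[f]] > 1)
      stop(sprintf("phantom spec field 'retina$%s': must lie in [0, 1]", f))
  }

  path <- utils::modifyList(base$pathology, compact(spec$pathology %||% list()))
  if (path$opacity_attenuation < 0 || path$opacity_attenuation > 1)
    stop("phantom spec field 'pathology$opacity_attenuation': must lie in [0, 1]")
  lens_front <- sum(media$thickness_mm[1:2])
  lens_back <- sum(media$thickness_mm[1:3])
  if (!is.na(path$opacity_position_mm) &&
      (path$opacity_position_mm < lens_front || path$opacity_position_mm > lens_back))
    stop("phantom spec field 'pathology$opacity_position_mm': must lie inside the lens segment [",
         sprintf("%.3f, %.3f", lens_front, lens_back), "] mm")

  structure(
    list(media = media, retina = retina, pathology = path,
         rpe_depth_mm = sum(media$thickness_mm)),
    class = "eye_phantom"
  )
}

#' @export
print.eye_phantom <- function(x, ...) {
  tr <- geometric_dimensions(x)
  cat("<eye_phantom>\n")
  cat(sprintf("  AXL %.3f mm | ACD %.3f mm | LT %.3f mm | CCT %.1f um\n",
              tr$axl_mm, tr$acd_mm, tr$lt_mm, tr$cct_um))
  if (x$retina$rpe_elevation_um > 0)
    cat(sprintf("  RPE elevated by %.0f um (AXL target: Bruch's membrane)\n",
                x$retina$rpe_elevation_um))
  if (x$retina$detachment_height_um > 0)
    cat(sprintf("  retinal detachment, height %.0f um\n", x$retina$detachment_height_um))
  if (isTRUE(x$pathology$opacity_attenuation > 0))
    cat(sprintf("  lens opacity at %.2f mm, attenuation %.2f\n",
                x$pathology$opacity_position_mm, x$pathology$opacity_attenuation))
  invisible(x)
}

# Geometric depth (mm from corneal apex) of every nominal boundary.
boundary_depths <- function(phantom) {
  d <- cumsum(phantom$media$thickness_mm)
  c(cornea_front = 0, cornea_back = d[1], lens_front = d[2],
    lens_back = d[3], retina_post = d[4])
}

# Optical depth (group-index-weighted path, mm) of every nominal boundary.
boundary_optical_depths <- function(phantom) {
  d <- cumsum(phantom$media$thickness_mm * phantom$media$group_index)
  c(cornea_front = 0, cornea_back = d[1], lens_front = d[2],
    lens_back = d[3], retina_post = d[4])
}

#' Ground-truth axial dimensions of a phantom
#'
#' Returns the geometric dimensions a perfect biometer should report:
#' AXL (anterior corneal surface to the posterior retinal boundary), ACD
#' (anterior corneal surface to anterior lens surface, i.e. including CCT),
#' LT and CCT. When the RPE is elevated (`rpe_elevation_um > 0`) the AXL
#' target is Bruch's membrane, not the elevated RPE; both depths are
#' reported so the manual-correction workflow can be verified against truth.
#'
#' @param phantom An [build_phantom()] object.
#' @return A list of class `biometry_truth` with elements `axl_mm`, `acd_mm`,
#'   `lt_mm`, `cct_um`, plus `rpe_mm` (depth of the imaged RPE reflector) and
#'   `bruch_mm` (depth of Bruch's membrane).
#' @export
geometric_dimensions <- function(phantom) {
  stopifnot(inherits(phantom, "eye_phantom"))
  th <- phantom$media$thickness_mm
  bruch_mm <- phantom$rpe_depth_mm + phantom$retina$bruch_offset_um / 1000
  rpe_mm <- phantom$rpe_depth_mm - phantom$retina$rpe_elevation_um / 1000
  axl_mm <- if (phantom$retina$rpe_elevation_um > 0) bruch_mm else phantom$rpe_depth_mm
  structure(
    list(
      axl_mm = axl_mm,
      acd_mm = th[1] + th[2],
      lt_mm = th[3],
      cct_um = th[1] * 1000,
      rpe_mm = rpe_mm,
      bruch_mm = bruch_mm
    ),
    class = "biometry_truth"
  )
}

#' @export
print.biometry_truth <- function(x, ...) {
  cat(sprintf("<biometry_truth> AXL %.4f mm | ACD %.4f mm | LT %.4f mm | CCT %.2f um\n",
              x$axl_mm, x$acd_mm, x$lt_mm, x$cct_um))
  invisible(x)
}

#' Optical path length between two boundaries
#'
#' Sum of group-index-weighted geometric thicknesses over the media traversed
#' between two anatomical boundaries; this is the quantity the OCT depth axis
#' actually measures.
#'
#' @param phantom An `eye_phantom`.
#' @param from,to Boundary ids among `cornea_front`, `cornea_back`,
#'   `lens_front`, `lens_back`, `retina_post`; `from` must be anterior to `to`.
#' @return Optical length in mm.
#' @export
optical_path <- function(phantom, from, to) {
  stopifnot(inherits(phantom, "eye_phantom"))
  opt <- boundary_optical_depths(phantom)
  from <- match.arg(from, BOUNDARIES)
  to <- match.arg(to, BOUNDARIES)
  if (match(from, BOUNDARIES) >= match(to, BOUNDARIES))
    stop("optical_path: 'from' must be anterior to 'to'")
  unname(opt[to] - opt[from])
}

# Optical depth of an arbitrary geometric depth z (mm from apex), piecewise
# through the media stack. Used to place intra-lens opacities.
geometric_to_optical_depth <- function(phantom, z_mm) {
  bounds <- boundary_depths(phantom)
  n <- phantom$media$group_index
  opt <- 0
  for (i in seq_len(4L)) {
    seg <- min(z_mm, bounds[i + 1L]) - bounds[i]
    if (seg <= 0) break
    opt <- opt + n[i] * seg
  }
  opt
}
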