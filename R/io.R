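#' Read a phantom specification from JSON
#'
#' The JSON schema (shipped at `inst/extdata/phantom-schema.json`) mirrors
#' [healthy_eye_spec()]: an ordered `media` array with `name`,
#' `thickness_mm`, `group_index`, `reflectivity`, plus optional `retina`
#' and `pathology` objects.
#'
#' @param path Path to a phantom JSON file.
#' @return An `eye_phantom` (validated via [build_phantom()]).
#' @export
read_phantom_spec <- function(path) {
  spec <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  build_phantom(spec)
}

#' Write a phantom specification to JSON
#'
#' @param phantom An `eye_phantom`.
#' @param path Output path.
#' @export
write_phantom_spec <- function(phantom, path) {
  stopifnot(inherits(phantom, "eye_phantom"))
  pathology <- phantom$pathology
  if (!is.finite(pathology$opacity_lateral_extent_mm))
    pathology$opacity_lateral_extent_mm <- NULL  # JSON has no Inf; reader defaults it
  jsonlite::write_json(list(media = phantom$media, retina = phantom$retina,
                            pathology = pathology),
                       path, auto_unbox = TRUE, pretty = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Serialize a boundary set to JSON
#'
#' Depths are optical millimetres on the apex reference; source and
#' confidence are kept per boundary.
#'
#' @param bset A `boundary_set`.
#' @param path Output path.
#' @export
write_boundary_json <- function(bset, path) {
  stopifnot(inherits(bset, "boundary_set"))
  jsonlite::write_json(list(units = "mm optical, apex-referenced",
                            boundaries = as.data.frame(bset)),
                       path, auto_unbox = TRUE, pretty = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Append a biometry result to a long-format measurements CSV
#'
#' Writes one row per parameter in the layout consumed by the statistics
#' module: `subject,eye,observer,session,shot_set,param,value,unit,status`.
#'
#' @param result A `biometry_result`.
#' @param path CSV path (created with header if absent).
#' @param subject,eye,observer,session,shot_set Identifying fields.
#' @export
append_biometry_csv <- function(result, path, subject = "S1", eye = "OD",
                                observer = 1, session = 1, shot_set = 1) {
  stopifnot(inherits(result, "biometry_result"))
  rows <- do.call(rbind, lapply(PARAMS, function(p) {
    e <- result$parameters[[p]]
    data.frame(subject = subject, eye = eye, observer = observer,
               session = session, shot_set = shot_set, param = p,
               value = e$mean, unit = unname(PARAM_UNITS[[p]]),
               status = e$status)
  }))
  utils::write.table(rows, path, sep = ",", row.names = FALSE,
                     col.names = !file.exists(path), append = file.exists(path),
                     qmethod = "double")
  invisible(path)
}

#' Read a long-format measurements CSV into a repeatability study
#'
#' Accepts the layout written by [append_biometry_csv()] (columns `subject`,
#' `observer`, `session` or `replicate`, `param` or `parameter`, `value`)
#' and returns a [repeatability_study()] table.
#'
#' @param path CSV path.
#' @return A `repeatability_study`.
#' @export
read_measurements_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("param" %in% names(d) && !"parameter" %in% names(d)) d$parameter <- d$param
  if ("session" %in% names(d) && !"replicate" %in% names(d)) d$replicate <- d$session
  repeatability_study(d[!is.na(d$value), , drop = FALSE])
}

#' Export a shot's measurement windows as a multi-page TIFF
#'
#' One 32-bit float page per acquired window, ordered role 1-4 within
#' horizontal then vertical. Requires the `tiff` package.
#'
#' @param shot A `boct_shot`.
#' @param path Output TIFF path.
#' @export
write_windows_tiff <- function(shot, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("write_windows_tiff requires the 'tiff' package")
  stopifnot(inherits(shot, "boct_shot"))
  pages <- list()
  for (o in c("horizontal", "vertical")) for (w in shot$windows[[o]]) {
    if (!is.null(w)) {
      img <- w$ascans / max(w$ascans, 1e-12)
      pages[[length(pages) + 1L]] <- img
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' Write a reproducibility manifest
#'
#' Records the configuration, seed and package version needed to reproduce
#' a run exactly.
#'
#' @param path Output JSON path.
#' @param config Configuration object/list to record.
#' @param seed Seed used.
#' @export
write_manifest <- function(path, config, seed) {
  jsonlite::write_json(
    list(package = "boct",
         version = as.character(utils::packageVersion("boct")),
         seed = seed, config = unclass(config),
         r_version = R.version.string),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA, na = "null", force = TRUE)
  invisible(path)
}

report_to_list <- function(r) unclass(r)[setdiff(names(unclass(r)), "data")]

write_repeatability_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(result$study),
                   file.path(out_dir, "measurements.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(intraobserver = lapply(result$intraobserver, lapply, report_to_list),
         interobserver = lapply(result$interobserver, report_to_list)),
    file.path(out_dir, "precision.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA, na = "null", force = TRUE)
  write_manifest(file.path(out_dir, "manifest.json"), result$protocol,
                 result$protocol$seed)
  invisible(out_dir)
}

write_agreement_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$pairs, file.path(out_dir, "pairs.csv"), row.names = FALSE)
  jsonlite::write_json(lapply(result$reports, report_to_list),
                       file.path(out_dir, "agreement.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA, na = "null",
                       force = TRUE)
  write_manifest(file.path(out_dir, "manifest.json"), result$protocol,
                 result$protocol$seed)
  invisible(out_dir)
}
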