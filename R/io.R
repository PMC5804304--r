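## Plain-text interchange: numeric CSV grids with JSON sidecars.

sidecar_path <- function(path) sub("\\.[^.]*$", ".json", path)

#' Write / read a Cartesian map with its JSON sidecar
#'
#' The CSV holds the numeric grid (row = y, column = x, no headers); the
#' sidecar records pixel pitch, origin, quantity, and the per-eye metadata.
#'
#' @param map a `cartesian_map`
#' @param meta an `eye_meta`
#' @param path CSV file path; the sidecar replaces the extension with .json
#' @return `write_cartesian_map` returns `path` invisibly;
#'   `read_cartesian_map` returns `list(map, meta)`
#' @export
write_cartesian_map <- function(map, meta, path) {
  stopifnot(inherits(map, "cartesian_map"))
  utils::write.table(map$values, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  side <- list(pitch_mm = map$pitch, origin_mm = map$origin,
               quantity = map$quantity,
               laterality = meta$laterality,
               axial_length_mm = meta$axial_length,
               disc_center_mm = meta$disc_center,
               fovea_center_mm = meta$fovea_center,
               disc_ellipse = meta$disc_ellipse)
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_cartesian_map
#' @export
read_cartesian_map <- function(path) {
  v <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(v) <- NULL
  side <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  map <- cartesian_map(v, pitch = side$pitch_mm, origin = side$origin_mm,
                       quantity = side$quantity)
  meta <- eye_meta(laterality = side$laterality,
                   axial_length = side$axial_length_mm,
                   disc_center = side$disc_center_mm,
                   fovea_center = side$fovea_center_mm,
                   disc_ellipse = side$disc_ellipse)
  list(map = map, meta = meta)
}

#' Write / read a polar annulus map with its JSON sidecar
#'
#' CSV rows are rings, columns angular samples; the sidecar records the
#' ring radii, quantity, and registration state.
#'
#' @param map a `polar_annulus_map`
#' @param path CSV file path
#' @return `write_polar_map` returns `path` invisibly; `read_polar_map`
#'   returns the `polar_annulus_map`
#' @export
write_polar_map <- function(map, path) {
  stopifnot(inherits(map, "polar_annulus_map"))
  utils::write.table(map$values, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  side <- list(radii_mm = map$radii, quantity = map$quantity,
               registered = map$registered,
               convention = "0=nasal midline, 180=temporal MPA, CCW right-eye handedness")
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_polar_map
#' @export
read_polar_map <- function(path) {
  v <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(v) <- NULL
  side <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  polar_annulus_map(v, radii = side$radii_mm, quantity = side$quantity,
                    registered = side$registered)
}

#' Write a per-eye analysis report as JSON
#'
#' @param report a report list from [analyze_eye()] or [run_pipeline()]
#' @param path file path
#' @return `path`, invisibly
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
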