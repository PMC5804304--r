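## Angular conventions
##
## Canonical (registered) frame, shared by all eyes after laterality
## normalization and maculopapillary-axis (MPA) alignment:
##   * origin at the disc center, distances in mm
##   * 0 deg  = nasal horizontal midline (+x)
##   * 180 deg = temporal MPA direction (-x after registration)
##   * angles increase counterclockwise for right eyes; left eyes are
##     mirrored first so all registered maps share one handedness
##   * superior hemisphere = (0, 180) deg, inferior = (180, 360) deg
## Angles are degrees everywhere except inside trigonometric evaluation.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

wrap360 <- function(x) x %% 360

#' Angular sample grid
#'
#' Bin centers used for all polar annulus maps: `n_theta` equal bins around
#' the circle, centered at (k - 1/2) * 360 / n_theta degrees so that no bin
#' straddles the hemisphere borders at 0 and 180 degrees.
#'
#' @param n_theta number of angular samples (default 1024)
#' @return numeric vector of bin-center angles in degrees
#' @export
theta_grid <- function(n_theta = 1024L) {
  (seq_len(n_theta) - 0.5) * 360 / n_theta
}

#' Default ring radii
#'
#' 21 equally spaced sampling-circle radii from 1.5 to 3.5 mm (diameters 3.0
#' to 7.0 mm), the annulus over which the NFL thickness map is analyzed.
#'
#' @param n number of rings
#' @param r_min,r_max innermost/outermost ring radius in mm
#' @return numeric vector of radii in mm
#' @export
default_radii <- function(n = 21L, r_min = 1.5, r_max = 3.5) {
  seq(r_min, r_max, length.out = n)
}

#' Per-eye metadata
#'
#' @param laterality "right" or "left"
#' @param axial_length axial eye length in mm (must lie in [20, 30])
#' @param disc_center optic disc center (x, y) in mm fundus coordinates
#' @param fovea_center foveal center (x, y) in mm fundus coordinates
#' @param disc_ellipse optional list(semi_axes = c(a, b) mm, rotation_deg)
#' @return an object of class `eye_meta`; the MPA angle (degrees) is derived
#'   from the disc and fovea centers and stored in `$mpa_angle`
#' @export
eye_meta <- function(laterality = c("right", "left"),
                     axial_length = 24.46,
                     disc_center = c(0, 0),
                     fovea_center = c(-4, 0),
                     disc_ellipse = list(semi_axes = c(0.9, 0.75),
                                         rotation_deg = 0)) {
  laterality <- match.arg(laterality)
  if (is.null(disc_center) || is.null(fovea_center) ||
      anyNA(disc_center) || anyNA(fovea_center)) {
    stop("incomplete metadata: disc_center and fovea_center are required")
  }
  if (axial_length < 20 || axial_length > 30) {
    stop("axial_length out of plausible range [20, 30] mm: ", axial_length)
  }
  out <- structure(
    list(laterality = laterality,
         axial_length = axial_length,
         disc_center = as.numeric(disc_center),
         fovea_center = as.numeric(fovea_center),
         disc_ellipse = disc_ellipse,
         mpa_angle = compute_mpa(disc_center, fovea_center)),
    class = "eye_meta")
  out
}

#' Polar annulus map
#'
#' A scalar field sampled on a fixed (ring radius x angle) grid around the
#' disc center: NFL thickness (um), flux density (mm^2 per bin), cos(beta),
#' or the ganglion-cell compensation coefficient gamma.
#'
#' @param values numeric matrix [ring x angle]
#' @param radii ring radii in mm (rows of `values`)
#' @param quantity one of "thickness_um", "flux_density", "cos_beta", "gamma"
#' @param registered logical; TRUE if the map is in the canonical angular
#'   convention (nasal midline at 0 deg, temporal MPA at 180 deg)
#' @return an object of class `polar_annulus_map`
#' @export
polar_annulus_map <- function(values,
                              radii = default_radii(),
                              quantity = c("thickness_um", "flux_density",
                                           "cos_beta", "gamma"),
                              registered = TRUE) {
  quantity <- match.arg(quantity)
  values <- as.matrix(values)
  if (nrow(values) != length(radii)) {
    stop("values must have one row per ring radius")
  }
  if (is.unsorted(radii, strictly = TRUE)) stop("radii must be increasing")
  if (quantity == "thickness_um" && any(values < 0, na.rm = TRUE)) {
    stop("thickness values must be >= 0")
  }
  if (quantity == "cos_beta" &&
      (any(values <= 0, na.rm = TRUE) || any(values > 1 + 1e-12, na.rm = TRUE))) {
    stop("cos_beta values must lie in (0, 1]")
  }
  if (quantity == "gamma" && any(values < 1 - 1e-9, na.rm = TRUE)) {
    stop("gamma values must be >= 1")
  }
  structure(
    list(values = values,
         radii = as.numeric(radii),
         theta = theta_grid(ncol(values)),
         quantity = quantity,
         registered = isTRUE(registered)),
    class = "polar_annulus_map")
}

#' @export
print.polar_annulus_map <- function(x, ...) {
  cat(sprintf("polar_annulus_map: %s, %d rings (%.2f-%.2f mm) x %d angles%s\n",
              x$quantity, nrow(x$values), min(x$radii), max(x$radii),
              ncol(x$values),
              if (x$registered) ", registered" else ", raw orientation"))
  invisible(x)
}

#' @export
print.eye_meta <- function(x, ...) {
  cat(sprintf("eye_meta: %s eye, AL %.2f mm, MPA %.2f deg\n",
              x$laterality, x$axial_length, x$mpa_angle))
  invisible(x)
}

## Periodic linear interpolation of each ring profile at shifted angles.
## `shift_deg` rotates the field counterclockwise: the returned sample at
## angle t equals the input field at angle t - shift_deg. Shifts that are
## exact multiples of the angular step reduce to a column permutation.
rotate_rows_periodic <- function(values, shift_deg) {
  n <- ncol(values)
  step <- 360 / n
  src <- (seq_len(n) - 1) - shift_deg / step
  i0 <- floor(src + 1e-12)
  w <- src - i0
  w[abs(w) < 1e-9] <- 0
  idx0 <- (as.integer(i0) %% n) + 1L
  idx1 <- ((as.integer(i0) + 1L) %% n) + 1L
  sweep(values[, idx0, drop = FALSE], 2, 1 - w, `*`) +
    sweep(values[, idx1, drop = FALSE], 2, w, `*`)
}

#' Register a polar map to the canonical orientation
#'
#' Rotates (and for left eyes, mirrors) a raw-orientation polar annulus map so
#' that all eyes share one convention: nasal midline at 0 deg, temporal MPA at
#' 180 deg, angles increasing counterclockwise in right-eye handedness, and
#' the superior hemisphere occupying (0, 180) deg. The whole map is rotated
#' rigidly by the MPA angle. Raw-orientation maps are assumed sampled with
#' angle measured counterclockwise from the +x fundus axis.
#'
#' @param map a `polar_annulus_map` with `registered = FALSE`
#' @param meta an `eye_meta`
#' @return the registered `polar_annulus_map`
#' @export
register_orientation <- function(map, meta) {
  stopifnot(inherits(map, "polar_annulus_map"), inherits(meta, "eye_meta"))
  if (isTRUE(map$registered)) return(map)
  if (is.null(meta$mpa_angle) || is.na(meta$mpa_angle)) {
    stop("incomplete metadata: MPA angle could not be derived")
  }
  v <- map$values
  if (meta$laterality == "left") {
    # mirror about the vertical fundus axis (x -> -x, raw angle t -> 180 - t):
    # the mirrored left eye has right-eye handedness with nasal at +x and
    # superior unchanged; bin centers at (k - 1/2) * step land back on the grid
    v <- mirror_columns_vertical(v)
  }
  mpa <- if (meta$laterality == "left") -meta$mpa_angle else meta$mpa_angle
  # raw frame: nasal = 0 deg (+x for a normalized right eye), MPA direction at
  # 180 + mpa; rotate by -mpa so the MPA sits at exactly 180 deg
  v <- rotate_rows_periodic(v, shift_deg = -mpa)
  out <- map
  out$values <- v
  out$registered <- TRUE
  out
}

#' Undo canonical registration
#'
#' Inverse of [register_orientation()]; used for round-trip checks and for
#' rendering results back in the raw fundus orientation.
#'
#' @inheritParams register_orientation
#' @return the raw-orientation `polar_annulus_map`
#' @export
unregister_orientation <- function(map, meta) {
  stopifnot(inherits(map, "polar_annulus_map"), inherits(meta, "eye_meta"))
  if (!isTRUE(map$registered)) return(map)
  mpa <- if (meta$laterality == "left") -meta$mpa_angle else meta$mpa_angle
  v <- rotate_rows_periodic(map$values, shift_deg = mpa)
  if (meta$laterality == "left") {
    v <- mirror_columns_vertical(v)
  }
  out <- map
  out$values <- v
  out$registered <- FALSE
  out
}

## column permutation realizing angle t -> 180 - t on the bin-center grid
mirror_columns_vertical <- function(values) {
  n <- ncol(values)
  idx <- ((n %/% 2L - seq_len(n)) %% n) + 1L
  values[, idx, drop = FALSE]
}

## indices of angular bins falling in each hemisphere (bin centers never sit
## exactly on 0/180 by construction of theta_grid)
hemisphere_bins <- function(theta) {
  list(superior = which(theta > 0 & theta < 180),
       inferior = which(theta > 180 & theta < 360))
}
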