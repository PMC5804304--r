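## Preprocessing: from a Cartesian NFL thickness map plus per-eye metadata to
## a corrected, registered polar annulus map of thickness.

#' Cartesian fundus map
#'
#' A scalar field on a regular mm grid in fundus coordinates. Rows index y
#' (increasing), columns index x (increasing).
#'
#' @param values numeric matrix [y x x]
#' @param pitch grid spacing in mm (isotropic)
#' @param origin (x, y) mm coordinates of the center of the first column/row
#' @param quantity free-text label ("thickness_um", "elevation_mm", ...)
#' @return object of class `cartesian_map`
#' @export
cartesian_map <- function(values, pitch, origin, quantity = "thickness_um") {
  values <- as.matrix(values)
  structure(list(values = values, pitch = pitch,
                 origin = as.numeric(origin), quantity = quantity),
            class = "cartesian_map")
}

cart_x <- function(map) map$origin[1] + (seq_len(ncol(map$values)) - 1) * map$pitch
cart_y <- function(map) map$origin[2] + (seq_len(nrow(map$values)) - 1) * map$pitch

#' @export
print.cartesian_map <- function(x, ...) {
  cat(sprintf("cartesian_map: %s, %d x %d px, pitch %.4g mm, x [%.2f, %.2f], y [%.2f, %.2f] mm\n",
              x$quantity, nrow(x$values), ncol(x$values), x$pitch,
              min(cart_x(x)), max(cart_x(x)), min(cart_y(x)), max(cart_y(x))))
  invisible(x)
}

#' Maculopapillary axis angle
#'
#' Signed angle between the fovea-to-disc axis and the horizontal, in
#' degrees, open interval (-90, 90). Positive when the disc sits superior to
#' the fovea along the axis (the typical configuration, population mean about
#' 7 degrees).
#'
#' @param disc_center,fovea_center (x, y) positions in mm fundus coordinates
#' @return MPA angle in degrees
#' @export
compute_mpa <- function(disc_center, fovea_center) {
  d <- as.numeric(disc_center) - as.numeric(fovea_center)
  if (sqrt(sum(d^2)) < 1e-9) {
    stop("disc and fovea centers coincide; MPA undefined")
  }
  if (abs(d[1]) < 1e-12) {
    stop("disc and fovea are vertically aligned; MPA angle undefined in (-90, 90)")
  }
  rad2deg(atan(d[2] / d[1]))
}

#' Tilt correction of an NFL thickness map
#'
#' Measured (axial) thickness overestimates true thickness where the inner
#' limiting membrane (ILM) is tilted with respect to the OCT axial line.
#' The correction multiplies thickness by cos(alpha), where alpha is the
#' angle between the local ILM surface normal and the axial direction:
#' cos(alpha) = (1 + |grad h|^2)^(-1/2) for an elevation graph h(x, y) in mm.
#' Gradients use central differences (one-sided at the borders).
#'
#' @param thickness `cartesian_map` of thickness (um)
#' @param ilm_elevation `cartesian_map` of ILM elevation (mm), same grid
#' @return corrected thickness `cartesian_map`; everywhere <= input
#' @export
tilt_correct <- function(thickness, ilm_elevation) {
  stopifnot(inherits(thickness, "cartesian_map"),
            inherits(ilm_elevation, "cartesian_map"))
  if (!identical(dim(thickness$values), dim(ilm_elevation$values)) ||
      abs(thickness$pitch - ilm_elevation$pitch) > 1e-12 ||
      any(abs(thickness$origin - ilm_elevation$origin) > 1e-9)) {
    stop("thickness and ILM elevation maps must share the same grid")
  }
  h <- ilm_elevation$values
  gy <- grad_1d(h, thickness$pitch, along = "rows")
  gx <- grad_1d(h, thickness$pitch, along = "cols")
  cos_alpha <- 1 / sqrt(1 + gx^2 + gy^2)
  out <- thickness
  out$values <- thickness$values * cos_alpha
  out
}

## central differences along rows (y) or columns (x); one-sided at borders
grad_1d <- function(m, pitch, along = c("rows", "cols")) {
  along <- match.arg(along)
  if (along == "cols") m <- t(m)
  n <- nrow(m)
  g <- matrix(0, n, ncol(m))
  if (n >= 3) g[2:(n - 1), ] <- (m[3:n, ] - m[1:(n - 2), ]) / (2 * pitch)
  if (n >= 2) {
    g[1, ] <- (m[2, ] - m[1, ]) / pitch
    g[n, ] <- (m[n, ] - m[n - 1, ]) / pitch
  }
  if (along == "cols") t(g) else g
}

#' Transverse magnification scale factor
#'
#' Bennett-style correction: the true transverse dimension scales with
#' (axial length - 1.82 mm) relative to the reference eye used for the scan
#' protocol (default 24.46 mm).
#'
#' @param axial_length axial eye length in mm
#' @param reference_axial_length reference axial length in mm
#' @return dimensionless scale factor
#' @export
magnification_scale <- function(axial_length, reference_axial_length = 24.46) {
  if (axial_length <= 1.82) stop("axial_length must exceed 1.82 mm")
  (axial_length - 1.82) / (reference_axial_length - 1.82)
}

#' Magnification correction of transverse dimensions
#'
#' Rescales the transverse (x, y) coordinates of a Cartesian map by the
#' axial-length-dependent magnification factor; thickness values are
#' unchanged. The accompanying metadata positions (disc, fovea) must be
#' rescaled with [magnification_correct_meta()] to stay consistent.
#'
#' @param map a `cartesian_map`
#' @param axial_length axial eye length in mm
#' @param reference_axial_length reference axial length in mm
#' @return map with pitch and origin multiplied by the scale factor
#' @export
magnification_correct <- function(map, axial_length,
                                  reference_axial_length = 24.46) {
  stopifnot(inherits(map, "cartesian_map"))
  s <- magnification_scale(axial_length, reference_axial_length)
  out <- map
  out$pitch <- map$pitch * s
  out$origin <- map$origin * s
  out
}

#' @rdname magnification_correct
#' @param meta an `eye_meta`
#' @export
magnification_correct_meta <- function(meta, axial_length = meta$axial_length,
                                       reference_axial_length = 24.46) {
  s <- magnification_scale(axial_length, reference_axial_length)
  out <- meta
  out$disc_center <- meta$disc_center * s
  out$fovea_center <- meta$fovea_center * s
  if (!is.null(meta$disc_ellipse$semi_axes)) {
    out$disc_ellipse$semi_axes <- meta$disc_ellipse$semi_axes * s
  }
  out$mpa_angle <- compute_mpa(out$disc_center, out$fovea_center)
  out
}

#' Resample a Cartesian thickness map onto the polar annulus grid
#'
#' Samples 21 concentric rings (radii 1.5 to 3.5 mm around the disc center)
#' at 1024 angular positions by bilinear interpolation, applying the
#' canonical orientation registration (laterality mirroring and rigid MPA
#' rotation) in the same sampling pass.
#'
#' @param map `cartesian_map` of thickness (um)
#' @param meta `eye_meta`
#' @param radii ring radii in mm
#' @param n_theta angular samples per ring
#' @return registered `polar_annulus_map` of thickness
#' @export
resample_polar <- function(map, meta, radii = default_radii(),
                           n_theta = 1024L) {
  stopifnot(inherits(map, "cartesian_map"), inherits(meta, "eye_meta"))
  theta <- theta_grid(n_theta)
  xg <- cart_x(map); yg <- cart_y(map)
  vals <- matrix(NA_real_, length(radii), n_theta)
  mirror <- meta$laterality == "left"
  mpa_eff <- if (mirror) -meta$mpa_angle else meta$mpa_angle
  for (i in seq_along(radii)) {
    r <- radii[i]
    # canonical angle -> raw fundus angle (inverse of the registration)
    t_norm <- theta + mpa_eff               # mirrored/normalized frame
    t_raw <- if (mirror) 180 - t_norm else t_norm
    xp <- meta$disc_center[1] + r * cos(deg2rad(t_raw))
    yp <- meta$disc_center[2] + r * sin(deg2rad(t_raw))
    if (any(xp < min(xg)) || any(xp > max(xg)) ||
        any(yp < min(yg)) || any(yp > max(yg))) {
      stop(sprintf("ring at r = %.2f mm falls outside the map extent", r))
    }
    vals[i, ] <- pracma::interp2(xg, yg, map$values, xp, yp, method = "linear")
  }
  polar_annulus_map(vals, radii = radii, quantity = "thickness_um",
                    registered = TRUE)
}

#' Full preprocessing of one eye
#'
#' Applies, in order: tilt correction (if an ILM elevation map is supplied),
#' magnification correction, and polar resampling with orientation
#' registration.
#'
#' @param thickness `cartesian_map` of thickness (um)
#' @param meta `eye_meta`
#' @param ilm_elevation optional `cartesian_map` of ILM elevation (mm)
#' @param reference_axial_length reference axial length in mm
#' @param radii,n_theta polar grid
#' @return list with elements `polar` (registered `polar_annulus_map`) and
#'   `meta` (magnification-corrected `eye_meta`)
#' @export
preprocess_eye <- function(thickness, meta, ilm_elevation = NULL,
                           reference_axial_length = 24.46,
                           radii = default_radii(), n_theta = 1024L) {
  if (!is.null(ilm_elevation)) {
    thickness <- tilt_correct(thickness, ilm_elevation)
  }
  thickness <- magnification_correct(thickness, meta$axial_length,
                                     reference_axial_length)
  meta2 <- magnification_correct_meta(meta, meta$axial_length,
                                      reference_axial_length)
  list(polar = resample_polar(thickness, meta2, radii, n_theta),
       meta = meta2)
}
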