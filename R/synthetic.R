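## Synthetic eyes with known ground truth
##
## The generator constructs NFL thickness maps from a known trajectory
## family so that every pipeline stage can be validated against exact
## truth: per-track flux is prescribed (equal by default), thickness is
## synthesized as T = D / (r * cos beta) so ring flux is conserved by
## construction, track widths follow a double-hump angular density (narrow
## tracks superotemporally and inferotemporally, reproducing the classic
## double-hump thickness profile while per-track flux stays uniform),
## macular RGC termination and wedge defects scale the per-track flux, and
## measurement noise is added last.

#' Canonical arcuate trajectory family
#'
#' Builds a 64-border trajectory map from a smooth angular profile: border
#' positions at the anchor radius follow a uniform + von Mises boundary
#' density (bumps at the superotemporal/inferotemporal bundle positions, so
#' tracks are narrowest there), and the arc coefficient b is zero within 60
#' degrees of the nasal midline (nasal trajectories are radial) and along
#' the maculopapillary axis, rising as b_max * sin^2 over the arcuate span
#' in between (mirrored with opposite sign in the inferior hemisphere); the
#' exponent c is shared within a hemisphere.
#'
#' @param n_tracks tracks per hemisphere
#' @param r0 anchor (reference) radius in mm
#' @param b_max peak arc coefficient (degrees / mm^c)
#' @param c_exp shared arcuate exponent
#' @param bump_center superior bump position in degrees (inferior mirrored)
#' @param bump_kappa von Mises concentration of the boundary-density bump
#' @param bump_weight bump amplitude relative to the uniform floor
#' @param jitter optional numeric vector of 64 per-border angular offsets
#'   (degrees) applied at all radii
#' @param radii radii stored with the map
#' @return a `trajectory_map`
#' @export
trajectory_family <- function(n_tracks = 32L, r0 = 0.85, b_max = 6,
                              c_exp = 1.5, bump_center = 120,
                              bump_kappa = 4, bump_weight = 2,
                              jitter = NULL, radii = default_radii()) {
  ag <- seq(0, 180, by = 0.05)
  dens <- 1 + bump_weight * exp(bump_kappa * (cos(deg2rad(ag - bump_center)) - 1))
  cdf <- cumsum(dens) - dens / 2
  cdf <- (cdf - cdf[1]) / (cdf[length(cdf)] - cdf[1])
  a_sup <- stats::approx(cdf, ag, xout = (1:(n_tracks - 1)) / n_tracks)$y
  a_inf <- 360 - rev(a_sup)
  a_all <- c(0, a_sup, 180, a_inf)               # 64 border positions at r0
  if (!is.null(jitter)) {
    stopifnot(length(jitter) == 64)
    j <- jitter
    j[c(1, n_tracks + 1)] <- 0                   # hemisphere borders fixed
    a_all <- a_all + j
  }
  b_of <- function(a) {
    # superior arc confined to (60, 180); inferior mirror on (180, 300)
    sup <- function(x) {
      ifelse(x > 60 & x < 180, b_max * sin(pi * (x - 60) / 120)^2, 0)
    }
    ifelse(a <= 180, sup(a), -sup(360 - a))
  }
  boundaries <- lapply(seq_along(a_all), function(i) {
    a <- a_all[i]
    fixed <- i == 1L || i == n_tracks + 1L
    b <- if (fixed) 0 else b_of(a)
    arcuate_model(a, b, if (b == 0) 1 else c_exp, r0, zero_b = b == 0)
  })
  trajectory_map(boundaries, radii)
}

#' Specification of a synthetic eye
#'
#' Captures every knob of the generator; defaults are the package's
#' reference study conditions. `mpa_angle = NULL` draws from the healthy
#' population distribution N(6.8, 3.1^2) degrees.
#'
#' @param seed integer RNG seed; same seed gives identical output
#' @param laterality "right" or "left"
#' @param axial_length axial length in mm
#' @param mpa_angle MPA angle in degrees, or NULL to draw
#' @param jitter_sd SD (degrees) of the per-eye smooth angular perturbation
#'   of border positions (low-order Fourier series in angle, 3 modes)
#' @param noise_sd_um additive Gaussian thickness noise SD in um
#' @param total_flux total NFF over the circle in mm^2 (0.94 mm^2 gives a
#'   ~100 um mean thickness at the innermost ring)
#' @param termination logical: apply macular RGC flux termination along
#'   temporal tracks
#' @param rgc `rgc_density_model` for the termination schedule (canonical
#'   frame); defaults to [rgc_density_model()] at the spec's fovea distance
#' @param fovea_distance disc-to-fovea distance in mm
#' @param zone_deg temporal angular zone for termination
#' @param defects list of `list(tracks = <indices 1..64>, scale = <(0,1]>)`
#'   wedge defects scaling per-track flux
#' @param b_max,c_exp,bump_center,bump_kappa,bump_weight family parameters,
#'   see [trajectory_family()]
#' @param smooth_fwhm_deg angular FWHM of the border-smoothing kernel
#' @param pitch Cartesian pixel pitch in mm (8 x 8 mm field)
#' @param radii,n_theta polar analysis grid
#' @return object of class `synthetic_eye_spec`
#' @export
synthetic_eye_spec <- function(seed = 1L, laterality = "right",
                               axial_length = 24.46, mpa_angle = NULL,
                               jitter_sd = 0, noise_sd_um = 0,
                               total_flux = 0.94, termination = FALSE,
                               rgc = NULL, fovea_distance = 4.0,
                               zone_deg = c(110, 270),
                               defects = list(),
                               b_max = 6, c_exp = 1.5, bump_center = 120,
                               bump_kappa = 4, bump_weight = 2,
                               smooth_fwhm_deg = 1.4, pitch = 0.025,
                               radii = default_radii(), n_theta = 1024L) {
  for (d in defects) {
    if (any(d$scale <= 0 | d$scale > 1)) stop("defect scale must be in (0, 1]")
  }
  if (is.null(rgc)) {
    rgc <- rgc_density_model(fovea_center = c(-fovea_distance, 0))
  }
  structure(as.list(environment()), class = "synthetic_eye_spec")
}

## smooth per-eye angular perturbation: 3-mode random Fourier series with
## total SD `sd` degrees, evaluated at border positions
draw_jitter_fun <- function(sd, n_modes = 3L) {
  if (sd <= 0) return(function(a) rep(0, length(a)))
  v <- sd^2 / n_modes
  ac <- stats::rnorm(n_modes, 0, sqrt(v))
  as <- stats::rnorm(n_modes, 0, sqrt(v))
  function(a) {
    w <- deg2rad(a)
    out <- numeric(length(a))
    for (k in seq_len(n_modes)) {
      out <- out + ac[k] * cos(k * w) + as[k] * sin(k * w)
    }
    out
  }
}

## ground-truth trajectory for a spec, with a non-crossing guard that halves
## the jitter amplitude if a draw would make borders cross
truth_trajectory <- function(spec, jitter_fun) {
  base <- trajectory_family(b_max = spec$b_max, c_exp = spec$c_exp,
                            bump_center = spec$bump_center,
                            bump_kappa = spec$bump_kappa,
                            bump_weight = spec$bump_weight,
                            radii = spec$radii)
  a0 <- vapply(base$boundaries, function(m) m$a, numeric(1))
  j <- jitter_fun(a0)
  for (try in 1:8) {
    traj <- trajectory_family(b_max = spec$b_max, c_exp = spec$c_exp,
                              bump_center = spec$bump_center,
                              bump_kappa = spec$bump_kappa,
                              bump_weight = spec$bump_weight,
                              jitter = j, radii = spec$radii)
    ba <- boundary_angles(traj, seq(min(spec$radii), 4.0, length.out = 15))
    if (all(apply(ba, 2, function(x) all(diff(x) > 0.05))) &&
        all(ba[64, ] < 359.95)) return(traj)
    j <- j / 2
  }
  trajectory_family(b_max = spec$b_max, c_exp = spec$c_exp,
                    bump_center = spec$bump_center,
                    bump_kappa = spec$bump_kappa,
                    bump_weight = spec$bump_weight, radii = spec$radii)
}

## per-track flux schedule [64 x n_r]: equal flux x (optionally) the macular
## termination schedule gated on the temporal zone; wedge defects are
## applied later as sharp angular masks (glaucomatous wedges have sharp
## edges, so they multiply the smoothed healthy profile rather than being
## blurred by the border-smoothing kernel)
track_flux_schedule <- function(spec, traj, r) {
  phi <- matrix(spec$total_flux / 64, 64, length(r))
  if (isTRUE(spec$termination)) {
    frac <- track_termination_fraction(traj, spec$rgc, r = r,
                                       r_in = min(spec$radii))
    cl <- centerline_angles(traj, r)
    inzone <- cl >= spec$zone_deg[1] & cl <= spec$zone_deg[2]
    s <- 1 - frac
    s[!inzone] <- 1
    phi <- phi * s
  }
  phi
}

## Gaussian circular smoothing of each row, kernel FWHM in degrees
smooth_rows_circular <- function(m, fwhm_deg) {
  n <- ncol(m)
  step <- 360 / n
  sigma <- fwhm_deg / 2.3548 / step
  if (sigma < 1e-9) return(m)
  half <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  t(apply(m, 1, function(x) {
    as.numeric(stats::filter(x, k, method = "convolution", sides = 2,
                             circular = TRUE))
  }))
}

## canonical-frame polar thickness (um) on an arbitrary (r x theta) grid
synth_polar_thickness <- function(spec, traj, radii, n_theta) {
  theta <- theta_grid(n_theta)
  step <- 360 / n_theta
  cb <- build_skew_map(traj, radii, n_theta)$values
  phi_n <- track_flux_schedule(spec, traj, radii)
  bb <- boundary_angles(traj, radii)             # [64 x n_r], bb[1, ] = 0
  nxt <- c(2:64, 1)
  up <- bb[nxt, , drop = FALSE]; up[64, ] <- up[64, ] + 360
  w <- deg2rad(up - bb)                          # widths, radians
  if (any(w <= 0)) stop("spec implies non-positive track width")
  dens <- phi_n / w                              # flux per radian
  edges <- deg2rad((0:n_theta) * step)
  out <- matrix(0, length(radii), n_theta)
  for (i in seq_along(radii)) {
    brd <- deg2rad(bb[, i])
    cumflux <- c(0, cumsum(phi_n[, i]))
    # cumulative flux at bin edges (piecewise linear, breakpoints at borders)
    k <- findInterval(edges, brd, rightmost.closed = FALSE)
    k[k < 1] <- 1
    cum_e <- cumflux[k] + dens[k, i] * (edges - brd[k])
    cum_e[length(cum_e)] <- cumflux[65]
    binavg <- diff(cum_e) / deg2rad(step)        # per-radian flux density
    out[i, ] <- binavg
  }
  out <- smooth_rows_circular(out, spec$smooth_fwhm_deg)
  # sharp wedge defects: per ring, scale every angular bin that overlaps the
  # affected tracks' ground-truth span. Quantizing the wedge edge outward to
  # whole bins makes the sharp defect exactly representable on the sampling
  # grid, so flux inside the span is scaled by exactly `scale`
  if (length(spec$defects)) {
    step_e <- 360 / n_theta
    bin_lo <- (0:(n_theta - 1)) * step_e
    bin_hi <- bin_lo + step_e
    for (d in spec$defects) {
      tk <- sort(d$tracks)
      for (i in seq_along(radii)) {
        lo <- bb[tk[1], i]
        hi <- if (max(tk) == 64L) 360 else bb[max(tk) + 1L, i]
        hit <- bin_hi > lo & bin_lo < hi
        out[i, hit] <- out[i, hit] * d$scale
      }
    }
  }
  # T (mm) = flux-per-radian / (r * cos beta); convert to um
  out <- out / sweep(cb, 1, radii, `*`) * 1000
  out
}

#' Generate a synthetic eye
#'
#' Produces an NFL thickness map with known ground truth. With
#' `output = "cartesian"` the map is an 8 x 8 mm raw-orientation Cartesian
#' grid plus metadata (the full pipeline input, including laterality
#' mirroring, MPA rotation, and magnification de-correction, so that
#' preprocessing recovers the canonical truth); with `output = "polar"` the
#' canonical registered polar map is returned directly (same construction,
#' no resampling step).
#'
#' @param spec a `synthetic_eye_spec`
#' @param output "cartesian" or "polar"
#' @return list with `thickness` (`cartesian_map` or `polar_annulus_map`),
#'   `meta` (`eye_meta`), `truth` (`trajectory_map`), `spec`
#' @export
generate_eye <- function(spec, output = c("cartesian", "polar")) {
  stopifnot(inherits(spec, "synthetic_eye_spec"))
  output <- match.arg(output)
  set.seed(spec$seed)
  mpa <- if (is.null(spec$mpa_angle)) stats::rnorm(1, 6.8, 3.1) else spec$mpa_angle
  jfun <- draw_jitter_fun(spec$jitter_sd)
  traj <- truth_trajectory(spec, jfun)

  mirror <- spec$laterality == "left"
  s_mag <- magnification_scale(spec$axial_length)
  fov_true <- c(-spec$fovea_distance * cos(deg2rad(mpa)),
                -spec$fovea_distance * sin(deg2rad(mpa)))
  if (mirror) fov_true[1] <- -fov_true[1]
  meta <- eye_meta(laterality = spec$laterality,
                   axial_length = spec$axial_length,
                   disc_center = c(0, 0),
                   fovea_center = fov_true / s_mag)

  if (output == "polar") {
    v <- synth_polar_thickness(spec, traj, spec$radii, spec$n_theta)
    if (spec$noise_sd_um > 0) {
      v <- pmax(v + stats::rnorm(length(v), 0, spec$noise_sd_um), 0)
    }
    thick <- polar_annulus_map(v, radii = spec$radii,
                               quantity = "thickness_um", registered = TRUE)
    return(list(thickness = thick, meta = meta, truth = traj, spec = spec,
                mpa_angle = mpa))
  }

  # fine canonical polar field, then resample onto the raw Cartesian grid;
  # the field is synthesized over the radii where the track model keeps
  # borders disjoint (analysis uses only 1.5-3.5 mm) and clamped outside
  rf <- seq(1.0, 4.0, by = 0.02)
  ntf <- 2048L
  vf <- synth_polar_thickness(spec, traj, rf, ntf)
  thf <- theta_grid(ntf)
  # periodic closure in angle for bilinear interpolation
  thf_ext <- c(thf[length(thf)] - 360, thf, thf[1] + 360)
  vf_ext <- cbind(vf[, ncol(vf)], vf, vf[, 1])

  n_px <- round(8 / spec$pitch)
  xs <- -4 + (seq_len(n_px) - 0.5) * spec$pitch
  ys <- xs
  # image coords -> true mm (magnification), then to canonical polar
  gx <- matrix(xs, n_px, n_px, byrow = TRUE) * s_mag
  gy <- matrix(ys, n_px, n_px) * s_mag
  if (mirror) gx <- -gx
  r_px <- sqrt(gx^2 + gy^2)
  t_raw <- rad2deg(atan2(gy, gx))
  t_norm <- t_raw                                 # right-eye handedness
  mpa_eff <- if (mirror) mpa else mpa             # mirrored frame keeps +mpa
  t_can <- wrap360(t_norm - mpa_eff)
  r_cl <- pmin(pmax(r_px, min(rf)), max(rf))
  vals <- pracma::interp2(thf_ext, rf, vf_ext, as.numeric(t_can),
                          as.numeric(r_cl), method = "linear")
  vals <- matrix(vals, n_px, n_px)
  if (spec$noise_sd_um > 0) {
    vals <- pmax(vals + stats::rnorm(length(vals), 0, spec$noise_sd_um), 0)
  }
  thick <- cartesian_map(vals, pitch = spec$pitch,
                         origin = c(xs[1], ys[1]),
                         quantity = "thickness_um")
  list(thickness = thick, meta = meta, truth = traj, spec = spec,
       mpa_angle = mpa)
}

#' Generate a synthetic cohort
#'
#' Healthy eyes share the canonical trajectory family with per-eye smooth
#' angular jitter; glaucomatous eyes add an arcuate wedge defect (contiguous
#' tracks scaled by a factor in (0.3, 0.6)). Cohort sizes default to 24
#' healthy and 10 glaucomatous eyes.
#'
#' @param n_healthy,n_glaucoma cohort sizes
#' @param seed RNG seed controlling all per-eye seeds and defect draws
#' @param jitter_sd per-eye angular jitter SD in degrees
#' @param noise_sd_um thickness noise SD in um
#' @param output "cartesian" or "polar" (see [generate_eye()])
#' @param ... further arguments passed to [synthetic_eye_spec()]
#' @return list with `healthy` and `glaucoma` (lists of [generate_eye()]
#'   results) and a `manifest` data frame of ground-truth descriptors
#' @export
generate_cohort <- function(n_healthy = 24L, n_glaucoma = 10L, seed = 1L,
                            jitter_sd = 5, noise_sd_um = 2,
                            output = "polar", ...) {
  stopifnot(n_healthy >= 0, n_glaucoma >= 0)
  set.seed(seed)
  eye_seeds <- sample.int(.Machine$integer.max %/% 2, n_healthy + n_glaucoma)
  healthy <- vector("list", n_healthy)
  glaucoma <- vector("list", n_glaucoma)
  rows <- list()
  for (i in seq_len(n_healthy)) {
    sp <- synthetic_eye_spec(seed = eye_seeds[i], jitter_sd = jitter_sd,
                             noise_sd_um = noise_sd_um, ...)
    healthy[[i]] <- generate_eye(sp, output = output)
    rows[[length(rows) + 1]] <- data.frame(
      id = sprintf("H%02d", i), group = "healthy", seed = eye_seeds[i],
      mpa_angle = healthy[[i]]$mpa_angle,
      defect_tracks = "", defect_scale = NA_real_)
  }
  for (i in seq_len(n_glaucoma)) {
    set.seed(eye_seeds[n_healthy + i])
    hemi <- sample(c("superior", "inferior"), 1)
    start <- sample(8:24, 1) + if (hemi == "inferior") 32L else 0L
    tracks <- start:(start + sample(4:7, 1))
    scale <- stats::runif(1, 0.3, 0.6)
    sp <- synthetic_eye_spec(seed = eye_seeds[n_healthy + i],
                             jitter_sd = jitter_sd,
                             noise_sd_um = noise_sd_um,
                             defects = list(list(tracks = tracks,
                                                 scale = scale)), ...)
    glaucoma[[i]] <- generate_eye(sp, output = output)
    rows[[length(rows) + 1]] <- data.frame(
      id = sprintf("G%02d", i), group = "glaucoma",
      seed = eye_seeds[n_healthy + i],
      mpa_angle = glaucoma[[i]]$mpa_angle,
      defect_tracks = paste(range(tracks), collapse = "-"),
      defect_scale = scale)
  }
  list(healthy = healthy, glaucoma = glaucoma,
       manifest = if (length(rows)) do.call(rbind, rows) else
         data.frame(id = character(), group = character(),
                    seed = integer(), mpa_angle = numeric(),
                    defect_tracks = character(), defect_scale = numeric()))
}
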