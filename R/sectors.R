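## Sector analysis: NFF per track, Garway-Heath-style 8-sector aggregation,
## deviation maps, and normative classification.

#' Eight-sector scheme anchored at the disc rim
#'
#' Angular demarcations at the 1.7-mm-diameter anchor circle dividing each
#' hemisphere into four sectors: papillomacular (PM, adjacent to the
#' temporal MPA), inner arcuate (IA), outer arcuate (OA), and temporal
#' field (TF, most nasal; nasal retina maps to the temporal visual field).
#' Default demarcations sit at 40, 80 and 120 degrees from the temporal
#' axis on each side (a Garway-Heath-style disc-rim division expressed in
#' the canonical nasal-origin convention); they are configurable and every
#' flux table records the anchors used.
#'
#' @param anchor_diameter anchor circle diameter in mm
#' @param anchor_angles 8 increasing demarcation angles in [0, 360), the
#'   first being the nasal midline at 0
#' @param labels sector labels, sector i spanning
#'   `[anchor_angles[i], anchor_angles[i+1])`
#' @return object of class `sector_scheme`
#' @export
sector_scheme <- function(anchor_diameter = 1.7,
                          anchor_angles = c(0, 60, 100, 140,
                                            180, 220, 260, 300),
                          labels = c("TF_sup", "OA_sup", "IA_sup", "PM_sup",
                                     "PM_inf", "IA_inf", "OA_inf", "TF_inf")) {
  if (any(anchor_angles < 0 | anchor_angles >= 360)) {
    stop("anchor angles must lie in [0, 360)")
  }
  if (is.unsorted(anchor_angles, strictly = TRUE)) {
    stop("anchor angles must be strictly increasing around the circle")
  }
  stopifnot(length(anchor_angles) == 8, length(labels) == 8)
  structure(list(anchor_diameter = anchor_diameter,
                 anchor_angles = anchor_angles, labels = labels),
            class = "sector_scheme")
}

#' Propagate sector demarcations outward along the trajectory field
#'
#' Each anchor demarcation is carried outward as an arcuate line anchored at
#' (r0, anchor angle), with arc parameters (b, c) interpolated in angle
#' between the template's border models within the hemisphere. Each of the
#' 64 tracks is assigned to exactly one sector by its centerline angle at
#' the anchor circle.
#'
#' @param template a `normative_template`
#' @param scheme a `sector_scheme`
#' @return list with `models` (8 `arcuate_model` demarcation lines),
#'   `assignment` (integer 64, sector index per track), `labels`
#' @export
propagate_sectors <- function(template, scheme = sector_scheme()) {
  stopifnot(inherits(template, "normative_template"),
            inherits(scheme, "sector_scheme"))
  traj <- template$trajectory
  r0 <- traj$boundaries[[1]]$r0
  av <- vapply(traj$boundaries, function(m) m$a, numeric(1))
  bv <- vapply(traj$boundaries, function(m) m$b, numeric(1))
  cv <- vapply(traj$boundaries, function(m) m$c, numeric(1))
  interp_par <- function(A) {
    # knots within the hemisphere containing A, including the fixed radial
    # borders; periodic closure for the inferior hemisphere's nasal end
    if (A <= 180) idx <- 1:33 else idx <- c(33:64, 1)
    x <- av[idx]; x[x == 0 & seq_along(idx) > 1] <- 360
    b <- stats::approx(x, bv[idx], xout = A, rule = 2, ties = mean)$y
    cc <- stats::approx(x, cv[idx], xout = A, rule = 2, ties = mean)$y
    list(b = b, c = max(cc, 0.05))
  }
  models <- lapply(scheme$anchor_angles, function(A) {
    if (A %in% c(0, 180)) return(arcuate_model(A, 0, 1, r0, zero_b = TRUE))
    p <- interp_par(A)
    arcuate_model(A, p$b, p$c, r0)
  })
  cl_a <- centerline_angles(traj, r0)[, 1]
  assignment <- findInterval(cl_a, c(scheme$anchor_angles, 360),
                             rightmost.closed = TRUE)
  assignment[assignment > 8L] <- 8L
  list(models = models, assignment = assignment, labels = scheme$labels)
}

## piecewise-linear cumulative flux around the full circle, evaluated at
## arbitrary angles (degrees); bin_flux over theta_grid bins
cum_flux_at <- function(bin_flux, angles) {
  n <- length(bin_flux)
  step <- 360 / n
  edges <- (0:n) * step
  cum <- c(0, cumsum(bin_flux))
  stats::approx(edges, cum, xout = angles, rule = 2)$y
}

#' NFF per track of a test eye
#'
#' Applies the normative template to a registered test-eye thickness map:
#' per ring and track, flux is the arc integration of the cosine-corrected
#' nerve fiber area over the track's angular span,
#' Phi(ring, n) = sum over theta in track of T * cos(beta) * r * dtheta.
#' The macular compensation gamma is never applied to test eyes. Track
#' summaries aggregate the rings by mean (each ring estimates the same
#' conserved flux; `ring_agg = "sum"` is available), the overall NFF is the
#' sum of track summaries, and sector fluxes sum the member tracks.
#'
#' @param test registered `polar_annulus_map` of thickness (um)
#' @param template a `normative_template` on the same grid
#' @param scheme a `sector_scheme`
#' @param ring_agg "mean" (default) or "sum" across the rings
#' @return object of class `flux_table` with `per_track` (matrix
#'   [ring x 64], mm^2), `track_flux` (64), `sector_flux` (named 8),
#'   `overall_flux`, `assignment`, `ring_agg`, `fingerprint`
#' @export
nff_per_track <- function(test, template, scheme = sector_scheme(),
                          ring_agg = c("mean", "sum")) {
  stopifnot(inherits(test, "polar_annulus_map"),
            inherits(template, "normative_template"))
  ring_agg <- match.arg(ring_agg)
  if (length(test$radii) != length(template$radii) ||
      any(abs(test$radii - template$radii) > 1e-9) ||
      ncol(test$values) != ncol(template$cos_beta$values)) {
    stop("test map and template grids do not match")
  }
  dens <- flux_density(test, cos_beta = template$cos_beta)
  ba <- boundary_angles(template$trajectory, test$radii)   # [64 x n_r]
  n_r <- length(test$radii)
  per_track <- matrix(0, n_r, 64)
  for (i in seq_len(n_r)) {
    cums <- cum_flux_at(dens$values[i, ], ba[, i])
    total <- sum(dens$values[i, ])
    per_track[i, ] <- c(diff(cums), total - cums[64])
  }
  track_flux <- if (ring_agg == "mean") colMeans(per_track) else
    colSums(per_track)
  prop <- propagate_sectors(template, scheme)
  sector_flux <- vapply(1:8, function(s) {
    sum(track_flux[prop$assignment == s])
  }, numeric(1))
  names(sector_flux) <- prop$labels
  structure(
    list(per_track = per_track,
         track_flux = track_flux,
         sector_flux = sector_flux,
         overall_flux = sum(track_flux),
         assignment = prop$assignment,
         ring_agg = ring_agg,
         anchor_angles = scheme$anchor_angles,
         fingerprint = flux_fingerprint(test, template, scheme, ring_agg)),
    class = "flux_table")
}

## FNV-1a hash of the analysis configuration, guarding against mixing a
## normative reference with a differently configured test pipeline
flux_fingerprint <- function(test, template, scheme, ring_agg) {
  key <- paste(c(format(test$radii, digits = 10),
                 ncol(test$values),
                 format(scheme$anchor_angles, digits = 10),
                 scheme$anchor_diameter, scheme$labels, ring_agg,
                 template$trajectory$boundaries[[1]]$r0),
               collapse = "|")
  fnv1a32(key)
}

fnv1a32 <- function(s) {
  # FNV-1a over the UTF-8 code points, 32-bit arithmetic carried in doubles
  # (split multiply keeps every intermediate exactly representable)
  h <- 2166136261
  p <- 16777619
  for (b in utf8ToInt(s)) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    h1 <- h %/% 65536; h0 <- h %% 65536
    h <- (((h1 * p) %% 65536) * 65536 + h0 * p) %% 4294967296
  }
  sprintf("%08x", h)
}

#' @export
print.flux_table <- function(x, ...) {
  cat(sprintf("flux_table: overall NFF %.4f mm^2 (%s over %d rings)\n",
              x$overall_flux, x$ring_agg, nrow(x$per_track)))
  print(round(x$sector_flux, 5))
  invisible(x)
}

#' Fraction deviation from a normal reference
#'
#' Elementwise 100 * (test - reference) / reference, the percentage
#' deviation map used to visualize focal loss. Zero reference entries are
#' masked as NA and flagged in the `masked` attribute.
#'
#' @param test numeric vector/matrix (e.g. thickness map values or per-track
#'   flux), or `polar_annulus_map` / `flux_table`
#' @param reference matching reference values
#' @return numeric deviations in percent, same shape as `test`
#' @export
deviation_map <- function(test, reference) {
  tv <- if (inherits(test, "polar_annulus_map")) test$values else
    if (inherits(test, "flux_table")) test$track_flux else test
  rv <- if (inherits(reference, "polar_annulus_map")) reference$values else
    if (inherits(reference, "flux_table")) reference$track_flux else reference
  if (length(tv) != length(rv)) stop("test and reference shapes differ")
  out <- 100 * (tv - rv) / rv
  masked <- rv == 0
  out[masked] <- NA_real_
  attr(out, "masked") <- any(masked)
  out
}

#' Classify sectors against the normative reference
#'
#' A sector is abnormal when its NFF falls strictly below the normative 5th
#' percentile (a value exactly at the percentile is classified normal).
#'
#' @param flux a `flux_table` for the test eye
#' @param normative a `normative_flux` built with the same configuration
#' @return data frame with sector, flux, reference p5, margin
#'   (flux - p5), and abnormal flag; overall row appended as attribute
#'   `overall`
#' @export
classify_sectors <- function(flux, normative) {
  stopifnot(inherits(flux, "flux_table"), inherits(normative, "normative_flux"))
  if (!identical(flux$fingerprint, normative$fingerprint)) {
    stop("configuration mismatch between test pipeline and normative table")
  }
  p5 <- normative$sector$p5[match(names(flux$sector_flux),
                                  normative$sector$sector)]
  out <- data.frame(
    sector = names(flux$sector_flux),
    flux = as.numeric(flux$sector_flux),
    p5 = p5,
    margin = as.numeric(flux$sector_flux) - p5,
    abnormal = as.numeric(flux$sector_flux) < p5)
  attr(out, "overall") <- data.frame(
    flux = flux$overall_flux,
    p5 = normative$overall$p5,
    abnormal = flux$overall_flux < normative$overall$p5)
  out
}
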