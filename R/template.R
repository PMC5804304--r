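## Normative template: population-average trajectory, cos beta map, and
## normative flux reference distributions.

#' Average per-eye trajectories into a normative template
#'
#' Averages boundary angular positions across registered eyes at the shared
#' ring radii (angle-space averaging; averaging the non-linearly coupled
#' model parameters directly would distort trajectories), refits the
#' arcuate model to each averaged border line, and derives the average
#' cos beta map from the averaged trajectory. Per-border angular SD at each
#' radius is retained as a variability summary.
#'
#' @param trajectories list of >= 2 `trajectory_map` objects from
#'   registered, laterality-normalized, magnification-corrected eyes
#' @param radii ring radii (mm) for the averaging and the cos beta map
#' @param n_theta angular samples of the derived cos beta map
#' @param r0 arcuate reference radius (mm)
#' @param c_bounds exponent bounds for the refits
#' @return object of class `normative_template` with elements `trajectory`,
#'   `cos_beta`, `boundary_sd` (matrix [64 x length(radii)], degrees),
#'   `radii`, `n_eyes`
#' @export
average_trajectories <- function(trajectories, radii = default_radii(),
                                 n_theta = 1024L, r0 = 0.85,
                                 c_bounds = c(0.05, 5)) {
  if (length(trajectories) < 2) stop("need at least 2 eyes to average")
  angs <- lapply(trajectories, boundary_angles, r = radii)  # [64 x n_r] each
  arr <- simplify2array(angs)                               # 64 x n_r x n_eye
  mean_ang <- apply(arr, c(1, 2), mean)
  sd_ang <- apply(arr, c(1, 2), stats::sd)
  boundaries <- vector("list", 64)
  for (j in 1:64) {
    if (j == 1L) {
      boundaries[[j]] <- arcuate_model(0, 0, 1, r0, zero_b = TRUE)
    } else if (j == 33L) {
      boundaries[[j]] <- arcuate_model(180, 0, 1, r0, zero_b = TRUE)
    } else {
      boundaries[[j]] <- fit_arcuate_model(radii, mean_ang[j, ], r0 = r0,
                                           c_bounds = c_bounds)
    }
  }
  traj <- trajectory_map(boundaries, radii)
  structure(
    list(trajectory = traj,
         cos_beta = build_skew_map(traj, radii, n_theta),
         boundary_sd = sd_ang,
         radii = radii,
         n_eyes = length(trajectories)),
    class = "normative_template")
}

#' @export
print.normative_template <- function(x, ...) {
  cat(sprintf("normative_template: averaged from %d eyes, %d rings (%.2f-%.2f mm)\n",
              x$n_eyes, length(x$radii), min(x$radii), max(x$radii)))
  invisible(x)
}

#' Normative flux reference distributions
#'
#' Empirical per-track and per-sector reference (mean, SD, 5th percentile as
#' a linear-interpolated order statistic) from the healthy cohort's flux
#' tables, all computed with the same template.
#'
#' @param flux_tables list of >= 2 `flux_table` objects (see
#'   [nff_per_track()])
#' @return object of class `normative_flux` with data frames `track` and
#'   `sector`, a row `overall`, and the shared config fingerprint
#' @export
build_normative_flux <- function(flux_tables) {
  if (length(flux_tables) < 2) stop("need at least 2 eyes")
  fp <- unique(vapply(flux_tables, function(x) x$fingerprint, character(1)))
  if (length(fp) != 1) {
    stop("flux tables were produced under differing configurations")
  }
  track_mat <- vapply(flux_tables, function(x) x$track_flux, numeric(64))
  sector_mat <- vapply(flux_tables, function(x) x$sector_flux,
                       numeric(length(flux_tables[[1]]$sector_flux)))
  overall <- vapply(flux_tables, function(x) x$overall_flux, numeric(1))
  summarize <- function(m) {
    data.frame(mean = rowMeans(m),
               sd = apply(m, 1, stats::sd),
               p5 = apply(m, 1, stats::quantile, probs = 0.05, names = FALSE))
  }
  tr <- summarize(track_mat); tr$track <- seq_len(nrow(tr))
  se <- summarize(sector_mat); se$sector <- rownames(sector_mat)
  structure(
    list(track = tr, sector = se,
         overall = data.frame(mean = mean(overall), sd = stats::sd(overall),
                              p5 = stats::quantile(overall, 0.05,
                                                   names = FALSE)),
         n_eyes = length(flux_tables),
         fingerprint = fp),
    class = "normative_flux")
}

## serialize an arcuate model for JSON
.model_to_list <- function(m) {
  list(a = m$a, b = m$b, c = m$c, r0 = m$r0, zero_b = m$zero_b)
}

.model_from_list <- function(l) {
  arcuate_model(l$a, l$b, l$c, l$r0, zero_b = isTRUE(l$zero_b))
}

#' Write / read a normative template as JSON
#'
#' The template file stores the 64 border models, radii, per-border angular
#' SDs, and (when attached) the normative flux tables, so a template built
#' once from a healthy cohort can be applied to any test eye.
#'
#' @param template a `normative_template`
#' @param path file path
#' @param normative optional `normative_flux` to embed
#' @return `write_template` returns `path` invisibly; `read_template`
#'   returns a list with `template` and `normative` (NULL if absent)
#' @export
write_template <- function(template, path, normative = NULL) {
  stopifnot(inherits(template, "normative_template"))
  obj <- list(
    radii = template$radii,
    n_eyes = template$n_eyes,
    boundaries = lapply(template$trajectory$boundaries, .model_to_list),
    boundary_sd = template$boundary_sd,
    n_theta = ncol(template$cos_beta$values))
  if (!is.null(normative)) {
    obj$normative <- list(track = normative$track, sector = normative$sector,
                          overall = normative$overall,
                          n_eyes = normative$n_eyes,
                          fingerprint = normative$fingerprint)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_template
#' @export
read_template <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = TRUE)
  boundaries <- lapply(seq_len(nrow(obj$boundaries)), function(i) {
    .model_from_list(as.list(obj$boundaries[i, ]))
  })
  radii <- as.numeric(obj$radii)
  traj <- trajectory_map(boundaries, radii)
  template <- structure(
    list(trajectory = traj,
         cos_beta = build_skew_map(traj, radii, as.integer(obj$n_theta)),
         boundary_sd = as.matrix(obj$boundary_sd),
         radii = radii,
         n_eyes = obj$n_eyes),
    class = "normative_template")
  normative <- NULL
  if (!is.null(obj$normative)) {
    normative <- structure(
      list(track = obj$normative$track, sector = obj$normative$sector,
           overall = obj$normative$overall, n_eyes = obj$normative$n_eyes,
           fingerprint = obj$normative$fingerprint),
      class = "normative_flux")
  }
  list(template = template, normative = normative)
}
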