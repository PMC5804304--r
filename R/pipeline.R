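## Configuration and end-to-end orchestration:
## simulate -> preprocess -> trace -> gamma -> template -> analyze.

#' Default pipeline configuration
#'
#' One nested list holding every physical constant and tunable of the
#' pipeline: the 21-ring 1.5-3.5 mm annulus with 1024 angular samples, the
#' arcuate reference radius r0 = 0.85 mm, the 0.01-degree convergence
#' tolerance, the 110-270 degree compensation zone, the 1.7-mm sector
#' anchor circle, and the 5% normative cutoff.
#'
#' @return nested configuration list
#' @export
nff_default_config <- function() {
  list(
    grid = list(n_rings = 21L, r_min = 1.5, r_max = 3.5, n_theta = 1024L),
    preprocess = list(reference_axial_length = 24.46),
    trace = list(n_tracks = 32L, r0 = 0.85, tol_deg = 0.01, max_iter = 50L,
                 c_min = 0.05, c_max = 5),
    compensation = list(zone_deg = c(110, 270), r_beyond = 6.0,
                        fovea_distance = 4.0,
                        rgc = list(peak_density = 35000, pit_radius = 0.2,
                                   peak_radius = 1.7, decay_scale = 1.5)),
    sectors = list(anchor_diameter = 1.7,
                   anchor_angles = c(0, 60, 100, 140, 180, 220, 260, 300),
                   labels = c("TF_sup", "OA_sup", "IA_sup", "PM_sup",
                              "PM_inf", "IA_inf", "OA_inf", "TF_inf"),
                   ring_agg = "mean", cutoff = 0.05),
    cohort = list(n_healthy = 24L, n_glaucoma = 10L, jitter_sd = 5,
                  noise_sd_um = 2, termination = FALSE, output = "polar")
  )
}

#' Validate a configuration against the package schema
#'
#' Recursively checks that every key exists in [nff_default_config()];
#' unknown keys are rejected by name. Returns the config merged over the
#' defaults.
#'
#' @param config nested list of overrides (possibly partial)
#' @return the merged, validated configuration
#' @export
validate_config <- function(config = list()) {
  defaults <- nff_default_config()
  merge <- function(def, cfg, prefix = "") {
    bad <- setdiff(names(cfg), names(def))
    if (length(bad)) {
      stop("unknown configuration key(s): ",
           paste0(prefix, bad, collapse = ", "))
    }
    for (k in names(cfg)) {
      if (is.list(def[[k]]) && !is.null(names(def[[k]]))) {
        def[[k]] <- merge(def[[k]], as.list(cfg[[k]]),
                          paste0(prefix, k, "."))
      } else {
        def[[k]] <- cfg[[k]]
      }
    }
    def
  }
  merge(defaults, config)
}

config_radii <- function(config) {
  default_radii(config$grid$n_rings, config$grid$r_min, config$grid$r_max)
}

config_scheme <- function(config) {
  sector_scheme(config$sectors$anchor_diameter,
                config$sectors$anchor_angles, config$sectors$labels)
}

#' Analyze one test eye against a normative template
#'
#' Computes the NFF-per-track flux table, the per-track and per-sector
#' fraction deviations from the normative mean, and the 5%-cutoff sector
#' classification.
#'
#' @param polar registered `polar_annulus_map` of thickness (um)
#' @param template a `normative_template`
#' @param normative a `normative_flux`
#' @param scheme a `sector_scheme`
#' @param ring_agg ring aggregation rule
#' @return report list: `flux` (`flux_table`), `sectors` (classification
#'   data frame with deviation %), `overall`
#' @export
analyze_eye <- function(polar, template, normative,
                        scheme = sector_scheme(), ring_agg = "mean") {
  ft <- nff_per_track(polar, template, scheme, ring_agg = ring_agg)
  cls <- classify_sectors(ft, normative)
  ref_mean <- normative$sector$mean[match(cls$sector,
                                          normative$sector$sector)]
  cls$deviation_pct <- as.numeric(deviation_map(cls$flux, ref_mean))
  track_dev <- deviation_map(ft$track_flux, normative$track$mean)
  list(flux = ft, sectors = cls,
       track_deviation_pct = as.numeric(track_dev),
       overall = attr(cls, "overall"))
}

#' Run the full synthetic-cohort pipeline
#'
#' Generates a synthetic cohort, traces every healthy eye (with macular
#' compensation when the cohort emulates RGC termination), averages the
#' healthy trajectories into a normative template, builds the normative
#' flux reference, and analyzes every eye against it. All randomness is
#' governed by `seed`; rerunning with the same config and seed reproduces
#' the reports exactly.
#'
#' @param config configuration overrides (see [nff_default_config()])
#' @param seed integer seed
#' @param out_dir optional output directory; when given, the template,
#'   normative tables, per-eye reports, and manifest are written as
#'   JSON/CSV
#' @return list with `template`, `normative`, `reports` (per eye),
#'   `manifest`, `gamma`, `timings` (per-stage seconds), `config`
#' @export
run_pipeline <- function(config = list(), seed = 1L, out_dir = NULL) {
  config <- validate_config(config)
  radii <- config_radii(config)
  scheme <- config_scheme(config)
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()

  co <- config$cohort
  cohort <- generate_cohort(n_healthy = co$n_healthy,
                            n_glaucoma = co$n_glaucoma, seed = seed,
                            jitter_sd = co$jitter_sd,
                            noise_sd_um = co$noise_sd_um,
                            termination = co$termination,
                            output = co$output,
                            radii = radii, n_theta = config$grid$n_theta)
  timings["simulate"] <- tic() - t0; t0 <- tic()

  get_polar <- function(eye) {
    if (inherits(eye$thickness, "polar_annulus_map")) return(eye$thickness)
    preprocess_eye(eye$thickness, eye$meta,
                   reference_axial_length = config$preprocess$reference_axial_length,
                   radii = radii, n_theta = config$grid$n_theta)$polar
  }
  healthy_polar <- lapply(cohort$healthy, get_polar)
  glaucoma_polar <- lapply(cohort$glaucoma, get_polar)
  timings["preprocess"] <- tic() - t0; t0 <- tic()

  gamma <- NULL
  if (isTRUE(co$termination)) {
    rg <- config$compensation$rgc
    rgc <- rgc_density_model(peak_density = rg$peak_density,
                             pit_radius = rg$pit_radius,
                             peak_radius = rg$peak_radius,
                             decay_scale = rg$decay_scale,
                             fovea_center = c(-config$compensation$fovea_distance, 0))
    gamma <- compensation_map(trajectory_family(radii = radii), rgc,
                              radii = radii, n_theta = config$grid$n_theta,
                              zone_deg = config$compensation$zone_deg,
                              r_beyond = config$compensation$r_beyond)
  }
  timings["gamma"] <- tic() - t0; t0 <- tic()

  tr <- config$trace
  traces <- lapply(healthy_polar, function(p) {
    trace_iterate(p, gamma = gamma, n_tracks = tr$n_tracks, r0 = tr$r0,
                  tol_deg = tr$tol_deg, max_iter = tr$max_iter,
                  c_bounds = c(tr$c_min, tr$c_max))
  })
  timings["trace"] <- tic() - t0; t0 <- tic()

  template <- average_trajectories(lapply(traces, `[[`, "trajectory"),
                                   radii = radii,
                                   n_theta = config$grid$n_theta,
                                   r0 = tr$r0,
                                   c_bounds = c(tr$c_min, tr$c_max))
  healthy_flux <- lapply(healthy_polar, nff_per_track, template = template,
                         scheme = scheme, ring_agg = config$sectors$ring_agg)
  normative <- build_normative_flux(healthy_flux)
  timings["template"] <- tic() - t0; t0 <- tic()

  analyze <- function(p) analyze_eye(p, template, normative, scheme,
                                     config$sectors$ring_agg)
  reports <- list(healthy = lapply(healthy_polar, analyze),
                  glaucoma = lapply(glaucoma_polar, analyze))
  timings["analyze"] <- tic() - t0

  out <- list(template = template, normative = normative,
              reports = reports, manifest = cohort$manifest,
              gamma = gamma, traces = traces,
              timings = timings, config = config, seed = seed)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_template(template, file.path(out_dir, "template.json"), normative)
    utils::write.csv(cohort$manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
    dump_report <- function(rep, id) {
      write_report(list(
        id = id,
        overall_flux_mm2 = rep$flux$overall_flux,
        track_flux_mm2 = rep$flux$track_flux,
        track_deviation_pct = rep$track_deviation_pct,
        sectors = rep$sectors,
        anchors_deg = rep$flux$anchor_angles,
        fingerprint = rep$flux$fingerprint),
        file.path(out_dir, paste0(id, ".json")))
    }
    for (i in seq_along(reports$healthy)) {
      dump_report(reports$healthy[[i]], sprintf("H%02d", i))
    }
    for (i in seq_along(reports$glaucoma)) {
      dump_report(reports$glaucoma[[i]], sprintf("G%02d", i))
    }
    write_report(list(seed = seed, timings = as.list(timings),
                      config = config),
                 file.path(out_dir, "run.json"))
  }
  invisible(out)
}
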