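# Shared fixtures, built once per test run. The expensive objects (traced
# cohorts, templates) are memoized so several test files can reuse them.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fx)) {
    assign(name, force(expr), envir = .fx)
  }
  get(name, envir = .fx)
}

# 20 arcuate eyes (per-eye jitter, no noise) and their traces
fx_clean_traces <- function() {
  fixture("clean_traces", {
    eyes <- lapply(1:20, function(i) {
      generate_eye(synthetic_eye_spec(seed = 1000 + i, jitter_sd = 5,
                                      noise_sd_um = 0), output = "polar")
    })
    traces <- lapply(eyes, function(e) trace_iterate(e$thickness))
    list(eyes = eyes, traces = traces)
  })
}

# the same 20 eyes with 2 um thickness noise
fx_noisy_traces <- function() {
  fixture("noisy_traces", {
    eyes <- lapply(1:20, function(i) {
      generate_eye(synthetic_eye_spec(seed = 1000 + i, jitter_sd = 5,
                                      noise_sd_um = 2), output = "polar")
    })
    traces <- lapply(eyes, function(e) trace_iterate(e$thickness))
    list(eyes = eyes, traces = traces)
  })
}

# 24 healthy eyes with 5-degree angular jitter -> normative template
fx_template24 <- function() {
  fixture("template24", {
    co <- generate_cohort(n_healthy = 24, n_glaucoma = 0, seed = 42,
                          jitter_sd = 5, noise_sd_um = 2)
    traces <- lapply(co$healthy, function(e) trace_iterate(e$thickness))
    tmpl <- average_trajectories(lapply(traces, `[[`, "trajectory"))
    list(cohort = co, traces = traces, template = tmpl)
  })
}

# matched-trajectory reference setting for the defect pipeline: no-jitter
# healthy eyes -> template + normative flux
fx_defect_setup <- function() {
  fixture("defect_setup", {
    co <- generate_cohort(n_healthy = 10, n_glaucoma = 0, seed = 7,
                          jitter_sd = 0, noise_sd_um = 2)
    traces <- lapply(co$healthy, function(e) trace_iterate(e$thickness))
    tmpl <- average_trajectories(lapply(traces, `[[`, "trajectory"))
    fts <- lapply(co$healthy, function(e) nff_per_track(e$thickness, tmpl))
    list(template = tmpl, normative = build_normative_flux(fts),
         flux_tables = fts)
  })
}

# boundary recovery errors (degrees) of a trace against the eye's own truth
boundary_errors <- function(trace, eye) {
  radii <- eye$thickness$radii
  err <- boundary_angles(trace$trajectory, radii) -
    boundary_angles(eye$truth, radii)
  abs(err[-c(1, 33), ])   # fixed hemisphere borders carry no information
}
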