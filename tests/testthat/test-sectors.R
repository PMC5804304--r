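radial_template <- function() {
  traj <- trajectory_family(b_max = 0, bump_weight = 0)
  structure(list(trajectory = traj,
                 cos_beta = build_skew_map(traj),
                 boundary_sd = matrix(0, 64, 21),
                 radii = default_radii(), n_eyes = 1),
            class = "normative_template")
}

test_that("sector scheme validates its demarcations", {
  s <- sector_scheme()
  expect_equal(length(s$anchor_angles), 8)
  expect_error(sector_scheme(anchor_angles = c(-5, 60, 100, 140, 180,
                                               220, 260, 300)), "0, 360")
  expect_error(sector_scheme(anchor_angles = c(0, 100, 60, 140, 180,
                                               220, 260, 300)), "increasing")
})

test_that("sector propagation partitions the tracks and follows the field", {
  # radial template: demarcation lines constant in radius
  pr <- propagate_sectors(radial_template())
  for (m in pr$models) {
    expect_equal(eval_arcuate(m, c(1.5, 2.5, 3.5)), rep(m$a, 3))
  }
  expect_true(all(sort(unique(pr$assignment)) == 1:8))
  expect_equal(length(pr$assignment), 64)

  # arcuate family: propagated demarcation tracks the family's own border
  fam <- trajectory_family()
  tmpl <- structure(list(trajectory = fam, cos_beta = build_skew_map(fam),
                         boundary_sd = matrix(0, 64, 21),
                         radii = default_radii(), n_eyes = 1),
                    class = "normative_template")
  pf <- propagate_sectors(tmpl)
  b_fam <- function(A) {
    sup <- function(x) ifelse(x > 60 & x < 180,
                              6 * sin(pi * (x - 60) / 120)^2, 0)
    ifelse(A <= 180, sup(A), -sup(360 - A))
  }
  for (k in seq_along(pf$models)) {
    A <- sector_scheme()$anchor_angles[k]
    if (A %in% c(0, 180)) next
    # ground truth: the family's own arc through the same anchor angle
    truth <- A + b_fam(A) * (3.5 - 0.85)^1.5
    expect_lt(abs(eval_arcuate(pf$models[[k]], 3.5) - truth), 1.0)
  }
})

test_that("per-track flux is symmetric, linear, and partitions the total", {
  tmpl <- radial_template()
  u <- polar_annulus_map(matrix(100, 21, 1024))
  ft <- nff_per_track(u, tmpl)
  # uniform field with radial uniform tracks: equal flux per track
  expect_lt(diff(range(ft$track_flux)) / mean(ft$track_flux), 1e-9)
  # partition: sector fluxes sum to the overall flux
  expect_equal(sum(ft$sector_flux), ft$overall_flux, tolerance = 1e-12)
  expect_equal(sum(ft$track_flux), ft$overall_flux, tolerance = 1e-12)

  # linearity
  ft2 <- nff_per_track(polar_annulus_map(matrix(200, 21, 1024)), tmpl)
  expect_equal(ft2$track_flux, 2 * ft$track_flux, tolerance = 1e-12)
  expect_equal(ft2$per_track, 2 * ft$per_track, tolerance = 1e-12)

  # ring aggregation rules
  fts <- nff_per_track(u, tmpl, ring_agg = "sum")
  expect_equal(fts$track_flux, 21 * ft$track_flux, tolerance = 1e-9)

  bad <- polar_annulus_map(matrix(100, 21, 512))
  expect_error(nff_per_track(bad, tmpl), "grids do not match")
})

test_that("skew correction lowers arcuate-sector flux, not nasal", {
  fx <- fx_defect_setup()
  eye <- generate_eye(synthetic_eye_spec(seed = 200, noise_sd_um = 0),
                      output = "polar")
  with_cos <- nff_per_track(eye$thickness, fx$template)
  flat <- fx$template
  flat$cos_beta <- polar_annulus_map(matrix(1, 21, 1024),
                                     quantity = "cos_beta")
  without <- nff_per_track(eye$thickness, flat)
  ratio <- with_cos$sector_flux / without$sector_flux
  expect_true(all(ratio <= 1 + 1e-12))
  expect_gt(ratio[["TF_sup"]], 0.99)     # near-radial nasal tracks
  expect_gt(ratio[["TF_inf"]], 0.99)
  expect_lt(ratio[["IA_sup"]], 0.97)     # arcuate bundles carry real skew
})

test_that("deviation maps are elementwise percentages with masking", {
  ref <- matrix(c(2, 4, 0, 8), 2)
  test <- matrix(c(2, 2, 1, 12), 2)
  d <- deviation_map(test, ref)
  expect_equal(d[1, 1], 0)
  expect_equal(d[2, 1], -50)
  expect_equal(d[2, 2], 50)
  expect_true(is.na(d[1, 2]))
  expect_true(attr(d, "masked"))
  # spreadsheet-style recomputation on a random pair
  set.seed(4)
  a <- matrix(runif(30, 1, 5), 5); b <- matrix(runif(30, 1, 5), 5)
  expect_equal(deviation_map(a, b), 100 * (a - b) / b,
               ignore_attr = TRUE)
})

test_that("classification applies a strict 5th-percentile cutoff", {
  fx <- fx_defect_setup()
  ft <- fx$flux_tables[[1]]

  # at the normative mean: all sectors normal
  ft_mean <- ft
  ft_mean$sector_flux[] <- fx$normative$sector$mean[
    match(names(ft$sector_flux), fx$normative$sector$sector)]
  cls <- classify_sectors(ft_mean, fx$normative)
  expect_false(any(cls$abnormal))

  # exactly at the percentile: classified normal (strict inequality)
  ft_p5 <- ft
  ft_p5$sector_flux[] <- fx$normative$sector$p5[
    match(names(ft$sector_flux), fx$normative$sector$sector)]
  cls5 <- classify_sectors(ft_p5, fx$normative)
  expect_false(any(cls5$abnormal))
  expect_equal(cls5$margin, rep(0, 8), tolerance = 1e-12)

  # configuration fingerprints must agree
  ft_bad <- ft
  ft_bad$fingerprint <- "deadbeef"
  expect_error(classify_sectors(ft_bad, fx$normative), "mismatch")
})

test_that("wedge defects reproduce their programmed depth and are flagged", {
  fx <- fx_defect_setup()
  spD <- synthetic_eye_spec(seed = 77, noise_sd_um = 2,
                            defects = list(list(tracks = 10:15, scale = 0.4)))
  spH <- synthetic_eye_spec(seed = 77, noise_sd_um = 2)
  ftD <- nff_per_track(generate_eye(spD, output = "polar")$thickness,
                       fx$template)
  ftH <- nff_per_track(generate_eye(spH, output = "polar")$thickness,
                       fx$template)
  ratio <- ftD$track_flux[10:15] / ftH$track_flux[10:15]
  expect_lt(max(abs(ratio / 0.4 - 1)), 0.02)
  # unaffected tracks barely move
  expect_lt(max(abs(ftD$track_flux[20:30] / ftH$track_flux[20:30] - 1)),
            0.02)
  cls <- classify_sectors(ftD, fx$normative)
  affected <- unique(ftD$assignment[10:15])
  expect_true(all(cls$abnormal[affected]))
})

test_that("arcuate defects hit arcuate sectors more often than PM/TF", {
  fx <- fx_defect_setup()
  co <- generate_cohort(n_healthy = 0, n_glaucoma = 8, seed = 19,
                        jitter_sd = 0, noise_sd_um = 2)
  flags <- sapply(co$glaucoma, function(e) {
    ft <- nff_per_track(e$thickness, fx$template)
    classify_sectors(ft, fx$normative)$abnormal
  })
  rate <- rowMeans(flags)
  names(rate) <- fx$normative$sector$sector
  arcuate <- mean(rate[c("IA_sup", "OA_sup", "IA_inf", "OA_inf")])
  quiet <- mean(rate[c("PM_sup", "TF_sup", "PM_inf", "TF_inf")])
  expect_gt(arcuate, quiet)
})
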