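test_that("the trajectory family is ordered, arcuate, and double-humped", {
  fam <- trajectory_family()
  ba <- boundary_angles(fam, default_radii())
  expect_true(all(apply(ba, 2, function(x) all(diff(x) > 0))))
  expect_equal(ba[1, ], rep(0, 21))
  expect_equal(ba[33, ], rep(180, 21))
  # narrowest tracks near the superotemporal bump
  w0 <- diff(ba[1:33, 1])
  expect_true(ba[which.min(w0), 1] > 90 && ba[which.min(w0), 1] < 150)
  # nasal borders near-radial, arcuate borders skewed
  expect_lt(abs(fam$boundaries[[2]]$b), 1)
  mid <- fam$boundaries[[17]]
  expect_gt(abs(mid$b), 3)
})

test_that("noise-free generated eyes conserve ring flux by construction", {
  # radial eye: exact conservation to float precision
  er <- generate_eye(synthetic_eye_spec(seed = 2, b_max = 0),
                     output = "polar")
  rf <- ring_flux(flux_density(er$thickness))
  expect_lt(max(abs(rf / mean(rf) - 1)), 1e-9)
  expect_equal(mean(rf), 0.94, tolerance = 1e-6)

  # arcuate eye: conserved after the generator's own cos beta correction
  ea <- generate_eye(synthetic_eye_spec(seed = 2), output = "polar")
  cb <- build_skew_map(ea$truth)
  rfa <- ring_flux(flux_density(ea$thickness, cos_beta = cb))
  expect_lt(max(abs(rfa / mean(rfa) - 1)), 1e-9)
})

test_that("generation is reproducible and seeds differ", {
  s <- synthetic_eye_spec(seed = 123, jitter_sd = 5, noise_sd_um = 2)
  e1 <- generate_eye(s, output = "polar")
  e2 <- generate_eye(s, output = "polar")
  expect_identical(e1$thickness$values, e2$thickness$values)
  expect_identical(e1$mpa_angle, e2$mpa_angle)
  e3 <- generate_eye(synthetic_eye_spec(seed = 124, jitter_sd = 5,
                                        noise_sd_um = 2), output = "polar")
  expect_false(identical(e1$thickness$values, e3$thickness$values))
})

test_that("the Cartesian path agrees with the direct polar construction", {
  sp <- synthetic_eye_spec(seed = 11, mpa_angle = 6.8, noise_sd_um = 0,
                           axial_length = 25.5)
  ec <- generate_eye(sp, output = "cartesian")
  expect_s3_class(ec$thickness, "cartesian_map")
  expect_equal(dim(ec$thickness$values), c(320L, 320L))
  pp <- preprocess_eye(ec$thickness, ec$meta)
  ep <- generate_eye(sp, output = "polar")
  d <- pp$polar$values - ep$thickness$values
  expect_lt(sqrt(mean(d^2)), 0.5)       # um, bilinear resampling error
  expect_lt(max(abs(d)), 2.5)
})

test_that("generated metadata encodes laterality, MPA, and magnification", {
  sp <- synthetic_eye_spec(seed = 6, laterality = "left", mpa_angle = 5,
                           axial_length = 26.28)
  e <- generate_eye(sp, output = "cartesian")
  expect_equal(e$meta$laterality, "left")
  expect_equal(e$meta$mpa_angle, -5, tolerance = 1e-9)
  s <- magnification_scale(26.28)
  expect_equal(sqrt(sum(e$meta$fovea_center^2)), 4.0 / s, tolerance = 1e-9)
})

test_that("cohorts share the family, record truth, and honor defects", {
  co <- generate_cohort(n_healthy = 3, n_glaucoma = 2, seed = 99,
                        jitter_sd = 5, noise_sd_um = 2)
  expect_length(co$healthy, 3)
  expect_length(co$glaucoma, 2)
  expect_equal(nrow(co$manifest), 5)
  expect_true(all(co$manifest$group == c(rep("healthy", 3),
                                         rep("glaucoma", 2))))
  expect_true(all(nchar(co$manifest$defect_tracks[4:5]) > 0))
  # distinct maps
  expect_false(identical(co$healthy[[1]]$thickness$values,
                         co$healthy[[2]]$thickness$values))

  co0 <- generate_cohort(0, 0, seed = 1)
  expect_equal(nrow(co0$manifest), 0)

  expect_error(synthetic_eye_spec(defects = list(list(tracks = 1:3,
                                                      scale = 1.5))),
               "scale")
})

test_that("defect eyes lose flux exactly where programmed", {
  spD <- synthetic_eye_spec(seed = 55, noise_sd_um = 0,
                            defects = list(list(tracks = 40:45,
                                                scale = 0.5)))
  spH <- synthetic_eye_spec(seed = 55, noise_sd_um = 0)
  eD <- generate_eye(spD, output = "polar")
  eH <- generate_eye(spH, output = "polar")
  cb <- build_skew_map(eH$truth)
  fD <- flux_density(eD$thickness, cos_beta = cb)
  fH <- flux_density(eH$thickness, cos_beta = cb)
  # total ring flux reduced by ~6/64 * 0.5
  expect_equal(mean(ring_flux(fD)) / mean(ring_flux(fH)),
               1 - 6 / 64 * 0.5, tolerance = 0.01)
})
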