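test_that("trajectory averaging is the boundary-wise angular mean", {
  fam <- trajectory_family()
  # identical inputs reproduce each input
  t1 <- average_trajectories(list(fam, fam, fam))
  expect_equal(boundary_angles(t1$trajectory, default_radii()),
               boundary_angles(fam, default_radii()), tolerance = 1e-6)
  expect_equal(max(t1$boundary_sd), 0, tolerance = 1e-9)

  # two radial maps at 40 and 50 degrees average to 45
  mk <- function(a) {
    b <- fam$boundaries
    b[[5]] <- arcuate_model(a, 0, 1, zero_b = TRUE)
    trajectory_map(b)
  }
  t2 <- average_trajectories(list(mk(40), mk(50)))
  expect_equal(eval_arcuate(t2$trajectory$boundaries[[5]], c(1.5, 2.5, 3.5)),
               rep(45, 3), tolerance = 1e-6)
  expect_error(average_trajectories(list(fam)), "at least 2")
})

test_that("averaging preserves monotone non-crossing boundaries", {
  fx <- fx_template24()
  ba <- boundary_angles(fx$template$trajectory, default_radii())
  expect_true(all(apply(ba, 2, function(x) all(diff(x) > 0))))
})

test_that("24 jittered eyes average back to the family truth", {
  fx <- fx_template24()
  fam <- trajectory_family()
  err <- abs(boundary_angles(fx$template$trajectory, 3.5) -
             boundary_angles(fam, 3.5))[-c(1, 33)]
  expect_lt(mean(err), 1.5)
  # per-border variability is of the order of the generator jitter
  expect_gt(mean(fx$template$boundary_sd[-c(1, 33), 21]), 1)
  expect_lt(mean(fx$template$boundary_sd[-c(1, 33), 21]), 8)
})

test_that("template cos beta reproduces the qualitative skew pattern", {
  fx <- fx_template24()
  cb <- fx$template$cos_beta
  nasal <- cb$theta < 60 | cb$theta > 300
  expect_true(all(cb$values[, nasal] > 0.99))
  # strongest skew sits temporally at the largest radii
  worst <- which(cb$values == min(cb$values), arr.ind = TRUE)[1, ]
  expect_gt(cb$radii[worst[1]], 3.0)
  expect_true(cb$theta[worst[2]] > 90 & cb$theta[worst[2]] < 270)
})

test_that("extrapolation follows the model and respects the cap", {
  m <- arcuate_model(30, 2, 1.5)
  expect_equal(extrapolate_model(m, 0.85), 30)
  expect_equal(extrapolate_model(m, 4.0), 30 + 2 * (4 - 0.85)^1.5)
  expect_error(extrapolate_model(m, 5.0), "extrapolation limit")
  expect_error(extrapolate_model(m, 0.5), "anchor")
})

test_that("normative flux reference gives the right order statistics", {
  fx <- fx_defect_setup()
  norm <- fx$normative
  expect_equal(nrow(norm$track), 64)
  expect_equal(nrow(norm$sector), 8)
  expect_true(all(norm$track$p5 <= norm$track$mean))

  # all-identical eyes: SD 0 and p5 at the common value
  same <- build_normative_flux(fx$flux_tables[c(1, 1, 1)])
  expect_equal(same$track$sd, rep(0, 64))
  expect_equal(same$track$p5, fx$flux_tables[[1]]$track_flux)

  # 24 draws from a known normal: p5 near the analytic quantile
  set.seed(31)
  stub <- lapply(1:24, function(i) {
    ft <- fx$flux_tables[[1]]
    ft$track_flux <- rnorm(64, 10, 1)
    ft$sector_flux[] <- rnorm(8, 10, 1)
    ft$overall_flux <- sum(ft$sector_flux)
    ft
  })
  nn <- build_normative_flux(stub)
  q5 <- qnorm(0.05, 10, 1)
  expect_equal(mean(nn$track$p5), q5, tolerance = 0.15)
})

test_that("template JSON round-trips losslessly", {
  fx <- fx_defect_setup()
  path <- tempfile(fileext = ".json")
  write_template(fx$template, path, fx$normative)
  back <- read_template(path)
  expect_equal(boundary_angles(back$template$trajectory, default_radii()),
               boundary_angles(fx$template$trajectory, default_radii()),
               tolerance = 1e-12)
  expect_equal(back$normative$sector$p5, fx$normative$sector$p5,
               tolerance = 1e-12)
  expect_equal(back$normative$fingerprint, fx$normative$fingerprint)
  unlink(path)
})
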