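test_that("flux density implements the polar flux element", {
  zero <- polar_annulus_map(matrix(0, 21, 1024))
  expect_equal(sum(flux_density(zero)$values), 0)

  # uniform 100 um ring: per-bin flux T*r*dtheta, ring flux 2*pi*r*T
  u <- polar_annulus_map(matrix(100, 21, 1024))
  d <- flux_density(u)
  i <- which(abs(u$radii - 2.0) < 1e-9)
  expect_equal(d$values[i, 1], 0.1 * 2.0 * (2 * pi / 1024))
  expect_equal(d$values[i, 1], 1.22718e-3, tolerance = 1e-5)
  expect_equal(ring_flux(d)[i], 2 * pi * 2.0 * 0.1)
  expect_equal(ring_flux(d)[i], 1.25664, tolerance = 1e-5)
})

test_that("equal-flux division splits each hemisphere exactly", {
  theta <- theta_grid(1024)

  # uniform density: boundaries at 180/32 = 5.625 degree intervals
  d <- divide_equal_flux(rep(1, 1024), theta)
  expect_equal(d$superior, seq(0, 180, by = 5.625))
  expect_equal(d$inferior, seq(180, 360, by = 5.625))

  # two rectangular bumps: 16 boundary intervals inside each bump, the
  # crossing boundary at the midpoint of the zero plateau between them
  f <- numeric(1024)
  bump1 <- theta > 20 & theta < 60
  bump2 <- theta > 120 & theta < 160
  f[bump1] <- 1; f[bump2] <- 1
  f[theta > 180] <- 1            # featureless inferior hemisphere
  d2 <- divide_equal_flux(f, theta)
  b <- d2$superior
  # 15 interior boundaries strictly inside each bump; the half-total
  # boundary sits at the midpoint of the zero plateau between them
  expect_equal(sum(b > 20 & b < 60), 15)
  expect_equal(sum(b > 60.5 & b < 119.5), 1)
  expect_equal(b[17], 90, tolerance = 0.5)
  expect_equal(sum(b > 120 & b < 160), 15)

  # by construction every track's flux equals total/32
  set.seed(5)
  g <- runif(1024, 0.1, 2)
  d3 <- divide_equal_flux(g, theta)
  step <- 360 / 1024
  edges <- (0:512) * step
  cum <- c(0, cumsum(g[theta < 180]))
  flux_at <- function(a) approx(edges, cum, xout = a)$y
  tf <- diff(sapply(d3$superior, flux_at))
  expect_lt(max(abs(tf / mean(tf) - 1)), 1e-9)

  expect_error(divide_equal_flux(c(rep(0, 512), rep(1, 512)), theta),
               "zero hemisphere flux")
})

test_that("division matches a dense brute-force cumulative inversion", {
  # oracle: cumulative sum on a 10^5-point grid, linear inversion
  oracle_divide <- function(f, theta) {
    fine <- seq(0, 180, length.out = 1e5)
    step <- 360 / length(theta)
    edges <- (0:sum(theta < 180)) * step
    cum <- c(0, cumsum(f[theta < 180]))
    dens_f <- approx(edges, cum, xout = fine)$y
    targets <- seq(0, max(dens_f), length.out = 33)
    sapply(targets, function(t) fine[which.min(abs(dens_f - t))])
  }
  theta <- theta_grid(1024)
  set.seed(11)
  worst <- 0
  for (k in 1:100) {
    f <- runif(1024, 0.05, 1) + runif(1, 0, 2) *
      exp(cos(pi / 180 * (theta - runif(1, 0, 360))) * runif(1, 0.5, 4))
    got <- divide_equal_flux(f, theta)$superior
    want <- oracle_divide(f, theta)
    worst <- max(worst, max(abs(got - want)))
  }
  expect_lt(worst, 0.01)
})

test_that("arcuate fits recover known parameters", {
  r <- default_radii()

  # exact recovery, noise free
  m <- fit_arcuate_model(r, 30 + 2.0 * (r - 0.85)^1.5)
  expect_equal(m$a, 30, tolerance = 1e-6)
  expect_equal(m$b, 2.0, tolerance = 1e-6)
  expect_equal(m$c, 1.5, tolerance = 1e-6)

  # radial track: exponent unidentifiable, flagged
  mr <- fit_arcuate_model(r, rep(45, 21))
  expect_equal(mr$a, 45)
  expect_equal(mr$b, 0)
  expect_equal(mr$c, 1)
  expect_true(mr$zero_b)

  # Monte Carlo under 0.5 deg angular noise: the mean recovered anchor
  # angle is within 0.5 deg of truth (a single draw carries sd ~0.75 deg
  # at this design: the anchor radius extrapolates below the data)
  errs <- vapply(1:100, function(s) {
    set.seed(s)
    phi <- 30 + 2.0 * (r - 0.85)^1.5 + rnorm(21, 0, 0.5)
    fit_arcuate_model(r, phi)$a - 30
  }, numeric(1))
  expect_lt(abs(mean(errs)), 0.5)
  expect_lt(stats::sd(errs), 1.5)

  expect_error(fit_arcuate_model(r[1:3], rep(1, 3)), "at least 5")
})

test_that("analytic skew angle matches a finite-difference oracle", {
  fd_beta <- function(m, r, h = 1e-6) {
    dphi <- (eval_arcuate(m, r + h) - eval_arcuate(m, r - h)) / (2 * h)
    atan(r * dphi * pi / 180) * 180 / pi
  }
  grid <- expand.grid(a = c(0, 30, 150), b = c(-6, -2, 0.5, 4, 8),
                      c = c(0.3, 0.8, 1, 1.5, 3))
  for (i in seq_len(nrow(grid))) {
    m <- arcuate_model(grid$a[i], grid$b[i], grid$c[i])
    for (r in c(1.5, 2.0, 3.0, 3.5)) {
      expect_equal(beta_from_model(m, r), fd_beta(m, r), tolerance = 1e-6)
    }
  }
  m0 <- arcuate_model(30, 0, 1)
  expect_equal(beta_from_model(m0, c(1.5, 3.5)), c(0, 0))
  expect_equal(cos(pi / 180 * beta_from_model(m0, 2)), 1, tolerance = 1e-12)
  expect_error(beta_from_model(m0, 0.5), "r >= r0")
})

test_that("skew map is exact for radial and analytic arcuate fields", {
  radial <- trajectory_family(b_max = 0)
  sm <- build_skew_map(radial, n_theta = 256)
  expect_equal(sm$values, matrix(1, 21, 256))

  # all tracks share (b, c): beta(r, theta) analytic everywhere
  traj <- trajectory_family(b_max = 4, bump_weight = 0)
  # force a common b on every border so interpolation is exact
  traj$boundaries <- lapply(traj$boundaries, function(m) {
    if (m$a %in% c(0, 180)) m else arcuate_model(m$a, ifelse(m$a < 180, 4, -4), 1.5)
  })
  sm2 <- build_skew_map(traj, n_theta = 512)
  beta_true <- function(r) atan(r * 4 * 1.5 * (r - 0.85)^0.5 * pi / 180) * 180 / pi
  for (i in c(1, 11, 21)) {
    r <- sm2$radii[i]
    # interior of the superior hemisphere, clear of the blending zones
    # next to the radial hemisphere borders
    cols <- sm2$theta > 30 & sm2$theta < 145
    beta_map <- acos(sm2$values[i, cols]) * 180 / pi
    expect_lt(max(abs(beta_map - beta_true(r))), 0.5)
  }
})

test_that("tracing converges to the generator's trajectory", {
  # radial ground truth: fixed point at iteration 2
  er <- generate_eye(synthetic_eye_spec(seed = 9, b_max = 0), output = "polar")
  trr <- trace_iterate(er$thickness)
  expect_true(trr$converged)
  expect_equal(trr$iterations, 2L)
  expect_lt(max(abs(trr$beta)), 0.01)

  # arcuate truth: boundary recovery and flux conservation
  ea <- generate_eye(synthetic_eye_spec(seed = 3), output = "polar")
  tra <- trace_iterate(ea$thickness)
  expect_true(tra$converged)
  expect_lte(tra$iterations, 50L)
  expect_lt(tail(tra$delta_history, 1), 0.01)
  err <- boundary_errors(tra, ea)
  expect_lt(median(err), 1.0)

  rf <- ring_flux(flux_density(ea$thickness, cos_beta = tra$cos_beta))
  expect_lt(stats::sd(rf) / mean(rf), 0.005)

  # track monotonicity at every radius
  ba <- boundary_angles(tra$trajectory, ea$thickness$radii)
  expect_true(all(apply(ba, 2, function(x) all(diff(x) > 0))))

  # idempotence at the fixed point: restarting from the converged
  # trajectory moves no boundary by >= 0.01 deg
  tra2 <- trace_iterate(ea$thickness, init = tra$trajectory)
  expect_lt(max(abs(boundary_angles(tra2$trajectory, ea$thickness$radii) -
                    ba)), 0.01)
})
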