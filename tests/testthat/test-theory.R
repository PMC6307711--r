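test_that("bulge profile is the exact triangular solution", {
  tp <- theory_params(v0 = 0.4, Dh = 1, alpha = 0.08, beta = 0.08)
  t <- 1000
  apex <- 0.4 * 0.08^2 * t / 8
  halfw <- 0.4 * 0.08 * t / 4
  expect_equal(bulge_profile(0, t, tp), apex)
  # continuous and exactly zero at the edge, zero beyond
  expect_equal(bulge_profile(halfw, t, tp), 0)
  expect_equal(bulge_profile(halfw + 5, t, tp), 0)
  # slope magnitude alpha/(2 Dh) on the flank
  x <- c(1, 2)
  expect_equal(diff(bulge_profile(x, t, tp)), -0.08 / 2)
  # alpha = 0: no bulge at all
  tp0 <- theory_params(v0 = 0.4, Dh = 1, alpha = 0)
  expect_true(all(bulge_profile(seq(-5, 5), t, tp0) == 0))
  expect_error(bulge_profile(0, -1, tp), "positive")
})

test_that("equilibrium fraction follows the piecewise-linear phase structure", {
  # beta Dh / (alpha v0) = 0.85, the printed parameter combination
  tp <- theory_params(v0 = 1, Dh = 1, alpha = 1, beta = 0.85)
  expect_equal(equilibrium_fraction(0.5, tp), 0.5)
  expect_equal(equilibrium_fraction(0.75, tp), 0.7125)
  # branch points: continuity where the linear branch meets 0 and 1
  bp <- 0.5 + 1 / (2 * 0.85)
  expect_equal(equilibrium_fraction(bp, tp), 1)
  expect_equal(equilibrium_fraction(bp + 0.1, tp), 1)
  expect_equal(equilibrium_fraction(1 - bp, tp), 0)
  # continuous and monotone non-decreasing across the whole range
  fs <- seq(-0.5, 1.5, by = 0.01)
  fe <- equilibrium_fraction(fs, tp)
  expect_true(all(diff(fe) >= 0))
  expect_true(all(fe >= 0 & fe <= 1))
  expect_lt(max(abs(diff(fe))), 0.02)   # no jumps
  # degenerate cases
  tpa <- theory_params(v0 = 1, Dh = 1, alpha = 1, beta = 0)
  expect_equal(equilibrium_fraction(c(0.2, 0.9), tpa), c(0.5, 0.5))
  tpn <- theory_params(v0 = 1, Dh = 1, alpha = 0, beta = 0)
  expect_error(equilibrium_fraction(0.3, tpn), "degenerate")
})

test_that("boundary drift and apex velocities match the closed forms", {
  expect_equal(boundary_drift_velocity(0.5, beta = 0.3), 0)
  expect_equal(boundary_drift_velocity(0, beta = 0.1), 0.05)
  # antisymmetric under f* -> 1 - f*
  expect_equal(boundary_drift_velocity(0.8, 0.2),
               -boundary_drift_velocity(0.2, 0.2))
  tp <- theory_params(v0 = 0.4, Dh = 1, alpha = 0.08)
  expect_equal(apex_velocity(tp), 0.4 * (1 + 8e-4))
  expect_equal(apex_velocity(theory_params(v0 = 0.4, Dh = 1, alpha = 0)), 0.4)
  # apex velocity equals the time derivative of the bulge apex height + v0
  dt <- 1e-3
  dapex <- (bulge_profile(0, 1 + dt, tp) - bulge_profile(0, 1, tp)) / dt
  expect_equal(apex_velocity(tp), tp$v0 + dapex)
})

test_that("flat noiseless front grows at v0 with f frozen", {
  tp <- theory_params(v0 = 0.7, Dh = 1, alpha = 0.3, Df = 0.5, beta = 0.4,
                      f_star = 0.5)
  ff <- front_fields(h = rep(2, 64), f = rep(0.3, 64))
  out <- integrate_front(ff, tp, t_end = 5, dt = 0.2)
  expect_equal(out$h, rep(2 + 0.7 * out$t, 64), tolerance = 1e-12)
  expect_equal(out$f, rep(0.3, 64), tolerance = 1e-12)
})

test_that("pure diffusion limit conserves the total fraction", {
  tp <- theory_params(v0 = 1, Dh = 1, alpha = 0, Df = 0.5, beta = 0)
  ff <- step_front_fields(128)
  out <- integrate_front(ff, tp, t_end = 50)
  expect_equal(sum(out$f), sum(ff$f), tolerance = 1e-8)
  expect_equal(out$h, rep(out$t, 128), tolerance = 1e-10)  # h decoupled
})

test_that("integrator refuses an unstable time step", {
  tp <- theory_params(v0 = 1, Dh = 2, alpha = 0, Df = 0.5, beta = 0)
  ff <- step_front_fields(64)
  expect_error(integrate_front(ff, tp, t_end = 1, dt = 0.5), "stability")
})

test_that("mirror symmetry: (f*, f) and (1 - f*, 1 - f reversed) trajectories match", {
  tp <- theory_params(v0 = 1, Dh = 1, alpha = 0.2, Df = 0.1, beta = 0.5,
                      f_star = 0.3)
  tpm <- theory_params(v0 = 1, Dh = 1, alpha = 0.2, Df = 0.1, beta = 0.5,
                       f_star = 0.7)
  ff <- step_front_fields(128)
  rev_f <- function(v) rev(v)
  ffm <- front_fields(h = rev(ff$h), f = 1 - rev(ff$f))
  a <- integrate_front(ff, tp, t_end = 30, dt = 0.1)
  b <- integrate_front(ffm, tpm, t_end = 30, dt = 0.1)
  expect_equal(rev(b$h), a$h, tolerance = 1e-9)
  expect_equal(1 - rev(b$f), a$f, tolerance = 1e-9)
})

test_that("multiplicative noise keeps f in [0, 1] and respects absorbing states", {
  set.seed(21)
  tp <- theory_params(v0 = 1, Dh = 1, alpha = 0.1, Df = 0.2, beta = 0.3,
                      f_star = 0.5, sigma_h = 0.05, sigma_f = 0.2)
  ff <- front_fields(h = rep(0, 128), f = rep(0.5, 128))
  out <- integrate_front(ff, tp, t_end = 20)
  expect_true(all(out$f >= 0 & out$f <= 1))
  expect_gt(var(out$f), 0)           # drift noise is active
  # monomorphic front stays monomorphic: noise amplitude vanishes
  ff0 <- front_fields(h = rep(0, 64), f = rep(0, 64))
  out0 <- integrate_front(ff0, tp, t_end = 10)
  expect_true(all(out0$f == 0))
})
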