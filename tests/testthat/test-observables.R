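test_that("front profile interpolates height and averages the band fraction", {
  cfg <- lattice_config(20, 50, N = 40)
  # flat saturated front occupying rows 1..12
  n1 <- matrix(0L, 20, 50); n2 <- matrix(0L, 20, 50)
  n1[, 1:12] <- 40L
  st <- chirex:::new_lattice_state(n1, n2, cfg, ylo = 1, yhi = 50)
  pr <- front_profile(st)
  expect_equal(pr$h, rep(12.5, 20))       # k + 1/2 convention
  expect_equal(pr$f, rep(1, 20))          # single strain
  # checkerboard mixture at equal density: f = 1/2 everywhere
  chk <- outer(1:20, 1:12, function(i, j) (i + j) %% 2L)
  n1c <- matrix(0L, 20, 50); n2c <- matrix(0L, 20, 50)
  n1c[, 1:12] <- 40L * chk
  n2c[, 1:12] <- 40L * (1L - chk)
  stc <- chirex:::new_lattice_state(n1c, n2c, cfg, ylo = 1, yhi = 50)
  prc <- front_profile(stc, band_depth = 12)
  expect_true(all(abs(prc$f - 0.5) <= 0.5 / 12 + 1e-9))
  expect_equal(global_fraction(prc), 0.5, tolerance = 1e-9)
})

test_that("heterozygosity behaves at its landmarks", {
  pr <- structure(list(f = c(0, 1, 0, 1), x = 1:4), class = "front_profile")
  expect_equal(heterozygosity(pr), 0)     # fully demixed
  pr$f <- rep(0.5, 4)
  expect_equal(heterozygosity(pr), 0.5)   # perfect mixing
  pr$f <- c(0.2, 0.8, NA, 0.5)
  H <- heterozygosity(pr)
  expect_true(H >= 0 && H <= 0.5)
})

test_that("expansion velocity recovers an exact synthetic slope", {
  t <- seq(0, 1000, by = 50)
  v <- expansion_velocity(t, 3 + 0.4 * t)
  expect_equal(v$v0, 0.4, tolerance = 1e-12)
  expect_lt(v$se, 1e-10)
  expect_error(expansion_velocity(c(1, 2), c(1, 2)), "few samples")
})

test_that("boundary extraction finds crossings, labels and parity", {
  # synthetic smooth profile with two crossings
  x <- 1:100
  f <- 0.5 + 0.45 * sin(2 * pi * (x - 0.5) / 100)
  pr <- structure(list(x = x, f = f, h = rep(10, 100)),
                  class = "front_profile")
  b <- extract_boundaries(pr, chi1 = 0.08, chi2 = -0.08)
  expect_equal(nrow(b), 2)
  expect_equal(sum(b$type == "in_flow"), sum(b$type == "out_flow"))
  # swapping the strain labels (f -> 1 - f, chi swapped) swaps the types
  pr2 <- pr; pr2$f <- 1 - f
  b2 <- extract_boundaries(pr2, chi1 = 0.08, chi2 = -0.08)
  expect_setequal(b$type, rev(b2$type))
  # no crossing: empty result
  pr3 <- pr; pr3$f <- rep(0.9, 100)
  expect_equal(nrow(extract_boundaries(pr3, 0.08, -0.08)), 0)
})

test_that("boundary tracking recovers an imposed drift velocity", {
  width <- 200
  times <- seq(0, 900, by = 100)
  v_true <- 0.08
  bl <- lapply(times, function(t)
    data.frame(x = (50 + v_true * t) %% width,
               type = "in_flow", stringsAsFactors = FALSE))
  tr <- track_boundaries(bl, times, width)
  expect_equal(length(tr), 1)
  fit <- boundary_track_velocity(tr[[1]])
  expect_equal(fit$v, v_true, tolerance = 1e-9)
  # a stationary boundary has zero fitted velocity
  bl0 <- lapply(times, function(t)
    data.frame(x = 120, type = "out_flow", stringsAsFactors = FALSE))
  expect_equal(boundary_track_velocity(track_boundaries(bl0, times, width)[[1]])$v, 0)
})

test_that("spiral fit is exact on an exact Bernoulli spiral", {
  tr <- make_fixture("spiral_track", c0 = 0.7, c1 = 0.3)
  sf <- spiral_fit(tr$r, tr$theta)
  expect_equal(sf$c1, 0.3, tolerance = 1e-12)
  expect_equal(sf$c0, 0.7, tolerance = 1e-12)
  expect_equal(sf$r_squared, 1, tolerance = 1e-12)
})

test_that("radial boundary angles recover a painted spiral pattern", {
  # paint an exact two-sector spiral pattern and re-measure it
  W <- 201; H <- 201; ctr <- c(101, 101); c1 <- 0.25
  cfg <- lattice_config(W, H, N = 10)
  xs <- matrix(seq_len(W), W, H) - ctr[1]
  ys <- matrix(seq_len(H), W, H, byrow = TRUE) - ctr[2]
  r <- sqrt(xs^2 + ys^2)
  th <- atan2(ys, xs)
  # two boundaries at theta = c1 ln r and pi + c1 ln r
  rel <- (th - c1 * log(pmax(r, 1))) %% (2 * pi)
  n1 <- matrix(0L, W, H); n2 <- matrix(0L, W, H)
  inside <- r <= 95 & r >= 1
  n1[inside & rel < pi] <- 10L
  n2[inside & rel >= pi] <- 10L
  st <- chirex:::new_lattice_state(n1, n2, cfg, ylo = 1, yhi = H,
                                   geometry = "radial")
  st$center <- ctr; st$radius0 <- 5
  sf <- radial_boundary_angles(st, r_range = c(10, 90), smooth_k = 3)
  expect_equal(sf$n_boundaries, 2)
  expect_equal(sf$c1, c1, tolerance = 0.05)
  expect_gt(sf$r_squared, 0.98)
})

test_that("boundary width measures local heterozygosity across a boundary", {
  cfg <- lattice_config(60, 40, N = 20)
  n1 <- matrix(0L, 60, 40); n2 <- matrix(0L, 60, 40)
  n1[1:30, ] <- 20L; n2[31:60, ] <- 20L       # deterministic sharp boundary
  st <- chirex:::new_lattice_state(n1, n2, cfg, ylo = 1, yhi = 40)
  bw <- boundary_width(st, y_window = c(5, 35))
  expect_equal(bw$width, 0)                    # monomorphic sites only
  # one mixed column: width of order one site
  n1[31, ] <- 10L; n2[31, ] <- 10L
  st$n1 <- n1; st$n2 <- n2
  bw2 <- boundary_width(st, y_window = c(5, 35))
  expect_equal(bw2$width, 0.5)
  # a broad mixed region is wider
  n1[25:36, ] <- 10L; n2[25:36, ] <- 10L
  st$n1 <- n1; st$n2 <- n2
  expect_gt(boundary_width(st, y_window = c(5, 35))$width, bw2$width)
})

test_that("bulge slope fit is exact on the exact triangle", {
  fx <- make_fixture("triangle_bulge", t = 2000)
  pr <- list(x = fx$x, h = fx$h)
  halfw <- fx$params$v0 * fx$params$alpha * fx$t / (4 * fx$params$Dh)
  sl <- fit_bulge_slopes(pr, x_b = 0, window = c(1, 0.9 * halfw))
  m <- fx$params$alpha / (2 * fx$params$Dh)
  expect_equal(sl$slope_left, m, tolerance = 1e-9)
  expect_equal(sl$slope_right, -m, tolerance = 1e-9)
})
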