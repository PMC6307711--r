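test_that("lattice_config validates geometry", {
  expect_error(lattice_config(2, 100, N = 10), ">= 3")
  expect_error(lattice_config(100, 100, N = 0), "N must be")
  expect_error(lattice_config(10, 10, N = 5, dx = 1, dy = 2), "equal")
})

test_that("linear front initial conditions realise the three arrangements", {
  cfg <- lattice_config(100, 200, N = 50)
  set.seed(1)
  # f0 = 0: no strain 1 anywhere, bottom rows at capacity
  st0 <- init_linear_front(cfg, f0 = 0, mode = "well_mixed")
  expect_true(all(st0$n1 == 0))
  expect_true(all(st0$n1[, 1:10] + st0$n2[, 1:10] == 50))
  # well-mixed at 1/2: global fraction within 3 s.e. of 1/2
  st <- init_linear_front(cfg, f0 = 0.5, mode = "well_mixed")
  ntot <- 100 * 10 * 50
  se <- sqrt(0.25 / ntot)
  expect_lt(abs(sum(st$n1) / ntot - 0.5), 3 * se)
  # two domains: exactly one boundary of each type under periodic x
  std <- init_linear_front(cfg, f0 = 0.5, mode = "two_domains")
  b <- extract_boundaries(front_profile(std), chi1 = 0.08, chi2 = -0.08)
  expect_equal(nrow(b), 2)
  expect_setequal(b$type, c("in_flow", "out_flow"))
  # single patch holds the requested width of strain 1
  stp <- init_linear_front(cfg, f0 = 0, mode = "single_patch",
                           patch_width = 11)
  expect_equal(sum(stp$n1[, 1] > 0), 11)
  expect_true(all(stp$n1[, 1:10] + stp$n2[, 1:10] == 50))
  expect_error(init_linear_front(cfg, f0 = 0.5, filled_rows = 195),
               "no room")
  expect_error(init_linear_front(cfg, f0 = 1.5), "\\[0, 1\\]")
})

test_that("circular colony init fills a disk at capacity", {
  cfg <- lattice_config(201, 201, N = 20)
  set.seed(2)
  st <- init_circular_colony(cfg, radius = 30, f0 = 0.5)
  pop <- sum(st$n1 + st$n2)
  expect_lt(abs(pop / (pi * 30^2 * 20) - 1), 0.05)     # disk area
  # f0 = 1 is absorbing: single-strain colony stays single-strain
  st1 <- init_circular_colony(cfg, radius = 20, f0 = 1)
  expect_true(all(st1$n2 == 0))
  run <- run_expansion(st1, lh_strain(), rh_strain(), max_steps = 50,
                       record_every = 50)
  expect_true(all(run$state$n2 == 0))
  expect_error(init_circular_colony(cfg, radius = 150, f0 = 0.5),
               "does not fit")
})

test_that("growth increment implements density-limited logistic growth", {
  p <- strain_params(g = 0.1)
  expect_equal(growth_increment(50, 200, p, N = 200), 0)   # at capacity
  expect_equal(growth_increment(0, 100, p, N = 200), 0)    # empty strain
  expect_equal(growth_increment(50, 100, p, N = 200), 2.5)
  expect_error(growth_increment(-1, 100, p, N = 200), "invalid")
  expect_error(growth_increment(50, 300, p, N = 200), "invalid")
})

test_that("directional flux matches the direction-relative migration rule", {
  p <- strain_params(g = 0.03, ml = 0.045, mr = 0.005)
  # crowded site on the left of the migration direction drives the flux
  expect_equal(directional_flux(100, 100, 0, 100, 0, 0, p, N = 100), 4.5)
  # full destination blocks migration entirely
  expect_equal(directional_flux(100, 100, 100, 100, 100, 100, p, N = 100), 0)
  # no coefficients, no flux
  p0 <- strain_params(g = 0.03)
  expect_equal(directional_flux(100, 100, 0, 100, 100, 100, p0, N = 100), 0)
  expect_error(directional_flux(120, 100, 0, 0, 0, 0, p, N = 100),
               "invalid")
})

test_that("migration conserves cells and spreads isolated sites evenly", {
  p <- full_strain_a()
  # uniform occupancy: all fluxes balance; the increment is exactly zero
  # away from the y edges (the closed top/bottom boundary perturbs the
  # density-dependent coefficients of the two outermost rows)
  cfg <- lattice_config(12, 12, N = 40)
  n1 <- matrix(10L, 12, 12); n2 <- matrix(5L, 12, 12)
  st <- chirex:::new_lattice_state(n1, n2, cfg, ylo = 1, yhi = 12,
                                   geometry = "radial")
  M <- migration_increment(st, 1, p)
  expect_equal(max(abs(M[, 3:10])), 0)
  expect_lt(abs(sum(M)), 1e-9)
  # random states: the field sums to zero (cells are only moved around)
  for (k in 1:5) {
    stk <- make_fixture("tiny_lattice", seed = k, width = 12, height = 12,
                        N = 30)
    stk$geometry <- "radial"
    expect_lt(abs(sum(migration_increment(stk, 1, p))), 1e-9)
    expect_lt(abs(sum(migration_increment(stk, 2, full_strain_b()))), 1e-9)
  }
  # isolated occupied site with only m0: loses 4 m0 n, neighbours get m0 n
  pm <- strain_params(g = 0, m0 = 0.05)
  n1 <- matrix(0L, 9, 9); n1[5, 5] <- 20L
  sti <- chirex:::new_lattice_state(n1, matrix(0L, 9, 9),
                                    lattice_config(9, 9, N = 40),
                                    ylo = 1, yhi = 9, geometry = "radial")
  Mi <- migration_increment(sti, 1, pm)
  expect_equal(Mi[5, 5], -4 * 0.05 * 20)
  expect_equal(Mi[4, 5], 0.05 * 20)
  expect_equal(Mi[5, 6], 0.05 * 20)
  expect_equal(sum(Mi), 0)
})

test_that("binomial sampling rounds have the right fixed points and moments", {
  N <- 100
  z <- matrix(0, 4, 4)
  # absorbing states of the demographic round
  expect_true(all(demographic_sampling(z, z, N) == 0))
  full <- matrix(N / 2, 4, 4)
  expect_true(all(demographic_sampling(full, full, N) == N))
  # absorbing states of the drift round
  n_new <- matrix(37, 4, 4)
  expect_true(all(drift_sampling(n_new, z, full)$n1 == 0))
  expect_true(all(drift_sampling(n_new, full, z)$n1 == 37))
  # moments at half capacity over many draws
  set.seed(3)
  m <- 1e5
  rho <- matrix(N / 4, m, 1)
  draws <- demographic_sampling(rho, rho, N)
  se <- sqrt(N * 0.5 * 0.5 / m)
  expect_lt(abs(mean(draws) - N / 2), 3 * se)
  k <- drift_sampling(matrix(100, m, 1), rho, rho)$n1
  expect_lt(abs(mean(k) - 50), 3 * sqrt(100 * 0.25 / m))
  # invalid probabilities are an internal error, not a silent clamp
  expect_error(demographic_sampling(matrix(80, 1, 1), matrix(80, 1, 1), N),
               "internal")
})
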