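test_that("deterministic update has the exact trivial fixed points", {
  cfg <- lattice_config(8, 8, N = 20)
  z <- matrix(0L, 8, 8)
  st <- chirex:::new_lattice_state(z, z, cfg, ylo = 1, yhi = 8)
  p <- full_strain_a()
  res <- deterministic_update(st, p, p, method = "fast")
  expect_true(all(res$rho1 == 0) && all(res$rho2 == 0))
  # g = 0, all m = 0: identity update
  p0 <- strain_params(g = 0)
  stk <- make_fixture("tiny_lattice", seed = 5, width = 8, height = 8, N = 20)
  res0 <- deterministic_update(stk, p0, p0, method = "vectorized")
  expect_equal(res0$rho1, stk$n1 + 0)
  expect_equal(res0$rho2, stk$n2 + 0)
})

test_that("compiled, vectorized and per-site reference updates agree exactly", {
  p1 <- full_strain_a(); p2 <- full_strain_b()
  for (k in 1:10) {
    st <- make_fixture("tiny_lattice", seed = k, width = 10, height = 10,
                       N = 30)
    a <- deterministic_update(st, p1, p2, method = "reference")
    b <- deterministic_update(st, p1, p2, method = "vectorized")
    co <- deterministic_update(st, p1, p2, method = "fast")
    expect_identical(b$rho1, a$rho1)
    expect_identical(b$rho2, a$rho2)
    expect_equal(co$rho1, a$rho1, tolerance = 0)
    expect_equal(co$rho2, a$rho2, tolerance = 0)
  }
})

test_that("x-reflection with ml/mr swap commutes with the update bit-for-bit", {
  p1 <- full_strain_a(); p2 <- full_strain_b()
  m1 <- swap_lr(p1); m2 <- swap_lr(p2)
  for (k in 1:10) {
    st <- make_fixture("tiny_lattice", seed = 100 + k, width = 10,
                       height = 10, N = 30)
    a <- deterministic_update(st, p1, p2, method = "fast")
    stm <- st
    stm$n1 <- reflect_x(st$n1); stm$n2 <- reflect_x(st$n2)
    b <- deterministic_update(stm, m1, m2, method = "fast")
    expect_identical(reflect_x(unclass(a$rho1)), unclass(b$rho1))
    expect_identical(reflect_x(unclass(a$rho2)), unclass(b$rho2))
  }
})

test_that("the direction-relative rule is equivariant under 90-degree rotation", {
  p1 <- full_strain_a(); p2 <- full_strain_b()
  for (k in 1:5) {
    st <- make_fixture("tiny_lattice", seed = 200 + k, width = 10,
                       height = 10, N = 30)
    a <- chirex:::det_update_reference(st$n1, st$n2, p1, p2, N = 30,
                                       dt = 1, periodic_y = TRUE)
    b <- chirex:::det_update_reference(rot90(st$n1), rot90(st$n2), p1, p2,
                                       N = 30, dt = 1, periodic_y = TRUE)
    expect_equal(rot90(a$rho1), b$rho1, tolerance = 1e-12)
    expect_equal(rot90(a$rho2), b$rho2, tolerance = 1e-12)
  }
})

test_that("occupancies stay in [0, N] and absorbing states persist", {
  set.seed(7)
  cfg <- lattice_config(40, 150, N = 25)
  st <- init_linear_front(cfg, f0 = 0.3)
  p1 <- lh_strain(); p2 <- rh_strain()
  for (i in 1:12) {
    st <- lattice_step(st, p1, p2, steps = 25)
    tot <- st$n1 + st$n2
    expect_true(all(st$n1 >= 0) && all(st$n2 >= 0))
    expect_true(all(tot <= 25))
  }
  # strain 2 alone: strain 1 never appears
  st2 <- init_linear_front(cfg, f0 = 0)
  st2 <- lattice_step(st2, p1, p2, steps = 300)
  expect_true(all(st2$n1 == 0))
  expect_gt(sum(st2$n2), sum(init_linear_front(cfg, f0 = 0)$n2))
})

test_that("neutral drift keeps the mean fraction and grows its variance", {
  # identical strains: f-bar is a martingale; across replicates the mean
  # stays at f0 while the variance increases with time
  p <- strain_params(g = 0.2, ml = 0.05, mr = 0.05)
  set.seed(11)
  early <- c(); late <- c()
  for (r in 1:24) {
    cfg <- lattice_config(30, 120, N = 10)
    st <- init_linear_front(cfg, f0 = 0.5)
    st <- lattice_step(st, p, p, steps = 150)
    early[r] <- global_fraction(front_profile(st))
    st <- lattice_step(st, p, p, steps = 250)
    late[r] <- global_fraction(front_profile(st))
  }
  se <- sd(late) / sqrt(length(late))
  expect_lt(abs(mean(late) - 0.5), 3 * se + 1e-12)
  expect_gt(var(late), var(early))
})

test_that("run_expansion records a growing front and stops at the top", {
  set.seed(13)
  cfg <- lattice_config(30, 150, N = 20)
  st <- init_linear_front(cfg, f0 = 0.5)
  run <- run_expansion(st, lh_strain(), rh_strain(), max_steps = 20000,
                       record_every = 100)
  expect_s3_class(run, "chirex_run")
  expect_equal(run$stop_reason, "hit_top")
  expect_true(all(diff(run$history$front) > -1e-9))
  expect_true(all(run$history$fbar >= 0 & run$history$fbar <= 1))
})
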