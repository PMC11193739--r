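test_that("depth attenuation reproduces the surface rate and hand values", {
  g <- default_grid
  p <- ref_params(KM1 = 0.01, zM = 50)
  k <- depth_rate_profile(p, g)
  expect_identical(k$KM[1], 0.01)          # exponent is 0 at z = 10 cm
  expect_identical(k$KP[1], unclass(p)[["KP1"]])
  # a layer with midpoint 60 cm and zM = 50 cm sits one e-fold below KM1
  g60 <- soil_profile_grid(cbind(top = c(0, 50), bottom = c(50, 70)))
  k60 <- depth_rate_profile(p, g60)
  expect_equal(k60$KM[2], 0.01 * exp(-1))
})

test_that("rate profiles are non-increasing with depth and flatten as the e-folding depth grows", {
  g <- default_grid
  k <- depth_rate_profile(ref_params(), g)
  expect_true(all(diff(k$KM) <= 0))
  expect_true(all(diff(k$KP) <= 0))
  kflat <- depth_rate_profile(ref_params(zM = 1e9, zP = 1e9), g)
  expect_equal(kflat$KM, rep(kflat$KM[1], 5), tolerance = 1e-6)
  # larger zM raises every sub-surface rate
  kfast <- depth_rate_profile(ref_params(zM = 30), g)
  kslow <- depth_rate_profile(ref_params(zM = 150), g)
  expect_true(all(kslow$KM[-1] > kfast$KM[-1]))
  expect_error(model_parameters(0.01, 0.2, 0, 100, 0.1, 0.3, 0, 0),
               "strictly positive")
})

test_that("layer balance matches an independent term-by-term oracle", {
  g <- default_grid
  # input-only response from empty pools
  r0 <- pool_rhs(rep(0, 5), rep(0, 5), ref_params(), c(5, 0, 0, 0, 0), g)
  expect_equal(r0$dPOC, c(5, 0, 0, 0, 0))
  expect_equal(r0$dMAOC, rep(0, 5))
  # single-layer closed-form fixed point
  g1 <- soil_profile_grid(cbind(0, 20))
  p1 <- ref_params(T_MAOCtoPOC = 0, T_POCtoMAOC = 0, D = 0, A = 0)
  r1 <- pool_rhs(10 / 0.2, 0, p1, 10, g1)
  expect_equal(r1$dPOC, 0)
  expect_equal(r1$dMAOC, 0)
  # randomized agreement with the oracle
  set.seed(71)
  for (rep in 1:10) {
    th <- random_params()
    poc <- runif(5, 0, 2000); maoc <- runif(5, 0, 8000)
    I <- runif(5, 0, 200)
    got <- pool_rhs(poc, maoc, th, I, g)
    want <- rhs_oracle(poc, maoc, th, I, g$midpoints)
    expect_equal(got$dPOC, want$dPOC, tolerance = 1e-12)
    expect_equal(got$dMAOC, want$dMAOC, tolerance = 1e-12)
  }
  expect_error(pool_rhs(rep(0, 3), rep(0, 5), ref_params(), rep(1, 5), g),
               "per layer")
})

test_that("steady state solves the balance exactly and scales linearly with inputs", {
  g <- default_grid
  # single-layer analytic solution
  g1 <- soil_profile_grid(cbind(0, 20))
  p1 <- ref_params(T_MAOCtoPOC = 0, D = 0, A = 0)
  st1 <- steady_state(p1, 10, g1)
  expect_equal(st1$POC, 10 / 0.2)
  expect_equal(st1$MAOC, 10 * 0.3 / 0.01)
  set.seed(72)
  for (rep in 1:10) {
    th <- random_params()
    I <- allocate_npp_by_depth(runif(1, 100, 1200), g)
    st <- steady_state(th, I, g)
    expect_true(st$admissible)
    r <- pool_rhs(st$POC, st$MAOC, th, I, g)
    scale <- max(abs(c(st$POC, st$MAOC)))
    expect_lt(max(abs(c(r$dPOC, r$dMAOC))) / scale, 1e-9)
    st2 <- steady_state(th, 2 * I, g)
    expect_equal(st2$POC, 2 * st$POC)
    expect_equal(st2$MAOC, 2 * st$MAOC)
  }
})

test_that("forward integration converges to the analytic steady state", {
  g <- default_grid
  p <- ref_params()
  I <- allocate_npp_by_depth(600, g)
  st <- steady_state(p, I, g)
  # starting at the fixed point stays there
  sim0 <- simulate_pools(p, I, g, initial = st, horizon = 500, step = 50)
  expect_equal(sim0$final$POC, st$POC, tolerance = 1e-7)
  expect_equal(sim0$final$MAOC, st$MAOC, tolerance = 1e-7)
  # spin-up from zero reaches it
  sim <- simulate_pools(p, I, g, horizon = 20000, step = 100)
  expect_equal(sim$final$MAOC, st$MAOC, tolerance = 1e-6)
  # refinement of the reporting step does not move the answer
  sim_h <- simulate_pools(p, I, g, horizon = 20000, step = 50)
  rel <- max(abs(c(sim_h$final$POC - sim$final$POC,
                   sim_h$final$MAOC - sim$final$MAOC))) /
    max(abs(c(sim$final$POC, sim$final$MAOC)))
  expect_lt(rel, 1e-6)
})

test_that("conservative transport keeps advected carbon in the column", {
  g <- default_grid
  # no decomposition: the only fluxes are transport, which must cancel
  p <- ref_params(KM1 = 0, KP1 = 0, T_MAOCtoPOC = 0, T_POCtoMAOC = 0,
                  D = 0.005, A = 0.005)
  poc <- c(500, 400, 300, 200, 100); maoc <- rev(poc)
  I <- rep(0, 5)
  cons <- pool_rhs(poc, maoc, p, I, g, conservative = TRUE)
  expect_equal(sum(cons$dPOC), 0, tolerance = 1e-12)
  expect_equal(sum(cons$dMAOC), 0, tolerance = 1e-12)
  # the literal scheme exports carbon out of the column
  lit <- pool_rhs(poc, maoc, p, I, g, conservative = FALSE)
  expect_lt(sum(lit$dPOC), 0)
})
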