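test_that("log-likelihood is the Gaussian misfit with its maximum at a perfect fit", {
  obs <- noiseless_obs()
  expect_equal(log_likelihood(unclass(ref_params()), obs), 0)
  # one pool off by exactly one standard deviation -> -0.5
  obs1 <- obs
  obs1$MAOC[2] <- obs1$MAOC[2] + obs1$MAOC_sd[2]
  expect_equal(log_likelihood(unclass(ref_params()), obs1), -0.5)
  # random parameter sets match the hand-summed oracle
  set.seed(81)
  for (rep in 1:8) {
    th <- random_params()
    expect_equal(log_likelihood(th, obs), loglik_oracle(th, obs),
                 tolerance = 1e-12)
  }
})

test_that("proposals are bounded symmetric steps scaled by the prior range", {
  priors <- default_prior_ranges()
  th <- setNames(colMeans(rbind(priors["min", ], priors["max", ])),
                 parameter_names())
  set.seed(82)
  rng <- priors["max", ] - priors["min", ]
  disp <- t(replicate(4000, propose_params(th, priors, 5) - th))
  for (nm in parameter_names()) {
    expect_true(all(abs(disp[, nm]) <= rng[nm] / 10 + 1e-12))
  }
  expect_equal(unname(colMeans(disp) / rng), rep(0, 8), tolerance = 0.01)
  # step divisor controls the width
  disp2 <- t(replicate(2000, propose_params(th, priors, 50) - th))
  expect_true(all(abs(disp2[, "zM"]) <= rng["zM"] / 100 + 1e-12))
})

test_that("a flat likelihood returns the uniform prior and chains stay in the box", {
  obs <- noiseless_obs(sd_frac = 1e9)  # sigma so wide the data carry no information
  priors <- default_prior_ranges()
  fit <- metropolis_hastings(obs, priors, mcmc_config(15000, seed = 5))
  nm <- parameter_names()
  expect_true(all(t(fit$accepted) >= priors["min", nm] &
                    t(fit$accepted) <= priors["max", nm]))
  # marginal means sit near the interval midpoints (random-walk chains are
  # strongly autocorrelated, so the margin is several percent of the range)
  mid <- (priors["min", nm] + priors["max", nm]) / 2
  rng <- priors["max", nm] - priors["min", nm]
  for (p in c("KM1", "zM", "T_POCtoMAOC")) {
    expect_lt(abs(mean(fit$samples[, p]) - mid[p]) / rng[p], 0.08)
  }
})

test_that("identical seeds give bit-identical chains", {
  obs <- noiseless_obs()
  a <- metropolis_hastings(obs, cfg = mcmc_config(1500, seed = 11))
  b <- metropolis_hastings(obs, cfg = mcmc_config(1500, seed = 11))
  expect_identical(a$accepted, b$accepted)
  expect_identical(a$summary, b$summary)
  c2 <- metropolis_hastings(obs, cfg = mcmc_config(1500, seed = 12))
  expect_false(identical(a$accepted, c2$accepted))
})

test_that("turnover arithmetic: reciprocal rates and pool-weighted profile means", {
  expect_equal(1 / 0.01, 100)
  expect_equal(profile_turnover(c(10, 20), c(100, 300)), 17.5)
  # degenerate single-sample chain: quantiles collapse onto the point value
  obs <- noiseless_obs()
  fit <- metropolis_hastings(obs, cfg = mcmc_config(300, seed = 3))
  fit$samples <- fit$samples[1, , drop = FALSE]
  tr <- turnover_times(fit)
  expect_equal(tr$profile$q05, tr$profile$median)
  expect_equal(tr$profile$q95, tr$profile$median)
  expect_true(all(tr$layers$median > 0))
  # profile mean lies between layer extremes for every pool
  full <- turnover_times(metropolis_hastings(obs, cfg = mcmc_config(2000, seed = 4)))
  for (pl in c("MAOC", "POC")) {
    lay <- full$layers[full$layers$pool == pl, "median"]
    prof <- full$profile[full$profile$pool == pl, "median"]
    expect_gte(prof, min(lay) * 0.999)
    expect_lte(prof, max(lay) * 1.001)
  }
})

test_that("grid inversion is order-independent, seeded per cell, and failure-isolated", {
  ds <- make_synthetic_dataset(2, seed = 31, noise_cv = 0.1)
  cfg <- mcmc_config(1200, seed = 50)
  a <- invert_grid(ds$observations, cfg = cfg)
  b <- invert_grid(ds$observations, cfg = cfg)
  expect_identical(a$posteriors, b$posteriors)
  expect_identical(a$turnover_profile, b$turnover_profile)
  # empty input gives an empty table, not an error
  e <- invert_grid(list(), cfg = cfg)
  expect_s3_class(e$posteriors, "data.frame")
  expect_identical(nrow(e$posteriors), 0L)
  # a broken cell is logged while the rest complete
  bad <- ds$observations
  bad[[1]]$inputs <- rep(NA_real_, 5)  # unsolvable cell
  res <- invert_grid(bad, cfg = mcmc_config(500, seed = 60))
  expect_identical(nrow(res$failures), 1L)
  expect_true(ds$observations[[2]]$cell_id %in% res$posteriors$cell_id)
})
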