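test_that("NPP depth allocation is a normalized geometric profile", {
  g <- default_grid
  I <- allocate_npp_by_depth(600, g, beta = 0.95, belowground_share = 0.5)
  expect_equal(sum(I), 300, tolerance = 1e-12)       # share * total
  expect_true(all(diff(I) < 0))                      # concentrates near surface
  # the beta -> 1 limit is uniform allocation
  Iu <- allocate_npp_by_depth(100, g, beta = 1 - 1e-9, belowground_share = 1)
  expect_equal(Iu, rep(20, 5), tolerance = 1e-4)
  # fractions sum to one for arbitrary beta
  for (b in c(0.5, 0.9, 0.99)) {
    f <- allocate_npp_by_depth(1, g, beta = b, belowground_share = 1)
    expect_equal(sum(f), 1, tolerance = 1e-12)
  }
  expect_error(allocate_npp_by_depth(100, g, beta = 1.2), "inside \\(0, 1\\)")
  expect_error(allocate_npp_by_depth(-5, g), "non-negative")
})

test_that("truth sampling is reproducible and its profiles sit at steady state", {
  a <- sample_truths(3, seed = 21)
  b <- sample_truths(3, seed = 21)
  expect_identical(a, b)
  for (tr in a) {
    r <- pool_rhs(tr$pools$POC, tr$pools$MAOC, tr$params, tr$inputs, tr$grid)
    scale <- max(abs(c(tr$pools$POC, tr$pools$MAOC)))
    expect_lt(max(abs(c(r$dPOC, r$dMAOC))) / scale, 1e-9)
    expect_true(tr$covariates$MAT >= -9 && tr$covariates$MAT <= 29)
    expect_true(tr$covariates$MAP >= 58 && tr$covariates$MAP <= 3128)
  }
})

test_that("covariate links carry the configured MAT slope and vanish when disabled", {
  # no link: MAT and zM uncorrelated beyond sampling noise
  t0 <- sample_truths(500, seed = 22, covariate_link = NULL)
  mat <- vapply(t0, function(tr) tr$covariates$MAT, numeric(1))
  zm <- vapply(t0, function(tr) tr$params[["zM"]], numeric(1))
  expect_lt(abs(cor(mat, zm)), 0.1)
  # stated slope recovered by regression within 20%
  t1 <- sample_truths(500, seed = 23, covariate_link = list(zM = 1.5))
  mat1 <- vapply(t1, function(tr) tr$covariates$MAT, numeric(1))
  zm1 <- vapply(t1, function(tr) tr$params[["zM"]], numeric(1))
  slope <- unname(coef(lm(zm1 ~ mat1))[2])
  expect_lt(abs(slope - 1.5) / 1.5, 0.2)
})

test_that("observation noise follows the configured coefficient of variation", {
  truths <- sample_truths(2, seed = 24)
  exact <- add_observation_noise(truths, noise_cv = 0, seed = 1)
  expect_equal(exact[[1]]$MAOC, truths[[1]]$pools$MAOC)
  expect_equal(exact[[2]]$POC, truths[[2]]$pools$POC)
  # Monte-Carlo check of the noise law on one pool value
  one <- truths[1]
  sds <- replicate(300, {
    o <- add_observation_noise(one, noise_cv = 0.05,
                               seed = sample.int(1e6, 1))
    o[[1]]$MAOC[1]
  })
  expect_equal(sd(sds), 0.05 * one[[1]]$pools$MAOC[1], tolerance = 0.15)
  # recorded sigma is cv * pool
  o <- add_observation_noise(one, noise_cv = 0.05, seed = 9)
  expect_equal(o[[1]]$MAOC_sd, pmax(0.05 * one[[1]]$pools$MAOC, 1))
  # negative draws are truncated and flagged
  tiny <- truths[1]
  tiny[[1]]$pools$POC <- rep(1e-3, 5)
  tiny[[1]]$pools$MAOC <- rep(1e-3, 5)
  noisy <- add_observation_noise(tiny, noise_cv = 5, seed = 2)
  expect_true(all(noisy[[1]]$POC >= 0))
  expect_gt(attr(noisy, "n_truncated"), 0)
})

test_that("dataset generation is bit-identical under a fixed config", {
  a <- make_synthetic_dataset(3, seed = 77, noise_cv = 0.1)
  b <- make_synthetic_dataset(3, seed = 77, noise_cv = 0.1)
  expect_identical(a$truths, b$truths)
  expect_identical(lapply(a$observations, unclass),
                   lapply(b$observations, unclass))
})
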