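test_that("importance normalization hits the endpoints and averages the two measures", {
  r <- normalize_importance(c(a = 0, b = 10), c(a = 0, b = 10))
  expect_equal(r$importance, c(0, 1))
  r2 <- normalize_importance(c(a = 0, b = 10), c(a = 10, b = 0))
  expect_equal(r2$importance, c(0.5, 0.5))
  # hand-computed three-covariate case
  gi <- c(a = 2, b = 6, c = 10); pi_ <- c(a = 1, b = 9, c = 5)
  r3 <- normalize_importance(gi, pi_)
  expect_equal(r3$importance,
               ((gi - 2) / 8 + (pi_ - 1) / 8) / 2,
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_warning(normalize_importance(c(a = 3, b = 3), c(a = 1, b = 2)),
                 "constant")
  expect_error(normalize_importance(c(1, 2), c(1, 2, 3)), "equal length")
})

make_signal_table <- function(n, seed) {
  set.seed(seed)
  d <- data.frame(x1 = runif(n), x2 = runif(n), x3 = runif(n),
                  x4 = runif(n), x5 = runif(n), x6 = runif(n))
  d$y <- 3 * d$x1 - 2 * d$x2 + rnorm(n, 0, 0.1)
  d
}

test_that("wrapper selection keeps informative covariates and honours its bounds", {
  d <- make_signal_table(250, 101)
  covs <- paste0("x", 1:6)
  hits <- 0L
  for (s in 1:5) {
    sel <- wrapper_select(d, "y", covs, learner = ranger_learner(num.trees = 150),
                          k = 5, seed = 200 + s)
    if (all(c("x1", "x2") %in% sel$selected)) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
  # min_covariates = all candidates -> identity selection
  sel_all <- wrapper_select(d, "y", covs, learner = ranger_learner(num.trees = 50),
                            min_covariates = 6, k = 5, seed = 1)
  expect_setequal(sel_all$selected, covs)
  # a single candidate is returned unchanged
  sel_one <- wrapper_select(d, "y", "x1", learner = ranger_learner(num.trees = 50),
                            k = 5, seed = 1)
  expect_identical(sel_one$selected, "x1")
})

test_that("k-fold cross-validation pools out-of-fold predictions deterministically", {
  d <- make_signal_table(300, 103)
  d$leak <- d$y
  cv_leak <- kfold_r2(d, "y", c("leak", "x3"),
                      learner = ranger_learner(num.trees = 300, mtry = 2),
                      k = 10, seed = 7)
  expect_gt(cv_leak$r2, 0.99)
  a <- kfold_r2(d, "y", paste0("x", 1:3), k = 10, seed = 9)
  b <- kfold_r2(d, "y", paste0("x", 1:3), k = 10, seed = 9)
  expect_identical(a, b)
  expect_error(kfold_r2(d[1:5, ], "y", "x1", k = 10), "must not exceed")
})

test_that("bootstrap maps are seeded-deterministic with coherent quantile bands", {
  d <- make_signal_table(200, 104)
  grid_new <- make_signal_table(40, 105)[, paste0("x", 1:6)]
  covs <- paste0("x", 1:3)
  a <- bootstrap_maps(d, "y", covs, grid_new,
                      learner = ranger_learner(num.trees = 100),
                      n_boot = 20, seed = 11)
  b <- bootstrap_maps(d, "y", covs, grid_new,
                      learner = ranger_learner(num.trees = 100),
                      n_boot = 20, seed = 11)
  expect_identical(a, b)
  expect_true(all(a$q05 <= a$q95))
  # frac = 1 with a deterministic learner collapses the band to zero width
  z <- bootstrap_maps(d, "y", covs, grid_new, learner = lm_learner(),
                      n_boot = 2, frac = 1, seed = 3)
  expect_equal(z$q05, z$q95, tolerance = 1e-12)
  # band contains the full-data prediction for most cells
  full_fit <- ranger_learner(num.trees = 100)$fit(d, "y", covs, seed = 11)
  full_pred <- ranger_learner(num.trees = 100)$predict(full_fit, grid_new)
  inside <- mean(full_pred >= a$q05 & full_pred <= a$q95)
  expect_gte(inside, 0.9)
})

test_that("storage aggregation converts areal densities to Pg with exact arithmetic", {
  # 1000 g C m^-2 over 1e12 m^2 is 1e15 g = 1 Pg C
  expect_equal(unname(aggregate_storage(matrix(1000, 1, 1), 1e12)), 1)
  m <- matrix(c(100, 200, 300, 50, 60, 70), nrow = 3)   # 3 cells x 2 layers
  areas <- c(1e10, 2e10, 3e10)
  hand <- (100 * 1e10 + 200 * 2e10 + 300 * 3e10 +
             50 * 1e10 + 60 * 2e10 + 70 * 3e10) / 1e15
  expect_equal(unname(aggregate_storage(m, areas)), hand, tolerance = 1e-12)
  expect_equal(unname(aggregate_storage(2 * m, areas)), 2 * hand)
  qs <- aggregate_storage(list(mean = m, q05 = m * 0.9, q95 = m * 1.1), areas)
  expect_equal(unname(qs["q95"] / qs["mean"]), 1.1)
  expect_error(aggregate_storage(m, c(1, 2)), "match")
})
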