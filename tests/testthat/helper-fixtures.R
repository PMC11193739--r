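# Shared fixtures and independent oracles for the test suite.

default_grid <- soil_profile_grid()

ref_params <- function(...) {
  args <- list(KM1 = 0.01, KP1 = 0.2, zM = 60, zP = 100,
               T_MAOCtoPOC = 0.1, T_POCtoMAOC = 0.3, D = 0.002, A = 0.002)
  args[names(list(...))] <- list(...)
  do.call(model_parameters, args)
}

# Draw a random admissible parameter vector inside the default prior box.
random_params <- function(priors = default_prior_ranges()) {
  nm <- parameter_names()
  th <- priors["min", nm] + runif(length(nm)) *
    (priors["max", nm] - priors["min", nm])
  names(th) <- nm
  th
}

# Independent term-by-term transcription of the layer balance equations,
# written with explicit scalar loops so it shares no code with pool_rhs().
rhs_oracle <- function(poc, maoc, theta, inputs, z) {
  n <- length(poc)
  km <- kp <- dpoc <- dmaoc <- numeric(n)
  for (i in 1:n) {
    km[i] <- theta[["KM1"]] * exp(-(z[i] - 10) / theta[["zM"]])
    kp[i] <- theta[["KP1"]] * exp(-(z[i] - 10) / theta[["zP"]])
  }
  for (i in 1:n) {
    poc_below <- if (i < n) poc[i + 1] else 0
    maoc_below <- if (i < n) maoc[i + 1] else 0
    dpoc[i] <- inputs[i] + maoc[i] * km[i] * theta[["T_MAOCtoPOC"]] -
      poc[i] * kp[i] + poc_below * theta[["D"]] - poc[i] * theta[["A"]]
    dmaoc[i] <- poc[i] * kp[i] * theta[["T_POCtoMAOC"]] - maoc[i] * km[i] +
      maoc_below * theta[["D"]] - maoc[i] * theta[["A"]]
  }
  list(dPOC = dpoc, dMAOC = dmaoc)
}

# Hand-summed Gaussian misfit oracle for the likelihood.
loglik_oracle <- function(theta, obs) {
  st <- steady_state(theta, obs$inputs, obs$grid)
  total <- 0
  for (i in seq_along(obs$MAOC)) {
    total <- total - (obs$MAOC[i] - st$MAOC[i])^2 / (2 * obs$MAOC_sd[i]^2)
    total <- total - (obs$POC[i] - st$POC[i])^2 / (2 * obs$POC_sd[i]^2)
  }
  total
}

# A noiseless observation profile generated from known parameters.
noiseless_obs <- function(params = ref_params(), npp = 600,
                          grid = default_grid, sd_frac = 0.1) {
  I <- allocate_npp_by_depth(npp, grid)
  st <- steady_state(params, I, grid)
  observation_profile("truth_cell", st$MAOC, st$POC, I, grid,
                      maoc_sd = sd_frac * st$MAOC, poc_sd = sd_frac * st$POC)
}

# Alternating +/-1 field on a k x k unit lattice; with rook (distance-1)
# neighbours every neighbouring product is -1, so Moran's I is exactly -1.
checkerboard <- function(k) {
  xy <- expand.grid(x = 1:k, y = 1:k)
  list(values = (-1)^(xy$x + xy$y), coords = as.matrix(xy))
}

# Deterministic linear-model learner satisfying the learner contract;
# used to test learner injection and exactly reproducible bootstrap bands.
lm_learner <- function() {
  structure(list(
    fit = function(data, response, covariates, seed = 1L) {
      stats::lm(stats::reformulate(covariates, response), data = data)
    },
    predict = function(model, newdata) {
      unname(stats::predict(model, newdata = newdata))
    },
    importance = function(data, response, covariates, seed = 1L) {
      fit <- stats::lm(stats::reformulate(covariates, response), data = data)
      imp <- abs(stats::coef(fit)[covariates])
      list(impurity = imp, permutation = imp)
    }
  ), class = "soc_learner")
}
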