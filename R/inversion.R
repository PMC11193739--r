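#' Gaussian log-likelihood of a parameter set given an observed profile
#'
#' Errors between observed and modeled pools are assumed independent,
#' zero-mean Gaussian per pool per layer, giving
#' `-sum((C_obs - C_mod)^2 / (2 sigma^2))` over both pools and all layers,
#' with the modeled pools taken from the analytic steady state. The maximum
#' (zero) is attained at a perfect fit. Parameter sets whose steady state is
#' singular or yields negative pools return `-Inf`, i.e. certain rejection.
#'
#' @param theta named numeric vector of the eight model parameters.
#' @param obs `obs_profile` (see [observation_profile()]).
#' @param conservative logical; use mass-conserving transport in the
#'   forward model.
#' @return Log-likelihood (dimensionless, <= 0).
#' @export
log_likelihood <- function(theta, obs, conservative = FALSE) {
  st <- tryCatch(steady_state(theta, obs$inputs, obs$grid, conservative),
                 error = function(e) NULL)
  if (is.null(st) || !st$admissible) return(-Inf)
  -sum((obs$MAOC - st$MAOC)^2 / (2 * obs$MAOC_sd^2)) -
    sum((obs$POC - st$POC)^2 / (2 * obs$POC_sd^2))
}

#' Metropolis-Hastings inversion of one observed profile
#'
#' Samples the posterior of the eight model parameters for a single grid
#' cell. The chain starts from a uniform draw inside the prior box, proposes
#' symmetric uniform steps scaled by the prior range (see
#' [propose_params()]), rejects proposals outside the box, and applies the
#' Metropolis criterion to the Gaussian steady-state likelihood. The first
#' half of the *accepted* samples is discarded as burn-in; summaries are
#' computed from the remainder. Identical inputs and seed give bit-identical
#' chains.
#'
#' @param obs `obs_profile` for the cell.
#' @param priors `prior_ranges` box (default [default_prior_ranges()]).
#' @param cfg `mcmc_config`.
#' @param conservative logical; forward-model transport variant.
#' @return An object of class `mcmc_chain`: accepted sample matrix,
#'   post-burn-in `samples`, acceptance statistics, posterior `summary`
#'   data frame, and the inputs needed for derived quantities.
#' @examples
#' \donttest{
#' g <- soil_profile_grid()
#' p <- model_parameters(0.01, 0.2, 60, 100, 0.1, 0.3, 0.002, 0.002)
#' I <- allocate_npp_by_depth(600, g)
#' truth <- steady_state(p, I, g)
#' obs <- observation_profile("cell1", truth$MAOC, truth$POC, I, g)
#' fit <- metropolis_hastings(obs, cfg = mcmc_config(2000, seed = 7))
#' fit$summary
#' }
#' @export
metropolis_hastings <- function(obs, priors = default_prior_ranges(),
                                cfg = mcmc_config(), conservative = FALSE) {
  stopifnot(inherits(obs, "obs_profile"), inherits(priors, "prior_ranges"))
  nm <- parameter_names()
  res <- mh_box_sampler(
    log_post = function(theta) log_likelihood(theta, obs, conservative),
    lower = priors["min", nm], upper = priors["max", nm],
    n_proposals = cfg$n_proposals, step_divisor = cfg$step_divisor,
    seed = cfg$seed, burn_in = cfg$burn_in
  )
  res$summary <- posterior_summary(res$samples)
  res$cell_id <- obs$cell_id
  res$obs <- obs
  res$priors <- priors
  res$config <- cfg
  class(res) <- "mcmc_chain"
  res
}

#' @export
print.mcmc_chain <- function(x, ...) {
  cat(sprintf("<mcmc_chain cell %s: %d/%d accepted (%.1f%%), %d retained>\n",
              x$cell_id, x$n_accepted, x$n_proposals,
              100 * x$acceptance_rate, nrow(x$samples)))
  print(x$summary)
  invisible(x)
}

#' Turnover times from a posterior chain
#'
#' For each retained posterior sample, layer decomposition rates are
#' rebuilt from the depth-attenuation profile, layer turnover times are
#' their reciprocals (`tau = 1/K`), and the 0--100 cm profile turnover is
#' the mean of layer turnover times weighted by that sample's steady-state
#' pool sizes. Posterior medians and 5%/95% quantiles are reported per
#' layer and for the profile means.
#'
#' @param chain `mcmc_chain` from [metropolis_hastings()].
#' @param grid `soil_grid`; defaults to the grid of the inverted profile.
#' @return List of class `turnover_result` with data frames `layers`
#'   (pool, layer, median, q05, q95 in yr) and `profile` (pool-weighted
#'   0--100 cm turnover, same quantiles).
#' @export
turnover_times <- function(chain, grid = chain$obs$grid) {
  samples <- chain$samples
  if (is.null(samples) || nrow(samples) == 0L)
    stop("chain has no retained samples")
  n <- grid$n_layers
  ns <- nrow(samples)
  tau_m <- tau_p <- matrix(NA_real_, ns, n)
  prof_m <- prof_p <- numeric(ns)
  for (s in seq_len(ns)) {
    theta <- samples[s, ]
    k <- depth_rate_profile(theta, grid)
    if (any(k$KM == 0) || any(k$KP == 0))
      stop("zero decomposition rate gives infinite turnover time")
    tau_m[s, ] <- 1 / k$KM
    tau_p[s, ] <- 1 / k$KP
    st <- steady_state(theta, chain$obs$inputs, grid)
    prof_m[s] <- sum(st$MAOC * tau_m[s, ]) / sum(st$MAOC)
    prof_p[s] <- sum(st$POC * tau_p[s, ]) / sum(st$POC)
  }
  qs <- function(x) c(median = stats::median(x),
                      q05 = unname(stats::quantile(x, 0.05)),
                      q95 = unname(stats::quantile(x, 0.95)))
  layer_tab <- do.call(rbind, lapply(seq_len(n), function(i) {
    rbind(data.frame(pool = "MAOC", layer = i, t(qs(tau_m[, i]))),
          data.frame(pool = "POC", layer = i, t(qs(tau_p[, i]))))
  }))
  profile_tab <- rbind(data.frame(pool = "MAOC", t(qs(prof_m))),
                       data.frame(pool = "POC", t(qs(prof_p))))
  structure(list(layers = layer_tab, profile = profile_tab,
                 profile_samples = data.frame(MAOC = prof_m, POC = prof_p)),
            class = "turnover_result")
}

#' Weighted profile-mean turnover time
#'
#' The 0--100 cm turnover of a pool is the mean of layer turnover times
#' weighted by layer pool sizes.
#'
#' @param tau numeric vector of layer turnover times (yr).
#' @param pools numeric vector of layer pool sizes (g C m^-2), same length.
#' @return Scalar weighted mean (yr).
#' @examples
#' profile_turnover(c(10, 20), c(100, 300))  # 17.5
#' @export
profile_turnover <- function(tau, pools) {
  stopifnot(length(tau) == length(pools), all(pools >= 0), sum(pools) > 0)
  sum(tau * pools) / sum(pools)
}

#' Invert a collection of observed profiles cell by cell
#'
#' Runs an independent Metropolis-Hastings inversion for every cell.
#' Each cell's chain is seeded from `cfg$seed + cell index`, so results do
#' not depend on execution order and individual failures do not stop the
#' run (failed cells are reported in the `failures` attribute).
#'
#' @param profiles list of `obs_profile` objects.
#' @param priors `prior_ranges`.
#' @param cfg `mcmc_config`; `cfg$seed` acts as the base seed.
#' @param conservative logical; forward-model transport variant.
#' @param keep_chains logical; retain the full chain objects (memory-heavy).
#' @return List with tidy data frames `posteriors` (cell_id, parameter,
#'   mean, median, q05, q95), `turnover_profile`, `turnover_layers`,
#'   `acceptance` (per-cell rates), plus `chains` when requested and a
#'   `failures` data frame.
#' @export
invert_grid <- function(profiles, priors = default_prior_ranges(),
                        cfg = mcmc_config(), conservative = FALSE,
                        keep_chains = FALSE) {
  empty <- list(
    posteriors = data.frame(cell_id = character(), parameter = character(),
                            mean = numeric(), median = numeric(),
                            q05 = numeric(), q95 = numeric()),
    turnover_profile = data.frame(cell_id = character(), pool = character(),
                                  median = numeric(), q05 = numeric(),
                                  q95 = numeric()),
    turnover_layers = data.frame(cell_id = character(), pool = character(),
                                 layer = integer(), median = numeric(),
                                 q05 = numeric(), q95 = numeric()),
    acceptance = data.frame(cell_id = character(), acceptance_rate = numeric()),
    failures = data.frame(cell_id = character(), error = character())
  )
  if (length(profiles) == 0L) return(empty)
  post <- tov <- tovl <- acc <- fails <- list()
  chains <- list()
  for (i in seq_along(profiles)) {
    obs <- profiles[[i]]
    cell_cfg <- cfg
    cell_cfg$seed <- cfg$seed + i
    out <- tryCatch({
      chain <- metropolis_hastings(obs, priors, cell_cfg, conservative)
      tr <- turnover_times(chain)
      list(chain = chain, turnover = tr)
    }, error = function(e) e)
    if (inherits(out, "error")) {
      fails[[length(fails) + 1L]] <-
        data.frame(cell_id = as.character(obs$cell_id),
                   error = conditionMessage(out))
      next
    }
    post[[i]] <- cbind(cell_id = as.character(obs$cell_id), out$chain$summary)
    tov[[i]] <- cbind(cell_id = as.character(obs$cell_id),
                      out$turnover$profile)
    tovl[[i]] <- cbind(cell_id = as.character(obs$cell_id),
                       out$turnover$layers)
    acc[[i]] <- data.frame(cell_id = as.character(obs$cell_id),
                           acceptance_rate = out$chain$acceptance_rate)
    if (keep_chains) chains[[as.character(obs$cell_id)]] <- out$chain
  }
  res <- list(posteriors = do.call(rbind, post),
              turnover_profile = do.call(rbind, tov),
              turnover_layers = do.call(rbind, tovl),
              acceptance = do.call(rbind, acc),
              failures = if (length(fails)) do.call(rbind, fails)
                         else empty$failures)
  if (is.null(res$posteriors)) res[names(empty)[1:4]] <- empty[1:4]
  if (keep_chains) res$chains <- chains
  res
}
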