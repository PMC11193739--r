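#' MCMC configuration
#'
#' @param n_proposals number of Metropolis proposals per chain.
#' @param step_divisor divisor of the prior range controlling the proposal
#'   step size; each parameter moves by `r * (max - min) / step_divisor`
#'   with `r` uniform on [-0.5, 0.5]. Default 5.
#' @param seed integer RNG seed; every chain is fully reproducible from it.
#' @param burn_in fraction of *accepted* samples discarded from the start
#'   of the chain. Default 0.5 (the first half).
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_proposals = 20000L, step_divisor = 5, seed = 1L,
                        burn_in = 0.5) {
  stopifnot(n_proposals > 0, step_divisor > 0, burn_in >= 0, burn_in < 1)
  structure(list(n_proposals = as.integer(n_proposals),
                 step_divisor = step_divisor, seed = as.integer(seed),
                 burn_in = burn_in),
            class = "mcmc_config")
}

#' Propose a new parameter vector
#'
#' Symmetric uniform random-walk proposal: each parameter is perturbed
#' independently by `r * (max - min) / step_divisor` with `r` uniform on
#' [-0.5, 0.5]. The proposal may leave the prior box; containment is
#' enforced at the acceptance step (out-of-box proposals are rejected),
#' which preserves detailed balance for the symmetric kernel.
#'
#' @param theta_old named numeric vector of current parameter values.
#' @param priors `prior_ranges` box.
#' @param step_divisor step-size divisor (default 5).
#' @return Named numeric vector of proposed values.
#' @export
propose_params <- function(theta_old, priors, step_divisor = 5) {
  nm <- parameter_names()
  rng <- priors["max", nm] - priors["min", nm]
  r <- stats::runif(length(nm), -0.5, 0.5)
  theta_old[nm] + r * rng / step_divisor
}

# Generic Metropolis sampler over a box-bounded parameter space with the
# uniform random-walk proposal above. `log_post` maps a named vector to a
# log-density (may return -Inf). Used both by the soil-profile inversion and
# by analytic cross-check problems.
mh_box_sampler <- function(log_post, lower, upper, n_proposals,
                           step_divisor = 5, seed = 1L, burn_in = 0.5,
                           init = NULL, max_init_tries = 1000L) {
  stopifnot(length(lower) == length(upper), all(lower < upper))
  d <- length(lower)
  nm <- names(lower)
  set.seed(seed)
  rng <- upper - lower
  # initial point: uniform in the box, redrawn until the posterior is finite
  theta <- init
  if (is.null(theta)) {
    for (i in seq_len(max_init_tries)) {
      theta <- lower + stats::runif(d) * rng
      if (is.finite(log_post(theta))) break
      theta <- NULL
    }
    if (is.null(theta))
      stop("could not find an admissible starting point inside the prior box")
  }
  names(theta) <- nm
  lp <- log_post(theta)
  accepted <- matrix(NA_real_, nrow = n_proposals, ncol = d,
                     dimnames = list(NULL, nm))
  lp_acc <- numeric(n_proposals)
  n_acc <- 0L
  for (it in seq_len(n_proposals)) {
    r <- stats::runif(d, -0.5, 0.5)
    cand <- theta + r * rng / step_divisor
    if (all(cand >= lower & cand <= upper)) {   # flat prior inside, -Inf outside
      lp_new <- log_post(cand)
      if (is.finite(lp_new) && log(stats::runif(1)) < (lp_new - lp)) {
        theta <- cand
        lp <- lp_new
        n_acc <- n_acc + 1L
        accepted[n_acc, ] <- theta
        lp_acc[n_acc] <- lp
      }
    }
  }
  if (n_acc == 0L)
    stop("Metropolis chain accepted no proposals; consider a larger ",
         "step_divisor (smaller steps) or wider observation uncertainty")
  accepted <- accepted[seq_len(n_acc), , drop = FALSE]
  lp_acc <- lp_acc[seq_len(n_acc)]
  keep <- seq.int(floor(n_acc * burn_in) + 1L, n_acc)
  list(accepted = accepted, log_post = lp_acc, n_accepted = n_acc,
       n_proposals = n_proposals, acceptance_rate = n_acc / n_proposals,
       samples = accepted[keep, , drop = FALSE],
       samples_log_post = lp_acc[keep])
}

posterior_summary <- function(samples) {
  data.frame(
    parameter = colnames(samples),
    mean = colMeans(samples),
    median = apply(samples, 2L, stats::median),
    q05 = apply(samples, 2L, stats::quantile, probs = 0.05, names = FALSE),
    q95 = apply(samples, 2L, stats::quantile, probs = 0.95, names = FALSE),
    row.names = NULL
  )
}
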