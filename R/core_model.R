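#' Depth-attenuated decomposition rate profiles
#'
#' Decomposition slows with depth following an exponential profile anchored
#' at the surface layer (midpoint 10 cm under the default grid):
#' `KM_i = KM1 * exp(-(z_i - 10)/zM)` and likewise for POC with `KP1`, `zP`,
#' where `z_i` is the midpoint depth of layer i in cm. At `z = 10` cm the
#' surface rate is reproduced exactly; larger e-folding depths give flatter
#' profiles.
#'
#' @param params `soc_params` parameter set (see [model_parameters()]).
#' @param grid `soil_grid` discretization (see [soil_profile_grid()]).
#' @return List with numeric vectors `KM` and `KP` (yr^-1, one per layer).
#' @examples
#' depth_rate_profile(model_parameters(0.01, 0.2, 50, 100, 0.1, 0.3, 0, 0),
#'                    soil_profile_grid())
#' @export
depth_rate_profile <- function(params, grid) {
  p <- unclass(params)
  if (p[["zM"]] <= 0 || p[["zP"]] <= 0)
    stop("e-folding depths must be strictly positive")
  z <- grid$midpoints
  list(KM = p[["KM1"]] * exp(-(z - 10) / p[["zM"]]),
       KP = p[["KP1"]] * exp(-(z - 10) / p[["zP"]]))
}

#' Time derivatives of the two-pool layered model
#'
#' Per-layer carbon balance of the particulate (POC) and mineral-associated
#' (MAOC) pools. In each layer i:
#' \deqn{dPOC_i/dt = I_i + MAOC_i KM_i T_{MAOCtoPOC} - POC_i KP_i
#'   + POC_{i+1} D - POC_i A}
#' \deqn{dMAOC_i/dt = POC_i KP_i T_{POCtoMAOC} - MAOC_i KM_i
#'   + MAOC_{i+1} D - MAOC_i A}
#' with virtual below-column pools set to zero. This literal scheme lets
#' advected carbon leave the column; `conservative = TRUE` switches to a
#' mass-conserving variant in which layer i also receives `A`-flux from the
#' layer above and loses `D`-flux upward, with zero-flux boundaries at the
#' surface and column bottom.
#'
#' @param poc,maoc numeric vectors of pool sizes per layer (g C m^-2).
#' @param params `soc_params` parameter set.
#' @param inputs numeric vector of NPP allocated to each layer
#'   (g C m^-2 yr^-1).
#' @param grid `soil_grid` discretization.
#' @param conservative logical; use the mass-conserving transport variant.
#'   Default `FALSE` (the literal scheme, used throughout the inversion).
#' @return List with `dPOC` and `dMAOC` (g C m^-2 yr^-1 per layer).
#' @export
pool_rhs <- function(poc, maoc, params, inputs, grid, conservative = FALSE) {
  n <- grid$n_layers
  if (length(poc) != n || length(maoc) != n || length(inputs) != n)
    stop("state and inputs must have one entry per layer")
  p <- unclass(params)
  k <- depth_rate_profile(params, grid)
  below <- function(x) c(x[-1L], 0)  # layer i+1, virtual bottom pool = 0
  dpoc <- inputs + maoc * k$KM * p[["T_MAOCtoPOC"]] - poc * k$KP +
    below(poc) * p[["D"]] - poc * p[["A"]]
  dmaoc <- poc * k$KP * p[["T_POCtoMAOC"]] - maoc * k$KM +
    below(maoc) * p[["D"]] - maoc * p[["A"]]
  if (conservative) {
    # replace the open-column transport by reciprocal fluxes with zero-flux
    # boundaries: D mixes upward (loss except at surface), A advects downward
    # (loss except at bottom), each loss matched by the neighbour's gain
    transport <- function(x) {
      d_loss <- p[["D"]] * x * c(0, rep(1, n - 1L))   # no upward flux out of layer 1
      a_loss <- p[["A"]] * x * c(rep(1, n - 1L), 0)   # no downward flux out of layer n
      gain <- c(d_loss[-1L], 0) + c(0, a_loss[-n])
      gain - d_loss - a_loss
    }
    dpoc <- inputs + maoc * k$KM * p[["T_MAOCtoPOC"]] - poc * k$KP + transport(poc)
    dmaoc <- poc * k$KP * p[["T_POCtoMAOC"]] - maoc * k$KM + transport(maoc)
  }
  list(dPOC = dpoc, dMAOC = dmaoc)
}

# Linear system M x = -b such that pool_rhs(x) = 0, with
# x = (POC_1..n, MAOC_1..n) and b = (I, 0).
steady_state_matrix <- function(params, grid, conservative = FALSE) {
  n <- grid$n_layers
  p <- unclass(params)
  k <- depth_rate_profile(params, grid)
  M <- matrix(0, 2L * n, 2L * n)
  ip <- seq_len(n)        # POC rows/cols
  im <- n + seq_len(n)    # MAOC rows/cols
  if (!conservative) {
    diag(M)[ip] <- -(k$KP + p[["A"]])
    diag(M)[im] <- -(k$KM + p[["A"]])
    if (n > 1L) {
      M[cbind(ip[-n], ip[-1L])] <- p[["D"]]
      M[cbind(im[-n], im[-1L])] <- p[["D"]]
    }
  } else {
    d_loss <- p[["D"]] * c(0, rep(1, n - 1L))
    a_loss <- p[["A"]] * c(rep(1, n - 1L), 0)
    diag(M)[ip] <- -(k$KP + d_loss + a_loss)
    diag(M)[im] <- -(k$KM + d_loss + a_loss)
    if (n > 1L) {
      M[cbind(ip[-n], ip[-1L])] <- p[["D"]]   # gain from below via D
      M[cbind(im[-n], im[-1L])] <- p[["D"]]
      M[cbind(ip[-1L], ip[-n])] <- p[["A"]]   # gain from above via A
      M[cbind(im[-1L], im[-n])] <- p[["A"]]
    }
  }
  M[cbind(ip, im)] <- k$KM * p[["T_MAOCtoPOC"]]   # MAOC -> POC source
  M[cbind(im, ip)] <- k$KP * p[["T_POCtoMAOC"]]   # POC -> MAOC source
  M
}

#' Semi-analytical steady state of the two-pool model
#'
#' Sets both time derivatives to zero and solves the resulting linear system
#' (2 x n_layers unknowns; 10 under the default grid) directly, replacing
#' iterative spin-up. A solution with any negative pool is flagged
#' inadmissible.
#'
#' @inheritParams pool_rhs
#' @return List of class `pool_state`: `POC`, `MAOC` (g C m^-2 per layer)
#'   and logical `admissible`.
#' @examples
#' p <- model_parameters(0.01, 0.2, 60, 100, 0.1, 0.3, 0.002, 0.002)
#' steady_state(p, inputs = c(150, 75, 40, 20, 15), soil_profile_grid())
#' @export
steady_state <- function(params, inputs, grid, conservative = FALSE) {
  n <- grid$n_layers
  if (length(inputs) != n) stop("inputs must have one entry per layer")
  M <- steady_state_matrix(params, grid, conservative)
  b <- c(inputs, rep(0, n))
  x <- tryCatch(solve(M, -b), error = function(e) {
    stop("singular steady-state system for parameters: ",
         paste(sprintf("%s=%.4g", parameter_names(),
                       unclass(params)[parameter_names()]), collapse = ", "),
         call. = FALSE)
  })
  st <- list(POC = x[seq_len(n)], MAOC = x[n + seq_len(n)])
  st$admissible <- all(is.finite(x)) && all(x >= -1e-9 * max(abs(x), 1))
  class(st) <- "pool_state"
  st
}

#' Integrate the two-pool model forward in time
#'
#' Numerical spin-up used to validate the analytic steady state; the
#' inversion itself always uses [steady_state()]. Uses an adaptive
#' stiff-capable integrator (`deSolve::lsoda`) with tight tolerances.
#'
#' @inheritParams pool_rhs
#' @param initial list with `POC` and `MAOC` starting pools (g C m^-2);
#'   default all-zero.
#' @param horizon integration time (yr).
#' @param step output time step (yr); controls reporting, not accuracy.
#' @return List with `trajectory` (deSolve matrix: time, POC1..n, MAOC1..n)
#'   and `final` (a `pool_state`).
#' @export
simulate_pools <- function(params, inputs, grid, initial = NULL,
                           horizon = 5000, step = 10, conservative = FALSE) {
  stopifnot(horizon > 0, step > 0)
  n <- grid$n_layers
  if (is.null(initial)) initial <- list(POC = rep(0, n), MAOC = rep(0, n))
  y0 <- c(initial$POC, initial$MAOC)
  M <- steady_state_matrix(params, grid, conservative)
  b <- c(inputs, rep(0, n))
  deriv <- function(t, y, parms) list(as.vector(M %*% y + b))
  out <- deSolve::lsoda(y0, times = seq(0, horizon, by = step), func = deriv,
                        parms = NULL, rtol = 1e-8, atol = 1e-8)
  yf <- out[nrow(out), -1L]
  if (any(!is.finite(yf)))
    stop("forward integration diverged (unstable parameter set)")
  final <- structure(list(POC = unname(yf[seq_len(n)]),
                          MAOC = unname(yf[n + seq_len(n)])),
                     class = "pool_state")
  final$admissible <- all(yf >= -1e-9 * max(abs(yf), 1))
  list(trajectory = out, final = final)
}

#' Spin-up horizon from the slowest system mode
#'
#' The linearized pool system relaxes as a sum of exponentials; the time to
#' steady state is governed by its slowest eigenmode, which pool recycling
#' can make much slower than the smallest decomposition rate alone. Returns
#' `n_efolds` e-folding times of that mode — long enough for transients to
#' decay below numerical tolerance.
#'
#' @inheritParams pool_rhs
#' @param n_efolds number of slowest-mode e-folds (default 35).
#' @return Horizon in years.
#' @export
spinup_horizon <- function(params, grid, conservative = FALSE, n_efolds = 35) {
  M <- steady_state_matrix(params, grid, conservative)
  rate <- min(abs(Re(eigen(M, only.values = TRUE)$values)))
  if (rate <= 0) stop("system has a non-decaying mode; no finite spin-up")
  n_efolds / rate
}

#' @export
print.pool_state <- function(x, ...) {
  cat("<pool_state>\n")
  print(data.frame(layer = seq_along(x$POC), POC = x$POC, MAOC = x$MAOC))
  if (isFALSE(x$admissible)) cat("warning: inadmissible (negative pools)\n")
  invisible(x)
}
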