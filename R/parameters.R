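#' Model parameters of the two-pool soil carbon model
#'
#' The eight per-grid-cell unknowns estimated by the Bayesian inversion:
#' surface decomposition rates of the mineral-associated (MAOC) and
#' particulate (POC) pools, the e-folding depths controlling how fast those
#' rates attenuate with depth, the two inter-pool transfer fractions, and
#' the first-order vertical exchange coefficients (diffusion-like upward
#' gain `D`, advection-like loss `A`).
#'
#' @param KM1 surface MAOC decomposition rate (yr^-1).
#' @param KP1 surface POC decomposition rate (yr^-1).
#' @param zM e-folding depth of MAOC decomposition (cm); larger values mean
#'   slower attenuation with depth.
#' @param zP e-folding depth of POC decomposition (cm).
#' @param T_MAOCtoPOC fraction of decomposed MAOC transferred to POC, in [0, 1].
#' @param T_POCtoMAOC fraction of decomposed POC transferred to MAOC, in [0, 1].
#' @param D upward diffusion-like exchange coefficient (yr^-1).
#' @param A downward advection-like loss coefficient (yr^-1).
#' @return A named numeric vector of class `soc_params`.
#' @examples
#' p <- model_parameters(KM1 = 0.01, KP1 = 0.2, zM = 60, zP = 100,
#'                       T_MAOCtoPOC = 0.1, T_POCtoMAOC = 0.3,
#'                       D = 0.002, A = 0.002)
#' @export
model_parameters <- function(KM1, KP1, zM, zP, T_MAOCtoPOC, T_POCtoMAOC, D, A) {
  p <- c(KM1 = KM1, KP1 = KP1, zM = zM, zP = zP,
         T_MAOCtoPOC = T_MAOCtoPOC, T_POCtoMAOC = T_POCtoMAOC, D = D, A = A)
  validate_parameters(p)
  structure(p, class = "soc_params")
}

#' Names of the eight model parameters, in canonical order
#' @return Character vector of length 8.
#' @export
parameter_names <- function() {
  c("KM1", "KP1", "zM", "zP", "T_MAOCtoPOC", "T_POCtoMAOC", "D", "A")
}

validate_parameters <- function(p) {
  nm <- parameter_names()
  if (!all(nm %in% names(p))) {
    stop("missing parameters: ", paste(setdiff(nm, names(p)), collapse = ", "))
  }
  if (any(!is.finite(p[nm]))) stop("parameters must be finite")
  if (any(p[nm] < 0)) stop("parameters must be non-negative")
  if (p["zM"] <= 0 || p["zP"] <= 0)
    stop("e-folding depths zM and zP must be strictly positive")
  if (p["T_MAOCtoPOC"] > 1 || p["T_POCtoMAOC"] > 1)
    stop("transfer fractions must lie in [0, 1]")
  invisible(p)
}

#' Coerce a named vector or list to model parameters
#' @param x named numeric vector or list holding the eight parameters.
#' @return A `soc_params` object.
#' @export
as_parameters <- function(x) {
  x <- unlist(x)
  nm <- parameter_names()
  do.call(model_parameters, as.list(x[nm]))
}

#' Default prior ranges for the Bayesian inversion
#'
#' Uniform prior box over the eight parameters. Surface turnover priors are
#' broad by design: POC turnover of 1--100 yr maps to `KP1` in [0.01, 1]
#' yr^-1, MAOC turnover of 10--1000 yr to `KM1` in [0.001, 0.1] yr^-1.
#' E-folding depths span 30--200 cm, transfer fractions the full unit
#' interval, and the vertical exchange coefficients a wide [0, 0.01] yr^-1.
#' All bounds are configurable; these defaults are documented stand-ins
#' suitable for the synthetic experiments shipped with the package.
#'
#' @param ... named overrides, each a length-2 numeric `c(min, max)`.
#' @return An object of class `prior_ranges`: a 2-row matrix (`min`, `max`)
#'   with one column per parameter.
#' @examples
#' pr <- default_prior_ranges(zM = c(30, 150))
#' @export
default_prior_ranges <- function(...) {
  box <- rbind(
    min = c(KM1 = 0.001, KP1 = 0.01, zM = 30, zP = 30,
            T_MAOCtoPOC = 0, T_POCtoMAOC = 0, D = 0, A = 0),
    max = c(KM1 = 0.1, KP1 = 1, zM = 200, zP = 200,
            T_MAOCtoPOC = 1, T_POCtoMAOC = 1, D = 0.01, A = 0.01)
  )
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% colnames(box)) stop("unknown parameter in prior override: ", nm)
    v <- as.numeric(over[[nm]])
    if (length(v) != 2L) stop("prior override for ", nm, " must be c(min, max)")
    box[, nm] <- v
  }
  prior_ranges(box)
}

#' Construct a prior-range box
#' @param box 2-row numeric matrix with rows `min`, `max` and one column per
#'   parameter (all eight required).
#' @return A `prior_ranges` object.
#' @export
prior_ranges <- function(box) {
  box <- as.matrix(box)
  nm <- parameter_names()
  if (!all(nm %in% colnames(box))) {
    stop("prior box must cover all parameters: ",
         paste(setdiff(nm, colnames(box)), collapse = ", "))
  }
  box <- box[, nm, drop = FALSE]
  rownames(box) <- c("min", "max")
  if (any(!is.finite(box))) stop("prior bounds must be finite")
  if (any(box["min", ] < 0)) stop("prior bounds must be non-negative")
  if (any(box["min", ] >= box["max", ]))
    stop("each prior must have min < max")
  structure(box, class = "prior_ranges")
}

in_prior_box <- function(theta, priors) {
  nm <- parameter_names()
  all(theta[nm] >= priors["min", nm] & theta[nm] <= priors["max", nm])
}
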