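#' Observed MAOC/POC depth profile for one grid cell
#'
#' Bundles the data the inversion needs for a single cell: observed pool
#' sizes per layer, their observation standard deviations, the NPP input
#' allocated to each layer, and the grid. When standard deviations are not
#' supplied they default to 10% of the observed pool with a small floor,
#' mirroring the default observation-noise level of the synthetic generator.
#'
#' @param cell_id identifier for the grid cell.
#' @param maoc,poc observed pool sizes per layer (g C m^-2).
#' @param inputs NPP allocation per layer (g C m^-2 yr^-1).
#' @param grid `soil_grid`.
#' @param maoc_sd,poc_sd observation standard deviations per layer
#'   (g C m^-2); `NULL` invokes the 10% fallback.
#' @param covariates optional named list or one-row data frame of site
#'   covariates (MAT, MAP, NPP, elevation, pH, clay+silt, land cover, ...).
#' @param sd_floor lower bound on the fallback standard deviation.
#' @return An object of class `obs_profile`.
#' @export
observation_profile <- function(cell_id, maoc, poc, inputs, grid,
                                maoc_sd = NULL, poc_sd = NULL,
                                covariates = NULL, sd_floor = 1) {
  n <- grid$n_layers
  stopifnot(length(maoc) == n, length(poc) == n, length(inputs) == n)
  if (any(maoc < 0) || any(poc < 0)) stop("observed pools must be non-negative")
  if (is.null(maoc_sd)) maoc_sd <- pmax(0.1 * maoc, sd_floor)
  if (is.null(poc_sd)) poc_sd <- pmax(0.1 * poc, sd_floor)
  if (any(maoc_sd <= 0) || any(poc_sd <= 0))
    stop("observation standard deviations must be positive")
  structure(list(cell_id = cell_id, MAOC = as.numeric(maoc),
                 POC = as.numeric(poc), MAOC_sd = as.numeric(maoc_sd),
                 POC_sd = as.numeric(poc_sd), inputs = as.numeric(inputs),
                 grid = grid, covariates = covariates),
            class = "obs_profile")
}

#' @export
print.obs_profile <- function(x, ...) {
  cat(sprintf("<obs_profile cell %s: %d layers>\n", x$cell_id, x$grid$n_layers))
  invisible(x)
}
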