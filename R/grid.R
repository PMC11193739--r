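#' Soil profile discretization
#'
#' Builds the layered soil profile that every computation in the package
#' shares: ordered depth intervals (cm), their midpoints and thicknesses.
#' The default is the five-layer 0--100 cm discretization (0--20, 20--40,
#' 40--60, 60--80, 80--100 cm), whose surface midpoint is 10 cm so the
#' depth-attenuation exponent is exactly zero in the top layer.
#'
#' @param layer_bounds numeric matrix or two-column data frame with one row
#'   per layer, columns giving the upper and lower depth of each layer in cm.
#'   Defaults to the five 20-cm layers spanning 0--100 cm.
#' @return An object of class `soil_grid`: a list with `bounds` (matrix,
#'   columns `top`, `bottom`), `midpoints` (cm), `thickness` (cm) and
#'   `n_layers`.
#' @examples
#' g <- soil_profile_grid()
#' g$midpoints  # 10 30 50 70 90
#' @export
soil_profile_grid <- function(layer_bounds = cbind(top = seq(0, 80, 20),
                                                   bottom = seq(20, 100, 20))) {
  b <- as.matrix(layer_bounds)
  if (ncol(b) != 2L) stop("layer_bounds must have two columns (top, bottom)")
  colnames(b) <- c("top", "bottom")
  storage.mode(b) <- "double"
  if (nrow(b) < 1L) stop("at least one layer is required")
  if (any(b[, "bottom"] <= b[, "top"]))
    stop("each layer must have bottom > top")
  if (nrow(b) > 1L && any(abs(b[-1L, "top"] - b[-nrow(b), "bottom"]) > 1e-9))
    stop("layers must be contiguous and strictly increasing")
  structure(list(
    bounds = b,
    midpoints = unname((b[, "top"] + b[, "bottom"]) / 2),
    thickness = unname(b[, "bottom"] - b[, "top"]),
    n_layers = nrow(b)
  ), class = "soil_grid")
}

#' @export
print.soil_grid <- function(x, ...) {
  cat(sprintf("<soil_grid: %d layers, %g-%g cm>\n",
              x$n_layers, x$bounds[1L, "top"], x$bounds[x$n_layers, "bottom"]))
  invisible(x)
}
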