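#' Global Moran's I with a permutation test
#'
#' Spatial autocorrelation statistic
#' `I = (n / S0) * sum_ij w_ij z_i z_j / sum_i z_i^2` with centered values
#' `z` and binary weights `w_ij = 1` for distinct points within the
#' distance threshold. Significance is assessed by seeded random
#' permutations of the values over the locations (one-sided by default:
#' positive autocorrelation).
#'
#' @param values numeric vector (non-constant, length >= 8).
#' @param coords two-column matrix or data frame of coordinates.
#' @param threshold neighbourhood distance; points at distance in
#'   (0, threshold] are neighbours. Default: the 10% quantile of pairwise
#'   distances.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed for the permutation test.
#' @param alternative `"greater"` (default), `"less"` or `"two.sided"`.
#' @return List with `I`, `p_value`, `n_perm`, `threshold` and the
#'   permutation distribution `I_perm`.
#' @export
morans_i <- function(values, coords, threshold = NULL, n_perm = 999L,
                     seed = 1L, alternative = "greater") {
  n <- length(values)
  if (n < 8L) stop("at least 8 points are required")
  if (stats::sd(values) == 0)
    stop("Moran's I is undefined for a constant field")
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == n)
  dmat <- as.matrix(stats::dist(coords))
  if (is.null(threshold))
    threshold <- stats::quantile(dmat[upper.tri(dmat)], 0.1, names = FALSE)
  W <- (dmat > 0 & dmat <= threshold) * 1
  s0 <- sum(W)
  if (s0 == 0) stop("no neighbours at the chosen distance threshold")
  z <- values - mean(values)
  I_obs <- (n / s0) * as.numeric(z %*% W %*% z) / sum(z^2)
  set.seed(seed)
  Zp <- vapply(seq_len(n_perm), function(i) z[sample.int(n)], numeric(n))
  I_perm <- (n / s0) * colSums(Zp * (W %*% Zp)) / sum(z^2)
  p <- switch(alternative,
    greater = (1 + sum(I_perm >= I_obs)) / (n_perm + 1),
    less = (1 + sum(I_perm <= I_obs)) / (n_perm + 1),
    two.sided = (1 + sum(abs(I_perm) >= abs(I_obs))) / (n_perm + 1),
    stop("unknown alternative: ", alternative))
  list(I = I_obs, p_value = p, n_perm = n_perm, threshold = threshold,
       I_perm = I_perm)
}

#' Empirical semivariogram
#'
#' Semivariance `gamma(h) = mean of 0.5 * (v_i - v_j)^2` over point pairs
#' whose separation falls in lag bin `h`. Bins are of equal width spanning
#' (0, half the maximum pairwise distance]; empty bins are reported as
#' `NA`, not zero.
#'
#' @param values numeric vector (length >= 2).
#' @param coords two-column matrix or data frame of coordinates.
#' @param n_bins number of lag bins (default 15).
#' @param cutoff largest lag considered; default half the maximum pairwise
#'   distance (extended to the full maximum if that leaves no pairs, as for
#'   very small point sets).
#' @return Data frame with `lag` (bin midpoint), `gamma` and `n_pairs`.
#' @export
semivariogram <- function(values, coords, n_bins = 15L, cutoff = NULL) {
  n <- length(values)
  if (n < 2L) stop("at least 2 points are required")
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == n)
  d <- stats::dist(coords)
  g <- 0.5 * stats::dist(values)^2
  dmax <- cutoff %||% (max(d) / 2)
  if (!any(d > 0 & d <= dmax)) dmax <- max(d)
  breaks <- seq(0, dmax, length.out = n_bins + 1L)
  bin <- cut(as.vector(d), breaks = breaks, include.lowest = FALSE)
  gv <- as.vector(g)
  out <- data.frame(
    lag = (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2,
    gamma = as.numeric(tapply(gv, bin, mean)),
    n_pairs = as.integer(table(bin))
  )
  out$gamma[out$n_pairs == 0L] <- NA_real_
  out
}
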