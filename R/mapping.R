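#' Normalized mean of impurity and permutation importance
#'
#' Each importance vector is min-max scaled to [0, 1] over the covariates,
#' and the covariate score is the elementwise mean of the two scaled
#' vectors. A constant vector carries no ranking information and is scaled
#' to all zeros with a warning.
#'
#' @param impurity,permutation equal-length named numeric vectors of raw
#'   importances (at least two covariates).
#' @return Data frame with columns `covariate`, `impurity_norm`,
#'   `permutation_norm`, `importance` (the normalized mean).
#' @examples
#' normalize_importance(c(a = 0, b = 10), c(a = 10, b = 0))
#' @export
normalize_importance <- function(impurity, permutation) {
  if (length(impurity) != length(permutation))
    stop("importance vectors must have equal length")
  if (length(impurity) < 2L) stop("at least two covariates are required")
  scale01 <- function(x, label) {
    r <- range(x)
    if (diff(r) == 0) {
      warning("constant ", label, " importance: normalized to zero")
      return(rep(0, length(x)))
    }
    (x - r[1L]) / diff(r)
  }
  gi <- scale01(impurity, "impurity")
  pi_ <- scale01(permutation, "permutation")
  data.frame(covariate = names(impurity) %||% seq_along(impurity),
             impurity_norm = unname(gi), permutation_norm = unname(pi_),
             importance = unname((gi + pi_) / 2))
}

#' Wrapper (recursive elimination) covariate selection
#'
#' Repeatedly refits the learner, each round dropping the covariate with
#' the lowest normalized mean importance, and records the cross-validated
#' RMSE of each candidate set. Returns the smallest set whose RMSE is
#' within `tolerance` (relative, default 1%) of the best RMSE seen.
#'
#' @param data data frame holding the response and candidate covariates.
#' @param response response column name.
#' @param covariates character vector of candidate covariate names.
#' @param learner a learner (default [ranger_learner()]).
#' @param min_covariates smallest set size to descend to (default 1).
#' @param k folds for the internal cross-validation (default 10).
#' @param seed integer seed controlling folds and fits.
#' @param tolerance relative RMSE slack for the parsimony rule.
#' @return List with `selected` (character vector), `trace` (data frame of
#'   set size, dropped covariate, RMSE) and `best_rmse`.
#' @export
wrapper_select <- function(data, response, covariates,
                           learner = ranger_learner(), min_covariates = 1L,
                           k = 10L, seed = 1L, tolerance = 0.01) {
  stopifnot(length(covariates) >= min_covariates, min_covariates >= 1L)
  current <- covariates
  sets <- list()
  trace <- list()
  round <- 0L
  repeat {
    round <- round + 1L
    cv <- kfold_r2(data, response, current, learner, k = k, seed = seed)
    sets[[round]] <- current
    trace[[round]] <- data.frame(n_covariates = length(current),
                                 rmse = cv$rmse, r2 = cv$r2,
                                 covariates = paste(current, collapse = "+"))
    if (length(current) <= min_covariates || length(current) < 2L) break
    imp <- learner$importance(data, response, current, seed = seed + round)
    rank <- normalize_importance(imp$impurity, imp$permutation)
    drop_cov <- rank$covariate[which.min(rank$importance)]
    current <- setdiff(current, drop_cov)
  }
  trace <- do.call(rbind, trace)
  best <- min(trace$rmse)
  ok <- which(trace$rmse <= best * (1 + tolerance))
  pick <- ok[which.min(trace$n_covariates[ok])]
  list(selected = sets[[pick]], trace = trace, best_rmse = best)
}

#' Out-of-fold cross-validated R-squared and RMSE
#'
#' Seeded k-fold assignment; out-of-fold predictions are pooled before
#' computing `R2 = 1 - SSE/SST` and RMSE.
#'
#' @inheritParams wrapper_select
#' @param k number of folds (default 10); must not exceed the row count.
#' @return List with `r2`, `rmse` and the pooled `predictions`.
#' @export
kfold_r2 <- function(data, response, covariates, learner = ranger_learner(),
                     k = 10L, seed = 1L) {
  n <- nrow(data)
  if (k > n) stop("k must not exceed the number of rows")
  set.seed(seed)
  folds <- sample(rep(seq_len(k), length.out = n))
  pred <- rep(NA_real_, n)
  for (f in seq_len(k)) {
    test <- folds == f
    model <- learner$fit(data[!test, , drop = FALSE], response, covariates,
                         seed = seed + f)
    pred[test] <- learner$predict(model, data[test, , drop = FALSE])
  }
  y <- data[[response]]
  sse <- sum((y - pred)^2)
  sst <- sum((y - mean(y))^2)
  list(r2 = 1 - sse / sst, rmse = sqrt(mean((y - pred)^2)),
       predictions = pred)
}

#' Bootstrap prediction maps with uncertainty bands
#'
#' Refits the learner on `n_boot` seeded random subsamples (without
#' replacement) of `frac` of the rows and predicts on the target grid,
#' reporting the per-cell mean and empirical 5%/95% quantiles across
#' bootstrap predictions. If a subsample collapses a categorical covariate
#' to a single level it is redrawn with a warning.
#'
#' @inheritParams wrapper_select
#' @param prediction_grid data frame of covariate values to predict on.
#' @param n_boot number of bootstrap fits (default 100).
#' @param frac fraction of rows in each subsample (default 0.9).
#' @return Data frame with per-row `mean`, `q05`, `q95` for the grid, plus
#'   attribute `predictions` (grid x n_boot matrix).
#' @export
bootstrap_maps <- function(data, response, covariates, prediction_grid,
                           learner = ranger_learner(), n_boot = 100L,
                           frac = 0.9, seed = 1L) {
  stopifnot(n_boot >= 2L, frac > 0, frac <= 1)
  n <- nrow(data)
  m <- ceiling(frac * n)
  cat_cols <- covariates[vapply(data[covariates], function(x)
    is.factor(x) || is.character(x), logical(1))]
  preds <- matrix(NA_real_, nrow(prediction_grid), n_boot)
  set.seed(seed)
  for (b in seq_len(n_boot)) {
    for (try in 1:25) {
      idx <- sample.int(n, m, replace = FALSE)
      sub <- data[idx, , drop = FALSE]
      degenerate <- any(vapply(cat_cols, function(cc)
        length(unique(sub[[cc]])) < 2L, logical(1)))
      if (!degenerate) break
      warning("degenerate bootstrap subsample (single-level factor); redrawn")
    }
    model <- learner$fit(sub, response, covariates, seed = seed + b)
    preds[, b] <- learner$predict(model, prediction_grid)
  }
  out <- data.frame(
    mean = rowMeans(preds),
    q05 = apply(preds, 1L, stats::quantile, probs = 0.05, names = FALSE),
    q95 = apply(preds, 1L, stats::quantile, probs = 0.95, names = FALSE)
  )
  attr(out, "predictions") <- preds
  out
}

#' Aggregate areal carbon densities to a total stock
#'
#' Sums per-cell, per-layer carbon densities (g C m^-2) times cell areas
#' (m^2) and converts to Pg C (1 Pg = 1e15 g). When bootstrap quantile maps
#' are supplied the same aggregation propagates their bands.
#'
#' @param content_maps numeric matrix (cells x layers) of carbon densities
#'   in g C m^-2, or a list of such matrices named `mean`, `q05`, `q95`.
#' @param cell_areas numeric vector of cell areas in m^2 (length = rows).
#' @return Named numeric: total stock in Pg C (with `q05`/`q95` when
#'   quantile maps were given).
#' @examples
#' aggregate_storage(matrix(1000, 1, 1), 1e12)  # 0.001 Pg C
#' @export
aggregate_storage <- function(content_maps, cell_areas) {
  total <- function(m) {
    m <- as.matrix(m)
    if (nrow(m) != length(cell_areas))
      stop("content map rows must match the number of cell areas")
    sum(colSums(m * cell_areas)) / 1e15
  }
  if (is.list(content_maps) && !is.data.frame(content_maps)) {
    vapply(content_maps, total, numeric(1))
  } else {
    c(stock_PgC = total(content_maps))
  }
}
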