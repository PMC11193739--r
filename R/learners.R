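#' Random-forest learner for the mapping workflow
#'
#' Wraps `ranger` behind the small learner contract the mapping functions
#' consume: `fit(data, response, covariates, seed)` returning a model,
#' `predict(model, newdata)` returning numeric predictions, and
#' `importance(model_data, response, covariates, seed)` returning impurity
#' and permutation importances (each measured on its own fit, as the two
#' measures require different forest configurations). Any regressor
#' satisfying the same contract can be injected in its place.
#'
#' @param num.trees number of trees (default 300).
#' @param ... further arguments forwarded to [ranger::ranger()].
#' @return A list of class `soc_learner` with elements `fit`, `predict`
#'   and `importance`.
#' @export
ranger_learner <- function(num.trees = 300, ...) {
  extra <- list(...)
  fit_one <- function(data, response, covariates, seed, importance = "none") {
    fm <- stats::reformulate(covariates, response)
    args <- c(list(formula = fm, data = data, num.trees = num.trees,
                   seed = seed, importance = importance,
                   respect.unordered.factors = "order"), extra)
    do.call(ranger::ranger, args)
  }
  structure(list(
    fit = function(data, response, covariates, seed = 1L) {
      fit_one(data, response, covariates, seed)
    },
    predict = function(model, newdata) {
      stats::predict(model, data = newdata)$predictions
    },
    importance = function(data, response, covariates, seed = 1L) {
      imp_g <- ranger::importance(
        fit_one(data, response, covariates, seed, importance = "impurity"))
      imp_p <- ranger::importance(
        fit_one(data, response, covariates, seed, importance = "permutation"))
      list(impurity = imp_g[covariates], permutation = imp_p[covariates])
    }
  ), class = "soc_learner")
}
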