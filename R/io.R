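#' Write observation profiles to a delimited table
#'
#' One row per (cell, layer) with columns `cell_id`, `lon`, `lat`,
#' `layer_top_cm`, `layer_bottom_cm`, `maoc`, `poc`, `maoc_sd`, `poc_sd`,
#' `npp_input` (the NPP allocated to that layer, g C m^-2 yr^-1) and any
#' covariate columns. Tab-separated plain text.
#'
#' @param observations list of `obs_profile` objects.
#' @param path output file path.
#' @param lonlat optional data frame with `cell_id`, `lon`, `lat`.
#' @return The path, invisibly.
#' @export
write_observations <- function(observations, path, lonlat = NULL) {
  rows <- lapply(observations, function(o) {
    n <- o$grid$n_layers
    df <- data.frame(
      cell_id = o$cell_id,
      layer_top_cm = o$grid$bounds[, "top"],
      layer_bottom_cm = o$grid$bounds[, "bottom"],
      maoc = o$MAOC, poc = o$POC, maoc_sd = o$MAOC_sd, poc_sd = o$POC_sd,
      npp_input = o$inputs
    )
    if (!is.null(o$covariates))
      df <- cbind(df, o$covariates[rep(1L, n), , drop = FALSE])
    df
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (!is.null(lonlat))
    tab <- merge(lonlat, tab, by = "cell_id", sort = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read observation profiles from a delimited table
#'
#' Inverse of [write_observations()]: reconstructs one `obs_profile` per
#' cell from a tab-separated table with one row per (cell, layer).
#'
#' @param path input file path.
#' @return List of `obs_profile` objects.
#' @export
read_observations <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  required <- c("cell_id", "layer_top_cm", "layer_bottom_cm", "maoc", "poc",
                "npp_input")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("observation table lacks columns: ", paste(missing, collapse = ", "))
  core <- c(required, "maoc_sd", "poc_sd", "lon", "lat")
  cov_cols <- setdiff(names(tab), core)
  lapply(split(tab, tab$cell_id)[unique(as.character(tab$cell_id))],
         function(d) {
    d <- d[order(d$layer_top_cm), ]
    grid <- soil_profile_grid(cbind(top = d$layer_top_cm,
                                    bottom = d$layer_bottom_cm))
    observation_profile(
      cell_id = d$cell_id[1L], maoc = d$maoc, poc = d$poc,
      inputs = d$npp_input, grid = grid,
      maoc_sd = if ("maoc_sd" %in% names(d)) d$maoc_sd else NULL,
      poc_sd = if ("poc_sd" %in% names(d)) d$poc_sd else NULL,
      covariates = if (length(cov_cols))
        d[1L, cov_cols, drop = FALSE] else NULL
    )
  })
}

#' Write truth records (parameters, pools, covariates) to a table
#'
#' One row per cell: true parameters, location, covariates, and the true
#' pool-weighted 0--100 cm turnover times implied by the noiseless steady
#' state (for scoring inversions).
#'
#' @param truths list of truth records from [sample_truths()].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_truths <- function(truths, path) {
  rows <- lapply(truths, function(tr) {
    k <- depth_rate_profile(tr$params, tr$grid)
    cbind(
      data.frame(cell_id = tr$cell_id, lon = tr$lon, lat = tr$lat),
      as.data.frame(as.list(tr$params)),
      data.frame(
        tau_maoc_profile = profile_turnover(1 / k$KM, tr$pools$MAOC),
        tau_poc_profile = profile_turnover(1 / k$KP, tr$pools$POC)
      ),
      tr$covariates
    )
  })
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a pool state as a layered delimited table
#'
#' @param state `pool_state`.
#' @param grid `soil_grid`.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_pool_state <- function(state, grid, path) {
  tab <- data.frame(layer_top_cm = grid$bounds[, "top"],
                    layer_bottom_cm = grid$bounds[, "bottom"],
                    MAOC = state$MAOC, POC = state$POC)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a parameter set to a flat key-value file
#'
#' Plain-text YAML with one key per parameter (`KM1`, `KP1`, `zM`, `zP`,
#' `T_MAOCtoPOC`, `T_POCtoMAOC`, `D`, `A`).
#'
#' @param params `soc_params`.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_parameters <- function(params, path) {
  yaml::write_yaml(as.list(unclass(params)[parameter_names()]), path)
  invisible(path)
}

#' Read a parameter set from a flat key-value file
#' @param path input file path.
#' @return A `soc_params` object.
#' @export
read_parameters <- function(path) {
  as_parameters(yaml::read_yaml(path))
}
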