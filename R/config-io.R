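#' Write parameter sets to a YAML configuration file
#'
#' Dumps PFT (and nested SOD) parameter sets to a human-editable YAML
#' file; [params_from_yaml()] reads it back through the validating
#' constructors.
#'
#' @param pfts Named list of `pft_parameters` (default: the shipped
#'   defaults for all three PFTs).
#' @param file Path to write.
#' @return `file`, invisibly.
#' @export
params_to_yaml <- function(pfts = default_pft(), file) {
  as_plain <- function(p) {
    x <- unclass(p)
    x$sod <- unclass(x$sod)
    x
  }
  yaml::write_yaml(lapply(pfts, as_plain), file)
  invisible(file)
}

#' Read parameter sets from a YAML configuration file
#'
#' @param file Path to a YAML file written by [params_to_yaml()] (or
#'   hand-edited in the same layout).
#' @return Named list of `pft_parameters`.
#' @export
params_from_yaml <- function(file) {
  raw <- yaml::read_yaml(file)
  lapply(raw, function(x) {
    sod <- do.call(sod_parameters, x$sod)
    x$sod <- NULL
    ## derived uptake maxima are stored explicitly; pass everything through
    x[vapply(x, is.null, logical(1))] <- NA_real_
    do.call(pft_parameters, c(x, list(sod = sod)))
  })
}

#' Simulation-result tables
#'
#' Flattens the monthly climatology of a gridded run into one tidy row
#' per (pft, box, month); suitable for CSV export alongside the
#' deficiency fields (`mn_def`, `mn_pot_def`, `fe_def`) and SOD
#' diagnostics (`eps_p`, `q_mn_min_eff`).
#'
#' @param sim A `grid_simulation`.
#' @param vars Monthly variables to include (default: a compact
#'   diagnostic set).
#' @return A data.frame.
#' @export
result_to_table <- function(sim,
                            vars = c("biomass", "chl_c", "q_fe", "q_mn",
                                     "mu", "mu_no_fe", "q_mn_req",
                                     "q_mn_min_eff", "eps_p",
                                     "mn_def", "mn_pot_def", "fe_def",
                                     "npp", "export")) {
  stopifnot(inherits(sim, "grid_simulation"))
  rows <- lapply(names(sim$results), function(pft) {
    mo <- sim$results[[pft]]$monthly
    nb <- nrow(mo$biomass)
    idx <- expand.grid(box = seq_len(nb), month = 1:12)
    out <- data.frame(
      experiment = sim$cfg$name, pft = pft,
      lat = sim$lat[idx$box], lon = sim$forcing$lon[idx$box],
      month = idx$month
    )
    for (v in vars) out[[v]] <- mo[[v]][cbind(idx$box, idx$month)]
    out
  })
  do.call(rbind, rows)
}
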