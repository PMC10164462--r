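#' Seasonal extreme (most deficient month) of a deficiency ratio
#'
#' Deficiency is most severe when the quota-to-requirement ratio is
#' smallest, so the seasonal extreme is the minimum over the 12 monthly
#' values; ties are broken by the earliest month.
#'
#' @param monthly A `n_box x 12` matrix of monthly deficiency ratios.
#' @return List with `extreme` (per-box minimum ratio) and `month`
#'   (1-12, the most deficient month).
#' @export
seasonal_extreme_deficiency <- function(monthly) {
  if (!is.matrix(monthly) || ncol(monthly) != 12) {
    stop("expected an n_box x 12 matrix of monthly ratios", call. = FALSE)
  }
  check_finite(monthly, "monthly ratios")
  m <- max.col(-monthly, ties.method = "first")
  list(extreme = monthly[cbind(seq_len(nrow(monthly)), m)], month = m)
}

#' Deficiency footprint area
#'
#' Total area of grid cells south of 30 degS whose seasonal-extreme
#' deficiency ratio is below 1.0. No distinction is made of the degree of
#' deficiency; a cell either counts fully or not at all.
#'
#' @param extreme Per-box seasonal-extreme ratios.
#' @param cell_area_km2 Per-box areas, km^2.
#' @param lat Per-box latitudes, degrees (negative south).
#' @param threshold Deficiency threshold (ratio below it counts).
#' @param lat_cut Northern boundary of the accounting region, degrees.
#' @return Footprint area, km^2.
#' @export
deficiency_footprint_area <- function(extreme, cell_area_km2, lat,
                                      threshold = 1.0, lat_cut = -30) {
  stopifnot(length(extreme) == length(cell_area_km2),
            length(extreme) == length(lat))
  sum(cell_area_km2[lat < lat_cut & extreme < threshold])
}

#' Footprint summary for one gridded run
#'
#' Seasonal-extreme deficiency footprints (km^2) per PFT for the three
#' metrics: Fe deficiency, Mn deficiency and potential Mn deficiency.
#'
#' @param sim A `grid_simulation`.
#' @return A data.frame with columns `pft`, `metric`, `area_km2`.
#' @export
footprint_summary <- function(sim) {
  stopifnot(inherits(sim, "grid_simulation"))
  metrics <- c(fe_def = "fe_def", mn_def = "mn_def", mn_pot_def = "mn_pot_def")
  rows <- lapply(names(sim$results), function(pft) {
    res <- sim$results[[pft]]
    data.frame(
      pft = pft,
      metric = names(metrics),
      area_km2 = vapply(metrics, function(v) {
        ext <- seasonal_extreme_deficiency(res$monthly[[v]])$extreme
        deficiency_footprint_area(ext, sim$cell_area_km2, sim$lat)
      }, numeric(1)),
      row.names = NULL
    )
  })
  do.call(rbind, rows)
}

#' Per-cell deficiency masks from a gridded run
#'
#' @param sim A `grid_simulation`.
#' @param pft PFT name.
#' @param metric One of `"fe_def"`, `"mn_def"`, `"mn_pot_def"`.
#' @return Logical vector, one element per box: seasonal-extreme ratio
#'   below 1.
#' @export
deficiency_mask <- function(sim, pft, metric) {
  stopifnot(inherits(sim, "grid_simulation"))
  res <- sim$results[[pft]]
  if (is.null(res)) stop("unknown PFT '", pft, "'", call. = FALSE)
  metric <- match.arg(metric, c("fe_def", "mn_def", "mn_pot_def"))
  seasonal_extreme_deficiency(res$monthly[[metric]])$extreme < 1.0
}

#' Annual net primary production and 100-m carbon export
#'
#' NPP sums `mu * biomass` over PFTs, converted to mg C m^-3 d^-1 and
#' integrated over the production layer (areal mg C m^-2 d^-1); the
#' biological-carbon-pump proxy is the sinking-detritus flux at the layer
#' base. Both are annual means of the monthly climatology; area-weighted
#' regional totals are reported in Tg C yr^-1 (360-day model year).
#'
#' @param sim A `grid_simulation` (must have converged unless
#'   `allow_unconverged`).
#' @param allow_unconverged Logical; refuse non-converged results by
#'   default.
#' @return List with per-box annual `npp` and `export` (mg C m^-2 d^-1),
#'   the monthly `npp_monthly`/`export_monthly` matrices (summed over
#'   PFTs, volumetric NPP in mg C m^-3 d^-1), and area-weighted totals
#'   `total_npp_tg` / `total_export_tg` plus the `e_ratio`.
#' @export
npp_and_export <- function(sim, allow_unconverged = FALSE) {
  stopifnot(inherits(sim, "grid_simulation"))
  conv <- vapply(sim$results, `[[`, logical(1), "converged")
  if (!all(conv) && !allow_unconverged) {
    stop("refusing diagnostics on non-converged result (PFTs: ",
         paste(names(conv)[!conv], collapse = ", "), ")", call. = FALSE)
  }
  npp_m <- Reduce(`+`, lapply(sim$results, function(r) r$monthly$npp))
  exp_m <- Reduce(`+`, lapply(sim$results, function(r) r$monthly$export))
  depth <- sim$opts$layer_depth
  npp_annual <- rowMeans(npp_m) * depth      # mg C m^-2 d^-1 over the layer
  export_annual <- rowMeans(exp_m)           # mg C m^-2 d^-1 at layer base
  area_m2 <- sim$cell_area_km2 * 1e6
  total_npp_tg <- sum(npp_annual * area_m2) * 360 / 1e18
  total_export_tg <- sum(export_annual * area_m2) * 360 / 1e18
  list(npp = npp_annual, export = export_annual,
       npp_monthly = npp_m, export_monthly = exp_m,
       total_npp_tg = total_npp_tg, total_export_tg = total_export_tg,
       e_ratio = total_export_tg / total_npp_tg)
}

#' Per-PFT share of regional NPP
#'
#' @param sim A `grid_simulation`.
#' @param allow_unconverged Passed through to convergence checking.
#' @return Named numeric vector of percentage contributions per PFT.
#' @export
npp_share <- function(sim, allow_unconverged = FALSE) {
  stopifnot(inherits(sim, "grid_simulation"))
  conv <- vapply(sim$results, `[[`, logical(1), "converged")
  if (!all(conv) && !allow_unconverged) {
    stop("refusing diagnostics on non-converged result", call. = FALSE)
  }
  area_m2 <- sim$cell_area_km2 * 1e6
  tot <- vapply(sim$results, function(r) {
    sum(rowMeans(r$monthly$npp) * area_m2)
  }, numeric(1))
  100 * tot / sum(tot)
}

#' Percent change of an experiment relative to the control
#'
#' `Delta = 100 * (experiment - control) / control`, computed per cell for
#' NPP and export and per PFT x metric for footprint areas. Cells where
#' the control value is zero are masked (`NA`), not infinite.
#'
#' @param experiment,control `grid_simulation` objects on the same grid
#'   and PFT set.
#' @param allow_unconverged Passed to [npp_and_export()].
#' @return List with per-box `npp_pct`, `export_pct` and a data.frame
#'   `footprints` (`pft`, `metric`, experiment/control areas and
#'   `pct_change`).
#' @export
compare_to_control <- function(experiment, control, allow_unconverged = FALSE) {
  stopifnot(inherits(experiment, "grid_simulation"),
            inherits(control, "grid_simulation"))
  if (length(experiment$lat) != length(control$lat) ||
      !identical(names(experiment$results), names(control$results))) {
    stop("experiment and control are on different grids or PFT sets",
         call. = FALSE)
  }
  pct <- function(e, c) ifelse(c == 0, NA_real_, 100 * (e - c) / c)
  fe <- npp_and_export(experiment, allow_unconverged)
  fc <- npp_and_export(control, allow_unconverged)
  fp_e <- footprint_summary(experiment)
  fp_c <- footprint_summary(control)
  fp <- merge(fp_e, fp_c, by = c("pft", "metric"),
              suffixes = c("_experiment", "_control"))
  fp$pct_change <- pct(fp$area_km2_experiment, fp$area_km2_control)
  list(npp_pct = pct(fe$npp, fc$npp),
       export_pct = pct(fe$export, fc$export),
       total_npp_pct = pct(fe$total_npp_tg, fc$total_npp_tg),
       total_export_pct = pct(fe$total_export_tg, fc$total_export_tg),
       footprints = fp)
}

#' Run the full factorial experiment suite on one forcing grid
#'
#' Runs the control and any subset of the eight trait experiments on the
#' same grid, returning the `grid_simulation` objects and a combined
#' footprint table with percent changes versus the control.
#'
#' @param grid A `forcing_grid` or `monthly_forcing`.
#' @param experiments Character vector of experiment names (default: all).
#' @param pfts Named list of `pft_parameters`.
#' @param opts A `sim_options`.
#' @return List with `runs` (named list of `grid_simulation`) and
#'   `footprints` (data.frame: `experiment`, `pft`, `metric`,
#'   `area_km2`, `pct_change_vs_control`).
#' @export
run_experiment_suite <- function(grid, experiments = experiment_names(),
                                 pfts = default_pft(), opts = sim_options()) {
  experiments <- union("control", experiments)
  forcing <- if (inherits(grid, "monthly_forcing")) grid else as_monthly_forcing(grid)
  runs <- lapply(stats::setNames(experiments, experiments), function(nm) {
    run_grid(forcing, experiment_config(nm), pfts, opts)
  })
  fp_c <- footprint_summary(runs$control)
  tables <- lapply(names(runs), function(nm) {
    fp <- footprint_summary(runs[[nm]])
    fp$experiment <- nm
    fp$pct_change_vs_control <- ifelse(
      fp_c$area_km2 == 0, NA_real_,
      100 * (fp$area_km2 - fp_c$area_km2) / fp_c$area_km2)
    fp[, c("experiment", "pft", "metric", "area_km2", "pct_change_vs_control")]
  })
  list(runs = runs, footprints = do.call(rbind, tables))
}
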