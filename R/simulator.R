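#' Simulator options
#'
#' Numerical and closure settings of the seasonal box-model engine.
#'
#' @param dt Explicit-Euler time step, d (in (0, 1]).
#' @param days_per_month Days per forcing month (12 x 30 = 360-day year).
#' @param max_cycles Cap on annual-cycle repetitions during spinup.
#' @param tol Year-over-year maximum relative change of monthly biomass,
#'   quotas and Chl:C below which the cycle is declared periodic.
#' @param loss_rate Linear biomass loss closure (background mortality), d^-1.
#' @param loss_quad Density-dependent loss closure (grazing),
#'   d^-1 (mmol C m^-3)^-1; the per-capita loss is
#'   `loss_rate + loss_quad * biomass`.
#' @param relax_rate Relaxation of box dissolved pools toward the forcing
#'   concentration (resupply by mixing/circulation), d^-1.
#' @param w_sink Detritus sinking speed, m d^-1.
#' @param remin_rate Detritus remineralization, d^-1.
#' @param layer_depth Depth of the production layer, m (export is
#'   evaluated at its base).
#' @param closed Logical; closed-box mode for conservation testing: no
#'   relaxation, no sinking, all losses and remineralization returned to
#'   the dissolved pools, inorganic carbon tracked explicitly.
#' @return An object of class `sim_options`.
#' @export
sim_options <- function(dt = 0.25, days_per_month = 30, max_cycles = 20,
                        tol = 1e-4, loss_rate = 0.02, loss_quad = 0.05,
                        relax_rate = 0.1,
                        w_sink = 10, remin_rate = 0.2, layer_depth = 100,
                        closed = FALSE) {
  stopifnot(dt > 0, dt <= 1, days_per_month >= 1, max_cycles >= 1,
            tol > 0, loss_rate >= 0, loss_quad >= 0, relax_rate >= 0,
            w_sink >= 0, remin_rate >= 0, layer_depth > 0)
  structure(as.list(environment()), class = "sim_options")
}

## internal: full box state (cell + dissolved pools + detritus + DIC),
## every field a length-n vector
init_box <- function(p, forcing, biomass_c = 0.5) {
  n <- nrow(forcing$par)
  cell <- initial_state(p, n, biomass_c)
  list(
    biomass = cell$biomass_c,
    q_n = cell$q_n, q_p = cell$q_p,
    q_si = if (p$name == "diatom") cell$q_si else rep(0, n),
    q_fe = cell$q_fe, q_mn = cell$q_mn, q_zn = cell$q_zn,
    chl_c = cell$chl_c,
    d_n = forcing$n[, 1], d_p = forcing$p[, 1], d_si = forcing$si[, 1],
    d_fe = forcing$d_fe[, 1], d_mn = forcing$d_mn[, 1],
    d_zn = forcing$d_zn[, 1],
    det = rep(0, n), dic = rep(0, n)
  )
}

## internal lean Euler step: pure arithmetic, no validation. `box` fields
## are equal-length vectors; `tgt` holds the forcing concentrations the
## dissolved pools relax toward. Exported step_cell() wraps this with
## input checking; the annual-cycle engine calls it directly.
step_core <- function(box, par, temperature, tgt, p, cfg, opts, chl_psii) {
  dt <- opts$dt
  B <- box$biomass
  chl_c <- box$chl_c

  ## temperature and light
  mu_t <- p$mu_max * p$temp_coeff^(temperature - p$t_ref)
  v_e <- mu_t * (1 - exp(-p$alpha_light * chl_c * par / mu_t))

  ## requirements
  chl_mol <- chl_c * (C_MOLAR_MASS / CHL_MOLAR_MASS)
  fe_atoms <- p$fe_per_psii + p$fe_per_psi / p$psii_psi_ratio
  q_fe_req <- p$q_fe_min + fe_atoms * chl_mol / chl_psii * 1e6
  q_def_fe <- (box$q_fe - q_fe_req) / p$q_fe_opt
  sp <- p$sod
  eps_p <- ifelse(q_def_fe < 1, sp$eps_p_max, sp$eps_p_min)
  q_mn_min_eff <- if (cfg$mnsod_enabled) {
    mnsod <- eps_p * v_e / (sp$eps_a * sp$kcat_ros * cfg$kcat_multiplier)
    pmax(p$q_mn_min, cfg$mnsod_reliance * sp$mn_per_sod * mnsod)
  } else {
    p$q_mn_min
  }
  q_mn_req <- q_mn_min_eff + p$mn_per_psii * chl_mol / chl_psii * 1e6

  ## limitation terms (Droop for N/P/Si/Fe, ratio for Mn), Liebig minimum
  lim_n <- clamp((box$q_n - p$q_n_min) / (p$q_n_max - p$q_n_min))
  lim_p <- clamp((box$q_p - p$q_p_min) / (p$q_p_max - p$q_p_min))
  lim_fe <- {
    span <- q_fe_req - p$q_fe_min
    ifelse(span <= 0, 1, clamp((box$q_fe - p$q_fe_min) / span))
  }
  lim_mn <- clamp(box$q_mn / q_mn_req)
  lim_no_fe <- pmin(lim_n, lim_p, lim_mn)
  if (p$name == "diatom") {
    lim_si <- clamp((box$q_si - p$q_si_min) / (p$q_si_max - p$q_si_min))
    lim_no_fe <- pmin(lim_no_fe, lim_si)
  } else {
    lim_si <- 1
  }
  lim_min <- pmin(lim_no_fe, lim_fe)
  mu <- v_e * lim_min
  mu_no_fe <- v_e * lim_no_fe

  ## uptake rates per mol C
  v_n <- p$vmax_n * box$d_n / (box$d_n + p$k_n) * clamp(1 - box$q_n / p$q_n_max)
  v_p <- p$vmax_p * box$d_p / (box$d_p + p$k_p) * clamp(1 - box$q_p / p$q_p_max)
  v_fe <- p$vmax_fe * box$d_fe / (box$d_fe + p$k_fe) *
    clamp(1 - box$q_fe / p$q_fe_max)
  k_mn_eff <- if (cfg$zn_mn_competition) {
    p$k_mn * (1 + box$d_zn / p$zn_inhibition_const)
  } else {
    p$k_mn
  }
  hyper_zn <- {
    thr <- p$zn_hyperacc_threshold
    ifelse(box$q_zn <= thr, 1,
           p$zn_hyperacc_floor + (1 - p$zn_hyperacc_floor) *
             exp(-p$zn_hyperacc_steepness * (box$q_zn / thr - 1)))
  }
  hyper_mn <- if (cfg$zn_hyperacc_affects_mn) hyper_zn else 1
  v_mn <- p$vmax_mn * box$d_mn / (box$d_mn + k_mn_eff) * hyper_mn *
    clamp(1 - box$q_mn / p$q_mn_max)
  v_zn <- p$vmax_zn * box$d_zn / (box$d_zn + p$k_zn) * hyper_zn *
    clamp(1 - box$q_zn / p$q_zn_max)

  ## carbon
  loss <- opts$loss_rate + opts$loss_quad * B
  growth_flux <- mu * B
  loss_flux <- loss * B
  B_new <- B + dt * (growth_flux - loss_flux)

  ## elemental pools (pairwise fluxes: conservative in closed mode);
  ## macronutrients umol l^-1 with q in mol/mol (unit 1), trace metals
  ## nmol l^-1 with q in umol/mol (unit 1e-3)
  closed <- opts$closed
  relax <- opts$relax_rate
  upd <- function(q, d, v, target, unit) {
    int_pool <- q * B * unit
    up <- v * B * unit
    lost <- loss * int_pool
    int_new <- int_pool + dt * (up - lost)
    d_new <- if (closed) d + dt * (lost - up)
             else pmax(d + dt * (relax * (target - d) - up), 0)
    list(q = int_new / (B_new * unit), d = d_new)
  }
  nn <- upd(box$q_n, box$d_n, v_n, tgt$n, 1)
  pp <- upd(box$q_p, box$d_p, v_p, tgt$p, 1)
  ss <- if (p$name == "diatom") {
    v_si <- p$vmax_si * box$d_si / (box$d_si + p$k_si) *
      clamp(1 - box$q_si / p$q_si_max)
    upd(box$q_si, box$d_si, v_si, tgt$si, 1)
  } else {
    list(q = box$q_si,
         d = if (closed) box$d_si
             else box$d_si + dt * relax * (tgt$si - box$d_si))
  }
  ff <- upd(box$q_fe, box$d_fe, v_fe, tgt$d_fe, 1e-3)
  mm <- upd(box$q_mn, box$d_mn, v_mn, tgt$d_mn, 1e-3)
  zz <- upd(box$q_zn, box$d_zn, v_zn, tgt$d_zn, 1e-3)

  ## detritus carbon and inorganic carbon
  sink_rate <- if (closed) 0 else opts$w_sink / opts$layer_depth
  det_new <- box$det + dt * (loss_flux - (sink_rate + opts$remin_rate) * box$det)
  dic_new <- box$dic + dt * (opts$remin_rate * box$det - growth_flux)

  ## photoacclimation toward a light/nutrient-dependent target
  theta_target <- clamp(
    p$theta_min + (p$theta_max - p$theta_min) * lim_min / (1 + par / 10),
    p$theta_min, p$theta_max)
  chl_new <- clamp(chl_c + (theta_target - chl_c) * (1 - exp(-0.5 * dt)),
                   p$theta_min, p$theta_max)

  box$biomass <- B_new
  box$q_n <- nn$q; box$d_n <- nn$d
  box$q_p <- pp$q; box$d_p <- pp$d
  box$q_si <- ss$q; box$d_si <- ss$d
  box$q_fe <- ff$q; box$d_fe <- ff$d
  box$q_mn <- mm$q; box$d_mn <- mm$d
  box$q_zn <- zz$q; box$d_zn <- zz$d
  box$det <- det_new
  box$dic <- dic_new
  box$chl_c <- chl_new

  mn_def <- box$q_mn / q_mn_req
  mn_pot_def <- ifelse(mu_no_fe > 0, box$q_mn * mu / (q_mn_req * mu_no_fe),
                       mn_def)
  fe_def <- (box$q_fe - q_fe_req) / p$q_fe_opt

  list(box = box,
       diag = list(mu = mu, mu_no_fe = mu_no_fe, mu_fe = v_e * lim_fe,
                   v_e = v_e, lim_fe = lim_fe, lim_mn = lim_mn,
                   lim_n = lim_n, lim_si = lim_si,
                   q_fe_req = q_fe_req, q_mn_req = q_mn_req,
                   q_mn_min_eff = rep(q_mn_min_eff, length.out = length(mu)),
                   eps_p = eps_p,
                   mn_def = mn_def, mn_pot_def = mn_pot_def,
                   fe_def = fe_def))
}

#' Advance one box model by one Euler step
#'
#' Explicit-Euler update of biomass, elemental quotas, Chl:C, dissolved
#' pools, detritus and inorganic carbon. Biomass grows at the realized
#' Liebig-minimum rate and decays at the loss closure
#' (`loss_rate + loss_quad * biomass`); quotas gain by uptake and are
#' diluted by growth; dissolved pools are drawn down by uptake and
#' replenished by relaxation toward the forcing concentration (open mode)
#' or by returned losses (closed mode). All fluxes are applied pairwise
#' to source and sink pools, so closed-mode elemental totals (C, N, P,
#' Si, Fe, Mn, Zn) are conserved to machine rounding over any horizon.
#'
#' @param box Engine state: list of equal-length vectors `biomass`,
#'   `q_n`, `q_p`, `q_si`, `q_fe`, `q_mn`, `q_zn`, `chl_c`, `d_n`,
#'   `d_p`, `d_si`, `d_fe`, `d_mn`, `d_zn`, `det`, `dic` (see
#'   [run_annual_cycle()] for the user-level entry point).
#' @param env List with `par` and `temperature` for this step (dissolved
#'   concentrations come from the box itself).
#' @param target List of forcing concentrations (`n`, `p`, `si`, `d_fe`,
#'   `d_mn`, `d_zn`) the dissolved pools relax toward in open mode.
#' @param p A `pft_parameters`.
#' @param cfg An `experiment_config`.
#' @param opts A `sim_options`.
#' @return List with the updated `box` and per-step diagnostics (`mu`,
#'   `mu_no_fe`, `mu_fe`, `v_e`, limitation terms, requirements,
#'   deficiency ratios, `eps_p`).
#' @export
step_cell <- function(box, env, target, p, cfg = experiment_config("control"),
                      opts = sim_options()) {
  for (f in c("biomass", "q_n", "q_p", "q_fe", "q_mn", "q_zn", "chl_c",
              "d_n", "d_p", "d_si", "d_fe", "d_mn", "d_zn")) {
    if (any(!is.finite(box[[f]]))) {
      stop("non-finite '", f, "' at box index ",
           paste(which(!is.finite(box[[f]])), collapse = ","), call. = FALSE)
    }
  }
  check_finite(env$par, "par")
  check_finite(env$temperature, "temperature")
  chl_psii <- if (is.na(cfg$chl_psii_override)) p$chl_psii else cfg$chl_psii_override
  step_core(box, env$par, env$temperature, target, p, cfg, opts, chl_psii)
}

## diagnostics recorded as monthly climatologies
MONTHLY_VARS <- c("biomass", "q_n", "q_fe", "q_mn", "q_zn", "chl_c",
                  "mu", "mu_no_fe", "v_e", "lim_fe", "lim_mn",
                  "q_fe_req", "q_mn_req", "q_mn_min_eff", "eps_p", "mn_ue",
                  "mn_def", "mn_pot_def", "fe_def", "npp", "export", "det")

## internal: run one annual cycle, accumulating monthly means
run_one_cycle <- function(box, forcing, p, cfg, opts, chl_psii) {
  n <- nrow(forcing$par)
  steps_per_month <- round(opts$days_per_month / opts$dt)
  w <- 1 / steps_per_month
  acc <- lapply(stats::setNames(MONTHLY_VARS, MONTHLY_VARS),
                function(v) matrix(0, n, 12))
  for (m in 1:12) {
    par_m <- forcing$par[, m]
    temp_m <- forcing$temperature[, m]
    tgt <- list(n = forcing$n[, m], p = forcing$p[, m], si = forcing$si[, m],
                d_fe = forcing$d_fe[, m], d_mn = forcing$d_mn[, m],
                d_zn = forcing$d_zn[, m])
    for (k in seq_len(steps_per_month)) {
      out <- step_core(box, par_m, temp_m, tgt, p, cfg, opts, chl_psii)
      box <- out$box
      d <- out$diag
      acc$biomass[, m] <- acc$biomass[, m] + w * box$biomass
      acc$q_n[, m] <- acc$q_n[, m] + w * box$q_n
      acc$q_fe[, m] <- acc$q_fe[, m] + w * box$q_fe
      acc$q_mn[, m] <- acc$q_mn[, m] + w * box$q_mn
      acc$q_zn[, m] <- acc$q_zn[, m] + w * box$q_zn
      acc$chl_c[, m] <- acc$chl_c[, m] + w * box$chl_c
      acc$mu[, m] <- acc$mu[, m] + w * d$mu
      acc$mu_no_fe[, m] <- acc$mu_no_fe[, m] + w * d$mu_no_fe
      acc$v_e[, m] <- acc$v_e[, m] + w * d$v_e
      acc$lim_fe[, m] <- acc$lim_fe[, m] + w * d$lim_fe
      acc$lim_mn[, m] <- acc$lim_mn[, m] + w * d$lim_mn
      acc$q_fe_req[, m] <- acc$q_fe_req[, m] + w * d$q_fe_req
      acc$q_mn_req[, m] <- acc$q_mn_req[, m] + w * d$q_mn_req
      acc$q_mn_min_eff[, m] <- acc$q_mn_min_eff[, m] + w * d$q_mn_min_eff
      acc$eps_p[, m] <- acc$eps_p[, m] + w * d$eps_p
      acc$mn_ue[, m] <- acc$mn_ue[, m] + w * d$mu / d$q_mn_req
      acc$mn_def[, m] <- acc$mn_def[, m] + w * d$mn_def
      acc$mn_pot_def[, m] <- acc$mn_pot_def[, m] + w * d$mn_pot_def
      acc$fe_def[, m] <- acc$fe_def[, m] + w * d$fe_def
      acc$npp[, m] <- acc$npp[, m] + w * d$mu * box$biomass * C_MOLAR_MASS
      acc$export[, m] <- acc$export[, m] +
        w * opts$w_sink * box$det * C_MOLAR_MASS
      acc$det[, m] <- acc$det[, m] + w * box$det
    }
  }
  list(box = box, monthly = acc)
}

#' Run one PFT to a periodic annual cycle
#'
#' Repeats the 12-month forcing cycle until the year-over-year maximum
#' relative change of monthly biomass, quotas and Chl:C falls below
#' `opts$tol`, or `opts$max_cycles` is reached. Returns the final-year
#' monthly climatology of states, growth terms, Mn budget and deficiency
#' diagnostics.
#'
#' @param forcing A `monthly_forcing` (fields `n_box x 12`).
#' @param p A `pft_parameters`.
#' @param cfg An `experiment_config`.
#' @param opts A `sim_options`.
#' @return An object of class `simulation_result`: `monthly` (named list
#'   of `n_box x 12` matrices: biomass, quotas, Chl:C, growth terms,
#'   limitation factors, Mn budget terms, deficiency ratios, NPP and
#'   export), `converged`, `cycles`, `conv_metric`, and the inputs.
#' @export
run_annual_cycle <- function(forcing, p, cfg = experiment_config("control"),
                             opts = sim_options()) {
  stopifnot(inherits(forcing, "monthly_forcing"),
            inherits(p, "pft_parameters"),
            inherits(cfg, "experiment_config"))
  for (f in c("par", "temperature", "n", "p", "si", "d_fe", "d_mn", "d_zn")) {
    check_finite(forcing[[f]], f)
  }
  chl_psii <- if (is.na(cfg$chl_psii_override)) p$chl_psii else cfg$chl_psii_override
  box <- init_box(p, forcing)
  prev <- NULL
  conv <- Inf
  cycles <- 0
  monthly <- NULL
  conv_vars <- c("biomass", "q_fe", "q_mn", "q_zn", "chl_c")
  for (cyc in seq_len(opts$max_cycles)) {
    out <- run_one_cycle(box, forcing, p, cfg, opts, chl_psii)
    box <- out$box
    monthly <- out$monthly
    cycles <- cyc
    if (!is.null(prev)) {
      conv <- max(vapply(conv_vars, function(v) {
        max(abs(monthly[[v]] - prev[[v]]) / (abs(prev[[v]]) + 1e-8))
      }, numeric(1)))
      if (conv < opts$tol) break
    }
    prev <- monthly
  }
  structure(
    list(monthly = monthly, final_box = box,
         converged = conv < opts$tol, cycles = cycles, conv_metric = conv,
         pft = p$name, cfg_name = cfg$name,
         forcing = forcing, p = p, cfg = cfg, opts = opts),
    class = "simulation_result"
  )
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("<simulation_result>", x$pft, "/", x$cfg_name, "-",
      nrow(x$monthly$biomass), "boxes\n")
  cat(sprintf("  %s after %d cycles (metric %.2e)\n",
              if (x$converged) "converged" else "NOT converged",
              x$cycles, x$conv_metric))
  invisible(x)
}

#' Run all PFTs over a forcing grid
#'
#' One independent seasonal box model per grid cell per PFT; cells do not
#' interact, so results are independent of evaluation order.
#'
#' @param grid A `forcing_grid` (or a prebuilt `monthly_forcing`).
#' @param cfg An `experiment_config`.
#' @param pfts Named list of `pft_parameters` (default all three).
#' @param opts A `sim_options`.
#' @return An object of class `grid_simulation`: `results` (named list of
#'   `simulation_result` per PFT), `forcing` (the `monthly_forcing`),
#'   `lat`, `cell_area_km2`, `cfg`, `opts`.
#' @export
run_grid <- function(grid, cfg = experiment_config("control"),
                     pfts = default_pft(), opts = sim_options()) {
  forcing <- if (inherits(grid, "monthly_forcing")) grid else as_monthly_forcing(grid)
  results <- lapply(pfts, function(p) run_annual_cycle(forcing, p, cfg, opts))
  failed <- names(results)[!vapply(results, `[[`, logical(1), "converged")]
  if (length(failed) > 0) {
    warning("non-converged PFTs: ", paste(failed, collapse = ", "),
            " (cycle cap ", opts$max_cycles, ")", call. = FALSE)
  }
  structure(
    list(results = results, forcing = forcing,
         lat = forcing$lat, cell_area_km2 = forcing$cell_area_km2,
         cfg = cfg, opts = opts),
    class = "grid_simulation"
  )
}

#' @export
print.grid_simulation <- function(x, ...) {
  cat("<grid_simulation>", x$cfg$name, "-",
      length(x$lat), "boxes x", length(x$results), "PFTs\n")
  for (nm in names(x$results)) print(x$results[[nm]])
  invisible(x)
}
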