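#' Environmental conditions for one box (or a vector of boxes)
#'
#' All fields may be equal-length vectors, one element per box; values are
#' recycled by the usual rules when scalar.
#'
#' @param par Photosynthetically available radiation, mol photons m^-2 d^-1
#'   (daily mean over the mixed layer).
#' @param temperature Water temperature, degrees C.
#' @param day_fraction Fraction of the day with daylight, dimensionless.
#' @param n,p,si Dissolved macronutrients, umol l^-1.
#' @param d_fe,d_mn,d_zn Dissolved trace metals, nmol l^-1.
#' @return An object of class `environment_conditions`.
#' @export
environment_conditions <- function(par, temperature, day_fraction = 0.5,
                                   n, p, si, d_fe, d_mn, d_zn) {
  env <- list(par = par, temperature = temperature,
              day_fraction = day_fraction,
              n = n, p = p, si = si, d_fe = d_fe, d_mn = d_mn, d_zn = d_zn)
  for (f in names(env)) check_finite(env[[f]], f)
  stopifnot(
    all(env$par >= 0),
    all(env$temperature >= -2),
    all(env$day_fraction >= 0 & env$day_fraction <= 1),
    all(env$n >= 0), all(env$p >= 0), all(env$si >= 0),
    all(env$d_fe >= 0), all(env$d_mn >= 0), all(env$d_zn >= 0)
  )
  structure(env, class = "environment_conditions")
}

#' Cell quota state
#'
#' Per-cell carbon biomass plus elemental quotas and the Chl:C ratio.
#' Fields may be equal-length vectors (one element per box).
#'
#' @param biomass_c Carbon biomass, mmol C m^-3.
#' @param q_n,q_p N and P quotas, mol (mol C)^-1.
#' @param q_si Si quota, mol (mol C)^-1 (diatoms; `NA` otherwise).
#' @param q_fe,q_mn,q_zn Trace-metal quotas, umol (mol C)^-1.
#' @param chl_c Chl:C ratio, mg Chl (mg C)^-1.
#' @param p The `pft_parameters` whose `theta_max` bounds `chl_c`.
#' @return An object of class `cell_quota_state`.
#' @export
cell_quota_state <- function(biomass_c, q_n, q_p, q_si = NA_real_,
                             q_fe, q_mn, q_zn, chl_c, p = NULL) {
  st <- list(biomass_c = biomass_c, q_n = q_n, q_p = q_p, q_si = q_si,
             q_fe = q_fe, q_mn = q_mn, q_zn = q_zn, chl_c = chl_c)
  for (f in setdiff(names(st), "q_si")) check_finite(st[[f]], f)
  stopifnot(
    all(st$biomass_c >= 0),
    all(st$q_n >= 0), all(st$q_p >= 0),
    all(is.na(st$q_si) | st$q_si >= 0),
    all(st$q_fe >= 0), all(st$q_mn >= 0), all(st$q_zn >= 0),
    all(st$chl_c > 0)
  )
  if (!is.null(p)) stopifnot(all(st$chl_c <= p$theta_max))
  structure(st, class = "cell_quota_state")
}

#' Default initial state for one PFT
#'
#' Mid-range quotas and a mid-range Chl:C; the spinup to a periodic annual
#' cycle removes sensitivity to this choice.
#'
#' @param p A `pft_parameters` object.
#' @param n Number of boxes.
#' @param biomass_c Initial biomass, mmol C m^-3.
#' @return A `cell_quota_state`.
#' @export
initial_state <- function(p, n = 1, biomass_c = 0.5) {
  one <- rep(1, n)
  cell_quota_state(
    biomass_c = biomass_c * one,
    q_n = (p$q_n_min + p$q_n_max) / 2 * one,
    q_p = (p$q_p_min + p$q_p_max) / 2 * one,
    q_si = if (p$name == "diatom") (p$q_si_min + p$q_si_max) / 2 * one else NA_real_,
    q_fe = (p$q_fe_min + p$q_fe_opt) * one,
    q_mn = 2 * p$q_mn_min * one,
    q_zn = 5 * one,
    chl_c = 0.5 * p$theta_max * one,
    p = p
  )
}

#' Temperature factor
#'
#' Eppley-style exponential response normalized to 1 at the reference
#' temperature: `f(T) = temp_coeff^(T - t_ref)`.
#'
#' @param temperature Degrees C.
#' @param p A `pft_parameters` object.
#' @return Dimensionless multiplier on `mu_max`.
#' @export
temperature_factor <- function(temperature, p) {
  p$temp_coeff^(temperature - p$t_ref)
}

#' Light-limited growth rate
#'
#' Saturating growth-irradiance law used as the photosynthetic energy rate
#' `v_e` of the ROS budget:
#' `v_e = mu_max f(T) (1 - exp(-alpha chl_c PAR / (mu_max f(T))))`.
#' Bounded by `mu_max f(T)`, zero in darkness, monotone non-decreasing in
#' both PAR and Chl:C.
#'
#' @param env An `environment_conditions` object.
#' @param state A `cell_quota_state` object.
#' @param p A `pft_parameters` object.
#' @return Light-limited growth rate, d^-1.
#' @export
light_limited_growth <- function(env, state, p) {
  check_finite(env$par, "par")
  check_finite(env$temperature, "temperature")
  stopifnot(all(env$par >= 0), all(state$chl_c > 0))
  mu_t <- p$mu_max * temperature_factor(env$temperature, p)
  mu_t * (1 - exp(-p$alpha_light * state$chl_c * env$par / mu_t))
}

#' Photoacclimation step
#'
#' Relaxes Chl:C toward a target that decreases with irradiance and
#' increases under nutrient-replete conditions, clamped to
#' `(theta_min, theta_max]`. The target is
#' `theta_min + (theta_max - theta_min) * nut / (1 + PAR / k_par)` with
#' `nut` the binding nutrient-limitation factor; relaxation time scale
#' `1 / rate`.
#'
#' @param state A `cell_quota_state`.
#' @param env An `environment_conditions`.
#' @param p A `pft_parameters`.
#' @param dt Time step, d (> 0).
#' @param nutrient_factor Binding nutrient limitation in `[0, 1]`
#'   (default 1 = replete).
#' @param rate Relaxation rate, d^-1.
#' @param k_par Irradiance scale of chlorophyll downregulation,
#'   mol photons m^-2 d^-1.
#' @return The state with updated `chl_c`; all other fields unchanged.
#' @export
photoacclimate <- function(state, env, p, dt, nutrient_factor = 1,
                           rate = 0.5, k_par = 10) {
  stopifnot(all(dt > 0))
  target <- p$theta_min +
    (p$theta_max - p$theta_min) * nutrient_factor / (1 + env$par / k_par)
  target <- clamp(target, p$theta_min, p$theta_max)
  state$chl_c <- state$chl_c + (target - state$chl_c) * (1 - exp(-rate * dt))
  state$chl_c <- clamp(state$chl_c, p$theta_min, p$theta_max)
  state
}

#' Required iron quota
#'
#' Fe needed for maintenance plus the photosynthetic apparatus:
#' `Q_Fe,req = q_fe_min + (fe_per_psii + fe_per_psi / psii_psi_ratio) *
#' chl_c_mol / chl_psii`, expressed in umol Fe (mol C)^-1. With the default
#' PSII:PSI ratio of 1 the stoichiometric coefficient is 3 + 12 = 15 Fe
#' atoms per PSII-normalized photosystem unit. A larger antenna (higher
#' Chl:PSII) spreads the same chlorophyll over fewer photosystems and so
#' lowers the requirement.
#'
#' @param state A `cell_quota_state` (only `chl_c` is used).
#' @param p A `pft_parameters`; `chl_psii` may be overridden per experiment.
#' @param chl_psii Optional antenna-size override, mol Chl (mol PSII)^-1.
#' @return Required Fe quota, umol Fe (mol C)^-1.
#' @export
fe_required_quota <- function(state, p, chl_psii = p$chl_psii) {
  if (any(chl_psii <= 0)) stop("chl_psii must be positive", call. = FALSE)
  atoms <- p$fe_per_psii + p$fe_per_psi / p$psii_psi_ratio
  p$q_fe_min + atoms * chl_mass_to_mol(state$chl_c) / chl_psii * 1e6
}

#' Droop-style quota limitation factor
#'
#' `clamp((q - q_min) / (q_req - q_min), 0, 1)`; returns 1 where the
#' requirement does not exceed the subsistence quota.
#'
#' @param q Current quota.
#' @param q_min Subsistence quota.
#' @param q_req Replete (required) quota.
#' @return Limitation factor in `[0, 1]`.
#' @export
quota_limitation <- function(q, q_min, q_req) {
  span <- q_req - q_min
  ifelse(span <= 0, 1, clamp((q - q_min) / span, 0, 1))
}

#' Growth limitation terms and realized growth
#'
#' Computes the per-nutrient limitation factors (Droop form for N, P, Si
#' and Fe; quota-to-requirement ratio for Mn), the light-limited rate
#' `v_e`, and aggregates by Liebig's law of the minimum:
#' `mu = v_e * min(lim_n, lim_p, lim_si, lim_fe, lim_mn)`. `mu_no_fe`
#' applies the same rule with the Fe term removed (the growth the cell
#' would achieve were Fe replete) and `mu_fe = v_e * lim_fe`. The Liebig
#' minimum keeps "limitation" (the binding constraint on growth) distinct
#' from "deficiency" (a quota below its requirement, which need not bind).
#'
#' @param env An `environment_conditions`.
#' @param state A `cell_quota_state`.
#' @param p A `pft_parameters`.
#' @param q_fe_req Required Fe quota, umol/mol (default from
#'   [fe_required_quota()]).
#' @param q_mn_req Required Mn quota, umol/mol (default from
#'   [required_mn_quota()] with the basal constant).
#' @return An object of class `growth_limitation` with fields `lim_light`,
#'   `lim_n`, `lim_p`, `lim_si`, `lim_fe`, `lim_mn`, `v_e`, `mu_fe`,
#'   `mu_no_fe`, `mu`.
#' @export
growth_limitation <- function(env, state, p,
                              q_fe_req = fe_required_quota(state, p),
                              q_mn_req = required_mn_quota(
                                p$q_mn_min, state$chl_c, p$chl_psii, p)) {
  v_e <- light_limited_growth(env, state, p)
  mu_t <- p$mu_max * temperature_factor(env$temperature, p)
  lim_n <- quota_limitation(state$q_n, p$q_n_min, p$q_n_max)
  lim_p <- quota_limitation(state$q_p, p$q_p_min, p$q_p_max)
  lim_si <- if (p$name == "diatom") {
    quota_limitation(state$q_si, p$q_si_min, p$q_si_max)
  } else {
    rep(1, length(v_e))
  }
  lim_fe <- quota_limitation(state$q_fe, p$q_fe_min, q_fe_req)
  lim_mn <- clamp(state$q_mn / q_mn_req, 0, 1)
  lim_min <- pmin(lim_n, lim_p, lim_si, lim_fe, lim_mn)
  lim_min_no_fe <- pmin(lim_n, lim_p, lim_si, lim_mn)
  structure(
    list(
      lim_light = v_e / mu_t,
      lim_n = lim_n, lim_p = lim_p, lim_si = lim_si,
      lim_fe = lim_fe, lim_mn = lim_mn,
      v_e = v_e,
      mu_fe = v_e * lim_fe,
      mu_no_fe = v_e * lim_min_no_fe,
      mu = v_e * lim_min
    ),
    class = "growth_limitation"
  )
}
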