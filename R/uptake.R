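#' Zn-hyperaccumulation downregulation factor
#'
#' When the internal Zn quota exceeds `zn_hyperacc_threshold`, transporter
#' downregulation reduces uptake smoothly toward a floor:
#' `factor = floor + (1 - floor) * exp(-s * (q_zn / threshold - 1))` for
#' `q_zn > threshold`, and 1 otherwise. In the control configuration only
#' Zn uptake is downregulated; with the hyperaccumulation experiment
#' toggle on, the same factor also applies to Mn uptake (both metals share
#' the transporter). Pass `apply_to_mn = FALSE` for the always-on Zn
#' branch, `apply_to_mn = TRUE` with `cfg$zn_hyperacc_affects_mn` for Mn.
#'
#' @param q_zn Internal Zn quota, umol Zn (mol C)^-1 (>= 0).
#' @param p A `pft_parameters` object.
#' @param enabled Logical; if `FALSE` the factor is 1 everywhere.
#' @return Downregulation factor in `(0, 1]`.
#' @export
zn_hyperaccumulation_factor <- function(q_zn, p, enabled = TRUE) {
  stopifnot(all(q_zn >= 0))
  if (!enabled) return(rep(1, length(q_zn)))
  thr <- p$zn_hyperacc_threshold
  fl <- p$zn_hyperacc_floor
  s <- p$zn_hyperacc_steepness
  ifelse(q_zn <= thr, 1, fl + (1 - fl) * exp(-s * (q_zn / thr - 1)))
}

## internal: linear quota-satiation factor, 1 at q = 0, 0 at q = q_max
satiation <- function(q, q_max) clamp(1 - q / q_max, 0, 1)

#' Manganese uptake rate
#'
#' Shared-transporter Michaelis-Menten uptake with dissolved Zn as a
#' competitive inhibitor:
#' `v_Mn = vmax_mn * dMn / (dMn + k_mn * (1 + dZn / zn_inhibition_const))`,
#' scaled by quota satiation (uptake shuts off as `q_mn` approaches
#' `q_mn_max`) and, when the hyperaccumulation experiment toggle is on, by
#' the Zn-downregulation factor. With transporter competition disabled the
#' inhibition term is 1.
#'
#' @param env An `environment_conditions`.
#' @param state A `cell_quota_state`.
#' @param p A `pft_parameters`.
#' @param cfg An `experiment_config` (toggles `zn_mn_competition`,
#'   `zn_hyperacc_affects_mn`). Defaults to the control configuration.
#' @return Mn uptake, umol Mn (mol C)^-1 d^-1.
#' @export
mn_uptake_rate <- function(env, state, p, cfg = experiment_config("control")) {
  if (any(env$d_mn < 0) || any(env$d_zn < 0)) {
    stop("dissolved concentrations must be non-negative", call. = FALSE)
  }
  k_eff <- if (cfg$zn_mn_competition) {
    p$k_mn * (1 + env$d_zn / p$zn_inhibition_const)
  } else {
    p$k_mn
  }
  hyper <- zn_hyperaccumulation_factor(state$q_zn, p,
                                       enabled = cfg$zn_hyperacc_affects_mn)
  p$vmax_mn * env$d_mn / (env$d_mn + k_eff) * hyper *
    satiation(state$q_mn, p$q_mn_max)
}

#' Iron uptake rate
#'
#' Michaelis-Menten uptake of dissolved Fe with linear quota satiation.
#'
#' @inheritParams mn_uptake_rate
#' @return Fe uptake, umol Fe (mol C)^-1 d^-1.
#' @export
fe_uptake_rate <- function(env, state, p) {
  if (any(env$d_fe < 0)) stop("d_fe must be non-negative", call. = FALSE)
  p$vmax_fe * env$d_fe / (env$d_fe + p$k_fe) *
    satiation(state$q_fe, p$q_fe_max)
}

#' Zinc uptake rate
#'
#' Michaelis-Menten uptake of dissolved Zn; the hyperaccumulation
#' downregulation of Zn transport is always active (control behaviour).
#'
#' @inheritParams mn_uptake_rate
#' @return Zn uptake, umol Zn (mol C)^-1 d^-1.
#' @export
zn_uptake_rate <- function(env, state, p) {
  if (any(env$d_zn < 0)) stop("d_zn must be non-negative", call. = FALSE)
  p$vmax_zn * env$d_zn / (env$d_zn + p$k_zn) *
    zn_hyperaccumulation_factor(state$q_zn, p, enabled = TRUE) *
    satiation(state$q_zn, p$q_zn_max)
}

#' Macronutrient uptake rates
#'
#' Michaelis-Menten uptake of dissolved N, P (and Si for diatoms) with
#' linear quota satiation.
#'
#' @inheritParams mn_uptake_rate
#' @return List with `v_n`, `v_p`, `v_si` (mol (mol C)^-1 d^-1; `v_si` is
#'   zero for non-silicifiers).
#' @export
macronutrient_uptake <- function(env, state, p) {
  if (any(env$n < 0) || any(env$p < 0) || any(env$si < 0)) {
    stop("dissolved concentrations must be non-negative", call. = FALSE)
  }
  v_n <- p$vmax_n * env$n / (env$n + p$k_n) *
    satiation(state$q_n, p$q_n_max)
  v_p <- p$vmax_p * env$p / (env$p + p$k_p) *
    satiation(state$q_p, p$q_p_max)
  v_si <- if (p$name == "diatom") {
    p$vmax_si * env$si / (env$si + p$k_si) *
      satiation(state$q_si, p$q_si_max)
  } else {
    rep(0, length(v_n))
  }
  list(v_n = v_n, v_p = v_p, v_si = v_si)
}
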