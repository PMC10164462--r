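#' Electron-leakage fraction
#'
#' The proportion of photosynthetic electron flow that leaks to molecular
#' oxygen, as a step function of cellular Fe status: `eps_p_max` (default
#' 30%) when the cell is Fe-deficient (`Q_defFe < 1`), `eps_p_min`
#' (default 5%) when Fe-replete (`Q_defFe >= 1`; the boundary belongs to
#' the replete branch). No interpolation between the two levels.
#'
#' @param q_def_fe Fe deficiency ratio (see [fe_deficiency_ratio()]).
#' @param sp A `sod_parameters` object.
#' @return Leakage fraction, dimensionless.
#' @export
electron_leakage_fraction <- function(q_def_fe, sp) {
  check_finite(q_def_fe, "q_def_fe")
  ifelse(q_def_fe < 1, sp$eps_p_max, sp$eps_p_min)
}

#' Net reactive-oxygen balance
#'
#' Normalized difference between ROS production (electron leakage scaled
#' by the photosynthetic energy rate) and ROS consumption by SOD:
#' `omega = (eps_p v_e - eps_a v_ros) / (eps_p v_e + eps_a v_ros)`,
#' bounded in (-1, 1].
#'
#' @param eps_p Electron-leakage fraction.
#' @param v_e Photosynthetic energy rate (light-limited growth), d^-1.
#' @param eps_a Efficacy of ROS consumption by MnSOD.
#' @param v_ros ROS consumption rate, d^-1.
#' @return The net ROS balance, dimensionless.
#' @export
ros_balance <- function(eps_p, v_e, eps_a, v_ros) {
  prod <- eps_p * v_e
  cons <- eps_a * v_ros
  if (any(prod + cons <= 0)) {
    stop("ros_balance undefined: eps_p*v_e + eps_a*v_ros must be positive",
         call. = FALSE)
  }
  (prod - cons) / (prod + cons)
}

#' ROS consumption rate
#'
#' `v_ROS = kcat_ros * [MnSOD]` — the maximum turnover rate of MnSOD times
#' its abundance.
#'
#' @param kcat_ros Maximum MnSOD turnover, d^-1 per unit MnSOD (>= 0).
#' @param mnsod MnSOD abundance per unit biomass (>= 0).
#' @return ROS consumption rate, d^-1.
#' @export
ros_consumption_rate <- function(kcat_ros, mnsod) {
  stopifnot(all(kcat_ros >= 0), all(mnsod >= 0))
  kcat_ros * mnsod
}

#' Steady-state MnSOD abundance
#'
#' The MnSOD abundance that exactly balances ROS production
#' (`omega = 0`): `[MnSOD] = eps_p v_e / (eps_a kcat_ros)`. Substituting
#' the result back through the consumption law returns a net ROS balance
#' of zero exactly.
#'
#' @param eps_p Electron-leakage fraction.
#' @param v_e Photosynthetic energy rate, d^-1.
#' @param sp A `sod_parameters` object (`eps_a`, `kcat_ros` > 0).
#' @return Steady-state MnSOD abundance (same units as consumed by
#'   [basal_mn_quota_from_sod()]).
#' @export
steady_state_mnsod <- function(eps_p, v_e, sp) {
  if (sp$eps_a <= 0 || sp$kcat_ros <= 0) {
    stop("eps_a and kcat_ros must be positive", call. = FALSE)
  }
  stopifnot(all(eps_p >= 0), all(v_e >= 0))
  eps_p * v_e / (sp$eps_a * sp$kcat_ros)
}

#' Basal Mn quota implied by the MnSOD requirement
#'
#' Converts a MnSOD abundance into the Mn maintenance quota
#' `Q_MnSOD,min = mnsod_reliance * mn_per_sod * [MnSOD]` (umol Mn
#' (mol C)^-1). A reliance of 0.5 represents cells meeting half their SOD
#' requirement with non-Mn cofactors (Fe, Cu, Ni SODs).
#'
#' @param mnsod MnSOD abundance (>= 0).
#' @param sp A `sod_parameters` object.
#' @return Basal Mn quota, umol Mn (mol C)^-1.
#' @export
basal_mn_quota_from_sod <- function(mnsod, sp) {
  stopifnot(all(mnsod >= 0))
  sp$mnsod_reliance * sp$mn_per_sod * mnsod
}

#' Effective basal Mn quota under a given SOD configuration
#'
#' With the MnSOD pathway disabled, the constant basal quota `q_mn_min`.
#' With it enabled, the MnSOD maintenance quota evaluated at the cell's
#' current Fe status and photosynthetic energy rate replaces the constant,
#' subject to a floor at `q_mn_min` representing non-SOD basal Mn demands
#' (so activating the pathway never lowers the requirement below the
#' control basal quota). A `kcat_multiplier > 1` represents more efficient
#' SOD enzymes and proportionally reduces the Mn needed.
#'
#' @param q_def_fe Fe deficiency ratio of the cell.
#' @param v_e Photosynthetic energy rate, d^-1.
#' @param p A `pft_parameters` object.
#' @param mnsod_enabled Logical; is the explicit MnSOD pathway active?
#' @param mnsod_reliance Override of `p$sod$mnsod_reliance` (optional).
#' @param kcat_multiplier Multiplier on `kcat_ros` (>= 1).
#' @return Effective basal Mn quota, umol Mn (mol C)^-1, plus the
#'   leakage fraction used, as a list with fields `q_mn_min_effective`
#'   and `eps_p`.
#' @export
effective_basal_mn_quota <- function(q_def_fe, v_e, p,
                                     mnsod_enabled = FALSE,
                                     mnsod_reliance = NULL,
                                     kcat_multiplier = 1) {
  sp <- p$sod
  if (!is.null(mnsod_reliance)) sp$mnsod_reliance <- mnsod_reliance
  eps_p <- electron_leakage_fraction(q_def_fe, sp)
  if (!mnsod_enabled) {
    return(list(q_mn_min_effective = rep(p$q_mn_min, length(eps_p)),
                eps_p = eps_p))
  }
  sp$kcat_ros <- sp$kcat_ros * kcat_multiplier
  mnsod <- steady_state_mnsod(eps_p, v_e, sp)
  q_sod <- basal_mn_quota_from_sod(mnsod, sp)
  list(q_mn_min_effective = pmax(p$q_mn_min, q_sod), eps_p = eps_p)
}
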