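#' Superoxide-dismutase (SOD) parameter set
#'
#' Parameters of the MnSOD/ROS balance. The electron-leakage fraction
#' `eps_p` switches between `eps_p_max` (Fe-deficient cell) and `eps_p_min`
#' (Fe-replete cell); leaked electrons generate reactive oxygen species
#' (ROS) that must be consumed by superoxide dismutase, whose Mn-containing
#' form carries `mn_per_sod` catalytic Mn atoms per accounted unit.
#'
#' `eps_a` (efficacy of ROS consumption) and `kcat_ros` (maximum MnSOD
#' turnover) are not observationally constrained; the default calibration
#' sets `eps_a * kcat_ros = eps_p_min * (1 d^-1) / (1 umol mol^-1)` so that
#' an Fe-replete cell growing at the 1 d^-1 reference requires a MnSOD
#' basal quota of exactly 1 umol Mn (mol C)^-1, the control-run basal Mn
#' quota. This keeps the MnSOD experiment comparable to the control
#' wherever cells are Fe-replete.
#'
#' @param eps_a Efficacy of ROS consumption by MnSOD, dimensionless (> 0).
#' @param kcat_ros Maximum MnSOD turnover, d^-1 per unit MnSOD (> 0).
#' @param eps_p_max Electron-leakage fraction under Fe deficiency (default 0.30).
#' @param eps_p_min Electron-leakage fraction when Fe-replete (default 0.05).
#' @param mnsod_reliance Fraction of the SOD requirement met by Mn-containing
#'   SOD, in `[0, 1]`. 0.5 represents reliance on alternative (Fe, Cu, Ni)
#'   SOD cofactors for half the requirement.
#' @param mn_per_sod Catalytic Mn atoms per accounted MnSOD unit.
#' @return An object of class `sod_parameters`.
#' @export
sod_parameters <- function(eps_a = 1.0,
                           kcat_ros = 0.05,
                           eps_p_max = 0.30,
                           eps_p_min = 0.05,
                           mnsod_reliance = 1.0,
                           mn_per_sod = 1) {
  stopifnot(
    eps_a > 0, kcat_ros > 0,
    eps_p_min > 0, eps_p_min <= eps_p_max, eps_p_max < 1,
    mnsod_reliance >= 0, mnsod_reliance <= 1,
    mn_per_sod > 0
  )
  structure(
    list(
      eps_a = eps_a, kcat_ros = kcat_ros,
      eps_p_max = eps_p_max, eps_p_min = eps_p_min,
      mnsod_reliance = mnsod_reliance, mn_per_sod = mn_per_sod
    ),
    class = "sod_parameters"
  )
}

#' Phytoplankton functional type (PFT) parameter set
#'
#' All physiological constants for one functional type: maximum growth,
#' temperature response, the growth-irradiance law, photoacclimation
#' bounds, photosystem stoichiometry (Mn and Fe atoms per PSII/PSI and the
#' antenna size Chl:PSII), basal and optimal micronutrient quotas,
#' macronutrient quota bounds, and uptake kinetics per dissolved nutrient.
#'
#' Stoichiometric constants carried here follow the classical photosystem
#' composition: 4 Mn atoms in the PSII water-oxidizing cluster, 3 Fe atoms
#' in PSII and 12 in PSI, with a default antenna size of
#' 1000 mol Chl (mol PSII)^-1 and an assumed PSII:PSI ratio of 1 (so 15 Fe
#' atoms per PSII-normalized photosystem unit). The basal Mn quota default
#' is 1 umol Mn (mol C)^-1.
#'
#' @param name One of `"diatom"`, `"nano"`, `"pico"`.
#' @param mu_max Maximum specific growth rate at the reference temperature, d^-1.
#' @param temp_coeff Eppley-style exponential base for the temperature factor.
#' @param t_ref Reference temperature, degrees C.
#' @param alpha_light Initial slope of the growth-irradiance curve,
#'   (mol photons m^-2 d^-1)^-1 d^-1 per unit Chl:C.
#' @param theta_max,theta_min Bounds of the Chl:C ratio, mg Chl (mg C)^-1.
#' @param chl_psii Antenna size, mol Chl (mol PSII)^-1.
#' @param psii_psi_ratio mol PSII (mol PSI)^-1.
#' @param mn_per_psii,fe_per_psii,fe_per_psi Metal atoms per photosystem.
#' @param q_mn_min Basal Mn quota, umol Mn (mol C)^-1.
#' @param q_mn_max Maximum Mn quota (uptake satiation), umol Mn (mol C)^-1.
#' @param q_fe_min,q_fe_opt,q_fe_max Minimum, optimal (luxury-uptake onset)
#'   and maximum Fe quotas, umol Fe (mol C)^-1.
#' @param q_zn_max Maximum Zn quota, umol Zn (mol C)^-1.
#' @param q_n_min,q_n_max N quota bounds, mol N (mol C)^-1.
#' @param q_p_min,q_p_max P quota bounds, mol P (mol C)^-1.
#' @param q_si_min,q_si_max Si quota bounds (diatoms only), mol Si (mol C)^-1;
#'   `NA` for non-silicifiers.
#' @param vmax_n,vmax_p,vmax_si Macronutrient maximum uptake,
#'   mol (mol C)^-1 d^-1.
#' @param vmax_fe,vmax_mn,vmax_zn Trace-metal maximum uptake,
#'   umol (mol C)^-1 d^-1.
#' @param k_n,k_p,k_si Macronutrient half-saturation, umol l^-1.
#' @param k_fe,k_mn,k_zn Trace-metal half-saturation, nmol l^-1.
#' @param zn_inhibition_const Dissolved-Zn concentration doubling the
#'   effective Mn half-saturation through shared-transporter competition,
#'   nmol l^-1.
#' @param zn_hyperacc_threshold Internal Zn quota above which transporter
#'   downregulation begins, umol Zn (mol C)^-1.
#' @param zn_hyperacc_floor Lower bound of the downregulation factor.
#' @param zn_hyperacc_steepness Exponential steepness of the downregulation
#'   response.
#' @param sod A [sod_parameters()] object.
#' @return An object of class `pft_parameters`.
#' @export
pft_parameters <- function(name,
                           mu_max,
                           temp_coeff = 1.066,
                           t_ref = 20,
                           alpha_light,
                           theta_max,
                           theta_min = theta_max / 10,
                           chl_psii = 1000,
                           psii_psi_ratio = 1,
                           mn_per_psii = 4L,
                           fe_per_psii = 3L,
                           fe_per_psi = 12L,
                           q_mn_min = 1.0,
                           q_mn_max,
                           q_fe_min, q_fe_opt, q_fe_max,
                           q_zn_max,
                           q_n_min = 0.05, q_n_max = 0.17,
                           q_p_min = 0.003, q_p_max = 0.012,
                           q_si_min = NA_real_, q_si_max = NA_real_,
                           vmax_n = 2 * mu_max * q_n_max,
                           vmax_p = 2 * mu_max * q_p_max,
                           vmax_si = if (is.na(q_si_max)) NA_real_ else 2 * mu_max * q_si_max,
                           vmax_fe, vmax_mn, vmax_zn,
                           k_n, k_p = k_n / 16, k_si = NA_real_,
                           k_fe, k_mn, k_zn,
                           zn_inhibition_const = 2.0,
                           zn_hyperacc_threshold = 15,
                           zn_hyperacc_floor = 0.2,
                           zn_hyperacc_steepness = 2,
                           sod = sod_parameters()) {
  name <- match.arg(name, c("diatom", "nano", "pico"))
  stopifnot(
    mu_max > 0, temp_coeff > 0, alpha_light > 0,
    theta_max > 0, theta_min > 0, theta_min < theta_max,
    chl_psii > 0, psii_psi_ratio > 0,
    mn_per_psii >= 1, fe_per_psii >= 1, fe_per_psi >= 1,
    mn_per_psii == round(mn_per_psii),
    fe_per_psii == round(fe_per_psii),
    fe_per_psi == round(fe_per_psi),
    q_mn_min > 0, q_mn_max > q_mn_min,
    q_fe_min > 0, q_fe_opt >= q_fe_min, q_fe_max > q_fe_opt,
    q_zn_max > 0,
    q_n_min > 0, q_n_max > q_n_min,
    q_p_min > 0, q_p_max > q_p_min,
    vmax_fe > 0, vmax_mn > 0, vmax_zn > 0,
    k_n > 0, k_p > 0, k_fe > 0, k_mn > 0, k_zn > 0,
    zn_inhibition_const > 0,
    zn_hyperacc_threshold > 0,
    zn_hyperacc_floor > 0, zn_hyperacc_floor < 1,
    zn_hyperacc_steepness > 0,
    inherits(sod, "sod_parameters")
  )
  if (name == "diatom") {
    stopifnot(!is.na(q_si_min), !is.na(q_si_max), q_si_max > q_si_min,
              !is.na(vmax_si), !is.na(k_si), k_si > 0)
  }
  structure(
    list(
      name = name, mu_max = mu_max, temp_coeff = temp_coeff, t_ref = t_ref,
      alpha_light = alpha_light, theta_max = theta_max, theta_min = theta_min,
      chl_psii = chl_psii, psii_psi_ratio = psii_psi_ratio,
      mn_per_psii = as.integer(mn_per_psii),
      fe_per_psii = as.integer(fe_per_psii),
      fe_per_psi = as.integer(fe_per_psi),
      q_mn_min = q_mn_min, q_mn_max = q_mn_max,
      q_fe_min = q_fe_min, q_fe_opt = q_fe_opt, q_fe_max = q_fe_max,
      q_zn_max = q_zn_max,
      q_n_min = q_n_min, q_n_max = q_n_max,
      q_p_min = q_p_min, q_p_max = q_p_max,
      q_si_min = q_si_min, q_si_max = q_si_max,
      vmax_n = vmax_n, vmax_p = vmax_p, vmax_si = vmax_si,
      vmax_fe = vmax_fe, vmax_mn = vmax_mn, vmax_zn = vmax_zn,
      k_n = k_n, k_p = k_p, k_si = k_si,
      k_fe = k_fe, k_mn = k_mn, k_zn = k_zn,
      zn_inhibition_const = zn_inhibition_const,
      zn_hyperacc_threshold = zn_hyperacc_threshold,
      zn_hyperacc_floor = zn_hyperacc_floor,
      zn_hyperacc_steepness = zn_hyperacc_steepness,
      sod = sod
    ),
    class = "pft_parameters"
  )
}

#' Default parameter sets for the three functional types
#'
#' Returns the fully-populated default parameterization for diatoms,
#' nanophytoplankton and picophytoplankton. Constants not constrained by
#' observation are calibration choices (see the methods vignette): pico
#' has the highest maximum growth rate and the largest Chl:C ceiling,
#' diatoms the lowest Mn quota (slowest Mn uptake kinetics) and the
#' poorest Fe-uptake affinity, giving the diatom > nano > pico ordering of
#' Fe stress typical of large-celled taxa.
#'
#' @param name Optional PFT name; if omitted, a named list of all three.
#' @return A `pft_parameters` object, or a named list of the three.
#' @export
#' @examples
#' p <- default_pft("diatom")
#' p$mn_per_psii  # 4 Mn atoms in the PSII water-oxidizing cluster
default_pft <- function(name = NULL) {
  all <- list(
    diatom = pft_parameters(
      name = "diatom", mu_max = 0.8, alpha_light = 2.5,
      theta_max = 0.040,
      q_mn_max = 20, q_fe_min = 3.0, q_fe_opt = 15, q_fe_max = 40,
      q_zn_max = 80,
      q_si_min = 0.04, q_si_max = 0.18,
      vmax_fe = 10, vmax_mn = 3.0, vmax_zn = 12,
      k_n = 1.0, k_si = 4.0,
      k_fe = 0.50, k_mn = 0.20, k_zn = 0.8
    ),
    nano = pft_parameters(
      name = "nano", mu_max = 1.0, alpha_light = 3.0,
      theta_max = 0.045,
      q_mn_max = 18, q_fe_min = 2.5, q_fe_opt = 12, q_fe_max = 35,
      q_zn_max = 70,
      vmax_fe = 16, vmax_mn = 3.5, vmax_zn = 12,
      k_n = 0.6,
      k_fe = 0.15, k_mn = 0.15, k_zn = 0.8
    ),
    pico = pft_parameters(
      name = "pico", mu_max = 1.2, alpha_light = 3.5,
      theta_max = 0.050,
      q_mn_max = 15, q_fe_min = 2.0, q_fe_opt = 8, q_fe_max = 30,
      q_zn_max = 60,
      vmax_fe = 20, vmax_mn = 4.5, vmax_zn = 12,
      k_n = 0.3,
      k_fe = 0.08, k_mn = 0.10, k_zn = 0.8
    )
  )
  if (is.null(name)) all else all[[match.arg(name, names(all))]]
}

#' @export
print.pft_parameters <- function(x, ...) {
  cat("<pft_parameters>", x$name, "\n")
  cat(sprintf("  mu_max %.2f d-1 | Chl:PSII %g | theta_max %.3f mg/mg\n",
              x$mu_max, x$chl_psii, x$theta_max))
  cat(sprintf("  Mn/PSII %d | Fe/PSII %d | Fe/PSI %d | PSII:PSI %g\n",
              x$mn_per_psii, x$fe_per_psii, x$fe_per_psi, x$psii_psi_ratio))
  cat(sprintf("  Q_Mn,min %.2f | Q_Fe,min %.2f | Q_Fe,opt %.2f umol/mol\n",
              x$q_mn_min, x$q_fe_min, x$q_fe_opt))
  invisible(x)
}

#' @export
print.sod_parameters <- function(x, ...) {
  cat("<sod_parameters>\n")
  cat(sprintf("  eps_p %g-%g | eps_a %g | kcat %g d-1 | reliance %g | Mn/SOD %g\n",
              x$eps_p_min, x$eps_p_max, x$eps_a, x$kcat_ros,
              x$mnsod_reliance, x$mn_per_sod))
  invisible(x)
}
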