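#' Required manganese quota
#'
#' The internal Mn concentration needed for photosynthesis and basal
#' metabolism:
#' `Q_Mn,req = Q_Mn,min + mn_per_psii * chl_c_mol / chl_psii`,
#' with `chl_c` converted from mg Chl (mg C)^-1 to mol Chl (mol C)^-1 and
#' the result expressed in umol Mn (mol C)^-1. The photosynthetic term
#' counts the 4 Mn atoms of the PSII water-oxidizing cluster per reaction
#' centre, so a larger antenna (higher Chl:PSII, fewer PSII per unit
#' chlorophyll) lowers the requirement.
#'
#' @param q_mn_min_effective Basal Mn quota, umol Mn (mol C)^-1 — the
#'   constant `q_mn_min` in the control configuration, or the MnSOD-derived
#'   maintenance quota when the SOD pathway is active.
#' @param chl_c Chl:C ratio, mg Chl (mg C)^-1.
#' @param chl_psii Antenna size, mol Chl (mol PSII)^-1 (> 0).
#' @param p A `pft_parameters` (supplies `mn_per_psii`).
#' @return Required Mn quota, umol Mn (mol C)^-1.
#' @export
#' @examples
#' p <- default_pft("diatom")
#' required_mn_quota(1, 0.0186, 1000, p)  # basal + photosynthetic term
required_mn_quota <- function(q_mn_min_effective, chl_c, chl_psii, p) {
  if (any(chl_psii <= 0)) stop("chl_psii must be positive", call. = FALSE)
  stopifnot(all(chl_c >= 0), all(q_mn_min_effective >= 0))
  q_mn_min_effective + p$mn_per_psii * chl_mass_to_mol(chl_c) / chl_psii * 1e6
}

#' Manganese use efficiency
#'
#' The rate at which carbon biomass can be produced per catalytic Mn atom:
#' `MnUE = mu / Q_Mn,req`.
#'
#' @param mu Specific growth rate, d^-1 (>= 0).
#' @param q_mn_req Required Mn quota, umol Mn (mol C)^-1 (> 0).
#' @return MnUE, mol C (umol Mn)^-1 d^-1.
#' @export
manganese_use_efficiency <- function(mu, q_mn_req) {
  if (any(q_mn_req <= 0)) stop("q_mn_req must be positive", call. = FALSE)
  stopifnot(all(mu >= 0))
  mu / q_mn_req
}

#' Maximum required manganese quota (Fe-replete growth)
#'
#' The Mn quota that would be required were Fe replete, obtained by
#' evaluating the requirement at the growth rate with the Fe constraint
#' removed: `Q_Mn,reqMAX = mu_no_fe / MnUE`. Equals `Q_Mn,req` when Fe is
#' not binding (`mu_no_fe == mu`) and exceeds it whenever Fe limitation
#' suppresses realized growth.
#'
#' @param mu_no_fe Growth rate with Fe limitation removed, d^-1.
#' @param mn_ue Manganese use efficiency, mol C (umol Mn)^-1 d^-1 (> 0).
#' @return Maximum required Mn quota, umol Mn (mol C)^-1.
#' @export
max_required_mn_quota <- function(mu_no_fe, mn_ue) {
  if (any(mn_ue <= 0)) stop("mn_ue must be positive", call. = FALSE)
  stopifnot(all(mu_no_fe >= 0))
  mu_no_fe / mn_ue
}

#' Manganese deficiency ratio
#'
#' `Q_Mn / Q_Mn,req`; a cell is Mn-deficient when the ratio falls below
#' 1.0 (insufficient resource to support growth). Ties at exactly 1.0 are
#' classified not-deficient.
#'
#' @param q_mn Mn quota, umol/mol (>= 0).
#' @param q_mn_req Required Mn quota, umol/mol (> 0).
#' @return The deficiency ratio (>= 0).
#' @export
mn_deficiency_ratio <- function(q_mn, q_mn_req) {
  if (any(q_mn_req <= 0)) stop("q_mn_req must be positive", call. = FALSE)
  stopifnot(all(q_mn >= 0))
  q_mn / q_mn_req
}

#' Potential manganese deficiency ratio
#'
#' `Q_Mn / Q_Mn,reqMAX` — Mn deficiency evaluated against the requirement
#' at Fe-replete growth. Never exceeds the actual deficiency ratio when
#' `mu_no_fe >= mu`, making it the more pessimistic metric.
#'
#' @param q_mn Mn quota, umol/mol.
#' @param q_mn_req_max Maximum required Mn quota, umol/mol (> 0).
#' @return The potential deficiency ratio (>= 0).
#' @export
potential_mn_deficiency_ratio <- function(q_mn, q_mn_req_max) {
  if (any(q_mn_req_max <= 0)) stop("q_mn_req_max must be positive", call. = FALSE)
  stopifnot(all(q_mn >= 0))
  q_mn / q_mn_req_max
}

#' Iron deficiency ratio
#'
#' The ratio of excess Fe quota to the optimum quota:
#' `(Q_Fe - Q_Fe,req) / Q_OptFe`. The optimum quota is the level at which
#' luxury uptake can occur; the cell is Fe-deficient when the ratio is
#' below 1, and the ratio is negative when the quota does not even cover
#' the requirement. This same quantity drives the electron-leakage switch
#' of the MnSOD pathway (see [electron_leakage_fraction()]).
#'
#' @param q_fe Fe quota, umol/mol.
#' @param q_fe_req Required Fe quota, umol/mol.
#' @param q_fe_opt Optimum Fe quota, umol/mol (> 0).
#' @return The deficiency ratio (may be negative).
#' @export
fe_deficiency_ratio <- function(q_fe, q_fe_req, q_fe_opt) {
  if (any(q_fe_opt <= 0)) stop("q_fe_opt must be positive", call. = FALSE)
  (q_fe - q_fe_req) / q_fe_opt
}

#' Deficiency diagnostics for one cell state
#'
#' Bundles the Mn, potential-Mn and Fe deficiency ratios and the
#' corresponding boolean flags (threshold 1.0, ties not deficient).
#'
#' @param q_mn,q_fe Quotas, umol/mol.
#' @param q_mn_req,q_mn_req_max Required and Fe-replete-required Mn quotas.
#' @param q_fe_req,q_fe_opt Required and optimum Fe quotas.
#' @return An object of class `deficiency_diagnostics` with the three
#'   ratios, `q_def_fe` (alias of `fe_deficiency` consumed by the SOD
#'   module) and `*_deficient` flags.
#' @export
deficiency_diagnostics <- function(q_mn, q_mn_req, q_mn_req_max,
                                   q_fe, q_fe_req, q_fe_opt) {
  mn_def <- mn_deficiency_ratio(q_mn, q_mn_req)
  mn_pot <- potential_mn_deficiency_ratio(q_mn, q_mn_req_max)
  fe_def <- fe_deficiency_ratio(q_fe, q_fe_req, q_fe_opt)
  structure(
    list(
      mn_deficiency = mn_def,
      mn_potential_deficiency = mn_pot,
      fe_deficiency = fe_def,
      q_def_fe = fe_def,
      mn_deficient = mn_def < 1.0,
      mn_potentially_deficient = mn_pot < 1.0,
      fe_deficient = fe_def < 1.0
    ),
    class = "deficiency_diagnostics"
  )
}
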