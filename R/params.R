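#' Transport parameters for the energy-flow network
#'
#' Bundles the free parameters of the residue-level rate model: two transport
#' coefficients scaling the structure-derived inter-residue rates, the heater
#' injection rate, the solvent cooling rate, a global quantum-correction
#' factor, and the geometric cutoffs used to detect contacts.
#'
#' Backbone rates are `k = D_B / d^2` with `d` the consecutive Calpha-Calpha
#' distance; contact rates (hydrogen bond or heater contact) are
#' `k = D_C / r^contact_exponent` with `r` the minimum relevant heavy-atom
#' distance. Defaults give backbone transfer times of ~0.25 ps per peptide
#' bond and contact transfer times of a few ps, the classical regime for
#' peptide vibrational energy flow; `k_s = 1/6` ps^-1 corresponds to the
#' ~6 ps solvent dissipation time observed experimentally.
#'
#' @param D_B backbone transport coefficient (A^2/ps).
#' @param D_C contact transport coefficient (A^2/ps).
#' @param k_h heater rate (1/ps): energy release from the photoexcited
#'   chromophore pool into its residue.
#' @param k_s cooling rate (1/ps): per-residue dissipation into the solvent.
#' @param Q dimensionless quantum-correction factor (>= 1) applied to the
#'   intramolecular channels; 1 means classical rates.
#' @param hb_cutoff donor-acceptor N...O distance cutoff (A) for hydrogen
#'   bonds.
#' @param hb_angle_min minimum N-H...O angle (degrees).
#' @param hc_cutoff heavy-atom distance cutoff (A) for heater contacts.
#' @param contact_exponent exponent `p` in `k = D_C / r^p`.
#' @return An object of class `transport_params`.
#' @export
transport_params <- function(D_B = 58, D_C = 2.5, k_h = 1, k_s = 1 / 6,
                             Q = 1, hb_cutoff = 3.5, hb_angle_min = 120,
                             hc_cutoff = 4.5, contact_exponent = 2) {
  p <- list(D_B = D_B, D_C = D_C, k_h = k_h, k_s = k_s, Q = Q,
            hb_cutoff = hb_cutoff, hb_angle_min = hb_angle_min,
            hc_cutoff = hc_cutoff, contact_exponent = contact_exponent)
  if (any(vapply(p[c("D_B", "D_C", "k_h", "k_s")], function(v) v < 0, logical(1))))
    stop("rates and transport coefficients must be >= 0")
  if (p$Q < 1) stop("quantum correction Q must be >= 1")
  if (p$hb_cutoff <= 0 || p$hc_cutoff <= 0) stop("cutoffs must be > 0")
  if (p$contact_exponent <= 0) stop("contact_exponent must be > 0")
  structure(p, class = "transport_params")
}

#' Heater specification: excitation energy and temperature jump
#'
#' Converts the chromophore excitation energy deposited by internal conversion
#' into an instantaneous temperature jump of the heater degrees of freedom,
#' `dT = E_exc / (k_B * n_dof_h)`. With the defaults (2 eV over 39 degrees of
#' freedom) the jump is ~595 K, i.e. a ~600 K heater jump on a 300 K baseline.
#'
#' @param E_exc excitation energy (eV).
#' @param n_dof_h number of heater degrees of freedom sharing the energy.
#' @param T_0 baseline temperature (K).
#' @return An object of class `heater_spec` with fields `E_exc`, `n_dof_h`,
#'   `T_0` and the derived `delta_T` (K).
#' @export
heater_spec <- function(E_exc = 2, n_dof_h = 39, T_0 = 300) {
  k_B_eV <- 8.617333262e-5  # Boltzmann constant, eV/K
  dT <- E_exc / (k_B_eV * n_dof_h)
  if (!is.finite(dT) || dT <= 0) stop("delta_T must be > 0")
  structure(list(E_exc = E_exc, n_dof_h = n_dof_h, T_0 = T_0, delta_T = dT),
            class = "heater_spec")
}
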