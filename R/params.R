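#' Physical parameters of the transport system
#'
#' Container for the physical constants of the biophysical model. Defaults
#' are the potato parameterization used throughout the package. Units follow
#' the internal convention: g, m, s, MPa, mol; concentrations in mol/m^3.
#'
#' @param rho_water density of water (g/m^3).
#' @param L_r radial hydraulic membrane permeability (m MPa^-1 s^-1).
#' @param mu_x dynamic viscosity of water / xylem sap (MPa s).
#' @param a_Ph phloem sieve element radius (m).
#' @param a_X xylem conduit radius (m).
#' @param k_p axial phloem permeability (m^2).
#' @param eps_p phloem elastic modulus (MPa).
#' @param eps_x xylem elastic modulus (MPa).
#' @param J_trans transpiration rate of the mature source leaves (g/s).
#' @param psi_soil soil water potential (MPa, non-positive in practice).
#' @param temperature temperature (K) used to form `RT`. Not part of the
#'   published parameter table; 293.15 K is an assumption of this package.
#' @param RT gas constant times temperature (MPa m^3 / mol).
#' @param V_suc sucrose partial molar volume (m^3/mol), used in the
#'   volume-fraction viscosity law. Default 2.157e-4 (342.3 g/mol at
#'   1587 kg/m^3); an assumption, not a published value.
#' @param r_vkr_ref reference lumped pathway resistance of the standard
#'   0.25 m pathway in the VKR model (mol s m^-6). Used to calibrate the
#'   number of parallel sieve tubes, see Details.
#' @param pathway_ref_length pathway length (m) to which `r_vkr_ref` refers.
#' @param N_Ph number of parallel phloem sieve tubes. If `NULL` (default) it
#'   is derived by the calibration in Details.
#' @param N_X number of parallel xylem conduits; defaults to `N_Ph`.
#' @param k_x axial xylem permeability (m^2); defaults to the
#'   Hagen--Poiseuille value `a_X^2 / 8`.
#'
#' @details
#' `N_Ph` is not a published number. It is fixed by the requirement that the
#' spatially explicit pathway and the lumped VKR pathway have equal
#' resistance at zero sucrose: the axial resistance of the standard
#' 0.25 m pathway at water viscosity,
#' \eqn{r = \mu_X L / (k_p N_{Ph} \pi a_{Ph}^2)} (MPa s/m^3), divided by
#' \eqn{RT} (which converts a pressure-per-volumetric-flow resistance into
#' the concentration-flux resistance of the lumped model, mol s m^-6), must
#' equal the VKR resistance at 0 mM sucrose,
#' \code{vkr_resistance(0, r_vkr_ref)} \eqn{= 0.3396\, r_{ref}}. With the
#' default constants this gives \eqn{N_{Ph} \approx 47.6}; it is an
#' effective (non-integer) conduit count.
#'
#' @return An object of class `plant_parameters` (a named list).
#' @examples
#' p <- plant_parameters()
#' p$N_Ph
#' @export
plant_parameters <- function(rho_water = 0.998e6,
                             L_r = 5e-8,
                             mu_x = 1.0019e-9,
                             a_Ph = 8.4e-6,
                             a_X = 30e-6,
                             k_p = 3.82e-12,
                             eps_p = 30,
                             eps_x = 750,
                             J_trans = 0.02,
                             psi_soil = 0,
                             temperature = 293.15,
                             RT = 8.314462618e-6 * temperature,
                             V_suc = 2.157e-4,
                             r_vkr_ref = 7.5e12,
                             pathway_ref_length = 0.25,
                             N_Ph = NULL,
                             N_X = NULL,
                             k_x = a_X^2 / 8) {
  if (is.null(N_Ph)) {
    r0_single <- mu_x * pathway_ref_length / (k_p * pi * a_Ph^2)
    N_Ph <- r0_single / (RT * vkr_resistance(0, r_vkr_ref, warn = FALSE))
  }
  if (is.null(N_X)) N_X <- N_Ph
  p <- list(rho_water = rho_water, L_r = L_r, mu_x = mu_x, a_Ph = a_Ph,
            a_X = a_X, k_p = k_p, eps_p = eps_p, eps_x = eps_x,
            J_trans = J_trans, psi_soil = psi_soil,
            temperature = temperature, RT = RT, V_suc = V_suc,
            r_vkr_ref = r_vkr_ref, pathway_ref_length = pathway_ref_length,
            N_Ph = N_Ph, N_X = N_X, k_x = k_x)
  must_pos <- setdiff(names(p), "psi_soil")
  bad <- must_pos[!vapply(p[must_pos], function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x > 0, logical(1))]
  if (length(bad)) stop("plant_parameters: non-positive or non-scalar value for: ", paste(bad, collapse = ", "))
  if (!is.numeric(psi_soil) || length(psi_soil) != 1 || !is.finite(psi_soil))
    stop("plant_parameters: psi_soil must be a finite scalar")
  structure(p, class = "plant_parameters")
}

#' @export
print.plant_parameters <- function(x, ...) {
  cat("Plant transport parameters (g, m, s, MPa, mol):\n")
  for (nm in names(x)) cat(sprintf("  %-18s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Axial phloem resistance of a pathway segment
#'
#' Resistance of a sieve-tube bundle of length `L` at viscosity `mu`,
#' \eqn{r = \mu L / (k_p N_{Ph} \pi a_{Ph}^2)}, in MPa s per m^3/s of
#' volumetric flow.
#'
#' @param L segment length (m).
#' @param mu sap dynamic viscosity (MPa s).
#' @param params a [plant_parameters] object.
#' @param N_Ph number of parallel conduits; default taken from `params`.
#' @return resistance (MPa s / m^3).
#' @examples
#' phloem_axial_resistance(0.25, plant_parameters()$mu_x, plant_parameters(), N_Ph = 1)
#' @export
phloem_axial_resistance <- function(L, mu, params = plant_parameters(), N_Ph = params$N_Ph) {
  mu * L / (params$k_p * N_Ph * pi * params$a_Ph^2)
}
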