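## SWEET/SUT radial sucrose exchange: public per-element operations and the
## net efflux diagnostic. The vectorized forms used inside the ODE live in
## munch.R (.radial_sucrose_terms).

#' SWEET-mediated sucrose efflux rate of one element
#'
#' \eqn{f_{SP6A} \cdot v_{max} V_{elem} \, c/(K_m + c)}: gradient-driven
#' sucrose export from the phloem into the apoplast, scaled by the SP6A
#' mitigation factor.
#'
#' @param c_phloem phloem sucrose concentration (mol/m^3).
#' @param kinetics a [transporter_kinetics] (volumetric units).
#' @param sp6a_factor SWEET capacity scaling in (0, 1]; 0.6 reproduces the
#'   reported 40% reduction by SP6A.
#' @param element_volume phloem volume of the element (m^3).
#' @return efflux rate (mol/s).
#' @examples
#' sweet_efflux_rate(70, transporter_kinetics(0.148, 70), 1, 1e-9)  # half-max
#' @export
sweet_efflux_rate <- function(c_phloem, kinetics = transporter_kinetics(0.148, 70),
                              sp6a_factor = 1, element_volume = 1) {
  stopifnot(all(c_phloem >= 0))
  sp6a_factor * kinetics$v_max * element_volume * c_phloem / (kinetics$K_m + c_phloem)
}

#' Combined SWEET + SUT retrieval rate of one element
#'
#' Sum of the SWEET retrieval and SUT retrieval Michaelis--Menten terms on
#' the apoplast concentration, times the element volume. The SWEET term is
#' scaled by the SP6A factor only when the configuration says SP6A affects
#' retrieval-side SWEET activity too (the default, since SP6A binds the
#' transporter itself).
#'
#' @param c_apoplast apoplast sucrose concentration (mol/m^3).
#' @param config a [radial_sucrose_config].
#' @param element_volume phloem volume of the element (m^3).
#' @return retrieval rate (mol/s), positive into the phloem.
#' @export
retrieval_rate <- function(c_apoplast, config = radial_sucrose_config(),
                           element_volume = 1) {
  stopifnot(all(c_apoplast >= 0))
  f_ret <- if (config$sp6a_scales_retrieval) config$sp6a_factor else 1
  (f_ret * config$sweet_retrieval$v_max *
     c_apoplast / (config$sweet_retrieval$K_m + c_apoplast) +
     config$sut_retrieval$v_max *
     c_apoplast / (config$sut_retrieval$K_m + c_apoplast)) * element_volume
}

#' Apoplast pool derivative of one element
#'
#' \eqn{dS_{apo}/dt = \mathrm{efflux} - \mathrm{retrieval} - k_{rm}
#' c_{apo} V_{elem}}: removal (uptake by the tissues surrounding the
#' phloem) is first-order in the apoplast concentration, scaled by the
#' element volume, so the steady state does not depend on the apoplast
#' volume fraction (which only sets the transient time scale of the pool).
#' The equal-and-opposite net term `retrieval - efflux` enters the phloem
#' sucrose balance.
#'
#' @param c_phloem phloem concentration of the element (mol/m^3).
#' @param S_apo apoplast sucrose content (mol).
#' @param config a [radial_sucrose_config].
#' @param element_volume phloem volume of the element (m^3).
#' @return list with `dS_apo` (mol/s) and the `efflux`, `retrieval`,
#'   `removal` components.
#' @export
apoplast_derivative <- function(c_phloem, S_apo, config = radial_sucrose_config(),
                                element_volume = 1) {
  c_apo <- S_apo / (config$apoplast_volume_fraction * element_volume)
  efflux <- sweet_efflux_rate(c_phloem, config$sweet_efflux, config$sp6a_factor,
                              element_volume)
  retrieval <- retrieval_rate(c_apo, config, element_volume)
  removal <- config$apoplast_removal_rate * c_apo * element_volume
  list(dS_apo = efflux - retrieval - removal,
       efflux = efflux, retrieval = retrieval, removal = removal)
}

#' Fraction of loaded sucrose lost by net radial efflux
#'
#' \eqn{(v_0 - v_1 - v_2)/v_0}: the share of the loading rate permanently
#' removed from the transport system via the apoplast at steady state.
#'
#' @param result a converged [integrate_to_steady_state] result.
#' @return dimensionless fraction in `[0, 1]`; 0 when radial sucrose
#'   exchange is disabled; `NA` (with a warning) when `v0 = 0`.
#' @export
net_efflux_fraction <- function(result) {
  stopifnot(inherits(result, "steady_state_result"))
  f <- result$fluxes
  if (f$v0 == 0) {
    warning("net_efflux_fraction undefined for v0 = 0")
    return(NA_real_)
  }
  (f$v0 - f$v1 - ifelse(is.na(f$v2), 0, f$v2)) / f$v0
}
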