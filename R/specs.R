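## Scenario building blocks: sinks, source, radial sucrose exchange, mesh
## specification and the full scenario configuration.

#' Sink water boundary conditions
#'
#' Three closure rules for the water exchanged by a sink with its
#' environment (used only in xylem-coupled mode):
#' \describe{
#'   \item{`wb_imposed_flux(q)`}{a fixed volumetric water flux `q` (m^3/s)
#'     on the sink xylem; positive = uptake, negative = evaporation.}
#'   \item{`wb_soil_coupled(permeability_factor, uptake_area)`}{water uptake
#'     from soil at potential `psi_soil` through an effective root membrane
#'     of area `uptake_area` (m^2) and permeability
#'     `permeability_factor * L_r`; a tuber is represented by reducing the
#'     permeability factor (e.g. 0.1 for a 90% reduction).}
#'   \item{`wb_evaporating(fraction)`}{fixed water extraction equal to
#'     `fraction` of the mature-leaf transpiration rate `J_trans` (a young
#'     sink leaf evaporates about 10%).}
#' }
#'
#' The effective root membrane area is not a published value; the default
#' 0.8 m^2 gives root water uptake of the order 2e-8 m^3/s at xylem
#' tensions of a few tenths of MPa, matching the transpiration demand.
#'
#' @param q imposed volumetric flux (m^3/s), positive for uptake.
#' @param permeability_factor dimensionless factor in (0, 1].
#' @param uptake_area effective root membrane area (m^2).
#' @param fraction evaporation as a fraction of `J_trans`, in (0, 1].
#' @return a `water_boundary` list.
#' @name water_boundary
NULL

#' @rdname water_boundary
#' @export
wb_imposed_flux <- function(q) {
  stopifnot(is.numeric(q), length(q) == 1, is.finite(q))
  structure(list(type = "imposed_flux", q = q), class = "water_boundary")
}

#' @rdname water_boundary
#' @export
wb_soil_coupled <- function(permeability_factor = 1, uptake_area = 0.8) {
  stopifnot(permeability_factor > 0, permeability_factor <= 1, uptake_area > 0)
  structure(list(type = "soil_coupled", permeability_factor = permeability_factor,
                 uptake_area = uptake_area), class = "water_boundary")
}

#' @rdname water_boundary
#' @export
wb_evaporating <- function(fraction = 0.1) {
  stopifnot(fraction > 0, fraction <= 1)
  structure(list(type = "evaporating", fraction = fraction), class = "water_boundary")
}

#' Per-sink unloading kinetics, pathway length and water boundary
#'
#' @param v_max maximal Michaelis--Menten unloading rate (mol/s). The
#'   standard sink strength is 12.5 nmol/s.
#' @param K_m unloading half-saturation concentration (mol/m^3, i.e. mM);
#'   standard affinity 75 mM.
#' @param pathway_length source-junction-to-sink distance (m).
#' @param water_boundary a [water_boundary] object.
#' @param r_ref lumped VKR reference resistance of this pathway
#'   (mol s m^-6). Defaults to the standard 7.5e12 scaled linearly with
#'   `pathway_length / 0.25`, mirroring the proportionality of resistance
#'   and length in the biophysical model.
#' @return an object of class `sink_spec`.
#' @export
sink_spec <- function(v_max = 12.5e-9, K_m = 75, pathway_length = 0.25,
                      water_boundary = wb_soil_coupled(1),
                      r_ref = 7.5e12 * pathway_length / 0.25) {
  stopifnot(inherits(water_boundary, "water_boundary"))
  if (!is.numeric(v_max) || v_max <= 0) stop("sink_spec: v_max must be > 0")
  if (!is.numeric(K_m) || K_m <= 0) stop("sink_spec: K_m must be > 0")
  if (!is.numeric(pathway_length) || pathway_length <= 0)
    stop("sink_spec: pathway_length must be > 0")
  structure(list(v_max = v_max, K_m = K_m, pathway_length = pathway_length,
                 water_boundary = water_boundary, r_ref = r_ref),
            class = "sink_spec")
}

#' Source loading specification
#'
#' @param v0 total sucrose loading rate (mol/s), distributed uniformly over
#'   the source-zone elements.
#' @param evaporation_mode water closure of the source zone in xylem-coupled
#'   mode: `"fixed"` extracts the transpiration rate `J_trans`;
#'   `"balance_sinks"` extracts the instantaneous net sum of the water flows
#'   at both sink boundaries (used with imposed sink fluxes).
#' @return an object of class `source_spec`.
#' @export
source_spec <- function(v0 = 12.5e-9, evaporation_mode = c("fixed", "balance_sinks")) {
  if (!is.numeric(v0) || v0 < 0) stop("source_spec: v0 must be >= 0")
  structure(list(v0 = v0, evaporation_mode = match.arg(evaporation_mode)),
            class = "source_spec")
}

#' Transporter kinetics (volumetric Michaelis--Menten)
#'
#' @param v_max maximal volumetric rate (mol m^-3 s^-1).
#' @param K_m half-saturation concentration (mol/m^3).
#' @return an object of class `transporter_kinetics`.
#' @export
transporter_kinetics <- function(v_max, K_m) {
  stopifnot(v_max > 0, K_m > 0)
  structure(list(v_max = v_max, K_m = K_m), class = "transporter_kinetics")
}

## Apoplast removal rate (s^-1, first-order in apoplast concentration per
## element volume): free parameter of the apoplast pool, calibrated once so
## that the maximum net efflux fraction over the 0.025-25 nmol/s loading
## scan in the leaf / root-tuber efflux scenario is about 23% of the
## loading rate, then frozen (see the methods vignette).
.k_removal_default <- 0.089

#' Radial sucrose exchange configuration (SWEET/SUT and apoplast pool)
#'
#' Bidirectional SWEET transporters mediate gradient-driven sucrose efflux
#' from the phloem into the apoplast and, together with proton-coupled SUT
#' importers, retrieval back into the phloem. Each element of the exchange
#' zones carries an explicit apoplast pool with first-order sucrose removal
#' (uptake by surrounding tissues). The phloem-mobile tuberization signal
#' SP6A binds SWEETs and reduces their transport capacity; `sp6a_factor`
#' scales the SWEET `v_max` (0.6 reproduces the reported 40% reduction).
#'
#' @param sweet_efflux,sweet_retrieval,sut_retrieval [transporter_kinetics];
#'   defaults (0.148, 70), (0.148, 10) and (0.117, 1) mol m^-3 s^-1 / mM.
#' @param apoplast_volume_fraction apoplast volume as a fraction of the
#'   phloem element volume (affects transients only, not steady states).
#' @param apoplast_removal_rate removal rate from the apoplast (s^-1),
#'   first-order in the apoplast concentration scaled by the element
#'   volume; the default is the calibrated value frozen in the package.
#' @param sp6a_factor multiplicative SWEET `v_max` scaling in (0, 1].
#' @param sp6a_scales_retrieval should SP6A also scale the SWEET retrieval
#'   term (default TRUE: SP6A binds the transporter itself); set FALSE for
#'   an efflux-only variant.
#' @param zones mesh zones that exchange sucrose with the apoplast; default
#'   the two long-distance pathways.
#' @return an object of class `radial_sucrose_config`.
#' @export
radial_sucrose_config <- function(sweet_efflux = transporter_kinetics(0.148, 70),
                                  sweet_retrieval = transporter_kinetics(0.148, 10),
                                  sut_retrieval = transporter_kinetics(0.117, 1),
                                  apoplast_volume_fraction = 0.05,
                                  apoplast_removal_rate = .k_removal_default,
                                  sp6a_factor = 1,
                                  sp6a_scales_retrieval = TRUE,
                                  zones = c("pathway_1", "pathway_2")) {
  stopifnot(inherits(sweet_efflux, "transporter_kinetics"),
            inherits(sweet_retrieval, "transporter_kinetics"),
            inherits(sut_retrieval, "transporter_kinetics"),
            apoplast_volume_fraction > 0, apoplast_removal_rate >= 0,
            sp6a_factor > 0, sp6a_factor <= 1)
  structure(list(sweet_efflux = sweet_efflux, sweet_retrieval = sweet_retrieval,
                 sut_retrieval = sut_retrieval,
                 apoplast_volume_fraction = apoplast_volume_fraction,
                 apoplast_removal_rate = apoplast_removal_rate,
                 sp6a_factor = sp6a_factor,
                 sp6a_scales_retrieval = sp6a_scales_retrieval,
                 zones = zones),
            class = "radial_sucrose_config")
}

#' Mesh specification (per-zone element counts and lengths)
#'
#' Default: 20 loading elements of 0.005 m, 30 long-distance pathway
#' elements per branch (length set by each sink's `pathway_length`), and 20
#' unloading elements of 0.005 m per sink.
#'
#' @param n_source,n_pathway,n_sink element counts per zone (>= 1).
#' @param source_element_length,sink_element_length element lengths (m).
#' @param shared_pathway_length optional length (m) of a shared pathway
#'   between the loading zone and the branching point (default 0: the
#'   junction is a zero-length, zero-resistance node).
#' @param n_shared element count of the shared pathway when present.
#' @return an object of class `mesh_spec`.
#' @export
mesh_spec <- function(n_source = 20, source_element_length = 0.005,
                      n_pathway = 30, n_sink = 20, sink_element_length = 0.005,
                      shared_pathway_length = 0, n_shared = 5) {
  stopifnot(n_source >= 1, n_pathway >= 1, n_sink >= 1,
            source_element_length > 0, sink_element_length > 0,
            shared_pathway_length >= 0, n_shared >= 1)
  structure(list(n_source = as.integer(n_source),
                 source_element_length = source_element_length,
                 n_pathway = as.integer(n_pathway),
                 n_sink = as.integer(n_sink),
                 sink_element_length = sink_element_length,
                 shared_pathway_length = shared_pathway_length,
                 n_shared = as.integer(n_shared)),
            class = "mesh_spec")
}

#' Full scenario configuration
#'
#' Bundles physical parameters, source and sink specifications, mesh layout,
#' the hydraulic mode and (optionally) radial sucrose exchange into a single
#' validated object consumed by the solvers and scenario drivers.
#'
#' @param parameters a [plant_parameters] object.
#' @param source a [source_spec].
#' @param sinks list of one or two [sink_spec] objects (two for the
#'   partitioning scenarios, one for single-sink gradient studies).
#' @param mesh a [mesh_spec].
#' @param hydraulic_mode `"phloem_only"` (radial water exchange with a
#'   reservoir at zero potential) or `"xylem_coupled"` (explicit
#'   cohesion-tension xylem).
#' @param radial_sucrose a [radial_sucrose_config] or `NULL` (disabled).
#' @param out_of_validity policy for the VKR viscosity polynomial outside
#'   its 0--1.5 M validity range (see [vkr_resistance]).
#' @param name scenario label carried into result tables and manifests.
#' @return an object of class `scenario_config`.
#' @export
scenario_config <- function(parameters = plant_parameters(),
                            source = source_spec(),
                            sinks = list(sink_spec(), sink_spec()),
                            mesh = mesh_spec(),
                            hydraulic_mode = c("phloem_only", "xylem_coupled"),
                            radial_sucrose = NULL,
                            out_of_validity = c("evaluate", "clamp"),
                            name = "custom") {
  hydraulic_mode <- match.arg(hydraulic_mode)
  out_of_validity <- match.arg(out_of_validity)
  if (inherits(sinks, "sink_spec")) sinks <- list(sinks)
  stopifnot(inherits(parameters, "plant_parameters"),
            inherits(source, "source_spec"), inherits(mesh, "mesh_spec"),
            is.list(sinks), all(vapply(sinks, inherits, logical(1), "sink_spec")))
  if (!length(sinks) %in% c(1L, 2L))
    stop("scenario_config: need one or two sinks, got ", length(sinks))
  if (!is.null(radial_sucrose) && !inherits(radial_sucrose, "radial_sucrose_config"))
    stop("scenario_config: radial_sucrose must be NULL or a radial_sucrose_config")
  structure(list(name = name, parameters = parameters, source = source,
                 sinks = sinks, mesh = mesh, hydraulic_mode = hydraulic_mode,
                 radial_sucrose = radial_sucrose,
                 out_of_validity = out_of_validity),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("Scenario '%s': %d sink(s), %s mode, radial sucrose %s\n",
              x$name, length(x$sinks), x$hydraulic_mode,
              if (is.null(x$radial_sucrose)) "off"
              else sprintf("on (sp6a_factor = %g)", x$radial_sucrose$sp6a_factor)))
  cat(sprintf("  loading v0 = %g nmol/s; sinks:\n", x$source$v0 * 1e9))
  for (i in seq_along(x$sinks)) {
    s <- x$sinks[[i]]
    cat(sprintf("   %d: v_max %g nmol/s, K_m %g mM, L %g m, water %s\n",
                i, s$v_max * 1e9, s$K_m, s$pathway_length, s$water_boundary$type))
  }
  invisible(x)
}

#' Validate a scenario configuration
#'
#' Returns diagnostics instead of throwing: each row has a `level`
#' (`"error"`, `"warning"` or `"note"`) and a message. Presets validate to
#' an empty table.
#'
#' @param config a [scenario_config].
#' @return data.frame with columns `level` and `message` (zero rows when
#'   nothing is flagged).
#' @export
validate_config <- function(config) {
  out <- list()
  add <- function(level, msg) out[[length(out) + 1]] <<- data.frame(level = level, message = msg)
  if (!inherits(config, "scenario_config")) {
    add("error", "not a scenario_config object")
  } else {
    vmax_tot <- sum(vapply(config$sinks, `[[`, numeric(1), "v_max"))
    if (config$source$v0 >= vmax_tot)
      add("warning", sprintf("no steady state: v0 (%g mol/s) >= total sink capacity (%g mol/s)",
                             config$source$v0, vmax_tot))
    for (i in seq_along(config$sinks)) {
      s <- config$sinks[[i]]
      if (s$K_m <= 0) add("error", sprintf("sink %d: K_m must be positive", i))
      if (s$v_max <= 0) add("error", sprintf("sink %d: v_max must be positive", i))
      if (s$pathway_length <= 0) add("error", sprintf("sink %d: pathway_length must be positive", i))
    }
    if (config$hydraulic_mode == "xylem_coupled") {
      types <- vapply(config$sinks, function(s) s$water_boundary$type, character(1))
      if (all(types == "imposed_flux") && config$source$evaporation_mode == "fixed") {
        net <- sum(vapply(config$sinks, function(s) s$water_boundary$q, numeric(1))) -
          config$parameters$J_trans / config$parameters$rho_water
        if (abs(net) > 1e-12 * max(config$parameters$J_trans / config$parameters$rho_water, 1e-30))
          add("error", "water closure violated: imposed sink fluxes do not balance fixed source transpiration; use evaporation_mode = 'balance_sinks'")
      }
    }
    if (length(config$sinks) == 1L)
      add("note", "single-sink configuration: partitioning outputs are undefined")
  }
  if (!length(out)) data.frame(level = character(0), message = character(0))
  else do.call(rbind, out)
}
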