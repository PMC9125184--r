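## Preset scenario catalogue. The printed scenario values live in the YAML
## files under inst/extdata/presets/, one per scenario name; this module
## only locates and loads them.

.preset_dir <- function() system.file("extdata", "presets", package = "munchflow")

#' List available preset scenarios
#' @return character vector of preset names.
#' @export
list_presets <- function() {
  sort(tools::file_path_sans_ext(list.files(.preset_dir(), pattern = "\\.yaml$")))
}

#' Load a preset scenario configuration
#'
#' The catalogue covers the in-silico experiments of the package:
#' \describe{
#'   \item{`vmax`}{sink-strength scenario: v_max 22.5 vs 2.5 nmol/s, equal
#'     affinity (75 mM) and pathways (0.25 m / 7.5e12 mol s m^-6).}
#'   \item{`km`}{sink-affinity scenario: K_m 75 vs 750 mM, equal v_max
#'     12.5 nmol/s.}
#'   \item{`resistance`}{pathway-resistance scenario: lengths 0.25 vs 5 m,
#'     lumped references 7.5e12 vs 1.5e14 mol s m^-6 (clamped viscosity
#'     polynomial, see [vkr_resistance]).}
#'   \item{`xylem_sweep`}{imposed xylem water boundaries: sink 2 uptake
#'     2e-8 m^3/s, sink 1 to be swept over [-1e-8, 2e-8] m^3/s, source
#'     evaporation balancing the sinks.}
#'   \item{`root_root`, `tuber_root`, `leaf_root`}{organ scenarios at soil
#'     water potential 0 MPa: roots take up water (permeability factor 1),
#'     tubers at 10% uptake permeability, young leaves evaporate 10% of the
#'     mature-leaf transpiration.}
#'   \item{`efflux_factorial`}{young leaf (0.1 m, evaporating) vs root/tuber
#'     (0.3 m, soil-coupled), equal baseline kinetics v_max 5 nmol/s / K_m
#'     75 mM, SWEET/SUT radial sucrose exchange along both pathways.}
#'   \item{`sp6a`}{as `efflux_factorial` with SWEET capacity reduced to 60%
#'     (SP6A-mediated efflux mitigation).}
#'   \item{`single_sink`}{one source, one 0.25 m pathway, one sink
#'     (v_max 25 nmol/s) for gradient studies.}
#' }
#'
#' @param name preset name, see [list_presets].
#' @return a [scenario_config].
#' @examples
#' preset_scenario("vmax")
#' @export
preset_scenario <- function(name) {
  path <- file.path(.preset_dir(), paste0(name, ".yaml"))
  if (!file.exists(path))
    stop("unknown preset '", name, "'; available: ",
         paste(list_presets(), collapse = ", "))
  load_config(path, quiet = TRUE)
}
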