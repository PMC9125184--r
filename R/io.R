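## Configuration files (YAML), result serialization and run manifests.

.cfg_schema_env <- new.env(parent = emptyenv())
.cfg_schema <- function() {
  if (is.null(.cfg_schema_env$schema)) {
    .cfg_schema_env$schema <- list(
      top = c("name", "parameters", "source", "sinks", "mesh", "hydraulic_mode",
              "radial_sucrose", "out_of_validity"),
      parameters = names(formals(plant_parameters)),
      source = c("v0", "evaporation_mode"),
      sink = c("v_max", "K_m", "pathway_length", "r_ref", "water_boundary"),
      water_boundary = c("type", "q", "permeability_factor", "uptake_area", "fraction"),
      mesh = names(formals(mesh_spec)),
      radial = c("sweet_efflux", "sweet_retrieval", "sut_retrieval",
                 "apoplast_volume_fraction", "apoplast_removal_rate",
                 "sp6a_factor", "sp6a_scales_retrieval", "zones"),
      kinetics = c("v_max", "K_m"))
  }
  .cfg_schema_env$schema
}

.check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop(sprintf("config schema violation in '%s': unknown key(s) %s",
                 where, paste(bad, collapse = ", ")), call. = FALSE)
}

.build_wb <- function(x, where) {
  if (is.null(x)) return(wb_soil_coupled(1))
  .check_keys(x, .cfg_schema()$water_boundary, where)
  switch(x$type,
         imposed_flux = wb_imposed_flux(x$q),
         soil_coupled = do.call(wb_soil_coupled, x[setdiff(names(x), "type")]),
         evaporating = wb_evaporating(x$fraction),
         stop("unknown water_boundary type '", x$type, "' in ", where, call. = FALSE))
}

.build_kin <- function(x, default, where) {
  if (is.null(x)) return(default)
  .check_keys(x, .cfg_schema()$kinetics, where)
  transporter_kinetics(x$v_max %||% default$v_max, x$K_m %||% default$K_m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a scenario configuration from a YAML file
#'
#' Reads a hierarchical key-value file whose schema mirrors
#' [scenario_config] field names exactly (all quantities in the internal
#' g/m/s/MPa/mol unit system). Missing fields are filled from the standard
#' defaults (a notice is logged for absent sink kinetics); unknown keys are
#' rejected.
#'
#' @param path path to the YAML file.
#' @param quiet suppress default-filling notices.
#' @return a [scenario_config].
#' @export
load_config <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  .check_keys(raw, .cfg_schema()$top, "top level")
  .check_keys(raw$parameters %||% list(), .cfg_schema()$parameters, "parameters")
  params <- do.call(plant_parameters, raw$parameters %||% list())
  .check_keys(raw$source %||% list(), .cfg_schema()$source, "source")
  src <- do.call(source_spec, raw$source %||% list())
  if (is.null(raw$sinks)) stop("config must define at least one sink")
  sinks <- lapply(seq_along(raw$sinks), function(i) {
    s <- raw$sinks[[i]]
    where <- paste0("sinks[", i, "]")
    .check_keys(s, .cfg_schema()$sink, where)
    if (is.null(s$v_max) && !quiet)
      message(sprintf("%s: v_max missing, using the standard sink strength 12.5 nmol/s", where))
    args <- s[setdiff(names(s), "water_boundary")]
    args$water_boundary <- .build_wb(s$water_boundary, paste0(where, "$water_boundary"))
    do.call(sink_spec, args)
  })
  .check_keys(raw$mesh %||% list(), .cfg_schema()$mesh, "mesh")
  mesh <- do.call(mesh_spec, raw$mesh %||% list())
  rs <- NULL
  if (!is.null(raw$radial_sucrose)) {
    r <- raw$radial_sucrose
    .check_keys(r, .cfg_schema()$radial, "radial_sucrose")
    dflt <- radial_sucrose_config()
    rs <- radial_sucrose_config(
      sweet_efflux = .build_kin(r$sweet_efflux, dflt$sweet_efflux, "sweet_efflux"),
      sweet_retrieval = .build_kin(r$sweet_retrieval, dflt$sweet_retrieval, "sweet_retrieval"),
      sut_retrieval = .build_kin(r$sut_retrieval, dflt$sut_retrieval, "sut_retrieval"),
      apoplast_volume_fraction = r$apoplast_volume_fraction %||% dflt$apoplast_volume_fraction,
      apoplast_removal_rate = r$apoplast_removal_rate %||% dflt$apoplast_removal_rate,
      sp6a_factor = r$sp6a_factor %||% dflt$sp6a_factor,
      sp6a_scales_retrieval = r$sp6a_scales_retrieval %||% dflt$sp6a_scales_retrieval,
      zones = unlist(r$zones) %||% dflt$zones)
  }
  scenario_config(parameters = params, source = src, sinks = sinks, mesh = mesh,
                  hydraulic_mode = raw$hydraulic_mode %||% "phloem_only",
                  radial_sucrose = rs,
                  out_of_validity = raw$out_of_validity %||% "evaluate",
                  name = raw$name %||% tools::file_path_sans_ext(basename(path)))
}

.unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), .unclass_deep) else x
}

#' Save a scenario configuration to a YAML file
#'
#' Inverse of [load_config]; numeric fields are written with 15 significant
#' digits so configurations round-trip without loss.
#'
#' @param config a [scenario_config].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  out <- list(name = config$name,
              hydraulic_mode = config$hydraulic_mode,
              out_of_validity = config$out_of_validity,
              parameters = .unclass_deep(config$parameters),
              source = .unclass_deep(config$source),
              sinks = .unclass_deep(config$sinks),
              mesh = .unclass_deep(config$mesh))
  if (!is.null(config$radial_sucrose))
    out$radial_sucrose <- .unclass_deep(config$radial_sucrose)
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Run manifest
#'
#' Provenance record attached to result files: configuration snapshot and
#' hash, package version and solver settings.
#'
#' @param config a [scenario_config].
#' @param solver named list of solver settings.
#' @param convergence named list of convergence summaries.
#' @return a list of class `run_manifest`.
#' @export
run_manifest <- function(config, solver = list(), convergence = list()) {
  tf <- tempfile()
  writeLines(deparse(.unclass_deep(config)), tf)
  h <- unname(tools::md5sum(tf))
  unlink(tf)
  structure(list(scenario = config$name,
                 package = "munchflow",
                 version = as.character(utils::packageVersion("munchflow")),
                 config_hash = h,
                 solver = solver,
                 convergence = convergence,
                 config = .unclass_deep(config)),
            class = "run_manifest")
}

#' Write result tables and their manifest
#'
#' Writes each table as `<scenario>_<table-name>.csv` (RFC-4180 style,
#' numeric fields at full precision) plus `<scenario>_manifest.json`.
#' Output is deterministic: rerunning with an identical configuration
#' yields byte-identical files.
#'
#' @param tables named list of data.frames.
#' @param manifest a [run_manifest].
#' @param out_dir output directory (created if needed).
#' @return character vector of the files written, invisibly.
#' @export
write_results <- function(tables, manifest, out_dir) {
  stopifnot(is.list(tables), !is.null(names(tables)), inherits(manifest, "run_manifest"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  old <- options(digits = 15); on.exit(options(old))
  files <- character(0)
  for (nm in names(tables)) {
    f <- file.path(out_dir, paste0(manifest$scenario, "_", nm, ".csv"))
    write.csv(format(tables[[nm]], digits = 15, trim = TRUE, scientific = NA),
              f, row.names = FALSE, quote = FALSE)
    files <- c(files, f)
  }
  mf <- file.path(out_dir, paste0(manifest$scenario, "_manifest.json"))
  jsonlite::write_json(unclass(manifest), mf, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(files, mf))
}
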