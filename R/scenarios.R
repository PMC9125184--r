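## Scenario drivers: loading-rate scans, model comparison, xylem sweep,
## organ triad, efflux/SP6A factorial and the step-response transient.

#' Logarithmically spaced loading-rate grid
#'
#' @param n number of points.
#' @param range loading-rate range (mol/s); default the standard scan range
#'   0.025--25 nmol/s.
#' @return numeric vector (mol/s), strictly increasing.
#' @export
loading_grid <- function(n = 40, range = c(0.025e-9, 25e-9)) {
  exp(seq(log(range[1]), log(range[2]), length.out = n))
}

## Integrate a sequence of loading rates with warm starts; returns a list of
## steady_state_result (or condition objects for failed rows).
.scan_steady <- function(config, v0_grid, warm_start = TRUE, ...) {
  out <- vector("list", length(v0_grid))
  init <- NULL
  for (k in seq_along(v0_grid)) {
    res <- tryCatch(integrate_to_steady_state(config, v0 = v0_grid[k], init = init, ...),
                    error = function(e) e)
    out[[k]] <- res
    if (warm_start && inherits(res, "steady_state_result") && res$converged)
      init <- res$state
    else init <- NULL
  }
  out
}

.with_v0 <- function(config, v0) { config$source$v0 <- v0; config }

.pc_or_na <- function(res) if (inherits(res, "steady_state_result")) res$PC1 else NA_real_

#' Single-sink concentration gradients and mean-pathway summaries
#'
#' Solves steady states of the single-sink configuration for pairs of
#' loading and maximal unloading rates and summarizes the pathway sucrose
#' gradient in both the spatially resolved and the linear-gradient
#' (lumped-model) sense, exposing the systematic underestimation of mean
#' concentration and resistance by the linear assumption.
#'
#' @param pairs data.frame with columns `v_load` and `v_max_un` (mol/s);
#'   default the three standard pairs (1, 25), (10, 25), (10, 15) nmol/s.
#' @param config single-sink [scenario_config].
#' @param ... passed to [integrate_to_steady_state].
#' @return list with `profiles` (per-element concentrations per run) and
#'   `summary` (one row per run: spatial and linear mean concentration and
#'   resistance).
#' @export
run_single_sink_gradient <- function(pairs = data.frame(v_load = c(1e-9, 10e-9, 10e-9),
                                                        v_max_un = c(25e-9, 25e-9, 15e-9)),
                                     config = preset_scenario("single_sink"), ...) {
  stopifnot(length(config$sinks) == 1)
  profiles <- list(); summ <- list()
  for (k in seq_len(nrow(pairs))) {
    res <- integrate_to_steady_state(config, v0 = pairs$v_load[k],
                                     vmax = pairs$v_max_un[k], ...)
    if (!res$converged) stop("single-sink run did not converge at v_load = ", pairs$v_load[k])
    sp <- mean_pathway_summary(res, "spatial")
    li <- mean_pathway_summary(res, "linear_vkr")
    profiles[[k]] <- data.frame(run = k, v_load = pairs$v_load[k],
                                v_max_un = pairs$v_max_un[k],
                                x = res$fields$x, zone = res$fields$zone,
                                c_ph = res$fields$c_ph)
    summ[[k]] <- data.frame(run = k, v_load = pairs$v_load[k],
                            v_max_un = pairs$v_max_un[k],
                            mean_c_spatial = sp$mean_c, mean_c_linear = li$mean_c,
                            mean_r_spatial = sp$mean_r, mean_r_linear = li$mean_r)
  }
  list(profiles = do.call(rbind, profiles), summary = do.call(rbind, summ))
}

#' Three-model partitioning comparison over a loading-rate scan
#'
#' Runs the VK, VKR and biophysical models over the same loading grid for
#' one of the two-sink presets and tabulates partitioning coefficients,
#' concentrations and resistance ratios per model. Rows where a model fails
#' (e.g. no steady state near total sink capacity) are flagged in `status`
#' and do not abort the scan.
#'
#' @param scenario preset name (`"vmax"`, `"km"` or `"resistance"`) or a
#'   two-sink [scenario_config].
#' @param grid loading rates (mol/s).
#' @param models subset of `c("vk", "vkr", "biophysical")`.
#' @param ... passed to [integrate_to_steady_state].
#' @return tidy data.frame: `scenario`, `model`, `v0`, `PC1`, `c0`, `c1`,
#'   `c2`, `r_ratio`, `physiological_flag`, `status`.
#' @export
run_model_comparison <- function(scenario = c("vmax", "km", "resistance"),
                                 grid = loading_grid(40),
                                 models = c("vk", "vkr", "biophysical"), ...) {
  config <- if (inherits(scenario, "scenario_config")) scenario
            else preset_scenario(match.arg(scenario))
  stopifnot(length(config$sinks) == 2)
  vmax_tot <- sum(vapply(config$sinks, `[[`, numeric(1), "v_max"))
  rows <- list()
  lump_row <- function(model, tab) {
    data.frame(scenario = config$name, model = model, v0 = tab$v0, PC1 = tab$PC1,
               c0 = tab$c0, c1 = tab$c1, c2 = tab$c2,
               r_ratio = tab$r1_eff / tab$r2_eff,
               physiological_flag = tab$physiological_flag, status = tab$status)
  }
  if ("vk" %in% models)
    rows$vk <- lump_row("vk", lumped_scan("vk", grid, config))
  if ("vkr" %in% models)
    rows$vkr <- lump_row("vkr", lumped_scan("vkr", grid, config))
  if ("biophysical" %in% models) {
    feasible <- grid < vmax_tot * (1 - 1e-9)
    res <- vector("list", length(grid))
    res[feasible] <- .scan_steady(config, grid[feasible], ...)
    bio <- lapply(seq_along(grid), function(k) {
      r <- res[[k]]
      if (!feasible[k] || !inherits(r, "steady_state_result") || !r$converged) {
        status <- if (!feasible[k]) "no steady state: v0 >= total sink capacity"
                  else if (inherits(r, "error")) conditionMessage(r) else "not converged"
        return(data.frame(scenario = config$name, model = "biophysical", v0 = grid[k],
                          PC1 = NA_real_, c0 = NA_real_, c1 = NA_real_, c2 = NA_real_,
                          r_ratio = NA_real_, physiological_flag = NA, status = status))
      }
      f <- r$fields
      c0 <- weighted.mean(f$c_ph[f$zone == "source"], f$length[f$zone == "source"])
      c1 <- weighted.mean(f$c_ph[f$zone == "sink_1"], f$length[f$zone == "sink_1"])
      c2 <- weighted.mean(f$c_ph[f$zone == "sink_2"], f$length[f$zone == "sink_2"])
      data.frame(scenario = config$name, model = "biophysical", v0 = grid[k],
                 PC1 = r$PC1, c0 = c0, c1 = c1, c2 = c2,
                 r_ratio = effective_resistance(r)$ratio,
                 physiological_flag = c0 > 100 & c0 < 2000, status = "ok")
    })
    rows$biophysical <- do.call(rbind, bio)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "manifest") <- run_manifest(config, solver = list(models = models, n_grid = length(grid)))
  out
}

#' Partitioning as a function of the sink-1 xylem water boundary
#'
#' Sweeps the imposed water flux of sink 1 from evaporation to root-like
#' uptake while sink 2 takes up water at a constant 2e-8 m^3/s, for several
#' loading rates; source evaporation balances the net sink water flow.
#' Water-potential profiles are recorded at the two sweep endpoints of the
#' lowest loading rate.
#'
#' @param flux_grid sink-1 volumetric water fluxes (m^3/s); negative =
#'   evaporation.
#' @param loading_rates loading rates (mol/s); the standard triple spans
#'   low, intermediate and high loading.
#' @param config base [scenario_config] (preset `xylem_sweep`).
#' @param ... passed to [integrate_to_steady_state].
#' @return list with `pc` (PC1 per flux and loading rate) and `profiles`
#'   (water potentials at the endpoint cases).
#' @export
run_xylem_sweep <- function(flux_grid = seq(-1e-8, 2e-8, length.out = 7),
                            loading_rates = c(2.5e-9, 12.5e-9, 22.5e-9),
                            config = preset_scenario("xylem_sweep"), ...) {
  stopifnot(config$hydraulic_mode == "xylem_coupled")
  pc <- list(); profiles <- list()
  for (v0 in loading_rates) {
    init <- NULL
    for (q1 in flux_grid) {
      cfg <- config
      cfg$sinks[[1]]$water_boundary <- wb_imposed_flux(q1)
      res <- tryCatch(integrate_to_steady_state(cfg, v0 = v0, init = init, ...),
                      error = function(e) e)
      ok <- inherits(res, "steady_state_result") && res$converged
      pc[[length(pc) + 1]] <- data.frame(v0 = v0, sink1_flux = q1,
                                         PC1 = if (ok) res$PC1 else NA_real_,
                                         converged = ok)
      if (ok) init <- res$state else init <- NULL
      if (ok && v0 == min(loading_rates) && q1 %in% range(flux_grid)) {
        pr <- water_potential_profile(res)
        pr$sink1_flux <- q1; pr$v0 <- v0
        profiles[[length(profiles) + 1]] <- pr
      }
    }
  }
  list(pc = do.call(rbind, pc),
       profiles = if (length(profiles)) do.call(rbind, profiles) else NULL)
}

#' Organ-type comparison: root-root, tuber-root, leaf-root
#'
#' Emergent xylem flow from soil/atmosphere boundaries: both sinks
#' soil-coupled (roots), the tuber at 10% uptake permeability, the young
#' leaf evaporating 10% of the mature-leaf transpiration. Returns PC1 per
#' case and loading rate plus xylem water-potential profiles at
#' `profile_v0`.
#'
#' @param grid loading rates (mol/s).
#' @param profile_v0 loading rate at which profiles are recorded.
#' @param ... passed to [integrate_to_steady_state].
#' @return list with `pc` and `profiles`.
#' @export
run_organ_triad <- function(grid = c(2.5e-9, 7.5e-9, 12.5e-9, 17.5e-9, 22.5e-9),
                            profile_v0 = 12.5e-9, ...) {
  cases <- c("root_root", "tuber_root", "leaf_root")
  pc <- list(); profiles <- list()
  for (case in cases) {
    config <- preset_scenario(case)
    res_list <- .scan_steady(config, grid, ...)
    for (k in seq_along(grid)) {
      r <- res_list[[k]]
      ok <- inherits(r, "steady_state_result") && r$converged
      pc[[length(pc) + 1]] <- data.frame(case = case, v0 = grid[k],
                                         PC1 = if (ok) r$PC1 else NA_real_,
                                         converged = ok)
    }
    pres <- integrate_to_steady_state(config, v0 = profile_v0, ...)
    pr <- water_potential_profile(pres)
    pr$case <- case; pr$v0 <- profile_v0
    profiles[[length(profiles) + 1]] <- pr
  }
  list(pc = do.call(rbind, pc), profiles = do.call(rbind, profiles))
}

#' Factorial effect of pathway length, xylem flow, efflux and SP6A on
#' root/tuber partitioning
#'
#' Young leaf vs root/tuber with incrementally added asymmetries:
#' `"length"` (0.1 vs 0.3 m, both root-like water uptake), `"xylem"`
#' (equal 0.25 m lengths, leaf evaporating vs root uptake) and
#' `"length_xylem"` (both), each with SWEET/SUT efflux off or on, SP6A off
#' (factor 1) or on (0.6), and root/tuber sink strength 5 or 15 nmol/s. A
#' sink-strength increase is accompanied by an equal source loading
#' increase, so those runs are keyed by the nominal loading rate but driven
#' at `v0 + (v_max_tuber - 5 nmol/s)`.
#'
#' @param grid nominal loading rates (mol/s).
#' @param conditions,efflux,sp6a,tuber_vmax factor levels to include.
#' @param ... passed to [integrate_to_steady_state].
#' @return tidy data.frame keyed by the condition flags with `PC_tuber`
#'   (partitioning toward the root/tuber sink), `efflux_fraction`,
#'   `converged` and `status`.
#' @export
run_efflux_sp6a_factorial <- function(grid = loading_grid(8, c(0.025e-9, 9.5e-9)),
                                      conditions = c("length", "xylem", "length_xylem"),
                                      efflux = c(FALSE, TRUE),
                                      sp6a = c(1, 0.6),
                                      tuber_vmax = c(5e-9, 15e-9), ...) {
  base <- preset_scenario("efflux_factorial")
  rows <- list()
  for (cond in conditions) for (ef in efflux) for (sf in sp6a) for (tv in tuber_vmax) {
    cfg <- base
    cfg$name <- paste0("factorial_", cond)
    if (cond == "length") {
      cfg$sinks[[1]]$water_boundary <- wb_soil_coupled(1)
    } else if (cond == "xylem") {
      cfg$sinks[[1]]$pathway_length <- 0.25
      cfg$sinks[[2]]$pathway_length <- 0.25
    }
    cfg$sinks[[1]]$r_ref <- 7.5e12 * cfg$sinks[[1]]$pathway_length / 0.25
    cfg$sinks[[2]]$r_ref <- 7.5e12 * cfg$sinks[[2]]$pathway_length / 0.25
    cfg$sinks[[2]]$v_max <- tv
    cfg$radial_sucrose <- if (ef) {
      rs <- base$radial_sucrose; rs$sp6a_factor <- sf; rs
    } else NULL
    init <- NULL
    for (v0 in grid) {
      v0_actual <- v0 + (tv - 5e-9)
      res <- tryCatch(integrate_to_steady_state(cfg, v0 = v0_actual, init = init, ...),
                      error = function(e) e)
      ok <- inherits(res, "steady_state_result") && res$converged
      init <- if (ok) res$state else NULL
      rows[[length(rows) + 1]] <- data.frame(
        condition = cond, efflux = ef, sp6a_factor = sf, tuber_vmax = tv,
        v0_nominal = v0, v0_actual = v0_actual,
        PC_tuber = if (ok) 1 - res$PC1 else NA_real_,
        PC1 = if (ok) res$PC1 else NA_real_,
        efflux_fraction = if (ok) net_efflux_fraction(res) else NA_real_,
        converged = ok,
        status = if (ok) "ok" else if (inherits(res, "error")) conditionMessage(res)
                 else "not converged")
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Lowest loading rate with non-negligible root/tuber partitioning
#'
#' Boundary of the zero-partitioning regime per factorial cell: the lowest
#' nominal loading rate at which `PC_tuber` exceeds `threshold`, reported
#' against both the combined and the per-sink unloading capacity.
#'
#' @param tbl output of [run_efflux_sp6a_factorial].
#' @param threshold PC_tuber threshold (default 0.01).
#' @return data.frame per condition cell with `v0_boundary` (mol/s, `NA`
#'   when partitioning never exceeds the threshold on the grid) and its
#'   ratio to the combined and tuber sink capacity.
#' @export
zero_partitioning_regime <- function(tbl, threshold = 0.01) {
  key <- interaction(tbl$condition, tbl$efflux, tbl$sp6a_factor, tbl$tuber_vmax, drop = TRUE)
  out <- lapply(split(tbl, key), function(d) {
    d <- d[order(d$v0_nominal), ]
    hit <- which(!is.na(d$PC_tuber) & d$PC_tuber > threshold)
    vb <- if (length(hit)) d$v0_nominal[hit[1]] else NA_real_
    cap <- 5e-9 + d$tuber_vmax[1]
    data.frame(condition = d$condition[1], efflux = d$efflux[1],
               sp6a_factor = d$sp6a_factor[1], tuber_vmax = d$tuber_vmax[1],
               v0_boundary = vb,
               frac_of_combined_capacity = vb / cap,
               frac_of_tuber_capacity = vb / d$tuber_vmax[1])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Transient partitioning response to a step change in one sink
#'
#' From a converged steady state, instantaneously changes sink 1's `v_max`
#' (default: halved) and follows the partitioning coefficient through the
#' transient. The post-step end point is verified against an independent
#' steady-state solve of the stepped configuration. Reports `t90`, the time
#' at which 90% of the partitioning shift is covered.
#'
#' @param config base [scenario_config]; default the standard symmetric
#'   two-sink system.
#' @param v0 loading rate (mol/s).
#' @param step list with `sink` (index) and `v_max_factor`.
#' @param t_grid observation times (s) of the transient.
#' @param ... passed to [integrate_to_steady_state].
#' @return list with `series` (data.frame `t`, `v1`, `v2`, `PC1`), `t90`
#'   (s), `pc_pre`, `pc_post` and `pc_post_independent`.
#' @export
run_step_response <- function(config = NULL, v0 = 12.5e-9,
                              step = list(sink = 1, v_max_factor = 0.5),
                              t_grid = seq(0, 4 * 3600, by = 60), ...) {
  if (is.null(config)) {
    config <- scenario_config(sinks = list(sink_spec(), sink_spec()),
                              name = "step_response")
  }
  base <- integrate_to_steady_state(config, v0 = v0, ...)
  if (!base$converged) stop("run_step_response: baseline did not converge")

  parms <- base$parms
  vmax_post <- parms$vmax
  vmax_post[step$sink] <- vmax_post[step$sink] * step$v_max_factor
  if (v0 >= sum(vmax_post)) stop("run_step_response: stepped capacity below the loading rate")

  ctx <- .make_context(config)
  parms_post <- list(v0 = parms$v0, vmax = vmax_post)
  y0 <- .pack(base$state, ctx)
  yref <- c(ctx$p$rho_water * ctx$vref_ph, 300 * ctx$vref_ph,
            if (ctx$xylem) ctx$p$rho_water * ctx$vref_x,
            if (ctx$radial) 300 * ctx$vref_ph[ctx$apo_idx] * ctx$rs$apoplast_volume_fraction)
  sol <- deSolve::ode(y0, t_grid, function(t, y, p) .rhs(t, y, ctx, parms_post),
                      parms = NULL, method = "lsodes", rtol = 1e-8,
                      atol = 1e-10 * yref, maxsteps = 50000)
  series <- do.call(rbind, lapply(seq_len(nrow(sol)), function(i) {
    st <- .unpack(as.numeric(sol[i, -1]), ctx)
    d <- .derive(st$W_Ph, st$S_Ph, ctx)
    v <- vapply(seq_along(ctx$sink_idx), function(j) {
      idx <- ctx$sink_idx[[j]]
      sum(vmax_post[j] / length(idx) * d$c_ph[idx] / (ctx$Km_el[idx] + d$c_ph[idx]))
    }, numeric(1))
    data.frame(t = sol[i, 1], v1 = v[1], v2 = v[2], PC1 = v[1] / sum(v))
  }))

  post <- integrate_to_steady_state(config, v0 = v0, vmax = vmax_post,
                                    init = .unpack(as.numeric(sol[nrow(sol), -1]), ctx), ...)
  post_cold <- integrate_to_steady_state(config, v0 = v0, vmax = vmax_post, ...)
  pc_pre <- base$PC1; pc_post <- post$PC1
  ## the partitioning coefficient jumps instantaneously when v_max steps
  ## (unloading scales immediately at unchanged concentrations); the
  ## adaptation time is that of the subsequent relaxation of the
  ## long-distance transport toward the new steady state
  pc_jump <- series$PC1[1]
  shift <- pc_post - pc_jump
  t90 <- NA_real_
  if (abs(shift) > 0) {
    target <- pc_jump + 0.9 * shift
    crossed <- if (shift > 0) series$PC1 >= target else series$PC1 <= target
    k <- which(crossed)[1]
    if (!is.na(k) && k > 1) {
      ## linear interpolation between the bracketing observations
      p1 <- series$PC1[k - 1]; p2 <- series$PC1[k]
      t90 <- series$t[k - 1] + (target - p1) / (p2 - p1) * (series$t[k] - series$t[k - 1])
    } else if (!is.na(k)) t90 <- series$t[k]
  }
  list(series = series, t90 = t90, pc_pre = pc_pre, pc_jump = pc_jump,
       pc_post = pc_post, pc_post_independent = post_cold$PC1)
}
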