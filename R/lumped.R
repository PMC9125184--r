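## Lumped two-sink models: VK (no resistance) and VKR (sucrose-dependent
## lumped pathway resistance).

#' Sucrose-dependent lumped pathway resistance
#'
#' Scales a reference pathway resistance by the quartic sucrose-viscosity
#' polynomial
#' \deqn{0.685 S^4 - 1.0411 S^3 + 0.9512 S^2 + 0.1364 S + 0.3396}
#' evaluated at the mid-pathway sucrose concentration `S_half` in molar
#' units. The polynomial is stated to be valid for 0--1.5 M; outside that
#' range a warning is raised and, depending on `policy`, the value is either
#' evaluated as printed (`"evaluate"`, default) or the polynomial argument is
#' clamped to the validity boundary (`"clamp"`). Clamping matters near total
#' sink capacity, where literal extrapolation of the quartic makes the
#' resistance blow up and the steady-state system loses its root.
#'
#' @param S_half mid-pathway sucrose concentration in mol/L (M).
#' @param r_ref reference resistance (mol s m^-6).
#' @param policy out-of-validity handling, `"evaluate"` or `"clamp"`.
#' @param warn warn when `S_half` leaves the 0--1.5 M validity range.
#' @return resistance (mol s m^-6), same length as `S_half`.
#' @examples
#' vkr_resistance(0, 7.5e12)      # 0.3396 * r_ref
#' vkr_resistance(1, 7.5e12)      # 1.0711 * r_ref
#' @export
vkr_resistance <- function(S_half, r_ref, policy = c("evaluate", "clamp"), warn = TRUE) {
  policy <- match.arg(policy)
  if (any(!is.finite(S_half))) stop("vkr_resistance: non-finite S_half")
  out <- S_half < 0 | S_half > 1.5
  if (any(out) && warn)
    warning(sprintf("vkr_resistance: %d value(s) outside the 0-1.5 M validity range (policy = '%s')",
                    sum(out), policy))
  S <- if (policy == "clamp") pmin(pmax(S_half, 0), 1.5) else S_half
  r_ref * (0.685 * S^4 - 1.0411 * S^3 + 0.9512 * S^2 + 0.1364 * S + 0.3396)
}

.sink_mat <- function(sinks) {
  ## accept list of sink_spec or a 2-column matrix/list(v_max=, K_m=)
  if (inherits(sinks, "sink_spec")) sinks <- list(sinks)
  if (is.list(sinks) && all(vapply(sinks, inherits, logical(1), "sink_spec"))) {
    v_max <- vapply(sinks, `[[`, numeric(1), "v_max")
    K_m <- vapply(sinks, `[[`, numeric(1), "K_m")
  } else if (is.list(sinks) && !is.null(sinks$v_max)) {
    v_max <- sinks$v_max; K_m <- sinks$K_m
  } else if (is.matrix(sinks)) {
    v_max <- sinks[, 1]; K_m <- sinks[, 2]
  } else stop("sinks must be sink_spec objects, a list(v_max=, K_m=), or a 2-column matrix")
  if (any(v_max <= 0) || any(K_m <= 0)) stop("sink v_max and K_m must be positive")
  cbind(v_max = v_max, K_m = K_m)
}

#' Solve the no-resistance (VK) two-sink model
#'
#' With no pathway resistance the source and sink concentrations are equal;
#' the shared concentration `c` is the unique positive root of
#' \eqn{\sum_i v_{max,i}\, c / (c + K_i) = v_0}. When all `K_m` are equal the
#' closed form \eqn{c = K v_0 / (\sum v_{max} - v_0)} is used.
#'
#' @param v0 total sucrose loading rate (mol/s); must satisfy
#'   `0 < v0 < sum(v_max)` for a steady state to exist.
#' @param sinks the two sinks: a list of [sink_spec] objects or
#'   `list(v_max =, K_m =)` vectors.
#' @return An object of class `vk_solution`: list with `c` (mol/m^3),
#'   unloading rates `v1`, `v2` (mol/s) and `PC1 = v1/(v1+v2)`.
#' @examples
#' vk_solve(12.5e-9, list(v_max = c(22.5e-9, 2.5e-9), K_m = c(75, 75)))$PC1  # 0.9
#' @export
vk_solve <- function(v0, sinks) {
  sm <- .sink_mat(sinks)
  vmax <- sm[, "v_max"]; K <- sm[, "K_m"]
  if (v0 < 0) stop("vk_solve: v0 must be non-negative")
  if (v0 >= sum(vmax))
    stop(sprintf("vk_solve: no steady state, v0 = %g >= total sink capacity %g mol/s", v0, sum(vmax)))
  if (v0 == 0) {
    c_root <- 0
  } else if (length(unique(K)) == 1L) {
    c_root <- K[1] * v0 / (sum(vmax) - v0)
  } else {
    g <- function(cc) sum(vmax * cc / (cc + K)) - v0
    hi <- max(K) * v0 / (sum(vmax) - v0) + max(K)
    while (g(hi) < 0) hi <- hi * 2
    c_root <- uniroot(g, c(0, hi), tol = .Machine$double.eps^0.75)$root
  }
  v <- vmax * c_root / (c_root + K)
  pc <- if (sum(v) > 0) v[1] / sum(v) else NA_real_
  structure(list(c = c_root, v1 = v[1], v2 = v[2], PC1 = pc), class = "vk_solution")
}

## Inner equation of the VKR system: for fixed source concentration c0 find
## the unique sink concentration ci in (0, c0) balancing pathway inflow
## c0 (c0 - ci) / r(S_half) against Michaelis-Menten unloading. The left side
## is strictly decreasing in ci (numerator falls, resistance rises with the
## mid concentration on [0, 1.5] M), the right side strictly increasing, so
## the root is unique.
.vkr_inner <- function(c0, v_max, K_m, r_ref, policy) {
  f <- function(ci) {
    r <- vkr_resistance((c0 + ci) / 2 / 1000, r_ref, policy = policy, warn = FALSE)
    c0 * (c0 - ci) / r - v_max * ci / (K_m + ci)
  }
  uniroot(f, c(0, c0), tol = .Machine$double.eps^0.9)$root
}

.vkr_rate <- function(ci, v_max, K_m) v_max * ci / (K_m + ci)

#' Solve the lumped sucrose-dependent-resistance (VKR) two-sink model
#'
#' Steady state of the three-unknown system in source and sink
#' concentrations `(c0, c1, c2)` (mol/m^3): for each sink the pathway flux
#' \eqn{c_0 (c_0 - c_i) / r_i} equals the Michaelis--Menten unloading rate,
#' with the lumped resistance \eqn{r_i} evaluated by [vkr_resistance] at the
#' mid-pathway concentration \eqn{(c_0 + c_i)/2} (converted to M), and the
#' unloading rates sum to the loading rate `v0`.
#'
#' The solver exploits that for fixed `c0` each sink equation has a unique
#' root `ci` in `(0, c0)` (bracketed bisection), and scans total unloading
#' over a logarithmic `c0` grid for all sign changes, so every biologically
#' valid root (all concentrations positive) is found. If several exist, the
#' smallest-`c0` root is returned and all roots are attached as attribute
#' `"all_roots"`.
#'
#' @inheritParams vk_solve
#' @param r_refs reference resistances of the two pathways (mol s m^-6).
#' @param out_of_validity policy passed to [vkr_resistance] when the mid
#'   concentration leaves the 0--1.5 M validity range of the viscosity
#'   polynomial: `"evaluate"` (as printed; default) or `"clamp"`.
#' @param c0_range search range for the source concentration (mol/m^3).
#' @param n_scan number of grid points of the sign-change scan.
#' @param residual_tol maximum admissible residual of the flux-balance
#'   equations (mol/s).
#' @return An object of class `vkr_solution`: list with `c0`, `c1`, `c2`
#'   (mol/m^3), `v1`, `v2` (mol/s), sucrose-adjusted resistances `r1_eff`,
#'   `r2_eff` (mol s m^-6), `PC1`, and `residual` (mol/s).
#' @examples
#' s <- vkr_solve(0.025e-9, list(v_max = c(22.5e-9, 2.5e-9), K_m = c(75, 75)),
#'                r_refs = c(7.5e12, 7.5e12))
#' s$PC1  # about 0.51, approaching 0.5 as v0 -> 0
#' @export
vkr_solve <- function(v0, sinks, r_refs,
                      out_of_validity = c("evaluate", "clamp"),
                      c0_range = c(1e-4, 1e6), n_scan = 250,
                      residual_tol = 1e-13) {
  policy <- match.arg(out_of_validity)
  sm <- .sink_mat(sinks)
  vmax <- sm[, "v_max"]; K <- sm[, "K_m"]
  stopifnot(length(r_refs) == nrow(sm), all(r_refs > 0))
  if (v0 <= 0 || v0 >= sum(vmax))
    stop(sprintf("vkr_solve: need 0 < v0 < total sink capacity (%g mol/s), got %g", sum(vmax), v0))

  G <- function(c0) {
    ci <- vapply(seq_len(nrow(sm)), function(i) .vkr_inner(c0, vmax[i], K[i], r_refs[i], policy), numeric(1))
    sum(.vkr_rate(ci, vmax, K)) - v0
  }
  grid <- exp(seq(log(c0_range[1]), log(c0_range[2]), length.out = n_scan))
  gv <- vapply(grid, G, numeric(1))
  sgn <- sign(gv)
  idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (!length(idx)) {
    stop(sprintf(paste0("vkr_solve: no root found for v0 = %g mol/s ",
                        "(max attainable total unloading on the scanned range: %g mol/s); ",
                        "consider out_of_validity = 'clamp'"), v0, max(gv) + v0))
  }
  roots <- lapply(idx, function(i) {
    c0 <- uniroot(G, grid[c(i, i + 1)], tol = .Machine$double.eps^0.9)$root
    ci <- vapply(seq_len(nrow(sm)), function(j) .vkr_inner(c0, vmax[j], K[j], r_refs[j], policy), numeric(1))
    r_eff <- vkr_resistance((c0 + ci) / 2 / 1000, r_refs, policy = policy, warn = FALSE)
    v <- .vkr_rate(ci, vmax, K)
    res <- max(abs(c0 * (c0 - ci) / r_eff - v), abs(sum(v) - v0))
    list(c0 = c0, c1 = ci[1], c2 = ci[2], v1 = v[1], v2 = v[2],
         r1_eff = r_eff[1], r2_eff = r_eff[2], PC1 = v[1] / sum(v), residual = res)
  })
  valid <- vapply(roots, function(r)
    all(c(r$c0, r$c1, r$c2) > 0) && r$residual < residual_tol, logical(1))
  if (!any(valid))
    stop(sprintf("vkr_solve: no biologically valid root below residual_tol; best residual %g mol/s",
                 min(vapply(roots, `[[`, numeric(1), "residual"))))
  roots <- roots[valid]
  ord <- order(vapply(roots, `[[`, numeric(1), "c0"))
  sol <- roots[[ord[1]]]
  S_half <- c(sol$c0 + sol$c1, sol$c0 + sol$c2) / 2 / 1000
  if (any(S_half > 1.5))
    warning(sprintf("vkr_solve: mid-pathway concentration up to %.2f M exceeds the 1.5 M polynomial validity (policy '%s')",
                    max(S_half), policy))
  structure(sol, class = "vkr_solution", all_roots = roots)
}

## Single-sink VKR analogue: source and one sink, lumped sucrose-dependent
## resistance. Used by the mean-pathway diagnostics to quantify how much a
## linear-gradient lumped description underestimates pathway concentration
## and resistance relative to the spatially explicit model.
.vkr_single <- function(v0, v_max, K_m, r_ref, policy = "evaluate") {
  if (v0 <= 0 || v0 >= v_max) stop("need 0 < v0 < v_max")
  G <- function(c0) .vkr_rate(.vkr_inner(c0, v_max, K_m, r_ref, policy), v_max, K_m) - v0
  grid <- exp(seq(log(1e-4), log(1e6), length.out = 200))
  gv <- vapply(grid, G, numeric(1))
  i <- which(sign(gv[-1]) * sign(gv[-length(gv)]) < 0)[1]
  if (is.na(i)) stop("no single-sink VKR root found")
  c0 <- uniroot(G, grid[c(i, i + 1)], tol = .Machine$double.eps^0.9)$root
  c1 <- .vkr_inner(c0, v_max, K_m, r_ref, policy)
  list(c0 = c0, c1 = c1,
       r_eff = vkr_resistance((c0 + c1) / 2 / 1000, r_ref, policy = policy, warn = FALSE))
}

#' Loading-rate scan of a lumped model
#'
#' Solves the VK or VKR model over a grid of loading rates and returns a
#' tidy table. Solver failures are recorded per row (`status` column) and do
#' not abort the scan.
#'
#' @param model `"vk"` or `"vkr"`.
#' @param loading_grid strictly increasing loading rates (mol/s).
#' @param scenario a [scenario_config]; sink kinetics, reference resistances
#'   and the out-of-validity policy are taken from it.
#' @return data.frame with columns `v0`, `c0`, `c1`, `c2`, `v1`, `v2`,
#'   `PC1`, `r1_eff`, `r2_eff`, `physiological_flag` (TRUE when the source
#'   concentration lies in the physiologically relevant 0.1--2 M band) and
#'   `status`.
#' @export
lumped_scan <- function(model = c("vk", "vkr"), loading_grid, scenario) {
  model <- match.arg(model)
  stopifnot(inherits(scenario, "scenario_config"))
  if (length(loading_grid) == 0)
    return(data.frame(v0 = numeric(0), c0 = numeric(0), c1 = numeric(0),
                      c2 = numeric(0), v1 = numeric(0), v2 = numeric(0),
                      PC1 = numeric(0), r1_eff = numeric(0), r2_eff = numeric(0),
                      physiological_flag = logical(0), status = character(0)))
  if (is.unsorted(loading_grid, strictly = TRUE))
    stop("lumped_scan: loading_grid must be strictly increasing")
  sinks <- scenario$sinks
  r_refs <- vapply(sinks, `[[`, numeric(1), "r_ref")
  rows <- lapply(loading_grid, function(v0) {
    out <- tryCatch({
      if (model == "vk") {
        s <- vk_solve(v0, sinks)
        data.frame(v0 = v0, c0 = s$c, c1 = s$c, c2 = s$c, v1 = s$v1, v2 = s$v2,
                   PC1 = s$PC1, r1_eff = NA_real_, r2_eff = NA_real_,
                   physiological_flag = s$c > 100 & s$c < 2000, status = "ok")
      } else {
        s <- suppressWarnings(vkr_solve(v0, sinks, r_refs,
                                        out_of_validity = scenario$out_of_validity))
        data.frame(v0 = v0, c0 = s$c0, c1 = s$c1, c2 = s$c2, v1 = s$v1, v2 = s$v2,
                   PC1 = s$PC1, r1_eff = s$r1_eff, r2_eff = s$r2_eff,
                   physiological_flag = s$c0 > 100 & s$c0 < 2000, status = "ok")
      }
    }, error = function(e) {
      data.frame(v0 = v0, c0 = NA_real_, c1 = NA_real_, c2 = NA_real_,
                 v1 = NA_real_, v2 = NA_real_, PC1 = NA_real_,
                 r1_eff = NA_real_, r2_eff = NA_real_,
                 physiological_flag = NA, status = conditionMessage(e))
    })
    out
  })
  do.call(rbind, rows)
}
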