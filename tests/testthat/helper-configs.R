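## Shared fixtures: reduced meshes for fast biophysical unit tests (the
## acceptance tests use the full default mesh) and the brute-force VKR
## oracle.

small_mesh <- function() {
  mesh_spec(n_source = 5, source_element_length = 0.02,
            n_pathway = 8, n_sink = 5, sink_element_length = 0.02)
}

small_two_sink <- function(v_max = c(12.5e-9, 12.5e-9), K_m = c(75, 75),
                           pathway_length = c(0.25, 0.25), ...) {
  scenario_config(sinks = list(sink_spec(v_max[1], K_m[1], pathway_length[1]),
                               sink_spec(v_max[2], K_m[2], pathway_length[2])),
                  mesh = small_mesh(), name = "test_small", ...)
}

## Brute-force oracle for the VKR steady state: iterative zooming grid
## search over (c0, c1/c0, c2/c0) minimizing the max-norm residual of the
## two flux-balance equations and total conservation. Independent of the
## nested-bisection solver used by vkr_solve.
vkr_poly_oracle <- function(S) 0.685 * S^4 - 1.0411 * S^3 + 0.9512 * S^2 + 0.1364 * S + 0.3396

vkr_grid_oracle <- function(v0, vmax, K, rref, outer_iter = 8, n_outer = 40,
                            n_inner = 2500) {
  ## residual of sink i's flux balance on a dense grid of candidate sink
  ## concentrations; two-stage grid refinement around the minimum
  inner_best <- function(c0, i) {
    ci <- seq(c0 * 1e-8, c0 * (1 - 1e-10), length.out = n_inner)
    for (stage in 1:3) {
      r <- rref[i] * vkr_poly_oracle((c0 + ci) / 2 / 1000)
      res <- abs(c0 * (c0 - ci) / r - vmax[i] * ci / (K[i] + ci))
      k <- which.min(res)
      lo <- ci[max(1, k - 2)]; hi <- ci[min(length(ci), k + 2)]
      ci_best <- ci[k]
      ci <- seq(lo, hi, length.out = n_inner)
    }
    ci_best
  }
  excess <- function(c0) {
    c1 <- inner_best(c0, 1); c2 <- inner_best(c0, 2)
    vmax[1] * c1 / (K[1] + c1) + vmax[2] * c2 / (K[2] + c2) - v0
  }
  lo <- 1e-3; hi <- 1e6
  for (it in seq_len(outer_iter)) {
    c0s <- exp(seq(log(lo), log(hi), length.out = n_outer))
    ex <- vapply(c0s, excess, numeric(1))
    k <- which(sign(ex[-1]) * sign(ex[-length(ex)]) < 0)[1]  # smallest-c0 root
    if (is.na(k)) stop("oracle: no sign change on the c0 grid")
    lo <- c0s[k]; hi <- c0s[k + 1]
  }
  c0 <- sqrt(lo * hi)
  c1 <- inner_best(c0, 1); c2 <- inner_best(c0, 2)
  v1 <- vmax[1] * c1 / (K[1] + c1); v2 <- vmax[2] * c2 / (K[2] + c2)
  list(c0 = c0, c1 = c1, c2 = c2, v1 = v1, v2 = v2, PC1 = v1 / (v1 + v2))
}
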