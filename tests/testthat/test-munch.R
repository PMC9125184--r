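test_that("derived fields: zero-sucrose limit, reference anchor, viscosity law", {
  cfg <- small_two_sink()
  p <- cfg$parameters
  st <- initial_state(cfg, c_init = 0)
  f <- derived_fields(st, cfg)
  expect_equal(unique(f$mu_ph), p$mu_x)          # water viscosity at S = 0
  expect_equal(unique(f$Pi_ph), 0)
  expect_equal(unique(f$P_ph), 0)                # volumes at reference
  expect_equal(f$psi_ph, f$P_ph + f$Pi_ph)
  ## volume-fraction viscosity, scalar check: V = 1e-9 m^3, S = 1e-6 mol
  phi <- 2.157e-4 * 1e-6 / (2.157e-4 * 1e-6 + 1e-9)
  expect_equal(phi, 0.17743, tolerance = 1e-4)
  expect_equal(exp(4.68 * 0.956 * phi / (1 - 0.956 * phi)), 2.6014, tolerance = 1e-4)
  st2 <- initial_state(cfg, c_init = 300)
  f2 <- derived_fields(st2, cfg)
  expect_equal(unique(f2$Pi_ph), -p$RT * 300)
  expect_true(all(f2$mu_ph > p$mu_x))
})

test_that("axial water flux: closed form, zero at equal pressure, antisymmetric", {
  cfg <- small_two_sink()
  p <- cfg$parameters
  st <- initial_state(cfg)
  f <- derived_fields(st, cfg)
  expect_equal(axial_water_flux(1, 2, f, p), 0)
  ## impose a pressure difference by hand
  f$P_ph[1] <- 0.1; f$P_ph[2] <- 0
  lbar <- (f$length[1] + f$length[2]) / 2
  expected <- p$N_Ph * pi * p$a_Ph^2 * p$k_p / f$mu_ph[1] * 0.1 / lbar * p$rho_water
  expect_equal(axial_water_flux(1, 2, f, p), expected)
  expect_equal(axial_water_flux(2, 1, f, p), -expected)
})

test_that("radial water flux follows the potential difference in both modes", {
  cfg <- small_two_sink(hydraulic_mode = "xylem_coupled")
  p <- cfg$parameters
  st <- initial_state(cfg)
  f <- derived_fields(st, cfg)
  f$psi_ph[3] <- 0
  expect_equal(radial_water_flux(3, f, p, "phloem_only"), 0)
  f$psi_ph[3] <- -0.5; f$psi_x[3] <- -0.2
  arad <- p$N_Ph * 2 * pi * p$a_Ph * f$length[3]
  expect_equal(radial_water_flux(3, f, p, "xylem_coupled"),
               p$L_r * arad * 0.3 * p$rho_water)
  f$psi_x[3] <- f$psi_ph[3]
  expect_equal(radial_water_flux(3, f, p, "xylem_coupled"), 0)
})

test_that("unloading kinetics: half-saturation, saturation and uniform split", {
  s <- sink_spec(v_max = 12.5e-9, K_m = 75)
  expect_equal(unloading_flux(75, s, 1), 6.25e-9)
  expect_equal(unloading_flux(1e9, s, 1), 12.5e-9, tolerance = 1e-6)
  expect_equal(unloading_flux(75, s, 20) * 20, 6.25e-9)
  cfg <- scenario_config()
  expect_equal(loading_flux(cfg, v0 = 10e-9), 0.5e-9)   # 20 source elements
  expect_equal(loading_flux(cfg, v0 = 0), 0)
})

test_that("time derivatives satisfy global sucrose balance at arbitrary states", {
  cfg <- small_two_sink()
  for (c0 in c(50, 300, 900)) {
    st <- initial_state(cfg, c_init = c0)
    ## perturb the state so axial and radial fluxes are non-trivial
    st$W_Ph <- st$W_Ph * seq(0.98, 1.02, length.out = length(st$W_Ph))
    st$S_Ph <- st$S_Ph * seq(1.1, 0.9, length.out = length(st$S_Ph))
    d <- time_derivatives(st, cfg, detail = TRUE)
    ## axial terms telescope; only summation order separates the two sides
    expect_equal(sum(d$derivatives$S_Ph),
                 sum(d$loading) - sum(d$unloading),
                 tolerance = 1e-12)
  }
})

test_that("three-element chain matches a hand-assembled balance", {
  cfg <- scenario_config(sinks = list(sink_spec(v_max = 10e-9, K_m = 75,
                                                pathway_length = 0.25)),
                         source = source_spec(v0 = 2e-9),
                         mesh = mesh_spec(n_source = 1, source_element_length = 0.1,
                                          n_pathway = 1, n_sink = 1,
                                          sink_element_length = 0.1),
                         name = "toy")
  p <- cfg$parameters
  st <- initial_state(cfg, c_init = 300)
  st$W_Ph <- st$W_Ph * c(1.01, 1.0, 0.99)   # pressure gradient source -> sink
  st$S_Ph <- st$S_Ph * c(1.2, 1.0, 0.8)
  d <- time_derivatives(st, cfg, detail = TRUE)

  ## hand assembly (independent scalar arithmetic)
  len <- c(0.1, 0.25, 0.1)
  A <- p$N_Ph * pi * p$a_Ph^2
  vref <- A * len
  V <- st$W_Ph / p$rho_water
  cc <- st$S_Ph / V
  P <- p$eps_p * (V - vref) / vref
  phi <- p$V_suc * st$S_Ph / (p$V_suc * st$S_Ph + V)
  mu <- p$mu_x * exp(4.68 * 0.956 * phi / (1 - 0.956 * phi))
  psi <- P - p$RT * cc
  q12 <- A * p$k_p / mean(mu[1:2]) * (P[1] - P[2]) / mean(len[1:2])
  q23 <- A * p$k_p / mean(mu[2:3]) * (P[2] - P[3]) / mean(len[2:3])
  qrad <- p$L_r * (p$N_Ph * 2 * pi * p$a_Ph * len) * (0 - psi)
  cup12 <- if (q12 > 0) cc[1] else cc[2]
  cup23 <- if (q23 > 0) cc[2] else cc[3]
  unload <- 10e-9 * cc[3] / (75 + cc[3])
  dW_hand <- p$rho_water * (c(-q12, q12 - q23, q23) + qrad)
  dS_hand <- c(-q12 * cup12 + 2e-9,
               q12 * cup12 - q23 * cup23,
               q23 * cup23 - unload)
  expect_equal(d$derivatives$W_Ph, dW_hand, tolerance = 1e-12)
  expect_equal(d$derivatives$S_Ph, dS_hand, tolerance = 1e-12)
})

test_that("fixed point: uniform zero-loading equilibrium has zero derivatives", {
  cfg <- small_two_sink()
  cfg$source$v0 <- 0
  st <- initial_state(cfg, c_init = 0)
  d <- time_derivatives(st, cfg)
  expect_equal(max(abs(d$W_Ph)), 0)
  expect_equal(max(abs(d$S_Ph)), 0)
})

test_that("symmetric two-sink steady state splits sucrose evenly and conserves mass", {
  cfg <- small_two_sink()
  res <- integrate_to_steady_state(cfg, v0 = 10e-9)
  expect_true(res$converged)
  expect_equal(res$PC1, 0.5, tolerance = 5e-3)
  expect_lt(res$conservation, 1e-6)
  expect_lt(abs(res$fluxes$v1 + res$fluxes$v2 - 10e-9) / 10e-9, 1e-6)
})

test_that("steady state is independent of the initial concentration", {
  cfg <- small_two_sink(v_max = c(20e-9, 5e-9))
  a <- integrate_to_steady_state(cfg, v0 = 10e-9, c_init = 100)
  b <- integrate_to_steady_state(cfg, v0 = 10e-9, c_init = 500)
  expect_true(a$converged && b$converged)
  expect_equal(a$PC1, b$PC1, tolerance = 1e-3)
})

test_that("Muench directionality: radial water enters phloem in source and pathway, leaves in sinks", {
  cfg <- small_two_sink(v_max = c(20e-9, 5e-9))
  res <- integrate_to_steady_state(cfg, v0 = 10e-9)
  d <- time_derivatives(res$state, cfg, detail = TRUE)
  zone <- res$fields$zone
  expect_true(all(d$Qrad[zone == "source"] > 0))
  expect_true(all(d$Qrad[grepl("^pathway", zone)] > 0))
  expect_true(all(d$Qrad[grepl("^sink", zone)] < 0))
})

test_that("loading beyond capacity is reported as divergence, not silence", {
  cfg <- small_two_sink()
  r <- tryCatch(suppressWarnings(integrate_to_steady_state(cfg, v0 = 40e-9, t_max = 1e5)),
                error = function(e) e)
  if (inherits(r, "steady_state_result")) expect_false(r$converged)
  else expect_match(conditionMessage(r), "non-finite|blow-up|failed")
})
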