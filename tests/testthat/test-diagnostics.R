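test_that("partitioning coefficient: definition, bounds and guards", {
  expect_equal(partitioning_coefficient(22.5, 2.5), 0.9)
  expect_equal(partitioning_coefficient(22.5e-9 * 3, 2.5e-9 * 3), 0.9)
  expect_equal(partitioning_coefficient(1, 1), 0.5)
  expect_equal(partitioning_coefficient(0, 2), 0)
  expect_warning(out <- partitioning_coefficient(0, 0), "undefined")
  expect_true(is.na(out))
  expect_error(partitioning_coefficient(-1, 2), "non-negative")
  ## PC1 + PC2 = 1 wherever defined
  v1 <- runif(20); v2 <- runif(20)
  expect_equal(partitioning_coefficient(v1, v2) + partitioning_coefficient(v2, v1),
               rep(1, 20))
})

test_that("effective resistance: zero-sucrose value, length linearity, branch ratio", {
  p <- plant_parameters()
  ## single-conduit 0.25 m pathway at water viscosity
  expect_equal(phloem_axial_resistance(0.25, p$mu_x, p, N_Ph = 1),
               2.958e11, tolerance = 1e-3)
  expect_equal(phloem_axial_resistance(0.5, p$mu_x, p, N_Ph = 1),
               2 * phloem_axial_resistance(0.25, p$mu_x, p, N_Ph = 1))
  ## in the sink-strength scenario the stronger sink's branch carries lower
  ## concentration, hence lower viscosity and resistance: r1/r2 < 1
  cfg <- small_two_sink(v_max = c(22.5e-9, 2.5e-9))
  res <- integrate_to_steady_state(cfg, v0 = 10e-9)
  er <- effective_resistance(res)
  expect_lt(er$ratio, 1)
  expect_equal(er$r1, effective_resistance(res, 1))
  ## zero-sucrose anchor: resistance of the long-distance pathway at c = 0
  ## equals the parameter-level formula
  st0 <- initial_state(cfg, c_init = 0)
  res0 <- res; res0$fields <- derived_fields(st0, cfg)
  expect_equal(effective_resistance(res0, 1, include_unloading = FALSE),
               phloem_axial_resistance(0.25, p$mu_x, p), tolerance = 1e-12)
})

test_that("mean pathway summaries: spatial vs chord vs lumped-VKR", {
  cfg <- scenario_config(sinks = list(sink_spec(v_max = 25e-9)),
                         mesh = small_mesh(), name = "single")
  res <- integrate_to_steady_state(cfg, v0 = 5e-9)
  sp <- mean_pathway_summary(res, "spatial")
  ch <- mean_pathway_summary(res, "linear_chord")
  lv <- mean_pathway_summary(res, "linear_vkr")
  ## lumped VKR underestimates both concentration and resistance
  expect_lt(lv$mean_c, sp$mean_c)
  expect_lt(lv$mean_r, sp$mean_r)
  ## chord mode agrees exactly with spatial for a uniform concentration
  st <- initial_state(cfg, c_init = 400)
  res_u <- res; res_u$fields <- derived_fields(st, cfg)
  spu <- mean_pathway_summary(res_u, "spatial")
  chu <- mean_pathway_summary(res_u, "linear_chord")
  expect_equal(spu$mean_c, chu$mean_c, tolerance = 1e-12)
  expect_equal(spu$mean_r, chu$mean_r, tolerance = 1e-12)
  ## non-converged input rejected
  res_bad <- res; res_bad$converged <- FALSE
  expect_error(mean_pathway_summary(res_bad), "converged")
})

test_that("mass-balance audit passes converged runs and fails truncated ones", {
  cfg <- small_two_sink()
  res <- integrate_to_steady_state(cfg, v0 = 10e-9)
  audit <- mass_balance_audit(res)
  expect_true(audit$pass)
  expect_lt(audit$sucrose_residual, 1e-6)
  ## negative control: a deliberately truncated run
  trunc <- integrate_to_steady_state(cfg, v0 = 10e-9, t_max = 10,
                                     polish = FALSE, conv_tol = 0)
  expect_false(mass_balance_audit(trunc)$pass)
})

test_that("water-potential profile carries the P + Pi decomposition and xylem columns", {
  cfg <- small_two_sink(hydraulic_mode = "xylem_coupled")
  cfg$sinks[[1]]$water_boundary <- wb_soil_coupled(1)
  cfg$sinks[[2]]$water_boundary <- wb_soil_coupled(1)
  res <- integrate_to_steady_state(cfg, v0 = 10e-9)
  pr <- water_potential_profile(res)
  expect_equal(pr$psi_ph, pr$P_ph + pr$Pi_ph)
  expect_true("psi_x" %in% names(pr))
  ## transpiring source end carries the most negative xylem potential
  expect_equal(which.min(pr$psi_x[pr$zone == "source"]), 1)
  ## phloem-only profiles have no xylem column
  res2 <- integrate_to_steady_state(small_two_sink(), v0 = 10e-9)
  expect_false("psi_x" %in% names(water_potential_profile(res2)))
})
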