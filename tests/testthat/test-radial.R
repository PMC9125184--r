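test_that("SWEET efflux: half-saturation, zero limit and SP6A scaling", {
  kin <- transporter_kinetics(0.148, 70)
  expect_equal(sweet_efflux_rate(70, kin, 1, 1e-9), 0.074e-9)
  expect_equal(sweet_efflux_rate(0, kin, 1, 1e-9), 0)
  cvals <- c(5, 70, 500)
  expect_equal(sweet_efflux_rate(cvals, kin, 0.6, 1e-9),
               0.6 * sweet_efflux_rate(cvals, kin, 1, 1e-9))
})

test_that("retrieval combines SWEET and SUT terms and saturates", {
  rs <- radial_sucrose_config()
  V <- 1e-9
  expect_equal(retrieval_rate(0, rs, V), 0)
  expect_equal(retrieval_rate(10, rs, V),
               (0.148 * 10 / 20 + 0.117 * 10 / 11) * V)
  expect_equal(retrieval_rate(1e9, rs, V), (0.148 + 0.117) * V, tolerance = 1e-6)
  ## SP6A scales the SWEET retrieval term only when configured to
  rs6 <- radial_sucrose_config(sp6a_factor = 0.6)
  expect_equal(retrieval_rate(10, rs6, V),
               (0.6 * 0.148 * 10 / 20 + 0.117 * 10 / 11) * V)
  rs6b <- radial_sucrose_config(sp6a_factor = 0.6, sp6a_scales_retrieval = FALSE)
  expect_equal(retrieval_rate(10, rs6b, V), retrieval_rate(10, rs, V))
})

test_that("apoplast pool: fixed point of the scalar balance", {
  rs <- radial_sucrose_config(apoplast_removal_rate = 0.5)
  V <- 1e-9; c_ph <- 300
  ## steady apoplast content: efflux = retrieval + removal
  g <- function(S) apoplast_derivative(c_ph, S, rs, V)$dS_apo
  S_star <- uniroot(g, c(0, 1e-3), tol = 1e-25)$root
  d <- apoplast_derivative(c_ph, S_star, rs, V)
  expect_lt(abs(d$dS_apo), 1e-15 * d$efflux)
  c_apo_star <- S_star / (rs$apoplast_volume_fraction * V)
  expect_equal(d$efflux - d$retrieval, 0.5 * c_apo_star * V,
               tolerance = 1e-10)
  ## no removal: retrieval alone balances efflux at a higher pool
  rs0 <- radial_sucrose_config(apoplast_removal_rate = 0)
  S0 <- uniroot(function(S) apoplast_derivative(c_ph, S, rs0, V)$dS_apo,
                c(0, 1e-2), tol = 1e-25)$root
  expect_gt(S0, S_star)
})

test_that("closed system (no removal) conserves total sucrose through the apoplast", {
  rs <- radial_sucrose_config(apoplast_removal_rate = 0)
  cfg <- small_two_sink(radial_sucrose = rs, hydraulic_mode = "xylem_coupled")
  st <- initial_state(cfg, c_init = 300)
  st$S_apo <- st$S_apo + 1e-12
  d <- time_derivatives(st, cfg, detail = TRUE)
  expect_equal(sum(d$derivatives$S_Ph) + sum(d$derivatives$S_apo),
               sum(d$loading) - sum(d$unloading), tolerance = 1e-12)
})

test_that("exchange is restricted to the long-distance pathway zones", {
  cfg <- small_two_sink(radial_sucrose = radial_sucrose_config(),
                        hydraulic_mode = "xylem_coupled")
  st <- initial_state(cfg, c_init = 300)
  d <- time_derivatives(st, cfg, detail = TRUE)
  zone <- derived_fields(st, cfg)$zone
  expect_true(all(d$JSrad[zone %in% c("source", "sink_1", "sink_2")] == 0))
  expect_true(any(d$JSrad[grepl("^pathway", zone)] != 0))
  ## uniform concentration: efflux per metre is uniform along the pathways
  eff <- d$radial$efflux
  len <- derived_fields(st, cfg)$length[grepl("^pathway", zone)]
  expect_equal(sd(eff / len) / mean(eff / len), 0, tolerance = 1e-12)
})

test_that("net efflux fraction: off means zero, on lies in (0, 1), longer branch leaks more", {
  cfg0 <- small_two_sink(hydraulic_mode = "xylem_coupled")
  cfg0$sinks[[2]]$water_boundary <- wb_soil_coupled(1)
  r0 <- integrate_to_steady_state(cfg0, v0 = 4e-9)
  expect_equal(net_efflux_fraction(r0), 0)
  cfg <- scenario_config(sinks = list(sink_spec(5e-9, 75, 0.1, wb_evaporating(0.1)),
                                      sink_spec(5e-9, 75, 0.3, wb_soil_coupled(1))),
                         mesh = small_mesh(), hydraulic_mode = "xylem_coupled",
                         radial_sucrose = radial_sucrose_config(),
                         name = "test_efflux")
  r <- integrate_to_steady_state(cfg, v0 = 2e-9)
  expect_true(r$converged)
  fr <- net_efflux_fraction(r)
  expect_gt(fr, 0); expect_lt(fr, 1)
  ## per-branch leakage: the 0.3 m branch exports more than the 0.1 m branch
  d <- time_derivatives(r$state, cfg, detail = TRUE)
  zone <- r$fields$zone[grepl("^pathway", r$fields$zone)]
  net <- d$radial$efflux - d$radial$retrieval
  expect_gt(sum(net[zone == "pathway_2"]), sum(net[zone == "pathway_1"]))
})

test_that("steady state is insensitive to the apoplast volume fraction", {
  base <- scenario_config(sinks = list(sink_spec(5e-9, 75, 0.1, wb_evaporating(0.1)),
                                       sink_spec(5e-9, 75, 0.3, wb_soil_coupled(1))),
                          mesh = small_mesh(), hydraulic_mode = "xylem_coupled",
                          radial_sucrose = radial_sucrose_config(apoplast_volume_fraction = 0.05),
                          name = "apo_a")
  alt <- base
  alt$radial_sucrose$apoplast_volume_fraction <- 0.2
  a <- integrate_to_steady_state(base, v0 = 2e-9)
  b <- integrate_to_steady_state(alt, v0 = 2e-9)
  expect_equal(a$PC1, b$PC1, tolerance = 1e-6)
  expect_equal(net_efflux_fraction(a), net_efflux_fraction(b), tolerance = 1e-6)
})
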