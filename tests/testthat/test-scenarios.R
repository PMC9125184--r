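## Scenario drivers on reduced meshes / coarse grids; the full-size
## reproductions live in test-acceptance.R.

test_that("model comparison table is tidy and reproduces the three regimes", {
  cfg <- small_two_sink(v_max = c(22.5e-9, 2.5e-9))
  cfg$name <- "vmax_small"
  grid <- loading_grid(4, c(0.5e-9, 20e-9))
  tab <- run_model_comparison(cfg, grid = grid)
  expect_setequal(unique(tab$model), c("vk", "vkr", "biophysical"))
  expect_equal(nrow(tab), 12)
  expect_true(all(tab$status == "ok"))
  expect_equal(tab$PC1[tab$model == "vk"], rep(0.9, 4), tolerance = 1e-12)
  vkr <- tab$PC1[tab$model == "vkr"]; bio <- tab$PC1[tab$model == "biophysical"]
  expect_true(all(diff(vkr) > 0))
  expect_true(all(diff(bio) > 0))
  ## rows at/above capacity are flagged but kept
  tab2 <- run_model_comparison(cfg, grid = c(1e-9, 26e-9), models = "biophysical")
  expect_match(tab2$status[2], "no steady state")
})

test_that("xylem sweep returns monotone partitioning and endpoint profiles", {
  cfg <- preset_scenario("xylem_sweep")
  cfg$mesh <- small_mesh()
  sw <- run_xylem_sweep(flux_grid = c(-1e-8, 0.5e-8, 2e-8),
                        loading_rates = 2.5e-9, config = cfg)
  expect_true(all(sw$pc$converged))
  expect_true(all(diff(sw$pc$PC1) < 0))                 # less uptake, more sugar
  expect_equal(sw$pc$PC1[sw$pc$sink1_flux == 2e-8], 0.5, tolerance = 5e-3)
  expect_true(!is.null(sw$profiles))
  ## evaporating endpoint reverses the xylem gradient along branch 1
  pr <- sw$profiles[sw$profiles$sink1_flux == -1e-8, ]
  b1 <- pr[pr$zone == "pathway_1", ]
  b2 <- pr[pr$zone == "pathway_2", ]
  expect_gt(sum(diff(b2$psi_x) > 0), 0)   # toward the root sink potential rises
  expect_gt(sum(diff(b1$psi_x) < 0), 0)   # toward the evaporating sink it falls
})

test_that("single-sink gradient study: steeper loading widens the lumped-model gap", {
  cfg <- preset_scenario("single_sink")
  cfg$mesh <- small_mesh()
  g <- run_single_sink_gradient(config = cfg)
  s <- g$summary
  expect_equal(nrow(s), 3)
  expect_true(all(s$mean_c_spatial > s$mean_c_linear))
  expect_true(all(s$mean_r_spatial > s$mean_r_linear))
  gap <- s$mean_c_spatial - s$mean_c_linear
  expect_gt(gap[s$v_load == 10e-9 & s$v_max_un == 25e-9],
            gap[s$v_load == 1e-9 & s$v_max_un == 25e-9])
  ## concentration falls monotonically from source to sink along the pathway
  pr <- g$profiles[g$profiles$run == 2 & grepl("pathway", g$profiles$zone), ]
  expect_true(all(diff(pr$c_ph) < 0))
})

test_that("factorial driver keys cells correctly and finds the zero-partitioning regime", {
  tab <- run_efflux_sp6a_factorial(grid = c(0.25e-9, 2e-9, 6e-9),
                                   conditions = "length_xylem",
                                   efflux = TRUE, sp6a = 1, tuber_vmax = 5e-9)
  expect_equal(nrow(tab), 3)
  expect_true(all(tab$converged))
  expect_true(all(tab$PC_tuber >= 0 & tab$PC_tuber <= 1))
  expect_true(all(tab$efflux_fraction > 0))
  zb <- zero_partitioning_regime(tab)
  expect_equal(nrow(zb), 1)
  expect_true(is.na(zb$v0_boundary) || zb$v0_boundary %in% tab$v0_nominal)
})

test_that("step response: zero step is flat; end point matches an independent solve", {
  cfg <- small_two_sink()
  flat <- run_step_response(cfg, v0 = 10e-9, step = list(sink = 1, v_max_factor = 1),
                            t_grid = seq(0, 600, by = 60))
  expect_true(is.na(flat$t90))
  expect_lt(diff(range(flat$series$PC1)), 1e-6)
  sr <- run_step_response(cfg, v0 = 10e-9, step = list(sink = 1, v_max_factor = 0.5),
                          t_grid = seq(0, 3600, by = 30))
  expect_equal(sr$pc_post, sr$pc_post_independent, tolerance = 1e-3)
  expect_true(sr$t90 > 0)
  ## the instantaneous jump reflects the scaled kinetics at frozen state
  expect_equal(sr$pc_jump, (0.5 * 12.5) / (0.5 * 12.5 + 12.5), tolerance = 1e-6)
  ## stepping the combined capacity below the loading rate is rejected
  cfg2 <- small_two_sink(v_max = c(12.5e-9, 2.5e-9))
  expect_error(run_step_response(cfg2, v0 = 10e-9,
                                 step = list(sink = 1, v_max_factor = 0.5)),
               "capacity")
})
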