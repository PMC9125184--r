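test_that("VK closed form: equal affinities give c = K v0 / (sum vmax - v0)", {
  s <- vk_solve(12.5e-9, list(v_max = c(12.5e-9, 12.5e-9), K_m = c(75, 75)))
  expect_equal(s$c, 75)
  expect_equal(s$v1 + s$v2, 12.5e-9, tolerance = 1e-12)
  ## unequal affinities: the root must satisfy the defining equation
  s2 <- vk_solve(24.9e-9, list(v_max = c(12.5e-9, 12.5e-9), K_m = c(75, 750)))
  g <- 12.5e-9 * s2$c / (s2$c + 75) + 12.5e-9 * s2$c / (s2$c + 750)
  expect_equal(g, 24.9e-9, tolerance = 1e-10)
})

test_that("VK partitioning equals the v_max ratio, independent of loading", {
  sinks <- list(v_max = c(22.5e-9, 2.5e-9), K_m = c(75, 75))
  for (v0 in c(0.025e-9, 2.5e-9, 12.5e-9, 24e-9))
    expect_equal(vk_solve(v0, sinks)$PC1, 0.9, tolerance = 1e-12)
  ## symmetric sinks split evenly
  expect_equal(vk_solve(5e-9, list(v_max = c(1e-8, 1e-8), K_m = c(75, 75)))$PC1, 0.5)
})

test_that("VK rejects loading at or above total sink capacity", {
  sinks <- list(v_max = c(22.5e-9, 2.5e-9), K_m = c(75, 75))
  expect_error(vk_solve(25e-9, sinks), "no steady state")
  expect_error(vk_solve(30e-9, sinks), "no steady state")
})

test_that("viscosity polynomial evaluates as printed and warns outside 0-1.5 M", {
  expect_equal(vkr_resistance(0, 7.5e12, warn = FALSE), 0.3396 * 7.5e12)
  expect_equal(vkr_resistance(1, 1, warn = FALSE), 1.0711)
  ## direct evaluation: 0.685*1.5^4 - 1.0411*1.5^3 + 0.9512*1.5^2
  ##                     + 0.1364*1.5 + 0.3396 = 2.6385
  expect_equal(vkr_resistance(1.5, 1, warn = FALSE), 2.6385, tolerance = 1e-9)
  expect_warning(vkr_resistance(2, 1), "validity")
  ## clamp policy freezes the polynomial at the validity edge
  expect_equal(suppressWarnings(vkr_resistance(3, 1, policy = "clamp")),
               vkr_resistance(1.5, 1, warn = FALSE))
})

test_that("VKR solution: symmetry, conservation and positive roots", {
  sinks <- list(v_max = c(12.5e-9, 12.5e-9), K_m = c(75, 75))
  s <- vkr_solve(10e-9, sinks, c(7.5e12, 7.5e12))
  expect_equal(s$PC1, 0.5, tolerance = 1e-10)
  expect_equal(s$c1, s$c2, tolerance = 1e-8)
  set.seed(7)
  for (k in 1:5) {
    vmax <- runif(2, 2e-9, 30e-9); K <- runif(2, 20, 600)
    rref <- 10^runif(2, 12, 13.5)
    v0 <- runif(1, 0.05, 0.9) * sum(vmax)
    s <- suppressWarnings(vkr_solve(v0, list(v_max = vmax, K_m = K), rref))
    expect_gt(s$c0, 0); expect_gt(s$c1, 0); expect_gt(s$c2, 0)
    expect_lt(abs(s$v1 + s$v2 - v0) / v0, 1e-10)
    expect_lt(s$residual, 1e-13)
  }
})

test_that("VKR agrees with the brute-force grid-search oracle", {
  set.seed(11)
  for (k in 1:3) {
    vmax <- runif(2, 2e-9, 25e-9); K <- runif(2, 30, 400)
    rref <- 10^runif(2, 12, 13.2)
    v0 <- runif(1, 0.1, 0.7) * sum(vmax)
    s <- suppressWarnings(vkr_solve(v0, list(v_max = vmax, K_m = K), rref))
    o <- vkr_grid_oracle(v0, vmax, K, rref)
    expect_equal(s$c0, o$c0, tolerance = 1e-4)
    expect_equal(s$PC1, o$PC1, tolerance = 1e-4)
  }
})

test_that("VKR reduces to VK as the reference resistances vanish", {
  sinks <- list(v_max = c(22.5e-9, 2.5e-9), K_m = c(75, 75))
  for (v0 in c(0.5e-9, 5e-9, 20e-9)) {
    pc_vk <- vk_solve(v0, sinks)$PC1
    pc_vkr <- vkr_solve(v0, sinks, c(7.5e12, 7.5e12) * 1e-6)$PC1
    expect_lt(abs(pc_vkr - pc_vk), 1e-3)
  }
})

test_that("VKR without clamping has no root near capacity in the resistance scenario", {
  ## literal evaluation of the quartic beyond 1.5 M makes resistance blow
  ## up, capping attainable total unloading below v0
  sinks <- list(v_max = c(12.5e-9, 12.5e-9), K_m = c(75, 75))
  expect_error(suppressWarnings(
    vkr_solve(24.5e-9, sinks, c(7.5e12, 1.5e14), out_of_validity = "evaluate")),
    "no root|no biologically valid root")
  s <- suppressWarnings(vkr_solve(24.5e-9, sinks, c(7.5e12, 1.5e14),
                                  out_of_validity = "clamp"))
  expect_equal(s$PC1, 0.5, tolerance = 0.01)
})

test_that("lumped_scan is tidy, flags failures, and matches its models", {
  cfg <- preset_scenario("vmax")
  expect_equal(nrow(lumped_scan("vk", numeric(0), cfg)), 0)
  grid <- loading_grid(6, c(0.1e-9, 20e-9))
  vk <- lumped_scan("vk", grid, cfg)
  expect_equal(vk$PC1, rep(0.9, nrow(vk)), tolerance = 1e-12)
  vkr <- lumped_scan("vkr", grid, cfg)
  expect_true(all(vkr$status == "ok"))
  expect_true(all(diff(vkr$PC1) > 0))          # saturating rise toward 0.9
  expect_true(all(vkr$PC1 <= 0.9 + 1e-12))     # weakest-sink prioritization
  expect_true(all(vkr$c0 > vkr$c1 & vkr$c0 > vkr$c2))
  ## rows beyond capacity are flagged, not fatal
  bad <- lumped_scan("vk", c(1e-9, 30e-9), cfg)
  expect_equal(bad$status[1], "ok")
  expect_match(bad$status[2], "no steady state")
  expect_true(is.na(bad$PC1[2]))
})
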