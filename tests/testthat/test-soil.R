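test_that("texture lookup fills the packaged hydraulic constants", {
  m <- montcalm$compartments
  expect_true(all(m$theta_fc == 0.22))
  expect_true(all(m$theta_sat == 0.41))
  expect_true(all(m$theta_wp == 0.10))
  expect_true(all(m$theta_ad == 0.05))
  k <- mecosta$compartments
  expect_true(all(k$theta_fc == 0.16))
  expect_true(all(k$theta_wp == 0.08))
  expect_gte(montcalm$depth, 0.47)
  expect_error(
    soil_profile(data.frame(top_m = 0, bottom_m = 0.45,
                            texture = "clay loam")),
    "unknown texture")
})

test_that("profile construction validates layer geometry", {
  expect_error(
    soil_profile(data.frame(top_m = 0.1, bottom_m = 0.45,
                            texture = "sandy loam")),
    "start at depth 0")
  expect_error(
    soil_profile(data.frame(top_m = c(0, 0.3), bottom_m = c(0.15, 0.45),
                            texture = "sandy loam")),
    "contiguous")
})

test_that("root-zone water depth matches the closed form", {
  p <- sandy_loam_profile()
  expect_equal(root_zone_water(rep(0.20, 12), p, zr = 0.47), 94.0,
               tolerance = 1e-12)
  expect_equal(root_zone_water(rep(0.25, 12), p, zr = 0.40),
               1000 * 0.25 * 0.40, tolerance = 1e-12)
  # gravel correction
  pg <- soil_profile(data.frame(top_m = 0, bottom_m = 0.6,
                                texture = "sandy loam", gravel_pct = 10))
  expect_equal(root_zone_water(rep(0.25, 12), pg, zr = 0.40), 90.0,
               tolerance = 1e-12)
  expect_error(root_zone_water(rep(0.2, 12), p, zr = 1.2), "profile depth")
  # monotone in water content and in depth at uniform theta
  expect_gt(root_zone_water(rep(0.22, 12), p, 0.47),
            root_zone_water(rep(0.20, 12), p, 0.47))
  expect_gt(root_zone_water(rep(0.2, 12), p, 0.47),
            root_zone_water(rep(0.2, 12), p, 0.30))
})

test_that("single-day water balance matches the frozen hand ledger", {
  # 3 compartments of 0.05 m at theta 0.40, 60 mm inflow, tau 0.5:
  # values computed by independent bucket bookkeeping before the build
  p <- sandy_loam_profile(depth_m = 0.15)
  out <- step_water_balance(rep(0.40, 3), p, water_in = 60,
                            e_demand = 0, tr_demand = 0, zr = 0.15)
  expect_equal(out$theta, c(0.315, 0.3625, 0.38625), tolerance = 1e-12)
  expect_equal(out$fluxes$runoff, 58.5, tolerance = 1e-12)
  expect_equal(out$fluxes$drainage, 8.3125, tolerance = 1e-12)
})

test_that("bucket filling below field capacity stores all inflow", {
  p <- sandy_loam_profile()
  th0 <- initial_water_state(p, 0.15)
  out <- step_water_balance(th0, p, 10, 0, 0, zr = 0.47)
  stored <- sum(out$theta * 0.05 * 1000) - sum(th0 * 0.05 * 1000)
  expect_equal(stored, 10, tolerance = 1e-9)
  expect_equal(out$fluxes$runoff, 0)
  expect_equal(out$fluxes$drainage, 0)
  # zero inputs leave the state untouched
  idle <- step_water_balance(th0, p, 0, 0, 0, zr = 0.47)
  expect_equal(idle$theta, th0)
  expect_equal(unlist(idle$fluxes), c(runoff = 0, drainage = 0,
                                      evaporation = 0, transpiration = 0))
})

test_that("extraction floors hold: wilting point for roots, air-dry for evaporation", {
  p <- sandy_loam_profile()
  th <- initial_water_state(p, "fc")
  for (i in 1:40) {
    out <- step_water_balance(th, p, 0, e_demand = 6, tr_demand = 8,
                              zr = 0.47)
    th <- out$theta
  }
  comp <- p$compartments
  expect_true(all(th <= comp$theta_sat + 1e-12))
  expect_true(all(th >= comp$theta_ad - 1e-12))
  # below the evaporation layer nothing dips under wilting point
  deep <- comp$top >= 0.05
  expect_true(all(th[deep] >= comp$theta_wp[deep] - 1e-12))
})

test_that("invalid inputs are rejected", {
  p <- sandy_loam_profile()
  th <- initial_water_state(p, "fc")
  expect_error(step_water_balance(th, p, -1, 0, 0, 0.47), ">= 0")
  expect_error(step_water_balance(th, p, 0, 0, 5, 0.47,
                                  weights = c(0.5, 0.5, 0.2, 0.1)),
               "sum to 1")
})
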