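test_that("thermal time applies the base and upper caps", {
  expect_equal(thermal_time(26, 14), 18)
  expect_equal(thermal_time(40, 30), 24)   # mean capped at t_upper
  expect_equal(thermal_time(2, 0), 0)      # at base temperature
  expect_equal(thermal_time(1, -5), 0)     # never negative
})

test_that("stress coefficient follows the convex closed form", {
  expect_equal(stress_coefficient(0, 3), 1)
  expect_equal(stress_coefficient(1, 3), 0)
  # frozen independent evaluation at the midpoint
  expect_equal(stress_coefficient(0.5, 3), 0.8175744761936437,
               tolerance = 1e-15)
  expect_error(stress_coefficient(0.5, -1), "shape")
})

test_that("stress coefficient is 1 below, 0 above, strictly decreasing between", {
  set.seed(42)
  for (i in 1:25) {
    p_up <- runif(1, 0, 0.6)
    p_lo <- runif(1, p_up + 0.1, 1)
    shape <- runif(1, 0.5, 6)
    d <- seq(0, 1.2, by = 0.01)
    ks <- stress_coefficient(relative_depletion(d, p_up, p_lo), shape)
    expect_true(all(ks[d <= p_up] == 1))
    expect_true(all(ks[d >= p_lo] == 0))
    mid <- ks[d > p_up & d < p_lo]
    if (length(mid) > 1) expect_true(all(diff(mid) < 0))
    # agreement with an independent direct evaluation
    dr <- pmin(pmax((d - p_up) / (p_lo - p_up), 0), 1)
    expect_lt(max(abs(ks - (1 - (exp(dr * shape) - 1) / (exp(shape) - 1)))),
              1e-12)
  }
})

test_that("canopy growth curve hits its anchors", {
  p <- default_params
  expect_equal(canopy_cover_growth(0, p), 0.6)                 # initial cover
  expect_equal(canopy_cover_growth(100, p), 3.6297884786477677,
               tolerance = 1e-12)                              # 0.6 * e^1.8
  expect_equal(canopy_cover_growth(1e4, p), 92.0)              # plateau
  # continuity at the half-cover crossover
  tau_half <- log((p$ccx / 2) / p$cc0) / p$cgc
  expect_equal(canopy_cover_growth(tau_half - 1e-9, p),
               canopy_cover_growth(tau_half + 1e-9, p), tolerance = 1e-6)
})

test_that("canopy step grows to the maximum and dies after vine kill", {
  p <- default_params
  ca <- default_calendar
  st <- crop_state(p)
  cc_series <- numeric(ca$harvest)
  for (dap in 1:ca$harvest) {
    st <- canopy_step(st, p, ca, dap, gdd_today = 17)
    cc_series[dap] <- st$cc
  }
  expect_true(all(cc_series[1:(ca$emergence - 1)] == 0))
  expect_equal(cc_series[ca$emergence], p$cc0)
  expect_equal(max(cc_series), p$ccx, tolerance = 1e-6)
  expect_true(all(cc_series <= p$ccx + 1e-9))
  expect_true(all(cc_series[(ca$vine_kill + 3):ca$harvest] == 0))
  # unstressed growth closes the canopy before tuber initiation ends
  expect_gt(cc_series[ca$early_bulk], 0.95 * p$ccx)
  # senescence starts the decline before vine kill
  expect_lt(cc_series[ca$vine_kill - 1], max(cc_series))
})

test_that("expansion stress slows canopy growth", {
  p <- default_params
  ca <- default_calendar
  grow <- function(ks) {
    st <- crop_state(p)
    for (dap in 1:45) st <- canopy_step(st, p, ca, dap, 17, ks_exp = ks)
    st$cc
  }
  expect_gt(grow(1), grow(0.5))
  expect_equal(grow(0), p$cc0)  # no expansion at full stress
})

test_that("root deepening follows the power curve between emergence and mid bulk", {
  ca <- default_calendar
  expect_equal(root_deepening(10, ca), 0.15)
  expect_equal(root_deepening(71, ca), 0.47)
  expect_equal(root_deepening(135, ca), 0.47)
  mid <- ca$emergence + (ca$mid_bulk - ca$emergence) / 2
  expect_equal(root_deepening(mid, ca), 0.26313708498984756,
               tolerance = 1e-12)
})

test_that("transpiration and evaporation demands partition with canopy cover", {
  p <- default_params
  expect_equal(daily_demands(0, 5, p)$tr_demand, 0)
  expect_equal(daily_demands(50, 0, p)$tr_demand, 0)
  expect_equal(daily_demands(50, 0, p)$e_demand, 0)
  # full effective cover: transpiration demand is KcTr * ET0
  expect_equal(daily_demands(100, 5, p)$tr_demand, 5.5, tolerance = 1e-9)
  expect_equal(daily_demands(100, 5, p)$e_demand, 0, tolerance = 1e-9)
  # stress scales transpiration only
  d <- daily_demands(60, 5, p, ks_sto = 0.5)
  expect_equal(d$tr_demand, daily_demands(60, 5, p)$tr_demand * 0.5)
  expect_error(daily_demands(120, 5, p), "cc")
})

test_that("biomass accumulates linearly in normalized transpiration", {
  p <- default_params
  expect_equal(accumulate_biomass(100, 0, 5, p$wp), 100)
  expect_equal(accumulate_biomass(0, 4.75, 5, 19), 18.05, tolerance = 1e-12)
  # sum of tr/et0 = 60 gives wp * 60
  b <- 0
  for (i in 1:60) b <- accumulate_biomass(b, 3, 5, 19)
  expect_equal(b, 19 * 36, tolerance = 1e-9)
  expect_warning(accumulate_biomass(0, 1, 0, 19), "zero reference ET")
})

test_that("harvest index builds linearly and yield follows the harvest equation", {
  ca <- default_calendar
  expect_equal(harvest_index(20, ca, 0.75), 0)
  expect_equal(harvest_index(43, ca, 0.75), 0)
  expect_equal(harvest_index(112, ca, 0.75), 0.75)
  expect_equal(harvest_index(135, ca, 0.75), 0.75)
  # midway through the build window
  expect_equal(harvest_index(77, ca, 0.75), 0.3695652173913043,
               tolerance = 1e-12)
  expect_equal(harvest_yield(1000, 0.75), 7.5)
  expect_equal(harvest_yield(0, 0.75), 0)
  expect_equal(harvest_yield(1000, harvest_index(77, ca, 0.75)),
               0.75 * 34 / 69 * 1000 * 0.01, tolerance = 1e-9)
})
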