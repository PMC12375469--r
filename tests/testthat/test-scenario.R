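test_that("season classification applies the deviation band", {
  expect_identical(unname(classify_season(340)), "wet")
  expect_identical(unname(classify_season(250)), "dry")
  expect_identical(unname(classify_season(284.5)), "normal")
  # every total gets exactly one label
  totals <- seq(150, 450, by = 0.5)
  labels <- classify_season(totals)
  expect_true(all(labels %in% c("wet", "normal", "dry")))
  # boundaries: strictly-above / strictly-below semantics
  th <- season_class_thresholds(284.5, 0.10)
  expect_identical(unname(classify_season(th["wet"])), "normal")
  expect_identical(unname(classify_season(th["dry"])), "normal")
})

test_that("log response ratio is zero at control, ln 2 at doubling, antisymmetric", {
  expect_equal(lnrr(5, 5), 0)
  expect_equal(lnrr(10, 5), log(2), tolerance = 1e-15)
  set.seed(3)
  a <- runif(50, 0.1, 100)
  b <- runif(50, 0.1, 100)
  expect_equal(lnrr(a, b), -lnrr(b, a), tolerance = 1e-12)
  expect_error(lnrr(-1, 5), "positive")
})

test_that("quadrant labels match effect-size signs with ties to the win half", {
  expect_identical(quadrant_label(0.10, 0.05), "win-win")
  expect_identical(quadrant_label(-0.10, 0.20), "lose-win")
  expect_identical(quadrant_label(0.10, -0.05), "win-lose")
  expect_identical(quadrant_label(-0.10, -0.05), "lose-lose")
  expect_identical(quadrant_label(0, 0), "win-win")  # control at the origin
})

test_that("a season run is deterministic and internally consistent", {
  wx <- quick_season(seed = 31)
  a <- run_quick(wx, policy = fc_policy(0.5), trace = TRUE)
  b <- run_quick(wx, policy = fc_policy(0.5), trace = TRUE)
  expect_identical(a, b)
  tr <- a$trace
  # trace invariants: canopy within bounds, biomass and HI non-decreasing
  expect_true(all(tr$cc >= 0 & tr$cc <= default_params$ccx + 1e-9))
  expect_true(all(diff(tr$b) >= -1e-12))
  expect_true(all(diff(tr$hi) >= -1e-12))
  expect_true(all(tr$ks_sto >= 0 & tr$ks_sto <= 1))
  # yield never exceeds the harvest-index ceiling
  expect_lte(a$yield_t_ha,
             default_params$hi0 * a$biomass_g_m2 * 0.01 + 1e-9)
  # water productivity consistent with its components
  expect_equal(a$wpc_kg_m3,
               a$yield_t_ha * 1000 /
                 (10 * (a$rain_total_mm + a$irrigation_total_mm)),
               tolerance = 1e-12)
})

test_that("rainfed dry seasons yield less than irrigated ones", {
  wx <- quick_season(seed = 41, target = 0)
  rf <- run_quick(wx, policy = irrigation_policy("rainfed"))
  ir <- run_quick(wx, policy = fc_policy(0.5))
  expect_lt(rf$yield_t_ha, ir$yield_t_ha)
})

test_that("a fully watered season shows no stomatal stress days", {
  wx <- quick_season(seed = 43)
  full <- run_quick(wx, policy = irrigation_policy("full"), trace = TRUE)
  expect_identical(full$stress_days, 0L)
  expect_true(all(full$trace$ks_sto == 1))
})

test_that("the scenario grid enumerates and sorts deterministically", {
  years <- list(y1 = season_spec(target_rain_mm = 300, seed = 1),
                y2 = season_spec(target_rain_mm = 260, seed = 2))
  policies <- list(fc_policy(0.3), fc_policy(0.5), fc_policy(0.7))
  g <- run_grid(years, list(montcalm = montcalm), default_params,
                default_calendar, policies)
  # 2 years x 1 soil x (3 policies + rainfed)
  expect_identical(nrow(g$results), 8L)
  expect_setequal(unique(g$results$policy),
                  c("fc30", "fc50", "fc70", "rainfed"))
  # permuting the year list leaves the sorted table unchanged
  g2 <- run_grid(rev(years), list(montcalm = montcalm), default_params,
                 default_calendar, policies)
  expect_identical(g$results, g2$results)
  # rows are consistent with their event logs
  for (i in seq_len(nrow(g$results))) {
    r <- g$results[i, ]
    e <- g$events[g$events$year == r$year & g$events$policy == r$policy, ]
    expect_identical(as.integer(nrow(e)), as.integer(r$irrigation_count))
    expect_equal(sum(e$mm), r$irrigation_total_mm)
  }
})

test_that("the trade-off table references the control at the origin", {
  years <- lapply(1:3, function(s) season_spec(target_rain_mm = 280 + 10 * s,
                                               seed = s))
  names(years) <- paste0("y", 1:3)
  g <- run_grid(years, list(montcalm = montcalm), default_params,
                default_calendar,
                list(fc_policy(0.3), fc_policy(0.5), fc_policy(0.7)))
  tab <- tradeoff_table(g$results, control = "fc50", grouping = "all")
  ctrl <- tab[tab$policy == "fc50", ]
  expect_equal(ctrl$lnrr_yield, 0)
  expect_equal(ctrl$lnrr_wpc, 0)
  expect_identical(ctrl$quadrant, "win-win")
  expect_true(all(tab$quadrant %in%
                    c("win-win", "win-lose", "lose-win", "lose-lose")))
  expect_error(tradeoff_table(g$results, control = "fc55"), "control")
})

test_that("stage correlations reproduce hand arithmetic and flag degenerate cells", {
  # direct closed-form check of the correlation used in the heat map
  x <- c(10, 20, 30)
  y <- c(2, 1, 6)
  expect_equal(stats::cor(x, y), 0.7559289460184545, tolerance = 1e-12)

  years <- lapply(1:4, function(s) season_spec(target_rain_mm = 240 + 25 * s,
                                               seed = 100 + s))
  names(years) <- paste0("y", 1:4)
  g <- run_grid(years, list(montcalm = montcalm), default_params,
                default_calendar, list(fc_policy(0.5), fc_policy(0.8)))
  sc <- stage_correlation_matrix(g, default_calendar)
  expect_true(all(is.na(sc$r["rainfed", ])))  # zero-variance cells flagged
  defined <- sc$r[!is.na(sc$r)]
  expect_true(all(defined >= -1 & defined <= 1))
  expect_identical(colnames(sc$r), stage_windows(default_calendar)$stage)
  # fewer than 3 years is refused
  g2 <- list(results = g$results[g$results$year %in% c("y1", "y2"), ],
             events = g$events)
  expect_error(stage_correlation_matrix(g2, default_calendar), "3 years")
})

test_that("packaged fixtures load with the calibrated values", {
  pp <- load_fixture("potato_2023")
  expect_equal(pp$hi0, 0.75)
  expect_equal(pp$wp, 19.0)
  expect_equal(pp$kctr, 1.10)
  expect_equal(pp$ccx, 92.0)
  expect_equal(pp$extraction, c(0.40, 0.30, 0.20, 0.10))
  ca <- load_fixture("calendar_2023")
  expect_identical(ca$tuber_init, 43L)
  expect_identical(ca$harvest, 135L)
  ss <- load_fixture("season_2023like")
  expect_equal(ss$target_rain_mm, 312.8)
  expect_error(load_fixture("nonesuch"), "unknown fixture")
})
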