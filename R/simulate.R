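# The daily season loop tying weather, soil, crop and irrigation together.

#' Simulate one growing season
#'
#' Runs the daily loop over a weather series: thermal time and root
#' deepening; infiltration of rain; the irrigation decision on the
#' post-rain water state; infiltration of the irrigation dose; cascade
#' drainage; stress coefficients from root-zone depletion; evaporation and
#' transpiration demands from the current canopy; extraction; canopy
#' advance (expansion scaled by the expansion stress, early senescence
#' after sustained severe depletion, vine-kill forcing); harvest-index
#' build and water-driven biomass accumulation.  The run is deterministic
#' given its inputs and closes the water balance every day.
#'
#' @param weather a `weather_series` data.frame covering at least the
#'   calendar's harvest day, with `et0_mm` populated.
#' @param profile a [soil_profile()].
#' @param params a [crop_params()].
#' @param calendar a [crop_calendar()].
#' @param policy an [irrigation_policy()].
#' @param initial_theta initial water state (see [initial_water_state()]).
#' @param trace if `TRUE`, attach the full daily trace.
#' @return An object of class `season_result`: yields (dry-matter and
#'   fresh-mass t ha-1), final biomass, the irrigation log and totals,
#'   season rainfall, crop water productivity (dry-matter basis), the
#'   count of stomatal-stress days, and optionally the daily `trace`
#'   data.frame (water state, fluxes, canopy, stress, biomass).
#' @examples
#' wx <- synthesize_season(season_spec(target_rain_mm = 284.5, seed = 11))
#' soil <- load_fixture("montcalm")
#' res <- run_season(wx, soil, crop_params(), crop_calendar(),
#'                   irrigation_policy("threshold", threshold = 0.5))
#' res$yield_t_ha
#' @export
run_season <- function(weather, profile, params, calendar, policy,
                       initial_theta = "fc", trace = FALSE) {
  n <- calendar$harvest
  if (nrow(weather) < n) stop("weather series shorter than the season")
  stopifnot(inherits(profile, "soil_profile"),
            inherits(params, "crop_params"),
            inherits(calendar, "crop_calendar"),
            inherits(policy, "irrigation_policy"))
  if (!"et0_mm" %in% names(weather)) stop("weather must include et0_mm")
  comp <- profile$compartments
  theta <- initial_water_state(profile, initial_theta)
  state <- crop_state(params)
  events <- list()
  last_event <- -Inf
  stress_days <- 0L

  tr_rows <- if (trace) vector("list", n) else NULL

  for (dap in seq_len(n)) {
    day <- weather[dap, ]
    gdd <- thermal_time(day$tmax_c, day$tmin_c, params$t_base, params$t_upper)
    state$zr <- max(root_deepening(dap, calendar, params$zr_min, params$zr_max),
                    params$zr_min)
    w_before <- profile_water(theta, profile)

    # rain in, then the irrigation decision on the post-rain state
    s_rain <- infiltrate(theta, profile, day$rain_mm)
    irr <- decide_irrigation(s_rain$theta, profile, state$zr, policy, dap,
                             last_event, start_dap_default = calendar$emergence,
                             et0 = day$et0_mm)
    if (irr > 0) {
      events[[length(events) + 1L]] <- c(dap = dap, mm = irr)
      last_event <- dap
    }
    s_irr <- infiltrate(s_rain$theta, profile, irr)
    s_drn <- drain_cascade(s_irr$theta, profile)
    theta <- s_drn$theta
    runoff <- s_rain$runoff + s_irr$runoff

    # stress from root-zone depletion
    tb <- rootzone_mean(theta, profile, state$zr)
    fcb <- rootzone_mean(comp$theta_fc, profile, state$zr)
    wpb <- rootzone_mean(comp$theta_wp, profile, state$zr)
    depl <- clip((fcb - tb) / (fcb - wpb), 0, Inf)
    ks_exp <- stress_coefficient(
      relative_depletion(depl, params$p_exp_upper, params$p_exp_lower),
      params$shape_exp)
    ks_sto <- stress_coefficient(
      relative_depletion(depl, params$p_sto_upper, 1), params$shape_sto)
    if (ks_sto < 1) stress_days <- stress_days + 1L
    kr <- kr_coefficient(theta, profile)

    # demands from the current canopy, then extraction
    dem <- daily_demands(state$cc, day$et0_mm, params, ks_sto = ks_sto, kr = kr)
    s_e <- extract_evaporation(theta, profile, dem$e_demand)
    s_t <- extract_transpiration(s_e$theta, profile, dem$tr_demand, state$zr,
                                 params$extraction)
    theta <- s_t$theta
    evap <- s_e$evaporation
    transp <- s_t$transpiration

    # canopy, harvest index, biomass
    state <- canopy_step(state, params, calendar, dap, gdd,
                         ks_exp = ks_exp,
                         sen_stressed = depl >= params$p_sen_upper)
    state$hi <- harvest_index(dap, calendar, params$hi0)
    state$b <- accumulate_biomass(state$b, transp, day$et0_mm, params$wp)

    if (trace) {
      tr_rows[[dap]] <- data.frame(
        dap = dap, rain = day$rain_mm, irrigation = irr, runoff = runoff,
        drainage = s_drn$drainage, evaporation = evap, transpiration = transp,
        et0 = day$et0_mm, w_profile = profile_water(theta, profile),
        w_change = profile_water(theta, profile) - w_before,
        theta_rz = tb, depletion = depl, ks_exp = ks_exp, ks_sto = ks_sto,
        kr = kr, cc = state$cc, zr = state$zr, b = state$b, hi = state$hi)
    }
  }

  log <- if (length(events)) {
    as.data.frame(do.call(rbind, events))
  } else data.frame(dap = integer(), mm = numeric())
  summ <- summarize_log(log)
  rain_total <- sum(weather$rain_mm[seq_len(n)])
  yield <- harvest_yield(state$b, state$hi, params$f_hi)
  wpc <- if (rain_total + summ$total_mm > 0 && yield > 0) {
    crop_water_productivity(yield * 1000, rain_total, summ$total_mm)$wpc_kg_m3
  } else 0

  structure(list(
    yield_t_ha = yield,
    yield_fresh_t_ha = yield / params$dry_matter_fraction,
    biomass_g_m2 = state$b, hi = state$hi,
    irrigation_log = log, irrigation_count = summ$count,
    irrigation_total_mm = summ$total_mm,
    rain_total_mm = rain_total, wpc_kg_m3 = wpc,
    stress_days = stress_days, policy = policy$name,
    theta_final = theta,
    trace = if (trace) do.call(rbind, tr_rows) else NULL
  ), class = "season_result")
}

#' @export
print.season_result <- function(x, ...) {
  cat(sprintf(
    "season [%s]: yield %.2f t/ha (dry), %d irrigation events (%.1f mm), rain %.1f mm, WPc %.2f kg/m3\n",
    x$policy, x$yield_t_ha, x$irrigation_count, x$irrigation_total_mm,
    x$rain_total_mm, x$wpc_kg_m3))
  invisible(x)
}
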