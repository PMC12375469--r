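# Potato crop parameterization and calendar.  Defaults are the calibrated
# values for the packaged potato parameter set; canopy growth/decay
# coefficients are expressed per growing-degree-day (base 2 C, cap 26 C),
# which closes the canopy three to four weeks after emergence, consistent
# with the prescribed phenology.

#' Crop parameters
#'
#' All tunable parameters of the crop engine with the packaged potato
#' defaults.  Canopy covers are in percent; `cgc`/`cdc` are fractional
#' rates per growing degree day; thresholds `p_*` are depletion fractions
#' of total available water in the root zone.
#'
#' @param cc0 initial canopy cover at emergence, percent.
#' @param ccx maximum canopy cover, percent.
#' @param cgc canopy growth coefficient, per degree-day.
#' @param cdc canopy decline coefficient, per degree-day.
#' @param t_base,t_upper base and upper temperature for thermal time, C.
#' @param zr_min,zr_max minimum (at emergence) and maximum effective
#'   rooting depth, m.
#' @param kctr crop transpiration coefficient at full canopy.
#' @param hi0 reference harvest index (fraction).
#' @param wp normalized water productivity, g m-2.
#' @param extraction root water extraction weights over root-zone quarters.
#' @param p_exp_upper,p_exp_lower depletion thresholds for canopy
#'   expansion stress.
#' @param shape_exp,shape_sto,shape_sen stress-curve shape factors.
#' @param p_sto_upper depletion threshold for stomatal closure (lower
#'   threshold is full depletion).
#' @param p_sen_upper depletion threshold for early canopy senescence.
#' @param sen_trigger_days consecutive days at or beyond `p_sen_upper`
#'   that trigger early senescence.
#' @param ks_cold cold-stress coefficient on transpiration (fixed 1).
#' @param f_hi harvest-index stress multiplier (fixed 1).
#' @param ke_max soil-evaporation coefficient ceiling.
#' @param dry_matter_fraction tuber dry-matter fraction used only for the
#'   optional fresh-mass conversion of yields.
#' @return An object of class `crop_params`.
#' @export
crop_params <- function(cc0 = 0.6, ccx = 92.0, cgc = 0.018, cdc = 0.008,
                        t_base = 2.0, t_upper = 26.0,
                        zr_min = 0.15, zr_max = 0.47,
                        kctr = 1.10, hi0 = 0.75, wp = 19.0,
                        extraction = c(0.40, 0.30, 0.20, 0.10),
                        p_exp_upper = 0.26, p_exp_lower = 0.66,
                        shape_exp = 3.0,
                        p_sto_upper = 0.65, shape_sto = 3.0,
                        p_sen_upper = 0.69, shape_sen = 3.0,
                        sen_trigger_days = 5L,
                        ks_cold = 1.0, f_hi = 1.0, ke_max = 1.10,
                        dry_matter_fraction = 0.20) {
  stopifnot(0 < cc0, cc0 < ccx, ccx <= 100, cgc > 0, cdc > 0,
            0 <= hi0, hi0 <= 1, zr_min > 0, zr_min <= zr_max,
            abs(sum(extraction) - 1) < 1e-9,
            0 <= p_exp_upper, p_exp_upper < p_exp_lower, p_exp_lower <= 1,
            shape_exp > 0, shape_sto > 0, shape_sen > 0)
  structure(as.list(environment()), class = "crop_params")
}

#' Crop developmental calendar in days after planting
#'
#' @param emergence,tuber_init,early_bulk,mid_bulk,late_bulk,senescence,vine_kill,harvest
#'   stage onset days after planting (strictly increasing); `harvest` is
#'   the season length.
#' @return An object of class `crop_calendar`.
#' @export
crop_calendar <- function(emergence = 21L, tuber_init = 43L,
                          early_bulk = 56L, mid_bulk = 71L,
                          late_bulk = 85L, senescence = 99L,
                          vine_kill = 112L, harvest = 135L) {
  d <- c(emergence = emergence, tuber_init = tuber_init,
         early_bulk = early_bulk, mid_bulk = mid_bulk,
         late_bulk = late_bulk, senescence = senescence,
         vine_kill = vine_kill, harvest = harvest)
  if (any(diff(d) <= 0)) stop("calendar stages must be strictly increasing")
  d <- stats::setNames(as.list(as.integer(d)), names(d))
  structure(d, class = "crop_calendar")
}

#' Stage windows implied by a calendar
#'
#' @param calendar a [crop_calendar()].
#' @return data.frame with `stage`, `from_dap`, `to_dap` (inclusive).
#' @export
stage_windows <- function(calendar) {
  ca <- calendar
  data.frame(
    stage = c("prior_emergence", "emergence", "tuber_initiation",
              "early_tuber_bulk", "mid_tuber_bulk", "late_tuber_bulk",
              "senescence"),
    from_dap = c(1L, ca$emergence, ca$tuber_init, ca$early_bulk,
                 ca$mid_bulk, ca$late_bulk, ca$senescence),
    to_dap = c(ca$emergence - 1L, ca$tuber_init - 1L, ca$early_bulk - 1L,
               ca$mid_bulk - 1L, ca$late_bulk - 1L, ca$senescence - 1L,
               ca$harvest),
    stringsAsFactors = FALSE
  )
}

#' Daily thermal time (growing degree days)
#'
#' `GDD = max(0, min(mean(tmax, tmin), t_upper) - t_base)`.
#'
#' @param tmax,tmin daily temperature extremes, C.
#' @param t_base,t_upper base and upper temperature, C.
#' @return Degree days (vectorized).
#' @export
thermal_time <- function(tmax, tmin, t_base = 2, t_upper = 26) {
  if (any(tmax < tmin)) stop("tmax must be >= tmin")
  pmax(0, pmin((tmax + tmin) / 2, t_upper) - t_base)
}

#' Water-stress coefficient
#'
#' Convex stress response `Ks = 1 - (exp(drel * shape) - 1) /
#' (exp(shape) - 1)` on the relative depletion `drel` in `[0, 1]`:
#' 1 (no stress) at `drel = 0`, 0 (full stress) at `drel = 1`, strictly
#' decreasing between.
#'
#' @param drel relative depletion within the process's threshold band,
#'   clipped to `[0, 1]`.
#' @param shape curve shape factor (> 0).
#' @return Ks in `[0, 1]` (vectorized in `drel`).
#' @export
stress_coefficient <- function(drel, shape) {
  if (shape <= 0) stop("shape must be > 0")
  drel <- clip(drel, 0, 1)
  1 - (exp(drel * shape) - 1) / (exp(shape) - 1)
}

#' Relative depletion for a stress process
#'
#' Root-zone depletion `D = (theta_fc - theta_bar) / (theta_fc - theta_wp)`
#' mapped into the process's threshold band:
#' `clip((D - p_upper) / (p_lower - p_upper), 0, 1)`.
#'
#' @param depletion depletion fraction of total available water.
#' @param p_upper upper (onset) threshold.
#' @param p_lower lower (full-stress) threshold; stomatal closure and
#'   senescence use 1.
#' @return Relative depletion in `[0, 1]`.
#' @export
relative_depletion <- function(depletion, p_upper, p_lower = 1) {
  if (p_lower <= p_upper) stop("p_lower must exceed p_upper")
  clip((depletion - p_upper) / (p_lower - p_upper), 0, 1)
}

#' Unstressed canopy cover growth curve
#'
#' Canopy cover at thermal time `tau` since emergence: exponential growth
#' `cc0 * exp(cgc * tau)` up to half the maximum cover, then exponential
#' approach `ccx - 0.25 * ccx^2 / cc0 * exp(-cgc * tau)`, clipped at `ccx`.
#'
#' @param tau thermal time since emergence, degree days.
#' @param params a [crop_params()].
#' @return Canopy cover, percent (vectorized).
#' @export
canopy_cover_growth <- function(tau, params) {
  cc <- params$cc0 * exp(params$cgc * tau)
  high <- cc > params$ccx / 2
  cc[high] <- params$ccx -
    0.25 * params$ccx^2 / params$cc0 * exp(-params$cgc * tau[high])
  clip(cc, 0, params$ccx)
}

# thermal time at which the unstressed growth curve reaches cover cc
canopy_growth_tau <- function(cc, params) {
  if (cc <= params$ccx / 2) {
    log(cc / params$cc0) / params$cgc
  } else {
    ratio <- max((params$ccx - cc) * 4 * params$cc0 / params$ccx^2, 1e-12)
    -log(ratio) / params$cgc
  }
}

#' Canopy decline curve
#'
#' Cover during senescence at thermal time `tau_s` since onset:
#' `cc_sen * (1 - 0.05 * (exp(rate * tau_s) - 1))` with
#' `rate = cdc / (cc_sen / 100)`, clipped to `[0, cc_sen]`.
#'
#' @param cc_sen cover at senescence onset, percent.
#' @param tau_s thermal time since onset, degree days.
#' @param params a [crop_params()].
#' @return Canopy cover, percent.
#' @export
canopy_cover_decline <- function(cc_sen, tau_s, params) {
  if (cc_sen <= 0) return(0)
  rate <- params$cdc / (cc_sen / 100)
  clip(cc_sen * (1 - 0.05 * (exp(rate * tau_s) - 1)), 0, cc_sen)
}

#' Initial crop state
#'
#' @param params a [crop_params()].
#' @return An object of class `crop_state` holding canopy cover, rooting
#'   depth, cumulative thermal time, biomass, harvest index and the
#'   senescence bookkeeping.
#' @export
crop_state <- function(params) {
  structure(list(cc = 0, zr = params$zr_min, gdd_cum = 0,
                 gdd_emerged = 0, b = 0, hi = 0,
                 senescing = FALSE, cc_sen = NA_real_, gdd_sen = 0,
                 sen_streak = 0L, cc_vk = NA_real_),
            class = "crop_state")
}

#' Advance canopy cover by one day
#'
#' Before emergence cover is zero.  During growth the day's unstressed
#' cover increment (from the growth curve at the state's equivalent
#' thermal time) is scaled by the expansion-stress coefficient `ks_exp`.
#' After senescence onset (calendar day, or earlier when depletion has
#' exceeded the senescence threshold for the trigger number of consecutive
#' days) cover follows the decline curve from the cover at onset.  From
#' the vine-kill day cover is forced linearly to zero within three days.
#'
#' @param state a [crop_state()].
#' @param params a [crop_params()].
#' @param calendar a [crop_calendar()].
#' @param dap day after planting.
#' @param gdd_today the day's thermal time, degree days.
#' @param ks_exp expansion-stress coefficient in `[0, 1]`.
#' @param sen_stressed logical: is depletion at or beyond the senescence
#'   threshold today?
#' @return The updated `crop_state`.
#' @export
canopy_step <- function(state, params, calendar, dap, gdd_today,
                        ks_exp = 1, sen_stressed = FALSE) {
  state$gdd_cum <- state$gdd_cum + gdd_today
  if (dap < calendar$emergence) {
    state$cc <- 0
    return(state)
  }
  if (dap == calendar$emergence) {
    # the growth curve starts from cc0 the day after emergence
    state$cc <- params$cc0
    return(state)
  }
  state$gdd_emerged <- state$gdd_emerged + gdd_today

  # early-senescence trigger bookkeeping
  state$sen_streak <- if (sen_stressed) state$sen_streak + 1L else 0L
  if (!state$senescing &&
      (dap >= calendar$senescence ||
         state$sen_streak >= params$sen_trigger_days)) {
    state$senescing <- TRUE
    state$cc_sen <- state$cc
    state$gdd_sen <- 0
  }

  if (dap >= calendar$vine_kill) {
    if (is.na(state$cc_vk)) state$cc_vk <- state$cc
    state$cc <- state$cc_vk * max(0, (calendar$vine_kill + 3 - dap) / 3)
  } else if (state$senescing) {
    state$gdd_sen <- state$gdd_sen + gdd_today
    state$cc <- canopy_cover_decline(state$cc_sen, state$gdd_sen, params)
  } else {
    tau <- canopy_growth_tau(max(state$cc, params$cc0), params)
    target <- canopy_cover_growth(tau + gdd_today, params)
    state$cc <- clip(state$cc + ks_exp * max(target - state$cc, 0),
                     0, params$ccx)
  }
  state
}

#' Effective rooting depth by day
#'
#' Roots deepen from `zr_min` at emergence to `zr_max` at the mid-tuber
#' bulking onset following a power curve with exponent 1.5 in the elapsed
#' time fraction, and stay at `zr_max` thereafter.
#'
#' @param dap day after planting.
#' @param calendar a [crop_calendar()].
#' @param zr_min,zr_max rooting depth bounds, m.
#' @return Rooting depth, m.
#' @export
root_deepening <- function(dap, calendar, zr_min = 0.15, zr_max = 0.47) {
  if (dap <= calendar$emergence) return(zr_min)
  if (dap >= calendar$mid_bulk) return(zr_max)
  frac <- (dap - calendar$emergence) / (calendar$mid_bulk - calendar$emergence)
  zr_min + (zr_max - zr_min) * frac^1.5
}

#' Daily transpiration and evaporation demands
#'
#' Transpiration demand `Ks_sto * Ks_cold * KcTr * cc_star * ET0` with the
#' micro-advection adjusted cover `cc_star = 1.72 c - c^2 + 0.3 c^3`
#' (`c` the fractional cover); evaporation demand
#' `Kr * Ke_max * (1 - cc_star) * ET0`.
#'
#' @param cc canopy cover, percent.
#' @param et0 reference evapotranspiration, mm d-1.
#' @param params a [crop_params()].
#' @param ks_sto stomatal stress coefficient.
#' @param kr evaporation reduction coefficient from surface-layer wetness.
#' @return list with `tr_demand` and `e_demand`, mm d-1.
#' @export
daily_demands <- function(cc, et0, params, ks_sto = 1, kr = 1) {
  if (cc < 0 || cc > 100) stop("cc must be in [0, 100]")
  cfrac <- cc / 100
  cc_star <- clip(1.72 * cfrac - cfrac^2 + 0.3 * cfrac^3, 0, 1)
  list(tr_demand = max(ks_sto * params$ks_cold * params$kctr * cc_star * et0, 0),
       e_demand = max(kr * params$ke_max * (1 - cc_star) * et0, 0))
}

#' Accumulate biomass from normalized transpiration
#'
#' Adds `wp * tr / et0` to the running aboveground biomass; on a day with
#' zero reference evapotranspiration but positive transpiration the
#' increment is skipped with a warning.
#'
#' @param b biomass so far, g m-2.
#' @param tr_realized realized transpiration, mm.
#' @param et0 reference evapotranspiration, mm.
#' @param wp normalized water productivity, g m-2.
#' @return Updated biomass, g m-2.
#' @export
accumulate_biomass <- function(b, tr_realized, et0, wp) {
  if (tr_realized <= 0) return(b)
  if (et0 <= 0) {
    warning("positive transpiration with zero reference ET; increment skipped")
    return(b)
  }
  b + wp * tr_realized / et0
}

#' Harvest index build-up
#'
#' Linear build from 0 at tuber initiation to the reference harvest index
#' at vine kill.
#'
#' @param dap day after planting.
#' @param calendar a [crop_calendar()].
#' @param hi0 reference harvest index (fraction).
#' @return Harvest index (fraction).
#' @export
harvest_index <- function(dap, calendar, hi0) {
  hi0 * clip((dap - calendar$tuber_init) /
               (calendar$vine_kill - calendar$tuber_init), 0, 1)
}

#' Tuber yield from biomass and harvest index
#'
#' `Y = f_hi * HI * B`, converted from g m-2 to t ha-1 (factor 0.01).
#' The returned yield is on the model's dry-matter basis; divide by the
#' dry-matter fraction for a fresh-mass equivalent.
#'
#' @param b aboveground biomass, g m-2.
#' @param hi current harvest index (fraction).
#' @param f_hi harvest-index stress multiplier.
#' @return Yield, t ha-1.
#' @export
harvest_yield <- function(b, hi, f_hi = 1) {
  if (b < 0 || hi < 0) stop("biomass and harvest index must be >= 0")
  f_hi * hi * b * 0.01
}
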