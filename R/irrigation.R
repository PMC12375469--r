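# Irrigation policies: field-capacity threshold triggering, fixed
# schedules, or rainfed.

#' Define an irrigation policy
#'
#' Threshold mode applies a fixed dose whenever less than `threshold` of
#' the root zone's plant-available water remains, i.e. when the
#' thickness-weighted water content falls below
#' `theta_wp + threshold * (theta_fc - theta_wp)` (the fraction-of-field-
#' capacity reading a threshold scheduler acts on).  The trigger is
#' evaluated after the day's rain has infiltrated, at most one event per
#' day, respecting the minimum interval and the start day.  Fixed mode
#' applies a prescribed schedule; rainfed never irrigates.  Full mode
#' refills the root zone to field capacity every day (a net-irrigation-
#' requirement schedule), so transpiration demand is always met; its event
#' depths vary with the day's deficit.
#'
#' @param mode one of `"threshold"`, `"fixed"`, `"rainfed"`, `"full"`.
#' @param threshold trigger as a fraction of field capacity (0-1),
#'   threshold mode only.
#' @param dose_mm depth per event, mm (default 15.24).
#' @param min_interval_days minimum days between events (>= 1).
#' @param start_dap first day events are allowed (default: emergence).
#' @param schedule data.frame with `dap` and `mm`, fixed mode only.
#' @param name optional label; defaults to a descriptive one.
#' @return An object of class `irrigation_policy`.
#' @examples
#' irrigation_policy("threshold", threshold = 0.5)
#' irrigation_policy("fixed", schedule = data.frame(dap = c(25, 60), mm = 16))
#' @export
irrigation_policy <- function(mode = c("threshold", "fixed", "rainfed", "full"),
                              threshold = NULL, dose_mm = 15.24,
                              min_interval_days = 1L, start_dap = NULL,
                              schedule = NULL, name = NULL) {
  mode <- match.arg(mode)
  if (mode == "threshold") {
    if (is.null(threshold)) stop("threshold mode needs `threshold`")
    stopifnot_scalar(threshold, "threshold", lo = 1e-9, hi = 1 - 1e-9)
    if (dose_mm <= 0) stop("dose_mm must be > 0")
  }
  if (mode == "fixed") {
    if (is.null(schedule) || !all(c("dap", "mm") %in% names(schedule))) {
      stop("fixed mode needs a schedule with columns dap, mm")
    }
    if (any(schedule$mm <= 0)) stop("scheduled depths must be > 0")
  }
  if (min_interval_days < 1) stop("min_interval_days must be >= 1")
  if (is.null(name)) {
    name <- switch(mode,
                   threshold = sprintf("fc%02d", round(100 * threshold)),
                   fixed = "fixed", rainfed = "rainfed", full = "full")
  }
  structure(list(mode = mode, threshold = threshold, dose_mm = dose_mm,
                 min_interval_days = as.integer(min_interval_days),
                 start_dap = start_dap, schedule = schedule, name = name),
            class = "irrigation_policy")
}

#' Decide the day's irrigation depth
#'
#' @param theta per-compartment volumetric water content (after the day's
#'   rain has infiltrated).
#' @param profile a [soil_profile()].
#' @param zr rooting depth, m.
#' @param policy an [irrigation_policy()].
#' @param dap day after planting.
#' @param last_event_dap day of the most recent event (`-Inf` if none).
#' @param start_dap_default fallback start day when the policy leaves
#'   `start_dap` unset (the caller passes the emergence day).
#' @param et0 the day's reference evapotranspiration, mm (used by full
#'   mode to buffer the surface against the day's evaporation).
#' @return Irrigation depth, mm (0 or the policy dose).
#' @export
decide_irrigation <- function(theta, profile, zr, policy, dap,
                              last_event_dap = -Inf,
                              start_dap_default = 1L, et0 = 0) {
  switch(policy$mode,
    rainfed = 0,
    full = {
      start <- if (is.null(policy$start_dap)) start_dap_default else policy$start_dap
      if (dap < start) return(0)
      # per-compartment refill to field capacity over the root zone, plus
      # the day's potential surface evaporation so the top quarter stays
      # extractable after evaporation
      comp <- profile$compartments
      ov <- overlap_m(profile, 0, zr)
      deficit <- sum(pmax(comp$theta_fc - theta, 0) * ov * 1000) + 1.1 * et0
      if (deficit > 0.01) deficit else 0
    },
    fixed = {
      i <- which(policy$schedule$dap == dap)
      if (length(i)) sum(policy$schedule$mm[i]) else 0
    },
    threshold = {
      start <- if (is.null(policy$start_dap)) start_dap_default else policy$start_dap
      if (dap < start) return(0)
      if (dap - last_event_dap < policy$min_interval_days) return(0)
      tb <- rootzone_mean(theta, profile, zr)
      fcb <- rootzone_mean(profile$compartments$theta_fc, profile, zr)
      wpb <- rootzone_mean(profile$compartments$theta_wp, profile, zr)
      if (tb < wpb + policy$threshold * (fcb - wpb)) policy$dose_mm else 0
    },
    stop("invalid policy mode")
  )
}

#' Summarize an irrigation log
#'
#' @param log data.frame with columns `dap` and `mm` (one row per event).
#' @return list with `count` and `total_mm`.
#' @export
summarize_log <- function(log) {
  if (is.null(log) || nrow(log) == 0) return(list(count = 0L, total_mm = 0))
  list(count = nrow(log), total_mm = sum(log$mm))
}
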