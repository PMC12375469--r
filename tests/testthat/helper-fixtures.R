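# shared builders for tests; everything is generated in code

default_params <- crop_params()
default_calendar <- crop_calendar()

montcalm <- load_fixture("montcalm")
mecosta <- load_fixture("mecosta")

# a single-texture profile handy for hand arithmetic
sandy_loam_profile <- function(depth_m = 0.60, compartment_m = 0.05,
                               tau = 0.5) {
  soil_profile(data.frame(top_m = 0, bottom_m = depth_m,
                          texture = "sandy loam"),
               depth_m = depth_m, compartment_m = compartment_m, tau = tau)
}

fc_policy <- function(threshold) {
  irrigation_policy("threshold", threshold = threshold)
}

quick_season <- function(seed, target = 284.5, ...) {
  synthesize_season(season_spec(target_rain_mm = target, seed = seed, ...))
}

run_quick <- function(weather, soil = montcalm, policy = fc_policy(0.5), ...) {
  run_season(weather, soil, default_params, default_calendar, policy, ...)
}

# closure residual of a traced run: daily storage change vs fluxes, mm
closure_residuals <- function(trace) {
  trace$w_change - (trace$rain + trace$irrigation - trace$runoff -
                      trace$drainage - trace$evaporation -
                      trace$transpiration)
}
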