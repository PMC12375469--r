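# Seeded synthetic growing-season weather: two-state Markov rainfall
# occurrence with gamma amounts rescaled to an exact season total,
# sinusoidal temperatures calibrated to target season means, and simple
# bounded-noise humidity/wind/radiation models.

#' Specification of a synthetic growing season
#'
#' Collects every control of the weather generator into a validated object.
#' The defaults emulate a humid-temperate potato season: 135 days from
#' planting on 10 May, a 284.5 mm season rainfall total, season-mean
#' maximum/minimum temperatures of 25.7/12.9 degrees C with the warm peak
#' in the late-tuber-bulk window, and a first-order wet/dry occurrence
#' chain with gamma rainfall amounts.
#'
#' @param planting planting date (`Date` or ISO string).
#' @param season_length number of simulated days (>= 1).
#' @param latitude site latitude, decimal degrees.
#' @param elevation site elevation, m.
#' @param target_rain_mm season rainfall total the generated series is
#'   rescaled to, mm (>= 0).
#' @param tmax_mean,tmin_mean target season-mean daily maximum/minimum
#'   temperature, degrees C.
#' @param tmax_amp,tmin_amp amplitude of the annual temperature cosine,
#'   degrees C.
#' @param temp_noise half-width of the uniform day-to-day temperature
#'   noise, degrees C.
#' @param doy_peak day of year of the warm peak (default 220, aligning
#'   with late tuber bulking).
#' @param p_wet_given_dry,p_wet_given_wet transition probabilities of the
#'   rainfall occurrence chain.
#' @param rain_shape,rain_scale gamma shape/scale of wet-day amounts (mm).
#' @param seed integer seed; identical specs generate identical series.
#' @return An object of class `season_spec`.
#' @export
season_spec <- function(planting = "2023-05-10",
                        season_length = 135,
                        latitude = 43.35,
                        elevation = 290,
                        target_rain_mm = 284.5,
                        tmax_mean = 25.7,
                        tmin_mean = 12.9,
                        tmax_amp = 6,
                        tmin_amp = 4,
                        temp_noise = 1.5,
                        doy_peak = 220,
                        p_wet_given_dry = 0.25,
                        p_wet_given_wet = 0.55,
                        rain_shape = 0.8,
                        rain_scale = 6,
                        seed = 1L) {
  planting <- as.Date(planting)
  stopifnot_scalar(season_length, "season_length", lo = 1)
  stopifnot_scalar(target_rain_mm, "target_rain_mm", lo = 0)
  stopifnot_scalar(latitude, "latitude", lo = -90, hi = 90)
  stopifnot_scalar(p_wet_given_dry, "p_wet_given_dry", 0, 1)
  stopifnot_scalar(p_wet_given_wet, "p_wet_given_wet", 0, 1)
  stopifnot_scalar(rain_shape, "rain_shape", lo = 1e-6)
  stopifnot_scalar(rain_scale, "rain_scale", lo = 1e-6)
  structure(list(
    planting = planting, season_length = as.integer(season_length),
    latitude = latitude, elevation = elevation,
    target_rain_mm = target_rain_mm,
    tmax_mean = tmax_mean, tmin_mean = tmin_mean,
    tmax_amp = tmax_amp, tmin_amp = tmin_amp,
    temp_noise = temp_noise, doy_peak = doy_peak,
    p_wet_given_dry = p_wet_given_dry, p_wet_given_wet = p_wet_given_wet,
    rain_shape = rain_shape, rain_scale = rain_scale,
    seed = as.integer(seed)
  ), class = "season_spec")
}

# draw one wet/dry occupancy sequence + gamma amounts (consumes RNG)
draw_rain <- function(n, spec) {
  wet <- logical(n)
  u <- stats::runif(n)
  wet[1] <- u[1] < spec$p_wet_given_dry
  for (i in 2:n) {
    p <- if (wet[i - 1]) spec$p_wet_given_wet else spec$p_wet_given_dry
    wet[i] <- u[i] < p
  }
  amounts <- numeric(n)
  nw <- sum(wet)
  if (nw > 0) {
    amounts[wet] <- stats::rgamma(nw, shape = spec$rain_shape,
                                  scale = spec$rain_scale)
  }
  amounts
}

#' Generate one season of daily weather
#'
#' Draws rainfall occurrence from a first-order two-state chain and wet-day
#' amounts from a gamma distribution, then rescales amounts multiplicatively
#' so the season total equals `spec$target_rain_mm` exactly.  Temperatures
#' follow an annual cosine whose baseline is calibrated so that the
#' deterministic season mean equals the spec's targets, plus bounded uniform
#' noise.  Humidity, wind and solar radiation are drawn with bounded noise
#' (wetter, dimmer days when it rains); reference evapotranspiration is
#' computed per day with [compute_et0()].
#'
#' @param spec a [season_spec()].
#' @param max_retries how many fresh rainfall draws to attempt when the
#'   target is positive but an all-dry sequence was drawn.
#' @return A `weather_series` data.frame with one row per day and columns
#'   `date`, `tmax_c`, `tmin_c`, `rain_mm`, `rhmax_pct`, `rhmin_pct`,
#'   `wind_ms`, `srad_mj`, `et0_mm`.
#' @examples
#' wx <- synthesize_season(season_spec(target_rain_mm = 312.8, seed = 7))
#' sum(wx$rain_mm)
#' @export
synthesize_season <- function(spec, max_retries = 10L) {
  stopifnot(inherits(spec, "season_spec"))
  n <- spec$season_length
  if (n < 1) stop("season length must be >= 1")
  dates <- spec$planting + seq_len(n) - 1L
  doy <- as.integer(format(dates, "%j"))

  with_seed(spec$seed, {
    rain <- draw_rain(n, spec)
    tries <- 0L
    while (spec$target_rain_mm > 0 && sum(rain) <= 0 && tries < max_retries) {
      rain <- draw_rain(n, spec)
      tries <- tries + 1L
    }
    if (spec$target_rain_mm > 0 && sum(rain) <= 0) {
      stop("could not draw a wet day for a positive rainfall target; ",
           "check the occurrence-chain parameters")
    }
    if (spec$target_rain_mm > 0) {
      rain <- rain * (spec$target_rain_mm / sum(rain))
    } else {
      rain[] <- 0
    }
    wet <- rain > 0

    # cosine baseline calibrated so the deterministic season mean is exact
    cosd <- cos(2 * pi * (doy - spec$doy_peak) / 365)
    tmax <- (spec$tmax_mean - spec$tmax_amp * mean(cosd)) +
      spec$tmax_amp * cosd + stats::runif(n, -spec$temp_noise, spec$temp_noise)
    tmin <- (spec$tmin_mean - spec$tmin_amp * mean(cosd)) +
      spec$tmin_amp * cosd + stats::runif(n, -spec$temp_noise, spec$temp_noise)
    tmin <- pmin(tmin, tmax - 0.2)

    rhmax <- clip(88 + 6 * wet + stats::runif(n, -5, 5), 40, 100)
    rhmin <- clip(rhmax - 42 + 12 * wet + stats::runif(n, -6, 6), 5, 100)
    rhmin <- pmin(rhmin, rhmax)
    wind <- pmax(0.3, 2.0 + stats::runif(n, -1.2, 1.2))

    ra <- extraterrestrial_radiation(doy, spec$latitude)
    kt <- ifelse(wet, stats::runif(n, 0.25, 0.45), stats::runif(n, 0.55, 0.75))
    srad <- kt * ra

    et0 <- compute_et0(tmax, tmin, rhmax, rhmin, wind, srad,
                       latitude = spec$latitude, doy = doy,
                       elevation = spec$elevation)

    structure(data.frame(
      date = dates, tmax_c = tmax, tmin_c = tmin, rain_mm = rain,
      rhmax_pct = rhmax, rhmin_pct = rhmin, wind_ms = wind,
      srad_mj = srad, et0_mm = et0
    ), class = c("weather_series", "data.frame"))
  })
}
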