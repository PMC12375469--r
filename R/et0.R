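# FAO-56 Penman-Monteith daily reference evapotranspiration and the
# radiation/psychrometric helpers it needs.  All functions are vectorized
# over days.

#' Saturation vapour pressure
#'
#' Tetens-form saturation vapour pressure at air temperature `t`.
#'
#' @param t air temperature, degrees C.
#' @return Saturation vapour pressure, kPa.
#' @export
svp <- function(t) 0.6108 * exp(17.27 * t / (t + 237.3))

#' Extraterrestrial radiation for daily periods
#'
#' Top-of-atmosphere solar radiation from latitude and day of year
#' (FAO-56 daily formulation).
#'
#' @param doy day of year (1-366).
#' @param latitude latitude, decimal degrees (positive north).
#' @return Extraterrestrial radiation, MJ m-2 d-1.
#' @export
extraterrestrial_radiation <- function(doy, latitude) {
  phi <- latitude * pi / 180
  dr  <- 1 + 0.033 * cos(2 * pi * doy / 365)
  dec <- 0.409 * sin(2 * pi * doy / 365 - 1.39)
  ws  <- acos(clip(-tan(phi) * tan(dec), -1, 1))
  (24 * 60 / pi) * 0.0820 * dr *
    (ws * sin(phi) * sin(dec) + cos(phi) * cos(dec) * sin(ws))
}

#' Adjust wind speed to the 2 m reference height
#'
#' Logarithmic wind profile conversion from measurement height `z` to the
#' 2 m height required by the reference-evapotranspiration equation.
#'
#' @param u wind speed at height `z`, m s-1.
#' @param z measurement height, m.
#' @return Wind speed at 2 m, m s-1.
#' @export
wind_to_2m <- function(u, z) {
  stopifnot(z > 0)
  if (isTRUE(all.equal(z, 2))) return(u)
  u * 4.87 / log(67.8 * z - 5.42)
}

#' Daily reference evapotranspiration (FAO-56 Penman-Monteith)
#'
#' Computes grass-reference evapotranspiration from daily temperature
#' extremes, relative-humidity extremes, 2 m wind speed and measured solar
#' radiation.  Net longwave radiation uses the clear-sky ratio with
#' elevation-corrected clear-sky radiation; soil heat flux is taken as zero
#' at the daily time step; the result is clipped at zero.
#'
#' @param tmax,tmin daily maximum/minimum air temperature, degrees C.
#' @param rhmax,rhmin daily maximum/minimum relative humidity, percent.
#' @param wind wind speed at 2 m, m s-1.
#' @param srad incoming solar radiation, MJ m-2 d-1.
#' @param latitude site latitude, decimal degrees.
#' @param doy day of year.
#' @param elevation site elevation above sea level, m (default 290).
#' @param rn optional net radiation override, MJ m-2 d-1; when supplied it
#'   replaces the value derived from `srad` (useful for stations measuring
#'   net radiation directly).
#' @return Reference evapotranspiration, mm d-1 (vectorized).
#' @examples
#' compute_et0(28, 16, 85, 55, 2, 24, latitude = 43.35, doy = 196)
#' @export
compute_et0 <- function(tmax, tmin, rhmax, rhmin, wind, srad,
                        latitude, doy, elevation = 290, rn = NULL) {
  if (any(tmax < tmin)) stop("tmax must be >= tmin")
  if (any(rhmin > rhmax) || any(rhmin < 0) || any(rhmax > 100)) {
    stop("relative humidity must satisfy 0 <= rhmin <= rhmax <= 100")
  }
  if (any(wind < 0) || any(srad < 0)) stop("wind and srad must be >= 0")

  tmean <- (tmax + tmin) / 2
  p     <- 101.3 * ((293 - 0.0065 * elevation) / 293)^5.26
  gamma <- 0.000665 * p
  es    <- (svp(tmax) + svp(tmin)) / 2
  ea    <- (svp(tmin) * rhmax / 100 + svp(tmax) * rhmin / 100) / 2
  delta <- 4098 * svp(tmean) / (tmean + 237.3)^2

  ra  <- extraterrestrial_radiation(doy, latitude)
  rso <- (0.75 + 2e-5 * elevation) * ra
  rns <- (1 - 0.23) * srad
  sb  <- 4.903e-9
  rnl <- sb * ((tmax + 273.16)^4 + (tmin + 273.16)^4) / 2 *
    (0.34 - 0.14 * sqrt(ea)) * (1.35 * clip(srad / rso, 0, 1) - 0.35)
  if (is.null(rn)) rn <- rns - rnl

  num <- 0.408 * delta * rn + gamma * (900 / (tmean + 273)) * wind * (es - ea)
  den <- delta + gamma * (1 + 0.34 * wind)
  pmax(num / den, 0)
}
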