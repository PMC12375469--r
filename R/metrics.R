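# Model-evaluation statistics, crop water productivity, and the
# composite-available-water series used for sensor comparison.

#' Model evaluation statistics
#'
#' Root mean square error `sqrt(mean((M - P)^2))`, mean bias error
#' `mean(P - M)`, index of agreement
#' `1 - sum((M - P)^2) / sum((|P - Mbar| + |M - Mbar|)^2)` and
#' Nash-Sutcliffe efficiency `1 - sum((M - P)^2) / sum((M - Mbar)^2)`.
#' With a single pair or a constant measured series the IA and NSE
#' denominators vanish; those metrics are returned as `NA` with the reason
#' in the `undefined` field.
#'
#' @param measured numeric vector of observations (M).
#' @param predicted numeric vector of model values (P), same length.
#' @return An object of class `metric_set`: list with `rmse`, `mbe`, `ia`,
#'   `nse`, `n` and `undefined` (named reasons for `NA` metrics).
#' @examples
#' compute_metrics(c(38.547), c(38.923))
#' @export
compute_metrics <- function(measured, predicted) {
  n <- length(measured)
  if (n == 0) stop("empty series")
  if (length(predicted) != n) stop("series lengths differ")
  if (anyNA(measured) || anyNA(predicted)) stop("NA values in series")
  err <- measured - predicted
  rmse <- sqrt(mean(err^2))
  mbe <- mean(predicted - measured)
  mbar <- mean(measured)
  undefined <- character()
  if (n < 2 || all(measured == measured[1])) {
    ia <- NA_real_
    nse <- NA_real_
    undefined <- c(
      ia = "denominator vanishes for a constant (or single) measured series",
      nse = "denominator vanishes for a constant (or single) measured series")
  } else {
    ia <- 1 - sum(err^2) / sum((abs(predicted - mbar) + abs(measured - mbar))^2)
    nse <- 1 - sum(err^2) / sum((measured - mbar)^2)
  }
  structure(list(rmse = rmse, mbe = mbe, ia = ia, nse = nse, n = n,
                 undefined = undefined), class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("n = %d  RMSE = %.4g  MBE = %+.4g  IA = %.4g  NSE = %.4g\n",
              x$n, x$rmse, x$mbe, x$ia, x$nse))
  if (length(x$undefined)) {
    cat("undefined:", paste(names(x$undefined), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Crop water productivity
#'
#' `WPc = yield / TWU` with total water use `TWU = (rain + irrigation)`
#' converted from mm to m3 ha-1 (factor 10).
#'
#' @param yield_kg_ha economic yield, kg ha-1.
#' @param rain_mm season rainfall, mm.
#' @param irrigation_mm season irrigation, mm.
#' @return list with `yield_kg_ha`, `twu_m3_ha`, `wpc_kg_m3`.
#' @examples
#' crop_water_productivity(38547, rain_mm = 312.8, irrigation_mm = 48)
#' @export
crop_water_productivity <- function(yield_kg_ha, rain_mm, irrigation_mm = 0) {
  total <- rain_mm + irrigation_mm
  if (total <= 0) stop("total water use must be > 0")
  if (yield_kg_ha < 0) stop("yield must be >= 0")
  twu <- total * 10
  list(yield_kg_ha = yield_kg_ha, twu_m3_ha = twu,
       wpc_kg_m3 = yield_kg_ha / twu)
}

#' Composite available water over monitored depth intervals
#'
#' Plant-available water (above wilting point) summed over the monitored
#' sensor depth intervals:
#' `CAW = sum over intervals of 1000 * max(0, theta - theta_wp) * thickness`.
#'
#' @param theta per-compartment volumetric water content.
#' @param profile a [soil_profile()].
#' @param intervals data.frame with `from_m`, `to_m`; defaults to the
#'   three 0.15 m monitoring intervals down to 0.45 m.
#' @return Composite available water, mm.
#' @export
composite_available_water <- function(theta, profile,
                                      intervals = data.frame(
                                        from_m = c(0, 0.15, 0.30),
                                        to_m = c(0.15, 0.30, 0.45))) {
  if (any(intervals$to_m > profile$depth + 1e-9)) {
    stop("interval outside profile")
  }
  comp <- profile$compartments
  total <- 0
  for (i in seq_len(nrow(intervals))) {
    ov <- overlap_m(profile, intervals$from_m[i], intervals$to_m[i])
    total <- total + sum(1000 * pmax(theta - comp$theta_wp, 0) * ov)
  }
  total
}
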