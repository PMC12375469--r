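# Delimited-text weather files: comma separated, one header row, ISO dates.

weather_columns <- c("date", "tmax_c", "tmin_c", "rain_mm",
                     "rhmax_pct", "rhmin_pct", "wind_ms", "srad_mj")

#' Write a weather series to a delimited text file
#'
#' Comma-delimited with a single header row, ISO-8601 dates and numeric
#' values at 6 significant digits; `et0_mm` is included when present.
#'
#' @param series a `weather_series` data.frame.
#' @param path output file path.
#' @param digits significant digits for numeric columns.
#' @return `path`, invisibly.
#' @export
write_weather <- function(series, path, digits = 6) {
  cols <- intersect(c(weather_columns, "et0_mm"), names(series))
  missing <- setdiff(weather_columns, cols)
  if (length(missing)) {
    stop("weather series is missing column(s): ", paste(missing, collapse = ", "))
  }
  out <- series[cols]
  for (nm in setdiff(cols, "date")) out[[nm]] <- signif(out[[nm]], digits)
  out$date <- format(as.Date(out$date), "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a weather series from a delimited text file
#'
#' Validates the eight required columns, contiguous ISO dates and the daily
#' value invariants (non-negative rain, wind and radiation; tmax >= tmin;
#' humidity ordering), reporting the offending row on failure.
#'
#' @param path input file path.
#' @return A `weather_series` data.frame.
#' @export
read_weather <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(weather_columns, names(x))
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "))
  }
  x$date <- as.Date(x$date)
  if (anyNA(x$date)) stop("unparseable date(s) in weather file")
  if (nrow(x) > 1 && any(diff(as.integer(x$date)) != 1L)) {
    stop("non-contiguous dates at row ",
         which(diff(as.integer(x$date)) != 1L)[1] + 1L)
  }
  bad <- which(x$rain_mm < 0)
  if (length(bad)) stop("negative rain at row ", bad[1])
  bad <- which(x$tmax_c < x$tmin_c)
  if (length(bad)) stop("tmax < tmin at row ", bad[1])
  bad <- which(x$rhmin_pct > x$rhmax_pct | x$rhmin_pct < 0 | x$rhmax_pct > 100)
  if (length(bad)) stop("invalid relative humidity at row ", bad[1])
  bad <- which(x$wind_ms < 0 | x$srad_mj < 0)
  if (length(bad)) stop("negative wind or radiation at row ", bad[1])
  class(x) <- c("weather_series", "data.frame")
  x
}
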