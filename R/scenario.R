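# Season classification, the (years x policies x soils) scenario grid,
# log-response-ratio trade-off quadrants, and the stage-correlation matrix.

#' Season classification thresholds
#'
#' @param mean_mm long-term mean growing-season rainfall, mm.
#' @param band fractional deviation band (default 0.10).
#' @return Named vector with `wet` and `dry` boundary totals, mm.
#' @export
season_class_thresholds <- function(mean_mm = 284.5, band = 0.10) {
  stopifnot_scalar(mean_mm, "mean_mm", lo = 1e-9)
  stopifnot_scalar(band, "band", lo = 1e-9, hi = 1 - 1e-9)
  c(wet = mean_mm * (1 + band), dry = mean_mm * (1 - band))
}

#' Classify a season by its rainfall total
#'
#' Wet when the total exceeds the mean by more than the band, dry when it
#' falls short by more than the band, normal otherwise.
#'
#' @param total_rain_mm growing-season rainfall total, mm (vectorized).
#' @param mean_mm long-term mean, mm.
#' @param band fractional band (default 0.10).
#' @return Character vector in `{"wet", "normal", "dry"}`.
#' @examples
#' classify_season(c(340, 250, 284.5))
#' @export
classify_season <- function(total_rain_mm, mean_mm = 284.5, band = 0.10) {
  th <- season_class_thresholds(mean_mm, band)
  ifelse(total_rain_mm > th["wet"], "wet",
         ifelse(total_rain_mm < th["dry"], "dry", "normal"))
}

#' Log response ratio
#'
#' Effect size `ln(x_treatment / x_control)`.
#'
#' @param x_treatment,x_control positive values.
#' @return `log(x_treatment) - log(x_control)` (vectorized).
#' @export
lnrr <- function(x_treatment, x_control) {
  if (any(x_treatment <= 0) || any(x_control <= 0)) {
    stop("log response ratio needs positive inputs")
  }
  log(x_treatment) - log(x_control)
}

# quadrant from the two effect-size signs; zero counts as the "win" half
# so the control sits at the origin as the reference, not a loss
quadrant_label <- function(lnrr_yield, lnrr_wpc) {
  y <- ifelse(lnrr_yield >= 0, "win", "lose")
  w <- ifelse(lnrr_wpc >= 0, "win", "lose")
  paste(y, w, sep = "-")
}

#' Run the scenario grid
#'
#' Simulates every (year x soil x policy) combination, always adding a
#' rainfed policy if absent, and returns one row per run with yield, crop
#' water productivity (dry-matter basis), irrigation summary and the
#' season's rainfall class.  Rows are sorted deterministically by soil,
#' policy and year.
#'
#' @param years named list of `weather_series` (or of [season_spec()]s,
#'   which are synthesized).
#' @param soils named list of [soil_profile()]s.
#' @param params a [crop_params()].
#' @param calendar a [crop_calendar()].
#' @param policies list of [irrigation_policy()]s.
#' @param class_mean_mm,class_band season-classification parameters.
#' @return list with `results` (data.frame: year, soil, policy, threshold,
#'   yield_t_ha, wpc_kg_m3, irrigation_count, irrigation_total_mm,
#'   rain_total_mm, season_class, stress_days) and `events` (data.frame of
#'   every irrigation event with its year/soil/policy).
#' @export
run_grid <- function(years, soils, params, calendar, policies,
                     class_mean_mm = 284.5, class_band = 0.10) {
  stopifnot(length(years) >= 1, length(policies) >= 1, length(soils) >= 1)
  if (is.null(names(years))) names(years) <- paste0("year", seq_along(years))
  if (is.null(names(soils))) names(soils) <- paste0("soil", seq_along(soils))
  years <- lapply(years, function(y) {
    if (inherits(y, "season_spec")) synthesize_season(y) else y
  })
  pnames <- vapply(policies, `[[`, "", "name")
  if (!"rainfed" %in% pnames) {
    policies <- c(policies, list(irrigation_policy("rainfed")))
    pnames <- c(pnames, "rainfed")
  }
  names(policies) <- pnames

  rows <- list()
  ev <- list()
  for (so in sort(names(soils))) {
    for (pn in pnames) {
      for (yr in sort(names(years))) {
        res <- run_season(years[[yr]], soils[[so]], params, calendar,
                          policies[[pn]])
        rows[[length(rows) + 1L]] <- data.frame(
          year = yr, soil = so, policy = pn,
          threshold = if (is.null(policies[[pn]]$threshold)) NA_real_
                      else policies[[pn]]$threshold,
          yield_t_ha = res$yield_t_ha, wpc_kg_m3 = res$wpc_kg_m3,
          irrigation_count = res$irrigation_count,
          irrigation_total_mm = res$irrigation_total_mm,
          rain_total_mm = res$rain_total_mm,
          season_class = classify_season(res$rain_total_mm,
                                         class_mean_mm, class_band),
          stress_days = res$stress_days,
          stringsAsFactors = FALSE)
        if (nrow(res$irrigation_log)) {
          ev[[length(ev) + 1L]] <- data.frame(
            year = yr, soil = so, policy = pn,
            res$irrigation_log, stringsAsFactors = FALSE)
        }
      }
    }
  }
  results <- do.call(rbind, rows)
  results <- results[order(results$soil, results$policy, results$year), ]
  rownames(results) <- NULL
  events <- if (length(ev)) do.call(rbind, ev) else {
    data.frame(year = character(), soil = character(), policy = character(),
               dap = integer(), mm = numeric())
  }
  list(results = results, events = events)
}

#' Yield vs water-productivity trade-off table
#'
#' For each policy (within each soil and season-class group) the log
#' response ratios of the group-mean yield and group-mean crop water
#' productivity against the control policy, with the quadrant label
#' (win-win, win-lose, lose-win, lose-lose); a zero effect on an axis
#' counts as the win half, so the control sits at the origin.
#'
#' @param results the `results` data.frame from [run_grid()].
#' @param control control policy name (default `"fc50"`).
#' @param grouping `"all"` or a subset of `{"wet", "normal", "dry"}`;
#'   `"all"` pools every year.
#' @return data.frame with soil, group, policy, mean yield and wpc, the
#'   two log response ratios and the quadrant label.
#' @export
tradeoff_table <- function(results, control = "fc50", grouping = "all") {
  out <- list()
  for (so in sort(unique(results$soil))) {
    for (grp in grouping) {
      sub <- results[results$soil == so, ]
      if (grp != "all") sub <- sub[sub$season_class == grp, ]
      if (!nrow(sub)) next
      if (!control %in% sub$policy) {
        stop("control policy '", control, "' missing in group ", grp)
      }
      agg <- stats::aggregate(cbind(yield_t_ha, wpc_kg_m3) ~ policy,
                              data = sub, FUN = mean)
      cy <- agg$yield_t_ha[agg$policy == control]
      cw <- agg$wpc_kg_m3[agg$policy == control]
      out[[length(out) + 1L]] <- data.frame(
        soil = so, group = grp, policy = agg$policy,
        mean_yield_t_ha = agg$yield_t_ha, mean_wpc_kg_m3 = agg$wpc_kg_m3,
        lnrr_yield = lnrr(agg$yield_t_ha, cy),
        lnrr_wpc = lnrr(agg$wpc_kg_m3, cw),
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, out)
  tab$quadrant <- quadrant_label(tab$lnrr_yield, tab$lnrr_wpc)
  rownames(tab) <- NULL
  tab
}

#' Pearson correlation of stage irrigation with seasonal yield
#'
#' For each (policy, developmental stage) cell, the Pearson correlation
#' across years between the irrigation depth applied within the stage
#' window and the seasonal yield.  Cells where either variable has zero
#' variance (e.g. a rainfed policy) are returned as `NA`.
#'
#' @param grid the list returned by [run_grid()].
#' @param calendar a [crop_calendar()] providing the stage windows.
#' @param soil soil name to analyse (default: first in the results).
#' @return An object of class `stage_correlation`: list with the `r`
#'   matrix (policies x stages), the per-cell sample size `n`, the stage
#'   window table and the soil.
#' @export
stage_correlation_matrix <- function(grid, calendar, soil = NULL) {
  results <- grid$results
  events <- grid$events
  if (is.null(soil)) soil <- sort(unique(results$soil))[1]
  results <- results[results$soil == soil, ]
  events <- events[events$soil == soil, , drop = FALSE]
  years <- sort(unique(results$year))
  if (length(years) < 3) stop("need at least 3 years per cell")
  sw <- stage_windows(calendar)
  policies <- sort(unique(results$policy))
  r <- matrix(NA_real_, length(policies), nrow(sw),
              dimnames = list(policies, sw$stage))
  for (p in policies) {
    yv <- vapply(years, function(y) {
      results$yield_t_ha[results$policy == p & results$year == y][1]
    }, numeric(1))
    for (s in seq_len(nrow(sw))) {
      xv <- vapply(years, function(y) {
        e <- events[events$policy == p & events$year == y, , drop = FALSE]
        sum(e$mm[e$dap >= sw$from_dap[s] & e$dap <= sw$to_dap[s]])
      }, numeric(1))
      if (stats::sd(xv) > 0 && stats::sd(yv) > 0) {
        r[p, sw$stage[s]] <- stats::cor(xv, yv, method = "pearson")
      }
    }
  }
  structure(list(r = r, n = length(years), stages = sw, soil = soil),
            class = "stage_correlation")
}

#' @export
print.stage_correlation <- function(x, ...) {
  cat("stage-correlation matrix (", x$soil, ", n = ", x$n, " years)\n",
      sep = "")
  print(round(x$r, 3))
  invisible(x)
}
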