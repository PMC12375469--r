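# Daily root-zone water balance: top-down infiltration with
# saturation-excess runoff, cascade drainage toward field capacity,
# evaporation from the surface layer and transpiration extraction from
# root-zone quarters.  All internal bookkeeping is in mm of water.

EVAP_LAYER_M <- 0.05  # thin surface layer subject to soil evaporation

# fill compartments to saturation top-down; excess leaves as runoff
infiltrate <- function(theta, profile, water_mm) {
  comp <- profile$compartments
  tmm <- comp$thickness * 1000
  for (i in seq_along(theta)) {
    if (water_mm <= 0) break
    room <- (comp$theta_sat[i] - theta[i]) * tmm[i]
    add <- min(room, water_mm)
    theta[i] <- theta[i] + add / tmm[i]
    water_mm <- water_mm - add
  }
  list(theta = theta, runoff = water_mm)
}

# each compartment releases tau * (water above field capacity); the release
# cascades into the compartment below (capped at saturation, any excess
# passing straight through); bottom outflow is deep drainage
drain_cascade <- function(theta, profile) {
  comp <- profile$compartments
  tmm <- comp$thickness * 1000
  inflow <- 0
  for (i in seq_along(theta)) {
    avail <- theta[i] * tmm[i] + inflow
    excess <- max(avail - comp$theta_fc[i] * tmm[i], 0)
    drained <- profile$tau * excess
    out <- drained + max(avail - drained - comp$theta_sat[i] * tmm[i], 0)
    theta[i] <- (avail - out) / tmm[i]
    inflow <- out
  }
  list(theta = theta, drainage = inflow)
}

# evaporate from the surface layer down to the air-dry floor, top-down
extract_evaporation <- function(theta, profile, demand_mm) {
  comp <- profile$compartments
  ov <- overlap_m(profile, 0, EVAP_LAYER_M)
  taken <- 0
  for (i in which(ov > 0)) {
    if (demand_mm <= taken) break
    avail <- max(theta[i] - comp$theta_ad[i], 0) * ov[i] * 1000
    take <- min(avail, demand_mm - taken)
    theta[i] <- theta[i] - take / (comp$thickness[i] * 1000)
    taken <- taken + take
  }
  list(theta = theta, evaporation = taken)
}

# transpiration from four equal root-zone quarters weighted 40-30-20-10;
# within a quarter extraction is proportional to water above wilting point;
# unmet quarter demand is not redistributed
extract_transpiration <- function(theta, profile, demand_mm, zr,
                                  weights = c(0.40, 0.30, 0.20, 0.10)) {
  if (abs(sum(weights) - 1) > 1e-9) stop("extraction weights must sum to 1")
  comp <- profile$compartments
  taken <- 0
  bounds <- zr * seq(0, 1, length.out = length(weights) + 1)
  for (q in seq_along(weights)) {
    ov <- overlap_m(profile, bounds[q], bounds[q + 1])
    avail_i <- pmax(theta - comp$theta_wp, 0) * ov * 1000
    avail <- sum(avail_i)
    want <- weights[q] * demand_mm
    take <- min(want, avail)
    if (take > 0) {
      share <- avail_i / avail
      theta <- theta - take * share / (comp$thickness * 1000)
    }
    taken <- taken + take
  }
  list(theta = theta, transpiration = taken)
}

#' Advance the soil water balance by one day
#'
#' Applies, in order: (1) infiltration of the day's rain plus irrigation,
#' filling compartments to saturation top-down with the excess leaving as
#' surface runoff; (2) cascade drainage of water above field capacity at
#' fraction `tau` per day, the bottom outflow leaving as deep drainage;
#' (3) soil evaporation from the top 0.10 m, floored at air-dry water
#' content; (4) transpiration extraction from four equal root-zone quarters
#' under the 40-30-20-10 weighting, floored at wilting point, with unmet
#' demand reducing the realized transpiration.  The change in profile
#' storage closes against the fluxes to numerical precision.
#'
#' @param theta per-compartment volumetric water content.
#' @param profile a [soil_profile()].
#' @param water_in rain + irrigation reaching the surface, mm.
#' @param e_demand potential soil evaporation, mm.
#' @param tr_demand potential crop transpiration, mm.
#' @param zr rooting depth, m.
#' @param weights extraction weights over root-zone quarters (sum to 1).
#' @return A list with the updated `theta` and `fluxes` (mm): `runoff`,
#'   `drainage`, `evaporation`, `transpiration`.
#' @export
step_water_balance <- function(theta, profile, water_in, e_demand, tr_demand,
                               zr, weights = c(0.40, 0.30, 0.20, 0.10)) {
  if (water_in < 0 || e_demand < 0 || tr_demand < 0) {
    stop("water input and demands must be >= 0")
  }
  s1 <- infiltrate(theta, profile, water_in)
  s2 <- drain_cascade(s1$theta, profile)
  s3 <- extract_evaporation(s2$theta, profile, e_demand)
  s4 <- extract_transpiration(s3$theta, profile, tr_demand, zr, weights)
  list(theta = s4$theta,
       fluxes = list(runoff = s1$runoff, drainage = s2$drainage,
                     evaporation = s3$evaporation,
                     transpiration = s4$transpiration))
}

# total profile storage, mm
profile_water <- function(theta, profile) {
  sum(theta * profile$compartments$thickness * 1000)
}

# soil-evaporation reduction coefficient from surface-layer wetness:
# 1 while the surface layer holds readily evaporable water (>= wilting
# point), declining linearly to 0 at air-dry
kr_coefficient <- function(theta, profile) {
  ov <- overlap_m(profile, 0, EVAP_LAYER_M)
  sel <- ov > 0
  ts <- sum(theta[sel] * ov[sel]) / sum(ov[sel])
  wp <- sum(profile$compartments$theta_wp[sel] * ov[sel]) / sum(ov[sel])
  ad <- sum(profile$compartments$theta_ad[sel] * ov[sel]) / sum(ov[sel])
  if (ts >= wp) 1 else clip((ts - ad) / (wp - ad), 0, 1)
}
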