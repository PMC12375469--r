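# Layered soil profile discretized into thin compartments, with a
# texture-class pedotransfer lookup for the hydraulic constants.

# class hydraulic constants (volumetric, m3 m-3); air-dry = wp/2
texture_lookup <- function() {
  data.frame(
    texture   = c("sandy loam", "loamy sand"),
    theta_sat = c(0.41, 0.38),
    theta_fc  = c(0.22, 0.16),
    theta_wp  = c(0.10, 0.08),
    stringsAsFactors = FALSE
  )
}

#' Build a discretized soil profile from layer descriptions
#'
#' Layers are given as contiguous depth intervals with a texture class
#' (plus optional bulk density, gravel fraction and overrides of the
#' hydraulic constants); hydraulic constants default to a pedotransfer
#' lookup by texture class (sandy loam: saturation 0.41, field capacity
#' 0.22, wilting point 0.10; loamy sand: 0.38, 0.16, 0.08; air-dry is half
#' the wilting point).  The profile is discretized into equal compartments
#' and, if needed, the deepest layer is extended so the profile covers
#' `depth_m`.
#'
#' @param layers data.frame with columns `top_m`, `bottom_m`, `texture`,
#'   optionally `bulk_density`, `gravel_pct`, `theta_sat`, `theta_fc`,
#'   `theta_wp`.
#' @param depth_m total discretized depth (>= maximum root depth).
#' @param compartment_m compartment thickness, m.
#' @param tau drainage coefficient: fraction of the water above field
#'   capacity that a compartment releases per day.
#' @return An object of class `soil_profile`: the per-compartment table of
#'   depths and hydraulic constants plus `tau` and the total depth.
#' @examples
#' soil_profile(data.frame(top_m = 0, bottom_m = 0.45, texture = "sandy loam"))
#' @export
soil_profile <- function(layers, depth_m = 0.60, compartment_m = 0.05,
                         tau = 0.5) {
  stopifnot(is.data.frame(layers), nrow(layers) >= 1)
  req <- c("top_m", "bottom_m", "texture")
  if (length(setdiff(req, names(layers)))) {
    stop("layers needs columns: ", paste(req, collapse = ", "))
  }
  layers <- layers[order(layers$top_m), , drop = FALSE]
  if (abs(layers$top_m[1]) > 1e-12) stop("layers must start at depth 0")
  if (nrow(layers) > 1 &&
      any(abs(layers$top_m[-1] - layers$bottom_m[-nrow(layers)]) > 1e-12)) {
    stop("layers must be contiguous")
  }
  if (any(layers$bottom_m <= layers$top_m)) stop("layer bottom must exceed top")

  lut <- texture_lookup()
  idx <- match(tolower(layers$texture), lut$texture)
  if (anyNA(idx)) {
    stop("unknown texture class: ",
         paste(unique(layers$texture[is.na(idx)]), collapse = ", "),
         " (known: ", paste(lut$texture, collapse = ", "), ")")
  }
  fill <- function(nm) {
    v <- lut[[nm]][idx]
    if (nm %in% names(layers)) {
      ov <- layers[[nm]]
      v <- ifelse(is.na(ov), v, ov)
    }
    v
  }
  theta_sat <- fill("theta_sat")
  theta_fc  <- fill("theta_fc")
  theta_wp  <- fill("theta_wp")
  gravel <- if ("gravel_pct" %in% names(layers)) {
    ifelse(is.na(layers$gravel_pct), 0, layers$gravel_pct)
  } else rep(0, nrow(layers))
  if (any(!(0 < theta_wp & theta_wp < theta_fc & theta_fc < theta_sat &
              theta_sat < 1))) {
    stop("hydraulic constants must satisfy 0 < wp < fc < sat < 1")
  }
  if (any(gravel < 0 | gravel >= 100)) stop("gravel must be in [0, 100)")

  # extend deepest layer to the discretized depth
  depth_m <- max(depth_m, max(layers$bottom_m))
  bottoms <- layers$bottom_m
  bottoms[nrow(layers)] <- depth_m

  n <- ceiling(depth_m / compartment_m - 1e-9)
  top <- (seq_len(n) - 1) * compartment_m
  bot <- pmin(seq_len(n) * compartment_m, depth_m)
  mid <- (top + bot) / 2
  li <- findInterval(mid, c(0, bottoms), rightmost.closed = TRUE)
  li <- clip(li, 1, nrow(layers))

  comp <- data.frame(
    top = top, bottom = bot, thickness = bot - top,
    theta_sat = theta_sat[li], theta_fc = theta_fc[li],
    theta_wp = theta_wp[li], theta_ad = theta_wp[li] / 2,
    gravel = gravel[li]
  )
  structure(list(compartments = comp, tau = tau, depth = depth_m,
                 layers = layers), class = "soil_profile")
}

#' Initial per-compartment water content
#'
#' @param profile a [soil_profile()].
#' @param at `"fc"`, `"wp"`, `"sat"` or a single volumetric water content
#'   applied to every compartment.
#' @return Numeric vector of volumetric water contents, one per compartment.
#' @export
initial_water_state <- function(profile, at = "fc") {
  comp <- profile$compartments
  if (is.character(at)) {
    switch(at,
           fc = comp$theta_fc, wp = comp$theta_wp, sat = comp$theta_sat,
           stop("unknown initial state: ", at))
  } else {
    stopifnot(is.numeric(at))
    if (length(at) == 1) rep(at, nrow(comp)) else {
      stopifnot(length(at) == nrow(comp)); at
    }
  }
}

# thickness of each compartment overlapping the depth interval [from, to]
overlap_m <- function(profile, from, to) {
  comp <- profile$compartments
  pmax(0, pmin(comp$bottom, to) - pmax(comp$top, from))
}

# thickness-weighted mean of a per-compartment quantity over [0, zr]
rootzone_mean <- function(x, profile, zr) {
  w <- overlap_m(profile, 0, zr)
  sum(x * w) / sum(w)
}

#' Root-zone stored water as an equivalent depth
#'
#' Stored water in the root zone, `Wr = 1000 * theta_bar * zr *
#' (1 - gravel/100)`, with `theta_bar` the thickness-weighted mean water
#' content over the interval from the surface to the rooting depth `zr` and
#' gravel the thickness-weighted mean gravel volume fraction.
#'
#' @param theta per-compartment volumetric water content.
#' @param profile a [soil_profile()].
#' @param zr rooting depth, m (0 < zr <= profile depth).
#' @return Stored root-zone water, mm.
#' @examples
#' p <- soil_profile(data.frame(top_m = 0, bottom_m = 0.45,
#'                              texture = "sandy loam"))
#' root_zone_water(initial_water_state(p, 0.20), p, zr = 0.47)
#' @export
root_zone_water <- function(theta, profile, zr) {
  if (zr <= 0 || zr > profile$depth + 1e-9) {
    stop("zr must be in (0, profile depth]")
  }
  tb <- rootzone_mean(theta, profile, zr)
  gb <- rootzone_mean(profile$compartments$gravel, profile, zr)
  1000 * tb * zr * (1 - gb / 100)
}
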