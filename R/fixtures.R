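# Packaged fixtures: the two experimental-site soils, the calibrated
# potato parameter set, the season calendar and a season-spec emulating
# the calibration year's rainfall total.  Stored as YAML under extdata so
# they are editable and round-trip through plain text.

#' Load a packaged fixture
#'
#' Available fixtures: `"montcalm"` and `"mecosta"` (three-layer soil
#' profiles, sandy loam and loamy sand), `"potato_2023"` (the calibrated
#' crop parameter set), `"calendar_2023"` (stage calendar) and
#' `"season_2023like"` (a season spec with a 312.8 mm rainfall target).
#'
#' @param name fixture name.
#' @return A [soil_profile()], [crop_params()], [crop_calendar()] or
#'   [season_spec()] according to the fixture.
#' @examples
#' load_fixture("potato_2023")$hi0
#' @export
load_fixture <- function(name) {
  known <- c("montcalm", "mecosta", "potato_2023", "calendar_2023",
             "season_2023like")
  if (!name %in% known) {
    stop("unknown fixture '", name, "' (known: ",
         paste(known, collapse = ", "), ")")
  }
  path <- system.file("extdata", paste0(name, ".yml"), package = "potatosim",
                      mustWork = TRUE)
  y <- yaml::read_yaml(path)
  switch(y$kind,
    soil = {
      layers <- do.call(rbind, lapply(y$layers, function(l) {
        data.frame(top_m = l$top_m, bottom_m = l$bottom_m,
                   texture = l$texture,
                   bulk_density = if (is.null(l$bulk_density)) NA_real_
                                  else l$bulk_density,
                   stringsAsFactors = FALSE)
      }))
      soil_profile(layers, depth_m = y$depth_m,
                   compartment_m = y$compartment_m, tau = y$tau)
    },
    crop = do.call(crop_params, y$params),
    calendar = do.call(crop_calendar, y$calendar),
    season = do.call(season_spec, y$spec),
    stop("unrecognized fixture kind: ", y$kind)
  )
}
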