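#' Published British Columbia reference travel distances
#'
#' Population-weighted mean one-way street distance (km) and duration (min)
#' from small health areas to their nearest emergency department, aggregated
#' to the five BC health authorities and to the urban/rural strata, together
#' with the published per-visit CO2-equivalent emissions (kg) for each. These
#' serve as printed inputs where the full provincial road network is not
#' available; the emission column is what [calibrate_emission_factor()] is
#' pinned against.
#'
#' @param level `"authority"` (five health authorities) or `"stratum"`
#'   (urban/rural).
#' @return tibble: `scope`, `distance_km`, `duration_min` (NA for strata,
#'   which were published without durations), `emissions_kg`.
#' @export
bc_reference_distances <- function(level = c("authority", "stratum")) {
  level <- match.arg(level)
  path <- system.file("extdata", "bc_authority_reference.csv",
                      package = "patientcost", mustWork = TRUE)
  ref <- as_tibble(utils::read.csv(path, colClasses = c(
    level = "character", scope = "character", distance_km = "numeric",
    duration_min = "numeric", emissions_kg = "numeric"
  )))
  ref[ref$level == level, setdiff(names(ref), "level")]
}
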