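# Annual population simulation: visit rates applied to a simulated
# population, unit costs applied to visits, totals by service and region,
# plus hybrid-care and ED-avoidance scenarios.

#' Default region shares for the simulated population
#'
#' Shares of the population across the five BC health authorities,
#' reflecting the provincial distribution (Fraser largest, Northern
#' smallest).
#'
#' @return named numeric vector summing to 1.
#' @export
default_region_shares <- function() {
  c("Fraser" = 0.37, "Interior" = 0.16, "Northern" = 0.06,
    "Vancouver Coastal" = 0.24, "Vancouver Island" = 0.17)
}

#' Default single-year age distribution
#'
#' Piecewise-uniform pyramid over ages 0-100 placing 14% of the population
#' at ages 0-14, 65% at 15-64, and 21% at 65+, approximating the provincial
#' age structure. Binned age shares for any age-group definition are
#' obtained by summing this pyramid, which is what lets age bins be
#' redefined without touching the population.
#'
#' @return numeric vector of shares named by age 0-100, summing to 1.
#' @export
default_age_pyramid <- function() {
  shares <- c(rep(0.14 / 15, 15), rep(0.65 / 50, 50), rep(0.21 / 36, 36))
  names(shares) <- 0:100
  shares
}

#' Specify a simulated population
#'
#' @param size number of persons (default 100,000).
#' @param region_shares named fractions summing to 1 (names are the region
#'   scopes costs will be looked up under).
#' @param age_pyramid single-year age shares summing to 1.
#' @param age_groups age-bin table; drives how the pyramid is binned and
#'   which bin carries lost productivity.
#' @return list of class `population_spec`.
#' @export
population_spec <- function(size = 100000,
                            region_shares = default_region_shares(),
                            age_pyramid = default_age_pyramid(),
                            age_groups = default_age_groups()) {
  assert_number(size, "size", min = 0)
  if (is.null(names(region_shares)) ||
      any(region_shares < 0) || abs(sum(region_shares) - 1) > 1e-9) {
    validation_error("region shares must be named, lie in [0, 1], and sum to 1")
  }
  if (any(age_pyramid < 0) || abs(sum(age_pyramid) - 1) > 1e-9) {
    validation_error("age pyramid shares must lie in [0, 1] and sum to 1")
  }
  age_groups <- validate_age_groups(age_groups)
  structure(
    list(size = size, region_shares = region_shares,
         age_pyramid = age_pyramid, age_groups = age_groups),
    class = "population_spec"
  )
}

#' Age-group shares implied by a population's pyramid
#'
#' @param pop a [population_spec()].
#' @return named numeric vector of shares, one per age-bin label.
#' @export
age_group_shares <- function(pop) {
  ages <- as.numeric(names(pop$age_pyramid))
  bins <- pop$age_groups
  out <- vapply(seq_len(nrow(bins)), function(i) {
    sum(pop$age_pyramid[ages >= bins$min_age[i] & ages < bins$max_age[i]])
  }, 0)
  names(out) <- bins$label
  out
}

#' Re-bin a population's age groups
#'
#' Replaces the age-group definition (e.g. 0-14/15-64/65+ by 0-19/20-59/
#' 60+); bin shares are recomputed from the single-year pyramid, and the
#' `working` flag of the new bin table decides which bin carries lost
#' productivity, which is how labor-force participation assumptions enter.
#' Bins must partition all ages, with exactly one working bin.
#'
#' @param pop a [population_spec()].
#' @param bins an age-bin table such as [alternate_age_groups()].
#' @return a new `population_spec`.
#' @export
rebin_ages <- function(pop, bins) {
  population_spec(pop$size, pop$region_shares, pop$age_pyramid, bins)
}

#' Annual visit rates per person
#'
#' Defaults: 2.7 physician visits, 2.5 telehealth visits (48 visits per
#' 1000 people per week converted to an annual per-person rate), and
#' 0.42573 ED visits per person-year, of which 60% present as CTAS I-III.
#'
#' @param physician,telehealth,ed visits per person-year.
#' @param ctas_i_iii_fraction fraction of ED visits triaged CTAS I-III.
#' @return list of class `visit_rates`.
#' @export
visit_rates <- function(physician = 2.7, telehealth = 2.5, ed = 0.42573,
                        ctas_i_iii_fraction = 0.6) {
  for (nm in c("physician", "telehealth", "ed")) assert_number(get(nm), nm, min = 0)
  assert_number(ctas_i_iii_fraction, "ctas_i_iii_fraction", min = 0, max = 1)
  structure(
    list(physician = physician, telehealth = telehealth, ed = ed,
         ctas_i_iii_fraction = ctas_i_iii_fraction),
    class = "visit_rates"
  )
}

#' Convert a weekly per-1000 visit rate to an annual per-person rate
#'
#' @param per_1000_per_week visits per 1000 people per week.
#' @param digits decimals to round to (default 1, as such rates are quoted).
#' @return visits per person per year.
#' @export
weekly_per_1000_to_annual <- function(per_1000_per_week, digits = 1) {
  round(per_1000_per_week * 52 / 1000, digits)
}

#' Allocate annual visits across services, regions, and age groups
#'
#' Total visits per service are `size x rate`; they are distributed over
#' region x age cells according to the population distribution. Expected
#' mode is the deterministic real-valued allocation; stochastic mode draws
#' a multinomial allocation with the given seed.
#'
#' @param pop a [population_spec()].
#' @param rates a [visit_rates()].
#' @param mode `"expected"` or `"stochastic"`.
#' @param seed seed for stochastic mode.
#' @return tibble: `service_type`, `region`, `age_group`, `visits`.
#' @export
allocate_visits <- function(pop, rates, mode = c("expected", "stochastic"),
                            seed = NULL) {
  mode <- match.arg(mode)
  service_totals <- c(
    ED_CTAS_I_III = pop$size * rates$ed * rates$ctas_i_iii_fraction,
    ED_CTAS_IV_V = pop$size * rates$ed * (1 - rates$ctas_i_iii_fraction),
    PHYSICIAN = pop$size * rates$physician,
    TELEHEALTH = pop$size * rates$telehealth
  )
  ashares <- age_group_shares(pop)
  cells <- tidyr::expand_grid(
    region = names(pop$region_shares),
    age_group = names(ashares)
  )
  cells$share <- pop$region_shares[cells$region] * ashares[cells$age_group]
  draw <- function(total) {
    if (mode == "expected") {
      total * cells$share
    } else {
      as.numeric(stats::rmultinom(1, size = round(total), prob = cells$share))
    }
  }
  body <- function() {
    purrr::map_dfr(names(service_totals), function(s) {
      tibble(service_type = s, region = cells$region,
             age_group = cells$age_group, visits = draw(service_totals[[s]]))
    })
  }
  if (mode == "stochastic") {
    if (is.null(seed)) validation_error("stochastic allocation requires a seed")
    with_local_seed(seed, body())
  } else {
    body()
  }
}

#' Annual totals of costs, distance, and emissions
#'
#' Applies the unit-cost database to an allocation of visits: each cell's
#' cost is visits x unit cost, its travel is visits x one-way distance (zero
#' for telehealth), and its emissions come from the per-visit emission
#' column, reported in metric tons.
#'
#' @param visits allocation from [allocate_visits()] (`region` values must
#'   match the `region_scope` values of the database).
#' @param unit_costs database from [build_unit_cost_database()].
#' @return list of class `simulation_result`: `cells` (per service x region
#'   x age), `by_service_region` (costs in the shape unit-cost reports
#'   use), `by_service`, and `totals` (visits, cost, distance_km,
#'   emissions_t).
#' @export
annual_totals <- function(visits, unit_costs) {
  uc <- unit_costs |>
    dplyr::select("region_scope", "service_type", "age_group",
                  unit_total = "total", "distance_km", "emissions_kg")
  cells <- dplyr::left_join(
    visits, uc,
    by = c(region = "region_scope", service_type = "service_type",
           age_group = "age_group")
  )
  if (any(is.na(cells$unit_total))) {
    bad <- cells[is.na(cells$unit_total), ][1, ]
    config_error(paste0(
      "no unit cost for (", bad$region, ", ", bad$service_type, ", ",
      bad$age_group, ")"
    ))
  }
  cells <- cells |>
    dplyr::mutate(
      cost = .data$visits * .data$unit_total,
      distance_km = .data$visits * .data$distance_km,
      emissions_t = .data$visits * .data$emissions_kg / 1000
    ) |>
    dplyr::select(-"unit_total", -"emissions_kg")
  by_service_region <- cells |>
    dplyr::group_by(.data$service_type, .data$region) |>
    dplyr::summarise(
      visits = sum(.data$visits), cost = sum(.data$cost),
      distance_km = sum(.data$distance_km),
      emissions_t = sum(.data$emissions_t), .groups = "drop"
    )
  by_service <- by_service_region |>
    dplyr::group_by(.data$service_type) |>
    dplyr::summarise(
      visits = sum(.data$visits), cost = sum(.data$cost),
      distance_km = sum(.data$distance_km),
      emissions_t = sum(.data$emissions_t), .groups = "drop"
    )
  structure(
    list(
      cells = cells,
      by_service_region = by_service_region,
      by_service = by_service,
      totals = list(
        visits = sum(cells$visits), cost = sum(cells$cost),
        distance_km = sum(cells$distance_km),
        emissions_t = sum(cells$emissions_t)
      )
    ),
    class = "simulation_result"
  )
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf(
    "<simulation_result> %s visits, $%s, %s km one-way, %.2f t CO2e\n",
    format(round(x$totals$visits), big.mark = ","),
    format(round(x$totals$cost), big.mark = ","),
    format(round(x$totals$distance_km), big.mark = ","),
    x$totals$emissions_t
  ))
  invisible(x)
}

#' Hybrid-care scenarios
#'
#' Scales a base in-person service linearly: at in-person fraction f, visits,
#' travel distance, and emissions are f times the base. If unit costs are
#' supplied, total cost is recomputed with the telehealth unit cost applied
#' to the diverted (1 - f) share.
#'
#' @param base_visits,base_distance_km,base_emissions_t base in-person
#'   annual totals.
#' @param in_person_fractions fractions in [0, 1].
#' @param in_person_cost_per_visit,telehealth_cost_per_visit optional
#'   per-visit costs used to recompute scenario costs.
#' @return tibble: `in_person_fraction`, `visits`, `distance_km`,
#'   `emissions_t` (and `cost` when unit costs are given).
#' @export
hybrid_scenarios <- function(base_visits, base_distance_km, base_emissions_t,
                             in_person_fractions,
                             in_person_cost_per_visit = NULL,
                             telehealth_cost_per_visit = NULL) {
  if (any(in_person_fractions < 0 | in_person_fractions > 1)) {
    validation_error("in-person fractions must lie in [0, 1]")
  }
  out <- tibble(
    in_person_fraction = in_person_fractions,
    visits = round_half_up(base_visits * in_person_fractions),
    distance_km = base_distance_km * in_person_fractions,
    emissions_t = base_emissions_t * in_person_fractions
  )
  if (!is.null(in_person_cost_per_visit) && !is.null(telehealth_cost_per_visit)) {
    out$cost <- base_visits * (
      in_person_fractions * in_person_cost_per_visit +
        (1 - in_person_fractions) * telehealth_cost_per_visit
    )
  }
  out
}

#' ED-avoidance scenario
#'
#' Reports the share of ED activity avoided when `avoided_fraction` of ED
#' visits are handled by telehealth instead: the row carries the avoided
#' visits (rounded half-up), and the distance and emissions they would have
#' generated.
#'
#' @param base_visits,base_distance_km,base_emissions_t base annual ED
#'   totals.
#' @param avoided_fraction fraction of ED visits avoided (default 0.6).
#' @return one-row tibble: `avoided_fraction`, `visits`, `distance_km`,
#'   `emissions_t`.
#' @export
ed_avoidance <- function(base_visits, base_distance_km, base_emissions_t,
                         avoided_fraction = 0.6) {
  assert_number(avoided_fraction, "avoided_fraction", min = 0, max = 1)
  tibble(
    avoided_fraction = avoided_fraction,
    visits = round_half_up(base_visits * avoided_fraction),
    distance_km = base_distance_km * avoided_fraction,
    emissions_t = base_emissions_t * avoided_fraction
  )
}
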