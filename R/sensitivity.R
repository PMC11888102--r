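# Deterministic one-way sensitivity analysis: one parameter is swept over a
# grid while all others stay at base case; every scenario is a pure function
# of (base inputs, overridden value).

#' Scenario grid for one-way sensitivity analysis
#'
#' Default grids: wage $16.75 (minimum wage), $20, $25, $30.54 (base case),
#' then $5 increments from $35 to $50; caregiver attendance 0, 25, 50 (base
#' case), 75 and 100%; travel scaling 50%-150% of base in 10% increments.
#'
#' @param parameter one of `"wage"`, `"attendance"`, `"travel_scale"`.
#' @param values optional numeric grid replacing the default.
#' @return list of class `scenario_grid` with `parameter` and `values`.
#' @export
scenario_grid <- function(parameter = c("wage", "attendance", "travel_scale"),
                          values = NULL) {
  parameter <- match.arg(parameter)
  if (is.null(values)) {
    values <- switch(parameter,
      wage = c(16.75, 20, 25, 30.54, 35, 40, 45, 50),
      attendance = c(0, 0.25, 0.50, 0.75, 1.00),
      travel_scale = seq(0.5, 1.5, by = 0.1)
    )
  }
  if (parameter == "attendance" && any(values < 0 | values > 1)) {
    validation_error("attendance grid values must lie in [0, 1]")
  }
  structure(list(parameter = parameter, values = values), class = "scenario_grid")
}

grid_base_value <- function(parameter, params) {
  switch(parameter,
    wage = params$hourly_wage,
    attendance = unname(params$attendance$outpatient[["working"]]),
    travel_scale = 1.0
  )
}

apply_scenario <- function(parameter, value, scopes, params,
                           scale_distance = TRUE, scale_duration = TRUE) {
  if (parameter == "wage") {
    params$hourly_wage <- value
  } else if (parameter == "attendance") {
    # a single province-wide attendance assumption: every fraction takes the
    # scenario value, so the absolute cost step is identical across age groups
    params$attendance <- list(
      outpatient = c(child = value, working = value, senior = value),
      hospitalization = c(child = value, working = value, senior = value)
    )
  } else if (parameter == "travel_scale") {
    if (scale_distance) scopes$distance_km <- scopes$distance_km * value
    if (scale_duration) scopes$duration_min <- scopes$duration_min * value
  }
  list(scopes = scopes, params = params)
}

#' Run a one-way sensitivity sweep
#'
#' Rebuilds the unit-cost database once per grid value, holding every other
#' parameter at base case, and reports each row's total next to its delta
#' versus the base-case database.
#'
#' @param grid a [scenario_grid()]; must contain the base-case value of its
#'   parameter (wage 30.54, attendance 0.50, travel scale 1.0 under default
#'   parameters), otherwise a validation error is raised.
#' @param scopes aggregated travel per scope (see
#'   [build_unit_cost_database()]).
#' @param params base-case [cost_parameters()].
#' @param profiles service time profiles.
#' @param age_groups age-bin table.
#' @param scale_distance,scale_duration for the travel grid, whether the
#'   scale factor applies to distance, duration, or (default) both jointly.
#' @return long tibble: `parameter`, `value`, `region_scope`,
#'   `service_type`, `age_group`, the three subunits, `total`,
#'   `delta_vs_base`.
#' @export
run_one_way <- function(grid, scopes, params = cost_parameters(),
                        profiles = default_service_profiles(),
                        age_groups = default_age_groups(),
                        scale_distance = TRUE, scale_duration = TRUE) {
  if (!inherits(grid, "scenario_grid")) {
    validation_error("`grid` must be a scenario_grid()")
  }
  base_value <- grid_base_value(grid$parameter, params)
  if (!any(abs(grid$values - base_value) < 1e-8)) {
    validation_error(sprintf(
      "the %s grid must contain the base-case value %s", grid$parameter,
      format(base_value)
    ))
  }
  base_db <- build_unit_cost_database(scopes, params, profiles, age_groups) |>
    dplyr::select("region_scope", "service_type", "age_group", base_total = "total")
  purrr::map_dfr(grid$values, function(v) {
    sc <- apply_scenario(grid$parameter, v, scopes, params,
                         scale_distance, scale_duration)
    build_unit_cost_database(sc$scopes, sc$params, profiles, age_groups) |>
      dplyr::mutate(parameter = grid$parameter, value = v, .before = 1) |>
      dplyr::left_join(base_db,
                       by = c("region_scope", "service_type", "age_group")) |>
      dplyr::mutate(delta_vs_base = .data$total - .data$base_total) |>
      dplyr::select(-"base_total", -"distance_km", -"duration_min", -"emissions_kg")
  })
}

#' Street-versus-haversine routing comparison
#'
#' Compares the two distance methods per region and summarizes how many
#' regions agree within the threshold; thin wrapper over
#' [compare_street_vs_haversine()] on a full geography.
#'
#' @param geography a `geography`.
#' @param threshold_km agreement threshold (default 10 km).
#' @return see [compare_street_vs_haversine()].
#' @export
routing_method_comparison <- function(geography, threshold_km = 10) {
  compare_street_vs_haversine(
    geography$regions, geography$facilities, geography$network, threshold_km
  )
}
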