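# Per-visit unit costs. Each unit cost is the sum of three subunits:
# lost productivity (human capital method: foregone time x average wage),
# informal caregiving (caregiver time x wage x attendance probability), and
# out-of-pocket expenses (vehicle, parking, meals, accommodation, data).
# Money is handled at cent precision; report views round half-up to dollars.

service_class <- function(service_type) {
  if (service_type == "HOSPITALIZATION") "hospitalization" else "outpatient"
}

age_role <- function(age_group, age_groups) {
  i <- match(age_group, age_groups$label)
  if (is.na(i)) i <- match(age_group, age_groups$role)
  if (is.na(i)) config_error(paste0("unknown age group: ", age_group))
  age_groups[i, ]
}

attendance_fraction <- function(params, service_type, role) {
  cls <- service_class(service_type)
  v <- params$attendance[[cls]]
  if (is.null(v) || !(role %in% names(v))) {
    config_error(paste0("no attendance fraction configured for ", cls, " / ", role))
  }
  unname(v[[role]])
}

#' Lost-productivity cost of one visit
#'
#' Values foregone paid or unpaid work by the human capital method: total
#' visit time (travel + wait + appointment) times the average hourly wage,
#' charged only to the working-age bin. Chargeable time is capped at
#' `productivity_cap_h_per_day` hours per 24-hour period, so a
#' hospitalization is charged 8 h per day of stay.
#'
#' @param age_group age-bin label or role.
#' @param vt a [visit_time()].
#' @param params [cost_parameters()].
#' @param service_type one of [SERVICE_TYPES].
#' @param age_groups age-bin table (default [default_age_groups()]).
#' @return cost in dollars.
#' @export
lost_productivity <- function(age_group, vt, params, service_type,
                              age_groups = default_age_groups()) {
  grp <- age_role(age_group, age_groups)
  if (!grp$working) return(0)
  cap <- params$productivity_cap_h_per_day
  hours <- if (service_class(service_type) == "hospitalization") {
    total <- vt$total_h + vt$stay_days * 24
    min(total, cap * ceiling(max(vt$stay_days, 1)))
  } else {
    min(vt$total_h, cap)
  }
  hours * params$hourly_wage
}

#' Informal-caregiving cost of one visit
#'
#' Caregiver time valued at the wage rate, weighted by the probability that
#' a caregiver attends (by age group and service class). The caregiver has
#' the same time commitment as the patient for outpatient visits; for
#' hospitalizations caregiver time is prorated to 8 h per day of stay.
#'
#' @inheritParams lost_productivity
#' @return cost in dollars.
#' @export
informal_caregiving <- function(age_group, service_type, vt, params,
                                age_groups = default_age_groups()) {
  grp <- age_role(age_group, age_groups)
  att <- attendance_fraction(params, service_type, grp$role)
  hours <- if (service_class(service_type) == "hospitalization") {
    params$productivity_cap_h_per_day * vt$stay_days
  } else {
    vt$total_h
  }
  att * hours * params$hourly_wage
}

#' Out-of-pocket cost of one in-person visit, itemized
#'
#' Vehicle cost is the distance basis times the per-km rate. Parking is one
#' city-core day for physician visits, one hospital day for ED visits, and
#' two hospital days for hospitalizations. One $15 meal is charged to the
#' patient for any ED visit; a hospitalization charges 3 caregiver meals per
#' day for the 2 admission/discharge days, weighted by the caregiver
#' attendance fraction. Caregiver accommodation (2 nights at the scope's
#' hotel rate, weighted by attendance) applies only to hospitalizations
#' whose one-way distance exceeds the 50 km threshold; it is always zero
#' for ED and physician visits.
#'
#' @param age_group age-bin label or role.
#' @param service_type one of [SERVICE_TYPES] (not `TELEHEALTH`).
#' @param distance_km one-way street distance to the facility.
#' @param scope region scope ("urban"/"rural" or an authority id) for
#'   parking and hotel rates.
#' @param params [cost_parameters()].
#' @param age_groups age-bin table.
#' @return named list: `vehicle`, `parking`, `meals`, `accommodation`,
#'   `data`, `total`.
#' @export
out_of_pocket <- function(age_group, service_type, distance_km, scope, params,
                          age_groups = default_age_groups()) {
  assert_number(distance_km, "distance_km", min = 0)
  grp <- age_role(age_group, age_groups)
  basis <- distance_km * (if (params$round_trip) 2 else 1)
  vehicle <- basis * params$vehicle_rate_per_km
  parking <- switch(service_type,
    PHYSICIAN = scope_rate(params, "parking_core_rate", scope),
    ED_CTAS_I_III = ,
    ED_CTAS_IV_V = scope_rate(params, "parking_hospital_rate", scope),
    HOSPITALIZATION = 2 * scope_rate(params, "parking_hospital_rate", scope),
    0
  )
  meals <- switch(service_type,
    ED_CTAS_I_III = ,
    ED_CTAS_IV_V = params$meal_value,
    HOSPITALIZATION = params$hospital_meals_per_day * params$hospital_meal_days *
      params$meal_value * attendance_fraction(params, service_type, grp$role),
    0
  )
  accommodation <- 0
  if (service_type == "HOSPITALIZATION" &&
      distance_km > params$accommodation_distance_threshold_km) {
    accommodation <- params$accommodation_nights *
      scope_rate(params, "hotel_rate", scope) *
      attendance_fraction(params, service_type, grp$role)
  }
  out <- list(vehicle = vehicle, parking = parking, meals = meals,
              accommodation = accommodation, data = 0)
  out$total <- vehicle + parking + meals + accommodation
  out
}

#' Per-visit CO2-equivalent emissions
#'
#' Linear in distance: distance x fuel consumption (L/km) x emission factor
#' (kg CO2e/L). The default factor of 2.1617 kg/L, combined with the
#' default 7.06 L/100 km, gives 0.1526 kg CO2e per km driven.
#'
#' @param distance_km travel distance in km (one-way by default; doubled
#'   when `params$round_trip` is set by the callers that apply the basis).
#' @param params [cost_parameters()].
#' @return kg CO2e.
#' @export
emissions_per_visit_kg <- function(distance_km, params = cost_parameters()) {
  if (any(distance_km < 0)) {
    abort("distance must be non-negative", class = "patientcost_invalid_argument")
  }
  distance_km * params$fuel_l_per_100km / 100 * params$emission_factor_kg_per_l
}

#' Calibrate the emission factor from a reference per-visit emission
#'
#' Solves emissions = distance x fuel/100 x factor for the factor, allowing
#' the engine to be pinned to a published per-visit emission figure.
#'
#' @param emissions_kg reference per-visit emissions (kg CO2e).
#' @param distance_km the distance that produced them (km).
#' @param fuel_l_per_100km fuel efficiency used (default 7.06).
#' @return emission factor in kg CO2e per litre.
#' @export
calibrate_emission_factor <- function(emissions_kg, distance_km, fuel_l_per_100km = 7.06) {
  assert_number(emissions_kg, "emissions_kg", min = 0)
  assert_number(distance_km, "distance_km", min = 1e-12)
  emissions_kg / (distance_km * fuel_l_per_100km / 100)
}

unit_cost_row <- function(scope, service_type, age_group, distance_km, duration_min,
                          params, profile, age_groups) {
  if (service_type == "TELEHEALTH") {
    return(telehealth_unit_cost(age_group, profile, params, age_groups) |>
             dplyr::mutate(region_scope = scope, .before = 1))
  }
  time_mult <- if (params$round_trip) 2 else 1
  vt <- visit_time(
    travel_min = duration_min * time_mult,
    wait_min = profile$wait_min,
    appointment_min = profile$appointment_min,
    stay_days = profile$stay_days
  )
  lp <- lost_productivity(age_group, vt, params, service_type, age_groups)
  cg <- informal_caregiving(age_group, service_type, vt, params, age_groups)
  oop <- out_of_pocket(age_group, service_type, distance_km, scope, params, age_groups)
  basis_km <- distance_km * time_mult
  tibble(
    region_scope = scope,
    service_type = service_type,
    age_group = age_group,
    distance_km = basis_km,
    duration_min = duration_min * time_mult,
    lost_productivity = round(lp, 2),
    informal_caregiving = round(cg, 2),
    out_of_pocket = round(oop$total, 2),
    total = round(lp, 2) + round(cg, 2) + round(oop$total, 2),
    emissions_kg = emissions_per_visit_kg(basis_km, params)
  )
}

#' Telehealth per-visit unit cost
#'
#' Travel time and travel-related expenses are zero: lost productivity and
#' caregiving are computed on wait + appointment time only, and the
#' out-of-pocket subunit is the data cost, a phone/internet-weighted rate
#' times the appointment minutes. The result is identical for every region
#' scope.
#'
#' @param age_group age-bin label or role.
#' @param profile one-row telehealth service profile (`wait_min`,
#'   `appointment_min`).
#' @param params [cost_parameters()].
#' @param age_groups age-bin table.
#' @return one-row unit-cost tibble (without `region_scope`).
#' @export
telehealth_unit_cost <- function(age_group, profile, params,
                                 age_groups = default_age_groups()) {
  vt <- visit_time(0, profile$wait_min, profile$appointment_min, 0)
  lp <- lost_productivity(age_group, vt, params, "TELEHEALTH", age_groups)
  cg <- informal_caregiving(age_group, "TELEHEALTH", vt, params, age_groups)
  data_rate <- params$telehealth_phone_weight * params$data_rate_phone +
    params$telehealth_internet_weight * params$data_rate_internet
  oop <- data_rate * profile$appointment_min
  tibble(
    service_type = "TELEHEALTH",
    age_group = age_group,
    distance_km = 0,
    duration_min = 0,
    lost_productivity = round(lp, 2),
    informal_caregiving = round(cg, 2),
    out_of_pocket = round(oop, 2),
    total = round(lp, 2) + round(cg, 2) + round(oop, 2),
    emissions_kg = 0
  )
}

#' Build the unit-cost database
#'
#' One row per region scope x service type x age group, each carrying the
#' three cost subunits, their total, the travel distance basis, and the
#' per-visit emissions. Totals are kept at cent precision;
#' [unit_cost_report()] produces the whole-dollar view.
#'
#' @param scopes tibble of aggregated travel per scope (from
#'   [aggregate_travel()]): `scope`, `distance_km`, `duration_min`.
#' @param params [cost_parameters()].
#' @param profiles service time profiles ([default_service_profiles()]).
#' @param age_groups age-bin table.
#' @return tibble with columns `region_scope`, `service_type`, `age_group`,
#'   `distance_km`, `duration_min`, `lost_productivity`,
#'   `informal_caregiving`, `out_of_pocket`, `total`, `emissions_kg`.
#' @export
build_unit_cost_database <- function(scopes, params = cost_parameters(),
                                     profiles = default_service_profiles(),
                                     age_groups = default_age_groups()) {
  if (!all(c("scope", "distance_km", "duration_min") %in% names(scopes))) {
    config_error("`scopes` needs columns scope, distance_km, duration_min")
  }
  absent <- setdiff(SERVICE_TYPES, profiles$service_type)
  if (length(absent) > 0) {
    config_error(paste0("missing time profile for service: ",
                        paste(absent, collapse = ", ")))
  }
  grid <- tidyr::expand_grid(
    scope = scopes$scope,
    service_type = profiles$service_type,
    age_group = age_groups$label
  )
  purrr::pmap_dfr(grid, function(scope, service_type, age_group) {
    sc <- scopes[scopes$scope == scope, ]
    pr <- profiles[profiles$service_type == service_type, ]
    if (nrow(pr) != 1) {
      config_error(paste0("missing time profile for service: ", service_type))
    }
    unit_cost_row(scope, service_type, age_group,
                  sc$distance_km, sc$duration_min, params, pr, age_groups)
  })
}

#' Whole-dollar report view of a unit-cost database
#'
#' Rounds the money columns half-up to whole dollars, as unit costs are
#' reported.
#'
#' @param db a unit-cost database from [build_unit_cost_database()].
#' @return the same tibble with money columns rounded to dollars.
#' @export
unit_cost_report <- function(db) {
  money <- c("lost_productivity", "informal_caregiving", "out_of_pocket", "total")
  db |> dplyr::mutate(dplyr::across(dplyr::all_of(money), ~ round_half_up(.x, 0)))
}
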