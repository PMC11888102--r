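#' Service types of the cost model
#'
#' Emergency-department visits are split by Canadian Triage Acuity Scale
#' (CTAS) group, I-III versus IV-V, because time spent in the department
#' differs between the two.
#'
#' @export
SERVICE_TYPES <- c(
  "ED_CTAS_I_III", "ED_CTAS_IV_V", "PHYSICIAN", "HOSPITALIZATION", "TELEHEALTH"
)

IN_PERSON_SERVICES <- setdiff(SERVICE_TYPES, "TELEHEALTH")

#' Cost-model parameters
#'
#' Returns the full parameter set of the costing model, with every value
#' defaulting to the base case: 2023 CAD average hourly wage of $30.54,
#' caregiver attendance of 100% (ages 0-14) and 50% (15+) for outpatient
#' visits and 75%/25% for hospitalizations, an 8 h/day cap on chargeable
#' time, a $0.50/km compact-car vehicle rate, $15 meals, caregiver
#' accommodation (2 nights) for hospitalizations beyond 50 km one-way,
#' fuel efficiency of 7.06 L/100 km and an emission factor of
#' 2.1617 kg CO2e per litre, and telehealth data costs weighted 80%
#' telephone / 20% internet.
#'
#' @param ... named overrides of any default listed below. Nested lists
#'   (e.g. `attendance`) are merged recursively; per-scope rate tables
#'   (`hotel_rate_by_scope`, `parking_core_rate_by_scope`,
#'   `parking_hospital_rate_by_scope`) are named numeric vectors keyed by
#'   region scope (health authority id or `"urban"`/`"rural"`) and fall
#'   back to the scalar default for scopes they omit.
#'
#' @return A validated list of class `cost_parameters`:
#' \describe{
#'   \item{hourly_wage}{average hourly wage, $/h (30.54)}
#'   \item{attendance}{caregiver attendance fractions by service class
#'     (`outpatient`, `hospitalization`) and age role
#'     (`child`, `working`, `senior`)}
#'   \item{productivity_cap_h_per_day}{chargeable hours per 24 h period (8)}
#'   \item{vehicle_rate_per_km}{all-in vehicle operating rate, $/km (0.50)}
#'   \item{fuel_l_per_100km}{fuel efficiency, L/100 km (7.06)}
#'   \item{emission_factor_kg_per_l}{kg CO2e emitted per litre burned (2.1617)}
#'   \item{meal_value}{value of one meal, $ (15)}
#'   \item{hospital_meals_per_day, hospital_meal_days}{caregiver meals for a
#'     hospitalization: 3 meals/day on the 2 admission/discharge days}
#'   \item{accommodation_distance_threshold_km}{one-way distance beyond which
#'     a hospitalization requires caregiver accommodation (50)}
#'   \item{accommodation_nights}{nights of caregiver accommodation (2)}
#'   \item{hotel_rate}{$/night (150), per-scope overrides in
#'     `hotel_rate_by_scope`}
#'   \item{parking_core_rate}{city-core parking, $/visit-day (6), used for
#'     physician visits}
#'   \item{parking_hospital_rate}{hospital parking, $/visit-day (10), used
#'     for ED visits and hospitalizations}
#'   \item{telehealth_phone_weight, telehealth_internet_weight}{modality
#'     weights for telehealth data costs (0.8/0.2, must sum to 1)}
#'   \item{data_rate_phone, data_rate_internet}{data cost, $/min (0.01/0.05)}
#'   \item{round_trip}{if `TRUE`, travel distance and travel time are doubled
#'     consistently for vehicle cost, emissions, and time costs; the default
#'     `FALSE` uses the one-way basis that the bundled per-visit emission
#'     references imply}
#'   \item{hospital_stay_days}{default length of stay, days (3)}
#'   \item{default_speed_urban_kmh, default_speed_rural_kmh}{speed limits
#'     imputed to road edges that lack one (50/80)}
#' }
#' @export
#' @examples
#' p <- cost_parameters(hourly_wage = 16.75)
#' p$hourly_wage
cost_parameters <- function(...) {
  defaults <- list(
    hourly_wage = 30.54,
    attendance = list(
      outpatient = c(child = 1.00, working = 0.50, senior = 0.50),
      hospitalization = c(child = 0.75, working = 0.25, senior = 0.25)
    ),
    productivity_cap_h_per_day = 8,
    vehicle_rate_per_km = 0.50,
    fuel_l_per_100km = 7.06,
    emission_factor_kg_per_l = 2.1617,
    meal_value = 15,
    hospital_meals_per_day = 3,
    hospital_meal_days = 2,
    accommodation_distance_threshold_km = 50,
    accommodation_nights = 2,
    hotel_rate = 150,
    hotel_rate_by_scope = c(),
    parking_core_rate = 6,
    parking_core_rate_by_scope = c(),
    parking_hospital_rate = 10,
    parking_hospital_rate_by_scope = c(),
    telehealth_phone_weight = 0.8,
    telehealth_internet_weight = 0.2,
    data_rate_phone = 0.01,
    data_rate_internet = 0.05,
    round_trip = FALSE,
    hospital_stay_days = 3,
    default_speed_urban_kmh = 50,
    default_speed_rural_kmh = 80
  )
  overrides <- list(...)
  if (length(overrides) == 1L && is.null(names(overrides)) && is.list(overrides[[1L]])) {
    overrides <- overrides[[1L]]
  }
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    validation_error(paste0("unknown cost parameter(s): ", paste(unknown, collapse = ", ")))
  }
  if (!is.null(overrides$attendance)) {
    overrides$attendance <- merge_attendance(defaults$attendance, overrides$attendance)
  }
  p <- utils::modifyList(defaults, overrides)
  validate_cost_parameters(p)
}

merge_attendance <- function(base, new) {
  for (cls in names(new)) {
    if (!cls %in% names(base)) {
      validation_error(paste0("unknown attendance service class: ", cls))
    }
    v <- unlist(new[[cls]])
    bad <- setdiff(names(v), names(base[[cls]]))
    if (length(bad) > 0 || is.null(names(v))) {
      validation_error(paste0(
        "attendance entries must be named child/working/senior, got: ",
        paste(names(v) %||% "<unnamed>", collapse = ", ")
      ))
    }
    base[[cls]][names(v)] <- v
  }
  base
}

validate_cost_parameters <- function(p) {
  rates <- c(
    "hourly_wage", "productivity_cap_h_per_day", "vehicle_rate_per_km",
    "fuel_l_per_100km", "emission_factor_kg_per_l", "meal_value",
    "hospital_meals_per_day", "hospital_meal_days",
    "accommodation_distance_threshold_km", "accommodation_nights",
    "hotel_rate", "parking_core_rate", "parking_hospital_rate",
    "data_rate_phone", "data_rate_internet", "hospital_stay_days",
    "default_speed_urban_kmh", "default_speed_rural_kmh"
  )
  for (nm in rates) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || is.na(p[[nm]]) || p[[nm]] < 0) {
      validation_error(paste0("parameter `", nm, "` must be a single non-negative number"))
    }
  }
  att <- unlist(p$attendance)
  if (any(att < 0 | att > 1)) {
    validation_error("attendance fractions must lie in [0, 1]")
  }
  for (cls in c("outpatient", "hospitalization")) {
    missing <- setdiff(c("child", "working", "senior"), names(p$attendance[[cls]]))
    if (length(missing) > 0) {
      validation_error(paste0(
        "attendance for ", cls, " is missing roles: ", paste(missing, collapse = ", ")
      ))
    }
  }
  w <- p$telehealth_phone_weight + p$telehealth_internet_weight
  if (p$telehealth_phone_weight < 0 || p$telehealth_internet_weight < 0 ||
      abs(w - 1) > 1e-9) {
    validation_error("telehealth modality weights must be non-negative and sum to 1")
  }
  if (!is.logical(p$round_trip) || length(p$round_trip) != 1L || is.na(p$round_trip)) {
    validation_error("`round_trip` must be TRUE or FALSE")
  }
  for (nm in c("hotel_rate_by_scope", "parking_core_rate_by_scope",
               "parking_hospital_rate_by_scope")) {
    v <- p[[nm]]
    if (length(v) > 0 && (!is.numeric(v) || is.null(names(v)) || any(v < 0))) {
      validation_error(paste0("`", nm, "` must be a named non-negative numeric vector"))
    }
  }
  structure(p, class = "cost_parameters")
}

#' Read cost parameters from a YAML configuration file
#'
#' Keys mirror the fields of [cost_parameters()]; unspecified keys fall back
#' to the base-case defaults (wage 30.54, 8 h cap, $15 meal, 50 km
#' accommodation threshold, 2 nights, 7.06 L/100 km, 0.8/0.2 telehealth
#' weights). An empty file yields the defaults unchanged.
#'
#' @param path path to a YAML file.
#' @return a `cost_parameters` object.
#' @export
read_parameters <- function(path) {
  if (!file.exists(path)) {
    config_error(paste0("parameter file not found: ", path))
  }
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  if (!is.list(cfg)) validation_error("parameter file must contain a mapping of keys to values")
  do.call(cost_parameters, cfg)
}

# per-scope rate with fall-back to the scalar default
scope_rate <- function(params, which, scope) {
  by_scope <- params[[paste0(which, "_by_scope")]]
  if (!is.null(by_scope) && length(by_scope) > 0) {
    if (scope %in% names(by_scope)) return(unname(by_scope[[scope]]))
  }
  default <- params[[which]]
  if (is.null(default) || is.na(default)) {
    config_error(paste0("no `", which, "` rate configured for region scope '", scope, "'"))
  }
  default
}

#' Age-group definitions
#'
#' Half-open integer-year bins partitioning the non-negative ages, with
#' exactly one bin flagged as the working-age bin; the flag, not the bin
#' label, drives lost-productivity and caregiver-attendance logic, so
#' alternate binnings need no further configuration.
#'
#' `default_age_groups()` gives 0-14 / 15-64 / 65+;
#' `alternate_age_groups()` gives 0-19 / 20-59 / 60+.
#'
#' @return a tibble with columns `role` (`child`/`working`/`senior`),
#'   `label`, `min_age`, `max_age` (exclusive; `Inf` for the last bin) and
#'   `working` (logical).
#' @export
default_age_groups <- function() {
  tibble(
    role = c("child", "working", "senior"),
    label = c("0-14", "15-64", "65+"),
    min_age = c(0, 15, 65),
    max_age = c(15, 65, Inf),
    working = c(FALSE, TRUE, FALSE)
  )
}

#' @rdname default_age_groups
#' @export
alternate_age_groups <- function() {
  tibble(
    role = c("child", "working", "senior"),
    label = c("0-19", "20-59", "60+"),
    min_age = c(0, 20, 60),
    max_age = c(20, 60, Inf),
    working = c(FALSE, TRUE, FALSE)
  )
}

validate_age_groups <- function(bins) {
  req <- c("role", "label", "min_age", "max_age", "working")
  if (!all(req %in% names(bins))) {
    validation_error(paste0(
      "age bins need columns: ", paste(setdiff(req, names(bins)), collapse = ", ")
    ))
  }
  bins <- dplyr::arrange(bins, .data$min_age)
  if (bins$min_age[1] != 0) validation_error("age bins must start at age 0")
  n <- nrow(bins)
  if (n > 1 && any(bins$min_age[-1] != bins$max_age[-n])) {
    validation_error("age bins must partition the ages with no gaps or overlaps")
  }
  if (!is.infinite(bins$max_age[n])) {
    validation_error("the last age bin must be open-ended (max_age = Inf)")
  }
  if (sum(bins$working) != 1L) {
    validation_error("exactly one age bin must be flagged as working")
  }
  bins
}

#' Service time profiles
#'
#' Wait and appointment durations per service type, plus length of stay for
#' hospitalizations. The defaults are field-realistic placeholders for
#' jurisdiction-specific schedules: higher-acuity ED visits (CTAS I-III)
#' spend about 4 h in the department, lower-acuity (IV-V) about 2.5 h, a
#' physician consult is 30 min waiting plus 30 min appointment, a telehealth
#' encounter 15 min waiting plus 25 min call, and a hospitalization lasts
#' `stay_days` days. Replace them with measured durations when available.
#'
#' @param stay_days hospitalization length of stay in days (default 3).
#' @return tibble with columns `service_type`, `wait_min`,
#'   `appointment_min`, `stay_days`.
#' @export
default_service_profiles <- function(stay_days = 3) {
  assert_number(stay_days, "stay_days", min = 0)
  tibble(
    service_type = c("ED_CTAS_I_III", "ED_CTAS_IV_V", "PHYSICIAN",
                     "HOSPITALIZATION", "TELEHEALTH"),
    wait_min = c(60, 90, 30, 0, 15),
    appointment_min = c(180, 60, 30, 0, 25),
    stay_days = c(0, 0, 0, stay_days, 0)
  )
}

#' Per-visit time breakdown
#'
#' @param travel_min one-way travel time in minutes (0 for telehealth).
#' @param wait_min,appointment_min waiting and appointment durations, minutes.
#' @param stay_days length of stay in days (hospitalization only).
#' @return list of class `visit_time` with `total_h`, the travel + wait +
#'   appointment time in hours under the configured travel-time basis.
#' @export
visit_time <- function(travel_min, wait_min, appointment_min, stay_days = 0) {
  for (nm in c("travel_min", "wait_min", "appointment_min", "stay_days")) {
    assert_number(get(nm), nm, min = 0)
  }
  structure(
    list(
      travel_min = travel_min, wait_min = wait_min,
      appointment_min = appointment_min, stay_days = stay_days,
      total_h = (travel_min + wait_min + appointment_min) / 60
    ),
    class = "visit_time"
  )
}
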