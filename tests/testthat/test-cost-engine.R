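base_params <- cost_parameters()

test_that("lost productivity follows the human capital method with the daily cap", {
  vt2 <- visit_time(30, 45, 45) # 2 h door to door
  expect_equal(lost_productivity("15-64", vt2, base_params, "PHYSICIAN"), 61.08)
  # zero outside the working-age bin
  expect_equal(lost_productivity("65+", vt2, base_params, "ED_CTAS_I_III"), 0)
  expect_equal(lost_productivity("0-14", vt2, base_params, "PHYSICIAN"), 0)
  # hospitalization: 8 h per 24 h period, so a 3-day stay charges 24 h
  vth <- visit_time(60, 0, 0, stay_days = 3)
  expect_equal(lost_productivity("15-64", vth, base_params, "HOSPITALIZATION"),
               3 * 8 * 30.54) # 732.96
  # uncapped, the 72 stayed hours alone would cost far more
  expect_equal(72 * 30.54, 2198.88)
  expect_gt(2198.88, 732.96)
  expect_error(visit_time(-10, 0, 0), class = "patientcost_invalid_argument")
})

test_that("informal caregiving applies attendance fractions to caregiver time", {
  vt3 <- visit_time(60, 60, 60) # 3 h
  expect_equal(informal_caregiving("0-14", "PHYSICIAN", vt3, base_params), 91.62)
  vt2 <- visit_time(30, 45, 45)
  expect_equal(informal_caregiving("65+", "ED_CTAS_I_III", vt2, base_params), 30.54)
  # hospitalization: attendance x 8 h/day x stay x wage
  vth <- visit_time(0, 0, 0, stay_days = 2)
  expect_equal(informal_caregiving("15-64", "HOSPITALIZATION", vth, base_params),
               0.25 * 2 * 8 * 30.54) # 122.16
  broken <- base_params
  broken$attendance$outpatient <- broken$attendance$outpatient[c("child", "senior")]
  expect_error(informal_caregiving("15-64", "PHYSICIAN", vt3, broken),
               class = "patientcost_configuration_error")
})

test_that("out-of-pocket items follow the service-specific rules", {
  p <- cost_parameters(vehicle_rate_per_km = 0.50,
                       parking_hospital_rate = 10, parking_core_rate = 6,
                       hotel_rate = 150)
  # physician visits never carry accommodation
  phys <- out_of_pocket("15-64", "PHYSICIAN", 30, "urban", p)
  expect_equal(phys$accommodation, 0)
  expect_equal(phys$parking, 6)
  expect_equal(phys$meals, 0)
  # urban lower-acuity ED visit: vehicle + hospital parking + one patient meal
  ed <- out_of_pocket("15-64", "ED_CTAS_IV_V", 18.94, "urban", p)
  expect_equal(ed$vehicle, 9.47)
  expect_equal(ed$parking, 10)
  expect_equal(ed$meals, 15)
  expect_equal(ed$accommodation, 0)
  expect_equal(round(ed$total, 2), 34.47)
  # hospitalization past the 50 km threshold: 2 nights x $150 x 25% attendance
  hosp <- out_of_pocket("15-64", "HOSPITALIZATION", 69.4, "north", p)
  expect_equal(hosp$accommodation, 75)
  expect_equal(hosp$parking, 20) # two hospital parking days
  expect_equal(hosp$meals, 3 * 2 * 15 * 0.25)
  # under the threshold: no accommodation even for hospitalizations
  near <- out_of_pocket("0-14", "HOSPITALIZATION", 30.6, "south", p)
  expect_equal(near$accommodation, 0)
  expect_equal(near$meals, 3 * 2 * 15 * 0.75)
  # per-scope rate without a fallback is a configuration error
  p2 <- p; p2$hotel_rate <- NA_real_
  p2$hotel_rate_by_scope <- c(north = 200)
  expect_error(out_of_pocket("15-64", "HOSPITALIZATION", 100, "elsewhere", p2),
               class = "patientcost_configuration_error")
  expect_equal(out_of_pocket("15-64", "HOSPITALIZATION", 100, "north", p2)$accommodation,
               2 * 200 * 0.25)
})

test_that("the round-trip flag doubles the travel basis consistently", {
  scopes <- reference_scopes()
  one_way <- build_unit_cost_database(scopes, cost_parameters())
  both_ways <- build_unit_cost_database(scopes, cost_parameters(round_trip = TRUE))
  expect_equal(both_ways$distance_km, one_way$distance_km * 2)
  expect_equal(both_ways$emissions_kg, one_way$emissions_kg * 2)
  expect_true(all(both_ways$total >= one_way$total - 1e-9))
})

test_that("telehealth unit costs ignore geography and travel", {
  profiles <- default_service_profiles()
  tele <- profiles[profiles$service_type == "TELEHEALTH", ]
  a <- telehealth_unit_cost("15-64", tele, base_params)
  expect_equal(a$distance_km, 0)
  expect_equal(a$emissions_kg, 0)
  # identical totals whatever the scope's distance profile
  scopes <- tibble::tibble(scope = c("near", "far"),
                           distance_km = c(1, 300), duration_min = c(2, 250))
  db <- build_unit_cost_database(scopes, base_params)
  rows <- db[db$service_type == "TELEHEALTH", ]
  for (ag in unique(rows$age_group)) {
    pair <- rows[rows$age_group == ag, ]
    expect_equal(pair$total[1], pair$total[2])
  }
  # children: no productivity, full caregiver attendance
  child <- telehealth_unit_cost("0-14", tele, base_params)
  expect_equal(child$lost_productivity, 0)
  expect_equal(child$informal_caregiving,
               round(1.0 * (tele$wait_min + tele$appointment_min) / 60 * 30.54, 2))
  # zero data rates zero the out-of-pocket subunit
  free <- cost_parameters(data_rate_phone = 0, data_rate_internet = 0)
  expect_equal(telehealth_unit_cost("15-64", tele, free)$out_of_pocket, 0)
})

test_that("per-visit emissions are linear in distance and match the references", {
  p <- cost_parameters()
  expect_equal(emissions_per_visit_kg(0, p), 0)
  expect_error(emissions_per_visit_kg(-1, p), class = "patientcost_invalid_argument")
  # homogeneity
  expect_equal(emissions_per_visit_kg(2 * 57.3, p), 2 * emissions_per_visit_kg(57.3, p))
  # the calibrated factor reproduces the published per-visit figures
  ref <- bc_reference_distances("authority")
  fraser <- ref[ref$scope == "Fraser", ]
  ef <- calibrate_emission_factor(fraser$emissions_kg, fraser$distance_km, 7.06)
  expect_equal(ef, p$emission_factor_kg_per_l, tolerance = 1e-4)
  got <- emissions_per_visit_kg(ref$distance_km, p)
  expect_true(all(abs(got - ref$emissions_kg) <= 0.01))
})

test_that("the unit-cost database has full cardinality and additive subunits", {
  scopes <- reference_scopes()
  db <- build_unit_cost_database(scopes)
  expect_equal(nrow(db), 2 * 5 * 3)
  expect_equal(db$total,
               db$lost_productivity + db$informal_caregiving + db$out_of_pocket)
  expect_true(all(db$lost_productivity >= 0 & db$informal_caregiving >= 0 &
                    db$out_of_pocket >= 0))
  # a missing time profile is a configuration error
  short <- default_service_profiles()[-1, ]
  expect_error(build_unit_cost_database(scopes, profiles = short),
               class = "patientcost_configuration_error")
})

test_that("age differences are symmetric for non-hospital in-person services", {
  # productivity Tw only for working; caregiving 1.0T / 0.5T / 0.5T: the
  # working-child gap equals the child-senior gap (0.5 x time cost)
  scopes <- reference_scopes()
  db <- unit_cost_report(build_unit_cost_database(scopes))
  for (sc in scopes$scope) {
    for (svc in c("ED_CTAS_I_III", "ED_CTAS_IV_V", "PHYSICIAN")) {
      rows <- db[db$region_scope == sc & db$service_type == svc, ]
      w <- rows$total[rows$age_group == "15-64"]
      c <- rows$total[rows$age_group == "0-14"]
      s <- rows$total[rows$age_group == "65+"]
      expect_lte(abs((w - c) - (c - s)), 1)
    }
  }
})

test_that("unit-cost totals are monotone in wage, distance, and attendance", {
  scopes <- reference_scopes()
  base <- build_unit_cost_database(scopes)
  richer <- build_unit_cost_database(scopes, cost_parameters(hourly_wage = 40))
  expect_true(all(richer$total >= base$total - 1e-9))
  farther <- scopes; farther$distance_km <- farther$distance_km * 1.5
  farther$duration_min <- farther$duration_min * 1.5
  far_db <- build_unit_cost_database(farther)
  expect_true(all(far_db$total >= base$total - 1e-9))
  keen <- cost_parameters(attendance = list(
    outpatient = c(child = 1, working = 0.8, senior = 0.8),
    hospitalization = c(child = 0.9, working = 0.5, senior = 0.5)
  ))
  keen_db <- build_unit_cost_database(scopes, keen)
  expect_true(all(keen_db$total >= base$total - 1e-9))
})

test_that("accommodation triggers exactly for scopes beyond 50 km one-way", {
  ref <- bc_reference_distances("authority")
  scopes <- tibble::tibble(scope = ref$scope, distance_km = ref$distance_km,
                           duration_min = ref$duration_min)
  db <- build_unit_cost_database(scopes)
  # recompute the accommodation item per scope for a hospitalization
  accom <- vapply(scopes$scope, function(sc) {
    out_of_pocket("15-64", "HOSPITALIZATION",
                  scopes$distance_km[scopes$scope == sc], sc,
                  cost_parameters())$accommodation
  }, 0)
  expect_equal(names(which(accom > 0)), "Northern")
  # and only hospitalization rows can carry it: ED/physician scopes with the
  # same distances never do
  for (svc in c("ED_CTAS_I_III", "ED_CTAS_IV_V", "PHYSICIAN")) {
    a <- out_of_pocket("15-64", svc, 69.4, "Northern", cost_parameters())$accommodation
    expect_equal(a, 0)
  }
})
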