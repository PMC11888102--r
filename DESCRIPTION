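Package: patientcost
Title: Geospatial Estimation of Patient-Paid Costs and CO2 Emissions of
    Health Care Visits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the costs patients and their families pay to attend
    in-person and telehealth health care visits (lost productivity via the
    human capital method, informal caregiving, and out-of-pocket expenses)
    together with the CO2-equivalent emissions attributable to medical
    travel. Small health regions are routed over a road network to their
    nearest emergency department to obtain street distances and durations,
    which are aggregated by health authority and by urban/rural class using
    population-weighted means and combined with wage, caregiver-attendance,
    vehicle, parking, meal, accommodation, and fuel parameters into a
    per-visit unit-cost database. Includes deterministic one-way sensitivity
    analysis (wage, caregiver attendance, travel scaling, street versus
    haversine routing), an annual population simulation with hybrid-care and
    emergency-department-avoidance scenarios, and a deterministic synthetic
    geography generator so the full pipeline runs without map downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    geosphere,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
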