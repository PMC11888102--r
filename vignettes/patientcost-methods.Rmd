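---
title: "Methods: geospatial estimation of patient-paid costs and travel emissions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geospatial estimation of patient-paid costs and travel emissions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patientcost)
```

## The problem and the approach

Health systems rarely account for what patients themselves pay to receive
care: foregone work time, a family member's accompaniment, vehicle and
parking and meal expenses, and — for future generations — the CO2 emitted
driving to appointments. These costs vary strongly with geography, because
travel distance to the nearest point of care does. This package makes that
geography the basis of the estimate: each small health region is routed
over the road network from its geographic centre to the nearest emergency
department (a proxy for the nearest point of acute care), and the resulting
street distance and duration feed a per-visit cost model whose remaining
inputs are ordinary public statistics (wages, parking and hotel rates, fuel
efficiency).

The pipeline is: geography → routing → aggregation → unit-cost database →
(sensitivity analysis | annual population simulation).

## Routing

`route_to_nearest_facility()` snaps the region centroid and every facility
to network nodes (nearest node by great-circle distance; ties go to the
lexicographically smallest node id, a deterministic and
serialization-stable rule) and takes the length-weighted shortest path;
the nearest facility is the one minimizing street *distance*, with ties
broken by facility id. Duration is not optimized separately: it is
accumulated over the chosen path as `sum(length / speed) * 60` minutes, so
distance and duration always describe the same route. Great-circle
distances use the haversine formula on a 6371 km sphere.

Per-region results aggregate to health authorities and to the urban/rural
strata (region classes 1–4 urban, 5–7 rural) by population-weighted mean.
`compare_street_vs_haversine()` quantifies how much the straight-line
shortcut underestimates street distance; on any network whose edges are at
least as long as their endpoints' straight-line separation — which the
synthetic generator guarantees — street ≥ haversine holds for every region.

## The cost model

Unit costs are per visit, for every region scope × service type × age
group, decomposed into three subunits (see `?cost_parameters` for the full
parameter table, units, and defaults):

* **Lost productivity** — the human capital method: visit time (travel +
  wait + appointment) × average hourly wage ($30.54, 2023 CAD), charged
  only to the working-age bin; 0–14 and 65+ are assumed to have no
  productivity cost. Chargeable time is capped at 8 h per 24-hour period,
  which for a hospitalization of `d` days means `8d` hours.
* **Informal caregiving** — caregiver time × wage × an attendance
  probability: 100% for children and 50% for ages 15+ at outpatient visits;
  75% / 25% for hospitalizations, with caregiver time prorated to 8 h per
  day of stay. The caregiver is assumed to commit the same travel, wait,
  and appointment time as the patient; whether drop-off/pick-up doubles
  caregiver travel is unknowable without survey data, so no doubling is
  applied.
* **Out-of-pocket** — vehicle cost at $0.50/km; parking (one city-core day
  for physician visits, one hospital day for ED visits, two hospital days
  for hospitalizations); one $15 meal for any ED patient regardless of age
  (the patient, not the caregiver, eats it — so it carries no attendance
  weight); 3 caregiver meals/day on the 2 admission/discharge days of a
  hospitalization, attendance-weighted; and caregiver accommodation
  (2 nights × the scope's hotel rate × attendance) only when a
  hospitalization's one-way distance exceeds 50 km. Telehealth visits
  replace all of this with data cost: a 0.8/0.2 telephone/internet-weighted
  $/min rate times appointment minutes, which makes telehealth unit costs
  identical across scopes.

Emissions per visit are `distance × fuel_l_per_100km / 100 ×
emission_factor_kg_per_l`, linear and homogeneous in distance.

### Travel basis: one-way

Vehicle cost, emissions, and travel time all use the one-way
centroid-to-facility distance by default. The bundled per-visit emission
references are arithmetically consistent with a one-way basis at
7.06 L/100 km, and consistency between money and carbon matters more than
either convention alone; `round_trip = TRUE` doubles distance and travel
time together.

### Emission-factor calibration

Published per-visit emission tables typically cite an external calculator
without printing its factor. We recover it once from the Fraser reference
row: `4.67 kg / (30.6 km × 0.0706 L/km) ≈ 2.1617 kg CO2e/L`, and the
package tests verify this single factor reproduces every other authority
and stratum reference cell to ±0.01 kg. The annual scenario table in the
same source implies a slightly lower ≈0.148 kg/km (vs 0.1526 kg/km here);
we calibrate to the per-visit tables and note the discrepancy rather than
averaging it away.

### Durations

Wait and appointment durations are jurisdiction-specific and usually live
in supplementary schedules. The defaults (`default_service_profiles()`)
are chosen once as field-realistic values: physician 30 min wait + 30 min
appointment; ED CTAS I–III 60 + 180 min (about four hours in the
department, typical of higher-acuity stays); ED IV–V 90 + 60 min;
telehealth 15 + 25 min; hospitalization length of stay 3 days. Absolute
dollar outputs shift with these inputs, which is why the test suite pins
the *structure* of the model — subunit additivity, age-gap symmetry,
monotonicity, linearity in wage and travel — rather than specific dollar
values, and why users with measured durations should supply their own
profiles.

### Numerical conventions

Money is computed in dollars at cent precision (subunits rounded to the
cent; the total is their exact sum) and reported rounded half-up to whole
dollars via `unit_cost_report()` — commercial rounding, not banker's
rounding, because that is how dollar tables are printed. Region centroids
are geometric centroids when a polygon is supplied (shoelace formula on
the ring), else the stored point; nothing in the inputs supports
population-weighting the centre, so that refinement is deliberately not
guessed at. Edges with missing speed limits would default to 50 km/h
(urban) / 80 km/h (rural), common Canadian defaults, configurable.

## Sensitivity analysis

`run_one_way()` is strictly deterministic and one-way: each scenario is a
pure function of the base inputs and a single overridden value, with no
state shared across scenarios. Grids default to the published sweeps —
wage $16.75 (minimum wage), $20, $25, $30.54 (base), $35–$50 by $5;
caregiver attendance 0–100% by 25%; travel 50–150% of base by 10% — and a
grid that omits its base value is rejected. The attendance scenario sets
*every* attendance fraction to the grid value (one province-wide
assumption), which is what makes the absolute cost step identical across
age groups; consequently its 50% grid point reproduces the base case
exactly for the 15+ outpatient rows whose base is 50%, while child and
hospitalization rows show the effect of replacing their higher base rates.
The travel scenario scales distance and duration jointly by default
(`scale_distance` / `scale_duration` can separate them, but a trip that is
50% longer in km and unchanged in minutes is rarely the question being
asked).

Structural consequences asserted in the tests: totals are affine in wage
with a grid-constant slope; each 25% attendance step moves a non-hospital
row by a constant absolute amount; travel scaling moves vehicle cost
exactly proportionally.

## Annual population simulation

`population_spec()` holds a population size (default 100,000), region
shares, and a *single-year* age pyramid; binned age shares are derived by
summing the pyramid over whatever age-group table is in force, which is
what lets `rebin_ages()` switch to 0–19/20–59/60+ (or any partition) with
no other changes — the `working` flag of the new bin table decides where
productivity applies, which is also how labor-force participation
assumptions enter. Defaults are chosen once as realistic provincial
values: region shares 0.37/0.16/0.06/0.24/0.17 across the five
authorities and a piecewise-uniform pyramid with 14%/65%/21% in
0–14/15–64/65+.

Visit rates default to 2.7 physician and 2.5 telehealth visits per
person-year (the latter from 48 visits per 1000 people per week × 52) and
0.42573 ED visits per person-year; 60% of ED visits are taken as CTAS
I–III, a realistic national triage mix, since the split is not printed in
the sources the other defaults come from. Expected-mode allocation is the
deterministic real-valued product `size × rate × region share × age
share` — annual totals of this kind are means, and printing them without
sampling noise is the honest default — while stochastic mode draws seeded
multinomials for uncertainty exploration; the tests check the two agree in
expectation over 200 seeds.

Hybrid-care scenarios scale in-person visits, distance, and emissions
linearly in the in-person fraction, optionally recosting diverted visits
at the telehealth unit cost. The ED-avoidance scenario reports the
*avoided* share (visits rounded half-up, distance and emissions exact),
matching how such rows are conventionally printed. One published implied
quantity is deliberately not forced: the annual scenario table implies a
fixed ~14.66 km per physician visit, which is not derivable from per-scope
weighted means; the package derives distance from its own geography and
leaves the difference visible.

## The synthetic geography

`generate_synthetic_geography()` builds a deterministic province-like
fixture: a 3×3 road grid (2 km spacing) around a hub with two emergency
departments, urban regions (classes 1–4) 0.6–15 km from the hub, and rural
regions (classes 5–7) on 30–300 km spokes, mirroring real nearest-facility
distances that span from under 1 km in population centres to over 300 km
in remote areas. A grid-plus-spokes topology guarantees connectivity, and
every edge's length is its endpoints' straight-line distance times a
circuity factor ≥ 1.15, so the street-≥-haversine invariant holds by
construction. What it does *not* emulate: ferry links, seasonal closures,
congestion, multiple competing road corridors, or realistic settlement
clustering — so passing tests show the pipeline's arithmetic and
invariants are right, not that any specific jurisdiction's distances are
reproduced. For real use, import a real geography via the documented
GeoJSON/CSV layout.

Test problem sizes are deliberately small — fixtures of 2–20 regions,
networks of 10–60 nodes (≤ 30 for the brute-force path-enumeration
oracle), 200 stochastic replicates — chosen so the full suite exercises
every oracle comparison in well under a minute while keeping the
enumeration oracles exact.

## Known limitations

* Absolute dollar outputs inherit the uncertainty of the duration,
  parking, and hotel defaults; only the model structure is validated
  against independent oracles.
* The routing model ignores time-of-day congestion, seasonal road
  conditions, and system constraints such as ED closures rerouting
  patients; it therefore tends to underestimate worst-case travel.
* Costs that resist monetization — stress, emotional labor, quality-of-care
  consequences — are out of scope, so totals are lower bounds on the true
  patient burden.
* The probabilistic layer is limited to seeded multinomial allocation;
  distributions over cost parameters (probabilistic sensitivity analysis)
  are intentionally not implemented, as the sensitivity design here is
  strictly deterministic one-way.
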