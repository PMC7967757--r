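---
title: "Methods: energy and economic assessment of fish co-stream processing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: energy and economic assessment of fish co-stream processing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(costream)
```

## Scope and modelling approach

`costream` is an early-stage techno-economic assessment (TEA) framework for
zero-waste processing of salmon filleting co-streams. It deliberately avoids
process simulation: each concept is a *fixed coefficient table* — inputs and
outputs per tonne of raw material (t_RM) — the way early TEA studies publish
their balances. There is no thermodynamics, no digestion kinetics, no
heat-demand time series; everything downstream (annualisation, energy
balance, cost/revenue statement, uncertainty) is exact arithmetic on those
coefficients. That makes every number reproducible to machine precision from
a small, auditable configuration file.

The battery limits are a regional system: one co-stream processing plant
(10,000 t_RM/a), road transport (100 km), and four farms (600 ha barley,
600 milking cows and 12,000 t/a of manure each) that receive residue for
co-digestion and digestate as fertiliser. Flows crossing this boundary are
priced; flows inside it (residue to the digester, digestate to the fields)
are internal transfers and carry no price.

## The four reference concepts

| id  | route | products | biogas branch |
|-----|-------|----------|---------------|
| I   | direct anaerobic co-digestion | electricity, digestate | yes (whole stream) |
| II  | formic-acid silage | liquid feed | no |
| III | thermal fractionation (>90 °C, tri-canter) | oil, protein concentrate, meal | no |
| IV  | two-stage thermal–enzymatic | premium oil, oil, protein hydrolysate | yes (130 kg/t_RM residue) |

Fixtures live in `inst/extdata/concepts/*.yaml`; every value is commented
with its meaning and units, and `load_concept()` validates the whole
structure on load.

## Energy model

Each technological operation *i* carries a direct (`E_d,i`) and indirect
(`E_ind,i`) energy input in MJ/t_RM; `total_energy_input()` sums
`E_TE,i = E_d,i + E_ind,i` over the ledger. The energy potential of the
digested biomass is taken as the CHP output,
`E_BM = (heat + electricity) × 3.6` MJ/t_RM, and the balance is
`E_final = E_BM − E_input` with ratio `E_BM / E_input`
(`energy_balance()`; the ratio is flagged `NA` rather than dividing by a
zero input).

The co-digestion plant is modelled by its per-t_RM output coefficients
(heat 1562 / 203 kWh, electricity 1213 / 158 kWh for the full-stream and
residue-only branches), scaled **linearly** with residue throughput at the
fixed 1:5 residue:manure ratio — no efficiency chain is modelled. A validity
bound guards physical plausibility: CHP heat + electricity (in MJ) may never
exceed the chemical energy of the methane produced at a lower heating value
of 35.9 MJ/m³.

Three numerical conventions matter:

* **kWh→MJ is fixed at 3.6.** The reference aggregate for the full-digestion
  branch is quoted as 9992 MJ/t_RM where the conversion gives 9990; the
  0.02% residual is treated as source rounding, and comparisons to quoted
  energy aggregates use a 0.5% tolerance.
* **Calibrated ledger entries.** The per-operation direct/indirect
  coefficients for field and farm operations are not published. The shipped
  ledgers carry the published per-operation aggregates (processing 82 / 326 /
  377 / 678, transport 82.1, digestion plant self-consumption 2196 / 293
  MJ/t_RM) plus one `field_operations` entry per biogas concept that closes
  the ledger to the published system totals (2548 and 1299 MJ/t_RM). These
  reconciliation entries are flagged `reconciliation: true` in the fixtures.
* **Unattributed electricity consumers.** The quoted net useful power
  (1042 / 66 kWh/t_RM, and −41 / −51 for the non-biogas concepts) implies
  roughly 11 kWh/t_RM more internal consumption than the listed loads. The
  consumer tables carry that gap as an explicit `unattributed` entry rather
  than silently inflating a named load. The discrepancy is surfaced, not
  resolved.

Transport energy is linear: `mass × distance × 0.821 MJ·t⁻¹·km⁻¹`, the
coefficient chosen so one tonne moved 100 km takes the quoted 82.1 MJ.

## Economic model

`economic_statement()` builds eight cost lines and up to five revenue lines,
all in USD/a, unrounded:

* *raw materials* — every purchased input that is not a utility
  (co-stream at 120 USD/t, formic acid, enzyme);
* *utilities* — steam, electricity, water;
* *labour* — operators × 65,000 USD/a × 1.4 (40% indirect on top);
* *logistics* — transported residue mass × 100 km × 0.1 USD·t⁻¹·km⁻¹;
* *maintenance* (2.5%/a), *other indirect* (1%/a) and straight-line
  *depreciation* over 15 a with zero salvage, all on the total investment;
* *mineral fertilisers* — from the farm balance below.

Revenues group the product slate as oil (premium + regular), protein
(hydrolysate or concentrate), meal (meal or silage) and energy. The energy
line sells **gross** CHP electricity (1213 / 158 kWh/t_RM) at 100 USD/MWh:
only the gross figure reproduces the published revenue line; heat is assumed
used internally and unsold. Profit is revenues − costs and
`ROI = profit / total investment`, computed on unrounded totals; only the
reporting layer rounds (0.1 M USD, whole percent). ROI on a zero investment
is flagged `NA`, not infinite. No discounting, tax or financing is modelled
— profitability is a single representative year.

**Steam units.** The source balance prints steam in kg/t_RM, but only a
t/t_RM reading reproduces the published utilities costs (e.g. 0.7 t ×
10,000 t_RM × 20 USD/t ≈ 0.2 M USD minus electricity). The fixtures
therefore carry steam as `t/tRM`; the unit is an ordinary stream attribute,
so a user who prefers the literal reading can change it.

**Farm fertiliser balance.** Each farm splits its 600 ha into 400 ha
receiving manure (30 t/ha) plus 484 kg/ha of mixed mineral fertiliser and
200 ha receiving 534 kg/ha of mineral fertiliser only; demand is
4 × (400·484 + 200·534) kg = 1201.6 t/a. Full digestion (concept I) covers
the whole demand with digestate (cost 0); the silage and thermal concepts
buy everything; the two-stage concept's smaller digestate stream offsets
part of it. No substitution formula is published for that partial case, so
the offset is a single calibrated parameter, `digestate_offset_t = 201.6`,
chosen once so the residual demand is 1000 t/a (0.5 M USD) as published;
it is documented in the fixture and never adjusted elsewhere. A negative
residual demand is clamped to zero with a warning.

**Mass closure.** `mass_closure()` reports kg-denominated outputs over the
raw-material input (1000 kg/t_RM). Auxiliary chemical inputs (6.7 kg/t_RM
formic acid, 1 kg/t_RM enzyme) are excluded from the denominator so the
ratio reads as product yield on the co-stream itself — this is what makes
the silage concept close at exactly 1.0. The structural validator, by
contrast, compares outputs against *all* kg-denominated inputs, so a balance
can never create mass.

## Uncertainty analysis

Five market factors are varied: raw material (co-stream price), energy
(electricity), fish oil (both oil qualities), fish protein (hydrolysate and
concentrate), fish meal (meal and silage). Two prices are driven rather than
independent: mineral fertilisers and formic acid reuse the energy factor's
multiplier — implemented as identical multiplicative factors, i.e. perfect
correlation, the minimal reading of "moves with the energy price".

* The band is multiplicative, `[1 − v, 1 + v]` with `v = 0.20` by default.
  The sampling distribution within the band is not specified by the source;
  the default is **uniform** (matches the stated bounds with no further
  assumptions), with a symmetric triangular option for users who prefer
  mass near the baseline.
* `run_monte_carlo()` re-evaluates the *full* economic statement per draw
  (default 10,000 iterations) rather than exploiting the model's linearity,
  so any future nonlinearity in the statement is automatically covered; the
  linear closed forms are kept in the test suite as independent oracles.
* Draws are consumed in factor-name-sorted order from one seeded generator,
  so results are identical across platforms and independent of the order
  factors were configured in; the sample stream is prefix-stable (the first
  *n* draws of a longer run equal a shorter run), and the caller's RNG state
  is restored afterwards.
* `sensitivity_ranking()` is the one-at-a-time view: profit at each factor's
  lower and upper bound with everything else at baseline, ranked by swing
  `|high − low|`, ties broken by factor name order. Whether the source study
  ranked factors jointly or one-at-a-time is ambiguous; both modes are
  provided (`mc`'s joint distribution vs the tornado table) and labelled.

Because profit is linear in prices, the swing of factor *f* equals
`2v × |net exposure_f|` and the Monte Carlo sd equals
`sqrt(Σ_f (c_f v)² / 3)` for uniform factors; both identities are asserted
in the tests (the former to 10⁻¹² relative, the latter within 5% at 10,000
iterations).

## Synthetic scenarios

`generate_scenario()` draws random scenarios with the reference structure:
a 1000 kg/t_RM raw-material input, an auxiliary chemical, steam/electricity
utilities, 1–n products rescaled to a drawn mass closure in (0, 1], an
optional residue stream with a co-digestion branch whose CHP output is drawn
*below* the methane energy bound, random prices, capex and opex. Validity
therefore holds by construction for every seed, which the test suite sweeps
(100 seeds).

The generator emulates the *structure* of real scenarios, not their
economics: its prices and yields are independent draws, so synthetic
scenarios carry no correlation between yield and price, no economies of
scale, and no technological realism in the energy ledger. Passing the
property tests demonstrates that the accounting machinery (identities,
linearity, serialisation, validation) is correct on arbitrary well-formed
inputs — it says nothing about how faithfully any particular real process is
parameterised.

## Reproduction of the published tables, and known deviations

`compare_to_reference()` recomputes all 85 published line items (costs,
revenues, profit, ROI, energy aggregates) from the fixtures and compares at
printed precision (0.1 M USD, whole percent, 0.5% for energy). 78 match.
Seven do not, and are shipped as flagged `known-deviation` rows rather than
silently tolerated or "fixed":

* concept III oil revenue (computed 2.24, printed 2.3 M USD), meal revenue
  (2.13 vs 2.2) and hence total revenue (6.08 vs 6.2) — the printed values
  are not consistent with the printed yields × prices;
* concept IV protein revenue (6.67 vs 6.6), and downstream of it the profit
  (5.90 vs 5.8) and ROI (52% vs 51%);
* concept IV total cost (3.84 vs 3.9, consistent with summing *rounded*
  lines rather than unrounded ones).

All deviations are 1–3% and do not change any ranking or conclusion. The
package always reports its own recomputed values; the mutated-fixture test
confirms the checker actually fails when an input changes.

Other minor source inconsistencies handled: the methane fraction is quoted
as both 65 and 64.9 vol-% (fixtures use 0.65; it only enters the sanity
bound), and the per-farm co-stream mass is quoted as 2400 t/a against a
10,000 t/a plant over four farms (the fixtures use the plant capacity
throughout).

## Degenerate inputs and problem sizes

Zero capacity yields all-zero flows and a fixed-costs-only statement; zero
variation collapses the Monte Carlo onto the deterministic baseline exactly;
zero energy input flags the ratio undefined; empty ledgers, empty balances,
unknown units, missing prices and infeasible generator ranges are rejected
with named errors. The test suite runs the full reference reproduction, a
100-seed generator sweep, 100-scenario oracle-equivalence checks and one
10,000-iteration Monte Carlo — about half a minute on one CPU, with the
acceptance script at a similar scale.

## Limitations

Fixed coefficients mean no response of yields to feed composition, no
part-load behaviour, and no seasonality. The economics are a single
representative year in USD (the 1.1 EUR→USD factor is retained as a display
constant only): no NPV/IRR, no transfer pricing between plant and farms.
The fertiliser balance is in mixed-fertiliser tonnes, not per-nutrient N/P/K
accounting, and the digestate offset for partial substitution is calibrated,
not mechanistic. Life-cycle/GHG assessment, digestion kinetics and logistics
routing are out of scope.
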