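---
title: "A relation-driven model of global food trade and nutrition security"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A relation-driven model of global food trade and nutrition security}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reltrade)
```

## The model

`reltrade` simulates world food trade as an agent-based model in which the
agents are countries. Unlike price-driven (general-equilibrium) trade
models, trade here is *relation-driven*: who trades with whom is decided by
a priority ranking over potential partners, built from four elements —
the partner's ability to pay (GDP per capita), geographic proximity, the
historic trade relationship, and the *emergent* trade relationship that
accumulates endogenously as pairs trade during a run. The simulated trade
flows, together with domestic production, determine each country's food
supply, and a nutrition pipeline converts that supply into per-capita
macro- and micronutrient intake, classified against demographically
weighted requirements.

### One simulated year

A time step is a year. Within a year, the stages run in a fixed order
(`step_year()`):

1. **Exogenous update.** GDP, population and per-commodity production are
   set from the year's inputs.
2. **Diet rescaling.** Each country's *typical diet* — its baseline
   per-commodity food consumption — is rescaled per commodity by the ratio
   of current to baseline global per-capita supply
   (`scale_typical_diet()`). Diets drift with what the world produces
   rather than jumping to a prescribed ideal.
3. **Trade positions.** A country that produced more than its diet target
   (in domestic-supply terms) offers the excess for export; one that
   produced less seeks to import the deficiency; at most one of the two is
   positive. Countries flagged as *intermediaries* for a commodity —
   baseline export exceeding 80% of baseline import, i.e. importing
   mainly to re-export — additionally demand their baseline re-export
   volume, rescaled with global supply (`determine_positions()`).
4. **Markets.** Each commodity market runs independently
   (`run_commodity_market()`); the outcome of one commodity does not
   affect another.
5. **Food supply.** Post-trade supply is (production + imports − exports),
   floored at zero, times the baseline food share of domestic supply.
   Stock variation is ignored: the accounting identity admits a stock
   term, but nothing in the model updates it, so it is held at zero.
6. **Nutrition.** The pipeline below turns food supply into classified
   per-capita intake.
7. **Emergent relationships.** Every realized transaction adds its tonnage
   to the pair's directed emergent-trade volumes, raising their mutual
   priority in later years (`update_emergent()`). Emergent volumes never
   decay; accumulation without decay is the default and only shipped
   behaviour.

### Partner ranking

For a ranking event with candidate set $C$, the priority a country
assigns to candidate $c$ is the weighted average

$$P(c) = \frac{w_g\,\tilde g_c + w_d\,\tilde d_c + w_h\,\tilde h_c +
w_e\,\tilde e_c}{w_g + w_d + w_h + w_e},$$

where $\tilde g_c$, $\tilde h_c$, $\tilde e_c$ are the candidate's GDP per
capita and the role-appropriate historic and emergent trade volumes,
min–max normalized over $C$, and $\tilde d_c$ is one minus the normalized
distance. Normalizing per ranking event makes the heterogeneous units
commensurable; an element on which all candidates tie is uninformative
and maps to 1. Scores lie in $[0,1]$ and exact ties are broken by a
seeded uniform draw, so runs are bit-reproducible under a fixed seed.
Historic and emergent volumes are kept separately for the import and
export roles of a relationship.

The four weights are the model's calibratable parameters. Because only
relative priorities matter, one degree of freedom is redundant and the
distance weight is fixed at 1. The shipped default,
`priority_weights()` = (1.40, 1, 1.40, 0.72), carries the weights
calibrated against observed FAO/Comtrade trade in the study this model
derives from; synthetic-world experiments typically override it.

### The market procedure

Within a commodity market, rounds repeat until a stopping rule fires. In
each round every importer with remaining demand posts one offer —
min(remaining demand, per-round cap) — to its top-ranked exporter with
remaining supply; each exporter then accepts the offers it received in
its own priority order until its supply is exhausted. The two-phase
(all offers, then all acceptances) schedule is order-independent within a
phase up to seeded tie-breaks, which makes runs reproducible where an
agent-sequential schedule would depend on an arbitrary agent ordering.
Intermediary imports re-enter the market as export supply in later
rounds of the same year.

Three parameters shape the market (`market_params()`):

* **Saturation** $s \in [0,1]$: the fraction of *potential* trade — the
  smaller of total demand and total supply at market open — that is
  realized. The market closes once cumulative realized trade reaches
  $s \times$ potential, with the final transaction truncated exactly at
  the target; at $s = 1$ all trade opportunities are realized and the
  market clears to min(demand, supply). Saturation is applied per
  commodity, which keeps scenario levels comparable across commodities.
  The scenario presets used throughout are low 0.6, medium 0.8 and high
  1.0.
* **Per-round cap** (tonnes): the most a country can trade per
  transaction per round, preventing large countries from crowding out
  small ones in a single round. Default: potential/10, which yields
  round counts in the 5–20 range on balanced markets. At $s = 1$ the
  total cleared volume is invariant to the cap; only round counts change.
* **max_rounds**: a safety bound (default 1000); reaching it with
  feasible offers outstanding logs a warning.

### Nutrition pipeline

Food supply per commodity is reduced by the regional household-waste
fraction (`default_waste_table()`, the Gustavsson et al. FAO estimates by
seven world regions and eleven food types) and by the commodity's
inedible fraction. Waste applies to the food component only;
pre-household losses are already netted out of the food share. The
edible remainder is multiplied by the commodity's nutrient composition
(per tonne of edible food) and divided by population × 365 to give
per-capita daily intake of 15 nutrients (calories, protein, fat, vitamin
C, vitamin A, folate, calcium, iron, zinc, fibre, thiamin, riboflavin,
niacin, vitamin B6, saturated fat).

Refinable staples (the cereals group) carry three composition variants —
unrefined, refined-unfortified, refined-fortified — selected by the
country's fortification profile, itself driven by income class. Refining
strips fibre and micronutrients; fortification restores most
micronutrients but not fibre.

Requirements per person per day are the population-share-weighted mean of
per-group requirements over the configured age–sex groups (default: four
age bands × two sexes). Energy requirements follow an
average-dietary-energy-requirement convention (physical activity level
1.75, BMI 21 kg/m² for adults). A country is *sufficient* in a nutrient
when intake ≥ requirement — the boundary is deliberately inclusive, since
the threshold convention is otherwise arbitrary. Fat is classified
against a (lower, upper) band — low / healthy / over — at 20–35% of the
group energy requirement; the band mechanism is generic, so other
nutrients (e.g. saturated fat) could be banded by configuration. The
reported margin (intake/requirement, or intake over the band's lower
bound) grades how far a country sits from the threshold.

## The synthetic world generator

No country-level input data ship with the package; `generate_world()`
draws worlds with the statistical structure the model assumes, at the
scale of the empirical setting by default (165 countries, 91
commodities):

* GDP per capita and population are log-normal; income classes are
  quartiles of GDP per capita; fortification profiles follow income.
* Demographics are Dirichlet draws over the age–sex groups, weighted
  towards working-age adults.
* Production of each commodity is spread over countries by a Dirichlet
  with a configurable concentration, and its global total balances the
  global domestic-supply-equivalent diet demand to within ±10% drawn
  noise — so every market has both sides populated and roughly half the
  countries are net importers of any commodity.
* Historic bilateral trade follows a gravity law (GDP product over
  distance) with log-normal noise, scaled to the baseline import totals;
  the directed import and export matrices are transposes of each other.
* A configurable fraction of countries receive an intermediary role in a
  few commodities, with matched re-export volume large enough that the
  80% rule flags them from their baseline flows alone.
* Household waste defaults to the published regional rates; synthetic
  countries are assigned regions uniformly.

Balance is the design goal, not realism in every marginal: the generator
does not reproduce FAO marginals, real geography, or the actual
commodity composition of any diet, and the nutrient composition table is
drawn log-normally around food-typical densities rather than taken from
a composition database. Tests passing on these worlds therefore
establish the *mechanics* of the model — conservation, clearing,
ranking, calibration recovery — not empirical adequacy for any real
country.

`generate_observations()` runs the annual cycle under known "true"
weights and perturbs the resulting volumes multiplicatively by a uniform
±noise, leaving partner identities untouched. This yields pseudo-observed
records with known ground truth for calibration experiments.

## Calibration

`calibrate()` implements the protocol: a Latin hypercube design over the
three free weights (exactly one point per equal stratum per dimension),
each coordinate mapped through the exponential transform
$w = 20^{2u-1}$, which spans $[0.05, 20]$ and puts the distance
benchmark weight 1 at the design midpoint — the printed range pins the
endpoints, and this is the simplest exponential form through them. Each
design point is simulated over the observation horizon with several
replicate seeds, and two match rates are averaged across replicates:

* **Volume match**: the fraction of observed per-country volumes
  (import, export, food; per commodity and year) that the simulation
  reproduces within ±20%, boundary inclusive; an observed zero matches
  only an exact simulated zero.
* **Partner match**: the fraction of observed (commodity, importer,
  exporter, year) records that occur in the simulation, regardless of
  volume.

The Pareto front of the design points (those not dominated on both
rates) is reported, and the selected point maximizes the equal-weight
mean of the two rates; ties break towards the higher partner rate, then
lexicographically by weights. At full empirical scale the partner metric
would be restricted to the commodity subset covered by bilateral data;
the restriction is exposed as a filter and defaults to all commodities.

### The recovery experiment

The parameter-recovery test generates observations from known weights
(gdp 6, dist 1, hist 2, emerg 0.3) on a 12-country × 3-commodity world
over 3 years at saturation 0.6 with 5% volume noise, and checks that
repeated calibrations (200 design points × 5 replicates) recover the
importance ordering of the three free weights. Two design choices matter
and are deliberate:

* *Saturation below 1.* At full saturation every feasible trade is
  eventually realized, so weights affect only pairing, not volumes, and
  the volume dimension carries no signal. At 0.6, low-priority countries
  are excluded, and both metrics respond to the weights.
* *Historic trade decorrelated from GDP* (`trade_noise_sdlog = 2`). Under
  a clean gravity law the historic element is nearly collinear with the
  GDP and distance elements, and the historic weight is unidentifiable
  from match rates. Strong log-normal noise breaks the collinearity, as
  non-gravity factors (colonial ties, trade blocs) do in reality.

## Numerical choices and conventions

* Quantities are tonnes/year; composition is per tonne of edible food;
  requirements and intake are per person per day (supply ÷ population ÷
  365).
* Distances are great-circle (haversine, sphere radius 6371 km) between
  country centroids; the upstream GIS layers name no metric, and
  centroid great-circle is reproducible without geometry dependencies.
* Market arithmetic uses a relative tolerance of $10^{-9}$ × potential
  for "remaining demand/supply" tests, so conservation holds to
  floating-point accuracy.
* Commodity markets run in the commodity table's order; since markets
  are independent and tie-breaks are the only RNG consumers, the order
  does not affect outcomes (asserted in the test suite).
* Degenerate ranking events (single candidate, or all candidates equal
  on an element) map the element to 1 rather than dropping it.
* The intermediary re-export baseline is min(baseline import, baseline
  export); whether intermediary demand rescales with global supply is
  unstated upstream, and it rescales here exactly like the diet.
* Problem sizes in the test suite (worlds of 2–30 countries, 1–6
  commodities; the recovery experiment above) are chosen so the whole
  suite establishes its properties on commodity hardware in minutes
  while exercising every code path; the generator defaults remain the
  full 165 × 91 scale.

## Limitations

* Prices, tariffs, quotas and transport costs are not modelled; the
  priority ranking absorbs ability-to-pay and proximity effects only.
* Within-country inequality of access to food is out of scope; intake is
  a national per-capita average.
* Supplementation and bioavailability adjustments are not modelled.
* The synthetic generator supports mechanism tests, not empirical
  prediction; reproducing observed world nutrition outcomes requires
  feeding real food-balance, composition and requirement tables through
  the same interfaces (`load_world()`).
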