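# reltrade

Relation-driven agent-based simulation of global food trade and its
consequences for national nutrition security.

## What it does

Most trade models are price-driven: volumes come from equilibrium
conditions on prices. `reltrade` instead models *relations*: country
agents rank potential partners by a weighted priority score and trade
with the highest-ranked ones first. For a candidate set $C$, the
priority of candidate $c$ is

$$P(c) = \frac{w_g\,\tilde g_c + w_d\,\tilde d_c + w_h\,\tilde h_c + w_e\,\tilde e_c}{w_g + w_d + w_h + w_e}$$

where $\tilde g$ (GDP per capita), $\tilde h$ (historic trade volume)
and $\tilde e$ (emergent trade volume, accumulated endogenously during
the run) are min–max normalized over $C$, and $\tilde d$ is one minus
normalized great-circle distance. Markets run in rounds — importers post
capped offers to their top exporter, exporters accept offers in their
own priority order — until realized trade reaches a *saturation*
fraction $s$ of the potential $\min(\sum \text{demand}, \sum
\text{supply})$. At $s = 1$ every market clears.

Realized trade plus domestic production gives each country's food
supply, which a nutrition pipeline (household waste by region, inedible
fractions, fortification-aware composition) converts into per-capita
daily intake of 15 macro- and micronutrients, classified against
demographically weighted requirements (fat against a 20–35%-of-energy
band).

A calibration harness recovers the priority weights from observed
trade: Latin hypercube design over the three free weights (distance
fixed at 1), exponential transform $w = 20^{2u-1}$ onto $[0.05, 20]$,
volume- and partner-match rates against the observed record, Pareto
front, and equal-weight selection.

Because no country-level data ship with the package, a synthetic world
generator (`generate_world()`) draws food-balance-sheet-like worlds —
gravity-law historic trade, concentrated production, intermediary
countries, Dirichlet demographics — at the empirical scale (165
countries × 91 commodities) by default. See the vignette
(`vignettes/relation-driven-trade.Rmd`) for the model description and
design choices.

## Worked example

Simulate three years of a 20-country, 8-commodity world under low (0.6)
and full (1.0) trade saturation and compare calorie sufficiency:

```r
library(reltrade)
w <- generate_world(world_gen_config(n_countries = 20, n_commodities = 8,
                                     seed = 42))
runs <- lapply(c(low = 0.6, high = 1.0), function(s)
  run_horizon(w, 2001:2003, params = market_params(saturation = s),
              seed = 1))

head(runs$high$transactions, 3)
#>   year commodity importer exporter  amount round
#> 1 2001      K001     C012     C001 1757959     1
#> 2 2001      K001     C009     C011 1737216     1
#> 3 2001      K001     C004     C011 2165303     1

head(intake_table(runs$high$world)[, c("country", "calories", "iron")], 4)
#>   country calories   iron
#> 1    C001     3339  9.063
#> 2    C002     8614 18.509
#> 3    C003     4432  9.299
#> 4    C004     2734  7.923

st <- sufficiency_table(lapply(runs, function(r)
  r$reports[r$reports$year == 2003, ]))
head(st[st$nutrient == "calories", ], 5)
#>     country nutrient   status_low status_high
#> 601    C001 calories   sufficient  sufficient
#> 602    C002 calories   sufficient  sufficient
#> 603    C003 calories   sufficient  sufficient
#> 604    C004 calories insufficient  sufficient
#> 605    C005 calories insufficient  sufficient
```

Transactions record who bought from whom, how much, and in which market
round. The intake table is per person per day (kcal for calories, mg for
iron); whether a value is "enough" depends on each country's
demographics, which is what the status table reports. In this world,
three countries are calorie-insufficient at low saturation and none at
full saturation — raising trade saturation closes the calorie gap, the
model's central qualitative behaviour.

A thin command-line front end over the same functions is installed at
`inst/cli/reltrade.R` (`generate`, `simulate`, `calibrate`, `report`).

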