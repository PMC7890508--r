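# Annual cycle: one simulated year chains exogenous updates, typical-diet
# rescaling, trade positions, the per-commodity markets, the food-supply
# identity, the nutrition pipeline and the emergent-relationship update.
# A horizon folds years so that emergent trade accumulates (path
# dependence).

#' Rescale the typical diet with global per-capita supply
#'
#' A country's diet target for the year is its baseline typical diet
#' scaled, per commodity, by the ratio of current to baseline global
#' per-capita supply: diets drift with what the world produces, rather
#' than jumping to a prescribed ideal.
#'
#' @param baseline_diet Country x commodity matrix of baseline food
#'   consumption, tonnes.
#' @param baseline_global_pc Per-commodity baseline global per-capita
#'   supply (tonnes/person/year).
#' @param current_global_pc Per-commodity current global per-capita supply.
#' @return Country x commodity diet-target matrix, tonnes.
#' @export
scale_typical_diet <- function(baseline_diet, baseline_global_pc,
                               current_global_pc) {
  consumed <- colSums(baseline_diet) > 0
  if (any(consumed & baseline_global_pc <= 0))
    stop("configuration error: zero baseline global supply for a consumed commodity")
  ratio <- ifelse(baseline_global_pc > 0,
                  current_global_pc / baseline_global_pc, 0)
  sweep(baseline_diet, 2, ratio, "*")
}

#' Inputs for one simulated year
#'
#' @param year Calendar year label.
#' @param gdp Per-country GDP; `NULL` keeps current values.
#' @param population Per-country population; `NULL` keeps current values.
#' @param production Country x commodity production, tonnes; `NULL` keeps
#'   the baseline production.
#' @return List of class `year_inputs`.
#' @export
year_inputs <- function(year, gdp = NULL, population = NULL,
                        production = NULL) {
  if (!is.null(population) && any(population <= 0))
    stop("population inputs must be positive")
  if (!is.null(production) && any(production < 0))
    stop("production inputs must be non-negative")
  structure(list(year = as.integer(year), gdp = gdp,
                 population = population, production = production),
            class = "year_inputs")
}

#' Simulate one year
#'
#' Executes, in order: (1) apply the year's exogenous GDP, population and
#' production; (2) rescale typical diets with global per-capita supply;
#' (3) determine trade positions for every country and commodity; (4) run
#' each commodity market independently (the trading outcome of one
#' commodity does not affect another); (5) set food supply = (production +
#' import - export) x food share, floored at zero; (6) run the nutrition
#' pipeline; (7) fold the year's transactions into the emergent trade
#' relationships.
#'
#' @param world A `trade_world`.
#' @param inputs A [year_inputs()].
#' @param params [market_params()].
#' @param weights [priority_weights()].
#' @param nutrition Run the nutrition pipeline (step 6). Turning it off
#'   (e.g. during calibration, which only needs trade volumes) skips the
#'   intake computation; `report` is then `NULL`.
#' @return List: `world` (advanced), `transactions`, `report` (sufficiency
#'   data frame), `rounds` (per-commodity round counts).
#' @export
step_year <- function(world, inputs, params = market_params(),
                      weights = priority_weights(), nutrition = TRUE) {
  stopifnot(inherits(inputs, "year_inputs"))
  n <- nrow(world$countries)
  k <- nrow(world$commodities)
  if (!is.null(inputs$gdp)) {
    if (length(inputs$gdp) != n) stop("input error: gdp must cover all countries")
    world$countries$gdp <- inputs$gdp
  }
  if (!is.null(inputs$population)) {
    if (length(inputs$population) != n)
      stop("input error: population must cover all countries")
    world$countries$population <- inputs$population
  }
  prod <- inputs$production %||% world$baseline$production
  if (!all(dim(prod) == c(n, k)))
    stop("input error: production must be a country x commodity matrix")
  world$current$year <- inputs$year
  world$current$production <- prod

  current_pc <- colSums(prod) / sum(world$countries$population)
  ratio <- ifelse(world$baseline$global_pc_supply > 0,
                  current_pc / world$baseline$global_pc_supply, 0)
  diet_target <- scale_typical_diet(world$baseline$typical_diet,
                                    world$baseline$global_pc_supply,
                                    current_pc)
  world <- determine_positions(world, diet_target, supply_ratio = ratio)

  imp <- matrix(0, n, k, dimnames = dimnames(prod))
  exp_ <- matrix(0, n, k, dimnames = dimnames(prod))
  tx <- vector("list", k)
  rounds <- integer(k)
  for (c_ix in seq_len(k)) {
    m <- run_commodity_market(world, c_ix, params, weights,
                              year = inputs$year)
    imp[, c_ix] <- m$import_realized
    exp_[, c_ix] <- m$export_realized
    tx[[c_ix]] <- m$transactions
    rounds[c_ix] <- m$rounds
  }
  transactions <- do.call(rbind, tx)
  world$current$import_realized <- imp
  world$current$export_realized <- exp_
  world$current$food_supply <-
    pmax(prod + imp - exp_, 0) * world$baseline$pct_food

  report <- NULL
  if (nutrition) {
    nut <- compute_nutrition(world)
    world <- nut$world
    report <- nut$report
  }
  world$relations <- update_emergent(world$relations, transactions,
                                     world$countries$id)
  list(world = world, transactions = transactions, report = report,
       rounds = rounds)
}

# long-format volume record of the current year, as consumed by the
# calibration volume metric
year_volumes <- function(world) {
  ids <- world$countries$id
  codes <- world$commodities$code
  yr <- world$current$year
  flow_df <- function(m, flow) {
    data.frame(country = rep(ids, times = length(codes)),
               flow = flow,
               commodity = rep(codes, each = length(ids)),
               year = yr, tonnes = as.vector(m),
               stringsAsFactors = FALSE)
  }
  rbind(flow_df(world$current$import_realized, "import"),
        flow_df(world$current$export_realized, "export"),
        flow_df(world$current$food_supply, "food"))
}

#' Simulate a horizon of consecutive years
#'
#' Folds [step_year()] over the years; emergent trade accumulates across
#' years so that partner rankings are path dependent. All randomness (tie
#' breaks in partner ranking) derives from `seed`.
#'
#' @param world A `trade_world`.
#' @param years Integer vector of consecutive years.
#' @param inputs Optional list of [year_inputs()] keyed by year (as
#'   character); years without an entry reuse baseline production and the
#'   current GDP/population.
#' @param params [market_params()].
#' @param weights [priority_weights()].
#' @param seed RNG seed; identical seeds give identical trajectories.
#' @param nutrition Run the nutrition pipeline each year; see
#'   [step_year()].
#' @return List: `world` (final state), `transactions`, `volumes` (long
#'   per-year record of import/export/food tonnes), `reports` (per-year
#'   sufficiency data frames with a year column), `rounds` (year x
#'   commodity matrix).
#' @export
run_horizon <- function(world, years, inputs = NULL,
                        params = market_params(),
                        weights = priority_weights(), seed = 1L,
                        nutrition = TRUE) {
  years <- as.integer(years)
  if (length(years) > 1 && any(diff(years) != 1L))
    stop("input error: years must be consecutive")
  set.seed(seed)
  tx <- list(); vols <- list(); reps <- list()
  rounds <- matrix(0L, length(years), nrow(world$commodities),
                   dimnames = list(years, world$commodities$code))
  for (ix in seq_along(years)) {
    y <- years[ix]
    yi <- inputs[[as.character(y)]] %||% year_inputs(y)
    st <- step_year(world, yi, params, weights, nutrition = nutrition)
    world <- st$world
    tx[[ix]] <- st$transactions
    vols[[ix]] <- year_volumes(world)
    if (!is.null(st$report)) {
      st$report$year <- y
      reps[[ix]] <- st$report
    }
    rounds[ix, ] <- st$rounds
  }
  list(world = world, transactions = do.call(rbind, tx),
       volumes = do.call(rbind, vols), reports = do.call(rbind, reps),
       rounds = rounds)
}
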