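# Synthetic world generation: builds worlds with the statistical structure
# the trade model assumes (gravity-like historic trade, concentrated
# production, intermediary countries, Dirichlet demographics) plus
# pseudo-observed trade generated under known priority weights, so the
# whole pipeline -- engine, nutrition, calibration -- is testable without
# external data downloads.

#' Configuration for the synthetic world generator
#'
#' Defaults emulate the scale of the empirical setting: 165 countries and
#' 91 food commodities, log-normal GDP per capita and population, and a
#' gravity-like historic trade network.
#'
#' @param n_countries Number of country agents.
#' @param n_commodities Number of food commodities.
#' @param seed RNG seed; fixed seed gives bit-identical worlds.
#' @param gdp_pc_meanlog,gdp_pc_sdlog Log-normal parameters for GDP per
#'   capita (currency units per person per year).
#' @param pop_meanlog,pop_sdlog Log-normal parameters for population.
#' @param production_concentration Dirichlet concentration for how
#'   production of each commodity spreads across countries; smaller values
#'   concentrate production in fewer countries.
#' @param frac_intermediary Fraction of countries given an intermediary
#'   (import-for-re-export) role in at least one commodity.
#' @param gravity_exponent Distance exponent of the gravity law generating
#'   historic trade volumes.
#' @param diet_sdlog Log-normal spread of country-level deviations from the
#'   global per-capita consumption rate of each commodity.
#' @param trade_noise_sdlog Log-normal noise on historic gravity volumes.
#' @return List of class `world_gen_config`.
#' @export
world_gen_config <- function(n_countries = 165, n_commodities = 91,
                             seed = 1L,
                             gdp_pc_meanlog = log(8000), gdp_pc_sdlog = 1.2,
                             pop_meanlog = log(8e6), pop_sdlog = 1.3,
                             production_concentration = 0.8,
                             frac_intermediary = 0.1,
                             gravity_exponent = 1,
                             diet_sdlog = 0.25,
                             trade_noise_sdlog = 0.5) {
  if (n_countries < 2) stop("n_countries must be >= 2")
  if (n_commodities < 1) stop("n_commodities must be >= 1")
  scales <- c(gdp_pc_sdlog, pop_sdlog, production_concentration,
              diet_sdlog, trade_noise_sdlog)
  if (any(scales <= 0)) stop("all scale parameters must be > 0")
  if (frac_intermediary < 0 || frac_intermediary > 1)
    stop("frac_intermediary must lie in [0, 1]")
  structure(list(n_countries = as.integer(n_countries),
                 n_commodities = as.integer(n_commodities),
                 seed = as.integer(seed),
                 gdp_pc_meanlog = gdp_pc_meanlog,
                 gdp_pc_sdlog = gdp_pc_sdlog,
                 pop_meanlog = pop_meanlog, pop_sdlog = pop_sdlog,
                 production_concentration = production_concentration,
                 frac_intermediary = frac_intermediary,
                 gravity_exponent = gravity_exponent,
                 diet_sdlog = diet_sdlog,
                 trade_noise_sdlog = trade_noise_sdlog),
            class = "world_gen_config")
}

#' Default age-sex groups
#'
#' Four age bands crossed with two sexes. The group list is configurable in
#' the requirement table; this is the shipped default.
#'
#' @return Character vector of 8 group labels.
#' @export
age_sex_groups <- function() {
  bands <- c("0_14", "15_39", "40_64", "65plus")
  as.vector(outer(c("m", "f"), bands, function(s, b) paste(s, b, sep = "_")))
}

# Per-group scaling of the adult-reference requirement row. Children need
# less in absolute terms; prime-age males the most.
group_requirement_factor <- function(groups = age_sex_groups()) {
  band <- sub("^[mf]_", "", groups)
  sex <- sub("_.*$", "", groups)
  f <- c("0_14" = 0.70, "15_39" = 1.10, "40_64" = 1.00, "65plus" = 0.85)[band]
  f <- f * ifelse(sex == "m", 1.08, 0.95)
  names(f) <- groups
  f
}

# Adult-reference daily requirement per nutrient. Energy follows an
# average-dietary-energy-requirement convention (physical activity level
# 1.75, BMI 21 kg/m2 for adults); micronutrient values are in the range of
# WHO/FAO adult recommendations. Fat is banded (20-35% of energy).
base_requirements <- function() {
  c(calories = 2200, protein = 55, fat = 0.20 * 2200 / 9, vitamin_c = 45,
    vitamin_a = 500, folate = 330, calcium = 800, iron = 12, zinc = 9,
    fibre = 22, thiamin = 1.1, riboflavin = 1.2, niacin = 13,
    vitamin_b6 = 1.2, saturated_fat = 8)
}

#' Synthetic requirement table
#'
#' Per age-sex group and nutrient, the required amount per person per day,
#' plus a (lower, upper) band for fat at 20-35% of the group's energy
#' requirement.
#'
#' @param groups Age-sex group labels.
#' @return List with `mean` (group x nutrient matrix), `fat_lower` and
#'   `fat_upper` (per-group vectors, g/person/day).
#' @export
synthetic_requirements <- function(groups = age_sex_groups()) {
  f <- group_requirement_factor(groups)
  base <- base_requirements()
  m <- outer(f, base)
  dimnames(m) <- list(groups, names(base))
  cal <- m[, "calories"]
  list(mean = m,
       fat_lower = 0.20 * cal / 9,
       fat_upper = 0.35 * cal / 9)
}

# Mean nutrient density per tonne of edible food (units of nutrient_units()
# per tonne), around which commodity-level densities vary log-normally.
base_densities <- function() {
  c(calories = 1.8e6, protein = 5.5e4, fat = 5.0e4, vitamin_c = 5.0e4,
    vitamin_a = 5.0e5, folate = 3.0e5, calcium = 7.0e5, iron = 1.0e4,
    zinc = 8.0e3, fibre = 2.0e4, thiamin = 1.0e3, riboflavin = 1.2e3,
    niacin = 1.2e4, vitamin_b6 = 1.2e3, saturated_fat = 1.8e4)
}

# Build the three fortification variants from a base composition matrix.
# Refining strips fibre and micronutrients from refinable (cereal)
# commodities; fortification restores most micronutrients but not fibre.
make_variants <- function(base, refinable) {
  micro <- c("vitamin_c", "vitamin_a", "folate", "calcium", "iron", "zinc",
             "thiamin", "riboflavin", "niacin", "vitamin_b6")
  unf <- base
  unf[refinable, micro] <- unf[refinable, micro] * 0.35
  unf[refinable, "fibre"] <- unf[refinable, "fibre"] * 0.30
  fort <- base
  fort[refinable, micro] <- fort[refinable, micro] * 0.90
  fort[refinable, "fibre"] <- fort[refinable, "fibre"] * 0.30
  list(unrefined = base, refined_unfortified = unf,
       refined_fortified = fort)
}

#' Generate a synthetic world
#'
#' Draws a full world state: country attributes (centroids, GDP,
#' population, Dirichlet demographics, waste regions, income classes),
#' commodity definitions with three-variant nutrient composition, baseline
#' food-balance flows constructed so that per commodity the global
#' production roughly balances global diet demand (within +/-20%, so both
#' market sides exist), intermediary countries satisfying the 80%
#' re-export rule on their baseline flows, and a gravity-like historic
#' bilateral trade matrix.
#'
#' @param cfg A [world_gen_config()].
#' @return A valid `trade_world` (passes [validate_world()]).
#' @examples
#' w <- generate_world(world_gen_config(n_countries = 6, n_commodities = 3))
#' validate_world(w)
#' @export
generate_world <- function(cfg = world_gen_config()) {
  stopifnot(inherits(cfg, "world_gen_config"))
  set.seed(cfg$seed)
  n <- cfg$n_countries
  k <- cfg$n_commodities
  ids <- sprintf("C%03d", seq_len(n))
  codes <- sprintf("K%03d", seq_len(k))

  gdp_pc <- stats::rlnorm(n, cfg$gdp_pc_meanlog, cfg$gdp_pc_sdlog)
  pop <- stats::rlnorm(n, cfg$pop_meanlog, cfg$pop_sdlog)
  qs <- stats::quantile(gdp_pc, c(0.25, 0.5, 0.75))
  income <- cut(gdp_pc, c(-Inf, qs, Inf),
                labels = c("low", "lower_middle", "upper_middle", "high"))
  income <- as.character(income)
  fmap <- default_fortification_map()

  countries <- data.frame(
    id = ids, name = paste("Country", seq_len(n)),
    lat = stats::runif(n, -55, 70), lon = stats::runif(n, -180, 180),
    region = sample(waste_regions(), n, replace = TRUE),
    income_class = income,
    fortification = unname(fmap[income]),
    population = pop, gdp = gdp_pc * pop,
    stringsAsFactors = FALSE)

  groups <- age_sex_groups()
  alpha <- c(m_0_14 = 3, f_0_14 = 3, m_15_39 = 5, f_15_39 = 5,
             m_40_64 = 4, f_40_64 = 4, m_65plus = 1.5, f_65plus = 1.5)
  g <- matrix(stats::rgamma(n * length(groups), shape = rep(alpha[groups],
                                                            each = n)),
              n, length(groups))
  demographics <- g / rowSums(g)
  dimnames(demographics) <- list(ids, groups)

  grp <- rep(food_groups(), length.out = k)
  commodities <- data.frame(
    code = codes, name = paste("Commodity", seq_len(k)), group = grp,
    edible_fraction = stats::runif(k, 0.6, 1),
    refinable = grp == "cereals",
    stringsAsFactors = FALSE)

  dens <- base_densities()
  base_comp <- matrix(stats::rlnorm(k * length(dens), meanlog = 0,
                                    sdlog = 0.6),
                      k, length(dens)) * rep(dens, each = k)
  dimnames(base_comp) <- list(codes, names(dens))
  composition <- make_variants(base_comp, commodities$refinable)

  # typical diet: global per-capita rate per commodity, country multiplier
  q <- stats::rlnorm(k, meanlog = log(0.5 / k), sdlog = 0.7)
  mult <- matrix(stats::rlnorm(n * k, 0, cfg$diet_sdlog), n, k)
  typical_diet <- outer(pop, q) * mult

  pct_food <- matrix(stats::runif(n * k, 0.6, 0.9), n, k)
  pct_loss <- matrix(stats::runif(n * k, 0.02, 0.08), n, k)
  ds_demand <- typical_diet / pct_food

  # production: global total balances global domestic-supply demand within
  # +/-10%; Dirichlet shares concentrate it in few countries
  shares <- matrix(stats::rgamma(n * k, shape = cfg$production_concentration),
                   n, k)
  shares <- sweep(shares, 2, colSums(shares), "/")
  global_target <- colSums(ds_demand) * stats::runif(k, 0.9, 1.1)
  if (any(global_target <= 0))
    stop("infeasible configuration: zero global demand for a commodity")
  production <- sweep(shares, 2, global_target, "*")

  imp <- pmax(ds_demand - production, 0)
  exp_ <- pmax(production - ds_demand, 0)

  # intermediaries: add matched import/export re-export volume large enough
  # that the 80% rule flags them on the resulting baseline flows
  n_int <- round(cfg$frac_intermediary * n)
  if (n_int > 0) {
    int_countries <- sample(n, n_int)
    for (i in int_countries) {
      for (c_ix in sample(k, min(k, sample(1:3, 1)))) {
        reexp <- 5 * imp[i, c_ix] + 0.05 * global_target[c_ix] / n
        imp[i, c_ix] <- imp[i, c_ix] + reexp
        exp_[i, c_ix] <- exp_[i, c_ix] + reexp
      }
    }
  }
  is_int <- imp > 0 & exp_ > 0.8 * imp
  reexport <- ifelse(is_int, pmin(imp, exp_), 0)

  dimnames(production) <- dimnames(imp) <- dimnames(exp_) <-
    dimnames(typical_diet) <- dimnames(pct_food) <- dimnames(pct_loss) <-
    dimnames(is_int) <- dimnames(reexport) <- list(ids, codes)

  baseline <- list(production = production, import = imp, export = exp_,
                   ds = production + imp - exp_, pct_food = pct_food,
                   pct_loss = pct_loss, typical_diet = typical_diet,
                   is_intermediary = is_int, reexport = reexport)

  # historic trade: gravity law on all-commodity pooled volumes, scaled to
  # the baseline import total; M[i, j] = volume i imported from j
  dist <- distance_matrix_km(countries$lat, countries$lon)
  gdp <- countries$gdp
  M <- outer(gdp, gdp) / pmax(dist, 100)^cfg$gravity_exponent
  diag(M) <- 0
  M <- M * matrix(stats::rlnorm(n * n, 0, cfg$trade_noise_sdlog), n, n)
  M <- M / sum(M) * sum(imp)
  zero_nn <- matrix(0, n, n, dimnames = list(ids, ids))
  dimnames(dist) <- dimnames(M) <- list(ids, ids)
  relations <- list(distance = dist, historic_import = M,
                    historic_export = t(M),
                    emergent_import = zero_nn,
                    emergent_export = zero_nn)

  world <- new_world(countries, demographics, commodities, composition,
                     baseline, relations, synthetic_requirements(groups),
                     default_waste_table())
  v <- validate_world(world)
  if (length(v))
    stop("generator produced an invalid world: ", paste(v, collapse = "; "))
  world
}

#' Generate pseudo-observed trade data under known weights
#'
#' Runs the annual cycle with a known ("true") weight vector and perturbs
#' the resulting per-country volumes multiplicatively by (1 + eps), eps
#' uniform in +/-`noise`. Trade partners are unaffected by the noise; only
#' volumes are. The output feeds the calibration match metrics, enabling
#' parameter-recovery experiments.
#'
#' @param world A `trade_world`.
#' @param true_weights [priority_weights()] used to simulate.
#' @param years Integer vector of consecutive years to simulate.
#' @param saturation Trade saturation of the generating run.
#' @param noise Relative volume perturbation half-width (0 = noiseless).
#' @param seed RNG seed for the simulation and the perturbation.
#' @return List of class `observed_trade` with `volumes` (country, flow,
#'   commodity, year, tonnes) and `transactions` (year, commodity,
#'   importer, exporter, tonnes).
#' @export
generate_observations <- function(world, true_weights, years = 2001:2003,
                                  saturation = 1, noise = 0, seed = 1L) {
  sim <- run_horizon(world, years = years,
                     params = market_params(saturation = saturation),
                     weights = true_weights, seed = seed)
  vols <- sim$volumes
  if (noise > 0) {
    set.seed(seed + 77003L)
    eps <- stats::runif(nrow(vols), -noise, noise)
    vols$tonnes <- vols$tonnes * (1 + eps)
  }
  structure(list(volumes = vols, transactions = sim$transactions,
                 years = years),
            class = "observed_trade")
}
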