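# Fixture builders: hand-assembled miniature worlds with fully
# controllable attributes, used to exercise the engine and the nutrition
# pipeline on known inputs. Everything is generated in code at test time.

micro_world <- function(n, k = 1,
                        gdp_pc = rep(1e4, n),
                        pop = rep(1e6, n),
                        dist = NULL,
                        hist_import = matrix(0, n, n),
                        emergent_import = matrix(0, n, n),
                        emergent_export = matrix(0, n, n),
                        production = matrix(0, n, k),
                        typical_diet = matrix(0, n, k),
                        pct_food = matrix(1, n, k),
                        reexport = matrix(0, n, k),
                        region = rep("Europe", n),
                        group = rep("cereals", k),
                        edible_fraction = rep(1, k),
                        composition = NULL,
                        waste = default_waste_table(),
                        requirements = synthetic_requirements(),
                        fortification = rep("unrefined", n)) {
  ids <- sprintf("C%02d", seq_len(n))
  codes <- sprintf("K%02d", seq_len(k))
  if (is.null(dist)) {
    dist <- matrix(1000, n, n)
    diag(dist) <- 0
  }
  nut <- nutrients()
  if (is.null(composition)) {
    composition <- matrix(1, k, length(nut), dimnames = list(codes, nut))
  }
  comp <- list(unrefined = composition,
               refined_unfortified = composition,
               refined_fortified = composition)
  groups <- rownames(requirements$mean)
  demographics <- matrix(1 / length(groups), n, length(groups),
                         dimnames = list(ids, groups))
  countries <- data.frame(
    id = ids, name = ids, lat = rep(0, n), lon = rep(0, n),
    region = region, income_class = rep("high", n),
    fortification = fortification, population = pop, gdp = gdp_pc * pop,
    stringsAsFactors = FALSE)
  commodities <- data.frame(
    code = codes, name = codes, group = group,
    edible_fraction = edible_fraction, refinable = group == "cereals",
    stringsAsFactors = FALSE)
  zero <- matrix(0, n, k, dimnames = list(ids, codes))
  dimnames(production) <- dimnames(typical_diet) <- dimnames(pct_food) <-
    dimnames(reexport) <- list(ids, codes)
  baseline <- list(
    production = production, import = zero, export = zero,
    ds = production, pct_food = pct_food,
    pct_loss = zero, typical_diet = typical_diet,
    is_intermediary = reexport > 0, reexport = reexport,
    global_pc_supply = colSums(production) / sum(pop))
  relations <- list(distance = dist,
                    historic_import = hist_import,
                    historic_export = t(hist_import),
                    emergent_import = emergent_import,
                    emergent_export = emergent_export)
  current <- list(
    year = 2001L, production = production,
    import_needed_domestic = zero,
    import_needed_intermediary = zero,
    export_available = zero,
    import_realized = zero, export_realized = zero,
    food_supply = zero,
    nutrient_intake = matrix(0, n, length(nut),
                             dimnames = list(ids, nut)),
    nutrient_requirement = matrix(0, n, length(nut),
                                  dimnames = list(ids, nut)))
  structure(list(countries = countries, demographics = demographics,
                 commodities = commodities, composition = comp,
                 baseline = baseline, relations = relations,
                 requirements = requirements, waste = waste,
                 group_map = waste_group_map(),
                 fortification_map = default_fortification_map(),
                 current = current),
            class = "trade_world")
}

# overwrite the market positions of one commodity directly
set_positions <- function(world, dem_dom, dem_int = NULL, sup, c_ix = 1) {
  n <- nrow(world$countries)
  if (is.null(dem_int)) dem_int <- rep(0, n)
  world$current$import_needed_domestic[, c_ix] <- dem_dom
  world$current$import_needed_intermediary[, c_ix] <- dem_int
  world$current$export_available[, c_ix] <- sup
  world
}

# random tie-free micro world with positions set, for engine/oracle suites
random_positioned_world <- function(n, k = 1) {
  w <- micro_world(n, k,
                   gdp_pc = stats::runif(n, 1e3, 5e4),
                   pop = stats::runif(n, 1e5, 1e8),
                   dist = {
                     d <- matrix(0, n, n)
                     d[upper.tri(d)] <- stats::runif(n * (n - 1) / 2,
                                                     100, 15000)
                     d + t(d)
                   },
                   hist_import = matrix(stats::runif(n * n, 0, 1e5), n, n),
                   emergent_import = matrix(stats::runif(n * n, 0, 1e4),
                                            n, n),
                   emergent_export = matrix(stats::runif(n * n, 0, 1e4),
                                            n, n))
  for (c_ix in seq_len(k)) {
    side <- stats::runif(n) < 0.5
    dem <- ifelse(side, stats::runif(n, 0, 100), 0)
    sup <- ifelse(!side, stats::runif(n, 0, 100), 0)
    dem_int <- ifelse(!side & stats::runif(n) < 0.2,
                      stats::runif(n, 0, 30), 0)
    w <- set_positions(w, dem, dem_int, sup, c_ix)
  }
  w
}
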