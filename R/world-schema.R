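# World state schema: the typed containers shared by the generator, the
# trade engine, the nutrition pipeline and the calibration harness, plus
# their validation.  A world is a plain list of class "trade_world" built
# around country x commodity matrices; see new_world() for the layout.

#' Nutrients tracked by the model
#'
#' The closed, ordered list of macro- and micronutrients carried through the
#' food-composition, intake and requirement computations. Units are declared
#' once in [nutrient_units()].
#'
#' @return Character vector of nutrient names.
#' @export
nutrients <- function() {
  c("calories", "protein", "fat", "vitamin_c", "vitamin_a", "folate",
    "calcium", "iron", "zinc", "fibre", "thiamin", "riboflavin", "niacin",
    "vitamin_b6", "saturated_fat")
}

#' Units per nutrient
#'
#' Intake and requirements are per person per day; composition values use
#' the same unit per tonne of edible food.
#'
#' @return Named character vector, one unit per entry of [nutrients()].
#' @export
nutrient_units <- function() {
  c(calories = "kcal", protein = "g", fat = "g", vitamin_c = "mg",
    vitamin_a = "ug_RAE", folate = "ug", calcium = "mg", iron = "mg",
    zinc = "mg", fibre = "g", thiamin = "mg", riboflavin = "mg",
    niacin = "mg", vitamin_b6 = "mg", saturated_fat = "g")
}

#' Aggregate food groups
#'
#' The 21 aggregate groups food commodities belong to, mirroring the
#' food-balance-sheet classification.
#'
#' @return Character vector of group labels.
#' @export
food_groups <- function() {
  c("cereals", "starchy_roots", "sugar_crops", "sugar_sweeteners", "pulses",
    "treenuts", "oilcrops", "vegetable_oils", "vegetables", "fruits",
    "spices", "stimulants", "alcoholic_beverages", "meat", "offal",
    "animal_fats", "eggs", "milk", "fish_seafood", "aquatic_products",
    "other")
}

#' Household-waste regions
#'
#' The seven world regions for which household food-waste rates are
#' tabulated.
#'
#' @return Character vector of region labels.
#' @export
waste_regions <- function() {
  c("Europe", "North America & Oceania", "Industrialized Asia",
    "Sub-Saharan Africa", "North Africa, West & Central Asia",
    "South & Southeast Asia", "Latin America")
}

#' Default household food-waste table
#'
#' Fraction of edible food wasted in household consumption, by region and
#' food type, from the Gustavsson et al. (FAO, 2011) global food-loss
#' estimates. Values are fractions in [0, 1] (e.g. 0.25 means 25% of the
#' food reaching households is wasted).
#'
#' @return Numeric matrix, regions in rows ([waste_regions()]), the eleven
#'   tabulated food types in columns.
#' @export
default_waste_table <- function() {
  types <- c("cereals", "roots_tubers", "oilseeds", "pulses", "nuts",
             "fruit", "vegetables", "meat", "offal", "fish", "milk")
  m <- rbind(
    c(25, 17, 4, 4, 4, 19, 19, 11, 11, 11,  7),   # Europe
    c(27, 30, 4, 4, 4, 28, 28, 11, 11, 33, 15),   # North America & Oceania
    c(20, 10, 4, 4, 4, 15, 15,  8,  8,  8,  5),   # Industrialized Asia
    c( 1,  2, 1, 1, 1,  5,  5,  2,  2,  2, 0.1),  # Sub-Saharan Africa
    c(12,  6, 2, 2, 2, 12, 12,  8,  8,  4,  2),   # N Africa, W & C Asia
    c( 3,  3, 1, 1, 1,  7,  7,  4,  4,  2,  1),   # South & Southeast Asia
    c(10,  4, 2, 2, 2, 10, 10,  6,  6,  4,  4)    # Latin America
  ) / 100
  dimnames(m) <- list(waste_regions(), types)
  m
}

#' Map aggregate food groups to waste-table food types
#'
#' The waste table distinguishes eleven food types while commodities are
#' classified into the 21 aggregate groups; this mapping assigns each group
#' the waste type whose handling at household level it most resembles.
#'
#' @return Named character vector: aggregate group -> waste-table column.
#' @export
waste_group_map <- function() {
  c(cereals = "cereals", starchy_roots = "roots_tubers",
    sugar_crops = "roots_tubers", sugar_sweeteners = "cereals",
    pulses = "pulses", treenuts = "nuts", oilcrops = "oilseeds",
    vegetable_oils = "oilseeds", vegetables = "vegetables",
    fruits = "fruit", spices = "vegetables", stimulants = "vegetables",
    alcoholic_beverages = "cereals", meat = "meat", offal = "offal",
    animal_fats = "meat", eggs = "milk", milk = "milk",
    fish_seafood = "fish", aquatic_products = "fish", other = "cereals")
}

#' Fortification variants and the income-class mapping
#'
#' Refinable staples (the cereals group) exist in three composition
#' variants: unrefined, refined without fortification, and refined with
#' micronutrient fortification. Which variant a country consumes is driven
#' by its income class; the default mapping reflects that refining is
#' common at higher incomes while fortification programmes concentrate in
#' middle-income countries.
#'
#' @return Named character vector: income class -> composition variant.
#' @export
default_fortification_map <- function() {
  c(low = "unrefined",
    lower_middle = "refined_fortified",
    upper_middle = "refined_fortified",
    high = "refined_unfortified")
}

#' Great-circle distance between two points
#'
#' Haversine distance on a sphere of radius 6371 km, used for the distance
#' element of trade priority between country centroids.
#'
#' @param lat1,lon1 Latitude/longitude of the first point, degrees.
#' @param lat2,lon2 Latitude/longitude of the second point, degrees.
#' @return Distance in km (vectorized).
#' @examples
#' great_circle_km(0, 0, 0, 180)  # half circumference, ~20015 km
#' @export
great_circle_km <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90) || any(abs(c(lon1, lon2)) > 180))
    stop("coordinates out of range: |lat| <= 90, |lon| <= 180 required")
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371) # km
}

#' Pairwise great-circle distance matrix
#'
#' @param lat,lon Numeric vectors of centroid coordinates, degrees.
#' @return Symmetric matrix of distances in km with zero diagonal.
#' @export
distance_matrix_km <- function(lat, lon) {
  n <- length(lat)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    m[i, ] <- great_circle_km(lat[i], lon[i], lat, lon)
  }
  # enforce exact symmetry and zero diagonal against floating-point drift
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}

#' Priority weights for trade-partner ranking
#'
#' The four weights of the trade-priority score. The distance weight is the
#' fixed benchmark (1 by convention): rankings are invariant to a common
#' rescaling, so one weight is redundant and calibration varies only the
#' other three.
#'
#' @param gdp Weight on partner GDP per capita.
#' @param dist Weight on (inverse) geographic distance; fixed at 1 during
#'   calibration.
#' @param hist Weight on historic trade volume with the partner.
#' @param emerg Weight on emergent (endogenously accumulated) trade volume.
#' @return Named numeric vector of class `priority_weights`.
#' @examples
#' priority_weights(1.40, 1, 1.40, 0.72)  # the shipped calibrated defaults
#' @export
priority_weights <- function(gdp = 1.40, dist = 1, hist = 1.40,
                             emerg = 0.72) {
  w <- c(gdp = unname(gdp)[1], dist = unname(dist)[1],
         hist = unname(hist)[1], emerg = unname(emerg)[1])
  if (any(!is.finite(w)) || any(w < 0))
    stop("priority weights must be finite and non-negative")
  if (sum(w) == 0) stop("at least one priority weight must be positive")
  structure(w, class = "priority_weights")
}

#' Market parameters
#'
#' @param saturation Trade saturation s in [0, 1]: the fraction of
#'   potential trade (the smaller of total demand and total supply at
#'   market open) that is realized. At s = 1 all trade opportunities are
#'   realized.
#' @param cap Maximum tonnes a country may trade per transaction per round.
#'   `NULL` (default) sets it to potential/10 at market open, which keeps
#'   markets in the 5-20 round range without letting large countries crowd
#'   out small ones.
#' @param max_rounds Safety bound on rounds per commodity market.
#' @return List of class `market_params`.
#' @export
market_params <- function(saturation = 1, cap = NULL, max_rounds = 1000L) {
  if (!is.numeric(saturation) || saturation < 0 || saturation > 1)
    stop("saturation must lie in [0, 1]")
  if (!is.null(cap) && (!is.numeric(cap) || cap <= 0))
    stop("cap must be positive or NULL")
  structure(list(saturation = saturation, cap = cap,
                 max_rounds = as.integer(max_rounds)),
            class = "market_params")
}

# Internal constructor; generate_world() and load_world() are the public
# entry points. All matrices are country x commodity unless noted.
new_world <- function(countries, demographics, commodities, composition,
                      baseline, relations, requirements, waste,
                      group_map = waste_group_map(),
                      fortification_map = default_fortification_map()) {
  n <- nrow(countries)
  k <- nrow(commodities)
  # baseline global per-capita supply anchors the annual diet rescaling
  baseline$global_pc_supply <-
    colSums(baseline$production) / sum(countries$population)
  current <- list(
    year = NA_integer_,
    production = baseline$production,
    import_needed_domestic = matrix(0, n, k),
    import_needed_intermediary = matrix(0, n, k),
    export_available = matrix(0, n, k),
    import_realized = matrix(0, n, k),
    export_realized = matrix(0, n, k),
    food_supply = matrix(0, n, k),
    nutrient_intake = matrix(0, n, length(nutrients()),
                             dimnames = list(countries$id, nutrients())),
    nutrient_requirement = matrix(0, n, length(nutrients()),
                                  dimnames = list(countries$id, nutrients()))
  )
  structure(list(countries = countries, demographics = demographics,
                 commodities = commodities, composition = composition,
                 baseline = baseline, relations = relations,
                 requirements = requirements, waste = waste,
                 group_map = group_map,
                 fortification_map = fortification_map,
                 current = current),
            class = "trade_world")
}

#' @export
print.trade_world <- function(x, ...) {
  cat(sprintf("<trade_world> %d countries x %d commodities, %d nutrients\n",
              nrow(x$countries), nrow(x$commodities), length(nutrients())))
  cat(sprintf("  current year: %s\n",
              ifelse(is.na(x$current$year), "(not simulated)",
                     x$current$year)))
  invisible(x)
}

viol <- function(fmt, ...) sprintf(fmt, ...)

#' Validate a world state
#'
#' Checks every structural invariant of the world state: demographic shares
#' summing to one, non-negative flows, food/loss shares, distance symmetry,
#' composition non-negativity, requirement positivity and band ordering,
#' waste fractions in range, and resolvability of every region/food-group
#' pair. Returns violations instead of failing so callers can report all
#' problems at once.
#'
#' @param world A `trade_world`.
#' @return Character vector of violation messages, each naming the
#'   country/commodity/field concerned; empty when the world is valid.
#' @export
validate_world <- function(world) {
  v <- character(0)
  cs <- world$countries
  cm <- world$commodities
  nut <- nutrients()

  if (any(cs$population <= 0))
    v <- c(v, viol("country %s: population must be > 0",
                   cs$id[cs$population <= 0]))
  if (any(abs(cs$lat) > 90 | abs(cs$lon) > 180))
    v <- c(v, viol("country %s: centroid out of range",
                   cs$id[abs(cs$lat) > 90 | abs(cs$lon) > 180]))
  bad_region <- !(cs$region %in% rownames(world$waste))
  if (any(bad_region))
    v <- c(v, viol("country %s: region '%s' not in waste table",
                   cs$id[bad_region], cs$region[bad_region]))

  dm <- world$demographics
  s <- rowSums(dm)
  off <- abs(s - 1) > 1e-9
  if (any(off))
    v <- c(v, viol("country %s: demographic shares sum to %.6f, not 1",
                   cs$id[off], s[off]))
  if (any(dm < 0))
    v <- c(v, viol("country %s: negative demographic share",
                   cs$id[apply(dm < 0, 1, any)]))

  if (any(cm$edible_fraction < 0 | cm$edible_fraction > 1))
    v <- c(v, viol("commodity %s: edible_fraction outside [0,1]",
                   cm$code[cm$edible_fraction < 0 | cm$edible_fraction > 1]))
  bad_group <- !(cm$group %in% names(world$group_map))
  if (any(bad_group))
    v <- c(v, viol("commodity %s: group '%s' not mappable to a waste type",
                   cm$code[bad_group], cm$group[bad_group]))

  for (variant in names(world$composition)) {
    comp <- world$composition[[variant]]
    if (!identical(colnames(comp), nut))
      v <- c(v, viol("composition variant %s: nutrient columns differ from the schema list", variant))
    if (any(comp < 0)) {
      bad <- which(rowSums(comp < 0) > 0)
      v <- c(v, viol("composition variant %s, commodity %s: negative nutrient amount",
                     variant, cm$code[bad]))
    }
  }

  b <- world$baseline
  for (f in c("production", "import", "export", "ds", "typical_diet",
              "reexport")) {
    if (any(b[[f]] < 0)) {
      idx <- which(b[[f]] < 0, arr.ind = TRUE)
      v <- c(v, viol("country %s, commodity %s: negative baseline %s",
                     cs$id[idx[, 1]], cm$code[idx[, 2]], f))
    }
  }
  share_sum <- b$pct_food + b$pct_loss
  if (any(b$pct_food < 0 | b$pct_loss < 0 | share_sum > 1 + 1e-9)) {
    idx <- which(b$pct_food < 0 | b$pct_loss < 0 | share_sum > 1 + 1e-9,
                 arr.ind = TRUE)
    v <- c(v, viol("country %s, commodity %s: food/loss shares invalid",
                   cs$id[idx[, 1]], cm$code[idx[, 2]]))
  }

  r <- world$relations
  if (any(r$distance < 0))
    v <- c(v, "relations: negative distance")
  if (max(abs(r$distance - t(r$distance))) > 1e-6)
    v <- c(v, "relations: distance matrix not symmetric")
  if (any(diag(r$distance) != 0))
    v <- c(v, "relations: non-zero distance diagonal")
  for (f in c("historic_import", "historic_export", "emergent_import",
              "emergent_export")) {
    if (any(r[[f]] < 0)) v <- c(v, viol("relations: negative %s", f))
  }
  if (max(abs(r$historic_import - t(r$historic_export))) > 1e-6)
    v <- c(v, "relations: historic import/export volumes inconsistent across the pair")

  rq <- world$requirements
  if (any(rq$mean <= 0))
    v <- c(v, "requirements: non-positive requirement entries")
  if (any(rq$fat_lower >= rq$fat_upper))
    v <- c(v, "requirements: fat band lower bound not below upper bound")
  if (!identical(sort(rownames(rq$mean)), sort(colnames(world$demographics))))
    v <- c(v, "requirements: age-sex groups differ from demographics")

  if (any(world$waste < 0 | world$waste > 1))
    v <- c(v, "waste table: fraction outside [0,1]")
  unmapped <- setdiff(unname(world$group_map), colnames(world$waste))
  if (length(unmapped))
    v <- c(v, viol("waste table: mapped food type '%s' missing", unmapped))

  cur <- world$current
  for (f in c("production", "import_needed_domestic",
              "import_needed_intermediary", "export_available",
              "import_realized", "export_realized", "food_supply")) {
    if (any(cur[[f]] < 0)) {
      idx <- which(cur[[f]] < 0, arr.ind = TRUE)
      v <- c(v, viol("country %s, commodity %s: negative current %s",
                     cs$id[idx[, 1]], cm$code[idx[, 2]], f))
    }
  }
  v
}
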