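# Nutrition pipeline: from per-commodity food supply to per-capita
# nutrient intake (household waste, inedible fraction, fortification
# variant) and sufficiency classification against demographically
# weighted requirements.  Fat is classified against a (lower, upper) band;
# all other nutrients against a single threshold, boundary inclusive.

# waste fraction per commodity for one country, resolved through the
# region x food-type table and the group -> food-type mapping
country_waste_fractions <- function(world, country_ix) {
  region <- world$countries$region[country_ix]
  if (!region %in% rownames(world$waste))
    stop("configuration error: region '", region, "' not in waste table")
  types <- world$group_map[world$commodities$group]
  if (anyNA(types))
    stop("configuration error: unmapped commodity group")
  unname(world$waste[region, types])
}

#' Edible food actually consumed
#'
#' Reduces per-commodity food supply by the household waste fraction for
#' the country's region and the commodity's food type, and by the
#' commodity's inedible fraction (peels, bones, ...). Waste applies to the
#' food component only; pre-household losses are already netted out of the
#' food share of domestic supply.
#'
#' @param world A `trade_world`.
#' @param country Country index or id.
#' @param food_supply Per-commodity food supply, tonnes; defaults to the
#'   country's current-year food supply.
#' @return Per-commodity tonnes of edible food consumed.
#' @export
edible_consumed <- function(world, country, food_supply = NULL) {
  ix <- if (is.character(country)) match(country, world$countries$id)
        else country
  if (is.na(ix)) stop("unknown country: ", country)
  if (is.null(food_supply)) food_supply <- world$current$food_supply[ix, ]
  waste <- country_waste_fractions(world, ix)
  food_supply * (1 - waste) * world$commodities$edible_fraction
}

#' Effective nutrient composition for a country
#'
#' For refinable commodities (the cereals group) the composition variant is
#' selected by the country's fortification profile -- unrefined, refined
#' without fortification, or refined and fortified; all other commodities
#' use the base composition regardless of country.
#'
#' @param world A `trade_world`.
#' @param country Country index or id.
#' @return Commodity x nutrient matrix (amount per tonne of edible food).
#' @export
effective_composition <- function(world, country) {
  ix <- if (is.character(country)) match(country, world$countries$id)
        else country
  if (is.na(ix)) stop("unknown country: ", country)
  variant <- world$countries$fortification[ix]
  if (!variant %in% names(world$composition))
    stop("configuration error: missing composition variant '", variant, "'")
  comp <- world$composition$unrefined
  ref <- world$commodities$refinable
  comp[ref, ] <- world$composition[[variant]][ref, ]
  comp
}

#' Per-capita daily nutrient intake
#'
#' Sums tonnes of edible food consumed times nutrient composition over all
#' commodities and converts to per person per day by dividing by
#' population x 365. Linear in consumption.
#'
#' @param edible Per-commodity tonnes of edible food consumed.
#' @param composition Commodity x nutrient matrix, amount per tonne.
#' @param population Persons; must be > 0.
#' @return Named nutrient vector, per person per day.
#' @export
intake_per_capita <- function(edible, composition, population) {
  if (population <= 0) stop("population must be > 0")
  drop(edible %*% composition) / (population * 365)
}

#' Population-weighted per-capita requirement
#'
#' Weights each age-sex group's daily requirement row by the group's
#' population share; the fat band endpoints are weighted the same way.
#'
#' @param demographics Named vector of group shares summing to 1.
#' @param requirements Requirement table: list with `mean` (group x
#'   nutrient), `fat_lower`, `fat_upper`.
#' @return List: `mean` (named nutrient vector, per person per day),
#'   `fat_lower`, `fat_upper` (scalars, g/person/day).
#' @export
requirement_per_capita <- function(demographics, requirements) {
  groups <- rownames(requirements$mean)
  if (!all(names(demographics) %in% groups) ||
      !all(groups %in% names(demographics)))
    stop("configuration error: demographic groups do not match the requirement table")
  if (abs(sum(demographics) - 1) > 1e-9)
    stop("demographic shares must sum to 1")
  d <- demographics[groups]
  list(mean = drop(d %*% requirements$mean),
       fat_lower = sum(d * requirements$fat_lower[groups]),
       fat_upper = sum(d * requirements$fat_upper[groups]))
}

#' Classify nutrient sufficiency
#'
#' Non-banded nutrients are `sufficient` when intake meets or exceeds the
#' requirement (boundary inclusive) and `insufficient` otherwise. Banded
#' nutrients (fat by default) are `low` below the lower bound, `over`
#' above the upper bound and `healthy` in between. The margin is
#' intake/requirement (for banded nutrients, intake over the lower bound),
#' grading how far a country sits from the threshold.
#'
#' @param intake Named nutrient vector, per person per day.
#' @param requirement Output of [requirement_per_capita()].
#' @param country Country id recorded in the report.
#' @param banded Names of band-classified nutrients.
#' @return Data frame: country, nutrient, intake, requirement, status,
#'   margin.
#' @export
classify_sufficiency <- function(intake, requirement, country = NA_character_,
                                 banded = "fat") {
  nut <- names(intake)
  req <- requirement$mean[nut]
  status <- ifelse(intake >= req, "sufficient", "insufficient")
  margin <- ifelse(req > 0, intake / req, NA_real_)
  for (b in intersect(banded, nut)) {
    lo <- requirement$fat_lower
    hi <- requirement$fat_upper
    status[b] <- if (intake[b] < lo) "low"
                 else if (intake[b] > hi) "over" else "healthy"
    req[b] <- lo
    margin[b] <- if (lo > 0) intake[b] / lo else NA_real_
  }
  data.frame(country = country, nutrient = nut,
             intake = unname(intake), requirement = unname(req),
             status = unname(status), margin = unname(margin),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Full nutrition pipeline for every country
#'
#' Applies waste/edibility adjustment, fortification-aware composition,
#' per-capita intake and requirement weighting, and classification, for
#' every country's current-year food supply.
#'
#' @param world A `trade_world` with `current$food_supply` set.
#' @return List: `world` (intake and requirement matrices filled in) and
#'   `report` (long sufficiency data frame over all countries).
#' @export
compute_nutrition <- function(world) {
  n <- nrow(world$countries)
  nut <- nutrients()
  cm <- world$commodities

  # waste fractions per country x commodity via region and food type
  types <- world$group_map[cm$group]
  waste <- world$waste[world$countries$region, types, drop = FALSE]
  edible <- world$current$food_supply * (1 - waste) *
    rep(cm$edible_fraction, each = n)

  # intake: countries grouped by fortification variant share a composition
  intake <- matrix(0, n, length(nut),
                   dimnames = list(world$countries$id, nut))
  for (variant in unique(world$countries$fortification)) {
    rows <- which(world$countries$fortification == variant)
    comp <- world$composition$unrefined
    comp[cm$refinable, ] <- world$composition[[variant]][cm$refinable, ]
    intake[rows, ] <- edible[rows, , drop = FALSE] %*% comp
  }
  intake <- intake / (world$countries$population * 365)

  rq <- world$requirements
  groups <- rownames(rq$mean)
  d <- world$demographics[, groups, drop = FALSE]
  req <- d %*% rq$mean
  fat_lo <- drop(d %*% rq$fat_lower[groups])
  fat_hi <- drop(d %*% rq$fat_upper[groups])

  world$current$nutrient_intake <- intake
  world$current$nutrient_requirement <- req[, nut, drop = FALSE]

  # long report; fat classified against its band, the rest by threshold
  status <- ifelse(intake >= req, "sufficient", "insufficient")
  margin <- intake / req
  req_rep <- req
  status[, "fat"] <- ifelse(intake[, "fat"] < fat_lo, "low",
                            ifelse(intake[, "fat"] > fat_hi, "over",
                                   "healthy"))
  margin[, "fat"] <- intake[, "fat"] / fat_lo
  req_rep[, "fat"] <- fat_lo
  report <- data.frame(
    country = rep(world$countries$id, times = length(nut)),
    nutrient = rep(nut, each = n),
    intake = as.vector(intake), requirement = as.vector(req_rep),
    status = as.vector(status), margin = as.vector(margin),
    stringsAsFactors = FALSE)
  list(world = world, report = report)
}
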