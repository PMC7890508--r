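# The relation-driven trade engine: trade positions, priority scoring and
# ranking of partners, and the round-based offer/acceptance market per
# commodity with a per-round transaction cap and a saturation stopping
# rule.  Within a year, markets for different commodities are independent.

`%||%` <- function(a, b) if (is.null(a)) b else a

# min-max normalization over a candidate set; when all candidates are
# equal on an element the element is uninformative and maps to 1
minmax01 <- function(x) {
  r <- range(x)
  if (r[2] - r[1] <= 0) return(rep(1, length(x)))
  (x - r[1]) / (r[2] - r[1])
}

#' Trade priority scores over a candidate set
#'
#' The priority a country assigns to each candidate partner is the
#' weighted average of four elements, each min-max normalized over the
#' candidate set of the current ranking event: the candidate's GDP per
#' capita (ability to pay), its proximity (1 minus normalized distance),
#' the historic trade volume with it in the relevant role, and the
#' emergent trade volume accumulated with it during the run. Scores lie in
#' [0, 1]; a candidate set where all members tie on an element scores 1 on
#' that element.
#'
#' @param gdp_pc Candidate GDP per capita values.
#' @param dist_km Distance from the ranking country to each candidate, km.
#' @param hist Historic trade volume with each candidate (role-appropriate
#'   direction), tonnes.
#' @param emerg Emergent trade volume with each candidate, tonnes.
#' @param weights [priority_weights()].
#' @return Numeric vector of scores in [0, 1], one per candidate.
#' @export
priority_score <- function(gdp_pc, dist_km, hist, emerg, weights) {
  if (!length(gdp_pc)) stop("empty candidate set: no ranking event")
  g <- minmax01(gdp_pc)
  # distance enters inverted; a degenerate (all-equal) element maps to 1
  d <- if (diff(range(dist_km)) <= 0) rep(1, length(dist_km))
       else 1 - minmax01(dist_km)
  h <- minmax01(hist)
  e <- minmax01(emerg)
  unname((weights["gdp"] * g + weights["dist"] * d +
            weights["hist"] * h + weights["emerg"] * e) / sum(weights))
}

# internal scorer working off pre-extracted world vectors; returns the
# candidate ordering (ties broken by a seeded uniform draw)
rank_order <- function(actor, cand, gdp_pc, dist, hist_mat, emerg_mat,
                       weights) {
  s <- priority_score(gdp_pc[cand], dist[actor, cand],
                      hist_mat[actor, cand], emerg_mat[actor, cand],
                      weights)
  order(-s, stats::runif(length(cand)))
}

#' Rank candidate trade partners
#'
#' Orders candidates by descending trade priority from the actor's point
#' of view. An importer ranking exporters uses its import-side historic
#' and emergent volumes; an exporter ranking importers uses the
#' export-side volumes. Exact score ties are broken by a uniform draw from
#' the current RNG stream, so orderings are reproducible under a fixed
#' seed.
#'
#' @param world A `trade_world`.
#' @param actor Country index of the ranking country.
#' @param candidates Integer vector of candidate country indices.
#' @param role `"importer"` (actor buys, candidates sell) or `"exporter"`.
#' @param weights [priority_weights()].
#' @return `candidates` permuted into descending-priority order.
#' @export
rank_partners <- function(world, actor, candidates,
                          role = c("importer", "exporter"), weights) {
  role <- match.arg(role)
  gdp_pc <- world$countries$gdp / world$countries$population
  r <- world$relations
  if (role == "importer") {
    hist_mat <- r$historic_import; emerg_mat <- r$emergent_import
  } else {
    hist_mat <- r$historic_export; emerg_mat <- r$emergent_export
  }
  candidates[rank_order(actor, candidates, gdp_pc, r$distance, hist_mat,
                        emerg_mat, weights)]
}

#' Determine trade positions for the year
#'
#' From current-year production and the (rescaled) typical-diet target,
#' each country either offers its excess for export or seeks to import its
#' deficiency -- at most one of the two per commodity. The comparison is in
#' domestic-supply terms: the diet target (food tonnes) is converted to the
#' domestic supply that delivers it via the baseline food share.
#' Intermediary countries additionally demand their baseline re-export
#' volume, rescaled with global supply.
#'
#' @param world A `trade_world` with `current$production` set.
#' @param diet_target Country x commodity matrix of food tonnes targeted
#'   for consumption; defaults to the baseline typical diet.
#' @param supply_ratio Per-commodity rescaling of intermediary re-export
#'   demand (global current/baseline per-capita supply); defaults to 1.
#' @return The world with `current$import_needed_domestic`,
#'   `current$import_needed_intermediary` and `current$export_available`
#'   filled in.
#' @export
determine_positions <- function(world, diet_target = NULL,
                                supply_ratio = NULL) {
  cur <- world$current
  if (is.null(cur$production) || !all(is.finite(cur$production)))
    stop("current-year production is not set")
  b <- world$baseline
  if (is.null(diet_target)) diet_target <- b$typical_diet
  k <- nrow(world$commodities)
  if (is.null(supply_ratio)) supply_ratio <- rep(1, k)
  if (any(diet_target > 0 & b$pct_food <= 0))
    stop("configuration error: positive diet target with zero food share")
  ds_target <- ifelse(b$pct_food > 0, diet_target / b$pct_food, 0)
  cur$import_needed_domestic <- pmax(ds_target - cur$production, 0)
  cur$export_available <- pmax(cur$production - ds_target, 0)
  cur$import_needed_intermediary <-
    sweep(b$reexport, 2, supply_ratio, "*")
  world$current <- cur
  world
}

empty_transactions <- function() {
  data.frame(year = integer(0), commodity = character(0),
             importer = character(0), exporter = character(0),
             amount = numeric(0), round = integer(0),
             stringsAsFactors = FALSE)
}

#' Run the market for one commodity
#'
#' Round-based offer/acceptance matching. Each round, every importer with
#' remaining demand offers min(remaining demand, cap) to its top-ranked
#' exporter with remaining supply; each exporter then accepts the offers it
#' received in its own priority order until its supply is exhausted.
#' Realized amounts decrement both sides; intermediary imports are
#' re-offered as export supply in subsequent rounds of the same year. The
#' market closes when cumulative realized trade reaches saturation x
#' potential (potential = min of total demand and total supply at market
#' open, with the final transaction truncated at the target), when no
#' feasible offer remains, or at `max_rounds`.
#'
#' @param world A `trade_world` with positions determined.
#' @param commodity Commodity code or index.
#' @param params [market_params()].
#' @param weights [priority_weights()].
#' @param year Year label recorded on transactions.
#' @return List: `transactions` (data frame: year, commodity, importer,
#'   exporter, amount, round), `import_realized` and `export_realized`
#'   (per-country vectors, tonnes), `rounds`, `potential` (tonnes).
#' @export
run_commodity_market <- function(world, commodity, params = market_params(),
                                 weights = priority_weights(),
                                 year = NA_integer_) {
  c_ix <- if (is.character(commodity))
    match(commodity, world$commodities$code) else commodity
  if (is.na(c_ix)) stop("unknown commodity: ", commodity)
  code <- world$commodities$code[c_ix]
  cur <- world$current
  n <- nrow(world$countries)
  rem_dd <- cur$import_needed_domestic[, c_ix]
  rem_di <- cur$import_needed_intermediary[, c_ix]
  rem_sup <- cur$export_available[, c_ix]

  total_dem <- sum(rem_dd + rem_di)
  total_sup <- sum(rem_sup)
  potential <- min(total_dem, total_sup)
  out <- list(transactions = empty_transactions(),
              import_realized = numeric(n), export_realized = numeric(n),
              rounds = 0L, potential = potential)
  if (potential <= 0) return(out)

  target <- params$saturation * potential
  cap <- params$cap %||% (potential / 10)
  tiny <- 1e-9 * max(potential, 1)

  gdp_pc <- world$countries$gdp / world$countries$population
  rel <- world$relations
  imp_real <- exp_real <- numeric(n)
  realized <- 0
  round <- 0L
  tx_i <- integer(0); tx_j <- integer(0)
  tx_a <- numeric(0); tx_r <- integer(0)

  while (realized < target - tiny && round < params$max_rounds) {
    round <- round + 1L
    importers <- which(rem_dd + rem_di > tiny)
    exporters <- which(rem_sup > tiny)
    if (!length(importers) || !length(exporters)) break

    # phase 1: every importer posts one offer to its top-ranked exporter
    offer_from <- integer(0); offer_to <- integer(0); offer_amt <- numeric(0)
    for (i in importers) {
      cand <- exporters[exporters != i]
      if (!length(cand)) next
      top <- cand[rank_order(i, cand, gdp_pc, rel$distance,
                             rel$historic_import, rel$emergent_import,
                             weights)[1]]
      offer_from <- c(offer_from, i)
      offer_to <- c(offer_to, top)
      offer_amt <- c(offer_amt, min(rem_dd[i] + rem_di[i], cap))
    }
    if (!length(offer_from)) break

    # phase 2: exporters accept received offers in their own priority order
    progressed <- FALSE
    for (j in sort(unique(offer_to))) {
      if (rem_sup[j] <= tiny) next
      sel <- which(offer_to == j)
      buyers <- offer_from[sel]
      ord <- rank_order(j, buyers, gdp_pc, rel$distance,
                        rel$historic_export, rel$emergent_export, weights)
      for (b in ord) {
        i <- buyers[b]
        a <- min(offer_amt[sel[b]], rem_sup[j], target - realized)
        if (a <= tiny) next
        dom <- min(a, rem_dd[i])
        rem_dd[i] <- rem_dd[i] - dom
        int <- a - dom
        rem_di[i] <- rem_di[i] - int
        rem_sup[j] <- rem_sup[j] - a
        rem_sup[i] <- rem_sup[i] + int # intermediary stock re-offered
        imp_real[i] <- imp_real[i] + a
        exp_real[j] <- exp_real[j] + a
        realized <- realized + a
        tx_i <- c(tx_i, i); tx_j <- c(tx_j, j)
        tx_a <- c(tx_a, a); tx_r <- c(tx_r, round)
        progressed <- TRUE
        if (realized >= target - tiny) break
      }
      if (realized >= target - tiny) break
    }
    if (!progressed) break
  }
  if (round >= params$max_rounds && realized < target - tiny)
    warning(sprintf("market %s closed at max_rounds with feasible offers remaining", code))

  out$transactions <- data.frame(
    year = rep(as.integer(year), length(tx_a)),
    commodity = rep(code, length(tx_a)),
    importer = world$countries$id[tx_i],
    exporter = world$countries$id[tx_j],
    amount = tx_a, round = tx_r, stringsAsFactors = FALSE)
  out$import_realized <- imp_real
  out$export_realized <- exp_real
  out$rounds <- round
  out
}

#' Accumulate emergent trade relationships
#'
#' Every realized transaction strengthens the pair's emergent trade
#' volumes: the exporter's export-side volume towards the importer and the
#' importer's import-side volume towards the exporter each grow by the
#' transacted amount. Emergent volumes start at zero and never decrease,
#' giving repeated partners a growing rank advantage (path dependence).
#'
#' @param relations The `relations` component of a `trade_world`.
#' @param transactions Transaction data frame from the closed year.
#' @param ids Country id vector defining the matrix indexing.
#' @return Updated relations list.
#' @export
update_emergent <- function(relations, transactions, ids) {
  if (!nrow(transactions)) return(relations)
  i <- match(transactions$importer, ids)
  j <- match(transactions$exporter, ids)
  if (anyNA(i) || anyNA(j)) stop("transaction references unknown country id")
  for (t in seq_along(i)) {
    relations$emergent_import[i[t], j[t]] <-
      relations$emergent_import[i[t], j[t]] + transactions$amount[t]
    relations$emergent_export[j[t], i[t]] <-
      relations$emergent_export[j[t], i[t]] + transactions$amount[t]
  }
  relations
}
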