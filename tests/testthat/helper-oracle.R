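# Independent reference implementations used as oracles. They are written
# as plain, explicit per-agent loops -- deliberately naive -- and assume
# tie-free inputs (continuous random attributes), so they need no RNG.

# weighted-average priority of one candidate set, element by element
oracle_scores <- function(gdp_pc, dist_km, hist, emerg, w) {
  nc <- length(gdp_pc)
  norm_one <- function(x, i) {
    lo <- min(x); hi <- max(x)
    if (hi - lo <= 0) return(1)
    (x[i] - lo) / (hi - lo)
  }
  s <- numeric(nc)
  for (i in seq_len(nc)) {
    g <- norm_one(gdp_pc, i)
    d <- if (max(dist_km) - min(dist_km) <= 0) 1 else 1 - norm_one(dist_km, i)
    h <- norm_one(hist, i)
    e <- norm_one(emerg, i)
    s[i] <- (w[["gdp"]] * g + w[["dist"]] * d + w[["hist"]] * h +
               w[["emerg"]] * e) / (w[["gdp"]] + w[["dist"]] +
                                      w[["hist"]] + w[["emerg"]])
  }
  s
}

# brute-force enactment of the round-based market procedure for one
# commodity: importers post one offer each to their best-scoring exporter,
# exporters accept received offers best-first, the final transaction is
# truncated at saturation x potential; intermediary imports re-enter as
# supply
oracle_market <- function(world, c_ix = 1, weights = priority_weights(),
                          s = 1, cap = NULL, max_rounds = 1000) {
  n <- nrow(world$countries)
  dd <- world$current$import_needed_domestic[, c_ix]
  di <- world$current$import_needed_intermediary[, c_ix]
  su <- world$current$export_available[, c_ix]
  gdp_pc <- world$countries$gdp / world$countries$population
  rel <- world$relations
  pot <- min(sum(dd + di), sum(su))
  tx <- data.frame(importer = character(0), exporter = character(0),
                   amount = numeric(0), round = integer(0),
                   stringsAsFactors = FALSE)
  if (pot <= 0) return(tx)
  target <- s * pot
  if (is.null(cap)) cap <- pot / 10
  tiny <- 1e-9 * max(pot, 1)
  realized <- 0
  for (round in seq_len(max_rounds)) {
    if (realized >= target - tiny) break
    imps <- which(dd + di > tiny)
    exps <- which(su > tiny)
    if (length(imps) == 0 || length(exps) == 0) break
    # offers
    off <- list()
    for (i in imps) {
      cand <- exps[exps != i]
      if (length(cand) == 0) next
      sc <- oracle_scores(gdp_pc[cand], rel$distance[i, cand],
                          rel$historic_import[i, cand],
                          rel$emergent_import[i, cand], weights)
      best <- cand[which.max(sc)]
      off[[length(off) + 1]] <- list(from = i, to = best,
                                     amt = min(dd[i] + di[i], cap))
    }
    if (length(off) == 0) break
    to_vec <- vapply(off, function(o) o$to, numeric(1))
    moved <- FALSE
    for (j in sort(unique(to_vec))) {
      if (su[j] <= tiny) next
      mine <- off[to_vec == j]
      froms <- vapply(mine, function(o) o$from, numeric(1))
      sc <- oracle_scores(gdp_pc[froms], rel$distance[j, froms],
                          rel$historic_export[j, froms],
                          rel$emergent_export[j, froms], weights)
      for (b in order(-sc)) {
        i <- froms[b]
        a <- min(mine[[b]]$amt, su[j], target - realized)
        if (a <= tiny) next
        dom <- min(a, dd[i])
        dd[i] <- dd[i] - dom
        di[i] <- di[i] - (a - dom)
        su[j] <- su[j] - a
        su[i] <- su[i] + (a - dom)
        realized <- realized + a
        moved <- TRUE
        tx <- rbind(tx, data.frame(
          importer = world$countries$id[i],
          exporter = world$countries$id[j], amount = a, round = round,
          stringsAsFactors = FALSE))
        if (realized >= target - tiny) break
      }
      if (realized >= target - tiny) break
    }
    if (!moved) break
  }
  tx
}

# O(n^2) pairwise-domination check for the Pareto front
oracle_pareto <- function(points) {
  keep <- rep(TRUE, nrow(points))
  for (i in seq_len(nrow(points))) {
    for (j in seq_len(nrow(points))) {
      if (i == j) next
      vi <- points$volume_rate[i]; pi <- points$partner_rate[i]
      vj <- points$volume_rate[j]; pj <- points$partner_rate[j]
      if (vj >= vi && pj >= pi && (vj > vi || pj > pi)) {
        keep[i] <- FALSE
        break
      }
    }
  }
  points[keep, , drop = FALSE]
}

# plain haversine evaluated from the textbook formula
oracle_haversine_km <- function(lat1, lon1, lat2, lon2) {
  to_rad <- pi / 180
  p1 <- lat1 * to_rad; p2 <- lat2 * to_rad
  dphi <- (lat2 - lat1) * to_rad
  dlam <- (lon2 - lon1) * to_rad
  a <- sin(dphi / 2)^2 + cos(p1) * cos(p2) * sin(dlam / 2)^2
  2 * 6371 * asin(sqrt(a))
}
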