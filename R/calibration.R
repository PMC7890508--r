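# Calibration of the priority weights: Latin hypercube design over the
# three free weights (distance fixed at 1), exponential transform to the
# [0.05, 20] ratio scale, volume and partner match rates against observed
# trade, replicate averaging, Pareto front and equal-weight selection.

#' Latin hypercube sample
#'
#' Stratified design on the unit cube: per dimension, exactly one point
#' falls in each of the n equal-probability strata.
#'
#' @param n Number of points.
#' @param dims Number of dimensions.
#' @param seed RNG seed.
#' @return n x dims matrix of points in (0, 1).
#' @export
lhs_sample <- function(n, dims = 3, seed = 1L) {
  if (n < 1 || dims < 1) stop("n and dims must be >= 1")
  set.seed(seed)
  lhs::randomLHS(n, dims)
}

#' Exponential weight transform
#'
#' Maps a unit-interval design coordinate to a priority weight on the
#' ratio scale [0.05, 20]: w = 20^(2u - 1). The midpoint u = 0.5 maps to
#' 1, parity with the fixed distance weight; the endpoints are 1/20 and 20
#' times as important as distance.
#'
#' @param u Numeric in [0, 1].
#' @return Weight in [0.05, 20].
#' @examples
#' transform_weight(c(0, 0.5, 1))  # 0.05, 1, 20
#' @export
transform_weight <- function(u) {
  if (any(u < 0 | u > 1)) stop("input error: u must lie in [0, 1]")
  20^(2 * u - 1)
}

# align two volume records on the full observed key set
volume_key <- function(v) paste(v$country, v$flow, v$commodity, v$year,
                                sep = "\r")

#' Trade-volume match rate
#'
#' Fraction of observed per-country volume records (import, export and
#' food, per commodity and year) that the simulation reproduces within a
#' relative tolerance band: a record matches when |sim - obs| <= tol x obs
#' (boundary inclusive; an observed zero matches only an exact simulated
#' zero).
#'
#' @param simulated,observed Long volume data frames with columns country,
#'   flow, commodity, year, tonnes.
#' @param tol Relative half-width of the match band.
#' @return Match rate in [0, 1].
#' @export
volume_match_rate <- function(simulated, observed, tol = 0.20) {
  ks <- volume_key(simulated)
  ko <- volume_key(observed)
  pos <- match(ko, ks)
  if (anyNA(pos)) {
    missing <- unique(paste(observed$country, observed$flow,
                            observed$commodity, observed$year)[is.na(pos)])
    stop("input error: observed keys absent from simulation: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  sim <- simulated$tonnes[pos]
  obs <- observed$tonnes
  match_ok <- ifelse(obs == 0, sim == 0, abs(sim - obs) <= tol * obs)
  mean(match_ok)
}

#' Trade-partner match rate
#'
#' Fraction of observed bilateral trade records (commodity, importer,
#' exporter, year) that also occur in the simulation, regardless of
#' volume.
#'
#' @param simulated,observed Transaction data frames with columns year,
#'   commodity, importer, exporter.
#' @return Match rate in [0, 1]; 0 when the simulation has no
#'   transactions.
#' @export
partner_match_rate <- function(simulated, observed) {
  key <- function(t) unique(paste(t$commodity, t$importer, t$exporter,
                                  t$year, sep = "\r"))
  ko <- key(observed)
  if (!length(ko)) return(1)
  if (!nrow(simulated)) return(0)
  mean(ko %in% key(simulated))
}

#' Pareto front of calibration points
#'
#' Retains exactly the points not strictly dominated on the two match-rate
#' dimensions: a point is dominated when another point is at least as good
#' on both rates and strictly better on at least one.
#'
#' @param points Data frame with columns `volume_rate` and `partner_rate`.
#' @return The non-dominated subset (rows of `points`, original order).
#' @export
pareto_front <- function(points) {
  if (!nrow(points)) stop("input error: no calibration points")
  v <- points$volume_rate
  p <- points$partner_rate
  n <- length(v)
  dominated <- vapply(seq_len(n), function(i) {
    any(v >= v[i] & p >= p[i] & (v > v[i] | p > p[i]))
  }, logical(1))
  points[!dominated, , drop = FALSE]
}

#' Select the calibrated point from a Pareto front
#'
#' Values the two match-rate dimensions equally: picks the front point
#' with the highest mean of volume and partner rate. Ties are broken by
#' the higher partner rate, then lexicographically by weights.
#'
#' @param front Data frame as returned by [pareto_front()].
#' @return The selected row.
#' @export
select_calibrated <- function(front) {
  if (!nrow(front)) stop("input error: empty Pareto front")
  score <- (front$volume_rate + front$partner_rate) / 2
  o <- order(-score, -front$partner_rate,
             front$w_gdp %||% rep(0, nrow(front)),
             front$w_hist %||% rep(0, nrow(front)),
             front$w_emerg %||% rep(0, nrow(front)))
  front[o[1], , drop = FALSE]
}

#' Calibrate the priority weights against observed trade
#'
#' Draws `n_points` weight vectors from a three-dimensional Latin
#' hypercube (coordinates mapped through [transform_weight()]; distance
#' weight fixed at 1), simulates each over the observation horizon with
#' `n_replicates` seeds, averages the volume and partner match rates
#' across replicates, and returns all points together with the Pareto
#' front and the equal-weight selection.
#'
#' @param world A `trade_world` (calibration starts from this state).
#' @param observed An `observed_trade` record (see
#'   [generate_observations()]).
#' @param n_points Number of Latin hypercube design points.
#' @param n_replicates Simulation replicates per point.
#' @param params [market_params()] used for the calibration runs.
#' @param seed Master seed; design and every replicate seed derive from
#'   it.
#' @return List of class `calibration_result`: `points` (data frame:
#'   w_gdp, w_hist, w_emerg, volume_rate, partner_rate, n_replicates),
#'   `front`, `selected`.
#' @export
calibrate <- function(world, observed, n_points = 100, n_replicates = 5,
                      params = market_params(), seed = 1L) {
  stopifnot(inherits(observed, "observed_trade"))
  u <- lhs_sample(n_points, 3, seed = seed)
  w <- transform_weight(u)
  colnames(w) <- c("w_gdp", "w_hist", "w_emerg")
  years <- observed$years
  vol_rate <- part_rate <- numeric(n_points)
  for (p in seq_len(n_points)) {
    wt <- priority_weights(gdp = w[p, "w_gdp"], dist = 1,
                           hist = w[p, "w_hist"], emerg = w[p, "w_emerg"])
    vr <- pr <- numeric(n_replicates)
    for (r in seq_len(n_replicates)) {
      rep_seed <- (seed * 1000L + p * 131L + r * 7L) %% 2147483647L
      sim <- run_horizon(world, years, params = params, weights = wt,
                         seed = rep_seed, nutrition = FALSE)
      vr[r] <- volume_match_rate(sim$volumes, observed$volumes)
      pr[r] <- partner_match_rate(sim$transactions, observed$transactions)
    }
    vol_rate[p] <- mean(vr)
    part_rate[p] <- mean(pr)
  }
  points <- data.frame(w_gdp = w[, "w_gdp"], w_hist = w[, "w_hist"],
                       w_emerg = w[, "w_emerg"], volume_rate = vol_rate,
                       partner_rate = part_rate,
                       n_replicates = n_replicates)
  front <- pareto_front(points)
  structure(list(points = points, front = front,
                 selected = select_calibrated(front)),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> %d points, %d on the Pareto front\n",
              nrow(x$points), nrow(x$front)))
  s <- x$selected
  cat(sprintf("  selected: w_gdp=%.3f w_hist=%.3f w_emerg=%.3f (dist fixed at 1)\n",
              s$w_gdp, s$w_hist, s$w_emerg))
  cat(sprintf("  volume match %.3f, partner match %.3f\n",
              s$volume_rate, s$partner_rate))
  invisible(x)
}
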