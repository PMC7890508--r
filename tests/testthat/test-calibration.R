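test_that("Latin hypercube samples are stratified per dimension", {
  x <- lhs_sample(4, 1, seed = 3)
  expect_equal(sort(floor(x * 4)), 0:3)
  y <- lhs_sample(50, 3, seed = 5)
  expect_equal(dim(y), c(50, 3))
  for (d in 1:3) {
    counts <- tabulate(floor(y[, d] * 50) + 1, nbins = 50)
    expect_true(all(counts == 1))
  }
  # reproducible under seed
  expect_identical(lhs_sample(10, 2, seed = 8), lhs_sample(10, 2, seed = 8))
  expect_error(lhs_sample(0, 1), ">= 1")
})

test_that("the exponential transform spans 0.05 to 20 through 1", {
  expect_equal(transform_weight(0), 0.05)
  expect_equal(transform_weight(1), 20)
  expect_equal(transform_weight(0.5), 1)
  u <- seq(0, 1, by = 0.05)
  w <- transform_weight(u)
  expect_true(all(diff(w) > 0))
  expect_true(all(w >= 0.05 & w <= 20))
  expect_error(transform_weight(1.1), "input error")
  expect_error(transform_weight(-0.01), "input error")
})

test_that("volume match rate counts records inside the 20% band", {
  vol <- function(tonnes, country = paste0("C", seq_along(tonnes))) {
    data.frame(country = country, flow = "import", commodity = "K01",
               year = 2001L, tonnes = tonnes, stringsAsFactors = FALSE)
  }
  expect_equal(volume_match_rate(vol(c(10, 20)), vol(c(10, 20))), 1)
  # boundary inclusive at exactly +20%
  expect_equal(volume_match_rate(vol(12), vol(10)), 1)
  expect_equal(volume_match_rate(vol(12.01), vol(10)), 0)
  # ratios 1.0, 1.3, 0.85 -> 2 of 3 match
  expect_equal(volume_match_rate(vol(c(10, 13, 8.5)), vol(c(10, 10, 10))),
               2 / 3)
  # an observed zero matches only a simulated zero
  expect_equal(volume_match_rate(vol(c(0, 0.1)), vol(c(0, 0))), 0.5)
  # record order does not matter
  s <- vol(c(10, 13, 8.5)); o <- vol(c(10, 10, 10))
  expect_equal(volume_match_rate(s[3:1, ], o), volume_match_rate(s, o))
  # simultaneous rescaling leaves the rate unchanged
  s2 <- s; o2 <- o
  s2$tonnes <- s2$tonnes * 1e6; o2$tonnes <- o2$tonnes * 1e6
  expect_equal(volume_match_rate(s2, o2), volume_match_rate(s, o))
  o_bad <- vol(5, country = "C99")
  expect_error(volume_match_rate(s, o_bad), "C99")
})

test_that("partner match rate is key-set containment", {
  tx <- function(imp, exp) {
    data.frame(year = 2001L, commodity = "K01", importer = imp,
               exporter = exp, stringsAsFactors = FALSE)
  }
  expect_equal(partner_match_rate(tx(c("A", "C"), c("B", "D")),
                                  tx(c("A", "C"), c("B", "D"))), 1)
  none <- data.frame(year = integer(0), commodity = character(0),
                     importer = character(0), exporter = character(0),
                     stringsAsFactors = FALSE)
  expect_equal(partner_match_rate(none, tx("A", "B")), 0)
  expect_equal(partner_match_rate(tx(c("A", "E"), c("B", "F")),
                                  tx(c("A", "C"), c("B", "D"))), 0.5)
  # volume plays no role; duplicate records count once
  expect_equal(partner_match_rate(tx(c("A", "A"), c("B", "B")),
                                  tx("A", "B")), 1)
})

test_that("the Pareto front keeps exactly the non-dominated points", {
  pts <- data.frame(volume_rate = c(1, 0, 0.5),
                    partner_rate = c(0, 1, 0.5))
  expect_equal(nrow(pareto_front(pts)), 3)
  pts2 <- rbind(pts, data.frame(volume_rate = 0.4, partner_rate = 0.4))
  f <- pareto_front(pts2)
  expect_equal(nrow(f), 3)
  expect_false(any(f$volume_rate == 0.4 & f$partner_rate == 0.4))
  # 200 random points against the O(n^2) domination oracle
  set.seed(19)
  r <- data.frame(volume_rate = runif(200), partner_rate = runif(200),
                  w_gdp = runif(200), w_hist = runif(200),
                  w_emerg = runif(200))
  expect_identical(pareto_front(r), oracle_pareto(r))
  # order independence
  perm <- sample(200)
  f1 <- pareto_front(r)
  f2 <- pareto_front(r[perm, ])
  expect_setequal(rownames(f1), rownames(f2))
})

test_that("selection maximizes the mean rate with the decided tie rules", {
  f <- data.frame(volume_rate = c(0.9, 0.6), partner_rate = c(0.1, 0.6),
                  w_gdp = c(1, 2), w_hist = c(1, 2), w_emerg = c(1, 2))
  expect_equal(select_calibrated(f)$volume_rate, 0.6)
  expect_equal(select_calibrated(f[1, ])$volume_rate, 0.9)
  # equal means: the higher partner rate wins
  t1 <- data.frame(volume_rate = c(0.8, 0.4), partner_rate = c(0.2, 0.6),
                   w_gdp = c(1, 2), w_hist = c(1, 2), w_emerg = c(1, 2))
  expect_equal(select_calibrated(t1)$partner_rate, 0.6)
  expect_error(select_calibrated(f[0, ]), "empty")
})

test_that("calibration is reproducible and anchored by the truth", {
  w <- generate_world(world_gen_config(n_countries = 8, n_commodities = 2,
                                       seed = 7, trade_noise_sdlog = 2))
  tw <- priority_weights(gdp = 6, dist = 1, hist = 2, emerg = 0.3)
  obs <- generate_observations(w, tw, years = 2001:2002, saturation = 0.8,
                               noise = 0, seed = 5)
  p <- market_params(saturation = 0.8)
  cal <- calibrate(w, obs, n_points = 8, n_replicates = 2, params = p,
                   seed = 3)
  cal2 <- calibrate(w, obs, n_points = 8, n_replicates = 2, params = p,
                    seed = 3)
  expect_identical(cal$points, cal2$points)
  expect_true(all(cal$points$volume_rate >= 0 &
                    cal$points$volume_rate <= 1))
  expect_true(all(cal$points$w_gdp >= 0.05 & cal$points$w_gdp <= 20))
  # every selected point lies on the front, the front within the points
  expect_true(nrow(merge(cal$selected, cal$front)) >= 1)
  expect_true(nrow(merge(cal$front, cal$points)) == nrow(cal$front))

  # with noiseless observations the true weights reproduce the record
  # exactly, so the true point attains the maximal attainable mean rate
  sim_truth <- run_horizon(w, 2001:2002, params = p, weights = tw,
                           seed = 5, nutrition = FALSE)
  expect_equal(volume_match_rate(sim_truth$volumes, obs$volumes), 1)
  expect_equal(partner_match_rate(sim_truth$transactions,
                                  obs$transactions), 1)
  best_rate <- max((cal$points$volume_rate + cal$points$partner_rate) / 2)
  expect_lte(best_rate, 1)

  # a single-point design is its own front and selection
  cal1 <- calibrate(w, obs, n_points = 1, n_replicates = 1, params = p,
                    seed = 2)
  expect_equal(nrow(cal1$front), 1)
  expect_equal(cal1$selected$w_gdp, cal1$points$w_gdp)
})
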