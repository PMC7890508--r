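test_that("trade positions split into need, excess and intermediary demand", {
  w <- micro_world(2, production = matrix(c(100, 80), 2, 1),
                   typical_diet = matrix(c(100, 100), 2, 1))
  w <- determine_positions(w, diet_target = w$baseline$typical_diet)
  # production equal to target: no position at all
  expect_equal(w$current$import_needed_domestic[1, 1], 0)
  expect_equal(w$current$export_available[1, 1], 0)
  # production 80 vs target 100: import the deficiency
  expect_equal(w$current$import_needed_domestic[2, 1], 20)
  expect_equal(w$current$export_available[2, 1], 0)

  # intermediary: production 120, target 100, baseline re-export 30
  wi <- micro_world(2, production = matrix(c(120, 100), 2, 1),
                    typical_diet = matrix(c(100, 100), 2, 1),
                    reexport = matrix(c(30, 0), 2, 1))
  wi <- determine_positions(wi, diet_target = wi$baseline$typical_diet)
  expect_equal(wi$current$import_needed_domestic[1, 1], 0)
  expect_equal(wi$current$import_needed_intermediary[1, 1], 30)
  expect_equal(wi$current$export_available[1, 1], 20)
  # intermediary demand rescales with global supply
  wi2 <- determine_positions(wi, diet_target = wi$baseline$typical_diet,
                             supply_ratio = 0.5)
  expect_equal(wi2$current$import_needed_intermediary[1, 1], 15)

  # diet target in food tonnes is compared in domestic-supply terms
  wf <- micro_world(1, production = matrix(50, 1, 1),
                    typical_diet = matrix(80, 1, 1),
                    pct_food = matrix(0.8, 1, 1))
  wf <- determine_positions(wf, diet_target = wf$baseline$typical_diet)
  expect_equal(wf$current$import_needed_domestic[1, 1], 100 - 50)

  # at most one of need / excess positive, across random inputs
  set.seed(8)
  wr <- micro_world(10, production = matrix(runif(10, 0, 200), 10, 1),
                    typical_diet = matrix(runif(10, 0, 200), 10, 1))
  wr <- determine_positions(wr, diet_target = wr$baseline$typical_diet)
  expect_true(all(wr$current$import_needed_domestic *
                    wr$current$export_available == 0))
})

test_that("priority scores follow the weighted average of normalized elements", {
  # only distance matters: nearest candidate scores highest
  s <- priority_score(c(5, 3, 1), c(100, 900, 500), c(0, 0, 0), c(0, 0, 0),
                      priority_weights(0, 1, 0, 0))
  expect_equal(which.max(s), 1)
  expect_true(all(s >= 0 & s <= 1))
  # single candidate: every element degenerates to 1
  expect_equal(priority_score(4, 200, 10, 0, priority_weights(2, 1, 1, 1)),
               1)
  # hand-built elements against the independent arithmetic oracle,
  # at the shipped calibrated weights
  w5 <- priority_weights(1.40, 1, 1.40, 0.72)
  g <- c(30000, 4000, 12000)
  d <- c(800, 4000, 2500)
  h <- c(1e5, 3e4, 0)
  e <- c(0, 2e3, 5e2)
  expect_equal(priority_score(g, d, h, e, w5), oracle_scores(g, d, h, e, w5))
  # strict monotonicity in each element, candidate set held fixed
  base <- priority_score(g, d, h, e, w5)
  g2 <- g; g2[2] <- 40000
  expect_gt(priority_score(g2, d, h, e, w5)[2], base[2])
  d2 <- d; d2[3] <- 3900
  expect_lt(priority_score(g, d2, h, e, w5)[3], base[3])
  expect_error(priority_score(numeric(0), numeric(0), numeric(0),
                              numeric(0), w5), "empty candidate")
})

test_that("partner ranking is score-then-sort with seeded tie breaks", {
  w <- micro_world(4, gdp_pc = c(2, 5, 3, 1))
  # only GDP matters: order by GDP per capita
  set.seed(1)
  expect_equal(rank_partners(w, 1, c(2, 3, 4), "importer",
                             priority_weights(1, 0, 0, 0)),
               c(2, 3, 4))
  # all-equal candidates: a reproducible seeded permutation
  we <- micro_world(5, gdp_pc = rep(10, 5))
  set.seed(7)
  o1 <- rank_partners(we, 1, 2:5, "importer", priority_weights())
  set.seed(7)
  o2 <- rank_partners(we, 1, 2:5, "importer", priority_weights())
  expect_identical(o1, o2)
  expect_setequal(o1, 2:5)

  # mixed elements against the exhaustive score-then-sort oracle
  set.seed(33)
  for (i in 1:50) {
    n <- sample(2:7, 1)
    wr <- micro_world(n, gdp_pc = runif(n, 1e3, 1e5),
                      dist = {
                        d <- matrix(0, n, n)
                        d[upper.tri(d)] <- runif(n * (n - 1) / 2, 10, 2e4)
                        d + t(d)
                      },
                      hist_import = matrix(runif(n * n, 0, 1e5), n, n),
                      emergent_import = matrix(runif(n * n, 0, 1e3), n, n))
    actor <- 1
    cand <- 2:n
    wts <- priority_weights(runif(1, 0, 3), 1, runif(1, 0, 3),
                            runif(1, 0, 3))
    got <- rank_partners(wr, actor, cand, "importer", wts)
    sc <- oracle_scores(wr$countries$gdp[cand] /
                          wr$countries$population[cand],
                        wr$relations$distance[actor, cand],
                        wr$relations$historic_import[actor, cand],
                        wr$relations$emergent_import[actor, cand], wts)
    expect_identical(got, cand[order(-sc)])
  }
})

test_that("a two-country market clears in capped rounds", {
  w <- micro_world(2)
  w <- set_positions(w, dem_dom = c(10, 0), sup = c(0, 8))
  m <- run_commodity_market(w, 1, market_params(saturation = 1, cap = 5))
  expect_equal(m$transactions$amount, c(5, 3))
  expect_equal(m$transactions$round, c(1L, 2L))
  expect_equal(m$transactions$importer, c("C01", "C01"))
  expect_equal(m$transactions$exporter, c("C02", "C02"))
  expect_equal(sum(m$import_realized), 8)
  expect_equal(m$potential, 8)

  # half saturation stops the market at half the potential
  m2 <- run_commodity_market(w, 1, market_params(saturation = 0.5, cap = 5))
  expect_equal(sum(m2$transactions$amount), 4)

  # no importer with positive demand: empty market
  w0 <- set_positions(w, dem_dom = c(0, 0), sup = c(0, 8))
  m0 <- run_commodity_market(w0, 1, market_params())
  expect_equal(nrow(m0$transactions), 0)
})

test_that("markets conserve mass and never over-trade", {
  set.seed(91)
  for (i in 1:20) {
    n <- sample(3:8, 1)
    w <- random_positioned_world(n)
    s <- sample(c(0.6, 0.8, 1), 1)
    m <- run_commodity_market(w, 1, market_params(saturation = s))
    expect_equal(sum(m$import_realized), sum(m$export_realized))
    expect_equal(sum(m$transactions$amount), sum(m$import_realized))
    need <- w$current$import_needed_domestic[, 1] +
      w$current$import_needed_intermediary[, 1]
    expect_true(all(m$import_realized <= need + 1e-9))
    # exporters may re-offer intermediary stock, never more than received
    sup <- w$current$export_available[, 1] + m$import_realized
    expect_true(all(m$export_realized <= sup + 1e-9))
    expect_true(all(m$transactions$amount > 0))
  }
})

test_that("realized volume is monotone in saturation and clears at s = 1", {
  set.seed(14)
  w <- random_positioned_world(6)
  totals <- vapply(c(0.6, 0.8, 1), function(s) {
    set.seed(100)
    sum(run_commodity_market(w, 1,
                             market_params(saturation = s))$import_realized)
  }, numeric(1))
  expect_true(all(diff(totals) >= -1e-9))
  pot <- min(sum(w$current$import_needed_domestic[, 1] +
                   w$current$import_needed_intermediary[, 1]),
             sum(w$current$export_available[, 1]))
  expect_equal(totals[3], pot, tolerance = 1e-9)
  expect_equal(totals[1], 0.6 * pot, tolerance = 1e-6)
})

test_that("total cleared volume at s = 1 is insensitive to the round cap", {
  set.seed(27)
  w <- random_positioned_world(6)
  pot <- min(sum(w$current$import_needed_domestic[, 1] +
                   w$current$import_needed_intermediary[, 1]),
             sum(w$current$export_available[, 1]))
  out <- lapply(c(pot / 3, pot / 10, pot / 25), function(cap) {
    set.seed(5)
    run_commodity_market(w, 1, market_params(saturation = 1, cap = cap))
  })
  tot <- vapply(out, function(m) sum(m$import_realized), numeric(1))
  expect_equal(tot[1], tot[2], tolerance = 1e-9)
  expect_equal(tot[2], tot[3], tolerance = 1e-9)
  # only the round counts change
  expect_lt(out[[1]]$rounds, out[[3]]$rounds)
})

test_that("emergent volumes accumulate per transaction and raise future rank", {
  w <- micro_world(3)
  rel0 <- w$relations
  expect_identical(update_emergent(rel0, empty_tx <- data.frame(
    year = integer(0), commodity = character(0), importer = character(0),
    exporter = character(0), amount = numeric(0), round = integer(0)),
    w$countries$id), rel0)

  tx <- data.frame(year = 2001L, commodity = "K01", importer = "C01",
                   exporter = "C03", amount = 7, round = 1L,
                   stringsAsFactors = FALSE)
  rel1 <- update_emergent(rel0, tx, w$countries$id)
  expect_equal(rel1$emergent_import[1, 3], 7)
  expect_equal(rel1$emergent_export[3, 1], 7)
  expect_equal(sum(rel1$emergent_import), 7)
  expect_equal(sum(rel1$emergent_export), 7)

  # the traded pair ranks strictly higher afterwards than without the trade
  wts <- priority_weights(0.5, 1, 0.5, 2)
  w_with <- w; w_with$relations <- rel1
  s_with <- priority_score(
    w_with$countries$gdp[2:3] / w_with$countries$population[2:3],
    w_with$relations$distance[1, 2:3],
    w_with$relations$historic_import[1, 2:3],
    w_with$relations$emergent_import[1, 2:3], wts)
  s_without <- priority_score(
    w$countries$gdp[2:3] / w$countries$population[2:3],
    w$relations$distance[1, 2:3],
    w$relations$historic_import[1, 2:3],
    w$relations$emergent_import[1, 2:3], wts)
  expect_gt(s_with[2] - s_with[1], s_without[2] - s_without[1])
})
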