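test_that("cost_surface maps suitability to traversal cost", {
  s <- matrix(1, 3, 3)
  cs <- cost_surface(s, epsilon = 0.01)
  expect_equal(unique(as.numeric(cs$cost)), 0.01)
  s2 <- matrix(0.5, 3, 3); s2[2, ] <- 0
  cs2 <- cost_surface(s2)
  expect_equal(unique(cs2$cost[2, ]), 1)
  # monotone decreasing in suitability
  grid <- seq(0, 1, by = 0.05)
  costs <- vapply(grid, function(v) cost_surface(matrix(v, 1, 1))$cost[1, 1],
                  numeric(1))
  expect_true(all(diff(costs) <= 0))
  expect_error(cost_surface(matrix(NA_real_, 2, 2)), "all-land")
  # threshold masking
  cs3 <- cost_surface(s2, threshold = 0.2)
  expect_false(any(cs3$mask[2, ]))
})

test_that("least-cost distance: closed form on a uniform straight line", {
  s <- matrix(0.5, 1, 6)  # cost 0.5 everywhere
  cs <- cost_surface(s, cell_size_km = 50)
  d <- least_cost_distance(cs, c(1, 1), cbind(1, 6))
  expect_equal(unname(d), 0.5 * 5 * 50)
})

test_that("source on land errors; unreachable targets are infinite", {
  s <- matrix(0.5, 3, 3)
  s[, 2] <- NA  # land wall splits the grid
  cs <- cost_surface(s)
  expect_error(least_cost_distance(cs, c(1, 2)), "land")
  d <- least_cost_distance(cs, c(1, 1), cbind(c(3, 1), c(1, 3)))
  expect_true(is.finite(d[1]))
  expect_equal(unname(d[2]), Inf)
})

test_that("Dijkstra equals the exhaustive path oracle on random 4x4 grids", {
  set.seed(19)
  for (rep in 1:20) {
    cost <- matrix(runif(16, 0.05, 1), 4, 4)
    if (rep > 10) cost[sample(16, 3)] <- NA  # some land
    mask <- !is.na(cost)
    if (!mask[1, 1] || !mask[4, 4]) next
    cs <- structure(list(cost = cost, mask = mask, cell_size_km = 50),
                    class = "cost_surface")
    d <- least_cost_distance(cs, c(1, 1), cbind(4, 4))
    bf <- brute_force_lcp(cost, 50, c(1, 1), c(4, 4))
    expect_equal(unname(d), bf, tolerance = 1e-9)
  }
})

test_that("raising an off-path cost never decreases distances", {
  set.seed(20)
  cost <- matrix(runif(25, 0.1, 1), 5, 5)
  cs <- structure(list(cost = cost, mask = matrix(TRUE, 5, 5),
                       cell_size_km = 1), class = "cost_surface")
  d0 <- least_cost_distance(cs, c(1, 1))
  cost2 <- cost; cost2[3, 3] <- cost2[3, 3] + 5
  cs2 <- structure(list(cost = cost2, mask = cs$mask, cell_size_km = 1),
                   class = "cost_surface")
  d1 <- least_cost_distance(cs2, c(1, 1))
  expect_true(all(d1 >= d0 - 1e-12))
})

test_that("shortest sea distance: reduction, symmetry, detours", {
  mask <- matrix(TRUE, 4, 5)
  d <- shortest_sea_distance(mask, c(1, 1), cbind(1, 5), cell_size_km = 50)
  # unit-cost reduction: equals least_cost_distance on an all-ones surface
  cs <- structure(list(cost = matrix(1, 4, 5), mask = mask,
                       cell_size_km = 50), class = "cost_surface")
  expect_equal(d, least_cost_distance(cs, c(1, 1), cbind(1, 5)))
  expect_equal(unname(d), 4 * 50)
  # symmetry
  d_ab <- shortest_sea_distance(mask, c(1, 1), cbind(4, 5))
  d_ba <- shortest_sea_distance(mask, c(4, 5), cbind(1, 1))
  expect_equal(unname(d_ab), unname(d_ba))
  # a land barrier forces a detour longer than the unobstructed route
  wall <- mask; wall[1:3, 3] <- FALSE
  d_wall <- shortest_sea_distance(wall, c(1, 1), cbind(1, 5))
  expect_gt(d_wall, d[1])
})

test_that("least-cost distance obeys the sandwich bound", {
  set.seed(21)
  for (rep in 1:5) {
    suit <- matrix(runif(30), 5, 6)
    cs <- cost_surface(suit, epsilon = 0.01, cell_size_km = 10)
    unit <- shortest_sea_distance(cs$mask, c(1, 1), cell_size_km = 10)
    lcp <- least_cost_distance(cs, c(1, 1))
    expect_true(all(lcp <= unit * max(cs$cost[cs$mask]) + 1e-9))
    expect_true(all(lcp >= unit * 0.01 - 1e-9))
  }
})

test_that("proportion-distance GLM: null and parameter recovery", {
  set.seed(22)
  # null: proportions independent of distance
  d <- seq(50, 1000, length.out = 20)
  n <- rep(200, 20)
  y_null <- rbinom(20, n, 0.4)
  f0 <- proportion_distance_glm(y_null, n - y_null, d)
  expect_lt(abs(f0$slope), 0.002)
  expect_lt(f0$r2, 0.15)
  # truth logit(pi) = 2 - 0.04 d, range chosen to span the logistic
  d2 <- seq(5, 150, length.out = 20)
  pi2 <- stats::plogis(2 - 0.04 * d2)
  y2 <- rbinom(20, 200, pi2)
  f2 <- proportion_distance_glm(y2, 200 - y2, d2)
  expect_lt(abs(f2$slope - (-0.04)) / 0.04, 0.2)
  expect_lt(abs(f2$intercept - 2) / 2, 0.2)
  expect_true(f2$r2 >= 0 && f2$r2 <= 1)
  expect_lt(f2$p_value, 0.001)
  expect_error(proportion_distance_glm(c(1, 2), c(1, 2), c(1, 2)), "strata")
})

test_that("complete separation falls back to a penalised fit", {
  d <- c(10, 20, 30, 200, 210, 220)
  y <- c(50, 50, 50, 0, 0, 0)
  expect_warning(f <- proportion_distance_glm(y, 50 - y, d), "separation")
  expect_true(f$separation)
  expect_lt(f$slope, 0)
  expect_true(is.finite(f$z))
})

test_that("compare_distance_models ranks the generating predictor first", {
  set.seed(23)
  d_true <- seq(20, 180, length.out = 15)
  y <- rbinom(15, 300, stats::plogis(2.5 - 0.04 * d_true))
  noisy <- d_true * 0.5 + rnorm(15, sd = 40)
  tab <- compare_distance_models(y, 300 - y,
                                 list(truth = d_true, noisy = noisy,
                                      dup = d_true))
  expect_true(tab$model[1] %in% c("truth", "dup"))
  expect_equal(tab$r2[tab$model == "truth"], tab$r2[tab$model == "dup"])
  # unit change rescales the slope but not R^2 or the ranking
  tab_m <- compare_distance_models(y, 300 - y,
                                   list(truth = d_true * 1000, noisy = noisy))
  expect_equal(tab_m$r2[tab_m$model == "truth"],
               tab$r2[tab$model == "truth"], tolerance = 1e-9)
})

test_that("regime detection: constant series, step series, segment means", {
  expect_equal(regime_shift_detect(rep(1, 20))$change_points, numeric(0))
  set.seed(24)
  x <- c(rnorm(14, 0, 0.5), rnorm(16, 5, 0.5))
  seg <- regime_shift_detect(x, years = 1:30, cutoff_years = 5,
                             significance = 0.1)
  expect_equal(seg$change_points, 15)
  # regime means are the segment means of the confirmed partition
  expect_equal(seg$regimes$mean, c(mean(x[1:14]), mean(x[15:30])))
  expect_error(regime_shift_detect(rnorm(8), cutoff_years = 5), "shorter")
})

test_that("mean_suitability_series averages sea cells then logs", {
  mask <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)
  l1 <- matrix(c(0.2, 0.4, 0.6, NA), 2, 2)
  gs <- grid_series(2000, list(l1), mask)
  ms <- mean_suitability_series(gs)
  expect_equal(ms$value, log(mean(c(0.2, 0.4, 0.6))))
  const <- grid_series(2000:2001, list(matrix(0.5, 2, 2), matrix(1, 2, 2)),
                       matrix(TRUE, 2, 2))
  msc <- mean_suitability_series(const)
  expect_equal(msc$value, c(log(0.5), log(1)))
  expect_equal(diff(msc$value), log(2))  # doubling shifts by log 2
  raw <- mean_suitability_series(const, transform = "identity")
  expect_equal(raw$value, c(0.5, 1))
})
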