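test_that("generators are pure functions of their seeds", {
  b1 <- gen_baselines(seed = 5); b2 <- gen_baselines(seed = 5)
  expect_identical(b1, b2)
  m1 <- gen_mixture_series(b1$freqs, seed = 6)
  m2 <- gen_mixture_series(b1$freqs, seed = 6)
  expect_identical(m1, m2)
  e1 <- gen_environment(seed = 7); e2 <- gen_environment(seed = 7)
  expect_identical(e1, e2)
  o1 <- gen_occurrences(e1, seed = 8); o2 <- gen_occurrences(e1, seed = 8)
  expect_identical(o1, o2)
  expect_false(identical(gen_baselines(seed = 5)$freqs,
                         gen_baselines(seed = 6)$freqs))
})

test_that("gen_baselines hits the target differentiation and validates fct", {
  b <- gen_baselines(fct = 0.1, n_loci = 200, n_per_pop = 60, seed = 9)
  bf <- allele_frequencies(b$table)
  groups <- as.list(setNames(bf$populations, bf$populations))
  realized <- mean(fct_rank_loci(bf, groups)$fct)
  expect_lt(abs(realized - 0.1) / 0.1, 0.30)
  expect_error(gen_baselines(fct = 0), "fct")
  expect_error(gen_baselines(fct = 0.6), "fct")
  expect_true(all(b$freqs > 0 & b$freqs < 1))
})

test_that("divergence controls assignment difficulty", {
  # near-zero divergence: held-out accuracy near chance (self-assignment
  # would be inflated by training bias)
  lo <- gen_baselines(fct = 0.001, n_loci = 81, n_per_pop = 30, seed = 10)
  bf <- allele_frequencies(lo$table)
  held <- gen_mixture_series(lo$freqs, sample_years = c(2000, 2001),
                             N_per_year = 100, sigma = 0, seed = 10)
  ll <- codmix:::.rm_loglik_matrix(held$mixed$calls, bf)
  acc_lo <- mean(bf$populations[max.col(ll)] == held$metadata$true_origin)
  expect_lt(acc_lo, 0.5)
  expect_gt(acc_lo, 0.15)
  # strong divergence: near-perfect self-assignment
  hi <- gen_baselines(fct = 0.2, n_loci = 81, n_per_pop = 30, seed = 10)
  bfh <- allele_frequencies(hi$table)
  llh <- codmix:::.rm_loglik_matrix(hi$table$calls, bfh)
  expect_gte(mean(bfh$populations[max.col(llh)] == hi$table$group_labels),
             0.99)
})

test_that("gen_mixture_series: degenerate sigma and law of large numbers", {
  b <- gen_baselines(seed = 11)
  m0 <- gen_mixture_series(b$freqs, sigma = 0, alpha0 = c(1, 0, -1),
                           N_per_year = 50, seed = 11)
  expect_true(all(apply(m0$truth$p_path, 2, function(col)
    max(col) - min(col)) < 1e-12))
  # empirical origin fractions approach p_t for large N
  mbig <- gen_mixture_series(b$freqs, sample_years = c(2000, 2010),
                             N_per_year = 5000, sigma = 0.3, seed = 12)
  emp <- prop.table(table(factor(mbig$metadata$true_origin,
                                 levels = mbig$truth$populations),
                          mbig$metadata$year), margin = 2)
  expect_lt(max(abs(emp[, 1] - mbig$truth$p_path[1, ])), 0.03)
  expect_lt(max(abs(emp[, 2] - mbig$truth$p_path[2, ])), 0.03)
})

test_that("generated mixtures satisfy downstream type invariants", {
  b <- gen_baselines(seed = 13, n_per_pop = 20)
  m <- gen_mixture_series(b$freqs, N_per_year = 30, seed = 13)
  expect_s3_class(m$mixed, "genotype_table")
  expect_true(all(m$mixed$calls %in% 0:2))
  expect_equal(nrow(m$metadata), nrow(m$mixed$calls))
  expect_equal(rowSums(m$truth$p_path), rep(1, 9), tolerance = 1e-12)
})

test_that("gen_life_table shapes are plausible and degenerate cases error", {
  lt <- gen_life_table()
  expect_true(all(diff(lt$weight) > 0))
  expect_true(all(diff(lt$maturity) > 0))
  # default table supports a wide range of replacement targets
  s0 <- ssb_per_recruit(0, normalize_selectivity(lt))
  for (frac in c(0.1, 0.5, 0.9)) {
    feq <- solve_feq(frac * s0, lt)
    expect_gt(feq, 0); expect_lt(feq, 2)
  }
  # maturity midpoint beyond max age: stock cannot replace itself
  barren <- gen_life_table(mat_a50 = 40)
  expect_error(solve_feq(5.56, barren), "cannot replace")
})

test_that("gen_environment builds regimes, coast and entry point", {
  env <- gen_environment(noise_sd = 0, seed = 14)
  ms <- vapply(env$grids$layers, function(m) mean(m[env$mask]), numeric(1))
  expect_equal(length(unique(round(ms, 9))), 2)  # two-level step function
  expect_true(env$mask[env$entry_cell[1], env$entry_cell[2]])
  # land along the eastern margin, sea in the west
  expect_true(all(env$mask[, 1]))
  expect_true(any(!env$mask))
  # warm years warmer than cold years
  warm <- env$grids$years %in% env$warm_years
  expect_gt(min(ms[warm]), max(ms[!warm]))
})

test_that("gen_occurrences: flat response gives 0.5 prevalence, sharp is separable", {
  env <- gen_environment(seed = 15)
  flat <- gen_occurrences(env, intercept = 0, slope = 0, n_records = 1500,
                          seed = 15)
  expect_equal(mean(flat$presence), 0.5, tolerance = 0.05)
  sharp <- gen_occurrences(env, truth = list(p = list(opt = 2, breadth = 0.4)),
                           intercept = 4, slope = 4, n_records = 1500,
                           seed = 16)
  score <- thermal_suitability(sharp$temperature, 2, 0.4)
  expect_gt(auc(score, sharp$presence), 0.8)
  expect_error(gen_occurrences(env, n_records = 0), "positive")
})

test_that("latitudinal_strata partitions the sea north to south", {
  env <- gen_environment(seed = 17)
  st <- latitudinal_strata(env$mask)
  expect_equal(nrow(st), sum(env$mask))
  expect_setequal(unique(st$stratum), c("1A", "1B", "1C", "1D", "1E", "1F"))
  # strata ordered by latitude band
  expect_lt(max(st$row[st$stratum == "1A"]), min(st$row[st$stratum == "1F"]))
})
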