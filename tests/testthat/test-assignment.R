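test_that("allele_frequencies counts reference copies and typed gene copies", {
  calls <- rbind(c(2L, 1L), c(2L, NA))
  gt <- genotype_table(calls, c("a", "b"), c("L1", "L2"),
                       group_labels = c("A", "A"))
  bf <- allele_frequencies(gt)
  expect_equal(unname(bf$x[, "A"]), c(4, 1))
  expect_equal(unname(bf$n[, "A"]), c(4, 2))
})

test_that("allele_frequencies matches a brute-force per-genotype tally", {
  set.seed(11)
  calls <- matrix(sample(c(0:2, NA), 15, replace = TRUE), 5, 3)
  labs <- c("A", "A", "B", "B", "B")
  gt <- genotype_table(calls, paste0("i", 1:5), paste0("L", 1:3), labs)
  bf <- allele_frequencies(gt)
  for (p in c("A", "B")) for (l in 1:3) {
    g <- calls[labs == p, l]
    x <- 0; n <- 0
    for (v in g) if (!is.na(v)) { x <- x + v; n <- n + 2 }
    expect_equal(unname(bf$x[l, p]), x)
    expect_equal(unname(bf$n[l, p]), n)
  }
})

test_that("F_CT ranking: fixed difference 1, identical 0, known ordering", {
  mk <- function(freqs, n = 100) {
    # build a baseline_frequencies object directly from group frequencies
    L <- nrow(freqs)
    structure(list(populations = colnames(freqs),
                   loci = paste0("L", seq_len(L)),
                   x = freqs * n, n = matrix(n, L, ncol(freqs),
                                             dimnames = dimnames(freqs))),
              class = "baseline_frequencies")
  }
  freqs <- cbind(A = c(1, 0.5, 0.9, 0.6, 0.5),
                 B = c(0, 0.5, 0.1, 0.4, 0.5))
  bf <- mk(freqs)
  r <- fct_rank_loci(bf, groups = list(g1 = "A", g2 = "B"))
  expect_equal(r$fct[r$locus == "L1"], 1)
  expect_equal(r$fct[r$locus == "L2"], 0)
  # freqs (0.9,0.1) > (0.6,0.4) > (0.5,0.5)
  expect_equal(r$locus[1:2], c("L1", "L3"))
  expect_equal(utils::tail(r$locus, 2), c("L2", "L5")) # both zero, name order
  expect_equal(fct_rank_loci(bf, list(g1 = "A", g2 = "B"), top_k = 2)$locus,
               c("L1", "L3"))
})

test_that("single-locus genotype probabilities form an exact distribution", {
  # prior-only case: P(hom)=0.375, P(het)=0.25
  lp <- codmix:::.rm_locus_logprobs(0, 0)
  expect_equal(as.numeric(exp(lp)), c(0.375, 0.25, 0.375))
  # fixed-reference limit: P(dosage 2) -> 1 as n grows
  n <- c(10, 100, 1e4)
  p2 <- exp(codmix:::.rm_locus_logprobs(n, n)[3, ])
  expect_equal(p2, (n + 0.5) * (n + 1.5) / ((n + 1) * (n + 2)))
  expect_true(all(diff(p2) > 0) && p2[3] > 0.9997)
  # sums to 1 over the three genotypes for random (x, n)
  set.seed(2)
  nn <- sample(1:200, 200, replace = TRUE)
  xx <- vapply(nn, function(n) sample(0:n, 1), numeric(1))
  expect_equal(colSums(exp(codmix:::.rm_locus_logprobs(xx, nn))),
               rep(1, 200))
})

test_that("genotype probability matches the Beta-posterior quadrature oracle", {
  x <- 7; n <- 20
  for (dosage in 0:2) {
    dens <- function(th) {
      g <- switch(dosage + 1, (1 - th)^2, 2 * th * (1 - th), th^2)
      g * stats::dbeta(th, x + 0.5, n - x + 0.5)
    }
    num <- stats::integrate(dens, 0, 1, rel.tol = 1e-10)$value
    expect_equal(exp(codmix:::.rm_locus_logprobs(x, n)[dosage + 1, ]), num,
                 tolerance = 1e-8)
  }
})

test_that("bayes_assign is symmetric, decisive on fixed differences, and invariant", {
  # two identical baselines -> (0.5, 0.5)
  calls <- matrix(rep(c(0L, 1L, 2L, 1L), 2), 4, 2)
  gt <- genotype_table(calls, paste0("i", 1:4), c("L1", "L2"),
                       c("A", "A", "B", "B"))
  gt$calls[3:4, ] <- gt$calls[1:2, ]
  bf <- allele_frequencies(gt)
  post <- bayes_assign(c(L1 = 1L, L2 = 2L), bf)
  expect_equal(unname(post), c(0.5, 0.5))

  # 10 fixed-difference loci -> posterior > 0.999 for the matching population
  L <- 10
  callsA <- matrix(2L, 20, L); callsB <- matrix(0L, 20, L)
  gt2 <- genotype_table(rbind(callsA, callsB), paste0("i", 1:40),
                        paste0("L", 1:L), rep(c("A", "B"), each = 20))
  bf2 <- allele_frequencies(gt2)
  g <- setNames(rep(2L, L), paste0("L", 1:L))
  p2 <- bayes_assign(g, bf2)
  expect_gt(p2[["A"]], 0.999)
  expect_equal(sum(p2), 1)

  # locus-order invariance and uninformative-locus invariance
  b <- tiny_baseline(seed = 5)
  bf3 <- allele_frequencies(b$table)
  g3 <- b$table$calls[1, ]
  perm <- sample(length(g3))
  expect_equal(bayes_assign(g3[perm], bf3), bayes_assign(g3, bf3))
  bf4 <- bf3
  bf4$loci <- c(bf3$loci, "Lsame")
  bf4$x <- rbind(bf3$x, Lsame = c(10, 10))
  bf4$n <- rbind(bf3$n, Lsame = c(20, 20))
  g4 <- c(g3, Lsame = 1L)
  expect_equal(unname(bayes_assign(g4, bf4)), unname(bayes_assign(g3, bf3)))
})

test_that("mc_exclusion_test bounds, tails and error handling", {
  b <- tiny_baseline(seed = 7, n_loci = 20)
  bf <- allele_frequencies(b$table)
  g <- b$table$calls[1, ]
  res <- mc_exclusion_test(g, bf, n_sim = 200, seed = 42)
  expect_true(all(res$p_values >= 1 / 201 & res$p_values <= 1))

  # all-alternate genotype vs a baseline nearly fixed for reference
  calls <- matrix(2L, 30, 15)
  calls[1, ] <- 1L  # keep one heterozygote so loci are not fully fixed
  gt <- genotype_table(calls, paste0("i", 1:30), paste0("L", 1:15), rep("A", 30))
  bfA <- allele_frequencies(gt)
  worst <- setNames(rep(0L, 15), paste0("L", 1:15))
  res2 <- mc_exclusion_test(worst, bfA, n_sim = 1000, seed = 1)
  expect_lt(res2$p_values[["A"]], 0.01)
  expect_true(res2$excluded[["A"]])

  expect_error(mc_exclusion_test(g, bf, n_sim = 50), "n_sim")
  empty <- setNames(rep(NA_integer_, length(g)), names(g))
  expect_error(mc_exclusion_test(empty, bf, n_sim = 200), "zero loci")
})

test_that("consensus_assign applies the strict dual threshold", {
  bayes <- c(A = 0.95, B = 0.03, C = 0.01, D = 0.01)
  dapc <- c(A = 0.92, B = 0.05, C = 0.02, D = 0.01)
  expect_equal(consensus_assign(bayes, dapc), "A")
  dapc_b <- c(A = 0.02, B = 0.95, C = 0.02, D = 0.01)
  expect_equal(consensus_assign(bayes, dapc_b), "DISCARDED")
  expect_equal(consensus_assign(replace(bayes, 1, 0.89), dapc), "DISCARDED")
  expect_equal(consensus_assign(c(A = 0.90, B = 0.1, C = 0, D = 0),
                                c(A = 0.99, B = 0.01, C = 0, D = 0)),
               "DISCARDED")  # strict >
})

test_that("tabulate_composition counts retained individuals per stratum", {
  asg <- data.frame(id = sprintf("i%02d", 1:10),
                    consensus = c(rep("A", 5), rep("B", 3),
                                  rep("DISCARDED", 2)))
  attr(asg, "populations") <- c("A", "B")
  meta <- data.frame(id = asg$id,
                     year = rep(c(1950, 1960), each = 5),
                     stratum = rep(c("1A", "1B"), 5))
  out <- tabulate_composition(asg, meta)
  expect_equal(sum(out$counts$N), 8)
  expect_equal(out$retention, 0.8)
  # no empty strata rows
  expect_true(all(out$counts$N > 0))
  expect_error(tabulate_composition(asg, meta[-1, ]), "missing")
})
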