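# Genetic stock identification against baseline spawning populations.
#
# Two routes: (1) a Bayesian compound-Dirichlet genotype likelihood
# (Rannala & Mountain) with a Monte-Carlo exclusion test, and (2) DAPC
# (see dapc.R). Individuals are kept only when both methods agree with
# posterior > 0.90 for the same population.

#' Baseline allele counts per population
#'
#' For each locus and population: `x` = reference-allele count among typed
#' individuals, `n` = 2 x number of typed individuals.
#'
#' @param baseline a [genotype_table()] with group labels
#' @return object of class `baseline_frequencies`: list with `populations`,
#'   `loci`, and matrices `x`, `n` (loci x populations)
#' @export
allele_frequencies <- function(baseline) {
  stopifnot(inherits(baseline, "genotype_table"))
  if (is.null(baseline$group_labels))
    .stop_fmt("baseline table must carry group labels")
  pops <- unique(baseline$group_labels)
  L <- length(baseline$locus_ids)
  x <- n <- matrix(0, L, length(pops),
                   dimnames = list(baseline$locus_ids, pops))
  for (j in seq_along(pops)) {
    sub <- baseline$calls[baseline$group_labels == pops[j], , drop = FALSE]
    x[, j] <- colSums(sub, na.rm = TRUE)
    n[, j] <- 2 * colSums(!is.na(sub))
    if (all(n[, j] == 0))
      .stop_fmt("population %s has no typed individuals at any locus", pops[j])
  }
  structure(list(populations = pops, loci = baseline$locus_ids, x = x, n = n),
            class = "baseline_frequencies")
}

#' Rank loci by among-group fixation index F_CT
#'
#' Among-group differentiation per locus: the gene-copy-weighted variance
#' of group allele frequencies divided by p(1-p) at the pooled frequency.
#' Monomorphic loci get F_CT = 0.
#'
#' @param baseline a `baseline_frequencies` object
#' @param groups named list partitioning the populations into >= 2 groups
#' @param top_k optionally return only the k highest-ranked loci
#' @return data.frame (locus, fct), sorted by decreasing F_CT
#' @export
fct_rank_loci <- function(baseline, groups, top_k = NULL) {
  stopifnot(inherits(baseline, "baseline_frequencies"))
  if (length(groups) < 2L) .stop_fmt("need at least two groups")
  all_pops <- unlist(groups)
  if (!all(all_pops %in% baseline$populations))
    .stop_fmt("unknown population in groups: %s",
              setdiff(all_pops, baseline$populations)[1L])
  gx <- sapply(groups, function(g)
    rowSums(baseline$x[, g, drop = FALSE]))
  gn <- sapply(groups, function(g)
    rowSums(baseline$n[, g, drop = FALSE]))
  p <- gx / gn
  w <- gn / rowSums(gn)
  pbar <- rowSums(w * p)
  denom <- pbar * (1 - pbar)
  fct <- rowSums(w * (p - pbar)^2) / denom
  fct[!is.finite(fct)] <- 0
  out <- data.frame(locus = baseline$loci, fct = fct)
  out <- out[order(-out$fct, out$locus), ]
  rownames(out) <- NULL
  if (!is.null(top_k)) out <- utils::head(out, top_k)
  out
}

# Per-locus log-probabilities of dosages 0/1/2 under the compound-Dirichlet
# posterior predictive with a symmetric Dirichlet(1/2, 1/2) prior:
#   c_ref = x + 1/2, c_alt = n - x + 1/2, C = n + 1
#   P(hom ref) = c_ref (c_ref + 1) / (C (C + 1))
#   P(het)     = 2 c_ref c_alt / (C (C + 1))
#   P(hom alt) = c_alt (c_alt + 1) / (C (C + 1))
# Returns a 3 x L matrix of logs (rows: dosage 0, 1, 2).
.rm_locus_logprobs <- function(x, n) {
  cr <- x + 0.5
  ca <- n - x + 0.5
  C <- n + 1
  d <- C * (C + 1)
  rbind(log(ca * (ca + 1) / d),
        log(2 * cr * ca / d),
        log(cr * (cr + 1) / d))
}

#' Rannala-Mountain genotype log-likelihood
#'
#' Log-probability of a multilocus genotype under one baseline population's
#' compound-Dirichlet genotype distribution; missing loci are skipped.
#'
#' @param genotype named (or baseline-ordered) vector of dosages in
#'   \{0,1,2\}, NA for missing
#' @param baseline a `baseline_frequencies` object
#' @param population population label (or index) within the baseline
#' @return scalar log-likelihood
#' @export
rm_genotype_loglik <- function(genotype, baseline, population) {
  stopifnot(inherits(baseline, "baseline_frequencies"))
  g <- .match_loci(genotype, baseline$loci)
  typed <- which(!is.na(g))
  if (!length(typed)) .stop_fmt("individual typed at zero loci")
  lp <- .rm_locus_logprobs(baseline$x[typed, population],
                           baseline$n[typed, population])
  sum(lp[cbind(g[typed] + 1L, seq_along(typed))])
}

.match_loci <- function(genotype, loci) {
  if (!is.null(names(genotype))) {
    extra <- setdiff(names(genotype), loci)
    if (length(extra))
      .stop_fmt("genotype locus %s not in baseline", extra[1L])
    g <- rep(NA_integer_, length(loci))
    names(g) <- loci
    g[names(genotype)] <- as.integer(genotype)
    g
  } else {
    if (length(genotype) != length(loci))
      .stop_fmt("unnamed genotype must match baseline locus count")
    as.integer(genotype)
  }
}

#' Bayesian assignment posterior over baseline populations
#'
#' Equal prior over populations; posteriors are softmax of the per-population
#' genotype log-likelihoods, computed with max-subtraction for stability.
#'
#' @inheritParams rm_genotype_loglik
#' @return named length-K simplex vector
#' @export
bayes_assign <- function(genotype, baseline) {
  ll <- vapply(baseline$populations,
               function(p) rm_genotype_loglik(genotype, baseline, p),
               numeric(1))
  w <- exp(ll - max(ll))
  w / sum(w)
}

# Vectorised per-population log-likelihoods for a whole genotype matrix
# (individuals x loci, aligned to baseline loci). Used by the batch
# assignment path and the exclusion test.
.rm_loglik_matrix <- function(calls, baseline) {
  K <- length(baseline$populations)
  out <- matrix(0, nrow(calls), K,
                dimnames = list(rownames(calls), baseline$populations))
  for (k in seq_len(K)) {
    lp <- .rm_locus_logprobs(baseline$x[, k], baseline$n[, k])  # 3 x L
    ll <- numeric(nrow(calls))
    for (d in 0:2) {
      idx <- calls == d
      idx[is.na(idx)] <- FALSE
      ll <- ll + (idx %*% lp[d + 1L, ])[, 1L]
    }
    out[, k] <- ll
  }
  out
}

#' Monte-Carlo exclusion test
#'
#' For each population, simulates `n_sim` individuals by drawing two alleles
#' per typed locus from the posterior-mean allele frequencies, and compares
#' the observed genotype log-likelihood with the simulated distribution.
#' The p-value uses the +1 correction: p = (1 + #\{sim <= obs\}) / (n_sim + 1).
#'
#' @inheritParams rm_genotype_loglik
#' @param n_sim number of simulated individuals per population (>= 100)
#' @param alpha exclusion significance level
#' @param seed optional integer seed
#' @return list with `p_values` (named length-K) and `excluded` (logical)
#' @export
mc_exclusion_test <- function(genotype, baseline, n_sim = 10000,
                              alpha = 0.01, seed = NULL) {
  if (n_sim < 100) .stop_fmt("n_sim must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  g <- .match_loci(genotype, baseline$loci)
  typed <- which(!is.na(g))
  if (!length(typed)) .stop_fmt("individual typed at zero loci")
  K <- length(baseline$populations)
  p_values <- setNames(numeric(K), baseline$populations)
  for (k in seq_len(K)) {
    x <- baseline$x[typed, k]; n <- baseline$n[typed, k]
    freq <- (x + 0.5) / (n + 1)          # posterior-mean frequencies
    lp <- .rm_locus_logprobs(x, n)       # 3 x L_typed
    obs <- sum(lp[cbind(g[typed] + 1L, seq_along(typed))])
    sim <- matrix(rbinom(n_sim * length(typed), 2L,
                         rep(freq, each = n_sim)), nrow = n_sim)
    sim_ll <- numeric(n_sim)
    for (d in 0:2)
      sim_ll <- sim_ll + ((sim == d) %*% lp[d + 1L, ])[, 1L]
    p_values[k] <- (1 + sum(sim_ll <= obs)) / (n_sim + 1)
  }
  list(p_values = p_values, excluded = p_values < alpha)
}

#' Consensus assignment from two membership vectors
#'
#' A label is returned only when both methods put strictly more than
#' `threshold` posterior mass on the same population; otherwise
#' `"DISCARDED"`.
#'
#' @param bayes,dapc length-K simplex vectors (same population order)
#' @param threshold consensus probability threshold (strict)
#' @return population label or `"DISCARDED"`
#' @export
consensus_assign <- function(bayes, dapc, threshold = 0.90) {
  stopifnot(length(bayes) == length(dapc))
  labs <- names(bayes) %||% paste0("P", seq_along(bayes))
  ok <- bayes > threshold & dapc > threshold
  if (any(ok)) labs[which(ok)[1L]] else "DISCARDED"
}

#' Assign a mixed-stock sample against a baseline
#'
#' Runs the Bayesian likelihood, the Monte-Carlo exclusion test, DAPC
#' projection, and the dual-threshold consensus for every individual.
#'
#' @param mixed a [genotype_table()] (labels ignored)
#' @param baseline a labelled [genotype_table()]
#' @param threshold consensus threshold (default 0.90)
#' @param n_sim simulated individuals for the exclusion test; 0 skips it
#' @param alpha exclusion significance level
#' @param seed integer seed for the exclusion simulations
#' @param n_pcs,n_da passed to [dapc_fit()]
#' @return data.frame of class `assignment_result`: id, bayes_* and dapc_*
#'   posteriors, excl_* p-values (NA when skipped), consensus label
#' @export
assign_individuals <- function(mixed, baseline, threshold = 0.90,
                               n_sim = 10000, alpha = 0.01, seed = 1,
                               n_pcs = NULL, n_da = NULL) {
  bfreq <- allele_frequencies(baseline)
  K <- length(bfreq$populations)
  calls <- mixed$calls[, bfreq$loci[bfreq$loci %in% mixed$locus_ids],
                       drop = FALSE]
  aligned <- matrix(NA_integer_, nrow(mixed$calls), length(bfreq$loci),
                    dimnames = list(mixed$individual_ids, bfreq$loci))
  aligned[, colnames(calls)] <- calls
  ll <- .rm_loglik_matrix(aligned, bfreq)
  bayes <- exp(ll - apply(ll, 1L, max))
  bayes <- bayes / rowSums(bayes)

  model <- dapc_fit(baseline, n_pcs = n_pcs, n_da = n_da)
  dapc <- dapc_predict(model, mixed)[, bfreq$populations, drop = FALSE]

  excl <- matrix(NA_real_, nrow(aligned), K)
  if (n_sim > 0) {
    for (i in seq_len(nrow(aligned))) {
      res <- mc_exclusion_test(aligned[i, ], bfreq, n_sim = n_sim,
                               alpha = alpha,
                               seed = derive_seed(seed, paste0("excl", i)))
      excl[i, ] <- res$p_values
    }
  }
  consensus <- vapply(seq_len(nrow(aligned)), function(i)
    consensus_assign(setNames(bayes[i, ], bfreq$populations),
                     setNames(dapc[i, ], bfreq$populations),
                     threshold = threshold), character(1))
  out <- data.frame(id = mixed$individual_ids, check.names = FALSE)
  for (k in seq_len(K)) out[[paste0("bayes_", bfreq$populations[k])]] <- bayes[, k]
  for (k in seq_len(K)) out[[paste0("dapc_", bfreq$populations[k])]] <- dapc[, k]
  for (k in seq_len(K)) out[[paste0("excl_", bfreq$populations[k])]] <- excl[, k]
  out$consensus <- consensus
  structure(out, populations = bfreq$populations,
            class = c("assignment_result", "data.frame"))
}

#' Tabulate consensus assignments into catch counts
#'
#' @param assignments an `assignment_result` (or data.frame with `id` and
#'   `consensus`)
#' @param metadata data.frame with columns id, year, stratum covering every
#'   assigned individual
#' @return list with `counts` (a [catch_count_table()], discarded
#'   individuals excluded, empty strata absent) and `retention` (fraction
#'   of individuals retained)
#' @export
tabulate_composition <- function(assignments, metadata) {
  if (!all(c("id", "year", "stratum") %in% names(metadata)))
    .stop_fmt("metadata needs columns id, year, stratum")
  miss <- setdiff(assignments$id, metadata$id)
  if (length(miss))
    .stop_fmt("metadata missing for individual %s", miss[1L])
  pops <- attr(assignments, "populations") %||%
    setdiff(unique(assignments$consensus), "DISCARDED")
  m <- metadata[match(assignments$id, metadata$id), ]
  kept <- assignments$consensus != "DISCARDED"
  key <- interaction(m$year[kept], m$stratum[kept], drop = TRUE)
  tab <- table(key, factor(assignments$consensus[kept], levels = pops))
  ks <- strsplit(rownames(tab), ".", fixed = TRUE)
  yr <- as.numeric(vapply(ks, `[[`, "", 1L))
  st <- vapply(ks, function(z) paste(z[-1L], collapse = "."), "")
  ord <- order(yr, st)
  counts <- catch_count_table(
    year = yr[ord], stratum = st[ord],
    counts = matrix(as.integer(tab), nrow(tab),
                    dimnames = list(NULL, pops))[ord, , drop = FALSE])
  list(counts = counts, retention = mean(kept))
}
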