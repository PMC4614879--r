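# Discriminant analysis of principal components on dosage data.
#
# PCA on the mean-imputed allele-frequency matrix (dosage / 2), then linear
# discriminant analysis on the retained PCs. New individuals are projected
# onto the discriminant axes and converted to memberships via a Gaussian
# kernel around the group centroids (identity covariance in discriminant
# space, equal priors): membership_k propto exp(-d_k^2 / 2).

#' Fit a DAPC model on a labelled baseline
#'
#' @param baseline a [genotype_table()] with group labels; every group needs
#'   >= 2 individuals
#' @param n_pcs number of principal components to retain; default: as many
#'   as explain 90% of variance, capped at n/3
#' @param n_da number of discriminant axes; default K - 1
#' @return object of class `dapc_model`
#' @export
dapc_fit <- function(baseline, n_pcs = NULL, n_da = NULL) {
  stopifnot(inherits(baseline, "genotype_table"))
  if (is.null(baseline$group_labels))
    .stop_fmt("baseline table must carry group labels")
  grp <- factor(baseline$group_labels)
  if (nlevels(grp) < 2L) .stop_fmt("DAPC needs at least two groups")
  if (any(table(grp) < 2L))
    .stop_fmt("every group needs at least 2 individuals")
  X <- baseline$calls / 2
  mu <- colMeans(X, na.rm = TRUE)
  mu[is.na(mu)] <- 0
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- mu[j]
  Xc <- sweep(X, 2L, mu)
  pca <- svd(Xc)
  ev <- pca$d^2
  keep <- ev > max(ev) * 1e-9
  cum <- cumsum(ev[keep]) / sum(ev[keep])
  if (is.null(n_pcs))
    n_pcs <- min(which(cum >= 0.90), floor(nrow(X) / 3))
  n_pcs <- max(1L, min(n_pcs, sum(keep), nrow(X) - 1L))
  if (n_pcs >= nrow(X))
    .stop_fmt("n_pcs must be smaller than the number of individuals")
  rot <- pca$v[, seq_len(n_pcs), drop = FALSE]
  scores <- Xc %*% rot
  colnames(scores) <- paste0("PC", seq_len(n_pcs))
  n_da <- min(n_da %||% (nlevels(grp) - 1L), nlevels(grp) - 1L, n_pcs)
  lda_fit <- MASS::lda(scores, grouping = grp)
  da <- scores %*% lda_fit$scaling[, seq_len(n_da), drop = FALSE]
  centroids <- apply(da, 2L, function(col) tapply(col, grp, mean))
  centroids <- matrix(centroids, nrow = nlevels(grp),
                      dimnames = list(levels(grp), colnames(da)))
  structure(list(loci = baseline$locus_ids, locus_means = mu,
                 rotation = rot, lda_scaling =
                   lda_fit$scaling[, seq_len(n_da), drop = FALSE],
                 centroids = centroids, groups = levels(grp),
                 n_pcs = n_pcs, n_da = n_da,
                 train_scores = da, train_groups = grp),
            class = "dapc_model")
}

#' @export
print.dapc_model <- function(x, ...) {
  cat(sprintf("dapc_model: %d groups, %d PCs, %d discriminant axes\n",
              length(x$groups), x$n_pcs, x$n_da))
  invisible(x)
}

#' Project genotypes onto a DAPC model and return memberships
#'
#' Missing calls are imputed to the training locus mean; loci absent from
#' the model are ignored and model loci absent from the data are treated
#' as missing.
#'
#' @param model a `dapc_model`
#' @param genotypes a [genotype_table()]
#' @return matrix (individuals x groups) of membership probabilities,
#'   rows summing to 1
#' @export
dapc_predict <- function(model, genotypes) {
  stopifnot(inherits(model, "dapc_model"), inherits(genotypes, "genotype_table"))
  common <- intersect(model$loci, genotypes$locus_ids)
  if (!length(common)) .stop_fmt("no loci overlap the DAPC model")
  X <- matrix(rep(model$locus_means, each = nrow(genotypes$calls)),
              nrow = nrow(genotypes$calls),
              dimnames = list(genotypes$individual_ids, model$loci))
  obs <- genotypes$calls[, common, drop = FALSE] / 2
  take <- !is.na(obs)
  X[, common][take] <- obs[take]
  Xc <- sweep(X, 2L, model$locus_means)
  da <- (Xc %*% model$rotation) %*% model$lda_scaling
  d2 <- outer(rowSums(da^2), rowSums(model$centroids^2), `+`) -
    2 * da %*% t(model$centroids)
  w <- exp(-(d2 - apply(d2, 1L, min)) / 2)
  memb <- w / rowSums(w)
  colnames(memb) <- model$groups
  memb
}
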