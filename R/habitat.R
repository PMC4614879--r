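# Ensemble habitat-suitability modelling: four techniques (quadratic
# logistic GLM, natural-spline GAM, gradient boosting, random forest),
# absence down-weighting to prevalence 0.5, repeated 80/20 split
# evaluation by AUC, and yearly hindcasting over temperature grids.

.techniques <- c("glm", "gam", "gbm", "rf")

#' Down-weight absences to balance presences
#'
#' Presences get weight 1; absences get n_presence / n_absence, so total
#' absence weight equals total presence weight (weighted prevalence 0.5).
#'
#' @param occ occurrence data.frame with a 0/1 `presence` column
#' @return numeric weight per record
#' @export
downweight_absences <- function(occ) {
  pres <- occ$presence
  n1 <- sum(pres == 1); n0 <- sum(pres == 0)
  if (n1 == 0 || n0 == 0)
    .stop_fmt("need at least one presence and one absence")
  ifelse(pres == 1, 1, n1 / n0)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC with ties counted at half weight.
#'
#' @param scores numeric prediction scores
#' @param labels 0/1 labels
#' @return AUC in \[0, 1\]
#' @export
auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) .stop_fmt("AUC needs both classes")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# One technique = fit(X, y, w) -> model; stats::predict gives probabilities.
.fit_technique <- function(tech, X, y, w, hyper) {
  df <- as.data.frame(X)
  df$.y <- y
  switch(tech,
    glm = {
      rhs <- paste(c(colnames(X), sprintf("I(%s^2)", colnames(X))),
                   collapse = " + ")
      fit <- stats::glm(stats::as.formula(paste(".y ~", rhs)), data = df,
                        family = stats::quasibinomial(), weights = w)
      structure(list(fit = fit), class = "codmix_sdm_glm")
    },
    gam = {
      rhs <- paste(sprintf("splines::ns(%s, df = %d)", colnames(X),
                           hyper$gam_df), collapse = " + ")
      fit <- stats::glm(stats::as.formula(paste(".y ~", rhs)), data = df,
                        family = stats::quasibinomial(), weights = w)
      structure(list(fit = fit), class = "codmix_sdm_glm")
    },
    gbm = fit_gbm(X, y, w, n_trees = hyper$gbm_trees, depth = hyper$gbm_depth,
                  shrinkage = hyper$gbm_shrinkage,
                  bag_fraction = hyper$gbm_bag),
    rf = fit_rf(X, y, w, n_trees = hyper$rf_trees))
}

#' @export
predict.codmix_sdm_glm <- function(object, newdata, ...) {
  as.numeric(stats::predict(object$fit, newdata = as.data.frame(newdata),
                            type = "response"))
}

#' Fit the four-technique SDM ensemble
#'
#' For each technique and each of `n_rep` seeded random 80/20 splits the
#' model is calibrated on the training fraction and scored by AUC on the
#' held-out fraction. Splits whose held-out part lacks a class are redrawn
#' (logged). Final members are refit on all records; the ensemble
#' prediction is their unweighted mean.
#'
#' @param occ occurrence data.frame (columns `presence` plus predictors)
#' @param weights case weights; default [downweight_absences()]
#' @param predictors predictor column names (default `"temperature"`,
#'   plus `"depth"` when present)
#' @param n_rep number of evaluation repetitions
#' @param train_frac training fraction per repetition
#' @param seed integer seed
#' @param hyper named list of technique hyperparameters (see defaults)
#' @return object of class `sdm_ensemble` with members, an `auc` table
#'   (technique x repetition) and the training predictor ranges
#' @export
fit_ensemble <- function(occ, weights = NULL, predictors = NULL,
                         n_rep = 10, train_frac = 0.8, seed = 1,
                         hyper = list()) {
  predictors <- predictors %||%
    intersect(c("temperature", "depth"), names(occ))
  if (!length(predictors)) .stop_fmt("no predictor columns found")
  hyper <- utils::modifyList(
    list(gam_df = 4L, gbm_trees = 1000L, gbm_depth = 3L,
         gbm_shrinkage = 0.01, gbm_bag = 0.5, rf_trees = 500L), hyper)
  X <- .as_predictor_matrix(occ, predictors)
  y <- occ$presence
  if (!all(y %in% c(0, 1))) .stop_fmt("presence must be 0/1")
  w <- weights %||% downweight_absences(occ)
  n <- nrow(X)
  n_train <- max(2L, round(train_frac * n))
  auc_tab <- matrix(NA_real_, length(.techniques), n_rep,
                    dimnames = list(.techniques, paste0("rep", seq_len(n_rep))))
  set.seed(derive_seed(seed, "sdm_splits"))
  for (r in seq_len(n_rep)) {
    for (try in 1:50) {
      tr <- sample.int(n, n_train)
      te <- setdiff(seq_len(n), tr)
      if (length(unique(y[tr])) == 2L && length(unique(y[te])) == 2L) break
      if (try == 50) .stop_fmt("cannot draw a split with both classes held out")
      .log_msg("degenerate split in repetition %d; redrawing", r)
    }
    for (tech in .techniques) {
      fit <- .fit_technique(tech, X[tr, , drop = FALSE], y[tr], w[tr], hyper)
      pr <- predict(fit, X[te, , drop = FALSE])
      auc_tab[tech, r] <- auc(pr, y[te])
    }
  }
  set.seed(derive_seed(seed, "sdm_final"))
  members <- lapply(setNames(.techniques, .techniques), function(tech)
    .fit_technique(tech, X, y, w, hyper))
  structure(list(members = members, auc = auc_tab, predictors = predictors,
                 ranges = apply(X, 2L, range), hyper = hyper),
            class = "sdm_ensemble")
}

#' @export
print.sdm_ensemble <- function(x, ...) {
  cat(sprintf("sdm_ensemble: %s | mean held-out AUC by technique:\n",
              paste(x$predictors, collapse = ", ")))
  print(round(rowMeans(x$auc), 3))
  invisible(x)
}

#' Predict suitability from an ensemble
#'
#' @param object an `sdm_ensemble`
#' @param newdata data.frame or matrix with the training predictors
#' @param members return the per-technique matrix instead of the mean
#' @param ... unused
#' @return numeric suitability in \[0, 1\] (or an n x 4 matrix)
#' @export
predict.sdm_ensemble <- function(object, newdata, members = FALSE, ...) {
  X <- .as_predictor_matrix(newdata, object$predictors)
  P <- vapply(object$members, function(m)
    pmin(pmax(predict(m, X), 0), 1), numeric(nrow(X)))
  P <- matrix(P, nrow = nrow(X), dimnames = list(NULL, names(object$members)))
  if (members) P else rowMeans(P)
}

#' Hindcast yearly suitability grids
#'
#' Applies the ensemble to every sea cell of every yearly layer
#' (interpreted as the first training predictor, temperature). Cells
#' outside the training predictor range are still predicted but counted
#' and reported via a warning.
#'
#' @param ensemble an `sdm_ensemble`
#' @param grids a [grid_series()] of the environmental predictor
#' @param member predict from a single named technique instead of the mean
#' @return a [grid_series()] of suitabilities in \[0, 1\]
#' @export
hindcast <- function(ensemble, grids, member = NULL) {
  stopifnot(inherits(ensemble, "sdm_ensemble"), inherits(grids, "grid_series"))
  sea <- which(grids$mask)
  pred_name <- ensemble$predictors[1L]
  rng <- ensemble$ranges[, pred_name]
  n_extrap <- 0L
  layers <- lapply(grids$layers, function(layer) {
    vals <- layer[sea]
    n_extrap <<- n_extrap + sum(vals < rng[1L] | vals > rng[2L])
    nd <- stats::setNames(data.frame(vals), pred_name)
    if (length(ensemble$predictors) > 1L)
      for (p in ensemble$predictors[-1L]) nd[[p]] <- mean(ensemble$ranges[, p])
    s <- if (is.null(member)) predict(ensemble, nd)
         else pmin(pmax(predict(ensemble$members[[member]],
                                .as_predictor_matrix(nd, ensemble$predictors)), 0), 1)
    out <- layer
    out[sea] <- s
    out
  })
  if (n_extrap > 0)
    warning(sprintf("%d grid cells outside the training predictor range (extrapolated)",
                    n_extrap))
  grid_series(grids$years, layers, grids$mask, grids$cell_size_km)
}

#' Summarise occupied temperatures per population
#'
#' @param occ occurrence data.frame with `presence`, `temperature` and
#'   `population` columns
#' @return data.frame per population: n, median, q25, q75, iqr, min, max of
#'   presence-record temperatures; populations without presences are
#'   omitted with a warning
#' @export
occupied_temperature_summary <- function(occ) {
  stopifnot(all(c("presence", "temperature", "population") %in% names(occ)))
  pres <- occ[occ$presence == 1, ]
  pops <- unique(occ$population)
  empty <- setdiff(pops, unique(pres$population))
  if (length(empty))
    warning(sprintf("population(s) without presences omitted: %s",
                    paste(empty, collapse = ", ")))
  do.call(rbind, lapply(split(pres$temperature, pres$population), function(tt) {
    q <- quantile(tt, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(n = length(tt), median = q[2L], q25 = q[1L], q75 = q[3L],
               iqr = q[3L] - q[1L], min = min(tt), max = max(tt))
  }))
}
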