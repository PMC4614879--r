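# R-side wrappers around the Rcpp CART learner: gradient boosting with
# Bernoulli loss and a probability random forest. Both honour case weights
# and R's RNG (reproducible under set.seed()).

.as_predictor_matrix <- function(x, predictors) {
  m <- as.matrix(as.data.frame(x)[predictors])
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) .stop_fmt("non-finite predictor values")
  m
}

#' Fit a gradient-boosted tree model (Bernoulli loss)
#'
#' Shrunken gradient boosting on the logit scale with depth-limited
#' regression trees fitted to the weighted gradient on a bagged subsample
#' each iteration.
#'
#' @param X numeric predictor matrix
#' @param y 0/1 response
#' @param w case weights
#' @param n_trees,depth,shrinkage,bag_fraction boosting hyperparameters
#' @param min_obs minimum observations per leaf
#' @return object of class `codmix_gbm`
#' @export
fit_gbm <- function(X, y, w = rep(1, length(y)), n_trees = 1000, depth = 3,
                    shrinkage = 0.01, bag_fraction = 0.5, min_obs = 5) {
  X <- as.matrix(X); storage.mode(X) <- "double"
  n <- nrow(X)
  pbar <- sum(w * y) / sum(w)
  pbar <- min(max(pbar, 1e-6), 1 - 1e-6)
  f0 <- log(pbar / (1 - pbar))
  f <- rep(f0, n)
  trees <- vector("list", n_trees)
  n_bag <- max(2L, floor(bag_fraction * n))
  for (m in seq_len(n_trees)) {
    p <- 1 / (1 + exp(-f))
    r <- y - p
    take <- sample.int(n, n_bag)
    tr <- .cpp_fit_tree(X[take, , drop = FALSE], r[take], w[take],
                        depth, min_obs, -1L)
    trees[[m]] <- tr
    f <- f + shrinkage * 4 * .cpp_predict_tree(tr, X)
  }
  structure(list(f0 = f0, trees = trees, shrinkage = shrinkage),
            class = "codmix_gbm")
}

#' @export
predict.codmix_gbm <- function(object, newdata, ...) {
  X <- as.matrix(newdata); storage.mode(X) <- "double"
  f <- rep(object$f0, nrow(X))
  for (tr in object$trees)
    f <- f + object$shrinkage * 4 * .cpp_predict_tree(tr, X)
  1 / (1 + exp(-f))
}

#' Fit a probability random forest
#'
#' Bagged deep regression trees on the 0/1 response with node-level random
#' feature subsampling; the forest prediction is the mean tree vote,
#' clipped to \[0, 1\].
#'
#' @inheritParams fit_gbm
#' @param n_trees number of trees
#' @param mtry features tried per split (default: all for <= 2 predictors,
#'   else floor(sqrt(d)))
#' @param max_depth,min_obs tree size controls
#' @return object of class `codmix_rf`
#' @export
fit_rf <- function(X, y, w = rep(1, length(y)), n_trees = 500, mtry = NULL,
                   max_depth = 12, min_obs = 5) {
  X <- as.matrix(X); storage.mode(X) <- "double"
  n <- nrow(X); d <- ncol(X)
  mtry <- mtry %||% if (d <= 2) d else max(1L, floor(sqrt(d)))
  trees <- vector("list", n_trees)
  for (b in seq_len(n_trees)) {
    take <- sample.int(n, n, replace = TRUE)
    trees[[b]] <- .cpp_fit_tree(X[take, , drop = FALSE], y[take], w[take],
                                max_depth, min_obs, as.integer(mtry))
  }
  structure(list(trees = trees), class = "codmix_rf")
}

#' @export
predict.codmix_rf <- function(object, newdata, ...) {
  X <- as.matrix(newdata); storage.mode(X) <- "double"
  p <- rowMeans(vapply(object$trees, function(tr) .cpp_predict_tree(tr, X),
                       numeric(nrow(X))))
  pmin(pmax(p, 0), 1)
}
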