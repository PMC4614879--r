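# Seascape connectivity and regime analysis: suitability-weighted
# least-cost-path distances across the sea grid (8-neighbour raster graph,
# Dijkstra via igraph), the static shortest-sea-distance baseline, the
# binomial GLM of catch proportion against distance, and STARS regime-shift
# detection on yearly mean suitability.

#' Build a traversal-cost surface from suitability
#'
#' Cost per cell = max(1 - suitability, epsilon); land is impassable.
#' Optionally a hard threshold masks cells below a minimum suitability.
#'
#' @param suitability numeric matrix in \[0, 1\] (NA = land), or a
#'   [grid_series()] together with `year`
#' @param epsilon cost floor on perfectly suitable cells
#' @param year layer to use when `suitability` is a grid series
#' @param threshold optional minimum suitability; cells below it become
#'   impassable
#' @param cell_size_km cell edge length (taken from the grid series when
#'   given)
#' @return object of class `cost_surface`: list(cost, mask, cell_size_km)
#' @export
cost_surface <- function(suitability, epsilon = 0.01, year = NULL,
                         threshold = NULL, cell_size_km = 50) {
  if (inherits(suitability, "grid_series")) {
    stopifnot(!is.null(year))
    cell_size_km <- suitability$cell_size_km
    suitability <- suitability$layers[[as.character(year)]]
  }
  s <- as.matrix(suitability)
  mask <- !is.na(s)
  if (!any(mask)) .stop_fmt("all-land grid: no sea cells")
  if (any(s[mask] < -1e-9 | s[mask] > 1 + 1e-9))
    .stop_fmt("suitability must lie in [0, 1]")
  if (!is.null(threshold)) mask <- mask & s >= threshold
  cost <- matrix(NA_real_, nrow(s), ncol(s))
  cost[mask] <- pmax(1 - s[mask], epsilon)
  structure(list(cost = cost, mask = mask, cell_size_km = cell_size_km),
            class = "cost_surface")
}

# 8-neighbour raster graph; edge weight = mean endpoint cost * step length
# in km (1 or sqrt(2) cells).
.grid_graph <- function(cost, mask, cell_size_km) {
  nr <- nrow(mask); nc <- ncol(mask)
  id <- matrix(NA_integer_, nr, nc)
  sea <- which(mask)
  id[sea] <- seq_along(sea)
  steps <- cbind(dr = c(1L, 0L, 1L, -1L), dc = c(0L, 1L, 1L, 1L),
                 len = c(1, 1, sqrt(2), sqrt(2)))
  rc <- arrayInd(sea, dim(mask))
  from <- to <- integer(0); wt <- numeric(0)
  for (k in seq_len(nrow(steps))) {
    r2 <- rc[, 1L] + steps[k, 1L]; c2 <- rc[, 2L] + steps[k, 2L]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    j <- (c2[ok] - 1L) * nr + r2[ok]
    ok2 <- !is.na(id[j])
    i1 <- sea[ok][ok2]; j1 <- j[ok2]
    from <- c(from, id[i1]); to <- c(to, id[j1])
    wt <- c(wt, (cost[i1] + cost[j1]) / 2 * steps[k, 3L] * cell_size_km)
  }
  g <- igraph::make_graph(rbind(from, to), n = length(sea), directed = FALSE)
  list(g = g, id = id, weights = wt)
}

.cell_index <- function(cells) {
  cells <- if (is.matrix(cells) || is.data.frame(cells)) as.matrix(cells)
           else matrix(cells, ncol = 2, byrow = TRUE)
  storage.mode(cells) <- "integer"
  cells
}

#' Least-cost accumulated distance from a source cell
#'
#' Dijkstra over the 8-neighbour sea graph with edge weight =
#' mean(endpoint costs) x step length x cell size. Unreachable targets get
#' +Inf.
#'
#' @param cs a [cost_surface()]
#' @param source length-2 (row, col) sea cell
#' @param targets n x 2 matrix of (row, col) target cells; default all sea
#'   cells
#' @return named numeric vector of accumulated km-weighted costs
#' @export
least_cost_distance <- function(cs, source, targets = NULL) {
  stopifnot(inherits(cs, "cost_surface"))
  src <- .cell_index(source)
  if (!isTRUE(cs$mask[src[1L, 1L], src[1L, 2L]]))
    .stop_fmt("source cell (%d, %d) is on land", src[1L, 1L], src[1L, 2L])
  gg <- .grid_graph(cs$cost, cs$mask, cs$cell_size_km)
  tg <- if (is.null(targets)) which(cs$mask, arr.ind = TRUE)
        else .cell_index(targets)
  tid <- gg$id[tg]
  if (anyNA(tid)) .stop_fmt("a target cell is on land")
  d <- igraph::distances(gg$g, v = gg$id[src],
                         to = tid, weights = gg$weights)[1L, ]
  setNames(as.numeric(d), paste(tg[, 1L], tg[, 2L], sep = ","))
}

#' Shortest sea distance (geodesic through sea cells)
#'
#' Dijkstra with unit cell cost: the static-geography baseline distance.
#'
#' @param mask logical sea mask
#' @param source,targets as in [least_cost_distance()]
#' @param cell_size_km cell edge length in km
#' @return named numeric vector of sea distances in km
#' @export
shortest_sea_distance <- function(mask, source, targets = NULL,
                                  cell_size_km = 50) {
  cost <- matrix(NA_real_, nrow(mask), ncol(mask))
  cost[mask] <- 1
  cs <- structure(list(cost = cost, mask = mask,
                       cell_size_km = cell_size_km), class = "cost_surface")
  least_cost_distance(cs, source, targets)
}

#' Binomial GLM of population proportion against distance
#'
#' Logistic regression of the per-stratum Iceland-offshore fraction on a
#' distance predictor, with the deviance-based coefficient of
#' determination R^2 = 1 - residual deviance / null deviance and a Wald-z
#' test on the slope. Complete separation triggers a ridge-penalised IRLS
#' fallback (flagged in the result).
#'
#' @param n_focal successes per stratum (e.g. Iceland-offshore counts)
#' @param n_other failures per stratum (e.g. West-Greenland-offshore counts)
#' @param distance distance predictor per stratum (km)
#' @return list: slope, intercept, se, z, p_value, r2, separation flag
#' @export
proportion_distance_glm <- function(n_focal, n_other, distance) {
  keep <- (n_focal + n_other) > 0
  if (sum(keep) < 3L) .stop_fmt("need >= 3 strata with nonzero totals")
  yy <- cbind(n_focal, n_other)[keep, , drop = FALSE]
  x <- distance[keep]
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(yy ~ x, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (sep || abs(coef(fit)[2L]) > 1e3) {
    sep <- TRUE
    warning("complete separation detected; using ridge-penalised fit")
    fit <- .ridge_logistic(yy, x, lambda = 1e-4)
    slope <- fit$beta[2L]; intercept <- fit$beta[1L]; se <- fit$se[2L]
    r2 <- fit$r2
  } else {
    slope <- coef(fit)[[2L]]; intercept <- coef(fit)[[1L]]
    se <- sqrt(diag(vcov(fit)))[2L]
    r2 <- 1 - fit$deviance / fit$null.deviance
  }
  z <- slope / se
  list(slope = slope, intercept = intercept, se = se, z = z,
       p_value = 2 * stats::pnorm(-abs(z)), r2 = max(0, min(1, r2)),
       separation = sep)
}

# Minimal ridge-penalised binomial IRLS on (intercept, slope).
.ridge_logistic <- function(yy, x, lambda = 1e-4, maxit = 100) {
  Xd <- cbind(1, x)
  ntot <- rowSums(yy)
  yfrac <- yy[, 1L] / ntot
  beta <- c(stats::qlogis(min(max(mean(yfrac), 0.01), 0.99)), 0)
  P <- diag(c(0, lambda))
  for (it in seq_len(maxit)) {
    eta <- Xd %*% beta
    mu <- stats::plogis(eta)
    W <- as.numeric(ntot * mu * (1 - mu))
    info <- crossprod(Xd, W * Xd) + P
    score <- crossprod(Xd, yy[, 1L] - ntot * mu) - P %*% beta
    step <- solve(info, score)
    beta <- beta + step
    if (max(abs(step)) < 1e-10) break
  }
  mu <- as.numeric(stats::plogis(Xd %*% beta))
  dev <- -2 * sum(stats::dbinom(yy[, 1L], ntot, mu, log = TRUE))
  p0 <- sum(yy[, 1L]) / sum(ntot)
  dev0 <- -2 * sum(stats::dbinom(yy[, 1L], ntot, p0, log = TRUE))
  se <- sqrt(diag(solve(crossprod(Xd, as.numeric(ntot * mu * (1 - mu)) * Xd) + P)))
  list(beta = as.numeric(beta), se = se, r2 = 1 - dev / dev0)
}

#' Compare distance predictors of catch proportion
#'
#' Fits [proportion_distance_glm()] for each candidate distance and ranks
#' the models by deviance R^2.
#'
#' @param n_focal,n_other per-stratum counts (as in
#'   [proportion_distance_glm()])
#' @param model_distances named list of per-stratum distance vectors, e.g.
#'   `list(population_lcp = ..., species_lcp = ..., static = ...)`
#' @return data.frame (model, r2, slope, p_value), sorted by decreasing R^2
#' @export
compare_distance_models <- function(n_focal, n_other, model_distances) {
  stopifnot(length(model_distances) >= 1, !is.null(names(model_distances)))
  rows <- lapply(names(model_distances), function(nm) {
    f <- proportion_distance_glm(n_focal, n_other, model_distances[[nm]])
    data.frame(model = nm, r2 = f$r2, slope = f$slope, p_value = f$p_value)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$r2), ]
  rownames(out) <- NULL
  out
}

#' Sequential t-test regime-shift detection (STARS)
#'
#' Basic Rodionov-style sequential detection: the threshold deviation is
#' diff = t_(1 - sig/2, 2l - 2) * sqrt(2 sigma_l^2 / l), with sigma_l^2 the
#' average variance of consecutive l-year windows. A value beyond the
#' current regime mean +/- diff opens a candidate shift, confirmed when the
#' cumulative regime-shift index over the following l years stays positive;
#' on confirmation the regime mean restarts at the shift year. Regime means
#' in the result are recomputed as full segment means of the confirmed
#' partition.
#'
#' @param values numeric series (e.g. log mean suitability per year)
#' @param years years, defaults to indices
#' @param cutoff_years the STARS cut-off length l
#' @param significance two-sided significance level for the threshold
#' @return object of class `regime_segmentation`: change-point years,
#'   per-regime means, the regime-shift index per candidate year, and the
#'   parameters
#' @export
regime_shift_detect <- function(values, years = seq_along(values),
                                cutoff_years = 5, significance = 0.1) {
  n <- length(values)
  l <- as.integer(cutoff_years)
  if (n < 2L * l)
    .stop_fmt("series length %d is shorter than 2 x cutoff (%d)", n, 2L * l)
  nwin <- n - l + 1L
  vars <- vapply(seq_len(nwin), function(i) var(values[i:(i + l - 1L)]),
                 numeric(1))
  sig2 <- mean(vars)
  diff_thr <- qt(1 - significance / 2, df = 2L * l - 2L) * sqrt(2 * sig2 / l)
  rsi <- setNames(rep(0, n), years)

  cps <- integer(0)
  regime_start <- 1L
  cur_mean <- mean(values[1:l])
  i <- l + 1L
  while (i <= n) {
    dev_up <- values[i] > cur_mean + diff_thr
    dev_dn <- values[i] < cur_mean - diff_thr
    confirmed <- FALSE
    if (dev_up || dev_dn) {
      lvl <- if (dev_up) cur_mean + diff_thr else cur_mean - diff_thr
      sgn <- if (dev_up) 1 else -1
      cum <- 0
      win <- i:min(i + l - 1L, n)
      ok <- TRUE
      for (j in win) {
        cum <- cum + sgn * (values[j] - lvl) / (l * sqrt(sig2))
        if (cum < 0) { ok <- FALSE; break }
      }
      rsi[i] <- if (ok) cum else 0
      if (ok) {
        confirmed <- TRUE
        cps <- c(cps, i)
        regime_start <- i
        cur_mean <- mean(values[i:min(i + l - 1L, n)])
        i <- i + 1L
      }
    }
    if (!confirmed) {
      # recalculate the running mean over the most recent values of the
      # current regime (at most l of them)
      lo <- max(regime_start, i - l + 1L)
      cur_mean <- mean(values[lo:i])
      i <- i + 1L
    }
  }
  bounds <- c(1L, cps, n + 1L)
  regimes <- data.frame(
    start_year = years[utils::head(bounds, -1L)],
    end_year = years[utils::tail(bounds, -1L) - 1L],
    mean = vapply(seq_len(length(bounds) - 1L), function(k)
      mean(values[bounds[k]:(bounds[k + 1L] - 1L)]), numeric(1)))
  structure(list(years = years, values = values,
                 change_points = years[cps], regimes = regimes, rsi = rsi,
                 cutoff_years = l, significance = significance,
                 threshold = diff_thr),
            class = "regime_segmentation")
}

#' @export
print.regime_segmentation <- function(x, ...) {
  cat(sprintf("regime_segmentation: %d change point(s) (cutoff %d yr, sig %.2g)\n",
              length(x$change_points), x$cutoff_years, x$significance))
  print(x$regimes)
  invisible(x)
}

#' Yearly mean suitability series
#'
#' Per-year mean over sea cells, optionally natural-log transformed (with a
#' floor of 1e-6 before the log).
#'
#' @param suitability a [grid_series()] of suitabilities
#' @param transform `"log"` (default) or `"identity"`
#' @return data.frame (year, value)
#' @export
mean_suitability_series <- function(suitability, transform = c("log", "identity")) {
  transform <- match.arg(transform)
  stopifnot(inherits(suitability, "grid_series"))
  if (!any(suitability$mask)) .stop_fmt("empty sea mask")
  v <- vapply(suitability$layers, function(m)
    mean(m[suitability$mask]), numeric(1))
  if (transform == "log") v <- log(pmax(v, 1e-6))
  data.frame(year = suitability$years, value = as.numeric(v))
}
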