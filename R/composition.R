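# State-space model of catch composition through time.
#
# Observations: per-sampling-time multinomial counts over K = 4 populations.
# Latent state: alpha_t in R^3 following a Gaussian random walk whose
# innovation variance scales with the elapsed time between samples,
#   alpha_t = alpha_{t-1} + eps_t,  eps_t ~ N(0, sigma^2 dt I).
# alpha maps to the 4-simplex by the additive-logistic transform with
# category 4 as reference. The path is estimated at its joint mode (Laplace
# / empirical-Bayes treatment); sigma maximises the Laplace-approximated
# marginal likelihood. Credible bands come from a Gaussian approximation
# around the mode, mapped through the transform.

#' Additive-logistic transform to the 4-simplex
#'
#' p_k = exp(a_k) / (1 + sum exp(a_j)) for k = 1..3, p_4 = 1 / (1 + sum).
#' Overflow is handled by max-subtraction.
#'
#' @param alpha length-3 numeric vector (or n x 3 matrix)
#' @return length-4 simplex vector (or n x 4 matrix)
#' @export
simplex_transform <- function(alpha) {
  if (is.matrix(alpha)) {
    a <- cbind(alpha, 0)
    a <- a - apply(a, 1L, max)
    e <- exp(a)
    return(e / rowSums(e))
  }
  stopifnot(length(alpha) == 3L, all(is.finite(alpha)))
  a <- c(alpha, 0)
  e <- exp(a - max(a))
  e / sum(e)
}

#' Inverse additive-logistic transform
#'
#' @param p length-4 simplex vector with entries in (0, 1)
#' @return length-3 numeric vector alpha with alpha_k = log(p_k / p_4)
#' @export
inverse_simplex_transform <- function(p) {
  stopifnot(length(p) == 4L, all(p > 0), abs(sum(p) - 1) < 1e-6)
  log(p[1:3] / p[4])
}

# Aggregate a catch_count_table to one count row per time.
.aggregate_counts <- function(counts) {
  pops <- attr(counts, "populations")
  agg <- rowsum(as.matrix(counts[pops]), counts$year)
  times <- as.numeric(rownames(agg))
  ord <- order(times)
  list(times = times[ord], counts = agg[ord, , drop = FALSE], pops = pops)
}

#' Joint log-likelihood of a latent path and the counts
#'
#' Multinomial observation terms plus Gaussian random-walk increment terms
#' with variance sigma^2 * dt. The initial state alpha_1 is diffuse (no
#' prior term).
#'
#' @param counts n x 4 matrix of counts, rows aligned with `times`
#' @param alpha_path n x 3 matrix of latent states
#' @param sigma innovation SD per sqrt(year), > 0
#' @param times strictly increasing decimal years
#' @param dt_scale logical; scale innovation variance by elapsed time
#'   (default TRUE). FALSE treats every step as dt = 1.
#' @return scalar log-likelihood
#' @export
joint_loglik <- function(counts, alpha_path, sigma, times, dt_scale = TRUE) {
  counts <- as.matrix(counts)
  n <- nrow(counts)
  stopifnot(nrow(alpha_path) == n, length(times) == n, sigma > 0)
  if (n > 1L && any(diff(times) <= 0))
    .stop_fmt("times must be strictly increasing")
  p <- simplex_transform(as.matrix(alpha_path))
  ll <- sum(lgamma(rowSums(counts) + 1)) - sum(lgamma(counts + 1)) +
    sum(counts * log(p))
  if (n > 1L) {
    dt <- if (dt_scale) diff(times) else rep(1, n - 1L)
    d <- diff(as.matrix(alpha_path))
    v <- sigma^2 * dt
    ll <- ll + sum(-0.5 * log(2 * pi * v) * 3 - rowSums(d^2) / (2 * v))
  }
  ll
}

# Negative joint loglik, gradient and Hessian in the flattened path
# (column-major: alpha[, 1], alpha[, 2], alpha[, 3]). The multinomial part
# couples the three coordinates within a time; the random-walk part is
# tridiagonal within a coordinate.
.nll_parts <- function(theta, counts, sigma, dt) {
  n <- nrow(counts)
  A <- matrix(theta, n, 3)
  p <- simplex_transform(A)
  N <- rowSums(counts)
  g_obs <- -(counts[, 1:3, drop = FALSE] - N * p[, 1:3, drop = FALSE])
  v <- sigma^2 * dt
  d <- diff(A)
  g_rw <- matrix(0, n, 3)
  if (n > 1L) {
    sc <- d / v
    g_rw[-1L, ] <- g_rw[-1L, ] + sc
    g_rw[-n, ] <- g_rw[-n, ] - sc
  }
  list(grad = as.numeric(g_obs + g_rw), p = p, N = N, v = v)
}

.nll_hessian <- function(theta, counts, sigma, dt) {
  n <- nrow(counts)
  A <- matrix(theta, n, 3)
  p <- simplex_transform(A)
  N <- rowSums(counts)
  H <- matrix(0, 3 * n, 3 * n)
  for (i in seq_len(n)) {
    pi3 <- p[i, 1:3]
    block <- N[i] * (diag(pi3) - tcrossprod(pi3))
    idx <- i + n * (0:2)
    H[idx, idx] <- H[idx, idx] + block
  }
  if (n > 1L) {
    v <- sigma^2 * dt
    for (k in 0:2) {
      off <- k * n
      for (i in seq_len(n - 1L)) {
        a <- off + i; b <- off + i + 1L
        w <- 1 / v[i]
        H[a, a] <- H[a, a] + w
        H[b, b] <- H[b, b] + w
        H[a, b] <- H[a, b] - w
        H[b, a] <- H[b, a] - w
      }
    }
  }
  H
}

#' Fit the compositional state-space model
#'
#' Inner step: the latent path is maximised at fixed sigma by BFGS with an
#' analytic gradient, started from zero. Outer step: sigma maximises the
#' Laplace-approximated marginal likelihood
#' log L(sigma) = joint(alpha_hat) + (3n/2) log(2 pi) - 0.5 log det H.
#'
#' @param counts a [catch_count_table()] (aggregated per year) or an
#'   n x 4 count matrix
#' @param times decimal years (taken from the table when omitted)
#' @param sigma fixed innovation SD, or NULL (default) to estimate it
#' @param dt_scale scale innovations with elapsed years (default TRUE)
#' @param n_draws Monte-Carlo draws for the credible bands
#' @param level credible level for the bands (default 0.90)
#' @param seed seed for the band draws
#' @return object of class `composition_series`: times, alpha_path, sigma,
#'   p_path, bands (arrays lo/hi), cov (posterior covariance of the path),
#'   logLik (Laplace marginal at the optimum)
#' @export
fit_state_space <- function(counts, times = NULL, sigma = NULL,
                            dt_scale = TRUE, n_draws = 4000, level = 0.90,
                            seed = 1) {
  if (inherits(counts, "catch_count_table")) {
    agg <- .aggregate_counts(counts)
    counts <- agg$counts
    times <- times %||% agg$times
    pops <- agg$pops
  } else {
    counts <- as.matrix(counts)
    pops <- colnames(counts) %||% paste0("P", 1:4)
    if (is.null(times)) times <- seq_len(nrow(counts))
  }
  if (ncol(counts) != 4L) .stop_fmt("expected 4 population columns")
  n <- nrow(counts)
  if (n < 2L && is.null(sigma))
    .stop_fmt("need >= 2 time points to estimate sigma")
  if (any(rowSums(counts) < 1)) .stop_fmt("every time needs N_i >= 1")
  dt <- if (n > 1L) { if (dt_scale) diff(times) else rep(1, n - 1L) } else numeric(0)

  inner <- function(sig) {
    fn <- function(th) -joint_loglik(counts, matrix(th, ncol = 3), sig,
                                     times, dt_scale = dt_scale)
    gr <- function(th) .nll_parts(th, counts, sig, dt)$grad
    fit <- optim(rep(0, 3 * n), fn, gr, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-12))
    if (fit$convergence != 0) {
      fit2 <- optim(fit$par, fn, gr, method = "BFGS",
                    control = list(maxit = 500, reltol = 1e-12))
      if (fit2$convergence != 0)
        .stop_fmt("inner optimisation failed to converge (code %d, sigma=%g)",
                  fit2$convergence, sig)
      fit <- fit2
    }
    fit
  }
  laplace <- function(log_sig) {
    sig <- exp(log_sig)
    fit <- inner(sig)
    H <- .nll_hessian(fit$par, counts, sig, dt)
    ld <- determinant(H, logarithm = TRUE)$modulus
    -fit$value + (3 * n / 2) * log(2 * pi) - 0.5 * as.numeric(ld)
  }
  if (is.null(sigma)) {
    opt <- optimize(laplace, interval = log(c(1e-3, 10)), maximum = TRUE,
                    tol = 1e-4)
    sigma <- exp(opt$maximum)
    marg <- opt$objective
  } else {
    marg <- if (n > 1L) laplace(log(sigma)) else NA_real_
  }
  fit <- inner(sigma)
  alpha_path <- matrix(fit$par, n, 3)
  H <- .nll_hessian(fit$par, counts, sigma, dt)
  cov <- solve(H)
  p_path <- simplex_transform(alpha_path)
  colnames(p_path) <- pops

  # credible bands: Gaussian approximation at the mode
  set.seed(seed)
  L <- t(chol(cov + diag(1e-10, nrow(cov))))
  z <- L %*% matrix(rnorm(3 * n * n_draws), ncol = n_draws)
  lo <- hi <- matrix(NA_real_, n, 4, dimnames = list(NULL, pops))
  qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  for (i in seq_len(n)) {
    draws <- t(fit$par[i + n * (0:2)] + z[i + n * (0:2), , drop = FALSE])
    pd <- simplex_transform(draws)
    for (k in 1:4) {
      q <- quantile(pd[, k], qs, names = FALSE)
      lo[i, k] <- min(q[1L], p_path[i, k])
      hi[i, k] <- max(q[2L], p_path[i, k])
    }
  }
  structure(list(times = times, counts = counts, alpha_path = alpha_path,
                 sigma = sigma, p_path = p_path,
                 bands = list(lo = lo, hi = hi, level = level),
                 cov = cov, populations = pops, dt_scale = dt_scale,
                 logLik = marg),
            class = "composition_series")
}

#' @export
print.composition_series <- function(x, ...) {
  cat(sprintf("composition_series: %d times (%g-%g), sigma = %.3f\n",
              length(x$times), min(x$times), max(x$times), x$sigma))
  print(round(cbind(year = x$times, x$p_path), 3))
  invisible(x)
}

#' Interpolate fitted proportions to arbitrary years
#'
#' Conditional on the fitted path, the random-walk smoother's mean at an
#' interior time is the time-weighted linear interpolation of the flanking
#' states (Brownian-bridge mean); outside the observation span the mean is
#' the nearest endpoint state (random-walk forecast).
#'
#' @param series a `composition_series`
#' @param years numeric years
#' @param max_extrapolate error beyond this many years outside the span
#' @return matrix length(years) x 4 of proportions
#' @export
interpolate_proportions <- function(series, years, max_extrapolate = 5) {
  t0 <- series$times
  if (any(years < min(t0) - max_extrapolate |
          years > max(t0) + max_extrapolate))
    .stop_fmt("year outside the observation span by more than %g years",
              max_extrapolate)
  A <- apply(series$alpha_path, 2L, function(col)
    approx(t0, col, xout = pmin(pmax(years, min(t0)), max(t0)))$y)
  A <- matrix(A, ncol = 3)
  p <- simplex_transform(A)
  colnames(p) <- series$populations
  p
}

#' Apportion total stock biomass by population
#'
#' @param series a fitted `composition_series`
#' @param biomass data.frame with columns year, biomass (tonnes of age-3+
#'   fish)
#' @return data.frame (year, population, p, biomass) of class
#'   `biomass_apportionment`; per-year biomasses sum to the total
#' @export
apportion_biomass <- function(series, biomass) {
  stopifnot(all(c("year", "biomass") %in% names(biomass)))
  p <- interpolate_proportions(series, biomass$year)
  out <- data.frame(
    year = rep(biomass$year, times = ncol(p)),
    population = rep(colnames(p), each = nrow(p)),
    p = as.numeric(p),
    biomass = as.numeric(p * biomass$biomass))
  structure(out[order(out$year, out$population), ],
            class = c("biomass_apportionment", "data.frame"))
}
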