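# Synthetic-data generators: every pipeline input with known ground truth.
#
# The default scenario mirrors the shape of the West Greenland cod archive:
# 4 baseline spawning populations x 81 biallelic SNPs, 9 sampling years
# between 1932 and 2012 with ~100 individuals per year, a cod-like life
# table over ages 3-12 with M = 0.2, and yearly temperature grids over
# 1948-2011 with warm/cold regimes on a coastline-masked 50-km grid.

.paper_years <- c(1932, 1952, 1962, 1977, 1980, 1989, 2000, 2008, 2012)
.default_pops <- c("wg_offshore", "wg_inshore", "ice_offshore", "ice_inshore")

#' Generate baseline spawning populations
#'
#' Balding-Nichols model: ancestral frequencies ~ U(0.1, 0.9); population
#' frequencies ~ Beta(p(1-F)/F, (1-p)(1-F)/F) so divergence is indexed by a
#' single F-like parameter; genotypes ~ Binomial(2, p_pop).
#'
#' @param n_pops number of populations
#' @param n_loci number of biallelic loci
#' @param fct target differentiation in (0, 0.5)
#' @param n_per_pop individuals per population
#' @param pop_names population labels
#' @param seed integer seed
#' @return list: `table` (a labelled [genotype_table()]), `freqs`
#'   (loci x populations true frequencies), `ancestral`
#' @export
gen_baselines <- function(n_pops = 4, n_loci = 81, fct = 0.1, n_per_pop = 50,
                          pop_names = NULL, seed = 1) {
  if (!is.finite(fct) || fct <= 0 || fct >= 0.5)
    .stop_fmt("fct must lie in (0, 0.5)")
  set.seed(seed)
  pop_names <- pop_names %||% paste0("P", seq_len(n_pops))
  anc <- runif(n_loci, 0.1, 0.9)
  shape <- (1 - fct) / fct
  freqs <- vapply(seq_len(n_pops), function(j)
    pmin(pmax(stats::rbeta(n_loci, anc * shape, (1 - anc) * shape),
              1e-3), 1 - 1e-3), numeric(n_loci))
  dimnames(freqs) <- list(paste0("L", seq_len(n_loci)), pop_names)
  calls <- do.call(rbind, lapply(seq_len(n_pops), function(j)
    matrix(rbinom(n_per_pop * n_loci, 2L, rep(freqs[, j], each = n_per_pop)),
           nrow = n_per_pop)))
  ids <- paste0(rep(pop_names, each = n_per_pop), "_",
                sprintf("%03d", sequence(rep(n_per_pop, n_pops))))
  gt <- genotype_table(calls, ids, rownames(freqs),
                       group_labels = rep(pop_names, each = n_per_pop))
  list(table = gt, freqs = freqs, ancestral = anc)
}

#' Generate a mixed-stock genotype series from a latent random walk
#'
#' Forward-simulates the composition model: a 3-D Gaussian random walk with
#' time-scaled innovations mapped to the 4-simplex; each year's individual
#' origins ~ Multinomial(N, p_t); genotypes drawn from the origin
#' population's true frequencies.
#'
#' @param freqs loci x 4 matrix of true baseline allele frequencies
#' @param sample_years sampling years (default the archive's 9 years)
#' @param N_per_year individuals per sampling year
#' @param sigma innovation SD per sqrt(year) (> 0 required; 0 allowed for a
#'   constant-proportion degenerate series)
#' @param alpha0 initial latent state (length 3)
#' @param stratum stratum label(s) recycled over individuals
#' @param dt_scale scale innovations with elapsed years
#' @param seed integer seed
#' @return list: `mixed` ([genotype_table()]), `metadata` (id, year,
#'   stratum, true_origin), `truth` (alpha_path, p_path, sigma, years)
#' @export
gen_mixture_series <- function(freqs, sample_years = .paper_years,
                               N_per_year = 100, sigma = 0.5,
                               alpha0 = c(0, 0, 0), stratum = "1D",
                               dt_scale = TRUE, seed = 1) {
  if (sigma < 0) .stop_fmt("sigma must be >= 0")
  stopifnot(ncol(freqs) == 4L)
  set.seed(seed)
  n <- length(sample_years)
  pops <- colnames(freqs) %||% paste0("P", 1:4)
  alpha <- matrix(0, n, 3)
  alpha[1L, ] <- alpha0
  if (n > 1L) {
    dt <- if (dt_scale) diff(sample_years) else rep(1, n - 1L)
    for (i in 2:n)
      alpha[i, ] <- alpha[i - 1L, ] + rnorm(3, 0, sigma * sqrt(dt[i - 1L]))
  }
  p <- simplex_transform(alpha)
  colnames(p) <- pops
  Ns <- rep_len(N_per_year, n)
  origin <- unlist(lapply(seq_len(n), function(i)
    sample.int(4L, Ns[i], replace = TRUE, prob = p[i, ])))
  year <- rep(sample_years, Ns)
  L <- nrow(freqs)
  calls <- matrix(rbinom(length(origin) * L, 2L,
                         prob = as.numeric(t(freqs)[origin, , drop = FALSE])),
                  nrow = length(origin))
  ids <- sprintf("M%04d", seq_along(origin))
  mixed <- genotype_table(calls, ids, rownames(freqs) %||% paste0("L", 1:L))
  metadata <- data.frame(id = ids, year = year,
                         stratum = rep_len(stratum, length(origin)),
                         true_origin = pops[origin])
  list(mixed = mixed, metadata = metadata,
       truth = list(alpha_path = alpha, p_path = p, sigma = sigma,
                    years = sample_years, populations = pops))
}

#' Generate a cod-like life table
#'
#' Von-Bertalanffy-type weight-at-age (cubed length curve), logistic
#' maturity and logistic selectivity over consecutive ages.
#'
#' @param recruit_age,max_age age span (default 3-12)
#' @param M natural mortality per year (scalar or per age)
#' @param w_inf asymptotic weight, kg
#' @param k von Bertalanffy growth coefficient
#' @param t0 von Bertalanffy age intercept
#' @param mat_a50,mat_slope maturity ogive midpoint and inverse slope
#' @param sel_a50,sel_slope selectivity ogive midpoint and inverse slope
#' @return a [life_table()]
#' @export
gen_life_table <- function(recruit_age = 3, max_age = 12, M = 0.2,
                           w_inf = 12, k = 0.15, t0 = 0,
                           mat_a50 = 5.5, mat_slope = 0.8,
                           sel_a50 = 4.5, sel_slope = 0.8) {
  ages <- recruit_age:max_age
  w <- w_inf * (1 - exp(-k * (ages - t0)))^3
  mat <- stats::plogis((ages - mat_a50) / mat_slope)
  sel <- stats::plogis((ages - sel_a50) / sel_slope)
  life_table(ages, M = rep_len(M, length(ages)), selectivity = sel,
             weight = w, maturity = mat)
}

#' Generate yearly temperature grids with climate regimes
#'
#' A latitudinal gradient (cold north) plus per-regime offsets plus seeded
#' cell noise, on a coastline-masked grid (land along the eastern margin)
#' with a designated southern-tip entry cell.
#'
#' @param years grid years (default 1948-2011)
#' @param nrow,ncol grid shape; row 1 is the northern edge
#' @param warm_years years belonging to the warm regime; the rest are cold
#' @param t_south,t_north mean temperature at the southern/northern edge, C
#' @param warm_offset,cold_offset regime offsets, C
#' @param noise_sd cell noise SD, C
#' @param cell_size_km cell edge, km
#' @param seed integer seed
#' @return list: `grids` (temperature [grid_series()]), `mask`,
#'   `entry_cell` (row, col at the southern tip), `warm_years`
#' @export
gen_environment <- function(years = 1948:2011, nrow = 20, ncol = 12,
                            warm_years = c(1948:1968, 1998:2011),
                            t_south = 4, t_north = 0,
                            warm_offset = 0.8, cold_offset = -0.8,
                            noise_sd = 0.3, cell_size_km = 50, seed = 1) {
  stopifnot(all(warm_years %in% years))
  set.seed(seed)
  # coastline: land occupies the eastern-most columns, wider in the north
  land_width <- round(seq(ncol * 0.4, ncol * 0.15, length.out = nrow))
  mask <- matrix(TRUE, nrow, ncol)
  for (r in seq_len(nrow))
    if (land_width[r] > 0) mask[r, (ncol - land_width[r] + 1L):ncol] <- FALSE
  lat_gradient <- seq(t_north, t_south, length.out = nrow)  # row 1 = north
  base <- matrix(rep(lat_gradient, ncol), nrow, ncol)
  layers <- lapply(years, function(y) {
    off <- if (y %in% warm_years) warm_offset else cold_offset
    base + off + matrix(rnorm(nrow * ncol, 0, noise_sd), nrow, ncol)
  })
  entry_col <- max(which(mask[nrow, ]))
  list(grids = grid_series(years, layers, mask, cell_size_km),
       mask = mask, entry_cell = c(nrow, entry_col), warm_years = warm_years)
}

#' Gaussian thermal suitability response
#'
#' @param temperature temperature in C
#' @param opt thermal optimum, C
#' @param breadth response SD, C
#' @return suitability in (0, 1\]
#' @export
thermal_suitability <- function(temperature, opt, breadth) {
  exp(-(temperature - opt)^2 / (2 * breadth^2))
}

#' Default thermal responses per population
#'
#' The West Greenland offshore population is colder-adapted and narrower;
#' the Iceland offshore population warmer with a broader range; the species
#' response pools them.
#' @return named list of (opt, breadth) pairs
#' @export
default_thermal_truth <- function() {
  list(species      = list(opt = 2.0, breadth = 1.8),
       wg_offshore  = list(opt = 1.0, breadth = 1.0),
       ice_offshore = list(opt = 3.0, breadth = 1.6))
}

#' Generate presence/absence occurrence records
#'
#' Cells and years are sampled uniformly over the sea; presence is
#' Bernoulli with probability logistic(a + b * log suitability) of the
#' record's population-specific thermal response, so sharp responses give
#' high class separation.
#'
#' @param env output of [gen_environment()]
#' @param truth named list of thermal responses (see
#'   [default_thermal_truth()]); a record's population is sampled uniformly
#'   from the non-species entries
#' @param n_records number of records
#' @param intercept,slope logistic link coefficients on log suitability
#' @param seed integer seed
#' @return occurrence data.frame: year, row, col, temperature, presence,
#'   population
#' @export
gen_occurrences <- function(env, truth = default_thermal_truth(),
                            n_records = 2000, intercept = 2, slope = 2,
                            seed = 1) {
  if (n_records <= 0) .stop_fmt("n_records must be positive")
  set.seed(seed)
  grids <- env$grids
  sea <- which(grids$mask, arr.ind = TRUE)
  ci <- sample.int(nrow(sea), n_records, replace = TRUE)
  yi <- sample.int(length(grids$years), n_records, replace = TRUE)
  temp <- vapply(seq_len(n_records), function(i)
    grids$layers[[yi[i]]][sea[ci[i], 1L], sea[ci[i], 2L]], numeric(1))
  pop_names <- setdiff(names(truth), "species")
  pop <- sample(pop_names, n_records, replace = TRUE)
  s <- vapply(seq_len(n_records), function(i) {
    tr <- truth[[pop[i]]]
    thermal_suitability(temp[i], tr$opt, tr$breadth)
  }, numeric(1))
  pr <- stats::plogis(intercept + slope * log(pmax(s, 1e-12)))
  data.frame(year = grids$years[yi], row = sea[ci, 1L], col = sea[ci, 2L],
             temperature = temp, presence = rbinom(n_records, 1L, pr),
             population = pop)
}

#' Label sea cells into latitudinal strata
#'
#' Bands of equal row span, named north to south (1A..1F by default),
#' emulating management divisions along a coast.
#'
#' @param mask logical sea mask (row 1 = north)
#' @param labels band labels from north to south
#' @return data.frame (row, col, stratum) over sea cells
#' @export
latitudinal_strata <- function(mask, labels = c("1A", "1B", "1C", "1D", "1E", "1F")) {
  sea <- which(mask, arr.ind = TRUE)
  band <- cut(sea[, 1L], breaks = seq(0.5, nrow(mask) + 0.5,
                                      length.out = length(labels) + 1L),
              labels = labels)
  data.frame(row = sea[, 1L], col = sea[, 2L], stratum = as.character(band))
}
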