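# Spawning-stock-biomass-per-recruit analysis and equilibrium fishing
# mortality. Survival follows N_{a+1} = N_a exp(-(F s_a + M_a)) with one
# recruit at the youngest age; SSB/R = sum N_a w_a m_a evaluated at the
# start of the year (an optional spawn-time fraction shifts it into the
# year). The fishing pattern is normalised so its mean over the reporting
# ages is 1, making the multiplier directly the reported mean F.

#' Normalise a life table's fishing pattern over reporting ages
#'
#' @param lt a [life_table()]
#' @param report_ages integer ages over which mean F is reported
#'   (default 5:12)
#' @return the life table with selectivity rescaled so
#'   mean(selectivity\[report_ages\]) == 1
#' @export
normalize_selectivity <- function(lt, report_ages = 5:12) {
  idx <- lt$age %in% report_ages
  if (!any(idx)) .stop_fmt("no reporting ages present in the life table")
  m <- mean(lt$selectivity[idx])
  if (m <= 0) .stop_fmt("fishing pattern is zero over the reporting ages")
  lt$selectivity <- lt$selectivity / m
  lt
}

#' Survivors-at-age per recruit
#'
#' @param F_mult fishing-mortality multiplier (>= 0) applied to the
#'   selectivity schedule
#' @param lt a [life_table()]
#' @return numeric vector of survivors per recruit, one per age;
#'   N\[recruit age\] = 1
#' @export
survivorship <- function(F_mult, lt) {
  if (!is.finite(F_mult) || F_mult < 0)
    .stop_fmt("F_mult must be a non-negative number")
  Z <- F_mult * lt$selectivity + lt$M
  n <- length(Z)
  N <- c(1, exp(-cumsum(Z[-n])))
  names(N) <- lt$age
  N
}

#' Spawning-stock biomass per recruit
#'
#' @inheritParams survivorship
#' @param spawn_frac fraction of the year's total mortality suffered before
#'   spawning (default 0: beginning-of-year SSB)
#' @return kg of spawning biomass produced per recruit
#' @export
ssb_per_recruit <- function(F_mult, lt, spawn_frac = 0) {
  N <- survivorship(F_mult, lt)
  if (spawn_frac > 0) {
    Z <- F_mult * lt$selectivity + lt$M
    N <- N * exp(-spawn_frac * Z)
  }
  sum(N * lt$weight * lt$maturity)
}

#' Solve for the equilibrium fishing mortality
#'
#' Finds the unique F at which SSB/R equals the replacement target, by
#' bracketed bisection on \[0, F_max\]. With the selectivity normalised over
#' `report_ages` the root is directly the mean F over those ages.
#'
#' @param target_ssbr replacement spawning biomass per recruit, kg
#' @param lt a [life_table()]
#' @param report_ages ages defining the reported mean F (default 5:12)
#' @param F_max upper bracket; targets needing F above this are treated as
#'   unattainable
#' @param spawn_frac passed to [ssb_per_recruit()]
#' @return F_eq, the mean fishing mortality over `report_ages`
#' @export
solve_feq <- function(target_ssbr, lt, report_ages = 5:12, F_max = 10,
                      spawn_frac = 0) {
  if (target_ssbr <= 0) .stop_fmt("target SSB/R must be positive")
  lt <- normalize_selectivity(lt, report_ages)
  s0 <- ssb_per_recruit(0, lt, spawn_frac)
  if (target_ssbr >= s0)
    .stop_fmt("stock cannot replace itself at F=0 (SSB/R(0) = %.4g kg <= target %.4g kg)",
              s0, target_ssbr)
  sF <- ssb_per_recruit(F_max, lt, spawn_frac)
  if (target_ssbr < sF)
    .stop_fmt("target SSB/R %.4g kg unattainable below F = %g", target_ssbr, F_max)
  root <- stats::uniroot(function(f) ssb_per_recruit(f, lt, spawn_frac) - target_ssbr,
                         lower = 0, upper = F_max,
                         tol = 1e-12 * max(1, target_ssbr))
  root$root
}

#' Replacement SSB per recruit from stock series
#'
#' Mean over years of SSB_t / R_(t + recruit_age): the average spawning
#' biomass that produced one recruit. Years with zero recruitment are
#' skipped with a warning.
#'
#' @param ssb data.frame (year, ssb) in kg (or any mass unit)
#' @param recruits data.frame (year, recruits)
#' @param recruit_age lag in years between spawning and recruitment
#'   (default 3)
#' @return mean SSB per recruit over the overlapping years
#' @export
replacement_ssbr <- function(ssb, recruits, recruit_age = 3) {
  stopifnot(all(c("year", "ssb") %in% names(ssb)),
            all(c("year", "recruits") %in% names(recruits)))
  ry <- recruits$year - recruit_age
  common <- intersect(ssb$year, ry)
  if (!length(common)) .stop_fmt("no overlapping years after lagging recruitment")
  s <- ssb$ssb[match(common, ssb$year)]
  r <- recruits$recruits[match(common + recruit_age, recruits$year)]
  zero <- r <= 0
  if (any(zero)) {
    warning(sprintf("skipping %d year(s) with zero recruitment", sum(zero)))
    s <- s[!zero]; r <- r[!zero]
  }
  if (!length(s)) .stop_fmt("no usable years (all recruitment zero)")
  mean(s / r)
}

#' Sensitivity of the equilibrium F to input errors
#'
#' `ssb_scale`: the factor k by which the replacement SSB/R target must be
#' over-estimated for the life table's F_eq to equal `reference_feq`
#' (solved directly from ssbr(reference_feq) = target/k).
#' `recruitment_scale`: identical factor interpretation, under-estimated
#' recruitment (the two act inversely on SSB/R). `growth_shift` /
#' `maturity_shift`: multiplies the weight (or maturity) schedule over a
#' grid of factors and reports the F_eq response curve.
#'
#' @param lt a [life_table()]
#' @param target_ssbr baseline replacement target, kg
#' @param reference_feq reference equilibrium F to match (scale modes)
#' @param mode one of ssb_scale, recruitment_scale, growth_shift,
#'   maturity_shift
#' @param factors multiplier grid for the shift modes
#' @param report_ages reporting ages
#' @return for scale modes: list(k, curve); for shift modes: data.frame
#'   (factor, feq)
#' @export
sensitivity_scan <- function(lt, target_ssbr, reference_feq = NULL,
                             mode = c("ssb_scale", "recruitment_scale",
                                      "growth_shift", "maturity_shift"),
                             factors = seq(0.5, 1.5, by = 0.1),
                             report_ages = 5:12) {
  mode <- match.arg(mode)
  if (mode %in% c("ssb_scale", "recruitment_scale")) {
    if (is.null(reference_feq)) .stop_fmt("reference_feq required for %s", mode)
    ltn <- normalize_selectivity(lt, report_ages)
    s_ref <- ssb_per_recruit(reference_feq, ltn)
    if (s_ref <= 0) .stop_fmt("reference F_eq unattainable")
    k <- target_ssbr / s_ref
    if (k < 1 / 100 || k > 100)
      .stop_fmt("implied factor k = %.3g outside [0.01, 100]", k)
    kgrid <- sort(unique(c(1, k, pretty(c(1, k), 8))))
    kgrid <- kgrid[kgrid > 0 & target_ssbr / kgrid < ssb_per_recruit(0, ltn)]
    curve <- data.frame(
      k = kgrid,
      feq = vapply(kgrid, function(kk)
        solve_feq(target_ssbr / kk, lt, report_ages), numeric(1)))
    list(mode = mode, k = k, curve = curve)
  } else {
    col <- if (mode == "growth_shift") "weight" else "maturity"
    feq <- vapply(factors, function(f) {
      lt2 <- lt
      lt2[[col]] <- if (col == "maturity") pmin(1, lt[[col]] * f)
                    else lt[[col]] * f
      s0 <- ssb_per_recruit(0, normalize_selectivity(lt2, report_ages))
      if (target_ssbr >= s0) return(NA_real_)
      solve_feq(target_ssbr, lt2, report_ages)
    }, numeric(1))
    data.frame(factor = factors, feq = feq)
  }
}

#' SSB-per-recruit curve over a fishing-mortality grid
#'
#' @param lt a [life_table()]
#' @param F_grid fishing mortalities (mean over `report_ages`)
#' @param report_ages reporting ages
#' @return data.frame (F, ssbr)
#' @export
ssbr_curve <- function(lt, F_grid = seq(0, 2, by = 0.01), report_ages = 5:12) {
  ltn <- normalize_selectivity(lt, report_ages)
  data.frame(F = F_grid,
             ssbr = vapply(F_grid, ssb_per_recruit, numeric(1), lt = ltn))
}
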