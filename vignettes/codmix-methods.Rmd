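---
title: "Methods behind codmix: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind codmix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`codmix` re-implements, as reusable and tested components, a complete
mixed-stock analysis of a long-exploited Atlantic cod fishery: who was
caught (genetic stock identification), how the catch composition moved
through eight decades (a compositional state-space model), which fishing
pressure each population could sustain (per-recruit equilibrium analysis),
and how climate shaped the seascape connecting spawning areas to fishing
grounds (ensemble habitat modelling, least-cost connectivity, regime
detection). The original archived-otolith data are not publicly deposited,
so everything here is exercised against a synthetic-data module with known
ground truth; this vignette states each model, its defaults, and the design
choices that were genuinely open.

## 1. Genetic stock identification

**Genotype model.** Individuals carry biallelic SNP genotypes stored as
reference-allele dosage in {0, 1, 2}. Baseline spawning populations supply
per-locus allele counts `x` (reference copies) out of `n` typed gene
copies. Missing calls are expected (archived DNA is degraded) and are
excluded per locus, not per individual, so partially typed fish remain
usable.

**Bayesian assignment.** The genotype likelihood is the compound-Dirichlet
(Beta-binomial) posterior predictive with a symmetric Dirichlet prior of
1/2 per allele — the published default of the Rannala–Mountain approach.
With `c_ref = x + 1/2`, `c_alt = n - x + 1/2`, `C = n + 1`:

- P(hom ref) = c_ref (c_ref + 1) / (C (C + 1))
- P(het) = 2 c_ref c_alt / (C (C + 1))
- P(hom alt) = c_alt (c_alt + 1) / (C (C + 1))

These sum to one exactly for any (x, n) — an identity the test suite
asserts over random draws. Posteriors over the K = 4 populations use equal
priors and max-subtracted softmax. No leave-one-out correction is applied:
mixed-stock individuals are never members of the baseline.

**Exclusion test.** For each population, `n_sim` individuals (default
10000, significance 0.01) are simulated from the posterior-mean allele
frequencies; the p-value is `(1 + #{sim <= obs}) / (n_sim + 1)`, the +1
correction avoiding exact zeros. Under the null the p-values are uniform
up to discreteness, which the calibration test checks by KS at a
desk-scale `n_sim = 1000`.

**DAPC.** Principal components are computed on the mean-imputed
allele-frequency matrix (dosage/2); linear discriminant axes are fitted on
the retained PCs (`MASS::lda`, which standardises within-group covariance
to the identity). Defaults: as many PCs as explain 90% of variance capped
at n/3, and K−1 discriminant axes. Membership of a projected individual is
`exp(-d_k^2/2)` to each group centroid, normalised — i.e. a Gaussian kernel
with identity covariance and equal priors in discriminant space. The
reference implementation delegates this step to `predict.dapc()` without
printing formulas; the kernel above is the standard choice consistent with
LDA's spherical within-group geometry.

**Consensus.** An individual is retained only when *both* methods put
strictly more than 0.90 posterior mass on the *same* population; everything
else is `DISCARDED`. The threshold is strict (`> 0.90`, not `>=`).

## 2. Catch composition through time

At sampling time `t_i` the `N_i` assigned fish follow a multinomial over
the four populations with probability vector `p_t`. The latent state is a
3-vector `alpha_t` following a Gaussian random walk,
`alpha_t = alpha_{t-1} + eps_t`, `eps_t ~ N(0, sigma^2 dt I)`, mapped to
the 4-simplex by the additive-logistic transform with category 4 as
reference — the unique standard map satisfying the stated simplex
constraints with a 3-D state.

Design choices:

- **Elapsed-time scaling.** Sampling years are irregular (gaps of 3 to 20
  years); innovations scale with `dt` so a 20-year gap carries 20 times
  the prior variance of a 1-year gap. A flag (`dt_scale = FALSE`) restores
  per-observation indexing.
- **sigma estimation.** The path is a random effect: `sigma` maximises the
  Laplace-approximated marginal likelihood (joint mode plus half
  log-determinant of the curvature), with the path re-maximised at each
  candidate `sigma` by BFGS with analytic gradients. Joint maximisation
  over `(alpha, sigma)` is degenerate (`sigma -> 0`) and is not offered.
- **Diffuse start.** `alpha_1` carries no prior term, so the 1932
  composition is informed by its sample alone.
- **Bands.** 90% credible bands come from 4000 seeded Gaussian draws
  around the mode (covariance = inverse curvature), mapped through the
  simplex transform.
- **A non-invariance worth knowing.** The isotropic innovation prior is
  *not* invariant to changing the reference category: relabelling category
  4 with category 1 transforms the state linearly with `A A' != I`, so
  fitted paths can differ slightly. Permutations of the three
  non-reference categories are exactly equivariant, and that is what the
  tests assert.

Biomass apportionment multiplies fitted (or interpolated) proportions with
a total-biomass series of age-3+ fish. Interpolation uses the
random-walk smoother's conditional mean — time-weighted linear
interpolation of the flanking states (a Brownian-bridge mean) — and
refuses to extrapolate more than 5 years beyond the sampled span.

## 3. Per-recruit equilibrium fishing mortality

Survival follows `N_{a+1} = N_a exp(-(F s_a + M_a))` from one recruit at
the youngest age (3 by default, no plus-group beyond age 12); spawning
biomass per recruit is `sum N_a w_a m_a`, evaluated at the start of the
year (an optional `spawn_frac` shifts spawning into the year; the default
0 reflects that no spawning timing is stated for the original analysis).
The fishing pattern is normalised so its mean over the reporting ages
(5–12) is 1, which makes the root of `ssbr(F) = target` directly the
reported mean `F_(5-12)`. The root is found by bracketed bisection on
[0, 10]; `ssbr` is strictly decreasing and convex there, so the root is
unique. The sensitivity mode `ssb_scale` answers "by what factor k must
the replacement target have been overestimated for `F_eq` to reach a
reference value" — solved from `ssbr(F_ref) = target/k` and verified
against a grid scan in the tests.

The published equilibrium points (`F_(5-12)` of 0.14 for West Greenland
offshore at SSB/R = 5.56 kg, 0.82 for Iceland offshore at 1.06 kg) rest on
age schedules from external stock-assessment sources that are not
deposited; the package cannot reproduce those exact numbers. For scale:
the package's synthetic cod-like life table (below) — fixed before any
equilibrium was computed — yields `F_eq(5.56) = 0.139` and
`F_eq(1.06) = 0.864` as computed by `solve_feq()` in the worked example,
showing the machinery lands in the published range on standard cod
schedules. Tests assert only solver properties and the productivity
ordering, never the printed values.

## 4. Habitat suitability ensemble

Four techniques, each predicting presence probability from temperature
(depth optional):

| member | form | fixed defaults |
|---|---|---|
| GLM | logistic, linear + quadratic terms | — |
| GAM | logistic on natural cubic splines | 4 df per predictor, unpenalised |
| GBM | gradient boosting, Bernoulli loss | 1000 trees, depth 3, shrinkage 0.01, bag 0.5 |
| RF | probability forest of deep CART trees | 500 trees, depth ≤ 12, min leaf 5 |

The source analysis names the four techniques but none of their
hyperparameters; the values above are conventional SDM settings and all
are configurable. The GBM leaf update uses the shrunken gradient step
(scaled by 4, the inverse Bernoulli variance at p = 0.5) rather than a
per-leaf Newton step; only the probability ranking matters for AUC-based
evaluation. The tree learner itself is a weighted exact-split CART in
C++, shared by GBM and RF, with node-level feature subsampling driven by
R's RNG so every fit is reproducible under a seed.

Absences are down-weighted to `n_presence / n_absence` so the weighted
prevalence is exactly 0.5. Evaluation: 10 seeded random 80/20 splits per
technique, AUC (rank-based, ties at half weight) on the held-out 20%;
degenerate splits (a single-class held-out set) are redrawn. Final members
are refit on all records and the ensemble prediction is their unweighted
mean, clipped to [0, 1]. Hindcasting applies the ensemble to every sea
cell of every yearly grid; out-of-range cells are predicted anyway but
counted and reported as extrapolations.

## 5. Seascape connectivity and regimes

Cell traversal cost is `max(1 - suitability, 0.01)`: continuous weighting,
no suitability threshold (a threshold option exists). The floor keeps
fully suitable water traversable at positive cost. Distances accumulate
over the 8-neighbour raster graph with edge weight = mean of the endpoint
costs × step length (1 or √2 cells × 50 km); Dijkstra runs on an igraph
representation, and a branch-and-bound enumeration over all simple paths
serves as the independent oracle on small grids. The static baseline is
the same graph with unit cost. A stratum's distance is the mean over its
sea cells, since the per-division aggregation used originally is unstated.

The proportion–distance model is a binomial GLM of the Iceland-offshore
fraction per stratum on distance, with deviance R²
(`1 - residual/null deviance`) and a Wald-z slope test; complete
separation triggers a lightly ridge-penalised IRLS fallback, flagged in
the result.

**Regime detection (STARS).** The sequential t-test algorithm in its basic
form: threshold `diff = t_{1-sig/2, 2l-2} sqrt(2 sigma_l^2 / l)` with
`sigma_l^2` the average variance of consecutive l-year windows; a value
beyond the current regime mean ± diff opens a candidate shift, confirmed
when the cumulative regime-shift index over the following l years stays
positive; the running regime mean uses at most the last l in-regime
values. No red-noise prewhitening and no Huber outlier weighting (both
extensions postdate the basic method and the source analysis specifies
only cut-off 5 years, significance 0.1). Reported regime means are full
segment means of the confirmed partition. Interpreting false alarms:
every tested year is one sequential test at level `sig`, so the
calibration test bounds the *per-test* confirmed-shift rate on white noise
(measured ≈ 0.035 at sig = 0.1); the *per-series* any-detection
probability on a 40-year series is much larger (≈ 0.68) — the familiar
multiplicity of sequential detection, inherent to the basic algorithm.

## 6. The synthetic world

The generators default to the shape of the original archive and state the
package's "known truth":

- **Baselines**: 4 populations × 81 biallelic SNPs, 50 individuals per
  population, Balding–Nichols divergence at `F = 0.1` (ancestral
  frequencies U(0.1, 0.9)) — differentiation indexed by the same F-style
  parameter the panel was selected on.
- **Mixture series**: 9 sampling years (1932, 1952, 1962, 1977, 1980,
  1989, 2000, 2008, 2012), ~100 fish per year, latent random walk with
  `sigma = 0.5` per √year and elapsed-time scaling, equal initial
  proportions.
- **Life table**: ages 3–12, M = 0.2, von-Bertalanffy-type weights
  (`w_inf` 12 kg, k 0.15), logistic maturity (a50 5.5) and selectivity
  (a50 4.5) — standard northern-cod magnitudes.
- **Environment**: 1948–2011 yearly 20 × 12 grids of 50-km cells, cold
  north / warm south gradient (0–4 °C), warm regimes 1948–1968 and
  1998–2011 offset ±0.8 °C, cell noise SD 0.3 °C, land along the eastern
  margin with a designated southern-tip entry cell.
- **Occurrences**: cells × years sampled uniformly at sea; presence is
  Bernoulli with a logistic link on the log of a Gaussian thermal
  response. The West Greenland offshore response is colder and narrower
  (optimum 1 °C, breadth 1) than Iceland offshore (3 °C, breadth 1.6),
  reproducing the reported ordering of occupied-temperature summaries.

What the synthetic world does *not* emulate: linkage between loci,
genotyping error, spatial autocorrelation of trawl stations, ocean
currents (connectivity is isotropic), and observation effort varying by
decade. A green test therefore establishes that the estimators recover a
truth of this structure at these sizes — not that the historical data
would yield the published numbers, which depend on undeposited inputs.

## 7. Numerical choices

- State-space inner optimisation: BFGS from a zero start with analytic
  gradient, relative tolerance 1e-12, one automatic restart; outer
  `sigma` search by Brent on log-sigma in [1e-3, 10], tolerance 1e-4.
- Bisection for `F_eq`: tolerance 1e-12 × target on the SSB/R scale,
  upper bracket F = 10 (targets needing more are "unattainable").
- Cost floor 0.01 on the cost surface; suitability floored at 1e-6 before
  the log in the mean-suitability series.
- Monomorphic loci have F_CT defined as 0; consensus ties at exactly the
  threshold are exclusive (strict >).
- Seeds: one master seed; each stage derives its own via a fixed integer
  hash (`derive_seed`), kept below 2^31.

## 8. Known limitations

- The Laplace/empirical-Bayes treatment of `sigma` is a point estimate;
  band coverage is approximate (the recovery test measures ≈ 88% for
  nominal 90% bands under the default scenario).
- The GBM member is calibrated only up to ranking, as noted above.
- Least-cost distances depend on the raster resolution and the
  8-neighbour metric; no correction for the ~8% octile-distance bias of
  grid paths is applied (it cancels in model comparisons on the same
  grid).
- The ridge fallback under complete separation gives finite but
  shrinkage-biased slopes; it exists to keep pipelines running, and flags
  itself.
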