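# codmix

Mixed-stock dynamics of Atlantic cod (*Gadus morhua*): an R package for
tracking which genetically distinct spawning populations a fishery
actually harvested, how that composition moved through decades, what
fishing pressure each population could sustain, and how ocean climate
shaped the connectivity between spawning areas and fishing grounds.

It is written for fisheries geneticists and quantitative ecologists who
have (or simulate) four kinds of inputs: biallelic SNP genotypes for
baseline spawning populations and mixed-stock catch samples, stratified
catch counts and total-biomass series, age-structured life tables, and
yearly gridded temperature fields.

## What it computes

- **Genetic stock identification** — compound-Dirichlet (Rannala–Mountain)
  genotype likelihoods with Monte-Carlo exclusion tests, DAPC membership
  probabilities, and the dual-method consensus rule (both posteriors
  > 0.90 for the same population, otherwise discarded); F_CT-based locus
  ranking for panel reduction.
- **Catch composition over time** — a state-space model with multinomial
  observations of a latent 3-D Gaussian random walk mapped to the
  4-simplex by the additive-logistic transform
  (p_k = e^{α_k} / (1 + Σ_j e^{α_j})); innovation SD σ estimated by
  Laplace-approximated marginal likelihood; credible bands; biomass
  apportionment.
- **Per-recruit analysis** — survivorship N_{a+1} = N_a e^{−(F s_a + M_a)}
  from one recruit, SSB/R = Σ N_a w_a m_a, the equilibrium fishing
  mortality F_eq solving SSB/R(F) = replacement target, and sensitivity
  scans (e.g. the SSB-overestimation factor).
- **Habitat suitability** — a four-member ensemble (quadratic logistic
  GLM, spline GAM, gradient-boosted trees, random forest; the tree
  learners are built in, no external ML dependency) with absence
  down-weighting, repeated 80/20 AUC evaluation, and yearly hindcasting.
- **Seascape connectivity** — suitability-weighted least-cost-path
  distances (cost = 1 − suitability) across the sea grid, static
  shortest-sea-distance baselines, binomial GLMs of catch proportion
  against distance with deviance R², and STARS regime-shift detection.
- **Synthetic data** — generators for every input above with known ground
  truth (Balding–Nichols baselines, forward-simulated composition walks,
  cod-like life tables, regime-structured temperature grids, thermal-niche
  occurrence records), so the full pipeline is testable end to end.

## Worked example

```r
library(codmix)

base <- gen_baselines(n_pops = 4, n_loci = 81, fct = 0.1,
                      n_per_pop = 50, seed = 1)
mix  <- gen_mixture_series(base$freqs, N_per_year = 100, sigma = 0.5, seed = 2)

asg <- assign_individuals(mix$mixed, base$table, threshold = 0.90,
                          n_sim = 0, seed = 1)
tab <- tabulate_composition(asg, mix$metadata)
tab$retention
#> [1] 0.912

fit <- fit_state_space(tab$counts, seed = 1)
fit
#> composition_series: 9 times (1932-2012), sigma = 0.537
#>       year    P1    P2    P3    P4
#>  [1,] 1932 0.262 0.223 0.305 0.211
#>  [2,] 1952 0.005 0.072 0.868 0.055
#>  [3,] 1962 0.002 0.013 0.960 0.025
#>  [4,] 1977 0.000 0.001 0.997 0.002
#>  ...
```

91% of simulated fish pass the dual >0.90 consensus; the fitted random-walk
SD (0.537) recovers the generating value (0.5), and the fitted proportions
track this replicate's drift of the catch toward population P3.

```r
lt <- gen_life_table()            # synthetic cod-like schedules, ages 3-12
solve_feq(5.56, lt)               # F_eq at a 5.56 kg replacement SSB/R
#> [1] 0.139
solve_feq(1.06, lt)               # F_eq at 1.06 kg
#> [1] 0.864
sensitivity_scan(lt, 5.56, reference_feq = solve_feq(1.06, lt),
                 mode = "ssb_scale")$k
#> [1] 5.25
```

A population needing 5.56 kg of spawners per recruit tolerates only
F ≈ 0.14, one needing 1.06 kg tolerates F ≈ 0.86 — so any fishing
mortality between the two sustains the productive population while
collapsing the vulnerable one; the replacement target would have to be
overestimated more than five-fold to close that gap. (These schedules are
synthetic stand-ins; see the methods vignette.)

The full synthetic pipeline (simulate → assign → compose → perrecruit →
sdm → seascape, with a hashed manifest) runs via

```r
run_pipeline(pipeline_config(out_dir = "out", seed = 1))
```

or from the shell: `inst/exec/codmix pipeline --config config.yaml`.

## Documentation

`vignettes/codmix-methods.Rmd` describes the models, priors, defaults,
numerical tolerances, the synthetic world and its limits, and every design
decision taken where the underlying analysis left choices open.
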