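# coralpp

Spatial point process analysis of sessile benthic communities from
annotated seabed photographs.

Solitary cup corals (and other sessile fauna) cannot move after
settlement, so the positions of adults inside a photographic sampling
frame record the processes that placed them there — substrate preference,
dispersal-limited recruitment around a parent, or nothing at all (complete
spatial randomness). `coralpp` provides the complete inferential pipeline
for a two-morph system observed in 1.75 m × 1.75 m sample boxes (3.06 m²
per site), for ecologists analysing such annotation data and for
methodologists who need a fully testable, simulation-backed
implementation.

## What it computes

For each morph's point pattern (n ≥ 30):

* **Pair correlation function** ĝ(r) on a 0.1 cm grid to 50 cm,
  Epanechnikov kernel of half-width 5 cm, translation or isotropic edge
  correction, divisor-d with boundary renormalisation so that E ĝ(r) = 1
  under CSR at every radius.
* **Four candidate models** — CSR; heterogeneous Poisson (HP) over three
  substrate categories (boulder / flat rock / debris-filled gulley);
  Thomas cluster (TC) with PCF
  g(r) = 1 + exp(−r²/4σ²)/(4πκσ²); and a substrate-thinned Thomas (HTC) —
  with TC/HTC fitted by minimum contrast (q = 1/4) against the
  identically kernel-smoothed theoretical curve.
* **Monte Carlo envelopes and Diggle's goodness-of-fit** p_d: pointwise
  trimmed envelopes (study fidelity 9999 simulations, 500 trimmed per
  tail) and the leave-one-out rank statistic, with TC scored on restricted
  10 cm and 20 cm ranges.
* **Reproductive diagnostics** from the fitted μ: offspring per non-empty
  cluster μ/(1−e^(−μ)) and cluster-membership probability 1−e^(−μ).
* **Community summaries**: densities, Bray–Curtis/average-linkage grouping
  into orange-dominant / pink-dominant / mixed, per-site same-morph
  nearest-neighbour medians, Wilcoxon rank-sum comparisons.
* **A synthetic-study generator** (`simulate_study()`) reproducing the
  three community types, so the whole pipeline is testable offline.

## Worked example

```r
library(coralpp)
win <- study_window()                      # 175 x 175 cm sample box
pat <- simulate_thomas(win, kappa = 0.002, sigma = 2, mu = 2.5,
                       seed = 42, morph = "orange")
#> Point pattern: 160 points (orange) in 175 x 175 cm window

fit <- fit_model(pat, "tc")
summary(fit)
#> Model tc (n = 160)
#>   lambda    kappa    sigma       mu
#> 0.005224 0.002843 1.887129 1.837410
#>   offspring per non-empty cluster: 2.1854
#>   P(individual in a cluster): 0.8408
```

The fit recovers the generating parameters (κ = 0.002 parents/cm²,
σ = 2 cm, μ = 2.5) to within the sampling error of a single 160-point
pattern: a parent density of ~0.0028/cm², a dispersal scale of ~1.9 cm,
and ~2.2 settled offspring in a typical non-empty cluster, with an 84%
chance that a random individual has at least one cluster sibling.

```r
env <- mc_envelope(fit_model(pat, "csr"), n_sims = 199, seed = 1)
diggle_gof(env)
#> Diggle GoF (csr model): u_obs = 87.93 over (0.1, 50.0) cm, p_d = 0.0050 (199 sims)

diggle_gof(mc_envelope(fit, n_sims = 199, seed = 2), r_range = c(0.1, 10))
#> Diggle GoF (tc model): u_obs = 0.5076 over (0.1, 10.0) cm, p_d = 0.8250 (199 sims)
```

Complete spatial randomness is rejected at the floor of the rank test
(p_d = 1/200 at 199 simulations) while the Thomas cluster model fits well
(p_d = 0.83): the pattern is recruitment-driven, not random. Scale
classification against the CSR envelope shows where:

```r
head(classify_scales(pair_correlation(pat), env), 3)
#>   r_lo r_hi      label
#> 1  0.1  8.6 aggregated
#> 2  8.7  9.8        CSR
#> 3  9.9 17.9 segregated

median(nn_distances(pat))
#> [1] 2.498089
```

Whole studies run through `simulate_study()` → `run_study()`, which
applies the ≥30-point rule, assigns community groups, fits and scores all
models per pattern, and writes summary/curve CSVs, a manifest and figures.

## Documentation

The methods vignette (`vignettes/coral-spatial-analysis.Rmd`) documents
the estimator conventions, the kernel-matched minimum contrast, the p_d
conventions, the synthetic generator's defaults and what they do and do
not emulate, and known limitations.
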