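# treelim

Bayesian limitation modelling of pantropical tree cover.

Explaining tropical tree cover where rainfall is intermediate is hard:
fire, rainfall seasonality, heat stress, windthrow and human land use all
co-vary, and attributing cover loss to any one of them requires a
framework that can remove each influence while holding the others in
place, with honest uncertainty. `treelim` implements such a framework
for ecologists and vegetation modellers: fractional tree cover on a
0.5° tropical grid is modelled as

```
TC = TCmax * prod_c f( k_c * (X_c - x0_c) ),    f(x) = 1 / (1 + e^-x)
```

a maximum cover multiplied by logistic limitations from five controls —
log-transformed mean annual precipitation (MAP), mean annual temperature
(MAT), shortwave radiation (SW), a composite environmental stress index
S (burnt area, rainfall seasonality, heat, wind) and a composite
human-pressure index LU (population density, urban, cropland, pasture):

```
X_c = sum_i v_i * x_i^p_i / sum_i v_i        (v_1 = 1; powers fitted for S)
```

The 23 free parameters are fitted to fractional-cover observations with
a zero-inflated logit-normal likelihood — a point mass at zero cover
with probability `(1 - TC^2)(1 - p0)`, plus a normal on the logit scale
with s.d. `sigma` — by adaptive Metropolis–Hastings MCMC. From the
posterior ensemble the package computes the downstream impact calculus:
absolute and relative impacts of each control and factor (by removal),
limitation and sensitivity maps, pairwise impact-difference
probabilities (Bhattacharyya coefficient), per-unit response curves,
+1% burnt-area and fire-without-humans counterfactuals (always paired by
posterior member), area-weighted biome tables and cover histograms.
A synthetic-data generator (spatially correlated drivers with a
configured fire–seasonality correlation, forward-simulated observations
with known parameters) makes the whole pipeline testable without any
external downloads; rainfall-seasonality metrics (MADD, MDDM, MADM,
MConc) and NetCDF I/O with bilinear regridding and tropics masking round
out the toolkit.

## Worked example

Generate the default synthetic study (50×50 cells, ~2,000 land cells),
fit on a 500-cell training split, and summarize fire impact by biome:

```r
library(treelim)
cfg     <- syntheticConfig(seed = 1)
drivers <- generateDrivers(cfg)
obs     <- simulateObservations(drivers, defaultTrueParams(), seed = 2)
split   <- splitTrain(obs, fraction = 0.25, seed = 3)
ens     <- samplePosterior(split$train, drivers,
                           config = chainConfig(nChains = 4, nIter = 2000,
                                                seed = 4))
ens
#> PosteriorEnsemble: 40 members x 23 parameters
#>   logLik range -544.0..-529.2
#>   mean acceptance 0.24
round(rhat(ens)[c("tc_max", "sigma", "p0")], 3)
#> tc_max  sigma     p0
#>  1.051  1.007  1.001

pc <- predictiveInterval(drivers, ens, obs = split$validation, seed = 5)
pc$pitCoverage
#> [1] 0.808

biomes <- generateBiomeMap(drivers)
tab <- aggregateByBiome(drivers, ens, targets = c("S", "burnt_area"),
                        biomes = biomes)
subset(tab, target == "burnt_area")
#>                          biome     target area_q10 rel_q10 area_q90 rel_q90
#> 8                   wet forest burnt_area    1.132   0.606    12.29     6.3
#> 9  summergreen forest/woodland burnt_area    5.065   8.681    17.17    25.4
#> 10                  dry forest burnt_area    1.704   5.699     6.08    17.7
#> 11           savanna/grassland burnt_area    4.235   6.669    17.50    22.2
#> 12                      desert burnt_area    0.178   2.564     1.35    14.9
#> 13               mediterranean burnt_area    0.528   1.740     3.54    10.1
#> 14                       (all) burnt_area   12.608   3.332    54.40    13.0
```

Reading the output: the chains converge for the key parameters
(split-Rhat near 1), 80.8% of held-out cells fall inside the 10–90%
posterior-predictive band (nominal 80%), and fire reduces relative tree
cover tropics-wide by 3.3–13.0% (10–90% bounds across posterior
members) on this synthetic fixture, with the largest effect in the
seasonal, fire-prone biomes — the same qualitative structure the
framework is designed to resolve on real drivers. `area` columns are in
equator-normalized cell-area units; `rel` columns are percent of the
cover that would exist without the factor.

A file-based pipeline with the same stages is available as
`runSimulate()` / `runFit()` / `runImpacts()` over a YAML config (thin
CLI wrapper in `inst/scripts/treelim.R`).

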