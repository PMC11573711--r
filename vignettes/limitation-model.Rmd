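---
title: "A Bayesian limitation model of tropical tree cover"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Bayesian limitation model of tropical tree cover}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(treelim)
```

## The model

`treelim` models fractional tree cover on a 0.5-degree tropical grid as a
maximum attainable cover multiplied by logistic limitations from five
controls:

$$TC = TC_{max} \prod_{c} f\!\big(k_c\,(X_c - x_{0,c})\big), \qquad
f(x) = \frac{1}{1 + e^{-x}}$$

The controls are mean annual precipitation (MAP, entered as
$\log(\mathrm{MAP} + 1/n_\mathrm{cells})$ so cover vanishes with
rainfall), mean annual temperature (MAT), shortwave radiation (SW), a
composite environmental stress index $S$ and a composite human-pressure
index $LU$. MAT and SW are multiplied together and reported as a single
"energy" control. $x_{0,c}$ is the control value at which cover halves
and $k_c$ the curve steepness, stored as a positive magnitude with the
sign supplied by the control specification: positive for MAP, MAT and SW,
negative for the suppressive $S$ and $LU$.

The composite indices combine scaled factors with fitted weights, and —
for stress only — fitted powers that let one extra degree of heat matter
more at high temperature than at low:

$$X_c = \frac{\sum_i v_i\, x_i^{\,p_i}}{\sum_i v_i}, \qquad v_1 \equiv 1$$

Stress combines burnt area, rainfall seasonality, heat (maximum
temperature of the warmest month) and wind; human pressure combines
population density, urban, cropland and pasture fractions, all with unit
powers. The first factor of each composite is the reference with weight
fixed at one; non-fractional drivers (MTWM, wind speed, population
density) are min-max scaled onto $[0,1]$ with bounds stored alongside the
data, because exponential(1) priors on weights and powers presuppose
commensurate factor scales. With five midpoints, five steepnesses, six
free weights, four stress powers, $TC_{max}$, the observation s.d.
$\sigma$ and the zero-inflation parameter $p_0$, the free parameter count
is

```{r}
countFreeParameters(defaultControlSpec())
```

## Observation model

Satellite-style fractional cover is approximately normal under a logit
transform, with an excess of exact zeros. The likelihood is therefore a
zero-inflated logit-normal: a cell observes exactly zero with probability
$(1 - TC^2)(1 - p_0)$, and otherwise a value whose logit is normal with
mean $\mathrm{logit}(TC)$ and s.d. $\sigma$. Observed and predicted
cover are clipped to $[10^{-6}, 1 - 10^{-6}]$ before the logit so data
containing exact 0 or 1 stay finite, and the logit Jacobian is omitted
because it is constant in the parameters and leaves the posterior shape
unchanged.

## Rainfall seasonality metrics

Four interchangeable proxies, all on $[0,1]$: MADD (fraction of days
below the 0.1 mm/day wet-day threshold), MDDM (dry-day fraction of the
driest month), MADM (minimum monthly precipitation times 12 over annual
precipitation; 1 means perfectly uniform) and MConc (the length of the
vector sum of monthly rainfall placed around the annual cycle, over total
rainfall). Month angles sit at month mid-points, $2\pi(m - 0.5)/12$; any
fixed convention leaves MConc invariant under cyclic rotation of the
monthly vector. Two conventions are worth stating explicitly: MDDM picks
the month with the *largest* dry-day fraction (the "driest month" in the
sense of fewest wet days; the literal smallest-fraction reading is kept
behind `driest = FALSE` for comparison), and cells with zero annual
rainfall return 0 for every metric — such cells are already driven to
zero cover by the precipitation control.

## Priors and inference

Priors are deliberately wide: uniform $[0,1]$ for $TC_{max}$ and $p_0$,
exponential with rate 1 for weights, powers, steepness magnitudes and
$\sigma$ (bounding steepness at zero; the sign lives in the control
specification), and normal priors for midpoints with mean and s.d. equal
to half the range of the corresponding control index (0.5 for the
fraction-valued composites). The $\sigma$ and $p_0$ priors are our
assumption; the error terms are part of the parameter vector but carry no
stated prior in the framework we implement.

Sampling is adaptive Metropolis–Hastings. Bounded parameters are
proposed on transformed scales (log for positive, logit for
unit-interval, with Jacobian corrections). A Laplace approximation of
the posterior (BFGS mode search plus inverse Hessian on the transformed
scale) is computed first and does two jobs: chains are initialized
overdispersed *around the mode* rather than at the prior centre — with
only a thousand warmup iterations, chains started in the prior's bulk
are still drifting toward the typical set when sampling begins, which
inflates split-Rhat — and the curvature seeds the initial proposal
scales. Each sweep then updates the 23 parameters one at a time
(per-control caching of the limitation-factor columns makes a
single-parameter update cheap), with per-parameter scales adapted toward
~0.234 acceptance during warmup, followed by a battery of full-vector
moves aimed at the ridge along which $TC_{max}$ trades off against the
steepness and midpoint parameters: joint random-walk proposals from a
covariance pooled across chains mid-warmup, heavy-tailed multivariate-t
independence proposals around the Laplace mode (each acceptance is a
complete decorrelation), and differential-evolution moves whose
difference vectors, drawn from the fixed pooled warmup history, track
the ridge's curvature. The kernel is frozen for the sampling phase. The
warmup half of each chain is discarded; ten evenly spaced members per
chain are retained with their log-likelihoods, and full post-warmup
chains are kept for split-Rhat diagnostics.
Ensembles fitted to different datasets or seasonality metrics are
combined by bootstrap with selection probability proportional to the
softmax of member log-likelihoods.

The default test-scale configuration is 4 chains of 2,000 iterations on
500 training cells (a 25% split of the ~2,000-cell synthetic fixture,
mirroring the 20%-for-training design at a desk-scale sample size);
the full-scale protocol of 10 chains of 10,000 iterations is a
`chainConfig()` away. At the test scale, split-Rhat for $TC_{max}$,
$\sigma$ and $p_0$ is typically 1.01–1.08; weakly identified midpoints
can sit higher, which the fit stage reports as a warning rather than a
failure.

## Impact calculus

Every impact measure rests on removal: $TC_*(i)$ is cover recomputed
without factor or control $i$. A whole control drops out of the product.
A factor inside a composite loses its term in the numerator of $X_c$
while the fitted normalization $\sum_i v_i$ is kept. The choice matters:
renormalizing the denominator instead would make removal of any
below-average stress (burnt area, in most cells) *raise* the composite
index and produce negative fire "impacts" over most of the domain, and
would give a nonzero fire impact even where nothing burns. Under the
convention used here a zero-valued factor is exactly a no-op, removal
never decreases cover, and relative impacts lie in $[0,1)$.

From removal follow the absolute impact $|TC_*(i) - TC|$, the relative
impact $(TC_*(i) - TC)/TC_*(i)$ (for a whole control identically
$1 - f_c$), the limitation $1 - f_c$ — normalized for $S$ and $LU$ by the
factor's value at zero stress, so no stress means no limitation — and the
sensitivity $R = 4 f_c (1 - f_c)\, TC_*(c)$, the logistic gradient
normalized to its midpoint maximum times unconstrained cover.
Significance of pairwise impact differences is summarized by the
Bhattacharyya coefficient of the two impact distributions on a shared
100-bin histogram: 1 for identical, 0 for disjoint distributions, with
the complementary "p-value" convention also reported. The printed
integral form of that statistic is not bounded for densities; the
discrete coefficient is, which is why it is the implementation.

Counterfactual experiments are always paired by posterior member, never
independently resampled, so parameter co-variation cancels in
differences: a uniform +1% burnt-area increment (cover loss per cell and
member), fire-without-humans (cover without human pressure versus without
human pressure and fire), and the same with burnt area replaced by a
member-sampled counterfactual ensemble representing fire without human
suppression. Per-unit response curves bin cells by factor level and
report $(TC_*(i) - TC) / (A_{bin} \cdot TC_*(i))$, where 1 means the
factor excludes cover over exactly its own area.

Biome summaries aggregate per posterior member first (area-weighted by
the cosine of latitude, optionally weighted further by a deciduous
fraction) and take 10–90% quantiles across members second, so the
reported bounds express framework uncertainty rather than cell-to-cell
spread. Quantiles use linear interpolation of order statistics
throughout; dominant-control maps may use the asymmetric 65/35%
convention by passing those levels.

## Synthetic study conditions

The generator defines the conditions every test runs under. Driver
fields are Gaussian white noise smoothed by a separable Gaussian kernel
(reflective padding), re-standardized, and rank-mapped onto per-driver
marginals: uniform over realistic tropical ranges for the climate drivers
(MAP 0–3500 mm/yr, MAT 5–32 °C, SW 150–280 W/m², MTWM 20–45 °C, wind
0–12 m/s) and right-skewed Beta marginals for the sparse fraction drivers
(burnt area, urban, cropland, pasture, population density), since those
are near zero over most real cells. Burnt area and seasonality share a
latent correlation of 0.6, emulating the co-variation of fire with
seasonal drought that makes their impacts hard to separate. The default
fixture is a 50×50-cell grid with 80% land (~2,000 cells, comparable to
a real training split), correlation length 5 cells, and generating
parameters chosen once so that every control is partially limiting
somewhere — midpoints inside each index's occupied range, moderate
steepness, $TC_{max} = 0.85$, $\sigma = 0.5$, $p_0 = 0.8$ (roughly a
fifth of cells observe exactly zero cover).

What the generator does *not* emulate: satellite sensor artifacts and
the systematic biases of real fractional-cover products,
between-product disagreement in burnt area and precipitation (supported
as multiple ensembles, not simulated), subgrid fire heterogeneity, and
soils. Passing tests therefore demonstrate that the pipeline recovers
known structure from data generated by its own observation model — a
self-consistency guarantee, not a validation against nature.

## Calibration and numerical choices

Predictive calibration is scored on held-out cells. Because the
predictive distribution has a point mass at zero, raw membership in the
empirical 10–90% interval is miscalibrated by construction: wherever
$P(\mathrm{obs} = 0) > 10\%$ the lower quantile is 0, the interval
absorbs the whole atom, and a perfectly calibrated model scores ~90%.
The calibration statistic is therefore a randomized probability integral
transform — the fraction of cells whose PIT falls between the interval
levels — which equals the nominal 80% for a calibrated model and is the
standard estimator for mixed discrete/continuous predictive
distributions. Both numbers are reported by `predictiveInterval()`.

Other conventions: observations and predictions clipped at $10^{-6}$
before logits; degenerate inputs (empty domains, unmapped biome codes,
all-masked interpolation patches) error or mask explicitly rather than
propagating silently; bilinear regridding drops masked source neighbours
and renormalizes their weights, masking a target cell only when all four
neighbours are masked; area weights are $\cos(\mathrm{lat})$ with full
cell area for coastal part-land cells (the framework has no sub-cell land
fraction); multi-year NetCDF inputs are averaged over their time axis on
read.

## Known limitations

MAT and SW enter untransformed; the precipitation transform is the only
documented driver transform, and the treatment of the other climate
controls before fitting is an assumption. The 20/80 train/validation
split draws from the same gridded product, so validation is not
independent of training in the real-data setting; the synthetic fixture
sidesteps this but inherits the caveat for real use. Scaled-down chains
can leave weakly identified midpoint/steepness pairs with elevated
split-Rhat — acceptable for the impact measures, which depend on the
well-mixed product structure, but worth rechecking at the full-scale
protocol for parameter-level inference. Factor-level impacts depend on
the removal convention discussed above; whole-control impacts do not.
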