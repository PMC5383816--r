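---
title: "Modelling suicide locations on a railway network: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling suicide locations on a railway network: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(railpp)
```

## The problem

Railway suicides can only occur on the railway network, so their spatial
analysis is a linear-network point pattern problem: densities are per unit
*arc length*, distances are shortest paths *along the tracks*, and any
planar-area method (kernel maps, elliptic scan statistics) is misspecified.
`railpp` implements a complete pipeline for such data:

1. **Case ingestion** — exclusion filtering of a raw operator case table and
   snapping of planar coordinates onto the network;
2. **Hotspot detection** robust to the roughly 1 km uncertainty of recorded
   case locations;
3. **A log-linear inhomogeneous Poisson process (IPP)** for the intensity of
   cases along the network, fitted by a quadrature GLM device;
4. **Validation** by simulation (coefficient Z-tests) and network pair
   correlation functions;
5. **A constrained-realization randomization test** of the hypothesis that
   psychiatric-institution locations have no influence on case locations;
6. **Per-hotspot excess risks** for each explanatory variable.

Because the motivating case data are confidential, the package ships a
synthetic-data generator (`synth_world()`) that reproduces the *statistical
structure* of the real inputs — a connected planar network with a multitrack
subnetwork, a log-normal population surface, hospitals concentrated in
populated areas, and cases drawn from a known log-linear intensity — so that
every stage is testable end to end against a known truth.

## Hotspots under location noise

Recorded case locations carry a measurement uncertainty of about 1 km along
the track (they derive from kilometre markers and station names). A hotspot
is therefore defined conservatively: a pixel only counts as part of a
hotspot if *at least 90% of an ensemble* of noise realizations places at
least one case in it.

`ensemble_quantile_image()` builds the ensemble:

* each of `n_real` (default 1000) realizations displaces all cases along the
  network by a Gaussian travel distance (`gaussian_displace()`, sd 1 km);
* box counts are taken on 1 km pixel grids at **16 origins** displaced by all
  combinations of {0, 250, 500, 750} m — the symmetric subdivision of the
  1 km pixel into 250 m subpixels. Averaging over displaced grids mitigates
  the modifiable areal unit problem (MAUP);
* every 250 m destination pixel inherits, per grid, the count of the 1 km
  pixel containing it, so each destination pixel accumulates
  `n_real x 16` counts (16 000 at the default);
* the image stores the pixel-wise lower 10% empirical quantile (type 1,
  left-continuous: the most conservative choice consistent with "lower
  quantile").

Pixels with quantile value above the threshold (default 0, i.e. *at least
one case* in ≥ 90% of the ensemble) are grouped by 8-connectivity;
groups whose border-to-border gap is at most 3 pixels (Chebyshev metric,
consistent with 8-connectivity) are merged transitively. Per hotspot the
summary reports the pixel area, the 10%–90% quantiles across noise
realizations of the case count inside the hotspot (an honest bracket for the
"approximate number of cases", which the ensemble makes available for free),
the maximum-mean-density pixel, and the air-line distance to the nearest
psychiatric institution.

**Design note — the inclusion threshold.** The numeric threshold applied to
the quantile image in the original analysis is not recoverable; we default
to "quantile strictly above zero" and expose it. On synthetic data the
hotspot count is insensitive to small threshold changes, but the absolute
number of hotspots is a property of the configuration, not of the method.

## The IPP and its quadrature

The intensity is modelled as
$$\lambda(x) = \exp\!\big(\theta_0 + \textstyle\sum_j \theta_j v_j(x)\big),$$
with respect to arc length, with five explanatory variables $v_j$:

| variable | construction | default |
|---|---|---|
| `psy` | bed counts of psychiatric institutions (total beds / number of department types), rasterized, offset by one, logarithmized, then Gaussian-smoothed | bandwidth 0.8 km |
| `pop` | population raster logarithmized then Gaussian-smoothed | bandwidth 1.6 km, 1 km source grid, 250 m working grid |
| `multitrack` | exact per-edge single/multitrack flag (proxy for traffic density) | — |
| `comp1`, `comp2` | first two components of a population-weighted centred PCA of the socio-economic rasters sampled at random network points | 20 000 sample points |

The two smoothing chains are deliberately asymmetric (population: log then
smooth; beds: offset, log, then smooth) — each follows its stated recipe;
the offset is required because bed counts are zero almost everywhere.
Kernels are truncated at 4 bandwidths per axis and renormalized.

Fitting uses the classical dummy-point device adapted to networks
(`build_design()` + `fit_ipp()`): the cases plus `n_dummy` (default 20 000)
uniform random dummy points jointly partition the network by nearest
shortest-path distance (`network_tessellation()`); each point's share
$w_i$ of arc length is its quadrature weight; with responses $y_i = 1/w_i$
for cases and $0$ for dummies, the weighted Poisson GLM with log link
maximizes the discretized IPP likelihood. The tessellation is computed
exactly per edge as a lower envelope of distance functions (no
discretization); where two or more generators are exactly equidistant over
a segment — the "critical node" overlaps that prevent a proper Voronoi
partition — the segment's length is divided among them proportionally to the
inverse shortest-path distance, which at an exact tie is an even split.
Weights always sum to the total network length (relative tolerance 1e-6),
and the unit tests verify agreement with an independent 1-metre
discretization oracle.

Location uncertainty propagates into the fit via `fit_with_noise()`: the
fit is repeated under 39 independent noise realizations (displacing the
cases, regenerating the dummies each time, since dummy selection is part of
the per-fit procedure) and the coefficient estimates are averaged.

**Numerical choices.** The GLM is solved by IRLS (`stats::glm.fit`) with the
quasipoisson family — identical estimating equations to Poisson, but it
skips the AIC term, which is undefined for the non-integer responses
$1/w_i$ — tolerance 1e-8, at most 100 iterations. Covariates are evaluated
at the *containing pixel* of each point (no interpolation; interpolation
would silently change the model). Co-located points can receive a zero
tessellation share; they are given a 1 nm share so $1/w$ stays finite, with
negligible likelihood contribution.

## Simulation-based validation

`simulate_fitted()` draws realizations of the fitted model on the 250 m
working grid: each pixel–edge subsegment receives intensity mass
`exp(linear predictor) x subsegment length`, and each realization places a
fixed number of cases multinomially over subsegments, uniformly within a
subsegment. Raster covariates contribute their pixel value (equivalent to
pixel-centre evaluation); the multitrack term uses the exact edge flag of
the subsegment rather than a rasterized version, so that pixels mixing
single- and multitrack edges do not acquire an artificial discretization
bias. Refitting each realization and comparing the refitted coefficients to
the simulation inputs with a Z-test based on the simulation variance
(`coefficient_z_test()`) checks that the grid is fine enough: all |Z| < 3
(in practice well below 1) at 199 realizations.

Because case patterns are simulated *conditionally on the case count*, the
intercept is only identified up to the normalization
$\theta_0^{\mathrm{eff}} = \theta_0 + \log(N/\Lambda)$ where $\Lambda$ is
the integrated intensity; tests compare the fitted intercept against this
effective value.

## Goodness of fit: pair correlations

`pair_correlation()` estimates the network pair correlation function
$g(r)$: the histogram of all pairwise shortest-path distances, normalized
bin-wise by the mean histogram of simulated null patterns (199 by default) —
either complete spatial randomness (CSR: uniform with respect to arc
length, conditioned on the observed count) or the fitted IPP. Pointwise
95% envelopes come from the empirical quantiles of the simulated
$g$ curves. Pairs in different network components or beyond the last bin
are excluded and reported. The default bins are 2 km wide (the bin width is
not prescribed by the method; 2 km resolves small-distance over-clustering
without empty bins at desk scale). `temporal_pair_correlation()` applies
the same estimator to event dates against a uniform-in-window null.

The envelope is pointwise: with $B$ usable bins one expects about 5% of
them outside a 95% band even under the null, and the calibration tests
assert an upper bound of 10%, not zero.

## The randomization test

The null hypothesis — psychiatric-institution locations do not influence
case locations — is tested with constrained-realization Monte Carlo
(`psych_randomization_test()`):

* surrogate configurations relocate every hospital independently to a
  population-weighted random location (hospitals are empirically more
  frequent in populated areas), keeping its bed attributes;
* a surrogate is accepted only if the weighted chi-squared distance
  $\chi^2 = \sum_k c(k)\,(n(k)-n_0(k))^2/n_0(k)$ between its bed-density
  histogram and the original one is at most 5000. The bin-centre weights
  $c(k)$ make bins of higher bed density (larger institutions) count more.
  The histogram evaluates the kernel bed-density surface (bandwidth 0.8 km,
  beds per km²) at a fixed set of uniform network points, drawn once and
  reused for every configuration so that sampling noise cancels from the
  comparison;
* the test statistic is the psychiatric coefficient of a three-covariate
  IPP fit (psy + population + multitrack); the one-sided p-value is
  $(1 + \#\{\text{surrogate stat} \ge \text{observed}\})/(n+1)$, matching
  the directional hypothesis that institutions increase nearby case
  intensity;
* `sensitivity_check()` sorts accepted surrogates into 12 equal groups by
  their $\chi^2$ and compares the statistic across groups with a
  Kruskal–Wallis test; a non-significant result indicates the acceptance
  threshold does not distort the null.

**Design notes.** (i) The quadrature (dummies + tessellation) and the
population/multitrack covariate columns are built once and shared across the
observed and all surrogate fits; only the psychiatric covariate column is
rebuilt per configuration. This removes quadrature Monte-Carlo noise from
the null distribution of the statistic. (ii) Histogram defaults — up to 30
bins with edges at the *quantiles* of the original configuration's density
values, 1000 evaluation points, densities in beds/km² — are choices the
method leaves open. Quantile bins guarantee every reference bin a positive
count; with equal-width bins the skewed density distribution leaves empty
interior reference bins, and the empty-bin penalty then turns acceptance
into a lottery over configurations. (iii) The chi-squared threshold keeps
the method's default of 5000. The statistic's scale depends on the chosen
units and binning: under these defaults typical relocation proposals score
in the tens-to-hundreds, so the threshold rejects only gross distortions
(e.g. mass in bins empty under the original support, which carry a large
configurable penalty, default 1e6); the Kruskal–Wallis sensitivity check is
the evidence that the test statistic is insensitive to the constraint's
exact strength. (iv) A surrogate whose fit does not converge (e.g. every
psychiatric institution relocated far from the network, leaving an aliased
covariate column) is resampled.

## Excess risk

For the fitted log-linear model the intensity factorizes,
$\lambda(x) = e^{\theta_0} \prod_j \mathrm{er}_j(x)$ with
$\mathrm{er}_j(x) = \exp(\theta_j u_j(x))$, where $u_j$ is the covariate
*exactly as it entered the GLM* (the smoothed log fields, the 0/1 flag);
this is the only reading under which the product reconstructs the fitted
intensity exactly, which `excess_risk()` verifies to 1e-10. Hotspot-level
excess risks are means over the hotspot's pixels; for the binary multitrack
variable they can therefore lie strictly between 1 and $e^{\theta}$ when a
hotspot mixes single- and multitrack pixels.

## The synthetic world

`synth_config()` fixes the study conditions; the defaults are one-time
choices meant to be realistic at desk scale, not tuning knobs:

* a grid-with-diagonals network over 32 km x 18 km with 2 km cells
  (~650 km of track — about a tenth of a national network), with a
  contiguous multitrack subnetwork carrying 25% of the length;
* a log-normal population surface on a 1 km grid with 3 km spatial
  autocorrelation (Gaussian-smoothed white noise, the same smoothing
  machinery the pipeline already needs);
* 40 hospitals placed with probability proportional to population, half
  with a psychiatric department, log-normal bed counts, 1 + Poisson(5)
  department types;
* socio-economic rasters on a coarse 2 km grid, built as known linear mixes
  of the standardized log-population field and an independent latent field
  plus noise, so PCA recovery is checkable; population enters the PCA on
  the log scale (its raw scale would otherwise dominate the centred,
  unscaled decomposition — the method centres but does not scale);
* cases drawn from the log-linear intensity with true coefficients
  `psy = 10, multitrack = 0.7, pop = 0.6, comp1 = 0.3, comp2 = -0.3`, and
  `N = 1130` retained cases. The psychiatric coefficient is an order of
  magnitude larger than the others because its covariate — the smoothed log
  of localized bed masses — has a correspondingly small numeric range; a
  coefficient of ~10 on this scale is a moderate local effect (and is the
  scale on which such coefficients are reported for real data);
* a raw case table of 1170 records, of which 4 are flagged as foreign
  (placed far outside the extent), 6 as inside trains (on-network, flag
  only), and 30 as off-network (rejection-sampled to be at least 200 m from
  every edge, beyond the 100 m snapping tolerance); clean records are
  jittered by up to 30 m so snapping is exercised. Sampling of case
  locations is exact inversion on a 10 m segmentation of the edges (no
  rejection step, exact conditional-on-N sampling).

What the generator does *not* emulate: real geography (no country outline,
no CRS), station structure, closed lines, seasonal or secular time trends,
and any dependence between cases beyond the inhomogeneous intensity. Tests
passing on this world therefore demonstrate correctness of the algorithms
under the model's own assumptions, not the adequacy of the model for any
particular real network.

## Problem sizes used in the shipped tests

The automated tests run the full algorithms at reduced ensemble sizes,
chosen once as the package's own desk-scale conditions: hotspot ensembles at
50–1000 realizations; the simulate–refit loop at the full 199 realizations
and 20 000 dummies on the ~650 km default network; pair-correlation
envelopes at 99 simulations; randomization-test calibration as 50 repeated
tests of 99 surrogates on a ~190 km fixture, and the power run at 199
surrogates at full scale. Calibration checks on the test's rejection rate
use binomial error bounds; power checks use a strong planted effect
(`psy = 15` with the socio components switched off, so the three-covariate
test model is correctly specified and the check isolates the psychiatric
mechanism).

## Known limitations

* Gaussian displacement through junctions chooses uniformly among the other
  incident edges and reflects at dead ends; the travelled arc length equals
  the drawn |Normal(0, σ)| displacement. Any length-preserving branching
  rule would be equally defensible; this one is direction-agnostic and
  reproducible.
* Networks with components that contain no quadrature points leave those
  components' length unassigned; all shipped generators produce connected
  networks.
* The pair correlation uses pointwise envelopes only (no global rank
  envelope test).
* The chi-squared constraint scale (bins, evaluation points, density units)
  is a convention; only the *relative* constraint strength is meaningful,
  and the sensitivity check is the guard against a distorting threshold.
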