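---
title: "Methods: national urban-forest carbon accounting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: national urban-forest carbon accounting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(urbancarbon)
```

## The problem

Canada reports greenhouse-gas removals by urban trees in the Settlements
category of its national inventory. Earlier reporting applied a single
carbon storage density (76.9 t C per hectare of canopy) and a single gross
sequestration rate (2.12 t C ha^-1^ yr^-1^) to every hectare of urban tree
canopy in the country — values extrapolated from United States data with a
growing-season correction, blind to the difference between a Vancouver-area
temperate rainforest street tree and a Prairie poplar. This package
implements an updated assessment procedure that derives regional carbon
densities from Canadian (plus one surrogate US) plot-based urban forest
assessments, and scales them to the national account through canopy cover.

The spatial unit is the *reconciliation unit* (RU): the intersection of an
ecozone with a provincial/territorial boundary. Eighteen RUs contain urban
area (population centres with more than 30,000 people and 400 people per
km^2^). Densities are derived at the *ecozone* level — urban forest
structure is assumed comparable across provincial boundaries within an
ecozone, but not across ecozone boundaries — and assigned to the RUs each
ecozone contains.

## The accounting model

The account is an IPCC Tier-2 gain calculation. For each RU,

$$\Delta C_G = A_T \times C_{RW},$$

where $A_T$ is the RU's urban tree canopy area (ha) and $C_{RW}$ is the
carbon rate per unit crown cover: a stock density (t C ha^-1^) for storage,
a gross rate (t C ha^-1^ yr^-1^) for sequestration. Net sequestration
subtracts emissions from biomass decay as a fixed fraction $f_{net}$ of
gross, and CO~2~ removals convert by the exact mass ratio 44/12.

`tier2_flux()`, `net_and_co2()` and `build_account()` implement this;
national totals are exact column sums over RUs, and the package asserts the
identities $net/gross = f_{net}$ and $CO_2/net = 44/12$ to machine
precision before any rounding.

**The f_net choice.** The source text states net sequestration as 74% of
gross; the published per-RU table columns imply a ratio of 0.749–0.750.
`accounting_config(f_net = )` exposes the choice; the default follows the
text (0.74). At national scale the two differ by about 1.2%, within the
tolerance of every check this package runs.

## Deriving the ecozone densities

Each assessed city contributes its total carbon storage and gross
sequestration (with sampling standard errors) over an attributed canopy
area: its assessment area times the canopy fraction of the RU containing it
(`city_canopy_area()`). The surrogate city for the Pacific Maritime ecozone
(Seattle) is the exception: its canopy came from its own satellite
estimate, carried as `canopy_area_override_ha`. That satellite value was
never published; the fixture ships the value back-calculated from the
published RU-1 storage total (5498.9 ha), which reproduces the published
RU-1 stock, flux, and baseline-difference values to their printed
precision, rather than the coarser value implied by the one-decimal density
table.

Ecozone pooling (`pool_ecozone_density()`) is canopy-area-weighted:
$\hat d = \sum_i C_i / \sum_i A_{T,i}$ over the cities of the ecozone. The
unweighted mean of city densities is also computed, but the weighted
estimator is the default because it reproduces the published multi-city
values: for the Subhumid Prairies the weighted estimator gives 55.1 against
the published 54.7 (a <1% gap attributable to the rounded canopy
fractions), while the unweighted mean gives 52.3. For the twelve-city
Mixedwood Plains the weighted estimator reproduces the published 57.8 and
2.4 exactly at printed precision — which also settles the parse of two
typographically garbled source rows (Bolton and Caledon, flagged in the
fixture), since those cities' densities are the published range endpoints
33.8 and 127.9 t C ha^-1^.

Three proxy rules complete the map (`derive_ecozone_densities()` with
`ecozone_rules.csv`): the Semiarid Prairies copy the Subhumid pooled pair;
the three boreal ecozones take constants from managed-boreal-forest
modelling (40.0 t C ha^-1^, 3.0 t C ha^-1^ yr^-1^); the Pacific Maritime
pools its single external surrogate city. Every RU must be covered or
`assign_ru_densities()` refuses, naming the gap.

Derived densities are carried unrounded into the account; the published
one-decimal table is also shipped (`load_printed_densities()`) for strict
replication. With printed densities the national storage is 27,294.0 kt C
and with unrounded densities 27,312.7 kt C, bracketing the published
27,297.8 within 0.07%.

## Canopy cover by point sampling

The canopy fractions in the RU table come from a national point-sampling
survey, which the `canopy_*` functions reimplement so that the design is
testable: a 1-km^2^ grid over urban imagery, a 25% simple random sample of
cells, 55 evenly spaced points per cell classified by landcover, with two
quality rules — any cell with 25% or less of its classified area urban is
discarded, and points on cloud or image distortion are removed before
estimation.

Design choices the source leaves open, fixed here:

- *Lattice geometry.* "Evenly spaced" is implemented as the
  rows-by-columns factorization of the point count closest to square (5
  times 11 for 55), centred with half-spacing margins. Orientation and
  offset are deterministic given the cell.
- *Cell urbanness.* The urban fraction is (canopy + other urban) over
  (canopy + other urban + non-urban); cloud pixels are excluded from the
  denominator.
- *Standard errors.* Points are spatially clustered within cells, so the
  binomial SE $\sqrt{p(1-p)/n}$ understates the design variance. Both the
  binomial SE and a cluster-level SE (spread of per-cell means over
  $\sqrt{k}$ cells) are reported; the national survey published a single
  0.2% canopy uncertainty without a formula, and reporting both lets a
  user reproduce either convention.
- *Input format.* Grids are plain-text integer matrices with a resolution
  header. Georeferenced raster formats are out of scope: the estimator
  needs only pixel classes and a resolution.

On synthetic rasters with independent pixels the estimator is design-
unbiased for its sampling frame and the nominal 95% binomial interval
covers truth at close to nominal rate (the test suite checks 93–97%
empirical coverage at over 1000 points). Real imagery violates pixel
independence — canopy is blotchy — which inflates the cluster SE relative
to the binomial SE; the clustered raster generator
(`generate_raster(clustering = TRUE)`) reproduces that qualitative
behaviour, and passing tests on independent-pixel rasters say nothing
about interpreter error or georegistration, which are not modelled.

## Uncertainty propagation

`run_monte_carlo()` propagates four uncertainty sources per iteration:

1. **Urban area**: a triangular factor with lower bound -10% (following
   inventory practice for urban activity data), mode 0, upper bound +33%.
   The upper bound is this package's reading of "the known area currently
   outside the analysis": the assessed centres comprise about 67% of
   national urban area. Configurable.
2. **Canopy cover**: normal, 0.2% by default, with both absolute
   (percentage-point) and relative semantics available since the source
   does not say which it used. Absolute is the default; at 0.2% the choice
   is immaterial.
3. **Carbon rate**: the three-class scheme below.
4. **Model**: one multiplicative normal factor, 20%, shared across RUs by
   default — a common model bias moves all RUs together, and this choice
   materially widens national bounds relative to independent draws; both
   options are exposed.

**Percentage-uncertainty semantics.** The stated 20% and 0.2% are treated
as 95%-confidence half-widths (standard in GHG inventory reporting) and
converted to standard deviations by dividing by 1.96. Read literally as a
standard deviation, a shared 20% model factor alone would give national
2.5/97.5 bounds of about ±39% — wider than the published national
sequestration bounds of (-33%, +38%), which the model factor is only one
component of. The half-width reading makes the published numbers
internally consistent; `percent_as_ci95 = FALSE` restores the literal
reading.

**The three classes** (`classify_ru()`, `build_rate_distributions()`):

- *City-covered* fraction of an RU (summed assessment area over urban
  area, capped at 1): one normal component per city at its own density and
  scaled sampling SE, weighted by canopy area.
- *Partial* remainder of such RUs: a normal at the RU's pooled city mean
  with the inter-city SD — the spread of city densities in the reference
  ecozone, the one with the most assessed cities (the twelve-city
  Mixedwood Plains in the national data).
- *Proxy* RUs with no assessed city: a normal at the assigned proxy mean
  whose SD combines the proxy's own pooled SE, the inter-city SD, and the
  inter-RU SD (spread of the 18 assigned density values). The source says
  only "plus SD"; components combine in quadrature by default
  (independence), with an additive option for sensitivity analysis.

The per-iteration canopy area is the *recorded* canopy area scaled
multiplicatively by the area factor and the relative canopy deviation,
rather than re-derived as urban area times cover: the published table
rounds those two columns independently, and scaling keeps the
zero-uncertainty limit exactly on the deterministic account (a property
the test suite asserts).

Negative component draws are truncated at zero and the truncation rate is
reported (about 3% at the default configuration, concentrated in proxy
RUs whose rate CV approaches 1). Truncation slightly inflates proxy-RU
means, which is why the mean-preservation check (Monte Carlo mean equals
deterministic value times the triangular mean factor, here 1.0767) is
asserted on city-covered RUs where truncation is negligible. Percentiles
use linear interpolation on order statistics; relative bounds are
reported against the Monte Carlo mean.

At the default configuration the national gross-sequestration bounds come
out near (-31%, +36%) against the published (-33%, +38%), and storage near
(-37%, +43%) against (-37%, +44%). Per-RU published bounds are *not*
reproducible: the source does not state which proxy city served each proxy
RU, only the class structure; the package asserts the class ordering
(proxy RUs wider than city-covered RUs) rather than per-RU values.

## Synthetic data

`synthetic_world()` fixes ground truth the pipeline must recover. Its
defaults are the study conditions: the 18 published RUs with their canopy
fractions, the published ecozone densities as truth, and plot-sampling
noise with a per-plot CV of 0.05, so that a city assessed with a few
hundred plots carries a relative SE of a few tenths of a percent to a few
percent, matching the magnitude of the published city SEs (roughly 2–30%
of totals). `generate_city()` perturbs true totals by normal noise with
relative SD $cv/\sqrt{n_{plots}}$ (truncated at zero with a warning;
a mean-one lognormal option keeps totals positive at high CV) and reports
the generating SD as the SE — so generated SEs are calibrated by
construction, which the suite verifies against replicate spreads.

What the generator does *not* emulate: allometric or species structure
(city totals are drawn directly, the plot model is upstream of this
artifact), spatial correlation between cities, and any bias shared across
assessments. Passing recovery tests therefore demonstrate that the
pooling, proxy, and accounting arithmetic is faithful and that calibrated
SEs propagate to calibrated intervals — not that real i-Tree assessments
are unbiased.

Problem sizes used by the test suite were chosen to make sampling noise
negligible relative to the tolerances checked: 200-seed unbiasedness and
600-replicate coverage runs for the canopy sampler, 10,000-iteration
reporting runs (with one 100,000-iteration convergence check), and
200-replicate-world interval-calibration runs at 1500 iterations each.

## Known limitations

- Dead organic matter, soils, harvested wood products, and tree-mortality
  dynamics are outside the account, as in the source assessment.
- The Mixedwood Plains inter-city SD stands in for inter-city variability
  everywhere; ecozones with one city contribute no variability information
  of their own.
- The boreal constants enter with zero proxy SE (their forest-model
  uncertainty is not published); proxy-RU bounds lean entirely on
  inter-city and inter-RU spread.
- Printed-table rounding propagates: quantities derived from the fixtures
  can differ from published values by up to about 1% (Prairie pooling),
  documented where it occurs.
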