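---
title: "Distance-based accessibility of cancer clinical trials: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance-based accessibility of cancer clinical trials: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctaccess)
```

## The model

`ctaccess` quantifies how reachable cancer clinical trials are for the
population of a country, on a uniform geographic grid. Demand is a gridded
population (one point per cell, emulating a 30-arc-min world grid, about
55 km at the equator); supply is a table of geocoded trial sites with the
number of trials activated per registration year. Each grid point $i$ is
served only by its nearest site $j$ — nearest-supply assignment is the
defining, and deliberately non-additive, feature of the index — and its
local accessibility is the Hansen-type gravity score

$$\mathrm{dAI}(i) \;=\; \frac{n_j}{\log s_i}\,\Bigl(\frac{1}{d_{ij}}\Bigr)^{\beta},
\qquad s_i = p_i \, r_c / 10^5 ,$$

where $n_j$ is the number of trials at the serving site, $d_{ij}$ the
great-circle distance in km, $p_i$ the cell population, and $r_c$ the
national cancer incidence per 100 000. The default impedance exponent is
$\beta = 0.5$: an inverse square-root decay, the regime that describes
human mobility at the typical patient-to-site travel scale. The logarithm
deliberately attenuates the influence of heterogeneous cancer incidence,
so that the index is driven by geography and supply rather than by
epidemiology.

The national index is the average of local values weighted on the log
patient volume,

$$\mathrm{dAI}_C = \frac{\sum_i \mathrm{dAI}(i)\, w_i}{\sum_i w_i},
\qquad w_i = \max(\log s_i, 1),$$

over the country's populated grid points. The travel-cost variant (tAI)
substitutes a generalized point-to-site cost for $d_{ij}$, with the
serving site chosen as the cost argmin; everything else is unchanged, so
a cost matrix numerically equal to the distances reproduces the dAI
surface exactly.

## Numerical choices and degenerate inputs

* **Log base and clamping.** "log" is the natural logarithm (configurable;
  within-country comparisons are invariant to the base). For cells with at
  most one expected patient, $\log s_i \le 0$ would flip the sign or blow
  up the score, so such cells are excluded from national aggregation, and
  log-weights are clamped below at 1. The local value itself uses the same
  clamp, so it is finite and non-negative for every populated cell.
* **Incidence scaling.** The per-100 000 rate is divided out so $s_i$ is
  an expected patient count. This constant is configurable off
  (`scale_per_100k = FALSE`); within a country it only rescales weights,
  and relative comparisons are unaffected.
* **Distance floor.** A point co-located with a site has $d = 0$. Every
  distance is floored, by default at half the grid-cell diagonal at the
  point's latitude ($\approx$ spacing $\times\,111.195\,
  \sqrt{1+\cos^2\phi}/2$ km $\approx 39$ km for a 0.5° grid in the
  mid-latitudes): the average distance of persons inside a cell to its
  centre is of cell order, so shorter distances are not resolved by the
  data. A scalar override is available and is what the closed-form unit
  tests use.
* **Tie-breaks.** Equidistant sites (within $10^{-9}$ km, so that
  geometrically symmetric configurations are not decided by floating-point
  noise) are resolved deterministically: larger $n_j$ first, then
  lexicographically smaller site id. The optimizer breaks candidate ties
  by (gain, population, point id). Determinism here is what makes
  byte-identical re-runs possible.
* **Zero supply.** Countries or years without a single site get index 0,
  not missing — "no accessibility" is a value on the scale. A year in
  which the whole pooled surface is 0 has no defined inequality and the
  Gini returns an explicit `NA` marker rather than 0.
* **Cross-border supply.** Nothing in the model forbids a grid point from
  being served by a site across a border; the default allows it, and a
  `within_country` switch restricts assignment to domestic sites. During
  optimization only the target country's index is maximized.
* **Year semantics.** A site contributes to year $y$ the trials registered
  in $y$; a cumulative-supply mode (all trials up to $y$) is available but
  not default. Year filters are closed intervals throughout.

## Inequality

Inequality of the accessibility distribution is measured by the Gini
index, computed in $O(n\log n)$ from the Lorenz trapezoids of the
value-sorted vector and verified in the test suite against the $O(n^2)$
pairwise definition
$G = \sum_{ij} |x_i - x_j| / (2 n^2 \bar{x})$.
Grid points are the units and are unweighted by default — zero-valued,
unserved cells are precisely the inequality being measured, so they are
included — with a population-weighted option. The global statistic pools
grid points across countries with the same machinery as the
within-country statistic (a country-level pooling is available as an
option); this is the only reading under which "global" and
"within-country" are the same quantity at different scopes.

## Trend statistics

National series are summarized by percent increments over a base year,
their trapezoidal AUC against the year axis (only AUC *ratios* are
interpreted, making the result invariant to the abscissa origin), and the
Mann–Kendall test. The test uses the sign-sum statistic
$S=\sum_{k<l}\mathrm{sign}(x_l-x_k)$ with Kendall's $\tau$-b (tie-corrected,
since annual index values can tie at 0). For tie-free series with
$n \le 10$ the exact permutation null of $S$ is used, computed from the
inversion-count recursion; otherwise a normal approximation with
tie-corrected variance and $\pm 1$ continuity correction. Significance is
reported at two-sided $p \le 0.05$ with no multiple-testing correction
across countries by default (a Benjamini–Hochberg option exists). The
ratio of accessibility-AUC to trials-AUC is the decoupling statistic:
values below 1 mean trial counts grew faster than accessibility, the
signature of growth concentrated at existing sites.

## Optimal placement

`greedy_place()` adds $k$ hypothetical sites of a given size sequentially:
every populated grid point of the country is a candidate, the best is
committed, and the search repeats — sequential rather than joint, because
the question asked is "where should the *next* site go". A candidate only
changes points it captures, so it is scored by an exact incremental update
of the committed surface; the tests verify exact agreement with full
recomputation and, at $k=1$, with exhaustive search (greedy *is*
exhaustive at $k=1$). At $k=2$ the suite compares against the joint
exhaustive optimum on a small instance and reports the optimality gap.
The default size of a new site is the median $n_j$ of the country's
existing sites that year. Unpopulated cells are never candidates: they
carry no weight, and placing there is dominated. Because supply is
nearest-only, adding a small site between a point and a larger site can
*lower* that point's local value while still raising the national index;
`adding_site_can_lower_local()` constructs and verifies this regression
toy.

## The synthetic-data generator

`make_country()` emulates the three real inputs (gridded population,
geocoded sites, national incidence) from a blueprint: a bounding box and
spacing, a population pattern (`uniform`, `urban_poles` with a
configurable mass share and Gaussian dispersion in cell units, or a
longitudinal `gradient`), and a site policy (`concentrated` places at
least 80% of a year's trials at the largest pole — the mechanism behind
high within-country inequality; `proportional` splits trials by cell
population; `random` scatters them). Populations are integer counts
allocated by largest remainder so they sum exactly to the blueprint
total. All generators are pure functions of (blueprint, seed).

`make_trend_panel()` builds replicate countries whose supply evolves under
a regime: `flat` (iid Poisson counts at fixed sites — the null of the
trend test), `linear`, `accelerating`, and `decoupled`, in which growth is
added only at the largest existing site. That site is deliberately placed
in a low-demand corner so its per-trial capture of the demand surface is
below the supply-weighted average; accessibility increments are then a
fixed fraction of trial increments and the decoupling ratio is below 1 in
every replicate by construction.

What the generator does *not* emulate: latitude-dependent cell areas
(blueprints operate in index space, whereas real 30-arc-min cells shrink
with latitude), demographic realism, registry reporting biases, or
travel-cost data beyond a congestion factor that inflates distances near
populous destinations. Passing tests therefore demonstrate that the
machinery recovers designed mechanisms — concentration raising
inequality, decoupled growth, congestion depressing tAI below dAI — not
that any real country attains a particular value.

## Problem sizes and test design

The suite works at deliberately small scale: grids of 50–150 points,
panels of 15 years, 500 replicates for the type-I check of the trend
test, 50 random instances for the optimizer oracle; the whole suite runs
in well under a minute and the acceptance script in under half a minute.
Seeds are fixed constants chosen once. Oracles are independent routes:
pairwise Gini, exhaustive permutation nulls, full-recomputation and joint
exhaustive search.

## A worked example

```{r example, eval = FALSE}
grid <- read_grid_csv(system.file("extdata/fixtures/bootland/grid.csv",
                                  package = "ctaccess"), spacing_deg = 1)
sites <- read_sites_csv(system.file("extdata/fixtures/bootland/sites.csv",
                                    package = "ctaccess"))
inc <- read_incidence_csv(system.file("extdata/fixtures/bootland/incidence.csv",
                                      package = "ctaccess"))
surf <- compute_surface(grid, sites, inc, year = 2019)
national_index(surf)
within_country_gini(surf, sites, year = 2019)
greedy_place(grid, sites, inc, country = "bootland", year = 2019,
             n_new = 4, k = 2)$steps
```

The `bootland` fixture is an entirely synthetic, boot-shaped country with
a dense north hosting all supply; the optimizer places the first new site
in the unserved south, and the relative gains are small because baseline
coverage is already reasonable — the same anti-monotonicity of gains in
baseline coverage that makes sparse countries the ones with the most to
win from a single well-placed site.

## Known limitations

The index ignores qualitative trial heterogeneity (phase, disease,
eligibility), uses trial counts rather than planned enrolment, and treats
distance as the sole access cost; the tAI comparison quantifies how much
that matters where cost data exist. Greedy placement is optimal per step,
not jointly. The data model accepts pre-tabulated CSVs only — raster
ingestion, geocoding and registry parsing are out of scope.
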