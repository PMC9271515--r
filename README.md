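# ctaccess

Geographic accessibility of cancer clinical trials, measured on gridded
population data.

Clinical trials concentrate in recurrent urban locations, so growth in
trial *numbers* does not automatically translate into growth in trial
*access* for patients who live far from the sites. `ctaccess` is for
health-services researchers and trial-policy analysts who want to
quantify that gap: it computes a distance-based accessibility index over
a population grid, aggregates it nationally, profiles inequality, tests
time trends, and searches for the site locations that would raise a
country's index the most.

## The index

For each populated grid point *i*, served only by its nearest trial site
*j* (nearest-supply assignment — deliberately non-additive):

    dAI(i) = n_j / log(s_i) * (1 / d_ij)^beta        s_i = p_i * r_c / 1e5

* `n_j` — trials activated at the serving site,
* `d_ij` — great-circle distance in km (floored at half a grid-cell
  diagonal; beta = 0.5, inverse square-root decay),
* `s_i` — expected patients: cell population times the national cancer
  incidence per 100 000, log-attenuated so epidemiology does not dominate
  geography.

The national index is the mean of local values weighted on
`max(log s_i, 1)`. A travel-cost variant (tAI) replaces distance with a
generalized cost matrix. On top of this sit: percent-of-reference
normalization across countries, global and within-country Gini/Lorenz
inequality, relative increments + AUC decoupling statistics, the
Mann–Kendall trend test (exact null for short series), scenario
simulation, and a greedy optimal-placement algorithm with an exact
incremental evaluator. A synthetic-country generator
(`country_blueprint()` / `make_country()` / `make_trend_panel()`) makes
the whole pipeline testable without any external download.

## Worked example

The shipped `bootland` fixture is a synthetic boot-shaped country on a 1°
grid: a dense north holding all three trial sites, an unserved south.

```r
library(ctaccess)
fx <- function(f) system.file("extdata/fixtures/bootland", f, package = "ctaccess")
grid  <- read_grid_csv(fx("grid.csv"), spacing_deg = 1)
sites <- read_sites_csv(fx("sites.csv"))
inc   <- read_incidence_csv(fx("incidence.csv"))

surf <- compute_surface(grid, sites, inc, year = 2019)
national_index(surf)
#> [1] 0.07453988
within_country_gini(surf, sites, year = 2019)$gini
#> [1] 0.3266757
greedy_place(grid, sites, inc, country = "bootland", year = 2019,
             n_new = 4, k = 2)$steps[, c("step", "point_id", "lat", "lon", "gain_pct")]
#>   step point_id lat lon gain_pct
#> 1    1    bl_35  39  16 7.052312
#> 2    2    bl_28  41  15 8.755561
```

The national index is 0.075 (dimensionless; comparable across countries
on the same grid scale), the within-country Gini of 0.33 reflects the
north–south supply imbalance, and the optimizer puts the first new
4-trial site at (39N, 16E) — the southern toe, the largest unserved
population mass — for a +7.1% national gain, with the second site adding
less (+1.7 points): gains shrink as coverage improves.

A thin CLI wraps the same functions
(`inst/cli/ctaccess.R <compute|tai|gini|trend|optimize|simulate|synth|report>`).

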