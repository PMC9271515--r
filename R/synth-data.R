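## Synthetic countries: grids, sites, incidence and cost matrices with
## controlled spatial structure, so every pipeline stage is testable
## without external downloads. All generators are pure functions of
## (blueprint, seed): the RNG state is set locally and restored.

#' Country blueprint
#'
#' Describes a synthetic country: bounding box and grid spacing, how the
#' population is spread (uniform, urban poles, or a longitudinal
#' gradient), the cancer incidence rate, and how trial sites are placed
#' ("concentrated" puts at least 80% of each year's trials at the largest
#' pole, "proportional" splits them by cell population, "random" scatters
#' them over populated cells).
#'
#' @param name Country label.
#' @param lat_range,lon_range Bounding box, decimal degrees.
#' @param spacing_deg Grid spacing in degrees (default 0.5, i.e. 30
#'   arc-min).
#' @param pattern Population pattern: `uniform`, `urban_poles`, `gradient`.
#' @param n_poles,pole_mass_share,pole_dispersion Urban-pole parameters:
#'   number of poles, fraction of the total population they hold, Gaussian
#'   spread of each pole in cell units (0 = all mass in the pole cell).
#' @param total_population Persons (> 0).
#' @param incidence_rate Cases per 100 000 per year (> 0).
#' @param site_policy `concentrated`, `proportional`, or `random`.
#' @param n_sites Trial locations per year.
#' @param trials_per_year Total trials registered each year (split across
#'   sites by the policy).
#' @param years Integer vector of years covered.
#' @param seed Integer seed; recorded in all outputs.
#' @return A `country_blueprint` list.
#' @export
country_blueprint <- function(name, lat_range = c(40, 45),
                              lon_range = c(10, 15), spacing_deg = 0.5,
                              pattern = c("uniform", "urban_poles", "gradient"),
                              n_poles = 2, pole_mass_share = 0.6,
                              pole_dispersion = 1,
                              total_population = 5e6, incidence_rate = 300,
                              site_policy = c("concentrated", "proportional",
                                              "random"),
                              n_sites = 3, trials_per_year = 20,
                              years = 2019, seed = 1L) {
  pattern <- match.arg(pattern)
  site_policy <- match.arg(site_policy)
  if (diff(range(lat_range)) <= 0 || diff(range(lon_range)) <= 0) {
    stop_ctaccess("degenerate bounding box", "ctaccess_validation_error")
  }
  if (total_population <= 0) {
    stop_ctaccess("'total_population' must be > 0", "ctaccess_validation_error")
  }
  if (incidence_rate <= 0) {
    stop_ctaccess("'incidence_rate' must be > 0", "ctaccess_validation_error")
  }
  structure(list(name = name, lat_range = sort(lat_range),
                 lon_range = sort(lon_range), spacing_deg = spacing_deg,
                 pattern = pattern, n_poles = n_poles,
                 pole_mass_share = pole_mass_share,
                 pole_dispersion = pole_dispersion,
                 total_population = total_population,
                 incidence_rate = incidence_rate, site_policy = site_policy,
                 n_sites = n_sites, trials_per_year = trials_per_year,
                 years = sort(unique(as.integer(years))),
                 seed = as.integer(seed)),
            class = "country_blueprint")
}

# integer allocation summing exactly to the target (largest-remainder
# method: every cell ends within one unit of its real share)
round_preserving_total <- function(x, total) {
  f <- floor(x)
  rem <- round(total - sum(f))
  if (rem > 0) {
    idx <- order(x - f, decreasing = TRUE)[seq_len(rem)]
    f[idx] <- f[idx] + 1
  }
  f
}

#' Generate a synthetic country
#'
#' @param bp A [country_blueprint()].
#' @return list with `grid` ([population_grid()]), `sites`
#'   ([trial_sites()] covering the blueprint years), and `incidence`
#'   ([incidence_table()] with the country's rate). Deterministic under
#'   the blueprint seed.
#' @export
make_country <- function(bp) {
  lats <- seq(bp$lat_range[1L], bp$lat_range[2L], by = bp$spacing_deg)
  lons <- seq(bp$lon_range[1L], bp$lon_range[2L], by = bp$spacing_deg)
  if (!length(lats) || !length(lons)) {
    stop_ctaccess("bounding box holds no grid points at this spacing",
                  "ctaccess_validation_error")
  }
  cells <- expand.grid(lat = lats, lon = lons, KEEP.OUT.ATTRS = FALSE)
  n <- nrow(cells)
  li <- match(cells$lat, lats)          # index-space coordinates
  lj <- match(cells$lon, lons)

  pop <- withr::with_seed(bp$seed, {
    switch(bp$pattern,
      uniform = rep(bp$total_population / n, n),
      gradient = {
        w <- lj / sum(lj)
        bp$total_population * w
      },
      urban_poles = {
        poles <- sample.int(n, bp$n_poles)
        # decreasing pole shares (largest pole holds the biggest slice)
        share <- 2^-(seq_len(bp$n_poles) - 1L)
        share <- share / sum(share) * bp$pole_mass_share
        dens <- rep((1 - bp$pole_mass_share) / n, n)
        for (p in seq_along(poles)) {
          d2 <- (li - li[poles[p]])^2 + (lj - lj[poles[p]])^2
          kern <- if (bp$pole_dispersion > 0) {
            exp(-d2 / (2 * bp$pole_dispersion^2))
          } else {
            as.numeric(d2 == 0)
          }
          dens <- dens + share[p] * kern / sum(kern)
        }
        bp$total_population * dens / sum(dens)
      })
  })
  pop <- round_preserving_total(pop, round(bp$total_population))

  grid <- population_grid(data.frame(
    id = sprintf("%s_%04d", bp$name, seq_len(n)),
    lat = cells$lat, lon = cells$lon, population = pop,
    country = bp$name, stringsAsFactors = FALSE), bp$spacing_deg)

  sites <- withr::with_seed(bp$seed + 1L, {
    do.call(rbind, lapply(bp$years, function(y) {
      make_year_sites(grid, bp, y)
    }))
  })

  list(grid = grid, sites = trial_sites(sites),
       incidence = incidence_table(data.frame(
         country = bp$name, rate_per_100k = bp$incidence_rate)))
}

# one year's supply under the blueprint's site policy
make_year_sites <- function(grid, bp, year) {
  pooled <- grid[grid$population > 0, , drop = FALSE]
  o <- order(-pooled$population, pooled$id)
  top <- pooled[o, , drop = FALSE]
  ns <- min(bp$n_sites, nrow(top))
  total <- bp$trials_per_year

  if (bp$site_policy == "concentrated") {
    loc <- top[seq_len(ns), , drop = FALSE]
    n_tr <- rep(1, ns)
    n_tr[1L] <- max(ceiling(0.8 * total), total - (ns - 1L))
    rest <- total - n_tr[1L]
    if (ns > 1L && rest > 0) {
      n_tr[-1L] <- round_preserving_total(rep(rest / (ns - 1L), ns - 1L), rest)
    }
  } else if (bp$site_policy == "proportional") {
    loc <- top[seq_len(ns), , drop = FALSE]
    n_tr <- round_preserving_total(total * loc$population / sum(loc$population),
                                   total)
  } else { # random
    pick <- sample.int(nrow(pooled), ns)
    loc <- pooled[pick, , drop = FALSE]
    n_tr <- round_preserving_total(rep(total / ns, ns), total)
  }
  keep <- n_tr >= 1
  data.frame(id = sprintf("%s_%d_s%02d", bp$name, year, seq_len(sum(keep))),
             lat = loc$lat[keep], lon = loc$lon[keep], year = year,
             n_trials = n_tr[keep], country = bp$name,
             stringsAsFactors = FALSE)
}

#' Synthetic point-to-site travel-cost matrix
#'
#' `distance` reproduces the great-circle distances; the congestion model
#' inflates each cost by a factor tied to the population rank of the
#' site's cell neighbourhood (busier destinations cost more), so every
#' cost is >= the distance.
#'
#' @param grid A [population_grid()].
#' @param sites A [trial_sites()] table.
#' @param model `"distance"` or `"distance_plus_congestion"`.
#' @param gamma Congestion strength (>= 0; 0 reduces to the distance
#'   model).
#' @param seed Unused by the deterministic models; kept so call sites can
#'   record one.
#' @return data.frame `point_id, site_id, cost` for every populated-point
#'   x site pair.
#' @export
make_cost_matrix <- function(grid, sites,
                             model = c("distance", "distance_plus_congestion"),
                             gamma = 0.3, seed = NULL) {
  model <- match.arg(model)
  pts <- grid[grid$population > 0, , drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(nrow(sites)), function(j) {
    d <- haversine_km(cbind(pts$lat, pts$lon),
                      c(sites$lat[j], sites$lon[j]))
    data.frame(point_id = pts$id, site_id = sites$id[j], cost = d,
               stringsAsFactors = FALSE)
  }))
  if (model == "distance_plus_congestion") {
    # congestion factor from the population rank of the site's own cell
    site_pop <- vapply(seq_len(nrow(sites)), function(j) {
      d <- haversine_km(cbind(pts$lat, pts$lon),
                        c(sites$lat[j], sites$lon[j]))
      pts$population[which.min(d)]
    }, numeric(1L))
    rk <- rank(site_pop, ties.method = "average") / length(site_pop)
    out$cost <- out$cost * (1 + gamma * rk[match(out$site_id, sites$id)])
  }
  out
}

#' Synthetic multi-country trend panel
#'
#' Builds `n_countries` small synthetic countries and evolves their trial
#' supply over `years` under a growth regime, returning the national index
#' series computed through the full pipeline together with total trial
#' counts:
#' * `flat` — iid Poisson trial counts at fixed sites (no trend; the null
#'   of the trend test),
#' * `linear` — deterministic +2 trials per site per year,
#' * `accelerating` — quadratic growth,
#' * `decoupled` — growth added only at the country's largest site, which
#'   sits in a low-demand corner, so trial counts grow strictly faster
#'   than accessibility by construction.
#'
#' @param n_countries Number of replicate countries.
#' @param regime Growth regime (above).
#' @param years Integer years (default 2005:2019).
#' @param seed Integer seed.
#' @return list `series` (national_series-style data.frame),
#'   `trials` (data.frame `country, year, total_trials`), and
#'   `sites_by_year` (the generated supply).
#' @export
make_trend_panel <- function(n_countries, regime = c("flat", "linear",
                                                     "accelerating",
                                                     "decoupled"),
                             years = 2005:2019, seed = 1L) {
  regime <- match.arg(regime)
  years <- sort(years)
  all_series <- NULL
  all_trials <- NULL
  all_sites <- NULL
  for (ci in seq_len(n_countries)) {
    name <- sprintf("synth%03d", ci)
    bp <- country_blueprint(
      name = name, lat_range = c(40, 43.5), lon_range = c(10, 13.5),
      spacing_deg = 0.5, pattern = "urban_poles", n_poles = 1,
      pole_mass_share = 0.7, pole_dispersion = 1,
      total_population = 5e6, incidence_rate = 300,
      site_policy = "proportional", n_sites = 3, trials_per_year = 24,
      years = years[1L], seed = seed + ci)
    cty <- make_country(bp)

    if (regime == "decoupled") {
      # the largest site sits in the low-demand corner: its per-trial
      # capture of the demand surface is below the supply-weighted mean,
      # so concentrating growth there decouples trials from accessibility
      ctr_lat <- mean(bp$lat_range)
      ctr_lon <- mean(bp$lon_range)
      d_ctr <- (cty$grid$lat - ctr_lat)^2 + (cty$grid$lon - ctr_lon)^2
      ctrs <- order(d_ctr, cty$grid$id)[1:2]
      base <- data.frame(
        id = paste0(name, c("_hub", "_c1", "_c2")),
        lat = c(bp$lat_range[1L], cty$grid$lat[ctrs]),
        lon = c(bp$lon_range[1L], cty$grid$lon[ctrs]),
        n_trials = c(12, 6, 6), country = name, stringsAsFactors = FALSE)
    } else {
      base <- as.data.frame(cty$sites)
      base$year <- NULL
    }

    sites_y <- withr::with_seed(seed * 1000L + ci, {
      do.call(rbind, lapply(seq_along(years), function(t) {
        n_tr <- regime_trials(base$n_trials, t, regime)
        data.frame(id = paste0(base$id, "_y", years[t]),
                   lat = base$lat, lon = base$lon, year = years[t],
                   n_trials = n_tr, country = name,
                   stringsAsFactors = FALSE)
      }))
    })
    # a site that drew zero trials simply supplies nothing that year
    sites_y <- trial_sites(sites_y[sites_y$n_trials >= 1, , drop = FALSE])

    ser <- national_series(cty$grid, sites_y, cty$incidence,
                           impedance_spec(), years = years)
    tri <- stats::aggregate(n_trials ~ year, data = as.data.frame(sites_y), sum)
    all_series <- rbind(all_series, ser)
    all_trials <- rbind(all_trials,
                        data.frame(country = name, year = tri$year,
                                   total_trials = tri$n_trials,
                                   stringsAsFactors = FALSE))
    all_sites <- rbind(all_sites, as.data.frame(sites_y))
  }
  list(series = structure(all_series,
                          class = c("national_series", "data.frame")),
       trials = all_trials, sites_by_year = all_sites)
}

# per-site trial counts at year step t (t = 1 is the base year)
regime_trials <- function(base_n, t, regime) {
  switch(regime,
    flat = stats::rpois(length(base_n), base_n),
    linear = base_n + 2 * (t - 1L),
    accelerating = base_n + (t - 1L)^2,
    decoupled = {
      n <- base_n
      big <- order(-n)[1L]
      n[big] <- n[big] + 4 * (t - 1L)
      n
    })
}
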