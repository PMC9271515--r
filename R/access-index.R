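## Local and national accessibility indices (dAI / tAI).
##
## The local index at grid point i served by its nearest site j is
##   dAI(i) = n_j / log(s_i) * (1 / d_ij)^beta
## with s_i the expected patient count of the cell, d_ij the great-circle
## distance (floored), and beta = 0.5 by default. The national index is the
## average of local values weighted on log(s_i).

#' Impedance specification
#'
#' Parameters of the distance-decay term and of the log-patient weighting.
#'
#' @param beta Impedance exponent on distance/cost (> 0, default 0.5:
#'   inverse square-root decay, the regime describing human mobility at the
#'   patient-to-site travel scale).
#' @param distance_floor_km Minimum separation in km before the power law is
#'   applied. `NULL` (default) floors each point at half its grid-cell
#'   diagonal, which shrinks with latitude; a positive scalar applies one
#'   floor everywhere.
#' @param cost_mode `"distance"` (great-circle km) or `"travel_cost"`
#'   (generalized cost supplied via a cost matrix).
#' @param log_base Base of the logarithm applied to expected patients
#'   (default natural log). Relative comparisons within a country are
#'   invariant to the base.
#' @param scale_per_100k Divide the population x incidence product by
#'   100 000 so s_i is an expected patient count (default TRUE); FALSE
#'   reproduces the raw product.
#' @param cumulative_years If TRUE a site contributes to year y all trials
#'   registered up to y; default FALSE (per-registration-year supply).
#' @return An `impedance_spec` list.
#' @export
impedance_spec <- function(beta = 0.5, distance_floor_km = NULL,
                           cost_mode = c("distance", "travel_cost"),
                           log_base = exp(1), scale_per_100k = TRUE,
                           cumulative_years = FALSE) {
  cost_mode <- match.arg(cost_mode)
  if (!is.finite(beta) || beta < 0) {
    stop_ctaccess("impedance exponent 'beta' must be >= 0",
                  "ctaccess_config_error")
  }
  if (!is.null(distance_floor_km) &&
      (!is.finite(distance_floor_km) || distance_floor_km <= 0)) {
    stop_ctaccess("'distance_floor_km' must be > 0 (or NULL for automatic)",
                  "ctaccess_config_error")
  }
  if (!is.finite(log_base) || log_base <= 1) {
    stop_ctaccess("'log_base' must be > 1", "ctaccess_config_error")
  }
  structure(list(beta = beta, distance_floor_km = distance_floor_km,
                 cost_mode = cost_mode, log_base = log_base,
                 scale_per_100k = scale_per_100k,
                 cumulative_years = cumulative_years),
            class = "impedance_spec")
}

# half grid-cell diagonal at a given latitude, km; the average distance of
# persons inside a cell to its centre is of this order, and it keeps a point
# co-located with a site from producing an infinite index
auto_floor_km <- function(lat, spacing_deg) {
  km_per_deg <- pi * EARTH_RADIUS_KM / 180
  spacing_deg * km_per_deg * sqrt(1 + cos(lat * pi / 180)^2) / 2
}

# log patient volume clamped below at 1; shared by the local formula's
# denominator and the national aggregation weights
log_weight <- function(patients, log_base = exp(1)) {
  pmax(log(pmax(patients, 1), base = log_base), 1)
}

#' Local accessibility value
#'
#' Evaluates the gravity-model formula `n_j / log(s_i) * (1/d)^beta` for
#' one (or a vector of) point-site pair(s). The log denominator is clamped
#' below at 1 and the distance at the floor. Points with no serving site
#' (`n_trials` 0 or NA) score 0.
#'
#' @param n_trials Trials at the serving site (n_j).
#' @param distance_km Separation (or generalized cost) to the serving site.
#' @param patients Expected patients at the point (s_i).
#' @param spec An [impedance_spec()]; its `distance_floor_km` must be set
#'   (compute_surface resolves the automatic floor from the grid).
#' @param floor_km Optional per-point floor overriding the spec's.
#' @return Non-negative local index values.
#' @export
local_dai <- function(n_trials, distance_km, patients, spec = impedance_spec(),
                      floor_km = NULL) {
  if (is.null(floor_km)) floor_km <- spec$distance_floor_km
  if (is.null(floor_km)) {
    stop_ctaccess("no distance floor: set 'distance_floor_km' in the spec or pass 'floor_km'",
                  "ctaccess_config_error")
  }
  if (any(floor_km <= 0)) {
    stop_ctaccess("distance floor must be > 0", "ctaccess_config_error")
  }
  if (any(patients < 0, na.rm = TRUE)) {
    stop_ctaccess("'patients' must be >= 0", "ctaccess_validation_error")
  }
  n <- ifelse(is.na(n_trials), 0, n_trials)
  d <- pmax(distance_km, floor_km)
  val <- n / log_weight(patients, spec$log_base) * (1 / d)^spec$beta
  ifelse(n <= 0, 0, val)
}

## ---- surface computation ---------------------------------------------------

# year filter honouring per-registration-year vs cumulative supply
filter_sites_year <- function(sites, year, cumulative = FALSE) {
  if (is.null(year)) return(sites)
  keep <- if (cumulative) sites$year <= year else sites$year == year
  sites[keep, , drop = FALSE]
}

# vectorised nearest assignment: distances of every populated point to every
# site, ties broken by (larger n_trials, then site id)
assign_nearest <- function(lat, lon, sites) {
  np <- length(lat)
  if (nrow(sites) == 0L) {
    return(list(site_id = rep(NA_character_, np),
                n_trials = rep(NA_real_, np),
                distance_km = rep(NA_real_, np)))
  }
  pts <- cbind(lat, lon)
  dm <- vapply(seq_len(nrow(sites)), function(j) {
    haversine_km(pts, c(sites$lat[j], sites$lon[j]))
  }, numeric(np))
  dm <- matrix(dm, nrow = np)
  pick <- vapply(seq_len(np), function(i) {
    pick_nearest(dm[i, ], sites$n_trials, sites$id)
  }, integer(1L))
  list(site_id = sites$id[pick], n_trials = sites$n_trials[pick],
       distance_km = dm[cbind(seq_len(np), pick)])
}

#' Accessibility surface
#'
#' Computes the local index for every populated grid point: expected
#' patients from population and national incidence, nearest-site
#' assignment, then the gravity formula. Countries (or whole grids) without
#' any site score 0 everywhere — the "no accessibility" convention.
#'
#' @param grid A [population_grid()].
#' @param sites A [trial_sites()] table.
#' @param incidence An [incidence_table()] covering every country of the grid.
#' @param spec An [impedance_spec()].
#' @param year Restrict supply to this registration year (`NULL`: use all
#'   rows as given).
#' @param within_country If TRUE each point may only be served by a site of
#'   its own country; default FALSE (nearest site regardless of borders).
#' @return An `access_surface` data.frame: one row per populated point with
#'   `point_id, lat, lon, country, population, patients, local_value,
#'   weight, serving_site_id, distance_km, aggregable`. Points with at most
#'   one expected patient carry `aggregable = FALSE` and are excluded from
#'   national aggregation (their log-weight is not meaningful).
#' @export
compute_surface <- function(grid, sites, incidence, spec = impedance_spec(),
                            year = NULL, within_country = FALSE) {
  sites <- filter_sites_year(sites, year, spec$cumulative_years)
  pts <- grid[grid$population > 0, , drop = FALSE]
  missing_rate <- setdiff(unique(pts$country), incidence$country)
  if (length(missing_rate)) {
    stop_ctaccess(paste0("missing incidence for: ",
                         paste(sort(missing_rate), collapse = ", ")),
                  "ctaccess_missing_incidence")
  }
  rate <- incidence$rate_per_100k[match(pts$country, incidence$country)]
  patients <- patients_at_point(pts$population, rate, spec$scale_per_100k)

  if (within_country) {
    asg <- list(site_id = rep(NA_character_, nrow(pts)),
                n_trials = rep(NA_real_, nrow(pts)),
                distance_km = rep(NA_real_, nrow(pts)))
    for (ctry in unique(pts$country)) {
      sel <- pts$country == ctry
      a <- assign_nearest(pts$lat[sel], pts$lon[sel],
                          sites[sites$country == ctry, , drop = FALSE])
      asg$site_id[sel] <- a$site_id
      asg$n_trials[sel] <- a$n_trials
      asg$distance_km[sel] <- a$distance_km
    }
  } else {
    asg <- assign_nearest(pts$lat, pts$lon, sites)
  }

  floor_km <- spec$distance_floor_km
  if (is.null(floor_km)) {
    floor_km <- auto_floor_km(pts$lat, attr(grid, "spacing_deg") %||% 0.5)
  }
  out <- data.frame(
    point_id = pts$id, lat = pts$lat, lon = pts$lon,
    country = pts$country, population = pts$population,
    patients = patients,
    local_value = local_dai(asg$n_trials, asg$distance_km, patients,
                            spec, floor_km = floor_km),
    weight = log_weight(patients, spec$log_base),
    serving_site_id = asg$site_id,
    serving_n_trials = asg$n_trials,
    distance_km = asg$distance_km,
    aggregable = patients > 1,
    stringsAsFactors = FALSE
  )
  structure(out, year = year, spec = spec,
            floor_km = floor_km,
            class = c("access_surface", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' National accessibility index
#'
#' Average of local values weighted on the (clamped) log expected patient
#' count; only aggregable points enter. An all-zero surface yields 0; a
#' surface with no aggregable point is an error.
#'
#' @param surface An `access_surface` (typically one country's rows).
#' @return Scalar index value >= 0.
#' @export
national_index <- function(surface) {
  s <- surface[surface$aggregable, , drop = FALSE]
  if (nrow(s) == 0L) {
    stop_ctaccess("no weighable population: every point excluded",
                  "ctaccess_no_weighable_population")
  }
  if (all(s$local_value == 0)) return(0)
  sum(s$local_value * s$weight) / sum(s$weight)
}

#' National index series
#'
#' Computes the per-country national index for each requested year.
#'
#' @inheritParams compute_surface
#' @param years Integer vector of years.
#' @param countries Countries to report (default: all in the grid).
#' @return A `national_series` data.frame `country, year, value`, years
#'   ascending within country.
#' @export
national_series <- function(grid, sites, incidence, spec = impedance_spec(),
                            years, countries = NULL,
                            within_country = FALSE) {
  countries <- countries %||% sort(unique(grid$country))
  res <- lapply(sort(years), function(y) {
    surf <- compute_surface(grid, sites, incidence, spec, year = y,
                            within_country = within_country)
    data.frame(country = countries, year = y,
               value = vapply(countries, function(ctry) {
                 national_index(surf[surf$country == ctry, , drop = FALSE])
               }, numeric(1L)),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$country, out$year), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("national_series", "data.frame"))
}

## ---- travel-cost variant ---------------------------------------------------

#' Travel-cost accessibility surface (tAI)
#'
#' Identical formula with a generalized travel cost replacing great-circle
#' distance; the serving site is the cost-argmin (same tie-break). With a
#' cost matrix numerically equal to the distances the tAI surface equals
#' the dAI surface.
#'
#' @inheritParams compute_surface
#' @param costs data.frame `point_id, site_id, cost` covering every
#'   populated-point x site pair (costs >= 0; the impedance floor applies).
#' @return An `access_surface`; `distance_km` holds the serving cost.
#' @export
compute_tai <- function(grid, sites, incidence, costs,
                        spec = impedance_spec(), year = NULL) {
  sites <- filter_sites_year(sites, year, spec$cumulative_years)
  pts <- grid[grid$population > 0, , drop = FALSE]
  missing_rate <- setdiff(unique(pts$country), incidence$country)
  if (length(missing_rate)) {
    stop_ctaccess(paste0("missing incidence for: ",
                         paste(sort(missing_rate), collapse = ", ")),
                  "ctaccess_missing_incidence")
  }
  rate <- incidence$rate_per_100k[match(pts$country, incidence$country)]
  patients <- patients_at_point(pts$population, rate, spec$scale_per_100k)

  np <- nrow(pts)
  if (nrow(sites) == 0L) {
    asg <- list(site_id = rep(NA_character_, np),
                n_trials = rep(NA_real_, np), cost = rep(NA_real_, np))
  } else {
    key <- paste(costs$point_id, costs$site_id, sep = "\r")
    cm <- matrix(NA_real_, nrow = np, ncol = nrow(sites))
    for (j in seq_len(nrow(sites))) {
      idx <- match(paste(pts$id, sites$id[j], sep = "\r"), key)
      cm[, j] <- costs$cost[idx]
    }
    if (anyNA(cm)) {
      bad <- which(is.na(cm), arr.ind = TRUE)[1L, ]
      stop_ctaccess(sprintf("cost matrix missing pair (point %s, site %s)",
                            pts$id[bad[1L]], sites$id[bad[2L]]),
                    "ctaccess_missing_cost")
    }
    pick <- vapply(seq_len(np), function(i) {
      pick_nearest(cm[i, ], sites$n_trials, sites$id)
    }, integer(1L))
    asg <- list(site_id = sites$id[pick], n_trials = sites$n_trials[pick],
                cost = cm[cbind(seq_len(np), pick)])
  }

  floor_km <- spec$distance_floor_km
  if (is.null(floor_km)) {
    floor_km <- auto_floor_km(pts$lat, attr(grid, "spacing_deg") %||% 0.5)
  }
  out <- data.frame(
    point_id = pts$id, lat = pts$lat, lon = pts$lon,
    country = pts$country, population = pts$population,
    patients = patients,
    local_value = local_dai(asg$n_trials, asg$cost, patients,
                            spec, floor_km = floor_km),
    weight = log_weight(patients, spec$log_base),
    serving_site_id = asg$site_id,
    serving_n_trials = asg$n_trials,
    distance_km = asg$cost,
    aggregable = patients > 1,
    stringsAsFactors = FALSE
  )
  structure(out, year = year, spec = spec,
            floor_km = floor_km,
            class = c("access_surface", "data.frame"))
}

## ---- cross-country normalization -------------------------------------------

#' Express national indices relative to a reference country
#'
#' Percent-of-reference per country: per year when `years` is NULL, or the
#' ratio of period means over a year window (the convention used to rank
#' countries against a stable reference such as the United States).
#'
#' @param series A `national_series` data.frame (`country, year, value`).
#' @param reference_country Country whose value defines 100.
#' @param years Optional closed year window for period-mean ratios.
#' @return data.frame with `pct_of_reference` and a logical `undefined`
#'   column flagging years (or windows) where the reference value is 0 —
#'   flagged, never silently dropped.
#' @export
normalize_to_reference <- function(series, reference_country, years = NULL) {
  if (!reference_country %in% series$country) {
    stop_ctaccess(sprintf("reference country '%s' absent from series",
                          reference_country), "ctaccess_validation_error")
  }
  if (!is.null(years)) {
    sel <- series$year %in% years
    means <- tapply(series$value[sel], series$country[sel], mean)
    ref <- means[[reference_country]]
    out <- data.frame(country = names(means),
                      pct_of_reference = if (ref > 0) 100 * as.numeric(means) / ref
                                         else NA_real_,
                      undefined = ref <= 0,
                      stringsAsFactors = FALSE, row.names = NULL)
    return(out)
  }
  ref <- series[series$country == reference_country, c("year", "value")]
  rv <- ref$value[match(series$year, ref$year)]
  undef <- is.na(rv) | rv <= 0
  data.frame(country = series$country, year = series$year,
             pct_of_reference = ifelse(undef, NA_real_,
                                       100 * series$value / rv),
             undefined = undef, stringsAsFactors = FALSE)
}

## ---- exports ---------------------------------------------------------------

#' Write an accessibility surface to CSV / GeoJSON
#'
#' The CSV carries `point_id,lat,lon,local_value,weight,serving_site_id,
#' distance_km`; the GeoJSON is a FeatureCollection of Point features with
#' the same properties, for mapping.
#'
#' @param surface An `access_surface`.
#' @param path Output path.
#' @export
write_surface_csv <- function(surface, path) {
  cols <- c("point_id", "lat", "lon", "local_value", "weight",
            "serving_site_id", "distance_km")
  write_table_csv(as.data.frame(surface)[cols], path)
}

#' @rdname write_surface_csv
#' @export
write_surface_geojson <- function(surface, path) {
  feats <- lapply(seq_len(nrow(surface)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(surface$lon[i], surface$lat[i])),
         properties = list(point_id = surface$point_id[i],
                           local_value = surface$local_value[i],
                           weight = surface$weight[i],
                           serving_site_id = surface$serving_site_id[i],
                           distance_km = surface$distance_km[i]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
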