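## Scenario simulation and greedy optimal placement of new trial sites.
##
## A candidate site only changes the local value of points for which it
## becomes the nearest supply, so a single candidate is evaluated by an
## incremental update of the committed surface; this is exact (and tested
## against full recomputation) because nearest-site selection is a pairwise
## tournament under the deterministic tie-break.

resolve_floor <- function(spec, lat, spacing_deg) {
  spec$distance_floor_km %||% auto_floor_km(lat, spacing_deg)
}

# incremental national index after adding a hypothetical site; surface must
# hold exactly the target country's populated points
index_with_candidate <- function(surface, cand_lat, cand_lon, cand_id,
                                 n_new, spec, spacing_deg) {
  d_c <- haversine_km(cbind(surface$lat, surface$lon), c(cand_lat, cand_lon))
  cur_d <- surface$distance_km
  cur_n <- surface$serving_n_trials
  cur_id <- surface$serving_site_id
  wins <- is.na(cur_d) |
    d_c < cur_d - DIST_TIE_TOL_KM |
    (abs(d_c - cur_d) <= DIST_TIE_TOL_KM &
       (n_new > cur_n | (n_new == cur_n & cand_id < cur_id)))
  if (!any(wins)) return(national_index(surface))
  floor_km <- resolve_floor(spec, surface$lat, spacing_deg)
  new_n <- ifelse(wins, n_new, cur_n)
  new_d <- ifelse(wins, d_c, cur_d)
  surface$local_value <- local_dai(new_n, new_d, surface$patients,
                                   spec, floor_km = floor_km)
  national_index(surface)
}

#' National index with a hypothetical new site
#'
#' Evaluates the target country's national index as if a site with `n_new`
#' trials were added at a candidate grid point, updating only the points
#' the candidate would capture (exactly equivalent to recomputing the whole
#' surface with the site added).
#'
#' @inheritParams compute_surface
#' @param candidate_id Id of a grid point of the target country.
#' @param n_new Trials at the hypothetical site (>= 1).
#' @param country Target country; default: the candidate point's country.
#' @param surface Optional precomputed baseline surface of the target
#'   country (as produced by [compute_surface()] and subset to it), to
#'   avoid recomputation inside search loops.
#' @return Scalar national index value.
#' @export
evaluate_candidate <- function(grid, sites, incidence, spec = impedance_spec(),
                               candidate_id, n_new, year = NULL,
                               country = NULL, surface = NULL) {
  if (n_new < 1) stop_ctaccess("'n_new' must be >= 1", "ctaccess_validation_error")
  row <- grid[grid$id == candidate_id, , drop = FALSE]
  if (nrow(row) != 1L) {
    stop_ctaccess(sprintf("candidate '%s' is not a grid point", candidate_id),
                  "ctaccess_validation_error")
  }
  country <- country %||% row$country
  if (row$country != country) {
    stop_ctaccess("candidate lies outside the target country's grid",
                  "ctaccess_validation_error")
  }
  if (is.null(surface)) {
    surface <- compute_surface(grid, sites, incidence, spec, year = year)
    surface <- surface[surface$country == country, , drop = FALSE]
  }
  index_with_candidate(surface, row$lat, row$lon, paste0("cand_", candidate_id),
                       n_new, spec, attr(grid, "spacing_deg") %||% 0.5)
}

#' Greedy placement of new trial sites
#'
#' Sequentially adds `k` hypothetical sites of `n_new` trials each to
#' maximize the target country's national index: every populated grid
#' point of the country is evaluated, the best is committed, and the
#' search repeats. Ties are broken by (gain, population, point id) so the
#' result is deterministic. At `k = 1` the greedy choice is by
#' construction the global optimum over the candidate set.
#'
#' @inheritParams evaluate_candidate
#' @param country Target country.
#' @param k Number of locations to add (>= 1).
#' @param n_new Trials per added site; default: the median `n_trials` of
#'   the country's existing sites in the year (1 if it has none).
#' @param candidate_top_n Optional pruning: only the top-N candidates by
#'   population are searched (default: all populated points).
#' @return A `placement_result` list: `baseline` index, `steps` data.frame
#'   (chosen point, index after, per-step and cumulative relative gain in
#'   %), and the full `evaluations` log of every candidate index at every
#'   step.
#' @export
greedy_place <- function(grid, sites, incidence, spec = impedance_spec(),
                         country, year = NULL, n_new = NULL, k = 1,
                         candidate_top_n = Inf) {
  if (k < 1) stop_ctaccess("'k' must be >= 1", "ctaccess_validation_error")
  spacing <- attr(grid, "spacing_deg") %||% 0.5
  cand <- grid[grid$country == country & grid$population > 0, , drop = FALSE]
  if (nrow(cand) == 0L) {
    stop_ctaccess(sprintf("no populated candidate points in '%s'", country),
                  "ctaccess_validation_error")
  }
  if (is.finite(candidate_top_n) && candidate_top_n < nrow(cand)) {
    o <- order(-cand$population, cand$id)
    cand <- cand[o[seq_len(candidate_top_n)], , drop = FALSE]
  }
  if (is.null(n_new)) {
    own <- filter_sites_year(sites, year, spec$cumulative_years)
    own <- own[own$country == country, , drop = FALSE]
    n_new <- if (nrow(own)) max(1, stats::median(own$n_trials)) else 1
  }

  cur_sites <- filter_sites_year(sites, year, spec$cumulative_years)
  surf_all <- compute_surface(grid, cur_sites, incidence, spec, year = NULL)
  surface <- surf_all[surf_all$country == country, , drop = FALSE]
  baseline <- national_index(surface)

  steps <- NULL
  evals <- NULL
  prev_index <- baseline
  for (step in seq_len(k)) {
    vals <- vapply(seq_len(nrow(cand)), function(i) {
      index_with_candidate(surface, cand$lat[i], cand$lon[i],
                           paste0("opt", step), n_new, spec, spacing)
    }, numeric(1L))
    evals <- rbind(evals, data.frame(step = step, point_id = cand$id,
                                     index = vals, stringsAsFactors = FALSE))
    gain <- vals - prev_index
    best <- order(-gain, -cand$population, cand$id)[1L]
    chosen <- cand[best, , drop = FALSE]

    new_site <- data.frame(id = paste0("opt", step), lat = chosen$lat,
                           lon = chosen$lon,
                           year = year %||% max(cur_sites$year, 0),
                           n_trials = n_new, country = country,
                           stringsAsFactors = FALSE)
    cur_sites <- rbind(cur_sites[names(new_site)], new_site)
    surf_all <- compute_surface(grid, cur_sites, incidence, spec, year = NULL)
    surface <- surf_all[surf_all$country == country, , drop = FALSE]
    after <- national_index(surface)

    steps <- rbind(steps, data.frame(
      step = step, point_id = chosen$id, lat = chosen$lat, lon = chosen$lon,
      n_trials_added = n_new, index_after = after,
      step_gain_pct = if (prev_index > 0) 100 * (after - prev_index) / prev_index
                      else ifelse(after > 0, Inf, 0),
      gain_pct = if (baseline > 0) 100 * (after - baseline) / baseline
                 else ifelse(after > 0, Inf, 0),
      stringsAsFactors = FALSE))
    prev_index <- after
  }
  structure(list(country = country, year = year, n_new = n_new,
                 baseline = baseline, steps = steps, evaluations = evals,
                 surface = surface),
            class = "placement_result")
}

## ---- scenario simulation ---------------------------------------------------

#' Scenario specification
#'
#' Exactly one perturbation of the supply or demand, with its magnitude
#' parameters and the seed that makes any random element reproducible.
#'
#' @param kind One of `add_sites`, `scale_trials`, `scale_population`,
#'   `move_sites`.
#' @param magnitude Named list of parameters: `add_sites` uses `n_sites`,
#'   `n_trials`; `scale_trials` and `scale_population` use `factor`;
#'   `move_sites` uses either a deterministic shift `dlat`/`dlon` or a
#'   random `jitter_sd_deg`.
#' @param seed Integer seed recorded in the result.
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(kind = c("add_sites", "scale_trials",
                                   "scale_population", "move_sites"),
                          magnitude = list(), seed = 1L) {
  kind <- match.arg(kind)
  structure(list(kind = kind, magnitude = magnitude, seed = as.integer(seed)),
            class = "scenario_spec")
}

#' Run a resource-allocation scenario
#'
#' Applies one perturbation to the inputs, recomputes the target country's
#' national index, and reports the relative gain. Reproducible under the
#' scenario seed.
#'
#' @inheritParams compute_surface
#' @param scenario A [scenario_spec()].
#' @param country Target country (default: the grid's single country).
#' @return list `baseline, perturbed, gain_pct, scenario`.
#' @export
run_scenario <- function(grid, sites, incidence, spec = impedance_spec(),
                         scenario, country = NULL, year = NULL) {
  if (!inherits(scenario, "scenario_spec")) {
    stop_ctaccess("'scenario' must be a scenario_spec()", "ctaccess_config_error")
  }
  country <- country %||% unique(grid$country)
  if (length(country) != 1L) {
    stop_ctaccess("specify one target country", "ctaccess_validation_error")
  }
  idx <- function(g, s) {
    surf <- compute_surface(g, s, incidence, spec, year = year)
    national_index(surf[surf$country == country, , drop = FALSE])
  }
  baseline <- idx(grid, sites)

  m <- scenario$magnitude
  g2 <- grid
  s2 <- sites
  withr::with_seed(scenario$seed, {
    if (scenario$kind == "add_sites") {
      pool <- grid[grid$country == country & grid$population > 0, , drop = FALSE]
      pick <- pool[sample.int(nrow(pool), m$n_sites %||% 1L), , drop = FALSE]
      add <- data.frame(id = paste0("scn", seq_len(nrow(pick))),
                        lat = pick$lat, lon = pick$lon,
                        year = year %||% max(sites$year, 0),
                        n_trials = m$n_trials %||% 1,
                        country = country, stringsAsFactors = FALSE)
      s2 <- rbind(as.data.frame(sites)[names(add)], add)
    } else if (scenario$kind == "scale_trials") {
      s2$n_trials <- s2$n_trials * (m$factor %||% 2)
    } else if (scenario$kind == "scale_population") {
      g2$population <- g2$population * (m$factor %||% 0.5)
    } else if (scenario$kind == "move_sites") {
      if (!is.null(m$jitter_sd_deg)) {
        s2$lat <- pmin(90, pmax(-90, s2$lat + stats::rnorm(nrow(s2), 0, m$jitter_sd_deg)))
        s2$lon <- pmin(180, pmax(-180, s2$lon + stats::rnorm(nrow(s2), 0, m$jitter_sd_deg)))
      } else {
        s2$lat <- pmin(90, pmax(-90, s2$lat + (m$dlat %||% 0)))
        s2$lon <- pmin(180, pmax(-180, s2$lon + (m$dlon %||% 0)))
      }
    }
  })
  perturbed <- idx(g2, s2)
  list(baseline = baseline, perturbed = perturbed,
       gain_pct = if (baseline > 0) 100 * (perturbed - baseline) / baseline
                  else ifelse(perturbed > 0, Inf, 0),
       scenario = scenario)
}

#' Demonstration: a new site can lower a point's local value
#'
#' Nearest-only supply is non-additive: a small site inserted between a
#' point and a larger site captures the point and can lower its local
#' value. Builds a two-point toy (one point 100 km from a 10-trial site)
#' and inserts a `new_site_trials`-trial site at `new_site_distance_km`,
#' returning the before/after local and national values.
#'
#' @param new_site_distance_km Distance of the inserted site from the
#'   focal point (default 25 km).
#' @param new_site_trials Trials at the inserted site (default 1).
#' @param spec Impedance spec (floor defaults to 1 km so the closed-form
#'   values are easy to read).
#' @return list with `before_local`, `after_local`, `before_national`,
#'   `after_national`, `local_lowered`.
#' @export
adding_site_can_lower_local <- function(new_site_distance_km = 25,
                                        new_site_trials = 1,
                                        spec = impedance_spec(distance_floor_km = 1)) {
  km_per_deg <- pi * EARTH_RADIUS_KM / 180
  grid <- population_grid(data.frame(
    id = c("p_focal", "p_near_big"),
    lat = c(0, 0),
    lon = c(0, 100 / km_per_deg),
    population = c(1000, 50000),
    country = "toyland"), spacing_deg = 0.5)
  inc <- incidence_table(data.frame(country = "toyland", rate_per_100k = 200))
  big <- data.frame(id = "s_big", lat = 0, lon = 100 / km_per_deg,
                    year = 2019, n_trials = 10, country = "toyland")
  small <- data.frame(id = "s_small", lat = 0,
                      lon = new_site_distance_km / km_per_deg,
                      year = 2019, n_trials = new_site_trials,
                      country = "toyland")
  before <- compute_surface(grid, trial_sites(big), inc, spec)
  after <- compute_surface(grid, trial_sites(rbind(big, small)), inc, spec)
  list(before_local = before$local_value[before$point_id == "p_focal"],
       after_local = after$local_value[after$point_id == "p_focal"],
       before_national = national_index(before),
       after_national = national_index(after),
       local_lowered = after$local_value[after$point_id == "p_focal"] <
         before$local_value[before$point_id == "p_focal"])
}
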