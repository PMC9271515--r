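## Gini-index inequality of accessibility, globally and within countries.
##
## G = sum_{i,j} w_i w_j |x_i - x_j| / (2 W^2 mu_w), computed in O(n log n)
## from the Lorenz trapezoids of the value-sorted vector. A mean-zero vector
## (a year with no trials anywhere) has no defined inequality and returns NA.

#' Gini index
#'
#' Inequality of a non-negative vector, optionally weighted. Zero-valued
#' units (unserved areas) are legitimate observations and are included.
#'
#' @param values Non-negative numeric vector.
#' @param weights Optional positive weights, same length (default: each
#'   unit counts once).
#' @return Gini in `[0, 1]`, or `NA_real_` when the mean is zero (no
#'   defined inequality — e.g. a year with no trials at all).
#' @examples
#' gini(c(1, 1, 1, 1))   # 0: perfect equality
#' gini(c(0, 0, 0, 1))   # 0.75: one unit holds everything
#' @export
gini <- function(values, weights = NULL) {
  if (any(!is.finite(values) | values < 0)) {
    stop_ctaccess("'values' must be finite and >= 0", "ctaccess_validation_error")
  }
  if (is.null(weights)) weights <- rep(1, length(values))
  if (length(weights) != length(values)) {
    stop_ctaccess("'weights' length must match 'values'", "ctaccess_validation_error")
  }
  if (any(!is.finite(weights) | weights <= 0)) {
    stop_ctaccess("'weights' must be > 0", "ctaccess_validation_error")
  }
  if (sum(values * weights) == 0) return(NA_real_)
  o <- order(values)
  x <- values[o]
  w <- weights[o]
  p <- cumsum(w) / sum(w)                    # cumulative unit share
  L <- cumsum(w * x) / sum(w * x)            # cumulative access share
  # 1 - 2 * area under the Lorenz polygon, by trapezoids from (0,0)
  dp <- diff(c(0, p))
  1 - sum(dp * (L + c(0, head(L, -1L))))
}

#' Lorenz curve points
#'
#' Cumulative share of units against cumulative share of access for the
#' value-sorted vector, starting at (0, 0) and ending at (1, 1).
#'
#' @inheritParams gini
#' @return data.frame `cum_units, cum_access`, convex and non-decreasing.
#' @export
lorenz_points <- function(values, weights = NULL) {
  if (any(!is.finite(values) | values < 0)) {
    stop_ctaccess("'values' must be finite and >= 0", "ctaccess_validation_error")
  }
  if (sum(values) == 0) {
    stop_ctaccess("all values are zero: Lorenz curve undefined",
                  "ctaccess_validation_error")
  }
  if (is.null(weights)) weights <- rep(1, length(values))
  o <- order(values)
  x <- values[o]
  w <- weights[o]
  data.frame(cum_units = c(0, cumsum(w) / sum(w)),
             cum_access = c(0, cumsum(w * x) / sum(w * x)))
}

#' Within-country Gini of local accessibility
#'
#' One Gini per country over its grid points' local values. Countries
#' without at least one trial site in the surface's supply are excluded
#' (their inequality is not informative, matching the convention of
#' displaying only countries with at least one trial).
#'
#' @param surface An `access_surface` with a `country` column.
#' @param sites The [trial_sites()] supply the surface was computed from
#'   (already year-filtered the same way), used for the inclusion rule;
#'   `NULL` keeps every country.
#' @param year Year label carried into the result.
#' @param weights `"none"` (default: each grid point one unit) or
#'   `"population"`.
#' @return data.frame `scope, year, gini, n_units`, one row per country.
#' @export
within_country_gini <- function(surface, sites = NULL, year = NULL,
                                weights = c("none", "population")) {
  weights <- match.arg(weights)
  countries <- sort(unique(surface$country))
  if (!is.null(sites)) {
    countries <- intersect(countries, unique(sites$country))
  }
  rows <- lapply(countries, function(ctry) {
    s <- surface[surface$country == ctry, , drop = FALSE]
    w <- if (weights == "population") s$population else NULL
    data.frame(scope = ctry, year = year %||% NA_integer_,
               gini = gini(s$local_value, w), n_units = nrow(s),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Global Gini of local accessibility
#'
#' Pools every grid point of every country into one vector; the same
#' machinery as the within-country statistic, so a one-country surface
#' gives the identical number.
#'
#' @inheritParams within_country_gini
#' @param level `"points"` (default: pool grid points) or `"countries"`
#'   (Gini over national index values, one unit per country).
#' @param incidence,spec Needed only for `level = "countries"` to aggregate.
#' @return One-row data.frame `scope, year, gini, n_units`.
#' @export
global_gini <- function(surface, year = NULL,
                        weights = c("none", "population"),
                        level = c("points", "countries")) {
  weights <- match.arg(weights)
  level <- match.arg(level)
  if (nrow(surface) == 0L) {
    stop_ctaccess("empty surface", "ctaccess_validation_error")
  }
  if (level == "countries") {
    vals <- vapply(split(surface, surface$country), national_index, numeric(1L))
    g <- gini(as.numeric(vals))
    n <- length(vals)
  } else {
    w <- if (weights == "population") surface$population else NULL
    g <- gini(surface$local_value, w)
    n <- nrow(surface)
  }
  data.frame(scope = "global", year = year %||% NA_integer_,
             gini = g, n_units = n, stringsAsFactors = FALSE)
}
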