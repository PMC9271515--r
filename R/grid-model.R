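#' @keywords internal
"_PACKAGE"

#' @importFrom stats median sd pnorm pt setNames
#' @importFrom utils read.csv write.csv head tail
NULL

## ---- validation helpers ----------------------------------------------------

stop_ctaccess <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "ctaccess_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

check_coords <- function(lat, lon, what = "coordinate") {
  bad_lat <- !is.finite(lat) | lat < -90 | lat > 90
  bad_lon <- !is.finite(lon) | lon < -180 | lon > 180
  if (any(bad_lat)) {
    stop_ctaccess(sprintf("%s: 'lat' out of [-90, 90] at position %d",
                          what, which(bad_lat)[1L]), "ctaccess_validation_error")
  }
  if (any(bad_lon)) {
    stop_ctaccess(sprintf("%s: 'lon' out of [-180, 180] at position %d",
                          what, which(bad_lon)[1L]), "ctaccess_validation_error")
  }
  invisible(TRUE)
}

## ---- great-circle geodesy --------------------------------------------------

# Mean Earth radius, km (IUGG R1). All great-circle distances use this value.
EARTH_RADIUS_KM <- 6371.0088

#' Great-circle distance in kilometres
#'
#' Haversine distance between points on the sphere of radius 6371.0088 km.
#' Both arguments are recycled row-wise, so a single point against a matrix
#' of points is allowed.
#'
#' @param a,b Latitude/longitude in decimal degrees (WGS84): either a
#'   length-2 numeric `c(lat, lon)` or a two-column matrix/data.frame with
#'   columns in (lat, lon) order.
#' @return Numeric vector of distances in km.
#' @examples
#' haversine_km(c(0, 0), c(0, 1))   # ~111.195 km, one degree on the equator
#' @export
haversine_km <- function(a, b) {
  a <- coerce_latlon(a, "a")
  b <- coerce_latlon(b, "b")
  check_coords(a[, 1L], a[, 2L], "a")
  check_coords(b[, 1L], b[, 2L], "b")
  # geosphere expects (lon, lat) and returns metres
  geosphere::distHaversine(a[, c(2L, 1L), drop = FALSE],
                           b[, c(2L, 1L), drop = FALSE],
                           r = EARTH_RADIUS_KM * 1000) / 1000
}

coerce_latlon <- function(x, name) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) {
    if (length(x) != 2L) {
      stop_ctaccess(sprintf("'%s' must be c(lat, lon) or a two-column matrix", name),
                    "ctaccess_validation_error")
    }
    x <- matrix(as.numeric(x), ncol = 2L)
  }
  storage.mode(x) <- "double"
  x
}

## ---- data model constructors ----------------------------------------------

#' Population grid
#'
#' The demand surface: one row per grid cell centre with its resident
#' population and country label. Mirrors a 30-arc-min gridded population
#' raster exported to points.
#'
#' @param df data.frame with columns `id, lat, lon, population, country`.
#' @param spacing_deg Nominal grid spacing in degrees (default 0.5).
#' @return A `population_grid` (data.frame subclass) with the spacing
#'   recorded as an attribute.
#' @export
population_grid <- function(df, spacing_deg = 0.5) {
  req <- c("id", "lat", "lon", "population", "country")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop_ctaccess(paste0("grid is missing columns: ", paste(miss, collapse = ", ")),
                  "ctaccess_schema_error")
  }
  df <- as.data.frame(df)[req]
  df$id <- as.character(df$id)
  df$country <- as.character(df$country)
  if (nrow(df) == 0L) stop_ctaccess("grid has no points", "ctaccess_validation_error")
  check_coords(df$lat, df$lon, "grid")
  if (any(!is.finite(df$population) | df$population < 0)) {
    stop_ctaccess("grid: 'population' must be finite and >= 0",
                  "ctaccess_validation_error")
  }
  if (anyDuplicated(df$id)) {
    stop_ctaccess("grid: duplicate point id", "ctaccess_validation_error")
  }
  if (anyDuplicated(df[c("lat", "lon")])) {
    stop_ctaccess("grid: duplicate (lat, lon) pair", "ctaccess_validation_error")
  }
  structure(df, spacing_deg = spacing_deg,
            class = c("population_grid", "data.frame"))
}

#' Trial-site table
#'
#' The supply: geocoded trial sites with the number of trials activated per
#' registration year, plus optional funder/phase strata tags.
#'
#' @param df data.frame with columns `id, lat, lon, year, n_trials, country`
#'   and optionally `funder`, `phase`.
#' @return A `trial_sites` data.frame subclass.
#' @export
trial_sites <- function(df) {
  req <- c("id", "lat", "lon", "year", "n_trials", "country")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop_ctaccess(paste0("sites are missing columns: ", paste(miss, collapse = ", ")),
                  "ctaccess_schema_error")
  }
  keep <- c(req, intersect(c("funder", "phase"), names(df)))
  df <- as.data.frame(df)[keep]
  df$id <- as.character(df$id)
  df$country <- as.character(df$country)
  if (nrow(df)) {
    check_coords(df$lat, df$lon, "sites")
    if (any(!is.finite(df$n_trials) | df$n_trials < 1)) {
      stop_ctaccess("sites: 'n_trials' must be >= 1", "ctaccess_validation_error")
    }
  }
  structure(df, class = c("trial_sites", "data.frame"))
}

#' Cancer incidence table
#'
#' National cancer incidence rates per 100 000 persons per year.
#'
#' @param df data.frame with columns `country, rate_per_100k` (rates > 0).
#' @return An `incidence_table` data.frame subclass.
#' @export
incidence_table <- function(df) {
  req <- c("country", "rate_per_100k")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop_ctaccess(paste0("incidence is missing columns: ",
                         paste(miss, collapse = ", ")), "ctaccess_schema_error")
  }
  df <- as.data.frame(df)[req]
  df$country <- as.character(df$country)
  if (any(!is.finite(df$rate_per_100k) | df$rate_per_100k <= 0)) {
    stop_ctaccess("incidence: rates must be > 0", "ctaccess_validation_error")
  }
  if (anyDuplicated(df$country)) {
    stop_ctaccess("incidence: duplicate country", "ctaccess_validation_error")
  }
  structure(df, class = c("incidence_table", "data.frame"))
}

## ---- nearest-site assignment ----------------------------------------------

# Distance comparisons treat |d1 - d2| <= tol km as a tie so that
# geometrically symmetric configurations are broken by the documented
# deterministic rule rather than by floating-point noise.
DIST_TIE_TOL_KM <- 1e-9

#' Nearest trial site for one grid point
#'
#' Returns the supplied site minimising great-circle distance to the point.
#' Equidistant sites are broken deterministically: larger `n_trials` first,
#' then lexicographically smaller site id.
#'
#' @param point One-row data.frame (or list) with `lat`, `lon`.
#' @param sites A [trial_sites()] table (non-empty).
#' @return list with `site_id`, `distance_km`, `n_trials`.
#' @export
nearest_site <- function(point, sites) {
  if (is.null(sites) || nrow(sites) == 0L) {
    stop_ctaccess("no supply: empty site collection", "ctaccess_no_supply")
  }
  d <- haversine_km(c(point$lat, point$lon),
                    cbind(sites$lat, sites$lon))
  pick <- pick_nearest(d, sites$n_trials, sites$id)
  list(site_id = sites$id[pick], distance_km = d[pick],
       n_trials = sites$n_trials[pick])
}

# index of the winning site given distances and tie-break keys
pick_nearest <- function(d, n_trials, ids) {
  dmin <- min(d)
  tied <- which(d <= dmin + DIST_TIE_TOL_KM)
  if (length(tied) > 1L) {
    o <- order(-n_trials[tied], ids[tied])
    tied <- tied[o]
  }
  tied[1L]
}

#' Expected patients at a grid point
#'
#' Product of cell population and the national incidence rate. With
#' `scale_per_100k = TRUE` (default) the per-100 000 rate is divided out so
#' the result is an expected patient count; turning it off reproduces the
#' raw product (relative results within a country are unaffected).
#'
#' @param population Persons in the cell (>= 0).
#' @param rate Incidence per 100 000 per year (> 0).
#' @param scale_per_100k Divide by 100 000 (default TRUE).
#' @return Expected number of patients, same length as `population`.
#' @export
patients_at_point <- function(population, rate, scale_per_100k = TRUE) {
  if (any(!is.finite(population) | population < 0)) {
    stop_ctaccess("'population' must be finite and >= 0",
                  "ctaccess_validation_error")
  }
  if (any(!is.finite(rate) | rate <= 0)) {
    stop_ctaccess("'rate' must be > 0", "ctaccess_validation_error")
  }
  if (scale_per_100k) population * rate / 1e5 else population * rate
}

## ---- CSV interfaces --------------------------------------------------------

#' Read the standard CSV inputs
#'
#' Headers are required; decimal separator is '.'.
#'
#' @param path File path.
#' @param spacing_deg Grid spacing recorded on the returned grid.
#' @return The corresponding validated object.
#' @name read_inputs
NULL

#' @rdname read_inputs
#' @export
read_grid_csv <- function(path, spacing_deg = 0.5) {
  population_grid(read.csv(path, colClasses = c(id = "character")),
                  spacing_deg = spacing_deg)
}

#' @rdname read_inputs
#' @export
read_sites_csv <- function(path) {
  trial_sites(read.csv(path, colClasses = c(id = "character")))
}

#' @rdname read_inputs
#' @export
read_incidence_csv <- function(path) {
  incidence_table(read.csv(path))
}

#' @rdname read_inputs
#' @export
read_cost_csv <- function(path) {
  df <- read.csv(path, colClasses = c(point_id = "character",
                                      site_id = "character"))
  req <- c("point_id", "site_id", "cost")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop_ctaccess(paste0("cost matrix is missing columns: ",
                         paste(miss, collapse = ", ")), "ctaccess_schema_error")
  }
  df[req]
}

# fixed 6-significant-digit formatting keeps repeated runs byte-identical;
# integer-valued columns (counts, years) are kept exact
write_table_csv <- function(df, path) {
  num <- vapply(df, function(x) {
    is.double(x) && !all(x == round(x), na.rm = TRUE)
  }, logical(1L))
  df[num] <- lapply(df[num], function(x) signif(x, 6L))
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write a grid / sites / incidence table back to CSV
#'
#' Numeric columns are written with 6 significant digits so identical runs
#' produce byte-identical files.
#'
#' @param x Object to write.
#' @param path Output path.
#' @export
write_input_csv <- function(x, path) write_table_csv(as.data.frame(x), path)
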