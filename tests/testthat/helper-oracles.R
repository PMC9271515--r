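# Independent oracles and toy builders shared across the suite.

fixture_path <- function(name, file) {
  system.file("extdata", "fixtures", name, file, package = "ctaccess",
              mustWork = TRUE)
}

read_fixture <- function(name) {
  list(grid = read_grid_csv(fixture_path(name, "grid.csv")),
       sites = read_sites_csv(fixture_path(name, "sites.csv")),
       incidence = read_incidence_csv(fixture_path(name, "incidence.csv")))
}

# O(n^2) pairwise Gini: sum |xi - xj| over all ordered pairs / (2 n^2 mean)
gini_bruteforce <- function(x, w = NULL) {
  if (is.null(w)) w <- rep(1, length(x))
  if (sum(w * x) == 0) return(NA_real_)
  num <- 0
  for (i in seq_along(x)) num <- num + sum(w[i] * w * abs(x[i] - x))
  num / (2 * sum(w)^2 * (sum(w * x) / sum(w)))
}

# all permutations of 1..n (n small)
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- (1:n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

mk_S <- function(x) {
  d <- outer(x, x, "-")
  sum(sign(d[lower.tri(d)]))
}

# exhaustive permutation two-sided p for a tie-free series
mk_perm_p <- function(x) {
  n <- length(x)
  pm <- all_perms(n)
  s_null <- apply(pm, 1L, mk_S)   # tie-free: S depends only on rank order
  mean(abs(s_null) >= abs(mk_S(x)))
}

# hand-sized surface row builder for national_index tests
surface_rows <- function(local_value, weight, aggregable = TRUE) {
  data.frame(point_id = paste0("p", seq_along(local_value)),
             local_value = local_value, weight = weight,
             aggregable = rep_len(aggregable, length(local_value)))
}

# random small instance on a lattice: unique coordinates guaranteed
random_instance <- function(seed, n_points = 60, n_sites = 2,
                            rate = 300) {
  withr::with_seed(seed, {
    lat0 <- runif(1, -50, 50)
    lon0 <- runif(1, -150, 150)
    cells <- expand.grid(lat = lat0 + 0.5 * (0:11), lon = lon0 + 0.5 * (0:11))
    pick <- sample.int(nrow(cells), n_points)
    grid <- population_grid(data.frame(
      id = sprintf("r_%03d", seq_len(n_points)),
      lat = cells$lat[pick], lon = cells$lon[pick],
      population = round(exp(rnorm(n_points, 9, 1))),
      country = "rland"))
    at <- sample.int(n_points, n_sites)
    sites <- trial_sites(data.frame(
      id = sprintf("s_%02d", seq_len(n_sites)),
      lat = grid$lat[at], lon = grid$lon[at], year = 2019,
      n_trials = sample(1:10, n_sites, replace = TRUE),
      country = "rland"))
    list(grid = grid, sites = sites,
         incidence = incidence_table(data.frame(country = "rland",
                                                rate_per_100k = rate)))
  })
}

# full-recomputation route for a hypothetical site (oracle for the
# incremental candidate evaluation)
index_with_site_full <- function(inst, point_id, n_new, cand_id,
                                 spec = impedance_spec()) {
  row <- inst$grid[inst$grid$id == point_id, ]
  extra <- data.frame(id = cand_id, lat = row$lat, lon = row$lon,
                      year = 2019, n_trials = n_new, country = row$country)
  sites2 <- trial_sites(rbind(as.data.frame(inst$sites)[names(extra)], extra))
  national_index(compute_surface(inst$grid, sites2, inst$incidence, spec))
}
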