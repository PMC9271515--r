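spec1 <- impedance_spec(distance_floor_km = 1)

test_that("local index matches the closed form on hand-evaluated cases", {
  expect_equal(local_dai(4, 4, exp(3), spec1), 4 / 3 * 1 / 2, tolerance = 1e-14)
  expect_equal(local_dai(1, 1, exp(1), spec1), 1, tolerance = 1e-14)
  # exponent-zero limit: distance drops out
  s0 <- impedance_spec(beta = 0, distance_floor_km = 1)
  expect_equal(local_dai(3, 57, exp(2), s0), 1.5, tolerance = 1e-14)
  expect_equal(local_dai(3, 2, exp(2), s0), local_dai(3, 9999, exp(2), s0))
  # no serving site scores zero
  expect_equal(local_dai(NA, NA, exp(2), spec1), 0)
})

test_that("local index is monotone in supply, distance, and patient volume", {
  withr::with_seed(7, {
    for (i in 1:50) {
      n <- sample(1:50, 1)
      d <- runif(1, 2, 500)    # above the 1 km floor
      s <- exp(runif(1, 1.1, 10))  # above the clamp
      base <- local_dai(n, d, s, spec1)
      expect_gt(local_dai(n + 1, d, s, spec1), base)
      expect_lt(local_dai(n, d * 1.5, s, spec1), base)
      expect_lte(local_dai(n, d, s * 1.5, spec1), base)
    }
  })
})

test_that("distances at or below the floor are all floored alike", {
  for (d in c(0, 0.25, 0.5, 1)) {
    expect_equal(local_dai(3, d, exp(2), spec1), local_dai(3, 1, exp(2), spec1))
  }
})

test_that("surface computation assigns nearest sites and scales as the closed form", {
  km1 <- 1 / (pi * 6371.0088 / 180)  # degrees spanning 1 km at the equator
  # two points, one site: A at floor distance, B at 4x floor -> ratio 2
  grid <- population_grid(data.frame(
    id = c("A", "B"), lat = c(0, 0), lon = c(10 * km1, 40 * km1),
    population = c(1e5, 1e5), country = "x"))
  sites <- trial_sites(data.frame(id = "s", lat = 0, lon = 0, year = 2019,
                                  n_trials = 2, country = "x"))
  inc <- incidence_table(data.frame(country = "x", rate_per_100k = 100))
  spec <- impedance_spec(distance_floor_km = 10)
  surf <- compute_surface(grid, sites, inc, spec, year = 2019)
  expect_equal(surf$local_value[surf$point_id == "A"] /
                 surf$local_value[surf$point_id == "B"], 2, tolerance = 1e-9)
  # singleton agreement with local_dai
  expect_equal(surf$local_value[1],
               local_dai(2, surf$distance_km[1], surf$patients[1], spec),
               tolerance = 1e-14)
  # no supply at all: every local value zero, index zero
  empty <- compute_surface(grid, sites, inc, spec, year = 2024)
  expect_true(all(empty$local_value == 0))
  expect_identical(national_index(empty), 0)
  # missing incidence names the country
  inc2 <- incidence_table(data.frame(country = "other", rate_per_100k = 100))
  expect_error(compute_surface(grid, sites, inc2, spec),
               "x", class = "ctaccess_missing_incidence")
})

test_that("national index is the weighted mean and stays within local bounds", {
  expect_equal(national_index(surface_rows(c(1, 3), c(1, 1))), 2)
  expect_equal(national_index(surface_rows(c(1, 3), c(1, 3))), 2.5)
  expect_equal(national_index(surface_rows(5, 2)), 5)
  expect_error(national_index(surface_rows(1, 1, aggregable = FALSE)),
               class = "ctaccess_no_weighable_population")
  withr::with_seed(33, {
    for (i in 1:20) {
      v <- runif(8, 0, 5)
      w <- runif(8, 0.5, 4)
      ni <- national_index(surface_rows(v, w))
      expect_gte(ni, min(v))
      expect_lte(ni, max(v))
    }
  })
})

test_that("tAI equals dAI when costs equal distances, and scales by the power law", {
  fx <- read_fixture("singlepole")
  spec <- impedance_spec(distance_floor_km = 5)
  costs <- make_cost_matrix(fx$grid, fx$sites, model = "distance")
  dai <- compute_surface(fx$grid, fx$sites, fx$incidence, spec, year = 2019)
  tai <- compute_tai(fx$grid, fx$sites, fx$incidence, costs, spec, year = 2019)
  expect_equal(tai$local_value, dai$local_value, tolerance = 1e-12)
  expect_identical(tai$serving_site_id, dai$serving_site_id)

  # all costs x4 vs distance halves every value through the square root,
  # provided nothing sits inside the floor
  costs4 <- costs
  costs4$cost <- costs4$cost * 4
  above <- dai$distance_km >= spec$distance_floor_km
  tai4 <- compute_tai(fx$grid, fx$sites, fx$incidence, costs4, spec, year = 2019)
  expect_equal(tai4$local_value[above], dai$local_value[above] / 2,
               tolerance = 1e-12)

  # a cost ranking that contradicts the distance ranking flips the serving site
  g2 <- population_grid(data.frame(id = "p", lat = 0, lon = 0,
                                   population = 1e5, country = "x"))
  s2 <- trial_sites(data.frame(id = c("near", "far"), lat = c(0, 0),
                               lon = c(0.5, 2), year = 2019,
                               n_trials = c(2, 2), country = "x"))
  i2 <- incidence_table(data.frame(country = "x", rate_per_100k = 100))
  cst <- data.frame(point_id = "p", site_id = c("near", "far"),
                    cost = c(500, 20))
  t2 <- compute_tai(g2, s2, i2, cst, impedance_spec(distance_floor_km = 1))
  expect_identical(t2$serving_site_id, "far")
  # a missing pair is named
  expect_error(compute_tai(g2, s2, i2, cst[1, ], impedance_spec(distance_floor_km = 1)),
               "far", class = "ctaccess_missing_cost")
})

test_that("normalization to a reference country behaves as a ratio", {
  ser <- data.frame(country = rep(c("ref", "half", "none"), each = 2),
                    year = rep(2018:2019, 3),
                    value = c(4, 8, 2, 4, 0, 0))
  out <- normalize_to_reference(ser, "ref")
  expect_equal(out$pct_of_reference[out$country == "ref"], c(100, 100))
  expect_equal(out$pct_of_reference[out$country == "half"], c(50, 50))
  # zero reference year flagged undefined, not dropped
  ser0 <- ser
  ser0$value[ser0$country == "ref" & ser0$year == 2018] <- 0
  out0 <- normalize_to_reference(ser0, "ref")
  expect_true(all(out0$undefined[out0$year == 2018]))
  expect_equal(nrow(out0), nrow(ser0))
  # window variant equals the ratio of period means
  win <- normalize_to_reference(ser, "ref", years = 2018:2019)
  expect_equal(win$pct_of_reference[win$country == "half"],
               100 * mean(c(2, 4)) / mean(c(4, 8)))
})
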