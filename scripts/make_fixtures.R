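#!/usr/bin/env Rscript
# Regenerates the toy fixture countries under inst/extdata/fixtures/.
# Run from the repository root after changing the generator.
library(ctaccess)

out_root <- "inst/extdata/fixtures"

emit <- function(name, grid, sites, incidence) {
  dir <- file.path(out_root, name)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_input_csv(grid, file.path(dir, "grid.csv"))
  write_input_csv(sites, file.path(dir, "sites.csv"))
  write_input_csv(incidence, file.path(dir, "incidence.csv"))
}

## twolobe: mirror-symmetric ribbon with two equal population masses and a
## single site at the western lobe — the canonical optimizer toy
lons <- seq(-3, 3, by = 0.5)
pop <- rep(50, length(lons))  # background below one expected patient per cell
pop[lons == -2.5] <- 4e5
pop[lons == 2.5] <- 4e5
emit("twolobe",
     population_grid(data.frame(id = sprintf("tl_%02d", seq_along(lons)),
                                lat = 0, lon = lons, population = pop,
                                country = "twolobe")),
     trial_sites(data.frame(id = "tl_site_w", lat = 0, lon = -2.5,
                            year = 2019, n_trials = 5, country = "twolobe")),
     incidence_table(data.frame(country = "twolobe", rate_per_100k = 300)))

## singlepole: one urban pole holding 80% of the population, supply
## concentrated there
sp <- make_country(country_blueprint(
  "singlepole", lat_range = c(40, 43), lon_range = c(20, 23),
  pattern = "urban_poles", n_poles = 1, pole_mass_share = 0.8,
  pole_dispersion = 1, total_population = 3e6, incidence_rate = 280,
  site_policy = "concentrated", n_sites = 2, trials_per_year = 10,
  years = 2019, seed = 42))
emit("singlepole", sp$grid, sp$sites, sp$incidence)

## uniform: flat population, proportional supply
un <- make_country(country_blueprint(
  "uniform", lat_range = c(50, 52.5), lon_range = c(4, 6.5),
  pattern = "uniform", total_population = 2e6, incidence_rate = 320,
  site_policy = "proportional", n_sites = 3, trials_per_year = 12,
  years = 2019, seed = 42))
emit("uniform", un$grid, un$sites, un$incidence)

## bootland: synthetic boot-shaped country on a 1-degree grid (population
## concentrated in the north, supply northern) — entirely synthetic, no
## real administrative data
cells <- list(
  # northern band (the "top" of the boot): dense
  expand.grid(lat = 44:46, lon = 8:13),
  # the shaft going south-east
  expand.grid(lat = 41:43, lon = 12:15),
  # the toe
  expand.grid(lat = 38:40, lon = 15:17)
)
bl <- do.call(rbind, cells)
north <- bl$lat >= 44
pop <- ifelse(north, 18e5, 6e5)
boot_grid <- population_grid(data.frame(
  id = sprintf("bl_%02d", seq_len(nrow(bl))),
  lat = bl$lat, lon = bl$lon, population = pop, country = "bootland"),
  spacing_deg = 1)
boot_sites <- trial_sites(data.frame(
  id = c("bl_n1", "bl_n2", "bl_c1"),
  lat = c(45, 45, 42), lon = c(9, 12, 13),
  year = 2019, n_trials = c(12, 8, 4), country = "bootland"))
emit("bootland", boot_grid, boot_sites,
     incidence_table(data.frame(country = "bootland", rate_per_100k = 350)))

cat("fixtures written under", out_root, "\n")
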