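# Shared fixture builders.  Everything is generated in code; nothing is
# read from disk except through explicit tempfile round trips.

# A minimal climate series: one variable over a date span.
toy_climate <- function(values, variable = "tavg_c",
                        start = as.Date("2012-09-01"),
                        station = "toy", elevation = 2000) {
  d <- data.frame(date = seq(start, by = "day", length.out = length(values)))
  d[[variable]] <- values
  climate_series(d, station_id = station, elevation_m = elevation)
}

# A hand-built breeding table (single site, first attempts).
toy_breeding <- function(years, y, response = "first_egg_date", site = "low") {
  stopifnot(length(years) == length(y))
  rec <- data.frame(
    nest_id = sprintf("t%03d", seq_along(y)), year = years, site = site,
    first_egg_date = if (response == "first_egg_date") round(y) else 130L,
    clutch_size = if (response == "clutch_size") as.integer(y) else 6L,
    brood_size = if (response == "brood_size") as.integer(y) else 5L,
    attempt_type = "first", stringsAsFactors = FALSE)
  rec$nestling_masses_g <- rep(list(numeric()), nrow(rec))
  bt <- build_breeding_table(rec)
  if (!response %in% c("first_egg_date", "clutch_size", "brood_size")) {
    bt[[response]] <- y
  }
  bt
}

# Synthetic dataset with one planted Gaussian climate-window effect on
# first egg date.  `std_slope` is the effect in residual-s.d. units per
# covariate-s.d. (computed from the realized per-year covariate), so the
# standardized effect size is exact by construction.
make_planted <- function(seed, years = 10, nests = 30, std_slope = 1,
                         resid_sd = 5, variable = "tmax_c",
                         window = c(43L, 94L)) {
  yrs <- 2013:(2013 + years - 1)
  cl <- simulate_climate(synthetic_site_params("low"), years = years, seed = seed)
  cov <- window_covariate(cl, variable,
                          list(open = window[1], close = window[2]), yrs)
  slope <- if (std_slope == 0) 0 else std_slope * resid_sd / sd(cov)
  truth <- synthetic_truth("low", years = yrs, overrides = list(
    first_egg_date = list(variable = variable, window = window,
                          slope = slope, noise = resid_sd, intercept = 140)))
  sb <- simulate_breeding(truth, cl, nests_per_year = nests, seed = seed + 5000)
  list(bt = build_breeding_table(sb$records), cl = cl, truth = truth,
       window = window, slope = slope)
}

window_jaccard <- nestwin:::window_jaccard
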