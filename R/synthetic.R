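# Synthetic montane climate and nest records with known ground truth.
#
# The generator emulates the structure of the study system: two elevation
# sites with distinct snow regimes in the northern Sierra Nevada, ten
# breeding seasons, tens of nests per site-year, and climate-window effects
# on responses with Gaussian (dates, masses, log CV) or generalized-Poisson
# (counts) noise.  It is first-class, seeded, bit-reproducible code — every
# pipeline stage is testable against the truth it records.

#' Default climate-process parameters for a synthetic site
#'
#' The low site sits near 2000 m (annual mean about 7 °C, shallower snow);
#' the high site near 2500 m is colder (about 3 °C lapse) with more
#' precipitation falling as snow, giving deeper and longer-lasting snowpack
#' — the contrast the study system exhibits.
#'
#' @param site `"low"` or `"high"`.
#' @return Named list of process parameters: seasonal temperature mean,
#'   amplitude and peak day, AR(1) coefficient and innovation s.d.,
#'   interannual year-effect s.d., diurnal half-range, precipitation
#'   occurrence/intensity and scale, snowfall temperature threshold, melt
#'   rate (mm of SWE per degree-day) and snowpack density.
#' @export
synthetic_site_params <- function(site = c("low", "high")) {
  site <- match.arg(site)
  base <- list(
    site = site,
    elevation_m = if (site == "low") 2045 else 2541,
    temp_mean_c = if (site == "low") 7.0 else 4.0,
    temp_amplitude_c = 9.5,
    temp_peak_doy = 205,          # late July
    ar1_rho = 0.7, ar1_sd_c = 2.2,
    year_sd_c = 1.2,              # interannual temperature variance
    diurnal_half_range_c = 7.5, diurnal_sd_c = 1.5,
    precip_base_prob = 0.08, precip_winter_prob = 0.30,
    precip_mean_mm = 9, precip_shape = 1.2,
    precip_scale = if (site == "low") 1.0 else 1.25,
    snow_temp_c = 1.0,            # rain/snow threshold on tavg
    melt_rate_mm_per_deg = 2.5,
    snow_density = 0.35)
  base
}

#' Simulate a daily climate series
#'
#' Daily mean temperature is a seasonal sinusoid plus a per-season year
#' effect plus AR(1) noise; minimum/maximum temperatures subtract/add
#' positive diurnal half-ranges.  Precipitation occurs with a
#' winter-peaking probability and gamma-distributed amounts; below the
#' snow threshold it accumulates as snow water equivalent, which melts at a
#' temperature-dependent rate and floors at zero; snow depth is SWE over a
#' fixed pack density.  Precipitation accumulation is nondecreasing and
#' zeroed each 1 September (already in the re-anchored convention).  Soil
#' moisture rises with rain and melt and decays through summer; soil
#' temperatures are depth-damped running means of air temperature, pulled
#' toward zero under snow.
#'
#' @param params a [synthetic_site_params()] list (fields may be
#'   overridden).
#' @param years number of breeding seasons (>= 2).
#' @param seed RNG seed; output is bit-reproducible for a fixed seed.
#' @param start_year first breeding year (default 2013); the series runs
#'   from 1 September of `start_year - 1` to 31 August of the last year.
#' @return A [climate_series()] with all eleven canonical variables.
#' @export
simulate_climate <- function(params = synthetic_site_params("low"),
                             years = 10L, seed = 1L, start_year = 2013L) {
  stopifnot(years >= 2)
  set.seed(seed)
  p <- params
  dates <- seq(season_anchor(start_year),
               as.Date(sprintf("%d-08-31", start_year + years - 1L)), by = "day")
  n <- length(dates)
  doy <- as.integer(format(dates, "%j"))
  md <- format(dates, "%m-%d")
  season <- cumsum(md == "09-01")           # 1-based season index

  year_eff <- rnorm(max(season), 0, p$year_sd_c)[season]
  eps <- numeric(n)
  eps[1] <- rnorm(1, 0, p$ar1_sd_c / sqrt(1 - p$ar1_rho^2))
  innov <- rnorm(n, 0, p$ar1_sd_c)
  for (i in 2:n) eps[i] <- p$ar1_rho * eps[i - 1] + innov[i]
  seasonal <- p$temp_mean_c +
    p$temp_amplitude_c * cos(2 * pi * (doy - p$temp_peak_doy) / 365.25)
  tavg <- seasonal + year_eff + eps
  hr_max <- abs(rnorm(n, p$diurnal_half_range_c, p$diurnal_sd_c)) + 0.5
  hr_min <- abs(rnorm(n, p$diurnal_half_range_c, p$diurnal_sd_c)) + 0.5
  tmax <- tavg + hr_max
  tmin <- tavg - hr_min

  winter_w <- (1 + cos(2 * pi * (doy - 15) / 365.25)) / 2   # peaks mid-January
  p_wet <- p$precip_base_prob + (p$precip_winter_prob - p$precip_base_prob) * winter_w
  wet <- runif(n) < p_wet
  amount <- ifelse(wet,
                   rgamma(n, shape = p$precip_shape,
                          scale = p$precip_mean_mm / p$precip_shape) * p$precip_scale,
                   0)

  swe <- numeric(n); sm5 <- numeric(n); sm51 <- numeric(n)
  st5 <- numeric(n); st20 <- numeric(n); st51 <- numeric(n)
  swe_prev <- 0; sm5_prev <- 12; sm51_prev <- 15
  st5_prev <- p$temp_mean_c; st20_prev <- p$temp_mean_c; st51_prev <- p$temp_mean_c
  for (i in seq_len(n)) {
    snowing <- tavg[i] < p$snow_temp_c
    sw <- swe_prev + if (snowing) amount[i] else 0
    melt <- if (tavg[i] > 0) min(sw, p$melt_rate_mm_per_deg * tavg[i]) else 0
    sw <- sw - melt
    swe[i] <- sw; swe_prev <- sw
    rain <- if (snowing) 0 else amount[i]
    sm5[i] <- min(45, max(3, sm5_prev * 0.97 + 0.35 * rain + 0.25 * melt))
    sm51[i] <- min(45, max(5, sm51_prev * 0.995 + 0.05 * (sm5[i] - sm51_prev)))
    sm5_prev <- sm5[i]; sm51_prev <- sm51[i]
    insul <- if (sw > 20) 0.15 else 1          # snowpack insulates the soil
    st5[i] <- st5_prev + 0.15 * (tavg[i] * insul - st5_prev)
    st20[i] <- st20_prev + 0.08 * (tavg[i] * insul - st20_prev)
    st51[i] <- st51_prev + 0.04 * (tavg[i] - st51_prev)
    st5_prev <- st5[i]; st20_prev <- st20[i]; st51_prev <- st51[i]
  }
  snow_depth <- swe / (10 * p$snow_density)

  accum <- stats::ave(ifelse(md == "09-01", 0, amount), season, FUN = cumsum)

  climate_series(
    data.frame(date = dates,
               precip_accum_mm = accum,
               snow_depth_cm = snow_depth,
               swe_mm = swe,
               tavg_c = tavg, tmax_c = tmax, tmin_c = tmin,
               soil_moist_5cm_pct = sm5, soil_moist_51cm_pct = sm51,
               soil_temp_5cm_c = st5, soil_temp_20cm_c = st20,
               soil_temp_51cm_c = st51),
    station_id = paste0("synthetic-", p$site),
    elevation_m = p$elevation_m)
}

#' Ground truth for synthetic breeding responses
#'
#' Encodes, per response, the true driving climate variable, its window
#' (anchor offsets), the effect slope (response units per covariate unit;
#' log scale for counts), intercept and noise (residual s.d. for Gaussian
#' responses, dispersion `phi` for counts).  Defaults mirror the kinds of
#' effects the study system shows: autumn maximum temperature driving low-
#' elevation first egg date, autumn snow water equivalent driving low-
#' elevation brood size, spring temperature driving high-elevation counts.
#' Any response's entry may be overridden; `slope = 0` plants no effect.
#'
#' @param site `"low"` or `"high"`.
#' @param years integer vector of breeding years covered.
#' @param overrides named list of per-response partial overrides, e.g.
#'   `list(first_egg_date = list(slope = 0))`.
#' @return A `synthetic_truth` list: `site`, `years`, `responses` (per
#'   response: `variable`, `window`, `slope`, `intercept`, `noise` or
#'   `phi`, `family`), plus nest-level parameters `within_nest_sd_g`,
#'   `renest_frac` and `second_brood_frac`.
#' @export
synthetic_truth <- function(site = "low", years = 2013:2022, overrides = list()) {
  resp <- if (site == "low") list(
    first_egg_date = list(variable = "tmax_c", window = c(43L, 94L),   # 14 Oct–4 Dec
                          slope = -1.5, intercept = 157, noise = 6,
                          family = "gaussian"),
    clutch_size    = list(variable = "tavg_c", window = c(203L, 261L),
                          slope = 0, intercept = log(6.8), phi = 0.8,
                          family = "genpois"),
    brood_size     = list(variable = "swe_mm", window = c(57L, 92L),   # 28 Oct–2 Dec
                          slope = 0.0035, intercept = 1.45, phi = 0.8,
                          family = "genpois"),
    mean_mass_g    = list(variable = "tavg_c", window = c(203L, 261L),
                          slope = 0, intercept = 11.8, noise = 0.7,
                          family = "gaussian"),
    log_cv_mass    = list(variable = "tmin_c", window = c(92L, 121L),  # 2–31 Dec
                          slope = 0.07, intercept = -2.49 + log(100), noise = 0.45,
                          family = "gaussian")
  ) else list(
    first_egg_date = list(variable = "precip_accum_mm", window = c(188L, 202L),
                          slope = 0.0089, intercept = 145, noise = 6,
                          family = "gaussian"),
    clutch_size    = list(variable = "tavg_c", window = c(203L, 261L), # 23 Mar–20 May
                          slope = 0.09, intercept = 1.57, phi = 0.8,
                          family = "genpois"),
    brood_size     = list(variable = "tavg_c", window = c(205L, 238L), # 25 Mar–27 Apr
                          slope = 0.11, intercept = 1.50, phi = 0.8,
                          family = "genpois"),
    mean_mass_g    = list(variable = "tavg_c", window = c(203L, 261L),
                          slope = 0, intercept = 11.5, noise = 0.7,
                          family = "gaussian"),
    log_cv_mass    = list(variable = "tmin_c", window = c(92L, 121L),
                          slope = 0, intercept = -2.8 + log(100), noise = 0.45,
                          family = "gaussian")
  )
  for (nm in names(overrides)) {
    resp[[nm]][names(overrides[[nm]])] <- overrides[[nm]]
  }
  structure(list(site = site, years = as.integer(years), responses = resp,
                 within_nest_sd_g = 0.6,
                 renest_frac = 0.025, second_brood_frac = 0.013),
            class = "synthetic_truth")
}

#' Simulate nest records against a climate series
#'
#' For each breeding year the true window's mean covariate `c` is computed
#' from the supplied climate series; Gaussian responses are drawn as
#' `Normal(intercept + slope * c, noise)` per nest, counts as generalized
#' Poisson with `mean = exp(intercept + slope * c)` and dispersion `phi`
#' (brood size is capped at clutch size).  Day-16 nestling masses are drawn
#' per nestling around each nest's mean so that the within-nest CV is
#' emergent rather than imposed.  A configurable fraction of renests and
#' second broods is injected (with late first egg dates) to exercise the
#' first-attempt filter; their ids are recorded in the returned truth.
#'
#' @param truth a [synthetic_truth()].
#' @param climate a [climate_series()] covering all true windows.
#' @param nests_per_year nests per site-year (default 50, the study's
#'   order of magnitude).
#' @param seed RNG seed; bit-reproducible for a fixed seed.
#' @return List with `records` (a raw nest-record data frame suitable for
#'   [build_breeding_table()]) and `truth` (the input truth augmented with
#'   the per-year covariates actually used and the injected extra-attempt
#'   nest ids).
#' @export
simulate_breeding <- function(truth, climate, nests_per_year = 50L, seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"), inherits(climate, "climate_series"))
  set.seed(seed)
  years <- truth$years
  resp <- truth$responses
  nyr <- length(years)

  cov_of <- function(tr) {
    w <- list(open = tr$window[1], close = tr$window[2])
    window_covariate(climate, tr$variable, w, years)
  }
  covs <- lapply(resp, cov_of)
  if (anyNA(unlist(covs))) stop("climate series does not cover a true window")
  truth$covariates <- covs

  recs <- list()
  extras <- list()
  extra_ids <- character(0)
  for (j in seq_len(nyr)) {
    yr <- years[j]
    n <- nests_per_year
    mu_fed <- resp$first_egg_date$intercept +
      resp$first_egg_date$slope * covs$first_egg_date[j]
    fed <- pmin(366L, pmax(1L, as.integer(round(
      rnorm(n, mu_fed, resp$first_egg_date$noise)))))
    mu_cl <- exp(resp$clutch_size$intercept +
                 resp$clutch_size$slope * covs$clutch_size[j])
    clutch <- pmax(1L, rgenpois(n, mu_cl, resp$clutch_size$phi))
    mu_br <- exp(resp$brood_size$intercept +
                 resp$brood_size$slope * covs$brood_size[j])
    brood <- pmin(clutch, rgenpois(n, mu_br, resp$brood_size$phi))
    mu_mass <- resp$mean_mass_g$intercept +
      resp$mean_mass_g$slope * covs$mean_mass_g[j]
    nest_mean <- rnorm(n, mu_mass, resp$mean_mass_g$noise)
    log_cv <- rnorm(n, resp$log_cv_mass$intercept +
                       resp$log_cv_mass$slope * covs$log_cv_mass[j],
                    resp$log_cv_mass$noise)
    target_sd <- exp(log_cv) / 100 * nest_mean
    masses <- lapply(seq_len(n), function(i) {
      if (brood[i] < 1) return(numeric())
      round(pmax(2, rnorm(brood[i], nest_mean[i], target_sd[i])), 2)
    })
    recs[[j]] <- data.frame(
      nest_id = sprintf("%s-%d-%03d", truth$site, yr, seq_len(n)),
      year = yr, site = truth$site, first_egg_date = fed,
      clutch_size = clutch, brood_size = brood,
      attempt_type = "first", stringsAsFactors = FALSE)
    recs[[j]]$nestling_masses_g <- masses

    # injected later attempts, removed by the first-attempt filter
    n_extra <- round(n * (truth$renest_frac + truth$second_brood_frac))
    if (n_extra > 0) {
      type <- rep(c("renest", "second_brood"), length.out = n_extra)
      ex <- data.frame(
        nest_id = sprintf("%s-%d-x%02d", truth$site, yr, seq_len(n_extra)),
        year = yr, site = truth$site,
        first_egg_date = pmin(366L, fed[seq_len(n_extra)] + 30L),
        clutch_size = pmax(1L, clutch[seq_len(n_extra)] - 1L),
        brood_size = pmax(0L, brood[seq_len(n_extra)] - 1L),
        attempt_type = type, stringsAsFactors = FALSE)
      ex$nestling_masses_g <- lapply(ex$brood_size, function(b) {
        if (b < 1) numeric() else round(rnorm(b, 11, 0.8), 2)
      })
      extra_ids <- c(extra_ids, ex$nest_id)
      extras[[length(extras) + 1L]] <- ex
    }
  }
  records <- do.call(rbind, c(recs, extras))
  rownames(records) <- NULL
  truth$extra_attempt_ids <- extra_ids
  list(records = records, truth = truth)
}
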