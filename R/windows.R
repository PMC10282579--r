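# Window grids and per-year window covariates.
#
# Windows live on a grid of integer day offsets from the 1 September
# anchor of each breeding season (see dates.R), so "14 Oct - 4 Dec" is the
# offset pair (43, 94) laid onto every season.

#' Reference date (as an anchor offset) for a response
#'
#' Windows for a response at a site may extend up to a response-specific
#' spring reference date: the earliest first egg date ever recorded at that
#' site for `first_egg_date`; that date plus 9 days for `clutch_size`
#' (maximum laying span); plus 40 days for all later responses (laying,
#' incubation/hatching and days to the day-16 nestling measures).
#'
#' @param response one of `first_egg_date`, `clutch_size`, `brood_size`,
#'   `mean_mass_g`, `cv_mass`, `log_cv_mass`.
#' @param site `"low"` or `"high"`.
#' @param breeding a [build_breeding_table()] result containing the site.
#' @return List with `doy` (day of year, non-leap convention) and `offset`
#'   (days from the 1 September anchor).
#' @export
reference_date <- function(response, site, breeding) {
  sub <- breeding[breeding$site == site, , drop = FALSE]
  if (!nrow(sub)) stop("no breeding records for site '", site, "'")
  base <- min(sub$first_egg_date, na.rm = TRUE)
  doy <- switch(response,
    first_egg_date = base,
    clutch_size    = base + 9L,
    base + 40L)
  list(doy = as.integer(doy), offset = doy_to_offset(doy))
}

#' Enumerate all admissible absolute windows
#'
#' Every contiguous `[open, close]` offset pair with duration
#' `close - open + 1 >= min_len` inside `[range_start, ref]`, each exactly
#' once.  At `stride = 1` the count is `(D - min_len + 1)(D - min_len + 2)/2`
#' with `D = ref - range_start + 1`.  A stride greater than 1 restricts both
#' endpoints to a coarser grid (used to speed up simulation studies; day
#' resolution is the default).
#'
#' @param range_start earliest allowed open offset (0 = 1 September).
#' @param ref latest allowed close offset (the reference date).
#' @param min_len minimum window length in days (default 14).
#' @param stride endpoint grid step in days (default 1).
#' @return Data frame with `open`, `close`, `duration`.
#' @export
enumerate_windows <- function(range_start, ref, min_len = 14L, stride = 1L) {
  range_start <- as.integer(range_start); ref <- as.integer(ref)
  D <- ref - range_start + 1L
  if (D < min_len) stop("span (", D, " days) shorter than the minimum window length")
  opens <- seq.int(range_start, ref - min_len + 1L, by = stride)
  out <- do.call(rbind, lapply(opens, function(o) {
    closes <- seq.int(o + min_len - 1L, ref, by = stride)
    data.frame(open = o, close = closes)
  }))
  out$duration <- out$close - out$open + 1L
  out
}

# Temporal Jaccard of two inclusive offset intervals.
window_jaccard <- function(open1, close1, open2, close2) {
  inter <- pmax(0L, pmin(close1, close2) - pmax(open1, open2) + 1L)
  union <- (close1 - open1 + 1L) + (close2 - open2 + 1L) - inter
  inter / union
}

#' Per-year mean of a climate variable over a window
#'
#' For each breeding year, the arithmetic mean of the variable over the
#' window's dates in that season (anchor = 1 September of the preceding
#' calendar year, so autumn windows attach to the following breeding
#' season).  Missing days are excluded from the mean; if the fraction of
#' present days falls below `completeness_floor` the value is set missing.
#'
#' @param series a [climate_series()].
#' @param variable canonical climate variable name.
#' @param window list or one-row data frame with `open` and `close` offsets.
#' @param years integer vector of breeding years.
#' @param completeness_floor minimum fraction of non-missing days
#'   (default 0.8).
#' @return Named numeric vector of per-year window means, with the per-year
#'   completeness fraction in attribute `"completeness"`.
#' @export
window_covariate <- function(series, variable, window, years,
                             completeness_floor = 0.8) {
  w <- data.frame(open = window$open[1], close = window$close[1])
  cm <- window_covariate_matrix(series, variable, w, years, completeness_floor)
  structure(setNames(cm$C[1, ], years), completeness = cm$completeness[1, ])
}

# Vectorised core: window means for every (window, year) pair via per-year
# cumulative sums.  Returns W x Y matrices C (means; NA below the
# completeness floor) and completeness.
window_covariate_matrix <- function(series, variable, windows, years,
                                    completeness_floor = 0.8) {
  stopifnot(inherits(series, "climate_series"))
  if (!variable %in% names(series$data)) {
    stop("variable '", variable, "' absent from climate series")
  }
  vals_all <- series$data[[variable]]
  dates <- series$data$date
  maxoff <- max(windows$close)
  W <- nrow(windows); Y <- length(years)
  C <- matrix(NA_real_, W, Y)
  comp <- matrix(0, W, Y)
  o <- windows$open; cl <- windows$close
  len <- cl - o + 1L
  for (j in seq_len(Y)) {
    idx <- match(season_anchor(years[j]) + 0:maxoff, dates)
    v <- vals_all[idx]                      # NA where date outside series
    present <- !is.na(v)
    cs <- c(0, cumsum(ifelse(present, v, 0)))
    cn <- c(0, cumsum(present))
    np <- cn[cl + 2L] - cn[o + 1L]
    sm <- cs[cl + 2L] - cs[o + 1L]
    comp[, j] <- np / len
    ok <- np > 0 & comp[, j] >= completeness_floor
    C[ok, j] <- sm[ok] / np[ok]
  }
  list(C = C, completeness = comp)
}
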