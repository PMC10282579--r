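#' Daily climate series for one station (or a station average)
#'
#' A `climate_series` holds a contiguous daily record of up to eleven
#' canonical climate variables: `precip_accum_mm`, `snow_depth_cm`,
#' `swe_mm`, `tavg_c`, `tmax_c`, `tmin_c`, `soil_moist_5cm_pct`,
#' `soil_moist_51cm_pct`, `soil_temp_5cm_c`, `soil_temp_20cm_c`,
#' `soil_temp_51cm_c`.  The date index is strictly increasing with a daily
#' step and no gaps; individual values may be `NA`.  Physical-consistency
#' violations (negative snow depth or snow water equivalent, or
#' `tmin > tavg` / `tavg > tmax` on a day where all three temperatures are
#' present) are recorded in the `flags` attribute rather than silently
#' altered.
#'
#' @param data data frame with a `date` column (`Date` or parseable
#'   `"%Y-%m-%d"` text) and any subset of the canonical variable columns.
#' @param station_id station identifier.
#' @param elevation_m station elevation in metres.
#'
#' @return An object of class `climate_series`: a list with elements
#'   `station_id`, `elevation_m`, `data` (gap-filled daily data frame),
#'   `flags` (data frame of date/variable/issue records) and `notes`
#'   (character log of normalisation actions).
#' @export
climate_series <- function(data, station_id, elevation_m) {
  stopifnot(is.data.frame(data), "date" %in% names(data))
  dates <- data$date
  if (!inherits(dates, "Date")) {
    parsed <- as.Date(as.character(dates), format = "%Y-%m-%d")
    bad <- which(is.na(parsed) & !is.na(dates) & nzchar(as.character(dates)))
    if (length(bad)) {
      stop("unparseable date in row ", bad[1], ": '", dates[bad[1]], "'")
    }
    if (anyNA(parsed)) stop("missing date in row ", which(is.na(parsed))[1])
    dates <- parsed
  }
  if (anyDuplicated(dates)) {
    stop("duplicate dates: ", paste(unique(dates[duplicated(dates)])[1], collapse = ", "))
  }
  ord <- order(dates)
  dates <- dates[ord]

  notes <- character()
  keep <- intersect(names(data), CLIMATE_VARS)
  unknown <- setdiff(names(data), c("date", CLIMATE_VARS))
  if (length(unknown)) {
    notes <- c(notes, paste0("ignored unrecognised columns: ",
                             paste(unknown, collapse = ", ")))
  }

  # contiguous daily index; days absent from the input become all-missing
  full <- seq(min(dates), max(dates), by = "day")
  out <- data.frame(date = full)
  idx <- match(full, dates)
  for (v in keep) out[[v]] <- as.numeric(data[[v]][ord])[idx]
  n_gap <- sum(is.na(idx))
  if (n_gap > 0) notes <- c(notes, paste0("filled ", n_gap, " missing calendar days with NA"))

  flags <- validate_climate_values(out)
  structure(
    list(station_id = as.character(station_id),
         elevation_m = as.numeric(elevation_m),
         data = out, flags = flags, notes = notes),
    class = "climate_series"
  )
}

# Flag (never fix) physical inconsistencies.
validate_climate_values <- function(df) {
  flags <- list()
  add <- function(dates, variable, issue) {
    if (length(dates)) {
      flags[[length(flags) + 1L]] <<- data.frame(
        date = dates, variable = variable, issue = issue)
    }
  }
  for (v in intersect(c("snow_depth_cm", "swe_mm"), names(df))) {
    add(df$date[which(df[[v]] < 0)], v, "negative value")
  }
  if (all(c("tmin_c", "tavg_c", "tmax_c") %in% names(df))) {
    ok <- !is.na(df$tmin_c) & !is.na(df$tavg_c) & !is.na(df$tmax_c)
    bad <- ok & (df$tmin_c > df$tavg_c | df$tavg_c > df$tmax_c)
    add(df$date[which(bad)], "tavg_c", "temperature ordering violated (tmin <= tavg <= tmax)")
  }
  if (length(flags)) do.call(rbind, flags) else
    data.frame(date = as.Date(character()), variable = character(), issue = character())
}

#' @export
print.climate_series <- function(x, ...) {
  vars <- setdiff(names(x$data), "date")
  cat("<climate_series> station ", x$station_id,
      " (", x$elevation_m, " m)\n", sep = "")
  cat("  ", nrow(x$data), " days: ", format(min(x$data$date)), " to ",
      format(max(x$data$date)), "\n", sep = "")
  cat("  variables: ", paste(vars, collapse = ", "), "\n", sep = "")
  if (nrow(x$flags)) cat("  ", nrow(x$flags), " consistency flag(s)\n", sep = "")
  invisible(x)
}

#' Read a daily climate station table
#'
#' Reads a comma-separated table with a header row, a date column and any
#' subset of the canonical climate variable columns, and returns a
#' gap-filled [climate_series()].  Unrecognised columns are ignored (with a
#' log entry in `notes`); empty cells become `NA`.
#'
#' @inheritParams climate_series
#' @param path path to a delimited text file.
#' @param col_map optional named character vector mapping file column names
#'   to canonical names, e.g. `c(TAVG = "tavg_c")`; the date column may be
#'   mapped with a `"date"` entry.
#' @return A [climate_series()].
#' @export
read_climate_daily <- function(path, station_id, elevation_m, col_map = NULL) {
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(col_map)) {
    hit <- match(names(raw), names(col_map))
    names(raw)[!is.na(hit)] <- col_map[hit[!is.na(hit)]]
  }
  if (!"date" %in% names(raw)) stop("no 'date' column found in ", path)
  climate_series(raw, station_id = station_id, elevation_m = elevation_m)
}

#' Write a climate series back to delimited text
#'
#' Inverse of [read_climate_daily()]: missingness is preserved exactly
#' (empty cells), so a write/read round trip reproduces the series.
#'
#' @param series a [climate_series()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_climate_daily <- function(series, path) {
  stopifnot(inherits(series, "climate_series"))
  df <- series$data
  df$date <- format(df$date, "%Y-%m-%d")
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Re-anchor precipitation accumulation to 1 September
#'
#' Provider accumulation counters (SNOTEL water-year convention) reset on
#' 1 October.  For breeding-season analyses the accumulation is re-anchored
#' so that each value measures cumulative precipitation since the most
#' recent 1 September: the value on every 1 September is 0 and values are
#' nondecreasing until the following 31 August.  Daily increments are the
#' day-to-day differences of the raw counter; any negative difference is
#' treated as a provider reset (the post-reset value is taken as the
#' increment) and logged.  Missing raw days contribute a zero increment and
#' are logged.
#'
#' @param series a [climate_series()] containing `precip_accum_mm`.
#' @return The series with `precip_accum_mm` replaced by the re-anchored
#'   accumulation.
#' @export
reanchor_precip_accum <- function(series) {
  stopifnot(inherits(series, "climate_series"))
  df <- series$data
  if (!"precip_accum_mm" %in% names(df)) {
    stop("variable 'precip_accum_mm' absent from series")
  }
  raw <- df$precip_accum_mm
  n <- length(raw)
  inc <- c(NA_real_, diff(raw))
  resets <- which(!is.na(inc) & inc < 0)
  if (length(resets)) {
    # counter restarted; accumulation since the reset is the new raw value
    inc[resets] <- pmax(raw[resets], 0)
  }
  n_missing <- sum(is.na(inc[-1]))
  inc[is.na(inc)] <- 0

  # anchor: the value reported on each 1 Sept is 0, so its own increment
  # does not carry into the season total
  md <- format(df$date, "%m-%d")
  inc[md == "09-01"] <- 0
  season <- cumsum(md == "09-01")
  out <- stats::ave(inc, season, FUN = cumsum)

  series$data$precip_accum_mm <- out
  notes <- character()
  if (length(resets)) {
    notes <- paste0("precip_accum_mm: treated ", length(resets),
                    " negative decrement(s) as provider resets")
  }
  if (n_missing > 0) {
    notes <- c(notes, paste0("precip_accum_mm: ", n_missing,
                             " missing day(s) contributed zero increment"))
  }
  series$notes <- c(series$notes, notes)
  series
}

#' Average two climate stations day by day
#'
#' Per date and variable, the arithmetic mean of the values present at the
#' two stations.  Where exactly one station reports a value, that value is
#' used (single-station days are counted in `notes`); where neither does,
#' the result is missing.  Station metadata on the result records both
#' inputs and the mean elevation.
#'
#' @param a,b [climate_series()] objects with overlapping date ranges.
#' @return A [climate_series()] spanning the union of the two date ranges.
#' @export
average_stations <- function(a, b) {
  stopifnot(inherits(a, "climate_series"), inherits(b, "climate_series"))
  ra <- range(a$data$date); rb <- range(b$data$date)
  if (ra[1] > rb[2] || rb[1] > ra[2]) stop("stations have no overlapping dates")

  full <- seq(min(ra[1], rb[1]), max(ra[2], rb[2]), by = "day")
  vars <- union(setdiff(names(a$data), "date"), setdiff(names(b$data), "date"))
  out <- data.frame(date = full)
  ia <- match(full, a$data$date); ib <- match(full, b$data$date)
  n_single <- 0L
  for (v in vars) {
    va <- if (v %in% names(a$data)) a$data[[v]][ia] else rep(NA_real_, length(full))
    vb <- if (v %in% names(b$data)) b$data[[v]][ib] else rep(NA_real_, length(full))
    m <- rowMeans(cbind(va, vb), na.rm = TRUE)
    m[is.nan(m)] <- NA_real_
    n_single <- n_single + sum(is.na(va) != is.na(vb))
    out[[v]] <- m
  }
  res <- climate_series(out,
    station_id = paste(a$station_id, b$station_id, sep = "+"),
    elevation_m = mean(c(a$elevation_m, b$elevation_m)))
  if (n_single > 0) {
    res$notes <- c(res$notes,
      paste0("station averaging: ", n_single,
             " variable-day(s) used a single station's value"))
  }
  res
}
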