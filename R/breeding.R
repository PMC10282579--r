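#' Read a nest-record table
#'
#' Reads a comma-separated table of per-nest breeding records with columns
#' `nest_id`, `year`, `site` (`"low"`/`"high"`), `first_egg_date`
#' (day-of-year integer), `clutch_size`, `brood_size`, `nestling_masses_g`
#' (day-16 masses in grams, semicolon-separated within the cell) and
#' `attempt_type` (`"first"`, `"renest"` or `"second_brood"`).
#'
#' @param path path to a delimited text file.
#' @return A data frame of nest records; `nestling_masses_g` is a
#'   list-column of numeric vectors.
#' @export
read_nest_records <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("nest_id", "year", "site", "first_egg_date", "clutch_size",
           "brood_size", "attempt_type")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("nest table missing column(s): ", paste(miss, collapse = ", "))
  if (!"nestling_masses_g" %in% names(df)) df$nestling_masses_g <- ""
  df$nestling_masses_g <- lapply(df$nestling_masses_g, function(s) {
    if (is.na(s) || !nzchar(s)) numeric() else
      as.numeric(strsplit(as.character(s), ";", fixed = TRUE)[[1]])
  })
  validate_nest_records(df)
  df
}

validate_nest_records <- function(df) {
  bad_site <- setdiff(unique(df$site), c("low", "high"))
  if (length(bad_site)) stop("unknown site value(s): ", paste(bad_site, collapse = ", "))
  bad_att <- setdiff(unique(df$attempt_type), c("first", "renest", "second_brood"))
  if (length(bad_att)) stop("unknown attempt_type value(s): ", paste(bad_att, collapse = ", "))
  fed <- df$first_egg_date
  if (any(!is.na(fed) & (fed < 1 | fed > 366))) stop("first_egg_date outside [1, 366]")
  invisible(df)
}

#' Write nest records to delimited text
#'
#' @param records nest-record data frame (masses as a list-column).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_nest_records <- function(records, path) {
  df <- records
  df$nestling_masses_g <- vapply(df$nestling_masses_g, function(m) {
    paste(format(m, trim = TRUE, digits = 10), collapse = ";")
  }, character(1))
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Build the analysis breeding table from raw nest records
#'
#' Restricts the records to first breeding attempts (renests and second
#' broods from the same season are removed) and derives the mass-based
#' responses: `mean_mass_g` (mean day-16 nestling mass), `cv_mass` (the
#' within-nest coefficient of variation, 100 x sample standard deviation /
#' mean) and `log_cv_mass` (natural log of `cv_mass`, defined only when
#' `cv_mass > 0`).  Rows whose recorded `brood_size` disagrees with the
#' number of nestling masses are kept but flagged, with the mass-derived
#' responses set missing.
#'
#' @param records nest-record data frame as returned by
#'   [read_nest_records()] or [simulate_breeding()].
#' @return A `breeding_table`: a data frame of first attempts with the
#'   derived response columns, carrying attributes `n_dropped` (renests and
#'   second broods removed) and `flagged` (nest ids with brood/mass
#'   mismatches).
#' @export
build_breeding_table <- function(records) {
  stopifnot(is.data.frame(records))
  first <- records[records$attempt_type == "first", , drop = FALSE]
  n_dropped <- nrow(records) - nrow(first)

  masses <- first$nestling_masses_g
  if (is.null(masses)) masses <- rep(list(numeric()), nrow(first))
  n_mass <- vapply(masses, length, integer(1))
  mismatch <- n_mass > 0 & !is.na(first$brood_size) & n_mass != first$brood_size

  mean_mass <- rep(NA_real_, nrow(first))
  cv <- rep(NA_real_, nrow(first))
  ok <- n_mass > 0 & !mismatch
  mean_mass[ok] <- vapply(masses[ok], mean, numeric(1))
  cv[ok] <- vapply(masses[ok], function(m) {
    if (length(m) < 2) return(NA_real_)
    100 * sd(m) / mean(m)
  }, numeric(1))

  first$mean_mass_g <- mean_mass
  first$cv_mass <- cv
  first$log_cv_mass <- ifelse(!is.na(cv) & cv > 0, log(cv), NA_real_)

  structure(first,
            class = c("breeding_table", "data.frame"),
            n_dropped = n_dropped,
            flagged = first$nest_id[mismatch])
}

# Per-year response values for a site, used by the window search.
# Returns list(year = integer vector per nest, y = response per nest).
response_rows <- function(breeding, response, site = NULL) {
  df <- breeding
  if (!is.null(site)) df <- df[df$site == site, , drop = FALSE]
  y <- df[[response]]
  keep <- !is.na(y)
  list(year = as.integer(df$year[keep]), y = as.numeric(y[keep]))
}
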