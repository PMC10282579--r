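# Year-block randomization gate (P-rand): does the observed top window beat
# the top windows of year-randomized datasets in which climate stays with
# its true season?

#' Randomize year labels at the year-block level
#'
#' Applies a uniformly random permutation (bijection, drawn without
#' replacement; the identity is an allowed draw) of the observed year
#' labels: every nest of an original year receives the same new year, so
#' the multiset of per-year nest groups is preserved while the pairing of
#' breeding data with each season's climate is broken.  The climate series
#' itself is untouched.
#'
#' @param breeding a breeding table (or any data frame with a `year`
#'   column) covering at least 2 distinct years.
#' @param rng_seed optional seed; when `NULL` the current RNG stream is
#'   used (as [compute_prand()] does internally).
#' @return The table with permuted `year` labels and the permutation stored
#'   in attribute `"year_map"` (named: original year -> new year).
#' @export
randomize_year_assignment <- function(breeding, rng_seed = NULL) {
  years <- sort(unique(breeding$year))
  if (length(years) < 2) stop("year randomization needs >= 2 distinct years")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  perm <- sample(years)
  out <- breeding
  out$year <- perm[match(breeding$year, years)]
  attr(out, "year_map") <- setNames(perm, years)
  out
}

#' Year-block randomization test for the chosen window (P-rand)
#'
#' Reruns the full sliding-window search (same grid, same settings as the
#' observed search) on `n_rand` year-randomized datasets and records each
#' randomization's top-window delta AICc and estimate sign.  Only
#' randomizations whose estimate sign matches the observed chosen window
#' are compared; `n_better` counts the sign-matched randomizations whose
#' top window performed strictly better (more negative delta AICc) than the
#' observed chosen window.  With `n_rand = 100` the observed window passes
#' (is judged unlikely to be a false positive) when `n_better <= 5`; for
#' other `n_rand` the threshold is `floor(0.05 * n_rand)`.
#'
#' Randomizations whose search wholly fails are logged and counted as
#' non-better.
#'
#' @param observed a `candidate_set` from [run_sliding_window()] with a
#'   populated `chosen` element.
#' @param breeding,series the data the observed search was run on.
#' @param n_rand number of randomizations (default 100).
#' @param seed RNG seed; with a fixed seed the result is bit-reproducible.
#' @return A `randomization_result`: list with `n_rand`, `table` (per
#'   randomization: delta AICc, sign, sign match), `n_sign_matched`,
#'   `n_better`, `threshold`, `prand_pass`, `observed_delta_aicc`,
#'   `n_failed`.
#' @export
compute_prand <- function(observed, breeding, series, n_rand = 100L,
                          seed = NULL) {
  stopifnot(inherits(observed, "candidate_set"), !is.null(observed$chosen))
  s <- observed$settings
  ctx <- build_search_context(breeding, series, s$variable, s$response,
                              s$family, s$site, s$min_len, s$stride,
                              s$range_start, s$ref, s$completeness_floor)
  obs_delta <- observed$chosen$delta_aicc
  obs_sign <- observed$chosen$sign

  if (!is.null(seed)) set.seed(seed)
  Y <- length(ctx$years)
  delta <- sign_r <- rep(NA_real_, n_rand)
  n_failed <- 0L
  for (r in seq_len(n_rand)) {
    # permuting year labels of nest blocks == re-pairing year groups with
    # covariate columns, so the search context is reused as-is
    perm <- sample.int(Y)
    top <- tryCatch(engine_top(ctx, perm), error = function(e) NULL)
    if (is.null(top)) { n_failed <- n_failed + 1L; next }
    delta[r] <- top$delta_aicc
    sign_r[r] <- top$sign
  }
  matched <- !is.na(sign_r) & sign_r == obs_sign & obs_sign != 0
  n_better <- sum(matched & delta < obs_delta, na.rm = TRUE)
  threshold <- floor(0.05 * n_rand)
  structure(
    list(n_rand = as.integer(n_rand),
         table = data.frame(delta_aicc = delta, sign = sign_r, matched = matched),
         n_sign_matched = sum(matched),
         n_better = n_better,
         threshold = as.integer(threshold),
         prand_pass = n_better <= threshold,
         observed_delta_aicc = obs_delta,
         observed_sign = obs_sign,
         n_failed = n_failed,
         seed = seed),
    class = "randomization_result")
}

#' @export
print.randomization_result <- function(x, ...) {
  cat("<randomization_result> n_rand =", x$n_rand, "\n")
  cat(sprintf("  observed deltaAICc = %.2f (sign %+d)\n",
              x$observed_delta_aicc, x$observed_sign))
  cat("  sign-matched:", x$n_sign_matched,
      "| better than observed:", x$n_better,
      "| threshold:", x$threshold, "\n")
  cat("  P-rand", if (x$prand_pass) "PASS (probably not a false positive)"
      else "FAIL (likely false positive)", "\n")
  if (x$n_failed) cat("  ", x$n_failed, " randomization(s) failed (counted non-better)\n")
  invisible(x)
}

#' Serialize a randomization result to JSON
#'
#' @param x a `randomization_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_randomization_result <- function(x, path) {
  stopifnot(inherits(x, "randomization_result"))
  jsonlite::write_json(
    list(n_rand = x$n_rand, n_sign_matched = x$n_sign_matched,
         n_better = x$n_better, threshold = x$threshold,
         prand_pass = x$prand_pass,
         observed_delta_aicc = x$observed_delta_aicc,
         n_failed = x$n_failed,
         rand_delta_aicc = x$table$delta_aicc, rand_sign = x$table$sign),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
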