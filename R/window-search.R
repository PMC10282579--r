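# Sliding-window search: fit every admissible window's covariate against
# the response and rank windows by AICc improvement over the intercept-only
# null fitted on identical rows (delta AICc; more negative = better).

# Precompute everything a search (or its randomizations) needs.  The
# response enters only through per-year sufficient statistics, so year-block
# randomizations amount to re-pairing year groups with covariate columns.
build_search_context <- function(breeding, series, variable, response, family,
                                 site = NULL, min_len = 14L, stride = 1L,
                                 range_start = 0L, ref = NULL,
                                 completeness_floor = 0.8) {
  if (is.null(site)) {
    us <- unique(breeding$site)
    if (length(us) != 1) stop("breeding table spans several sites; supply `site`")
    site <- us
  }
  rows <- response_rows(breeding, response, site)
  years <- sort(unique(rows$year))
  if (length(years) < 2) stop("sliding-window search needs >= 2 distinct years")
  if (length(rows$y) < 10) stop("sliding-window search needs >= 10 non-missing nests")
  if (is.null(ref)) ref <- reference_date(response, site, breeding)$offset

  windows <- enumerate_windows(range_start, ref, min_len = min_len, stride = stride)
  cm <- window_covariate_matrix(series, variable, windows, years, completeness_floor)

  yi <- match(rows$year, years)
  n_y <- as.numeric(tabulate(yi, nbins = length(years)))
  Sy_y <- as.numeric(rowsum(rows$y, yi, reorder = TRUE))
  Syy_y <- as.numeric(rowsum(rows$y^2, yi, reorder = TRUE))

  list(windows = windows, C = cm$C, completeness = cm$completeness,
       years = years, year_index = yi, y = rows$y,
       n_y = n_y, Sy_y = Sy_y, Syy_y = Syy_y,
       settings = list(variable = variable, response = response,
                       family = family, site = site, min_len = min_len,
                       stride = stride, range_start = range_start, ref = ref,
                       completeness_floor = completeness_floor))
}

# Exact ML Gaussian fits for every window at once, via per-year sufficient
# statistics.  `perm` re-pairs year groups with covariate columns (year-block
# randomization); NULL means the observed pairing.
engine_gaussian <- function(ctx, perm = NULL) {
  C <- ctx$C
  if (!is.null(perm)) C <- C[, perm, drop = FALSE]
  M <- !is.na(C)
  C0 <- ifelse(M, C, 0)

  nw   <- drop(M  %*% ctx$n_y)
  Syw  <- drop(M  %*% ctx$Sy_y)
  Syyw <- drop(M  %*% ctx$Syy_y)
  Sxw  <- drop(C0 %*% ctx$n_y)
  Sxxw <- drop(C0^2 %*% ctx$n_y)
  Sxyw <- drop(C0 %*% ctx$Sy_y)
  yrs_used <- rowSums(M)

  Sxx_c <- Sxxw - Sxw^2 / nw
  Sxy_c <- Sxyw - Sxw * Syw / nw
  Syy_c <- Syyw - Syw^2 / nw

  valid <- yrs_used >= 2 & nw >= 4 & Sxx_c > 1e-10 & Syy_c > 0
  slope <- ifelse(valid, Sxy_c / Sxx_c, NA_real_)
  rss <- Syy_c - slope * Sxy_c
  valid <- valid & !is.na(rss) & rss > 1e-12
  ll1 <- -nw / 2 * (log(2 * pi * rss / nw) + 1)
  aicc1 <- -2 * ll1 + 6 + 24 / (nw - 4)              # k = 3
  ll0 <- -nw / 2 * (log(2 * pi * Syy_c / nw) + 1)
  aicc0 <- -2 * ll0 + 4 + 12 / (nw - 3)              # k = 2
  se <- sqrt(rss / (nw - 2) / Sxx_c)

  data.frame(open = ctx$windows$open, close = ctx$windows$close,
             duration = ctx$windows$duration, n = nw,
             estimate = slope, se = se, statistic = slope / se,
             aicc = aicc1, null_aicc = aicc0, delta_aicc = aicc1 - aicc0,
             valid = valid)
}

# Generalized-Poisson fits window by window (counts).  Null fits are cached
# per pattern of usable years so each distinct row set is fitted once.
engine_genpois <- function(ctx, perm = NULL) {
  C <- ctx$C
  if (!is.null(perm)) C <- C[, perm, drop = FALSE]
  W <- nrow(ctx$windows)
  est <- se <- stat <- a1 <- a0 <- nn <- rep(NA_real_, W)
  valid <- rep(FALSE, W)
  null_cache <- new.env(parent = emptyenv())

  for (w in seq_len(W)) {
    xv <- C[w, ctx$year_index]
    keep <- !is.na(xv)
    if (length(unique(ctx$year_index[keep])) < 2) next
    yk <- ctx$y[keep]; xk <- xv[keep]
    if (length(yk) < 4 || var(xk) < 1e-12) next
    key <- paste(which(!is.na(C[w, ])), collapse = ",")
    nf <- null_cache[[key]]
    if (is.null(nf)) {
      nf <- tryCatch(fit_genpois_glm(yk, matrix(1, length(yk),
                                                dimnames = list(NULL, "intercept"))),
                     error = function(e) NULL)
      null_cache[[key]] <- if (is.null(nf)) FALSE else nf
    }
    if (isFALSE(nf) || is.null(nf)) next
    fit <- tryCatch(fit_genpois_glm(yk, cbind(intercept = 1, climate = xk)),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged || !nf$converged) next
    est[w] <- fit$coefficients$estimate[2]
    se[w] <- fit$coefficients$se[2]
    stat[w] <- fit$coefficients$statistic[2]
    a1[w] <- fit$aicc; a0[w] <- nf$aicc; nn[w] <- length(yk)
    valid[w] <- TRUE
  }
  data.frame(open = ctx$windows$open, close = ctx$windows$close,
             duration = ctx$windows$duration, n = nn,
             estimate = est, se = se, statistic = stat,
             aicc = a1, null_aicc = a0, delta_aicc = a1 - a0, valid = valid)
}

run_engine <- function(ctx, perm = NULL) {
  if (ctx$settings$family == "gaussian") engine_gaussian(ctx, perm)
  else engine_genpois(ctx, perm)
}

# Delta AICc and estimate sign of the best window only (randomizations).
engine_top <- function(ctx, perm = NULL) {
  fits <- run_engine(ctx, perm)
  fits <- fits[fits$valid, , drop = FALSE]
  if (!nrow(fits)) return(NULL)
  i <- which.min(fits$delta_aicc)
  list(delta_aicc = fits$delta_aicc[i], sign = sign(fits$estimate[i]))
}

# Refit the chosen window with the full estimators, for downstream LRT /
# reporting.  Rows are the nests of years with a non-missing covariate.
refit_window <- function(ctx, open, close) {
  w <- which(ctx$windows$open == open & ctx$windows$close == close)
  xv <- ctx$C[w[1], ctx$year_index]
  keep <- !is.na(xv)
  y <- ctx$y[keep]; x <- xv[keep]
  X <- cbind(intercept = 1, climate = x)
  colnames(X)[2] <- ctx$settings$variable
  null_X <- X[, 1, drop = FALSE]
  if (ctx$settings$family == "gaussian") {
    fit <- fit_gaussian_lm(y, X); null_fit <- fit_gaussian_lm(y, null_X)
  } else {
    fit <- fit_genpois_glm(y, X); null_fit <- fit_genpois_glm(y, null_X)
  }
  covariate <- setNames(ctx$C[w[1], ], ctx$years)
  list(window = list(open = open, close = close,
                     duration = close - open + 1L,
                     label = window_label(open, close)),
       fit = fit, null_fit = null_fit,
       delta_aicc = fit$aicc - null_fit$aicc,
       sign = sign(fit$coefficients$estimate[2]),
       covariate = covariate)
}

#' Sliding-window search for one climate/response pair
#'
#' Enumerates every admissible absolute window between `range_start`
#' (default 1 September of the preceding autumn) and the response's
#' reference date, builds the per-year window-mean covariate, fits the
#' response model for each window and ranks windows by the AICc improvement
#' over the intercept-only null fitted on identical rows.  Windows within
#' 2 delta-AICc of the best are marked equivalent, and substantially
#' overlapping equivalents are collapsed to the lowest-delta-AICc member
#' (see [collapse_equivalent_windows()]).
#'
#' The search is deterministic: no randomness is involved.
#'
#' @param breeding a [build_breeding_table()] result.
#' @param series a [climate_series()].
#' @param variable canonical climate variable name.
#' @param response response column name in `breeding`.
#' @param family `"gaussian"` or `"genpois"`.
#' @param site site to analyse (`"low"`/`"high"`); may be omitted when the
#'   table holds a single site.
#' @param min_len minimum window length in days (default 14).
#' @param stride window-endpoint grid step in days (default 1, the full
#'   day-resolution grid).
#' @param range_start earliest open offset (0 = 1 September).
#' @param ref latest close offset; defaults to [reference_date()].
#' @param completeness_floor minimum per-window fraction of non-missing
#'   climate days (default 0.8).
#' @param jaccard_threshold overlap threshold for collapsing equivalent
#'   windows (default 0.75).
#' @return A `candidate_set`: list with `all_fits` (data frame of every
#'   fitted window, ascending delta AICc), `top_set` (windows within 2
#'   delta AICc of the best after overlap collapsing), `chosen` (the
#'   lowest-delta-AICc survivor, with full fit, null fit and per-year
#'   covariate values), `n_failed` (windows excluded because their fit
#'   failed or their covariate was degenerate) and `settings`.
#' @export
run_sliding_window <- function(breeding, series, variable, response, family,
                               site = NULL, min_len = 14L, stride = 1L,
                               range_start = 0L, ref = NULL,
                               completeness_floor = 0.8,
                               jaccard_threshold = 0.75) {
  family <- match.arg(family, c("gaussian", "genpois"))
  ctx <- build_search_context(breeding, series, variable, response, family,
                              site, min_len, stride, range_start, ref,
                              completeness_floor)
  fits <- run_engine(ctx)
  n_failed <- sum(!fits$valid)
  fits <- fits[fits$valid, setdiff(names(fits), "valid"), drop = FALSE]
  if (!nrow(fits)) stop("all window fits failed for ", variable, " / ", response)
  fits <- fits[order(fits$delta_aicc, fits$open, fits$close), , drop = FALSE]
  rownames(fits) <- NULL
  fits$label <- window_label(fits$open, fits$close)

  cands <- structure(
    list(all_fits = fits, top_set = NULL, chosen = NULL,
         n_failed = n_failed, settings = ctx$settings),
    class = "candidate_set")
  cands <- collapse_equivalent_windows(cands, jaccard_threshold = jaccard_threshold)
  cands$chosen <- refit_window(ctx, cands$chosen_row$open, cands$chosen_row$close)
  cands
}

#' Collapse temporally overlapping equivalent windows
#'
#' Windows within 2 delta-AICc of the best are equivalent in performance.
#' Equivalents whose day sets overlap substantially (temporal Jaccard at or
#' above `jaccard_threshold`) are grouped, and within each group only the
#' lowest-delta-AICc member survives; non-overlapping equal performers are
#' all retained in `top_set`.  `chosen` is the overall lowest-delta-AICc
#' survivor.
#'
#' @param cands a `candidate_set`.
#' @param jaccard_threshold overlap threshold (default 0.75).
#' @param delta_equiv equivalence band in delta-AICc units (default 2).
#' @return The `candidate_set` with `top_set`, `chosen_row` (and, when the
#'   set came from [run_sliding_window()], `chosen`) updated; the
#'   pre-collapse equivalence set is kept as `top_set_full`.
#' @export
collapse_equivalent_windows <- function(cands, jaccard_threshold = 0.75,
                                        delta_equiv = 2) {
  stopifnot(inherits(cands, "candidate_set"))
  fits <- cands$all_fits
  best <- min(fits$delta_aicc)
  ts <- fits[fits$delta_aicc <= best + delta_equiv, , drop = FALSE]
  ts <- ts[order(ts$delta_aicc, ts$open, ts$close), , drop = FALSE]

  group <- integer(nrow(ts))
  reps <- integer(0)                      # row indices of group representatives
  for (i in seq_len(nrow(ts))) {
    j <- NA_integer_
    for (r in seq_along(reps)) {
      if (window_jaccard(ts$open[i], ts$close[i],
                         ts$open[reps[r]], ts$close[reps[r]]) >= jaccard_threshold) {
        j <- r; break
      }
    }
    if (is.na(j)) { reps <- c(reps, i); j <- length(reps) }
    group[i] <- j
  }
  ts$overlap_group <- group
  survivors <- ts[reps, , drop = FALSE]
  survivors$n_equivalent <- as.integer(table(group)[as.character(seq_along(reps))])

  cands$top_set_full <- ts
  cands$top_set <- survivors
  cands$chosen_row <- survivors[1, , drop = FALSE]
  cands
}

#' @export
print.candidate_set <- function(x, ...) {
  s <- x$settings
  cat("<candidate_set> ", s$variable, " -> ", s$response,
      " (", s$family, ", site ", s$site, ")\n", sep = "")
  cat("  ", nrow(x$all_fits), " windows fitted (stride ", s$stride,
      ", span 0..", s$ref, "); ", x$n_failed, " failed\n", sep = "")
  if (!is.null(x$chosen)) {
    ch <- x$chosen
    cat(sprintf("  chosen: %s  deltaAICc = %.2f  estimate = %.4g (se %.3g)\n",
                ch$window$label, ch$delta_aicc,
                ch$fit$coefficients$estimate[2], ch$fit$coefficients$se[2]))
  }
  cat("  top set (after overlap collapsing): ", nrow(x$top_set), " window(s)\n", sep = "")
  invisible(x)
}

#' Export a candidate set to delimited text and JSON
#'
#' @param cands a `candidate_set`.
#' @param csv_path,json_path output paths; either may be `NULL` to skip.
#' @return Invisibly, the summary list written to JSON.
#' @export
export_candidate_set <- function(cands, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(cands, "candidate_set"))
  if (!is.null(csv_path)) {
    write.csv(cands$all_fits[, c("open", "close", "label", "duration", "n",
                                 "estimate", "se", "delta_aicc", "aicc")],
              csv_path, row.names = FALSE)
  }
  summary <- list(
    settings = cands$settings,
    chosen = list(window = cands$chosen$window,
                  delta_aicc = cands$chosen$delta_aicc,
                  estimate = cands$chosen$fit$coefficients$estimate[2],
                  se = cands$chosen$fit$coefficients$se[2]),
    top_set = cands$top_set[, c("open", "close", "label", "delta_aicc")],
    n_windows = nrow(cands$all_fits), n_failed = cands$n_failed)
  if (!is.null(json_path)) {
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  invisible(summary)
}
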