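# Staged final-model selection: LRT screening + P-rand gate, deduplication
# of climatically similar variables with overlapping windows, collinearity
# pruning, and all-subsets AICc competition.

# Normalise one variable's (search, randomization) pair into the entry
# format the selection stages consume.
candidate_entry <- function(variable, cands, rand = NULL) {
  ch <- cands$chosen
  lr <- lrt(ch$fit, ch$null_fit)
  list(variable = variable, window = ch$window, fit = ch$fit,
       null_fit = ch$null_fit, aicc = ch$fit$aicc,
       delta_aicc = ch$delta_aicc, lrt_p = lr$p,
       prand_pass = if (is.null(rand)) NA else rand$prand_pass,
       covariate = ch$covariate)
}

#' Screen candidate variables by LRT and the randomization gate
#'
#' A variable's chosen window is retained only if its single-covariate
#' model improves significantly on the null by likelihood-ratio test
#' (`p < alpha`) *and* its randomization gate passed (windows judged likely
#' false positives are not considered further).  An empty result is valid
#' and reported downstream as "no significant climatic predictors".
#'
#' @param cands list of candidate entries; each element is either a list
#'   `list(variable, cands, rand)` pairing a variable name with its
#'   [run_sliding_window()] and [compute_prand()] results, or an entry
#'   already built by those stages.
#' @param alpha LRT screening level (default 0.05).
#' @return List of retained entries (possibly empty), each carrying
#'   `variable`, `window`, `fit`, `aicc`, `lrt_p`, `prand_pass`,
#'   `covariate`.
#' @export
screen_candidates <- function(cands, alpha = 0.05) {
  entries <- lapply(cands, function(e) {
    if (!is.null(e$cands)) candidate_entry(e$variable, e$cands, e$rand) else e
  })
  keep <- vapply(entries, function(e) {
    isTRUE(e$lrt_p < alpha) && isTRUE(e$prand_pass)
  }, logical(1))
  entries[keep]
}

#' Deduplicate climatically similar variables with overlapping windows
#'
#' Variables in the same similarity family (the three air temperatures;
#' soil moisture depths; soil temperature depths; snow depth, snow water
#' equivalent and precipitation accumulation) often pick near-identical
#' windows.  Within each family, variables whose chosen windows overlap
#' (temporal Jaccard at or above `jaccard_threshold`) are grouped and only
#' the lowest-AICc member of each group survives; non-overlapping family
#' members all survive.  Displaced equivalents are recorded in the
#' survivor's `equivalents` field.
#'
#' @param retained list of entries from [screen_candidates()].
#' @param jaccard_threshold overlap threshold (default 0.75).
#' @param families named list of variable-name families; defaults to the
#'   built-in similarity families.
#' @return Deduplicated list of entries.
#' @export
dedupe_similar_variables <- function(retained, jaccard_threshold = 0.75,
                                     families = VARIABLE_FAMILIES) {
  if (length(retained) < 2) return(retained)
  vars <- vapply(retained, `[[`, character(1), "variable")
  fam_of <- rep(NA_character_, length(vars))
  for (f in names(families)) fam_of[vars %in% families[[f]]] <- f

  drop <- logical(length(retained))
  for (f in unique(stats::na.omit(fam_of))) {
    idx <- which(fam_of == f)
    if (length(idx) < 2) next
    idx <- idx[order(vapply(retained[idx], `[[`, numeric(1), "aicc"))]
    reps <- integer(0)
    for (i in idx) {
      wi <- retained[[i]]$window
      placed <- FALSE
      for (r in reps) {
        wr <- retained[[r]]$window
        if (window_jaccard(wi$open, wi$close, wr$open, wr$close) >= jaccard_threshold) {
          drop[i] <- TRUE
          retained[[r]]$equivalents <- c(retained[[r]]$equivalents,
                                         retained[[i]]$variable)
          placed <- TRUE
          break
        }
      }
      if (!placed) reps <- c(reps, i)
    }
  }
  retained[!drop]
}

#' Prune collinear covariates
#'
#' Pairwise Pearson correlations are computed among the retained per-year
#' window covariates; while any pair has `|r|` at or above `threshold`, the
#' higher-AICc member of the worst pair is dropped.  Iterated until no pair
#' exceeds the threshold.
#'
#' @param retained list of entries from [dedupe_similar_variables()].
#' @param threshold absolute correlation cutoff (default 0.7).
#' @return List of entries with no remaining pair at `|r| >= threshold`.
#' @export
prune_collinear <- function(retained, threshold = 0.7) {
  while (length(retained) >= 2) {
    k <- length(retained)
    worst <- NULL; worst_r <- -Inf
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      ci <- retained[[i]]$covariate; cj <- retained[[j]]$covariate
      common <- intersect(names(ci)[!is.na(ci)], names(cj)[!is.na(cj)])
      if (length(common) < 3) next
      r <- abs(pearson_r(ci[common], cj[common]))
      if (r > worst_r) { worst_r <- r; worst <- c(i, j) }
    }
    if (is.null(worst) || worst_r < threshold) break
    aiccs <- c(retained[[worst[1]]]$aicc, retained[[worst[2]]]$aicc)
    retained <- retained[-worst[which.max(aiccs)]]
  }
  retained
}

#' All-subsets AICc competition among retained covariates
#'
#' Fits the response against every non-empty subset of the retained
#' variables (each entering as its own chosen window's per-year mean,
#' expanded to nests) on a common set of rows, and reports all models
#' within `delta_equiv` AICc of the best, with coefficients, standard
#' errors, test statistics and AICc.
#'
#' @param retained list of entries surviving [prune_collinear()].
#' @param breeding the breeding table the searches were run on.
#' @param response,family,site analysis identifiers (taken from the
#'   entries' fits where omitted).
#' @param delta_equiv reporting band in AICc units (default 2).
#' @return A `final_model_report`: list with `response`, `site`, `family`,
#'   `retained_variables`, `correlation_matrix` (pairwise Pearson r among
#'   retained per-year covariates), `models` (list of `list(variables,
#'   fit)` sorted by AICc, all within the band) and `n_rows`.  With no
#'   retained variables the report is empty ("no significant climatic
#'   predictors").
#' @export
select_final_models <- function(retained, breeding, response, family,
                                site = NULL, delta_equiv = 2) {
  family <- match.arg(family, c("gaussian", "genpois"))
  report <- structure(
    list(response = response, site = site, family = family,
         retained_variables = vapply(retained, `[[`, character(1), "variable"),
         correlation_matrix = NULL, models = list(), n_rows = 0L),
    class = "final_model_report")
  if (!length(retained)) return(report)
  if (length(retained) > 12) stop("subset search guard: more than 12 retained variables")

  rows <- response_rows(breeding, response, site)
  vars <- report$retained_variables
  Xall <- sapply(retained, function(e) {
    unname(e$covariate[as.character(rows$year)])
  })
  Xall <- matrix(Xall, ncol = length(retained), dimnames = list(NULL, vars))
  keep <- complete.cases(Xall)
  y <- rows$y[keep]; Xall <- Xall[keep, , drop = FALSE]
  report$n_rows <- length(y)

  if (length(vars) >= 2) {
    cm <- diag(1, length(vars)); dimnames(cm) <- list(vars, vars)
    for (i in seq_len(length(vars) - 1)) for (j in (i + 1):length(vars)) {
      ci <- retained[[i]]$covariate; cj <- retained[[j]]$covariate
      common <- intersect(names(ci)[!is.na(ci)], names(cj)[!is.na(cj)])
      cm[i, j] <- cm[j, i] <- if (length(common) >= 3)
        pearson_r(ci[common], cj[common]) else NA_real_
    }
    report$correlation_matrix <- cm
  }

  fitter <- if (family == "gaussian") fit_gaussian_lm else fit_genpois_glm
  subsets <- lapply(seq_len(2^length(vars) - 1), function(m) {
    which(bitwAnd(m, 2^(seq_along(vars) - 1)) > 0)
  })
  fits <- lapply(subsets, function(s) {
    X <- cbind(intercept = 1, Xall[, s, drop = FALSE])
    tryCatch(fitter(y, X), error = function(e) NULL)
  })
  ok <- !vapply(fits, is.null, logical(1))
  subsets <- subsets[ok]; fits <- fits[ok]
  if (!length(fits)) return(report)
  aiccs <- vapply(fits, `[[`, numeric(1), "aicc")
  ord <- order(aiccs)
  within <- ord[aiccs[ord] <= min(aiccs) + delta_equiv]
  report$models <- lapply(within, function(i) {
    list(variables = vars[subsets[[i]]], fit = fits[[i]])
  })
  report
}

#' @export
print.final_model_report <- function(x, ...) {
  cat("<final_model_report> ", x$response, " at ", x$site,
      " elevation (", x$family, ")\n", sep = "")
  if (!length(x$models)) {
    cat("  no significant climatic predictors\n")
    return(invisible(x))
  }
  cat("  retained variables: ", paste(x$retained_variables, collapse = ", "),
      " (n = ", x$n_rows, " nests)\n", sep = "")
  for (i in seq_along(x$models)) {
    m <- x$models[[i]]
    cat(sprintf("  model %d (AICc %.2f): %s\n", i, m$fit$aicc,
                paste(m$variables, collapse = " + ")))
    print(m$fit$coefficients, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Flatten a final-model report into a coefficient table
#'
#' One row per coefficient per competing model, in the layout of a
#' published fixed-effects table (estimate, s.e., t/z statistic, p, AICc).
#'
#' @param x a `final_model_report`.
#' @param ... unused.
#' @return A data frame.
#' @export
as.data.frame.final_model_report <- function(x, ...) {
  if (!length(x$models)) {
    return(data.frame(response = character(), site = character(),
                      model = integer(), term = character(),
                      estimate = numeric(), se = numeric(),
                      statistic = numeric(), p_value = numeric(),
                      aicc = numeric()))
  }
  do.call(rbind, lapply(seq_along(x$models), function(i) {
    co <- x$models[[i]]$fit$coefficients
    data.frame(response = x$response, site = x$site %||% NA_character_,
               model = i, term = co$term, estimate = co$estimate,
               se = co$se, statistic = co$statistic, p_value = co$p_value,
               aicc = x$models[[i]]$fit$aicc)
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a final-model report to CSV and JSON
#'
#' @param x a `final_model_report`.
#' @param csv_path,json_path output paths; either may be `NULL`.
#' @return Invisibly, the coefficient table.
#' @export
export_final_model_report <- function(x, csv_path = NULL, json_path = NULL) {
  tab <- as.data.frame(x)
  if (!is.null(csv_path)) write.csv(tab, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(response = x$response, site = x$site, family = x$family,
           retained_variables = x$retained_variables,
           n_rows = x$n_rows, coefficients = tab),
      json_path, auto_unbox = TRUE, digits = NA, dataframe = "rows", na = "null")
  }
  invisible(tab)
}

#' Across-year variation test for a response
#'
#' Likelihood-ratio test of a year-as-categorical-factor model against the
#' intercept-only null, with the family matched to the response.
#'
#' @param breeding breeding table.
#' @param response response column.
#' @param family `"gaussian"` or `"genpois"`.
#' @param site optional site restriction.
#' @return List with `chisq`, `df` (number of years minus 1) and `p`.
#' @export
across_year_test <- function(breeding, response, family, site = NULL) {
  family <- match.arg(family, c("gaussian", "genpois"))
  rows <- response_rows(breeding, response, site)
  if (length(unique(rows$year)) < 2) stop("across-year test needs >= 2 years")
  X <- stats::model.matrix(~ factor(rows$year))
  colnames(X) <- c("intercept", paste0("year", sort(unique(rows$year))[-1]))
  X0 <- X[, 1, drop = FALSE]
  fitter <- if (family == "gaussian") fit_gaussian_lm else fit_genpois_glm
  lr <- lrt(fitter(rows$y, X), fitter(rows$y, X0))
  list(chisq = lr$chisq, df = lr$df, p = lr$p)
}

#' Ordinary least-squares linear trend test
#'
#' OLS slope of a value on year with a two-sided t test; used to ask
#' whether a breeding parameter drifted consistently over the study.
#'
#' @param values numeric vector.
#' @param years integer vector of the same length (at least 3 distinct
#'   points).
#' @return List with `slope`, `t` and `p`.
#' @export
linear_trend_test <- function(values, years) {
  stopifnot(length(values) == length(years), length(values) >= 3)
  fit <- summary(lm(values ~ years))
  co <- fit$coefficients
  if (nrow(co) < 2) return(list(slope = 0, t = 0, p = 1))
  list(slope = unname(co[2, 1]), t = unname(co[2, 3]), p = unname(co[2, 4]))
}
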