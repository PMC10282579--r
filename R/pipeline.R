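# End-to-end orchestration: per-variable sliding windows -> randomization
# gate -> staged model selection, for every response x site.

#' Analysis run configuration
#'
#' Bundles every tunable the pipeline uses, with the defaults of the study
#' protocol: the five responses and their families (first egg date,
#' mean nestling mass and log CV Gaussian; clutch and brood size
#' generalized Poisson), all eleven climate variables, windows of at least
#' 14 days starting no earlier than 1 September, a 2 delta-AICc
#' equivalence band, 0.75 temporal-Jaccard overlap collapsing, 100
#' randomizations with the `<= floor(0.05 n)` pass rule, LRT screening at
#' alpha 0.05 and a 0.7 absolute-correlation collinearity cutoff.
#'
#' @param responses named character vector mapping response columns to
#'   families.
#' @param variables climate variables to search.
#' @param sites sites to analyse.
#' @param min_len,stride,range_start window grid controls (`stride = 1` is
#'   the full day-resolution grid; coarser strides speed up simulation
#'   studies).
#' @param n_rand randomizations for the P-rand gate.
#' @param seed base RNG seed for the gate.
#' @param alpha LRT screening level.
#' @param delta_equiv AICc equivalence band.
#' @param jaccard_threshold window-overlap collapsing threshold.
#' @param r_threshold collinearity cutoff on |Pearson r|.
#' @param completeness_floor minimum non-missing fraction per window.
#' @return A validated `nestwin_config` list.
#' @export
nestwin_config <- function(responses = c(first_egg_date = "gaussian",
                                         clutch_size = "genpois",
                                         brood_size = "genpois",
                                         mean_mass_g = "gaussian",
                                         log_cv_mass = "gaussian"),
                           variables = CLIMATE_VARS,
                           sites = c("low", "high"),
                           min_len = 14L, stride = 1L, range_start = 0L,
                           n_rand = 100L, seed = 1L, alpha = 0.05,
                           delta_equiv = 2, jaccard_threshold = 0.75,
                           r_threshold = 0.7, completeness_floor = 0.8) {
  stopifnot(all(responses %in% c("gaussian", "genpois")),
            !is.null(names(responses)), all(nzchar(names(responses))),
            min_len >= 1, stride >= 1, n_rand >= 1,
            alpha > 0, delta_equiv > 0, jaccard_threshold > 0,
            r_threshold > 0, completeness_floor > 0)
  structure(as.list(environment()), class = "nestwin_config")
}

#' Run the full climate-window analysis
#'
#' For every configured site and response: run the sliding-window search
#' for each climate variable, gate each variable's chosen window with the
#' year-block randomization test (run only for windows that pass LRT
#' screening — a variable failing the screen is dropped regardless of the
#' gate), then apply the staged selection protocol
#' ([screen_candidates()] -> [dedupe_similar_variables()] ->
#' [prune_collinear()] -> [select_final_models()]).  Also computes the
#' across-year variation test per response.  Deterministic for a fixed
#' config seed.
#'
#' @param breeding a [build_breeding_table()] result covering the
#'   configured sites.
#' @param climate named list of [climate_series()], one per site.
#' @param config a [nestwin_config()].
#' @return A `nestwin_run`: list with `config`, `results` (per site, per
#'   response: `candidates` — per-variable search, gate and screening
#'   detail — and `report`, a `final_model_report`), `across_year` (data
#'   frame of variation tests) and `log` (character vector of stage
#'   messages).
#' @export
run_full_analysis <- function(breeding, climate, config = nestwin_config()) {
  stopifnot(inherits(config, "nestwin_config"),
            all(config$sites %in% names(climate)))
  log <- character()
  note <- function(...) log <<- c(log, paste0(...))
  results <- list()
  ay <- list()
  seed_counter <- 0L

  for (site in config$sites) {
    results[[site]] <- list()
    for (response in names(config$responses)) {
      family <- config$responses[[response]]
      entries <- list()
      for (variable in config$variables) {
        cs <- tryCatch(
          run_sliding_window(breeding, climate[[site]], variable, response,
                             family, site = site,
                             min_len = config$min_len, stride = config$stride,
                             range_start = config$range_start,
                             completeness_floor = config$completeness_floor,
                             jaccard_threshold = config$jaccard_threshold),
          error = function(e) {
            note("search failed [", site, "/", response, "/", variable, "]: ",
                 conditionMessage(e))
            NULL
          })
        if (is.null(cs)) next
        entry <- candidate_entry(variable, cs)
        seed_counter <- seed_counter + 1L
        if (entry$lrt_p < config$alpha) {
          rand <- compute_prand(cs, breeding, climate[[site]],
                                n_rand = config$n_rand,
                                seed = (config$seed + 7919L * seed_counter) %% .Machine$integer.max)
          entry$prand_pass <- rand$prand_pass
          entry$rand <- rand
        } else {
          entry$prand_pass <- FALSE
          note("LRT screen dropped ", variable, " for ", site, "/", response,
               " (p = ", signif(entry$lrt_p, 3), "); gate skipped")
        }
        entry$search <- cs
        entries[[variable]] <- entry
      }
      retained <- screen_candidates(entries, alpha = config$alpha)
      retained <- dedupe_similar_variables(retained,
                                           jaccard_threshold = config$jaccard_threshold)
      retained <- prune_collinear(retained, threshold = config$r_threshold)
      report <- select_final_models(retained, breeding, response, family,
                                    site = site,
                                    delta_equiv = config$delta_equiv)
      results[[site]][[response]] <- list(candidates = entries, report = report)
      ay[[length(ay) + 1L]] <- data.frame(
        site = site, response = response,
        chisq = NA_real_, df = NA_integer_, p = NA_real_)
      t <- tryCatch(across_year_test(breeding, response, family, site = site),
                    error = function(e) NULL)
      if (!is.null(t)) {
        ay[[length(ay)]][, c("chisq", "df", "p")] <-
          list(t$chisq, as.integer(t$df), t$p)
      }
    }
  }
  structure(list(config = config, results = results,
                 across_year = do.call(rbind, ay), log = log),
            class = "nestwin_run")
}

#' @export
print.nestwin_run <- function(x, ...) {
  cat("<nestwin_run>\n")
  for (site in names(x$results)) {
    for (response in names(x$results[[site]])) {
      rep <- x$results[[site]][[response]]$report
      vars <- rep$retained_variables
      cat("  ", site, "/", response, ": ",
          if (length(vars)) paste(vars, collapse = " + ")
          else "no significant climatic predictors",
          " (", length(rep$models), " final model(s))\n", sep = "")
    }
  }
  if (length(x$log)) cat("  log:", length(x$log), "message(s)\n")
  invisible(x)
}

#' Re-validate every invariant of a completed run
#'
#' Checks the structural invariants of the output bundle: final-model
#' covariates are subsets of the retained variables, models are sorted by
#' AICc and lie within the equivalence band, no reported model contains a
#' covariate pair at or above the collinearity cutoff, and every retained
#' variable passed both the LRT screen and the randomization gate.
#'
#' @param run a `nestwin_run`.
#' @return `TRUE` invisibly; stops with a message on the first violation.
#' @export
validate_run <- function(run) {
  stopifnot(inherits(run, "nestwin_run"))
  cfg <- run$config
  for (site in names(run$results)) for (response in names(run$results[[site]])) {
    res <- run$results[[site]][[response]]
    rep <- res$report
    for (m in rep$models) {
      if (!all(m$variables %in% rep$retained_variables)) {
        stop("final model covariates outside retained set: ", site, "/", response)
      }
    }
    if (length(rep$models) >= 2) {
      aiccs <- vapply(rep$models, function(m) m$fit$aicc, numeric(1))
      if (is.unsorted(aiccs)) stop("final models not sorted by AICc")
      if (max(aiccs) > min(aiccs) + cfg$delta_equiv + 1e-9) {
        stop("final model outside the AICc equivalence band")
      }
    }
    cm <- rep$correlation_matrix
    if (!is.null(cm)) {
      off <- abs(cm[upper.tri(cm)])
      if (any(off >= cfg$r_threshold, na.rm = TRUE)) {
        stop("retained covariates still collinear: ", site, "/", response)
      }
    }
    for (v in rep$retained_variables) {
      e <- res$candidates[[v]]
      if (!(isTRUE(e$lrt_p < cfg$alpha) && isTRUE(e$prand_pass))) {
        stop("retained variable failed a gate: ", v, " at ", site, "/", response)
      }
    }
  }
  invisible(TRUE)
}
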