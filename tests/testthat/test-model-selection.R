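mk_entry <- function(variable, open = 43L, close = 94L, aicc = 100,
                     lrt_p = 0.001, prand_pass = TRUE, covariate = NULL) {
  list(variable = variable,
       window = list(open = open, close = close,
                     duration = close - open + 1L),
       aicc = aicc, lrt_p = lrt_p, prand_pass = prand_pass,
       covariate = covariate)
}

test_that("screening keeps only variables passing both the LRT and the randomization gate", {
  entries <- list(
    mk_entry("tavg_c", lrt_p = 0.20, prand_pass = TRUE),    # not significant
    mk_entry("swe_mm", lrt_p = 0.001, prand_pass = FALSE),  # likely false positive
    mk_entry("tmax_c", lrt_p = 0.001, prand_pass = TRUE))
  kept <- screen_candidates(entries)
  expect_equal(vapply(kept, `[[`, character(1), "variable"), "tmax_c")
  # empty result is allowed: "no significant climatic predictors"
  expect_length(screen_candidates(entries[1:2]), 0)
  # boundary: p exactly alpha is not significant
  expect_length(screen_candidates(list(mk_entry("a", lrt_p = 0.05))), 0)
})

test_that("similar variables with overlapping windows collapse to the lowest AICc member", {
  # three air temperatures sharing one window -> lowest AICc survives
  e <- list(mk_entry("tavg_c", aicc = 101), mk_entry("tmax_c", aicc = 99.5),
            mk_entry("tmin_c", aicc = 102))
  out <- dedupe_similar_variables(e)
  expect_equal(vapply(out, `[[`, character(1), "variable"), "tmax_c")
  expect_setequal(out[[1]]$equivalents, c("tavg_c", "tmin_c"))

  # same family, disjoint windows (spring tavg vs autumn tmin): both survive
  e2 <- list(mk_entry("tavg_c", open = 205L, close = 250L, aicc = 100),
             mk_entry("tmin_c", open = 50L, close = 75L, aicc = 101))
  expect_length(dedupe_similar_variables(e2), 2)

  # different families never compete
  e3 <- list(mk_entry("tavg_c", aicc = 100), mk_entry("swe_mm", aicc = 99))
  expect_length(dedupe_similar_variables(e3), 2)

  # single entry unchanged
  expect_length(dedupe_similar_variables(e[2]), 1)
})

test_that("collinearity pruning iterates to an uncorrelated set favouring low AICc", {
  yrs <- as.character(2013:2022)
  set.seed(61)
  base <- rnorm(10)
  cov_dup <- setNames(base, yrs)
  indep <- setNames(rnorm(10), yrs)
  while (abs(cor(base, indep)) >= 0.5) indep <- setNames(rnorm(10), yrs)

  # duplicated covariate: higher-AICc copy dropped
  e <- list(mk_entry("tavg_c", aicc = 100, covariate = cov_dup),
            mk_entry("soil_temp_5cm_c", aicc = 95, covariate = cov_dup))
  out <- prune_collinear(e)
  expect_equal(vapply(out, `[[`, character(1), "variable"), "soil_temp_5cm_c")

  # weakly correlated pair both kept
  e2 <- list(mk_entry("tavg_c", aicc = 100, covariate = cov_dup),
             mk_entry("swe_mm", aicc = 95, covariate = indep))
  expect_length(prune_collinear(e2), 2)

  # three mutually correlated variables -> single lowest-AICc survivor
  e3 <- list(
    mk_entry("tavg_c", aicc = 100,
             covariate = setNames(base + rnorm(10, 0, 0.05), yrs)),
    mk_entry("swe_mm", aicc = 97,
             covariate = setNames(base + rnorm(10, 0, 0.05), yrs)),
    mk_entry("soil_moist_5cm_pct", aicc = 99,
             covariate = setNames(base + rnorm(10, 0, 0.05), yrs)))
  out3 <- prune_collinear(e3)
  expect_equal(vapply(out3, `[[`, character(1), "variable"), "swe_mm")
})

test_that("all-subsets selection reports exactly the models within 2 AICc of the best", {
  set.seed(71)
  yrs <- 2013:2022
  a <- setNames(rnorm(10), yrs)
  b <- setNames(rnorm(10), yrs)
  year <- rep(yrs, each = 20)
  y <- 0.8 * a[as.character(year)] + 0.8 * b[as.character(year)] + rnorm(200)
  bt <- toy_breeding(year, y, response = "resp")
  retained <- list(mk_entry("tavg_c", covariate = a, aicc = 0),
                   mk_entry("swe_mm", covariate = b, aicc = 0))
  rep_ <- select_final_models(retained, bt, "resp", "gaussian", site = "low")

  # oracle: enumerate the three subsets directly
  X <- cbind(av = unname(a[as.character(year)]), sw = unname(b[as.character(year)]))
  fits <- list(fit_gaussian_lm(y, cbind(intercept = 1, X[, 1, drop = FALSE])),
               fit_gaussian_lm(y, cbind(intercept = 1, X[, 2, drop = FALSE])),
               fit_gaussian_lm(y, cbind(intercept = 1, X)))
  aiccs <- vapply(fits, `[[`, numeric(1), "aicc")
  expected_n <- sum(aiccs <= min(aiccs) + 2)
  expect_length(rep_$models, expected_n)
  got <- vapply(rep_$models, function(m) m$fit$aicc, numeric(1))
  expect_equal(got, sort(aiccs[aiccs <= min(aiccs) + 2]), tolerance = 1e-9)
  expect_false(is.unsorted(got))
  expect_true(all(vapply(rep_$models, function(m)
    all(m$variables %in% rep_$retained_variables), logical(1))))
  expect_equal(dim(rep_$correlation_matrix), c(2, 2))

  # single retained variable -> that model reported
  r1 <- select_final_models(retained[1], bt, "resp", "gaussian", site = "low")
  expect_length(r1$models, 1)
  expect_equal(r1$models[[1]]$variables, "tavg_c")

  # empty retained set -> empty report
  r0 <- select_final_models(list(), bt, "resp", "gaussian", site = "low")
  expect_length(r0$models, 0)
  expect_equal(nrow(as.data.frame(r0)), 0)
})

test_that("the selection stages are idempotent on their own output", {
  yrs <- as.character(2013:2022)
  set.seed(81)
  e <- list(mk_entry("tavg_c", open = 200L, close = 240L, aicc = 100,
                     covariate = setNames(rnorm(10), yrs)),
            mk_entry("swe_mm", open = 50L, close = 90L, aicc = 98,
                     covariate = setNames(rnorm(10), yrs)))
  while (abs(cor(e[[1]]$covariate, e[[2]]$covariate)) >= 0.5) {
    e[[2]]$covariate <- setNames(rnorm(10), yrs)
  }
  once <- prune_collinear(dedupe_similar_variables(screen_candidates(e)))
  twice <- prune_collinear(dedupe_similar_variables(screen_candidates(once)))
  expect_identical(once, twice)
})

test_that("across-year variation test has the factor df and detects planted year effects", {
  # identical per-year response distributions -> no year signal
  y0 <- rep(c(128, 130, 132, 135), times = 5)
  bt0 <- toy_breeding(rep(2013:2017, each = 4), y0)
  t0 <- across_year_test(bt0, "first_egg_date", "gaussian")
  expect_equal(t0$df, 4)
  expect_lt(t0$chisq, 1e-8)
  expect_equal(t0$p, 1, tolerance = 1e-6)

  # planted year effects at study-scale n
  set.seed(91)
  yrs <- rep(2013:2022, each = 40)
  eff <- rnorm(10, 0, 6)[match(yrs, 2013:2022)]
  bt1 <- toy_breeding(yrs, round(130 + eff + rnorm(length(yrs), 0, 5)))
  t1 <- across_year_test(bt1, "first_egg_date", "gaussian")
  expect_lt(t1$p, 0.001)
  expect_equal(t1$df, 9)

  # count response goes through the genpois family
  set.seed(92)
  btc <- toy_breeding(rep(2013:2016, each = 25),
                      rpois(100, rep(c(4, 6, 5, 7), each = 25)),
                      response = "clutch_size")
  tc <- across_year_test(btc, "clutch_size", "genpois")
  expect_equal(tc$df, 3)
  expect_lt(tc$p, 0.01)
})

test_that("linear trend test recovers exact trends and holds its size", {
  flat <- suppressWarnings(linear_trend_test(rep(5, 10), 2013:2022))
  expect_equal(flat$slope, 0)
  exact <- suppressWarnings(linear_trend_test(2 + 0.5 * (2013:2022), 2013:2022))
  expect_equal(exact$slope, 0.5, tolerance = 1e-10)
  expect_lt(exact$p, 1e-10)

  set.seed(101)
  rej <- mean(replicate(500, linear_trend_test(rnorm(10), 2013:2022)$p < 0.05))
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.09)
})
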