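test_that("window enumeration matches the closed form on every span", {
  expect_equal(nrow(enumerate_windows(0, 13)), 1)           # D = 14
  expect_equal(nrow(enumerate_windows(0, 19)), 28)          # D = 20: 7+6+...+1
  for (D in 14:60) {
    w <- enumerate_windows(0, D - 1)
    expect_equal(nrow(w), (D - 13) * (D - 12) / 2)
    expect_true(all(w$duration >= 14))
    expect_false(anyDuplicated(paste(w$open, w$close)) > 0)
  }
  # full autumn-to-3-May span (non-leap): offsets 0..244
  expect_equal(nrow(enumerate_windows(0, 244)), 27028)
  expect_error(enumerate_windows(0, 10), "shorter")
})

test_that("reference dates follow the earliest first egg date plus the stage offsets", {
  bt <- toy_breeding(rep(2013:2015, each = 4),
                     c(130, 125, 128, 131, 123, 126, 129, 135, 140, 124, 127, 133))
  r <- reference_date("first_egg_date", "low", bt)
  expect_equal(r$doy, 123)                      # earliest = 3 May
  expect_equal(r$offset, 121 + 123)             # 1 Sept anchor offset
  expect_equal(reference_date("clutch_size", "low", bt)$doy, 123 + 9)
  expect_equal(reference_date("brood_size", "low", bt)$doy, 123 + 40)
  expect_equal(reference_date("mean_mass_g", "low", bt)$doy, 123 + 40)
  expect_error(reference_date("first_egg_date", "high", bt), "no breeding records")
})

test_that("window covariates are per-season means that attach autumn to the following spring", {
  # constant series -> covariate equals the constant in every year
  n <- as.integer(as.Date("2015-08-31") - as.Date("2012-09-01")) + 1L
  s <- toy_climate(rep(3.5, n))
  wc <- window_covariate(s, "tavg_c", list(open = 10, close = 40), 2013:2015)
  expect_equal(as.numeric(wc), rep(3.5, 3))

  # values 1..14 in the first 14 days of the 2013 season -> mean 7.5
  v <- rep(0, n); v[1:14] <- 1:14
  wc2 <- window_covariate(toy_climate(v), "tavg_c", list(open = 0, close = 13),
                          2013:2015)
  expect_equal(as.numeric(wc2), c(7.5, 0, 0))

  # an autumn window (14 Oct-4 Dec = offsets 43..94) reads autumn-2012
  # values for breeding year 2013
  d <- seq(as.Date("2012-09-01"), as.Date("2013-08-31"), by = "day")
  v3 <- as.numeric(d >= as.Date("2012-10-14") & d <= as.Date("2012-12-04"))
  wc3 <- window_covariate(toy_climate(v3), "tavg_c", list(open = 43, close = 94),
                          2013)
  expect_equal(as.numeric(wc3), 1)

  # missing days: below the completeness floor the value is dropped
  v4 <- rep(1, n); v4[1:8] <- NA
  wc4 <- window_covariate(toy_climate(v4), "tavg_c", list(open = 0, close = 13),
                          2013, completeness_floor = 0.8)
  expect_true(is.na(wc4[1]))
  expect_equal(attr(wc4, "completeness")[1], 6 / 14)
  wc5 <- window_covariate(toy_climate(v4), "tavg_c", list(open = 0, close = 13),
                          2013, completeness_floor = 0.4)
  expect_equal(as.numeric(wc5[1]), 1)   # mean over the present days only
})

test_that("the sliding-window search is deterministic and its fast path equals the full fit", {
  d <- make_planted(3, years = 6, nests = 12)
  a <- run_sliding_window(d$bt, d$cl, "tmax_c", "first_egg_date", "gaussian",
                          site = "low", stride = 7)
  b <- run_sliding_window(d$bt, d$cl, "tmax_c", "first_egg_date", "gaussian",
                          site = "low", stride = 7)
  expect_identical(a$all_fits, b$all_fits)

  # chosen window refit through fit_gaussian_lm agrees exactly with the
  # vectorised sufficient-statistics engine
  row <- a$all_fits[1, ]
  expect_equal(a$chosen$fit$coefficients$estimate[2], row$estimate, tolerance = 1e-9)
  expect_equal(a$chosen$fit$coefficients$se[2], row$se, tolerance = 1e-9)
  expect_equal(a$chosen$fit$aicc, row$aicc, tolerance = 1e-9)
  expect_equal(a$chosen$null_fit$aicc, row$null_aicc, tolerance = 1e-9)

  # with complete climate data the null AICc is common to all windows
  expect_lt(diff(range(a$all_fits$null_aicc)), 1e-9)
  # all_fits is sorted ascending by delta AICc and top_set is within 2
  expect_false(is.unsorted(a$all_fits$delta_aicc))
  expect_true(all(a$top_set$delta_aicc <= min(a$all_fits$delta_aicc) + 2))
  expect_gte(nrow(a$top_set), 1)
})

test_that("search preconditions are enforced", {
  d <- make_planted(5, years = 6, nests = 12)
  one_year <- d$bt[d$bt$year == 2013, ]
  expect_error(run_sliding_window(one_year, d$cl, "tmax_c", "first_egg_date",
                                  "gaussian", site = "low"), "2 distinct years")
  tiny <- d$bt[c(1:5, 13:16), ]   # two years, nine nests
  expect_error(run_sliding_window(tiny, d$cl, "tmax_c", "first_egg_date",
                                  "gaussian", site = "low"), "10 non-missing")
})

test_that("overlap collapsing keeps the best of each overlapping group and all disjoint equivalents", {
  mk_cands <- function(df) {
    df$duration <- df$close - df$open + 1L
    df$label <- nestwin:::window_label(df$open, df$close)
    structure(list(all_fits = df[order(df$delta_aicc), ],
                   settings = list()), class = "candidate_set")
  }
  # two near-identical windows (J = 52/53) and one disjoint, all within 2
  df <- data.frame(open = c(43L, 43L, 150L), close = c(94L, 95L, 170L),
                   delta_aicc = c(-10, -9.5, -9.2), estimate = 1,
                   se = 1, statistic = 1, n = 100, aicc = 0, null_aicc = 10)
  cc <- collapse_equivalent_windows(mk_cands(df))
  expect_equal(nrow(cc$top_set), 2)
  expect_equal(cc$chosen_row$open, 43L)
  expect_equal(cc$chosen_row$close, 94L)       # lowest delta of its group
  expect_equal(cc$top_set$n_equivalent, c(2L, 1L))
  expect_equal(nrow(cc$top_set_full), 3)

  # single-member top set is unchanged
  df1 <- df[1, ]
  c1 <- collapse_equivalent_windows(mk_cands(df1))
  expect_equal(nrow(c1$top_set), 1)

  # disjoint equal performers are both retained; chosen is the lower delta
  df2 <- data.frame(open = c(10L, 100L), close = c(40L, 130L),
                    delta_aicc = c(-8, -7.5), estimate = 1, se = 1,
                    statistic = 1, n = 100, aicc = 0, null_aicc = 8)
  c2 <- collapse_equivalent_windows(mk_cands(df2))
  expect_equal(nrow(c2$top_set), 2)
  expect_equal(c2$chosen_row$open, 10L)
})

test_that("a genpois search recovers a planted count effect on a reduced grid", {
  yrs <- 2013:2020
  cl <- simulate_climate(synthetic_site_params("high"), years = 8, seed = 9)
  cov <- window_covariate(cl, "tavg_c", list(open = 205, close = 238), yrs)
  truth <- synthetic_truth("high", years = yrs, overrides = list(
    brood_size = list(variable = "tavg_c", window = c(205L, 238L),
                      slope = 1.2 / sd(cov), intercept = 1.5, phi = 0.8)))
  sb <- simulate_breeding(truth, cl, nests_per_year = 30, seed = 10)
  bt <- build_breeding_table(sb$records)
  cs <- run_sliding_window(bt, cl, "tavg_c", "brood_size", "genpois",
                           site = "high", stride = 10)
  expect_lt(cs$chosen$delta_aicc, -2)
  expect_gt(window_jaccard(cs$chosen$window$open, cs$chosen$window$close,
                           205, 238), 0.3)
  expect_equal(cs$chosen$sign, 1)
  expect_s3_class(cs$chosen$fit, "nestwin_fit")
  expect_equal(cs$chosen$fit$family, "genpois")
})

test_that("candidate sets export to delimited text and JSON", {
  d <- make_planted(8, years = 6, nests = 12)
  cs <- run_sliding_window(d$bt, d$cl, "tmax_c", "first_egg_date", "gaussian",
                           site = "low", stride = 14)
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  export_candidate_set(cs, csv, js)
  tab <- read.csv(csv)
  expect_equal(nrow(tab), nrow(cs$all_fits))
  j <- jsonlite::read_json(js)
  expect_equal(j$n_windows, nrow(cs$all_fits))
  expect_equal(j$chosen$delta_aicc, cs$chosen$delta_aicc, tolerance = 1e-12)
})
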