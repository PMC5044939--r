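tab1_maize <- hannover_yields("maize")
tab1_wheat <- hannover_yields("winter_wheat")

test_that("percent error matches the reported per-year values", {
  # reported values carry one printed decimal; compare at that precision
  expect_equal(percent_error(482.9, 753.1), 55.9, tolerance = 0.1 / 55.9)
  expect_lt(abs(percent_error(414.2, 418.0) - 0.9), 0.05)
  expect_equal(percent_error(100, 100), 0)
  expect_error(percent_error(0, 10), "positive")
})

test_that("the adjustment factor is the ratio of series means", {
  expect_equal(adjustment_factor(c(1, 2), c(1, 2)), 1)
  expect_equal(adjustment_factor(c(2, 4), c(4, 8)), 0.5)
  expect_error(adjustment_factor(1:3, 1:2), "equal length")
  expect_error(adjustment_factor(1, 1), "at least 2")
  # the maize comparison series gives the reported 0.72 at two decimals
  f <- adjustment_factor(tab1_maize$observed, tab1_maize$predicted)
  expect_equal(round(f, 2), 0.72)
  f_w <- adjustment_factor(tab1_wheat$observed, tab1_wheat$predicted)
  expect_lt(abs(f_w - 0.80), 0.01)
})

test_that("applying the factor reproduces the reported adjusted yields", {
  expect_lt(abs(apply_adjustment(753.1, 0.72) - 542.2), 0.05)
  expect_lt(abs(apply_adjustment(794.2, 0.72) - 571.8), 0.05)
  expect_equal(apply_adjustment(123.4, 1), 123.4)
  expect_error(apply_adjustment(1, 0), "positive")
})

test_that("rmse and the overall percent error have their closed forms", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(25 / 2))
  expect_equal(rmse(5, 7), 2)   # single pair: absolute difference
  expect_error(rmse(1:2, 1:3), "equal length")
  expect_equal(overall_percent_error(42.9, 445.1), 9.638, tolerance = 1e-3)
  expect_equal(overall_percent_error(0, 10), 0)
  expect_equal(overall_percent_error(10, 100), 10)
  expect_error(overall_percent_error(1, 0), "positive")
})

test_that("the Willmott index reproduces hand-computed cases and its bounds", {
  expect_equal(willmott_index(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(willmott_index(c(1, 2, 3), c(3, 2, 1)), 0)   # 8/8
  expect_equal(willmott_index(c(1, 2, 3), c(1, 2, 4)), 12 / 13)
  expect_equal(willmott_index(c(2, 2), c(2, 2)), 1)   # degenerate: perfect
  # bounded in [0, 1] under fuzzing
  withr::with_seed(123, {
    for (i in 1:200) {
      o <- stats::rnorm(sample(2:20, 1), sd = sample(c(0.1, 1, 50), 1))
      p <- o + stats::rnorm(length(o), sd = sample(c(0, 0.5, 10), 1))
      d <- willmott_index(o, p)
      expect_true(d >= 0 && d <= 1)
    }
  })
})

test_that("correlation is invariant under positive scaling and adjustment", {
  r <- pearson_r(1:10, (1:10)^2)
  withr::with_seed(5, {
    o <- stats::rnorm(20, 50, 10)
    p <- o + stats::rnorm(20, 0, 5)
    base <- pearson_r(o, p)$r
    for (k in c(0.72, 0.8, 3.7)) {
      expect_equal(pearson_r(o, apply_adjustment(p, k))$r, base,
                   tolerance = 1e-12)
    }
  })
  expect_equal(pearson_r(1:5, 1:5)$r, 1)
  expect_equal(pearson_r(1:5, 5:1)$r, -1)
  expect_error(pearson_r(c(1, 1, 1), 1:3), "zero-variance")
})

test_that("the comparison-series correlations match the reported levels", {
  r_m <- pearson_r(tab1_maize$observed, tab1_maize$predicted)
  r_w <- pearson_r(tab1_wheat$observed, tab1_wheat$predicted)
  expect_lt(abs(r_m$r - 0.75), 0.02)
  expect_lt(abs(r_w$r - 0.60), 0.02)
  expect_lt(r_m$p_value, 0.01)
  expect_lt(r_w$p_value, 0.01)
})

test_that("mean adjusted equals mean observed under the full-precision factor", {
  o <- tab1_maize$observed
  p <- tab1_maize$predicted
  f <- adjustment_factor(o, p)
  expect_equal(mean(apply_adjustment(p, f)), mean(o), tolerance = 1e-12)
  # with a rounded factor the residual is mean(pred) times the rounding delta
  f2 <- round(f, 2)
  expect_equal(mean(apply_adjustment(p, f2)) - mean(o),
               mean(p) * (f2 - f), tolerance = 1e-9)
})

test_that("the report assembles rows and footer consistently", {
  rep <- build_validation_report(tab1_maize$observed, tab1_maize$predicted,
                                 years = tab1_maize$year, crop = "maize")
  expect_s3_class(rep, "validation_report")
  expect_equal(nrow(rep$rows), 27)
  expect_equal(rep$mean_adjusted, rep$mean_obs, tolerance = 1e-12)
  expect_equal(rep$pearson_r,
               pearson_r(tab1_maize$observed, tab1_maize$predicted)$r)
  expect_output(print(rep), "Factor adjust")

  # fixed-factor mode uses the supplied factor verbatim
  repf <- build_validation_report(tab1_maize$observed, tab1_maize$predicted,
                                  factor_mode = "fixed", factor = 0.72)
  expect_equal(repf$rows$adjusted, tab1_maize$predicted * 0.72)

  # degenerate constant series: factor 1, rmse 0, d 1
  const <- build_validation_report(rep(5, 6), rep(5, 6))
  expect_equal(const$factor, 1)
  expect_equal(const$rmse, 0)
  expect_equal(const$willmott_d, 1)
})

test_that("a planted field-vs-trial gap is recovered by the computed factor", {
  withr::with_seed(11, {
    pred <- stats::runif(27, 400, 700)
    obs <- 0.75 * pred * exp(stats::rnorm(27, 0, 0.02))
    rep <- build_validation_report(obs, pred)
    expect_lt(abs(rep$factor - 0.75), 0.01)
  })
})

test_that("soil-quality pre-filters drop the units a crop is not grown on", {
  sim <- tidyr::crossing(crop = c("maize", "winter_wheat", "cup_plant"),
                         nfk_class = c(50, 90, 140, 200)) |>
    dplyr::mutate(dm_yield = 10)
  out <- filter_validation_units(sim)
  expect_equal(sort(out$nfk_class[out$crop == "winter_wheat"]), c(140, 200))
  expect_equal(sort(out$nfk_class[out$crop == "maize"]), c(50, 90, 140, 200))
  expect_equal(sum(out$crop == "cup_plant"), 4)   # no rule: untouched
})
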