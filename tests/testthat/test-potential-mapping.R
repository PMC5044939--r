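test_that("period averaging is a plain group mean", {
  sim <- tibble::tibble(
    soil_type = "L", nfk_class = 200, climate_region = "R1", crop = "maize",
    year = c(1990, 1991, 1992), dm_yield = c(10, 12, 18)
  )
  out <- average_over_period(sim, 1991:1992)
  expect_equal(out$mean_dm_yield, 15)
  expect_equal(out$n_years, 2)
  expect_message(average_over_period(sim, 1980), "no simulated years")
  expect_error(average_over_period(sim, integer(0)), "non-empty")
})

test_that("period averaging matches an independent group-by re-mean", {
  mp <- average_over_period(dplyr::filter(fix_sim, crop == "maize"),
                            1991:2007)
  sub <- dplyr::filter(fix_sim, crop == "maize", year %in% 1991:2007)
  key <- paste(sub$soil_type, sub$nfk_class, sub$climate_region)
  ora <- tapply(sub$dm_yield, key, mean)
  expect_equal(
    as.vector(ora[paste(mp$soil_type, mp$nfk_class, mp$climate_region)]),
    mp$mean_dm_yield
  )
})

test_that("yield-curve fitting interpolates exactly through three points", {
  # collinear: the quadratic term vanishes and the line is exact
  lin <- fit_yield_curve(c(50, 100, 150), c(5, 10, 15))
  expect_equal(lin$coefficients[3], 0, tolerance = 1e-8)
  expect_equal(interpolate_yield(lin, c(50, 125, 150)), c(5, 12.5, 15),
               tolerance = 1e-8)
  # points from a known quadratic are recovered exactly
  f <- function(x) 2 + 0.1 * x - 2e-4 * x^2
  quad <- fit_yield_curve(c(60, 140, 260), f(c(60, 140, 260)))
  expect_equal(quad$coefficients, c(2, 0.1, -2e-4), tolerance = 1e-8)
  expect_equal(interpolate_yield(quad, 200), f(200), tolerance = 1e-8)
})

test_that("yield-curve fitting validates its inputs", {
  expect_error(fit_yield_curve(c(50, 100), c(5, 10)), "at least 3")
  expect_error(fit_yield_curve(c(50, 50, 100), c(5, 6, 10)), "duplicate")
})

test_that("a loam-like response (strong gain then decline) fits concave", {
  # strong gains between 100 and 150 mm, declining gains beyond
  curve <- fit_yield_curve(c(100, 150, 200, 250, 300),
                           c(10, 15, 17.5, 19, 19.5))
  expect_lt(curve$coefficients[3], 0)   # negative quadratic term
  mid <- interpolate_yield(curve, 175)
  expect_gt(mid, 15)
  expect_lt(mid, 19)
})

test_that("interpolation clamps to the fitted domain and stays continuous", {
  curve <- fit_yield_curve(c(100, 150, 200), c(10, 15, 17))
  expect_equal(interpolate_yield(curve, 50), interpolate_yield(curve, 100))
  expect_equal(interpolate_yield(curve, 400), interpolate_yield(curve, 200))
  eps <- 1e-6
  expect_equal(interpolate_yield(curve, 100 - eps),
               interpolate_yield(curve, 100 + eps), tolerance = 1e-4)
  # negative values are floored at zero with a warning
  neg <- fit_yield_curve(c(10, 20, 30), c(-2, -1, 1))
  expect_warning(v <- interpolate_yield(neg, 10), "floored")
  expect_equal(v, 0)
})

test_that("curves are fitted per crop, soil type and region group", {
  mp <- average_over_period(fix_sim, 1991:2007)
  curves <- fit_yield_curves(mp)
  # 8 types x 5 regions x 4 crops
  expect_equal(nrow(curves), 160)
  expect_s3_class(curves$curve[[1]], "yield_curve")
})

test_that("the soil-map join preserves cardinality and flags bad records", {
  mp <- average_over_period(fix_sim, 1991:2007)
  curves <- fit_yield_curves(mp)
  soil_map <- dplyr::bind_rows(
    gen_soil_map(fix_cfg)[1:50, ],
    tibble::tibble(unit_id = "bad1", soil_type = "??", soil_number = 50,
                   climate_region = "R1", x = 1, y = 1)
  )
  out <- join_potentials(soil_map, curves)
  expect_equal(nrow(out), nrow(soil_map))
  expect_true(all(!is.na(out$potential_maize[out$soil_type != "??"])))
  expect_equal(out$reason[out$unit_id == "bad1"], "unknown_soil_type")
  expect_true(is.na(out$potential_maize[out$unit_id == "bad1"]))

  empty <- join_potentials(soil_map[0, ], curves)
  expect_equal(nrow(empty), 0)

  # strict mode rejects a map with too many unresolvable records
  many_bad <- dplyr::mutate(soil_map, soil_type = "??")
  expect_error(join_potentials(many_bad, curves, strict = TRUE),
               "unresolvable")
})

test_that("band classification uses half-open lower-inclusive bands", {
  expect_equal(as.character(classify_band(11.9)), "<12")
  expect_equal(as.character(classify_band(12.0)), "12-14")
  expect_equal(as.character(classify_band(16.5)), "16-17")
  expect_equal(as.character(classify_band(19)), ">=19")
  expect_equal(as.character(classify_band(c(13, 17))), c("12-14", "17-19"))
  expect_error(classify_band(10, edges = c(12, 12)), "strictly increasing")
})
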