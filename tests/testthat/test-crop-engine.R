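test_that("data-unit construction reproduces the aggregation cardinality", {
  units <- build_data_units(regions = paste0("R", 1:5))
  expect_equal(nrow(units), 175)   # 35 class pairs x 5 regions
  expect_equal(nrow(dplyr::distinct(units)), 175)

  expect_equal(nrow(build_data_units(list(S = c(50, 90, 140)), "R1")), 3)
  sel <- list(S = c(50, 90, 140), C = c(50, 90, 140, 200))
  expect_equal(nrow(build_data_units(sel, c("R1", "R2"))), 14)
})

test_that("data-unit construction validates the class selection", {
  expect_error(build_data_units(list(S = c(50, 90, 200)), "R1"),
               "not in the reference table")
  expect_error(build_data_units(list(S = c(50, 90)), "R1"), "3 to 5")
  expect_error(build_data_units(list(L = nfk_classes("L")[1:6]), "R1"),
               "3 to 5")
})

test_that("yield is zero when the whole season stays at or below base temperature", {
  maize <- fix_crops$maize
  cold <- dplyr::mutate(fix_season_climate, t_mean = maize$temp_base - 1)
  expect_equal(simulate_yield(maize, cold, nfk = 200), 0)
})

test_that("the unlimited-water, optimal-temperature yield has its closed form", {
  maize <- fix_crops$maize
  lush <- dplyr::mutate(fix_season_climate, t_mean = maize$temp_optimum,
                        precip_sum = 1e6)
  expect_equal(simulate_yield(maize, lush, nfk = 200),
               maize$harvest_index * maize$max_monthly_growth *
                 length(maize$season))
})

test_that("the engine matches an independent re-implementation of the update rule", {
  # straight-line re-implementation of the monthly bucket rule
  oracle <- function(crop, t_mean, precip, nfk, k = 5.5) {
    W <- nfk
    total <- 0
    for (i in seq_along(t_mean)) {
      W <- min(nfk, W + precip[i])
      D <- crop$crop_coefficient * max(0, k * t_mean[i])
      f <- min(1, max(0, (t_mean[i] - crop$temp_base) /
                        (crop$temp_optimum - crop$temp_base)))
      s <- if (D > 0) min(1, W / D) else 1
      total <- total + crop$max_monthly_growth * f * s
      W <- max(0, W - D)
    }
    min(crop$harvest_index * total, crop$yield_ceiling)
  }
  for (crop_name in names(fix_crops)) {
    crop <- fix_crops[[crop_name]]
    cal <- yieldscape:::season_calendar(crop$season)
    idx <- match(cal$month, fix_season_climate$month)
    t_mean <- fix_season_climate$t_mean[idx]
    precip <- fix_season_climate$precip_sum[idx]
    for (nfk in c(50, 90, 140, 200, 300)) {
      expect_identical(simulate_yield(crop, fix_season_climate, nfk),
                       oracle(crop, t_mean, precip, nfk))
    }
  }
})

test_that("vectorized and scalar engines agree bit for bit", {
  crop <- fix_crops$maize
  cal <- yieldscape:::season_calendar(crop$season)
  idx <- match(cal$month, fix_season_climate$month)
  nfk <- seq(50, 300, by = 10)
  vec <- yieldscape:::simulate_yield_vec(
    crop, fix_season_climate$t_mean[idx], fix_season_climate$precip_sum[idx],
    nfk)
  sca <- vapply(nfk, function(v) simulate_yield(crop, fix_season_climate, v),
                0)
  expect_identical(vec, sca)
})

test_that("yield is non-decreasing and saturating in water capacity", {
  for (crop_name in c("maize", "triticale")) {
    crop <- fix_crops[[crop_name]]
    y <- vapply(50:300, function(v) simulate_yield(crop, fix_season_climate, v),
                0)
    expect_true(all(diff(y) >= -1e-12))
    # saturation: the top of the range is flat
    expect_equal(y[251], y[201])
  }
})

test_that("the engine is deterministic", {
  a <- simulate_yield(fix_crops$maize, fix_season_climate, 137)
  b <- simulate_yield(fix_crops$maize, fix_season_climate, 137)
  expect_identical(a, b)
})

test_that("season months missing from the climate are an input error", {
  expect_error(
    simulate_yield(fix_crops$maize, fix_season_climate[1:4, ], 200),
    "missing season month"
  )
})

test_that("run_units emits one row per unit, crop and year", {
  expect_equal(nrow(fix_sim), 175 * 4 * 27)
  one_crop <- dplyr::filter(fix_sim, crop == "maize")
  expect_equal(nrow(one_crop), 4725)   # 175 units x 27 years

  small <- run_units(fix_units[1, ], fix_monthly,
                     fix_crops[c("maize", "triticale")], 1990:1991,
                     fix_regions)
  expect_equal(nrow(small), 4)
  empty <- run_units(fix_units[1, ], fix_monthly, fix_crops["maize"],
                     integer(0), fix_regions)
  expect_equal(nrow(empty), 0)
})

test_that("missing climate is skipped with a message, or fatal in strict mode", {
  expect_message(
    out <- run_units(fix_units[1, ], fix_monthly, fix_crops["maize"],
                     c(1990, 2050), fix_regions),
    "missing climate"
  )
  expect_equal(out$year, 1990)
  expect_error(
    suppressMessages(
      run_units(fix_units[1, ], fix_monthly, fix_crops["maize"],
                c(1990, 2050), fix_regions, strict = TRUE)
    ),
    "missing climate"
  )
})

test_that("winter crops draw their autumn months from the previous year", {
  # triticale for the first harvest year needs the spin-up year's autumn
  first_year <- min(fix_cfg$years)
  out <- run_units(fix_units[1, ], fix_monthly, fix_crops["triticale"],
                   first_year, fix_regions)
  expect_equal(nrow(out), 1)
  expect_gt(out$dm_yield, 0)
})

test_that("the C4 crop out-yields the C3 crops in a warm, watered season", {
  warm <- dplyr::mutate(fix_season_climate,
                        t_mean = t_mean + ifelse(month %in% 4:10, 4, 0),
                        precip_sum = 500)
  yields <- vapply(fix_crops, simulate_yield, 0, climate = warm, nfk = 250)
  expect_gt(yields[["maize"]], yields[["winter_wheat"]])
  expect_gt(yields[["maize"]], yields[["triticale"]])
  expect_gt(yields[["maize"]], yields[["cup_plant"]])
})

test_that("triticale's yield spread across sandy nFK classes is narrower than maize's", {
  sandy <- dplyr::filter(fix_sim, soil_type %in% c("S", "Sl"),
                         crop %in% c("maize", "triticale")) |>
    dplyr::group_by(crop, nfk_class) |>
    dplyr::summarise(m = mean(dm_yield), .groups = "drop") |>
    dplyr::group_by(crop) |>
    dplyr::summarise(spread = max(m) - min(m))
  expect_lt(sandy$spread[sandy$crop == "triticale"],
            sandy$spread[sandy$crop == "maize"])
})
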