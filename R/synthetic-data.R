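#' Configuration of the synthetic region generator
#'
#' Bundles the study conditions the generators emulate: a soil map with a
#' sandy north and a loamy south, daily weather for five stations over the
#' 1981-2007 analysis years, and observed yield statistics embedding a known
#' multiplicative field-vs-trial gap and a pre-2000 linear breeding trend.
#'
#' @param seed Integer seed; all generators are pure functions of the
#'   configuration.
#' @param n_units Number of soil-map records (default 5,000; the full-scale
#'   preset of the emulated region is 114,357).
#' @param n_stations Number of climate stations / regions (default 5).
#' @param years Harvest years (default 1981:2007).
#' @param gap_factor Multiplicative field-vs-trial yield gap planted into
#'   the observed series (default 0.75).
#' @param trend_slope Breeding-trend slope planted into the winter-cereal
#'   observed series, dt/ha per year before the pivot (default 0.9).
#' @param trend_pivot Pivot year of the planted trend (default 2000).
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   year-to-year noise (default 0.07).
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1, n_units = 5000, n_stations = 5,
                             years = 1981:2007, gap_factor = 0.75,
                             trend_slope = 0.9, trend_pivot = 2000,
                             noise_cv = 0.07) {
  stopifnot(gap_factor > 0, gap_factor <= 1, noise_cv >= 0, n_units >= 1,
            n_stations >= 1, length(years) >= 1)
  structure(
    list(seed = as.integer(seed), n_units = n_units, n_stations = n_stations,
         years = years, gap_factor = gap_factor, trend_slope = trend_slope,
         trend_pivot = trend_pivot, noise_cv = noise_cv),
    class = "synthetic_config"
  )
}

#' Climate regions of the synthetic study area
#'
#' Five vertical bands across a 100 x 100 planar study area, each
#' represented by one station at the band centre.
#'
#' @param config A [synthetic_config()].
#' @return Tibble with `region_id`, `station_id`, rectangle bounds and
#'   centroid columns.
#' @export
synthetic_regions <- function(config = synthetic_config()) {
  k <- config$n_stations
  width <- 100 / k
  tibble::tibble(
    region_id = paste0("R", seq_len(k)),
    station_id = sprintf("ST%02d", seq_len(k)),
    xmin = (seq_len(k) - 1) * width,
    xmax = seq_len(k) * width,
    ymin = 0, ymax = 100,
    cx = (seq_len(k) - 0.5) * width,
    cy = 50
  )
}

# type mixtures of the north-south soil gradient; soil numbers drawn
# uniformly within per-type quality spans
.soil_mix_north <- c(S = 0.35, Sl = 0.25, lS = 0.20, SL = 0.08,
                     sL = 0.05, L = 0.03, LC = 0.02, C = 0.02)
.soil_mix_south <- c(S = 0.03, Sl = 0.05, lS = 0.07, SL = 0.10,
                     sL = 0.25, L = 0.30, LC = 0.12, C = 0.08)
.soil_number_span <- list(S = c(7, 35), Sl = c(10, 45), lS = c(12, 60),
                          SL = c(15, 75), sL = c(20, 85), L = c(25, 95),
                          LC = c(20, 80), C = c(15, 65))

#' Generate the synthetic soil map
#'
#' Random soil-evaluation records over the study area with a
#' latitude-dependent texture mixture (north of y = 50 mostly sands, south
#' mostly loams), soil numbers drawn per type within its quality span, and
#' climate regions assigned from the region bands.
#'
#' @param config A [synthetic_config()].
#' @return Tibble with `unit_id`, `soil_type`, `soil_number`,
#'   `climate_region`, `x`, `y`.
#' @export
gen_soil_map <- function(config = synthetic_config()) {
  regions <- synthetic_regions(config)
  withr::with_seed(config$seed + 101L, {
    n <- config$n_units
    x <- stats::runif(n, 0, 100)
    y <- stats::runif(n, 0, 100)
    north <- y > 50
    soil_type <- character(n)
    soil_type[north] <- sample(names(.soil_mix_north), sum(north),
                               replace = TRUE, prob = .soil_mix_north)
    soil_type[!north] <- sample(names(.soil_mix_south), sum(!north),
                                replace = TRUE, prob = .soil_mix_south)
    soil_number <- vapply(soil_type, function(st) {
      span <- .soil_number_span[[st]]
      sample(span[1]:span[2], 1)
    }, 0L)
    units <- tibble::tibble(
      unit_id = sprintf("U%06d", seq_len(n)),
      soil_type = soil_type,
      soil_number = unname(soil_number),
      x = x, y = y
    )
    assign_climate_region(units, regions)
  })
}

# Hannover-like monthly normals used by the weather generator
.monthly_normal_temp <- c(0.9, 1.4, 4.4, 8.4, 13.0, 15.9, 17.8, 17.4,
                          13.9, 9.6, 4.9, 1.9)
.monthly_normal_precip <- c(51, 39, 51, 45, 56, 65, 67, 62, 51, 48, 52, 58)

#' Generate daily climate for all synthetic stations
#'
#' Seeded daily weather per station: temperatures follow the monthly normal
#' cycle of a temperate maritime lowland plus Gaussian day-to-day noise and
#' a small fixed station offset; precipitation is an intermittent gamma
#' process whose monthly expectations equal the normals (May 56 mm, June
#' 65 mm, July 67 mm). One spin-up calendar year before the first harvest
#' year is included so winter-crop seasons of the first year are covered.
#'
#' @param config A [synthetic_config()].
#' @return Tibble of daily records: `station_id`, `date`, `t_mean`,
#'   `t_min`, `t_max`, `precip`.
#' @export
gen_daily_climate <- function(config = synthetic_config()) {
  years <- (min(config$years) - 1):max(config$years)
  dates <- seq(as.Date(paste0(min(years), "-01-01")),
               as.Date(paste0(max(years), "-12-31")), by = "day")
  month <- as.integer(format(dates, "%m"))
  ndays_in_month <- days_in_month(as.integer(format(dates, "%Y")), month)
  stations <- sprintf("ST%02d", seq_len(config$n_stations))
  offsets <- seq(-0.6, 0.6, length.out = config$n_stations)
  p_wet <- 0.5
  shape <- 0.8
  withr::with_seed(config$seed + 202L, {
    recs <- lapply(seq_along(stations), function(s) {
      n <- length(dates)
      t_mean <- .monthly_normal_temp[month] + offsets[s] +
        stats::rnorm(n, 0, 2.5)
      wet <- stats::rbinom(n, 1, p_wet)
      scale <- .monthly_normal_precip[month] / (ndays_in_month * p_wet * shape)
      precip <- wet * stats::rgamma(n, shape = shape, scale = scale)
      tibble::tibble(
        station_id = stations[s],
        date = dates,
        t_mean = t_mean,
        t_min = t_mean - stats::runif(n, 2, 6),
        t_max = t_mean + stats::runif(n, 2, 6),
        precip = precip
      )
    })
    dplyr::bind_rows(recs)
  })
}

#' Generate observed regional yield statistics
#'
#' Builds observed series from predicted regional means under the
#' generator's data-generating assumption: regional statistics are the
#' trial-level potential times the field-vs-trial gap, minus a breeding
#' trend for winter cereals in pre-pivot years, times multiplicative
#' lognormal noise (mean 1, coefficient of variation `noise_cv`).
#'
#' @param config A [synthetic_config()].
#' @param predicted Tibble with `crop`, `year`, `predicted` (regional mean
#'   predictions in statistics units, e.g. from
#'   [predicted_statistics_series()]).
#' @param trend_crops Crops receiving the planted breeding trend (default
#'   `"winter_wheat"`).
#' @return Tibble with `crop`, `year`, `observed`.
#' @export
gen_observed_yields <- function(config, predicted,
                                trend_crops = "winter_wheat") {
  stopifnot(all(c("crop", "year", "predicted") %in% names(predicted)))
  sdlog <- sqrt(log(1 + config$noise_cv^2))
  withr::with_seed(config$seed + 303L, {
    noise <- if (sdlog > 0) {
      exp(stats::rnorm(nrow(predicted), -sdlog^2 / 2, sdlog))
    } else {
      rep(1, nrow(predicted))
    }
    trend <- ifelse(
      predicted$crop %in% trend_crops & predicted$year < config$trend_pivot,
      config$trend_slope * (config$trend_pivot - predicted$year), 0
    )
    tibble::tibble(
      crop = predicted$crop,
      year = predicted$year,
      observed = (config$gap_factor * predicted$predicted - trend) * noise
    )
  })
}

#' Regional mean predicted series in statistics units
#'
#' Collapses a simulated-yield table to one predicted value per crop and
#' year: the validation pre-filter is applied, dry-matter yields are
#' averaged over the remaining data units and converted to the crop's
#' statistics unit.
#'
#' @param sim Simulated-yield tibble from [run_units()].
#' @param config A [conversion_config()].
#' @param rules Validation filter rules, see [validation_filter_rules()].
#' @return Tibble with `crop`, `year`, `predicted`.
#' @export
predicted_statistics_series <- function(sim, config = conversion_config(),
                                        rules = validation_filter_rules()) {
  filter_validation_units(sim, rules) |>
    dplyr::group_by(.data$crop, .data$year) |>
    dplyr::summarise(mean_dm = mean(.data$dm_yield), .groups = "drop") |>
    dplyr::rowwise() |>
    dplyr::mutate(predicted = dm_to_statistics(.data$mean_dm, .data$crop,
                                               config)) |>
    dplyr::ungroup() |>
    dplyr::select("crop", "year", "predicted")
}

#' Generate the full synthetic dataset
#'
#' Runs the whole input-generation chain once: soil map, regions, daily and
#' monthly climate, data units, engine runs for the requested crops,
#' regional predicted series, and observed yield statistics for the crops
#' with a statistics analogue.
#'
#' @param config A [synthetic_config()].
#' @param crops Crop names to simulate (default all four shipped crops).
#' @param observed_crops Crops for which observed statistics are generated
#'   (default maize and winter wheat).
#' @return List with elements `config`, `soil_map`, `regions`, `daily`,
#'   `monthly`, `units`, `sim`, `predicted`, `observed`.
#' @export
synthetic_dataset <- function(config = synthetic_config(),
                              crops = c("maize", "winter_wheat", "triticale",
                                        "cup_plant"),
                              observed_crops = c("maize", "winter_wheat")) {
  soil_map <- gen_soil_map(config)
  regions <- synthetic_regions(config)
  daily <- gen_daily_climate(config)
  monthly <- aggregate_daily_to_monthly(daily)
  units <- build_data_units(regions = regions$region_id)
  params <- crop_parameters()[crops]
  sim <- run_units(units, monthly, params, config$years, regions)
  predicted <- predicted_statistics_series(
    dplyr::filter(sim, .data$crop %in% observed_crops))
  observed <- gen_observed_yields(config, predicted)
  list(config = config, soil_map = soil_map, regions = regions, daily = daily,
       monthly = monthly, units = units, sim = sim, predicted = predicted,
       observed = observed)
}
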