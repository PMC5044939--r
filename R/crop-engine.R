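#' Load crop parameter sets
#'
#' Reads the YAML parameter files of the surrogate crop growth engine. The
#' shipped parameter sets (maize, winter wheat, triticale, cup plant) are a
#' transparent stand-in calibration: they are tuned once so that regional
#' mean yields on the synthetic region fall in realistic bands for the
#' crops, and make no claim about any external crop model.
#'
#' @param crop Optional crop name; if `NULL`, all parameter files in `path`
#'   are loaded.
#' @param path Directory of crop YAML files; defaults to the parameter sets
#'   shipped with the package.
#' @return A single `crop_parameters` object, or a named list of them.
#' @export
crop_parameters <- function(crop = NULL, path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "crops", package = "yieldscape",
                        mustWork = TRUE)
  }
  files <- list.files(path, pattern = "\\.ya?ml$", full.names = TRUE)
  if (length(files) == 0) stop("no crop parameter files in ", path,
                               call. = FALSE)
  crops <- lapply(files, function(f) {
    validate_crop_parameters(yaml::read_yaml(f))
  })
  names(crops) <- vapply(crops, `[[`, "", "crop")
  if (is.null(crop)) return(crops)
  if (!crop %in% names(crops)) {
    stop("no parameter file for crop '", crop, "'", call. = FALSE)
  }
  crops[[crop]]
}

validate_crop_parameters <- function(p) {
  required <- c("crop", "pathway", "season", "max_monthly_growth",
                "temp_optimum", "temp_base", "crop_coefficient",
                "harvest_index")
  missing <- setdiff(required, names(p))
  if (length(missing) > 0) {
    stop("crop parameters missing field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  p$season <- as.integer(unlist(p$season))
  if (is.null(p$yield_ceiling)) p$yield_ceiling <- 30
  stopifnot(
    p$pathway %in% c("C3", "C4"),
    length(p$season) > 0, all(p$season %in% 1:12),
    p$harvest_index > 0, p$harvest_index <= 1,
    p$temp_base < p$temp_optimum,
    p$max_monthly_growth > 0, p$crop_coefficient > 0
  )
  # contiguous, allowing one wrap across the year boundary for winter crops
  if (sum(diff(p$season) != 1) > 1) {
    stop("crop season must be contiguous (one year-boundary wrap allowed)",
         call. = FALSE)
  }
  structure(p, class = "crop_parameters")
}

#' @export
print.crop_parameters <- function(x, ...) {
  cat(sprintf(
    "crop '%s' (%s): season months %s, G_max %.2f t DM/ha/month, T_base %.1f C, T_opt %.1f C, kc %.2f, harvest index %.2f\n",
    x$crop, x$pathway, paste(x$season, collapse = ","),
    x$max_monthly_growth, x$temp_base, x$temp_optimum,
    x$crop_coefficient, x$harvest_index
  ))
  invisible(x)
}

# season months as (month, year_offset) pairs: months before the wrap point
# of a winter crop belong to the previous calendar year
season_calendar <- function(season) {
  wrap <- which(diff(season) < 0)
  offset <- rep(0L, length(season))
  if (length(wrap) == 1) offset[seq_len(wrap)] <- -1L
  tibble::tibble(month = season, year_offset = offset)
}

#' Default selection of nFK classes per soil type
#'
#' The aggregation runs the engine for only 3-5 nFK classes per soil type.
#' Which classes compose the canonical 35 is not recorded anywhere, so this
#' default is a documented, configurable guess: all classes for S, Sl, lS
#' and LC, the five highest classes for SL, sL and L, and the three highest
#' for C -- totalling 35.
#'
#' @return Named list: soil type to numeric vector of nFK class values (mm).
#' @export
default_class_selection <- function() {
  list(
    S  = c(50, 90, 140),
    Sl = c(50, 90, 140, 200),
    lS = c(50, 90, 140, 200, 250),
    SL = c(90, 140, 200, 250, 270),
    sL = c(90, 140, 200, 250, 270),
    L  = c(140, 200, 250, 270, 300),
    LC = c(50, 90, 140, 200, 250),
    C  = c(90, 140, 200)
  )
}

#' Build the simulation data units
#'
#' Crosses the selected (soil type, nFK class) pairs with the climate
#' regions; each resulting data unit is simulated once per crop and year in
#' place of the many thousands of individual soil-map records it stands for.
#' The default selection of 35 class pairs times 5 regions yields 175 units.
#'
#' @param class_selection Named list mapping soil type to 3-5 selected nFK
#'   class values, each drawn from the type's reference classes.
#' @param regions Character vector of region ids, or a data frame with a
#'   `region_id` column.
#' @param reference Reference table, see [nfk_reference()].
#' @return Tibble with columns `soil_type`, `nfk_class`, `climate_region`.
#' @examples
#' nrow(build_data_units(regions = paste0("R", 1:5)))  # 175
#' @export
build_data_units <- function(class_selection = default_class_selection(),
                             regions, reference = nfk_reference()) {
  if (is.data.frame(regions)) regions <- regions$region_id
  assert_soil_type(names(class_selection))
  pairs <- lapply(names(class_selection), function(st) {
    classes <- class_selection[[st]]
    if (length(classes) < 3 || length(classes) > 5) {
      stop("class selection for ", st, " must contain 3 to 5 classes",
           call. = FALSE)
    }
    bad <- setdiff(classes, nfk_classes(st, reference))
    if (length(bad) > 0) {
      stop("selected nFK class(es) not in the reference table for ", st, ": ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    tibble::tibble(soil_type = st, nfk_class = classes)
  })
  tidyr::crossing(dplyr::bind_rows(pairs),
                  climate_region = as.character(regions)) |>
    dplyr::arrange(.data$climate_region, .data$soil_type, .data$nfk_class)
}

# temperature response: piecewise linear between base and optimum, 1 above
temperature_response <- function(t_mean, temp_base, temp_optimum) {
  pmin(1, pmax(0, (t_mean - temp_base) / (temp_optimum - temp_base)))
}

# evaporative demand proxy of the surrogate engine, mm/month: linear in
# monthly mean temperature (one bulk coefficient; no radiation/wind terms)
evaporative_demand <- function(t_mean, mm_per_degree = 5.5) {
  pmax(0, mm_per_degree * t_mean)
}

#' Simulate one season's dry-matter yield (surrogate engine)
#'
#' A transparent water- and temperature-limited monthly bucket model. For
#' each season month: the soil water store (capacity `nfk`, starting full)
#' is refilled by the month's precipitation and capped at capacity; crop
#' water demand is `crop_coefficient` times a temperature-linear evaporative
#' demand; growth is `max_monthly_growth` times a piecewise-linear
#' temperature response (0 at/below `temp_base`, 1 at/above `temp_optimum`)
#' times the supply/demand ratio capped at 1. Yield is `harvest_index` times
#' the summed increments, capped at the crop's ceiling. Deterministic for
#' fixed inputs.
#'
#' @param crop A `crop_parameters` object.
#' @param climate Monthly climate rows covering the crop's season, with
#'   columns `month`, `t_mean` and `precip_sum`; rows are matched to the
#'   season months (for winter crops the caller supplies the previous year's
#'   autumn months, see [run_units()]).
#' @param nfk Plant-available field capacity of the unit, mm (> 0).
#' @param demand_mm_per_degree Bulk coefficient of the evaporative-demand
#'   proxy, mm per month per degree C (default 5.5).
#' @return Dry-matter yield in t DM/ha.
#' @export
simulate_yield <- function(crop, climate, nfk, demand_mm_per_degree = 5.5) {
  stopifnot(inherits(crop, "crop_parameters"), nfk > 0)
  cal <- season_calendar(crop$season)
  idx <- match(cal$month, climate$month)
  if (anyNA(idx)) {
    stop("climate is missing season month(s): ",
         paste(cal$month[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  t_mean <- climate$t_mean[idx]
  precip <- climate$precip_sum[idx]
  water <- nfk
  biomass <- 0
  for (m in seq_along(t_mean)) {
    water <- min(nfk, water + precip[m])
    demand <- crop$crop_coefficient *
      evaporative_demand(t_mean[m], demand_mm_per_degree)
    stress <- if (demand > 0) min(1, water / demand) else 1
    f_t <- temperature_response(t_mean[m], crop$temp_base, crop$temp_optimum)
    biomass <- biomass + crop$max_monthly_growth * f_t * stress
    water <- water - min(water, demand)
  }
  min(crop$harvest_index * biomass, crop$yield_ceiling)
}

# vectorized over nfk: same update rule with a vector-valued water store;
# used by run_units for speed, checked against simulate_yield in the tests
simulate_yield_vec <- function(crop, t_mean, precip, nfk,
                               demand_mm_per_degree = 5.5) {
  water <- nfk
  biomass <- numeric(length(nfk))
  for (m in seq_along(t_mean)) {
    water <- pmin(nfk, water + precip[m])
    demand <- crop$crop_coefficient *
      evaporative_demand(t_mean[m], demand_mm_per_degree)
    stress <- if (demand > 0) pmin(1, water / demand) else rep(1, length(nfk))
    f_t <- temperature_response(t_mean[m], crop$temp_base, crop$temp_optimum)
    biomass <- biomass + crop$max_monthly_growth * f_t * stress
    water <- water - pmin(water, demand)
  }
  pmin(crop$harvest_index * biomass, crop$yield_ceiling)
}

#' Run the crop engine over all data units, crops and years
#'
#' Executes [simulate_yield()] for every data unit x crop x harvest year.
#' Winter crops (a season wrapping the year boundary) draw their autumn
#' months from the year before the harvest year. Unit-years whose climate is
#' missing are skipped with a message, or abort the run in strict mode.
#'
#' @param units Data-unit tibble from [build_data_units()].
#' @param monthly Monthly climate tibble (see
#'   [aggregate_daily_to_monthly()]).
#' @param crops List of `crop_parameters` objects.
#' @param years Integer vector of harvest years.
#' @param region_stations Data frame mapping `region_id` to `station_id`
#'   (one station per region).
#' @param strict If `TRUE`, missing climate aborts instead of skipping.
#' @param demand_mm_per_degree Passed to the engine, see [simulate_yield()].
#' @return Tibble with one row per unit x crop x year: columns `soil_type`,
#'   `nfk_class`, `climate_region`, `crop`, `year`, `dm_yield`.
#' @export
run_units <- function(units, monthly, crops, years, region_stations,
                      strict = FALSE, demand_mm_per_degree = 5.5) {
  if (inherits(crops, "crop_parameters")) crops <- list(crops)
  if (is.null(names(crops)) || any(names(crops) == "")) {
    names(crops) <- vapply(crops, `[[`, "", "crop")
  }
  stopifnot(all(c("region_id", "station_id") %in% names(region_stations)))
  key <- paste(monthly$station_id, monthly$year, monthly$month)
  out <- vector("list", 0)
  skipped <- character(0)
  for (region in unique(units$climate_region)) {
    station <- region_stations$station_id[
      match(region, region_stations$region_id)]
    if (is.na(station)) {
      stop("no station mapped to region ", region, call. = FALSE)
    }
    in_region <- units[units$climate_region == region, ]
    for (crop_name in names(crops)) {
      crop <- crops[[crop_name]]
      cal <- season_calendar(crop$season)
      for (yr in years) {
        idx <- match(paste(station, yr + cal$year_offset, cal$month), key)
        if (anyNA(idx)) {
          skipped <- c(skipped, sprintf("%s/%s/%d", region, crop_name, yr))
          next
        }
        dm <- simulate_yield_vec(
          crop, monthly$t_mean[idx], monthly$precip_sum[idx],
          in_region$nfk_class, demand_mm_per_degree
        )
        out[[length(out) + 1]] <- tibble::tibble(
          soil_type = in_region$soil_type,
          nfk_class = in_region$nfk_class,
          climate_region = region,
          crop = crop_name,
          year = yr,
          dm_yield = dm
        )
      }
    }
  }
  if (length(skipped) > 0) {
    msg <- paste0("missing climate for ", length(skipped),
                  " region/crop/year combination(s): ",
                  paste(utils::head(skipped, 5), collapse = ", "),
                  if (length(skipped) > 5) ", ...")
    if (strict) stop(msg, call. = FALSE) else message(msg, "; skipped")
  }
  if (length(out) == 0) {
    return(tibble::tibble(
      soil_type = character(0), nfk_class = numeric(0),
      climate_region = character(0), crop = character(0),
      year = integer(0), dm_yield = numeric(0)
    ))
  }
  dplyr::bind_rows(out)
}
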