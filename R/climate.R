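#' Aggregate daily station climate to monthly values
#'
#' Converts daily station records into the monthly values the crop engine
#' consumes. Temperatures are averaged; precipitation is carried both as the
#' monthly total (`precip_sum`, what the water balance needs) and as the
#' daily mean (`precip_mean`), so either monthly convention is recoverable.
#' Months missing more than `max_missing_days` calendar days are flagged in
#' the `incomplete` column and reported via a message; empty months are
#' simply absent.
#'
#' @param daily Data frame with columns `station_id`, `date` (Date or
#'   ISO-8601 string), `t_mean`, `t_min`, `t_max` (degrees C) and `precip`
#'   (mm/day).
#' @param max_missing_days Missing-day tolerance per month before a month is
#'   flagged (default 5).
#' @return Tibble with one row per station, year and month: `t_mean`,
#'   `t_min`, `t_max`, `precip_sum`, `precip_mean`, `n_days`, `incomplete`.
#' @export
aggregate_daily_to_monthly <- function(daily, max_missing_days = 5) {
  stopifnot(all(c("station_id", "date", "t_mean", "precip") %in% names(daily)))
  daily <- dplyr::mutate(daily, date = as.Date(.data$date))
  if (anyDuplicated(daily[c("station_id", "date")]) > 0) {
    stop("duplicate (station_id, date) records in daily climate input",
         call. = FALSE)
  }
  if (any(daily$precip < 0, na.rm = TRUE)) {
    stop("negative precipitation in daily climate input", call. = FALSE)
  }
  if (all(c("t_min", "t_max") %in% names(daily))) {
    bad <- with(daily, t_min > t_mean | t_mean > t_max)
    if (any(bad, na.rm = TRUE)) {
      warning(sum(bad, na.rm = TRUE),
              " daily records violate t_min <= t_mean <= t_max", call. = FALSE)
    }
  } else {
    daily$t_min <- daily$t_mean
    daily$t_max <- daily$t_mean
  }
  monthly <- daily |>
    dplyr::mutate(
      year = as.integer(format(.data$date, "%Y")),
      month = as.integer(format(.data$date, "%m"))
    ) |>
    dplyr::group_by(.data$station_id, .data$year, .data$month) |>
    dplyr::summarise(
      t_mean = mean(.data$t_mean),
      t_min = mean(.data$t_min),
      t_max = mean(.data$t_max),
      precip_sum = sum(.data$precip),
      precip_mean = mean(.data$precip),
      n_days = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      incomplete = days_in_month(.data$year, .data$month) - .data$n_days >
        max_missing_days
    )
  if (any(monthly$incomplete)) {
    message(sum(monthly$incomplete), " month(s) flagged incomplete (more than ",
            max_missing_days, " missing days)")
  }
  monthly
}

days_in_month <- function(year, month) {
  nxt_y <- ifelse(month == 12L, year + 1L, year)
  nxt_m <- ifelse(month == 12L, 1L, month + 1L)
  as.integer(as.Date(sprintf("%d-%02d-01", nxt_y, nxt_m)) -
               as.Date(sprintf("%d-%02d-01", year, month)))
}

#' Long-term monthly normal
#'
#' Arithmetic mean of one calendar month's values over a period of years
#' (e.g. the 1981-2010 precipitation normal for May).
#'
#' @param monthly Monthly climate tibble from [aggregate_daily_to_monthly()].
#' @param month Calendar month (1-12).
#' @param period Integer vector of years, default `1981:2010`.
#' @param var Column to average, default `"precip_sum"`.
#' @return Scalar mean value.
#' @export
long_term_monthly_mean <- function(monthly, month, period = 1981:2010,
                                   var = "precip_sum") {
  sel <- monthly[monthly$month == month & monthly$year %in% period, ]
  if (nrow(sel) == 0) {
    stop("no data for month ", month, " within the requested period",
         call. = FALSE)
  }
  mean(sel[[var]])
}

#' Relative surplus of a value over a reference
#'
#' `100 * (value - reference) / reference`, the percentage by which e.g. a
#' month's rainfall exceeds its long-term normal.
#'
#' @param value Observed value (same units as `reference`).
#' @param reference Reference value, must be positive.
#' @return Percent surplus (negative for a deficit).
#' @examples
#' relative_surplus(108, 56)  # about 93
#' @export
relative_surplus <- function(value, reference) {
  if (any(reference <= 0)) {
    stop("reference must be positive", call. = FALSE)
  }
  100 * (value - reference) / reference
}

#' Assign soil units to discrete climate regions
#'
#' Each climate region is represented by exactly one station and, in this
#' planar setting, a rectangular extent plus a centroid. A unit keeps an
#' explicit `climate_region` if it has one; otherwise it is assigned by
#' containment in a region's rectangle, falling back to the nearest region
#' centroid. Units with neither an explicit region nor coordinates raise an
#' error.
#'
#' @param units Data frame of soil units; optional columns `climate_region`,
#'   `x`, `y`.
#' @param regions Data frame with columns `region_id`, `station_id` and
#'   either rectangle bounds `xmin`, `xmax`, `ymin`, `ymax` and/or centroid
#'   `cx`, `cy`.
#' @return `units` with `climate_region` filled for every row.
#' @export
assign_climate_region <- function(units, regions) {
  if (nrow(regions) == 0) stop("regions must be non-empty", call. = FALSE)
  if (anyDuplicated(regions$region_id) > 0) {
    stop("duplicate region ids", call. = FALSE)
  }
  has_box <- all(c("xmin", "xmax", "ymin", "ymax") %in% names(regions))
  if (!all(c("cx", "cy") %in% names(regions))) {
    if (!has_box) stop("regions need rectangle bounds or centroids",
                       call. = FALSE)
    regions$cx <- (regions$xmin + regions$xmax) / 2
    regions$cy <- (regions$ymin + regions$ymax) / 2
  }
  region <- if ("climate_region" %in% names(units)) {
    as.character(units$climate_region)
  } else {
    rep(NA_character_, nrow(units))
  }
  todo <- which(is.na(region) | region == "")
  if (length(todo) > 0) {
    if (!all(c("x", "y") %in% names(units))) {
      stop(length(todo),
           " unit(s) have no explicit climate region and no coordinates",
           call. = FALSE)
    }
    for (i in todo) {
      x <- units$x[i]; y <- units$y[i]
      if (is.na(x) || is.na(y)) {
        stop("unit without explicit climate region has missing coordinates",
             call. = FALSE)
      }
      hit <- if (has_box) {
        which(x >= regions$xmin & x <= regions$xmax &
                y >= regions$ymin & y <= regions$ymax)
      } else {
        integer(0)
      }
      region[i] <- if (length(hit) > 0) {
        regions$region_id[hit[1]]
      } else {
        regions$region_id[which.min((regions$cx - x)^2 + (regions$cy - y)^2)]
      }
    }
  }
  unknown <- setdiff(unique(region), regions$region_id)
  if (length(unknown) > 0) {
    stop("explicit climate region(s) not in the region table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  units$climate_region <- region
  units
}
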