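#' Average simulated yields over a climate period
#'
#' Mean dry-matter yield per (soil type, nFK class, climate region, crop)
#' over the selected years. Groups without any simulated year in the period
#' are absent from the result (and counted in a message).
#'
#' @param sim Simulated-yield tibble from [run_units()].
#' @param period Integer vector of years (e.g. `1991:2007`).
#' @return Tibble with `soil_type`, `nfk_class`, `climate_region`, `crop`,
#'   `mean_dm_yield`, `n_years`.
#' @export
average_over_period <- function(sim, period) {
  if (length(period) == 0) stop("period must be non-empty", call. = FALSE)
  groups_all <- dplyr::distinct(
    sim, .data$soil_type, .data$nfk_class, .data$climate_region, .data$crop)
  out <- sim |>
    dplyr::filter(.data$year %in% period) |>
    dplyr::group_by(.data$soil_type, .data$nfk_class, .data$climate_region,
                    .data$crop) |>
    dplyr::summarise(mean_dm_yield = mean(.data$dm_yield),
                     n_years = dplyr::n(), .groups = "drop")
  dropped <- nrow(groups_all) - nrow(out)
  if (dropped > 0) {
    message(dropped, " group(s) had no simulated years in the period; excluded")
  }
  out
}

#' Fit a polynomial nFK-to-yield interpolation curve
#'
#' Least-squares polynomial of degree `min(2, n - 1)` through the
#' (nFK class, mean yield) points of one crop x soil type x region group.
#' The curves are pure interpolation devices for transferring the aggregated
#' yields onto the soil map; evaluation is clamped to the fitted nFK domain
#' so no extrapolated (possibly negative) values can occur.
#'
#' @param nfk Numeric vector of nFK values (mm), >= 3 distinct points.
#' @param yield Mean dry-matter yields (t DM/ha) at those points.
#' @param crop,soil_type,climate_region Optional labels stored on the curve.
#' @return A `yield_curve` object: coefficients (ascending powers), `domain`
#'   in mm, labels.
#' @export
fit_yield_curve <- function(nfk, yield, crop = NULL, soil_type = NULL,
                            climate_region = NULL) {
  if (anyDuplicated(nfk) > 0) stop("duplicate nFK values", call. = FALSE)
  if (length(nfk) < 3) {
    stop("need at least 3 points to fit a yield curve", call. = FALSE)
  }
  stopifnot(length(nfk) == length(yield))
  deg <- min(2, length(nfk) - 1)
  fit <- stats::lm(yield ~ stats::poly(nfk, deg, raw = TRUE),
                   data = data.frame(nfk = nfk, yield = yield))
  structure(
    list(
      crop = crop, soil_type = soil_type, climate_region = climate_region,
      degree = deg,
      coefficients = unname(stats::coef(fit)),
      domain = range(nfk),
      points = tibble::tibble(nfk = nfk, yield = yield)
    ),
    class = "yield_curve"
  )
}

#' @export
print.yield_curve <- function(x, ...) {
  lab <- paste(c(x$crop, x$soil_type, x$climate_region), collapse = " / ")
  cat(sprintf(
    "yield curve%s: degree %d on nFK [%g, %g] mm, %d points\n",
    if (nzchar(lab)) paste0(" (", lab, ")") else "", x$degree,
    x$domain[1], x$domain[2], nrow(x$points)
  ))
  invisible(x)
}

#' Evaluate a yield interpolation curve
#'
#' Polynomial evaluation clamped to the curve's fitted nFK domain; values
#' are floored at zero (with a warning) so a potential can never be
#' negative.
#'
#' @param curve A `yield_curve` from [fit_yield_curve()].
#' @param nfk nFK values (mm) at which to interpolate.
#' @return Interpolated yields, t DM/ha.
#' @export
interpolate_yield <- function(curve, nfk) {
  stopifnot(inherits(curve, "yield_curve"))
  x <- pmin(pmax(nfk, curve$domain[1]), curve$domain[2])
  y <- eval_poly(curve$coefficients, x)
  if (any(y < 0)) {
    warning("negative interpolated yield(s) floored at 0", call. = FALSE)
    y <- pmax(y, 0)
  }
  y
}

#' @export
predict.yield_curve <- function(object, nfk, ...) {
  interpolate_yield(object, nfk)
}

#' Fit yield curves for every crop x soil type x region group
#'
#' @param mean_yields Output of [average_over_period()].
#' @return Tibble with one row per group and a list-column `curve`; groups
#'   with fewer than 3 nFK points are dropped with a message.
#' @export
fit_yield_curves <- function(mean_yields) {
  nested <- mean_yields |>
    dplyr::group_by(.data$crop, .data$soil_type, .data$climate_region) |>
    tidyr::nest() |>
    dplyr::ungroup()
  ok <- vapply(nested$data, nrow, 0L) >= 3
  if (any(!ok)) {
    message(sum(!ok), " group(s) with < 3 nFK points; no curve fitted")
  }
  nested <- nested[ok, ]
  nested$curve <- Map(
    function(d, crop, st, cr) {
      fit_yield_curve(d$nfk_class, d$mean_dm_yield, crop = crop,
                      soil_type = st, climate_region = cr)
    },
    nested$data, nested$crop, nested$soil_type, nested$climate_region
  )
  dplyr::select(nested, -"data")
}

#' Classify a potential into a yield band
#'
#' Half-open, lower-inclusive bands between the configured edges, with open
#' bands below the first and at/above the last edge. The default edges
#' follow the potential ranges the analysis distinguishes (below 12, 12-14,
#' 14-16, 16-17, 17-19, 19+ t DM/ha).
#'
#' @param value Yields, t DM/ha.
#' @param edges Strictly increasing band edges, default
#'   `c(12, 14, 16, 17, 19)`.
#' @return Factor of band labels (`"<12"`, `"12-14"`, ..., `">=19"`).
#' @examples
#' classify_band(c(11.9, 12, 16.5))
#' @export
classify_band <- function(value, edges = c(12, 14, 16, 17, 19)) {
  if (any(diff(edges) <= 0)) {
    stop("edges must be strictly increasing", call. = FALSE)
  }
  labels <- c(
    paste0("<", edges[1]),
    if (length(edges) > 1) {
      paste0(edges[-length(edges)], "-", edges[-1])
    },
    paste0(">=", edges[length(edges)])
  )
  idx <- findInterval(value, edges) + 1L
  factor(labels[idx], levels = labels)
}

#' Join per-crop yield potentials onto a soil map
#'
#' Transfers the aggregated, interpolated yields onto every soil-map record:
#' each record's continuous nFK estimate (from its soil type and soil
#' number) is run through the yield curve of its (crop, soil type, region)
#' group, optionally multiplied by a per-crop adjustment factor, and
#' classified into a yield band. Cardinality is preserved exactly: one
#' output row per input record, with unresolvable records carrying `NA`
#' potentials and a reason code.
#'
#' @param soil_map Data frame with `unit_id`, `soil_type`, `soil_number`,
#'   `climate_region` (or a pre-computed `nfk_mm` column).
#' @param curves Curve table from [fit_yield_curves()].
#' @param nfk_curves Continuous nFK curves, see [fit_nfk_curves()]; ignored
#'   when `soil_map` already has `nfk_mm`.
#' @param adjustment_factors Named per-crop multiplicative factors applied
#'   to the interpolated potentials (default 1).
#' @param band_edges Passed to [classify_band()].
#' @param strict If `TRUE`, abort when more than `max_unresolved` of records
#'   are unresolvable for any crop.
#' @param max_unresolved Tolerated unresolvable fraction in strict mode
#'   (default 0.1).
#' @return Tibble with one row per soil-map record: the id columns,
#'   `nfk_mm`, and per crop `potential_<crop>`, `band_<crop>`, plus a
#'   `reason` column (`NA` when fully resolved).
#' @export
join_potentials <- function(soil_map, curves, nfk_curves = default_nfk_curves(),
                            adjustment_factors = NULL,
                            band_edges = c(12, 14, 16, 17, 19),
                            strict = FALSE, max_unresolved = 0.1) {
  crops <- unique(curves$crop)
  out <- tibble::as_tibble(soil_map)
  n <- nrow(out)
  if (n == 0) {
    for (crop in crops) {
      out[[paste0("potential_", crop)]] <- numeric(0)
      out[[paste0("band_", crop)]] <- character(0)
    }
    out$reason <- character(0)
    return(out)
  }
  known <- out$soil_type %in% soil_type_codes
  out$nfk_mm <- NA_real_
  if ("nfk_mm" %in% names(soil_map)) {
    out$nfk_mm <- soil_map$nfk_mm
  } else if (any(known)) {
    out$nfk_mm[known] <- estimate_nfk(out$soil_type[known],
                                      out$soil_number[known], nfk_curves)
  }
  reason <- ifelse(known, NA_character_, "unknown_soil_type")
  curve_key <- paste(curves$crop, curves$soil_type, curves$climate_region)
  for (crop in crops) {
    fac <- if (!is.null(adjustment_factors) && crop %in% names(adjustment_factors)) {
      adjustment_factors[[crop]]
    } else 1
    pot <- rep(NA_real_, n)
    idx <- match(paste(crop, out$soil_type, out$climate_region), curve_key)
    no_curve <- known & is.na(idx)
    reason[is.na(reason) & no_curve] <- "no_yield_curve"
    for (ci in unique(idx[!is.na(idx)])) {
      rows <- which(!is.na(idx) & idx == ci & !is.na(out$nfk_mm))
      pot[rows] <- interpolate_yield(curves$curve[[ci]], out$nfk_mm[rows]) * fac
    }
    out[[paste0("potential_", crop)]] <- pot
    out[[paste0("band_", crop)]] <- classify_band(pot, band_edges)
  }
  out$reason <- reason
  unresolved <- mean(!is.na(reason))
  if (strict && unresolved > max_unresolved) {
    stop(sprintf("%.1f%% of soil-map records unresolvable (limit %.1f%%)",
                 100 * unresolved, 100 * max_unresolved), call. = FALSE)
  }
  out
}
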