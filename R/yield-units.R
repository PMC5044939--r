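#' Unit-conversion configuration
#'
#' Bundles the constants converting engine output (t dry matter/ha) into the
#' units of regional harvest statistics: the assumed silage-maize dry-matter
#' fraction, the whole-plant to grain regression constants for winter
#' cereals, and the pivot year of the breeding-trend correction.
#'
#' @param maize_dm_fraction Dry-matter content assumed for maize harvested
#'   for silage (default 0.35).
#' @param grain_intercept,grain_slope_divisor Constants of the grain
#'   regression, see [dm_to_grain()].
#' @param trend_pivot_year First year without a breeding-trend deduction
#'   (default 2000).
#' @return A `conversion_config` list.
#' @export
conversion_config <- function(maize_dm_fraction = 0.35,
                              grain_intercept = 51.377,
                              grain_slope_divisor = 2.5188,
                              trend_pivot_year = 2000) {
  stopifnot(maize_dm_fraction > 0, maize_dm_fraction < 1,
            grain_slope_divisor > 0)
  structure(
    list(maize_dm_fraction = maize_dm_fraction,
         grain_intercept = grain_intercept,
         grain_slope_divisor = grain_slope_divisor,
         trend_pivot_year = trend_pivot_year),
    class = "conversion_config"
  )
}

#' Convert dry matter to fresh mass
#'
#' `dm * 10 / dm_fraction`: t dry matter/ha to deci-tons fresh mass/ha, the
#' unit of the silage-maize harvest statistics.
#'
#' @param dm Dry-matter yield, t DM/ha (non-negative).
#' @param dm_fraction Dry-matter content of the fresh mass, in (0, 1).
#' @return Fresh-mass yield in dt/ha.
#' @examples
#' dm_to_fresh(21, 0.35)  # 600
#' @export
dm_to_fresh <- function(dm, dm_fraction = 0.35) {
  if (any(dm_fraction <= 0 | dm_fraction >= 1)) {
    stop("dm_fraction must be in (0, 1)", call. = FALSE)
  }
  if (any(dm < 0)) stop("dry matter must be non-negative", call. = FALSE)
  dm * 10 / dm_fraction
}

#' Convert whole-plant dry matter to grain yield
#'
#' Affine regression relating whole-plant biomass to grain yield in winter
#' cereals: `grain [dt/ha] = (dm [t/ha] * 10 + 51.377) / 2.5188`. The
#' positive intercept makes extrapolation to very small biomass meaningless,
#' so inputs below the validity window raise an error.
#'
#' @param dm Whole-plant dry matter, t DM/ha.
#' @param intercept,divisor Regression constants.
#' @param validity Validity window of `dm` (default `c(4, 30)`); below it is
#'   an error, above it a warning.
#' @return Grain yield in dt/ha.
#' @examples
#' dm_to_grain(10)  # about 60.1
#' @export
dm_to_grain <- function(dm, intercept = 51.377, divisor = 2.5188,
                        validity = c(4, 30)) {
  if (any(dm < validity[1])) {
    stop("dry matter below the validity window of the grain regression (",
         validity[1], " t/ha)", call. = FALSE)
  }
  if (any(dm > validity[2])) {
    warning("dry matter above the validity window of the grain regression",
            call. = FALSE)
  }
  (dm * 10 + intercept) / divisor
}

#' Deduct the breeding trend from predicted yields
#'
#' Regional yield statistics of winter cereals embed decades of breeding
#' progress, while a model calibrated on recent trials predicts
#' current-variety yields for every year. This correction fits an ordinary
#' least-squares regression of the observed yields on the year over the
#' pre-pivot window (where the trend exists) and subtracts
#' `slope * (pivot - year)` from the prediction of every year before the
#' pivot; years at or after the pivot are unchanged.
#'
#' @param predicted Numeric vector of predicted yields by year.
#' @param observed Numeric vector of observed yields, same years.
#' @param years Integer vector of years for both series.
#' @param pivot Pivot year (default 2000): no deduction from this year on.
#' @param fit_years Years used for the trend regression; default all years
#'   before the pivot.
#' @return A `trend_deduction` object: a list with `table` (tibble of year,
#'   predicted, deduction, adjusted), the fitted `slope` (units/yr), its
#'   standard error `slope_se`, and `pivot`.
#' @export
breeding_trend_deduct <- function(predicted, observed, years, pivot = 2000,
                                  fit_years = NULL) {
  stopifnot(length(predicted) == length(observed),
            length(observed) == length(years))
  if (anyDuplicated(years) > 0) stop("duplicate years", call. = FALSE)
  if (is.null(fit_years)) fit_years <- years[years < pivot]
  fit_years <- intersect(fit_years, years)
  if (length(fit_years) == 0) {
    # pivot precedes the whole series: nothing to deduct
    return(structure(
      list(table = tibble::tibble(year = years, predicted = predicted,
                                  deduction = 0, adjusted = predicted),
           slope = 0, slope_se = NA_real_, pivot = pivot),
      class = "trend_deduction"
    ))
  }
  if (length(observed) < 5 || length(unique(fit_years)) < 2) {
    stop("trend regression needs >= 5 observed years and >= 2 distinct fit years",
         call. = FALSE)
  }
  sel <- years %in% fit_years
  fit <- stats::lm(obs ~ year,
                   data = data.frame(obs = observed[sel], year = years[sel]))
  slope <- unname(stats::coef(fit)["year"])
  # summary.lm warns on exactly collinear (noise-free) inputs; the SE is
  # still the right degenerate value there
  slope_se <- suppressWarnings(
    unname(summary(fit)$coefficients["year", "Std. Error"]))
  deduction <- ifelse(years < pivot, slope * (pivot - years), 0)
  structure(
    list(table = tibble::tibble(year = years, predicted = predicted,
                                deduction = deduction,
                                adjusted = predicted - deduction),
         slope = slope, slope_se = slope_se, pivot = pivot),
    class = "trend_deduction"
  )
}

#' @export
print.trend_deduction <- function(x, ...) {
  cat(sprintf(
    "breeding-trend deduction: slope %.3f units/yr (SE %.3f), pivot %d, %d year(s) deducted\n",
    x$slope, x$slope_se, x$pivot, sum(x$table$deduction != 0)
  ))
  invisible(x)
}

#' Convert simulated dry matter to harvest-statistics units
#'
#' Applies the crop-appropriate conversion: silage maize and the whole-plant
#' energy crops to dt fresh mass/ha via [dm_to_fresh()]; winter cereals
#' reported as grain to dt grain/ha via [dm_to_grain()].
#'
#' @param dm Dry-matter yields, t DM/ha.
#' @param crop Crop name (`"maize"`, `"winter_wheat"`, `"triticale"`,
#'   `"cup_plant"`).
#' @param config A [conversion_config()].
#' @return Yields in the statistics unit of the crop.
#' @export
dm_to_statistics <- function(dm, crop, config = conversion_config()) {
  switch(crop,
    winter_wheat = dm_to_grain(dm, config$grain_intercept,
                               config$grain_slope_divisor),
    maize = ,
    triticale = ,
    cup_plant = dm_to_fresh(dm, config$maize_dm_fraction),
    stop("unknown crop '", crop, "'", call. = FALSE)
  )
}
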