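#' Percent error of a prediction
#'
#' `100 * (predicted - observed) / observed`.
#'
#' @param observed Observed values (> 0).
#' @param predicted Predicted values.
#' @return Percent error (positive = overestimate), full precision.
#' @examples
#' percent_error(414.2, 418.0)  # about 0.9
#' @export
percent_error <- function(observed, predicted) {
  if (any(observed <= 0)) stop("observed must be positive", call. = FALSE)
  100 * (predicted - observed) / observed
}

#' Field-vs-trial adjustment factor
#'
#' Ratio of the mean observed yield (regional statistics) to the mean
#' predicted yield (trial-calibrated model): the multiplicative correction
#' for the gap between controlled field trials and practical agriculture.
#'
#' @param observed,predicted Equal-length yield series (>= 2 values).
#' @return The full-precision factor; round to 2 decimals for reporting.
#' @export
adjustment_factor <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    stop("observed and predicted must have equal length", call. = FALSE)
  }
  if (length(observed) < 2) stop("need at least 2 years", call. = FALSE)
  mp <- mean(predicted)
  if (mp <= 0) stop("mean predicted yield must be positive", call. = FALSE)
  mean(observed) / mp
}

#' Apply the adjustment factor to predictions
#'
#' @param predicted Predicted yields.
#' @param factor Positive adjustment factor.
#' @return `predicted * factor`.
#' @export
apply_adjustment <- function(predicted, factor) {
  if (any(factor <= 0)) stop("factor must be positive", call. = FALSE)
  predicted * factor
}

#' Root-mean-square error
#'
#' @param observed,compared Equal-length series.
#' @return `sqrt(mean((compared - observed)^2))`, in the series' units.
#' @export
rmse <- function(observed, compared) {
  if (length(observed) != length(compared)) {
    stop("series must have equal length", call. = FALSE)
  }
  if (length(observed) < 1) stop("empty series", call. = FALSE)
  sqrt(mean((compared - observed)^2))
}

#' Overall percent error from the RMSE
#'
#' `100 * rmse / mean_observed`: the RMSE expressed relative to the mean
#' observed yield.
#'
#' @param rmse RMSE in yield units.
#' @param mean_observed Mean observed yield (> 0).
#' @return Percent.
#' @export
overall_percent_error <- function(rmse, mean_observed) {
  if (any(mean_observed <= 0)) {
    stop("mean observed must be positive", call. = FALSE)
  }
  100 * rmse / mean_observed
}

#' Willmott index of agreement
#'
#' Willmott's (1981) bounded measure of model agreement:
#' `d = 1 - sum((P - O)^2) / sum((|P - mean(O)| + |O - mean(O)|)^2)`,
#' in \[0, 1\] with 1 for perfect agreement. A zero denominator (both series
#' constant and equal) is defined as perfect agreement.
#'
#' @param observed,compared Equal-length series (>= 2 values).
#' @return Index of agreement in \[0, 1\].
#' @examples
#' willmott_index(c(1, 2, 3), c(1, 2, 4))  # 12/13
#' @export
willmott_index <- function(observed, compared) {
  if (length(observed) != length(compared)) {
    stop("series must have equal length", call. = FALSE)
  }
  if (length(observed) < 2) stop("need at least 2 values", call. = FALSE)
  o_bar <- mean(observed)
  denom <- sum((abs(compared - o_bar) + abs(observed - o_bar))^2)
  if (denom == 0) return(1)
  d <- 1 - sum((compared - observed)^2) / denom
  min(max(d, 0), 1)
}

#' Pearson correlation between observed and compared series
#'
#' Product-moment correlation with its two-sided p-value (via
#' [stats::cor.test()]). Invariant under the affine yield adjustment, so
#' observed-vs-predicted and observed-vs-adjusted give the same r.
#'
#' @param observed,compared Equal-length series (>= 3 values, each with
#'   nonzero variance).
#' @return List with elements `r` and `p_value`.
#' @export
pearson_r <- function(observed, compared) {
  if (length(observed) != length(compared)) {
    stop("series must have equal length", call. = FALSE)
  }
  if (length(observed) < 3) stop("need at least 3 values", call. = FALSE)
  if (stats::sd(observed) == 0 || stats::sd(compared) == 0) {
    stop("correlation undefined for zero-variance series", call. = FALSE)
  }
  ct <- stats::cor.test(observed, compared)
  list(r = unname(ct$estimate), p_value = ct$p.value)
}

#' Soil-quality pre-filters for the yield comparison
#'
#' Regional statistics reflect the soils a crop is actually grown on, so the
#' simulated side of the comparison is pre-filtered by nFK: winter cereals
#' are not grown on very light soils (keep units with nFK strictly above
#' 90 mm), while maize tolerates almost everything (drop only units below
#' 40 mm of field capacity).
#'
#' @return Named list of rules: per crop, `min_nfk_mm` and whether the bound
#'   is `exclusive`.
#' @export
validation_filter_rules <- function() {
  list(
    winter_wheat = list(min_nfk_mm = 90, exclusive = TRUE),
    triticale = list(min_nfk_mm = 90, exclusive = TRUE),
    maize = list(min_nfk_mm = 40, exclusive = FALSE)
  )
}

#' Filter simulated yields for the validation comparison
#'
#' Applies the per-crop nFK rules of [validation_filter_rules()] to a
#' simulated-yield table; crops without a rule pass unfiltered.
#'
#' @param sim Simulated-yield tibble (needs `crop` and `nfk_class`).
#' @param rules Rule list, default [validation_filter_rules()].
#' @return Filtered tibble.
#' @export
filter_validation_units <- function(sim, rules = validation_filter_rules()) {
  keep <- rep(TRUE, nrow(sim))
  for (crop in names(rules)) {
    rule <- rules[[crop]]
    i <- sim$crop == crop
    keep[i] <- if (isTRUE(rule$exclusive)) {
      sim$nfk_class[i] > rule$min_nfk_mm
    } else {
      sim$nfk_class[i] >= rule$min_nfk_mm
    }
  }
  sim[keep, ]
}

#' Build the calibration-and-validation report
#'
#' Assembles the full observed-vs-predicted comparison for one crop: per
#' year the observed and predicted yields, the percent error of the
#' prediction, the adjusted prediction (predicted times the adjustment
#' factor) and its percent error; below, the column means, the adjustment
#' factor, the RMSE, the overall percent error, the Pearson correlation and
#' the Willmott index of agreement.
#'
#' @param observed,predicted Equal-length yield series.
#' @param years Optional years for the rows.
#' @param factor_mode `"computed"` derives the factor as
#'   mean(observed)/mean(predicted); `"fixed"` uses `factor` as given.
#' @param factor Factor used when `factor_mode = "fixed"`.
#' @param rmse_basis,willmott_basis Which series the RMSE and the Willmott
#'   index compare against the observations: the `"adjusted"` (default) or
#'   the raw `"predicted"` series.
#' @param crop Optional crop label carried into the report.
#' @return A `validation_report`: list with the per-year `rows` tibble
#'   (`year`, `observed`, `predicted`, `e_pct`, `adjusted`, `ae_pct`) and the
#'   footer statistics `mean_obs`, `mean_pred`, `mean_adjusted`, `factor`
#'   (full precision), `rmse`, `overall_error_pct`, `pearson_r`, `p_value`,
#'   `willmott_d`.
#' @export
build_validation_report <- function(observed, predicted, years = NULL,
                                    factor_mode = c("computed", "fixed"),
                                    factor = NULL,
                                    rmse_basis = c("adjusted", "predicted"),
                                    willmott_basis = c("adjusted", "predicted"),
                                    crop = NULL) {
  factor_mode <- match.arg(factor_mode)
  rmse_basis <- match.arg(rmse_basis)
  willmott_basis <- match.arg(willmott_basis)
  if (length(observed) != length(predicted)) {
    stop("observed and predicted must have equal length", call. = FALSE)
  }
  if (is.null(years)) years <- seq_along(observed)
  fac <- if (factor_mode == "fixed") {
    if (is.null(factor)) stop("factor_mode 'fixed' needs a factor",
                              call. = FALSE)
    factor
  } else {
    adjustment_factor(observed, predicted)
  }
  adjusted <- apply_adjustment(predicted, fac)
  rows <- tibble::tibble(
    year = years,
    observed = observed,
    predicted = predicted,
    e_pct = percent_error(observed, predicted),
    adjusted = adjusted,
    ae_pct = percent_error(observed, adjusted)
  )
  basis <- function(which) if (which == "adjusted") adjusted else predicted
  # degenerate (constant) series have no defined correlation; the rest of
  # the report is still meaningful
  r <- tryCatch(pearson_r(observed, predicted),
                error = function(e) list(r = NA_real_, p_value = NA_real_))
  structure(
    list(
      crop = crop,
      rows = rows,
      factor_mode = factor_mode,
      factor = fac,
      mean_obs = mean(observed),
      mean_pred = mean(predicted),
      mean_adjusted = mean(adjusted),
      rmse = rmse(observed, basis(rmse_basis)),
      rmse_basis = rmse_basis,
      overall_error_pct = overall_percent_error(
        rmse(observed, basis(rmse_basis)), mean(observed)),
      pearson_r = r$r,
      p_value = r$p_value,
      willmott_d = willmott_index(observed, basis(willmott_basis)),
      willmott_basis = willmott_basis
    ),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, digits = 1, ...) {
  if (!is.null(x$crop)) cat("Validation report:", x$crop, "\n")
  rows <- dplyr::mutate(x$rows, dplyr::across(-"year", \(v) round(v, digits)))
  print(as.data.frame(rows), row.names = FALSE)
  cat(sprintf("Mean      %8.1f %8.1f %6.1f %8.1f %6.1f\n",
              x$mean_obs, x$mean_pred, mean(x$rows$e_pct),
              x$mean_adjusted, mean(x$rows$ae_pct)))
  cat(sprintf("Factor adjust  %.2f (%s, full precision %.4f)\n",
              x$factor, x$factor_mode, x$factor))
  cat(sprintf("RMSE           %.1f (vs %s)\n", x$rmse, x$rmse_basis))
  cat(sprintf("%% error        %.1f\n", x$overall_error_pct))
  cat(sprintf("Pearson r      %.2f (p = %.2g)\n", x$pearson_r, x$p_value))
  cat(sprintf("WIA            %.2f (vs %s)\n", x$willmott_d, x$willmott_basis))
  invisible(x)
}

#' @export
as.data.frame.validation_report <- function(x, ...) {
  as.data.frame(x$rows)
}
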