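#' Soil type codes of the soil-evaluation classification
#'
#' The eight dominant soil texture classes used in the German soil
#' evaluation (Bodenschaetzung): sand through clay. All pedotransfer
#' functions in the package accept exactly these codes.
#'
#' @format Character vector of length 8.
#' @export
soil_type_codes <- c("S", "Sl", "lS", "SL", "sL", "L", "LC", "C")

.soil_type_names <- c(
  S  = "sand",
  Sl = "slightly loamy sand",
  lS = "loamy sand",
  SL = "very loamy sand",
  sL = "sandy loam",
  L  = "loam",
  LC = "heavy loam",
  C  = "clay"
)

#' Long names for soil type codes
#'
#' @param code Character vector of soil type codes (see [soil_type_codes]).
#' @return Character vector of long names.
#' @examples
#' soil_type_name(c("S", "L"))
#' @export
soil_type_name <- function(code) {
  assert_soil_type(code)
  unname(.soil_type_names[code])
}

#' nFK class values (mm) used by the reference table
#' @export
nfk_class_values <- c(50, 90, 140, 200, 250, 270, 300)

assert_soil_type <- function(soil_type) {
  bad <- setdiff(unique(soil_type), soil_type_codes)
  if (length(bad) > 0) {
    stop("unknown soil type code(s): ", paste(bad, collapse = ", "),
         " (valid: ", paste(soil_type_codes, collapse = ", "), ")",
         call. = FALSE)
  }
  invisible(soil_type)
}

# Soil numbers are integer-valued by convention; accept numerics but floor
# them (with a warning) so interval membership stays well defined.
normalize_soil_number <- function(soil_number) {
  if (!is.numeric(soil_number)) {
    stop("soil_number must be numeric", call. = FALSE)
  }
  if (any(soil_number %% 1 != 0, na.rm = TRUE)) {
    warning("non-integer soil numbers floored to integers", call. = FALSE)
    soil_number <- floor(soil_number)
  }
  if (any(soil_number < 1 | soil_number > 100, na.rm = TRUE)) {
    stop("soil_number outside [1, 100]", call. = FALSE)
  }
  soil_number
}

.pkg_cache <- new.env(parent = emptyenv())

#' Reference table mapping soil type and soil number to nFK classes
#'
#' Reads the shipped pedotransfer reference table: per soil type, contiguous
#' soil-number intervals (lower bound exclusive, upper bound inclusive, the
#' last interval open-ended upward) and the plant-available field capacity
#' (nFK) class value in mm assigned to each interval.
#'
#' @param path Optional path to an alternative reference CSV with columns
#'   `soil_type`, `interval_lo_exclusive`, `interval_hi_inclusive` (empty for
#'   the open-ended top interval) and `nfk_mm`.
#' @return A tibble with columns `soil_type`, `lo` (exclusive), `hi`
#'   (inclusive, `Inf` for the top interval) and `nfk_mm`.
#' @export
nfk_reference <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.pkg_cache$nfk_reference)) {
      return(.pkg_cache$nfk_reference)
    }
    path <- system.file("extdata", "nfk_reference.csv", package = "yieldscape",
                        mustWork = TRUE)
    cache <- TRUE
  } else {
    cache <- FALSE
  }
  raw <- readr::read_csv(path, show_col_types = FALSE)
  tab <- tibble::tibble(
    soil_type = raw$soil_type,
    lo = as.numeric(raw$interval_lo_exclusive),
    hi = ifelse(is.na(raw$interval_hi_inclusive), Inf,
                as.numeric(raw$interval_hi_inclusive)),
    nfk_mm = as.numeric(raw$nfk_mm)
  )
  validate_nfk_reference(tab)
  if (cache) .pkg_cache$nfk_reference <- tab
  tab
}

validate_nfk_reference <- function(tab) {
  assert_soil_type(tab$soil_type)
  for (st in unique(tab$soil_type)) {
    x <- tab[tab$soil_type == st, ]
    if (!all(diff(x$nfk_mm) > 0)) {
      stop("nFK class values must strictly increase for type ", st,
           call. = FALSE)
    }
    if (!all(x$lo[-1] == x$hi[-nrow(x)])) {
      stop("intervals must be contiguous for type ", st, call. = FALSE)
    }
    if (!is.infinite(x$hi[nrow(x)])) {
      stop("last interval must be open-ended for type ", st, call. = FALSE)
    }
    if (!all(x$nfk_mm %in% nfk_class_values)) {
      stop("nFK class values outside the reference set for type ", st,
           call. = FALSE)
    }
  }
  invisible(tab)
}

#' nFK class values available for a soil type
#'
#' @param soil_type A single soil type code.
#' @inheritParams classify_nfk
#' @return Numeric vector of class values (mm), increasing.
#' @export
nfk_classes <- function(soil_type, reference = nfk_reference()) {
  stopifnot(length(soil_type) == 1)
  assert_soil_type(soil_type)
  reference$nfk_mm[reference$soil_type == soil_type]
}

#' Classify a soil-evaluation record into its nFK class
#'
#' Looks up the plant-available field capacity class (mm) for a soil type and
#' soil quality number (Bodenzahl) in the reference table. Interval
#' membership follows the table's printed predicates: a soil number equal to
#' an upper bound belongs to that interval.
#'
#' @param soil_type Character vector of soil type codes.
#' @param soil_number Integer vector of soil quality numbers in \[1, 100\]
#'   (recycled against `soil_type`).
#' @param reference Reference table as returned by [nfk_reference()].
#' @return Numeric vector of nFK class values in mm.
#' @examples
#' classify_nfk("S", 20)   # 50
#' classify_nfk("L", 96)   # 300
#' @export
classify_nfk <- function(soil_type, soil_number, reference = nfk_reference()) {
  assert_soil_type(soil_type)
  soil_number <- normalize_soil_number(soil_number)
  n <- max(length(soil_type), length(soil_number))
  soil_type <- rep_len(soil_type, n)
  soil_number <- rep_len(soil_number, n)
  out <- numeric(n)
  for (st in unique(soil_type)) {
    x <- reference[reference$soil_type == st, ]
    i <- soil_type == st
    # lo exclusive / hi inclusive: findInterval on the upper bounds with
    # left-open intervals gives the row index directly
    idx <- findInterval(soil_number[i], x$hi, left.open = TRUE) + 1L
    out[i] <- x$nfk_mm[idx]
  }
  out
}

# Anchor points used for curve fitting: interval midpoints, with the
# open-ended top interval anchored at its lower bound plus half the width of
# the preceding interval.
nfk_anchors <- function(soil_type, reference = nfk_reference()) {
  x <- reference[reference$soil_type == soil_type, ]
  n <- nrow(x)
  mid <- (x$lo + x$hi) / 2
  mid[n] <- x$lo[n] + (x$hi[n - 1] - x$lo[n - 1]) / 2
  tibble::tibble(soil_number = mid, nfk_mm = x$nfk_mm)
}

#' Fit a continuous nFK approximation curve for one soil type
#'
#' Turns the discrete reference classes into a continuous soil-number to nFK
#' curve: a least-squares polynomial through anchor points placed at the
#' interval midpoints (the open-ended top interval is anchored just above its
#' lower bound). The smallest degree (up to `max_degree`) whose fit
#' reproduces every anchor within `tol_mm` is used; if the raw polynomial
#' dips anywhere on the integer soil-number grid it is repaired by isotonic
#' projection onto non-decreasing values.
#'
#' @param soil_type A single soil type code.
#' @param reference Reference table, see [nfk_reference()].
#' @param max_degree Highest polynomial degree tried (default 4).
#' @param tol_mm Anchor reproduction tolerance in mm (default 5).
#' @return An object of class `nfk_curve` with elements `soil_type`,
#'   `degree`, `coefficients` (ascending powers), `domain` (soil numbers),
#'   `range` (mm), `anchors`, `max_residual`, and the evaluation `grid`.
#' @export
fit_nfk_curve <- function(soil_type, reference = nfk_reference(),
                          max_degree = 4, tol_mm = 5) {
  stopifnot(length(soil_type) == 1)
  assert_soil_type(soil_type)
  if (sum(reference$soil_type == soil_type) < 2) {
    stop("need at least 2 anchor points to fit an nFK curve for type ",
         soil_type, call. = FALSE)
  }
  a <- nfk_anchors(soil_type, reference)
  fit <- NULL
  for (deg in seq_len(min(max_degree, nrow(a) - 1))) {
    cand <- stats::lm(nfk_mm ~ stats::poly(soil_number, deg, raw = TRUE),
                      data = a)
    if (max(abs(stats::resid(cand))) <= tol_mm) {
      fit <- cand
      break
    }
  }
  if (is.null(fit)) {
    # exact interpolation as a last resort keeps the anchor guarantee
    deg <- nrow(a) - 1
    fit <- stats::lm(nfk_mm ~ stats::poly(soil_number, deg, raw = TRUE),
                     data = a)
  }
  coefs <- unname(stats::coef(fit))
  domain <- range(a$soil_number)
  rng <- range(a$nfk_mm)
  # evaluation grid over the whole admissible soil-number range: polynomial
  # on the anchor domain, clamped into the class-value range, pinned to the
  # range endpoints at soil numbers 1 and 100
  grid_x <- sort(unique(c(1:100, domain)))
  grid_y <- eval_poly(coefs, pmin(pmax(grid_x, domain[1]), domain[2]))
  grid_y <- pmin(pmax(grid_y, rng[1]), rng[2])
  grid_y[1] <- rng[1]
  grid_y[length(grid_y)] <- rng[2]
  if (any(diff(grid_y) < 0)) {
    grid_y <- stats::isoreg(grid_x, grid_y)$yf
  }
  structure(
    list(
      soil_type = soil_type,
      degree = deg,
      coefficients = coefs,
      domain = domain,
      range = rng,
      anchors = a,
      max_residual = max(abs(grid_interp(grid_x, grid_y, a$soil_number) - a$nfk_mm)),
      grid = tibble::tibble(soil_number = grid_x, nfk_mm = grid_y)
    ),
    class = "nfk_curve"
  )
}

eval_poly <- function(coefs, x) {
  drop(outer(x, seq_along(coefs) - 1, `^`) %*% coefs)
}

grid_interp <- function(x, y, xout) {
  stats::approx(x, y, xout = xout, rule = 2)$y
}

#' @export
print.nfk_curve <- function(x, ...) {
  cat(sprintf(
    "nFK curve for %s (%s): degree %d, domain soil numbers [%.1f, %.1f], range [%g, %g] mm, max anchor residual %.2f mm\n",
    x$soil_type, soil_type_name(x$soil_type), x$degree,
    x$domain[1], x$domain[2], x$range[1], x$range[2], x$max_residual
  ))
  invisible(x)
}

#' @export
predict.nfk_curve <- function(object, soil_number, ...) {
  y <- grid_interp(object$grid$soil_number, object$grid$nfk_mm, soil_number)
  pmin(pmax(y, object$range[1]), object$range[2])
}

#' Fit nFK curves for every soil type
#'
#' @inheritParams fit_nfk_curve
#' @return Named list of [fit_nfk_curve()] objects, one per soil type.
#' @export
fit_nfk_curves <- function(reference = nfk_reference(), max_degree = 4,
                           tol_mm = 5) {
  types <- unique(reference$soil_type)
  stats::setNames(
    lapply(types, fit_nfk_curve, reference = reference,
           max_degree = max_degree, tol_mm = tol_mm),
    types
  )
}

default_nfk_curves <- function() {
  if (is.null(.pkg_cache$nfk_curves)) {
    .pkg_cache$nfk_curves <- fit_nfk_curves()
  }
  .pkg_cache$nfk_curves
}

#' Continuous nFK estimate for soil type and soil number
#'
#' Evaluates the fitted soil-number to nFK curve of a soil type, clamped to
#' the curve's valid domain and to the type's class-value range, so the
#' estimate never leaves \[nfk_min, nfk_max\].
#'
#' @inheritParams classify_nfk
#' @param curves Named list of curves as from [fit_nfk_curves()]; defaults to
#'   curves fitted from the shipped reference table.
#' @return Numeric vector of continuous nFK estimates in mm.
#' @examples
#' estimate_nfk("S", 11)    # about 50
#' estimate_nfk("L", 100)   # clamped to 300
#' @export
estimate_nfk <- function(soil_type, soil_number, curves = default_nfk_curves()) {
  assert_soil_type(soil_type)
  soil_number <- normalize_soil_number(soil_number)
  missing <- setdiff(unique(soil_type), names(curves))
  if (length(missing) > 0) {
    stop("no fitted nFK curve for soil type(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  n <- max(length(soil_type), length(soil_number))
  soil_type <- rep_len(soil_type, n)
  soil_number <- rep_len(soil_number, n)
  out <- numeric(n)
  for (st in unique(soil_type)) {
    i <- soil_type == st
    out[i] <- predict(curves[[st]], soil_number[i])
  }
  out
}

#' Add nFK columns to a soil-unit table
#'
#' Convenience wrapper used by the command-line interface: appends the
#' discrete class (`nfk_class_mm`) and the continuous estimate
#' (`nfk_est_mm`) to a soil-unit table with columns `soil_type` and
#' `soil_number`.
#'
#' @param units Data frame with at least `soil_type` and `soil_number`.
#' @inheritParams estimate_nfk
#' @return `units` with columns `nfk_class_mm` and `nfk_est_mm` added.
#' @export
add_nfk <- function(units, curves = default_nfk_curves()) {
  stopifnot(all(c("soil_type", "soil_number") %in% names(units)))
  dplyr::mutate(
    units,
    nfk_class_mm = classify_nfk(.data$soil_type, .data$soil_number),
    nfk_est_mm = estimate_nfk(.data$soil_type, .data$soil_number, curves)
  )
}
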