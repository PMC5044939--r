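#' Observed and predicted regional yields, Hannover region 1981-2007
#'
#' The bundled reference comparison table for the region of Hannover: per
#' crop (silage maize in dt fresh mass/ha, winter wheat in dt grain/ha) and
#' year, the observed regional harvest statistic, the crop-model prediction,
#' and the reported percent-error, adjusted-yield and adjusted-percent-error
#' columns at their original one-decimal precision. This table is the input
#' for reproducing the calibration-and-validation statistics (adjustment
#' factors 0.72 and 0.80, correlations, error measures).
#'
#' @param crop Optional crop filter (`"maize"` or `"winter_wheat"`).
#' @return Tibble with columns `crop`, `year`, `observed`, `predicted`,
#'   `e_pct`, `adjusted`, `ae_pct`.
#' @export
hannover_yields <- function(crop = NULL) {
  path <- system.file("extdata", "hannover_yields_1981_2007.csv",
                      package = "yieldscape", mustWork = TRUE)
  tab <- readr::read_csv(path, show_col_types = FALSE)
  if (!is.null(crop)) {
    stopifnot(crop %in% unique(tab$crop))
    tab <- tab[tab$crop == crop, ]
  }
  tab
}

#' Notable monthly rainfall events, Hannover region
#'
#' Bundled monthly rainfall totals of the unusually wet months that explain
#' the largest single-year validation errors, together with the matching
#' 1981-2010 long-term normals: May and June 1981 and July 2002.
#'
#' @return Tibble with columns `event`, `year`, `month`, `observed_mm`,
#'   `normal_mm`.
#' @export
hannover_rainfall_events <- function() {
  path <- system.file("extdata", "hannover_rainfall_events.csv",
                      package = "yieldscape", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE)
}
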