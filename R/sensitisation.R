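#' Read sensitisation studies from CSV
#'
#' Columns: `id,x,y,rate,n_tested,kind`, where `kind` is `"overall"`
#' (sensitisation to any allergen among the general population) or
#' `"ragweed_given_sensitised"` (ragweed sensitisation among sensitised
#' patients).
#'
#' @param path CSV path.
#' @return A data.frame with validated columns.
#' @export
read_studies <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "x", "y", "rate", "n_tested", "kind")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("study CSV missing columns: ", paste(miss, collapse = ", "))
  validate_studies(df)
  df[need]
}

validate_studies <- function(df) {
  if (any(df$rate < 0 | df$rate > 1)) stop("study rates must lie in [0, 1]")
  if (any(df$n_tested < 1)) stop("n_tested must be >= 1")
  ok <- df$kind %in% c("overall", "ragweed_given_sensitised")
  if (!all(ok)) stop("unknown study kind: ", paste(unique(df$kind[!ok]), collapse = ", "))
  invisible(df)
}

#' Grid ragweed sensitisation rates
#'
#' Interpolates the two study layers independently by IDW and multiplies them
#' cellwise: overall sensitisation rate among the population times the
#' ragweed-specific rate among sensitised persons. The product is the gridded
#' ragweed sensitisation rate among the general population. Rates are clamped
#' to [0, 1] after interpolation as a guard (IDW cannot overshoot the input
#' range, but degenerate configurations are cheap to protect against).
#'
#' @param overall Data.frame of studies with `kind == "overall"`.
#' @param conditional Data.frame of studies with
#'   `kind == "ragweed_given_sensitised"`.
#' @param spec A [grid_spec()].
#' @param power,k IDW parameters passed to [interpolate_idw()].
#' @return A [raster_grid()] of rates in [0, 1].
#' @export
grid_sensitisation <- function(overall, conditional, spec, power = 2, k = 12) {
  if (!nrow(overall) || !nrow(conditional)) stop("both study lists must be nonempty")
  if (!all(overall$kind == "overall"))
    stop("mixed kinds in the 'overall' study list")
  if (!all(conditional$kind == "ragweed_given_sensitised"))
    stop("mixed kinds in the 'conditional' study list")
  ov <- interpolate_idw(data.frame(x = overall$x, y = overall$y,
                                   value = overall$rate), spec, power, k)
  cd <- interpolate_idw(data.frame(x = conditional$x, y = conditional$y,
                                   value = conditional$rate), spec, power, k)
  v <- pmin(pmax(ov$values * cd$values, 0), 1)
  raster_grid(spec, v)
}

#' Clinically relevant patient grid
#'
#' Multiplies the gridded sensitisation rate by the population raster and by
#' the country-level clinical-relevance rate (the fraction of sensitised
#' persons who actually express symptoms). Each cell belongs to exactly one
#' country per the country-code raster.
#'
#' @param sens Sensitisation-rate [raster_grid()] in [0, 1].
#' @param population Population-count [raster_grid()] (>= 0).
#' @param country_grid Integer country-code [raster_grid()].
#' @param clinical_rates Named numeric vector: country code -> clinical
#'   relevance rate in [0, 1].
#' @return A [raster_grid()] of patient counts; cellwise <= population.
#' @export
clinical_patients_grid <- function(sens, population, country_grid, clinical_rates) {
  if (!same_spec(sens$spec, population$spec) ||
      !same_spec(sens$spec, country_grid$spec))
    stop("sensitisation, population and country rasters must share a grid spec")
  if (any(clinical_rates < 0 | clinical_rates > 1, na.rm = TRUE))
    stop("clinical relevance rates must lie in [0, 1]")
  codes <- country_grid$values
  present <- unique(codes[!is.na(codes)])
  missing_codes <- setdiff(as.character(present), names(clinical_rates))
  if (length(missing_codes))
    stop("clinical relevance rate missing for country code(s): ",
         paste(missing_codes, collapse = ", "))
  rel <- matrix(NA_real_, nrow(codes), ncol(codes))
  ok <- !is.na(codes)
  rel[ok] <- clinical_rates[as.character(codes[ok])]
  raster_grid(sens$spec, sens$values * population$values * rel)
}

#' Zero patients below the pollen-exposure threshold
#'
#' Locations with very low seasonal ragweed pollen (strictly below
#' `threshold`, default 10 grains/m3 seasonal integral) contribute zero
#' patients. Cells are set to 0, not nodata: they stay in all aggregations.
#' The operation is idempotent.
#'
#' @param patients Patient-count [raster_grid()].
#' @param pollen Seasonal pollen integral [raster_grid()].
#' @param threshold Minimum seasonal integral (grains/m3), default 10.
#' @return A [raster_grid()].
#' @export
apply_exposure_mask <- function(patients, pollen, threshold = 10) {
  if (!same_spec(patients$spec, pollen$spec))
    stop("patients and pollen rasters must share a grid spec")
  stopifnot(threshold >= 0)
  v <- patients$values
  low <- !is.na(pollen$values) & pollen$values < threshold
  v[low & !is.na(v)] <- 0
  raster_grid(patients$spec, v)
}

#' Sum patients per country
#'
#' @param patients Patient-count [raster_grid()].
#' @param country_grid Country-code [raster_grid()] on the same spec.
#' @return A list with `by_country` (named numeric vector of per-country
#'   totals over non-nodata cells) and `total` (their exact sum).
#' @export
count_patients <- function(patients, country_grid) {
  if (!same_spec(patients$spec, country_grid$spec))
    stop("patients and country rasters must share a grid spec")
  ok <- !is.na(patients$values) & !is.na(country_grid$values)
  by_country <- tapply(patients$values[ok],
                       as.character(country_grid$values[ok]), sum)
  by_country <- stats::setNames(as.numeric(by_country), names(by_country))
  list(by_country = by_country, total = sum(by_country))
}
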