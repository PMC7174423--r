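#' Per-patient annual cost
#'
#' Combines the median annual treatment cost with the socio-economic
#' work-loss share: `round_half_up(median_treatment_cost * (1 +
#' work_loss_ratio))`, to the nearest Euro. With the reference inputs (median
#' treatment cost EUR 565, work-loss ratio 18.5%) this gives EUR 670 per
#' patient and year.
#'
#' @param median_treatment_cost Median treatment cost, EUR/patient/year.
#' @param work_loss_ratio Ratio of work-absence costs to medical expenses
#'   (fraction, e.g. 0.185).
#' @return Integer Euro amount.
#' @export
per_patient_cost <- function(median_treatment_cost = 565,
                             work_loss_ratio = 0.185) {
  stopifnot(median_treatment_cost >= 0, work_loss_ratio >= 0)
  raw <- round(median_treatment_cost * (1 + work_loss_ratio), 6)  # kill fp dust
  as.integer(floor(raw + 0.5))  # round half up, not banker's rounding
}

#' Median treatment cost from a country cost table
#'
#' @param costs Data.frame with a numeric `cost_eur` column (one row per
#'   country-treatment estimate).
#' @return The median cost in EUR.
#' @export
median_treatment_cost <- function(costs) {
  if (!"cost_eur" %in% names(costs)) stop("cost table missing column 'cost_eur'")
  stats::median(costs$cost_eur)
}

#' PPP-weighted cost aggregation
#'
#' Converts per-country patient counts to annual costs, weighting the common
#' per-patient cost by country-level purchasing-power-parity adjusted health
#' expenditure per capita. Weights are normalised by the patient-weighted
#' mean weight, so uniform weights reproduce `total patients x cost` exactly
#' and rescaling all weights by a common factor changes nothing.
#'
#' @param patients_by_country Named numeric vector of patient counts.
#' @param cost Per-patient annual cost in EUR (see [per_patient_cost()]).
#' @param ppp Named numeric vector of positive PPP weights; must cover every
#'   country with patients. Ignored entries for other countries are allowed.
#' @param reference Either `"patient_weighted_mean"` (default) or the name of
#'   a country whose weight serves as the reference level.
#' @return An object of class `cost_summary`: list with `by_country` (EUR per
#'   year), `total` (their exact sum), `per_patient_cost`, `ppp_reference`.
#' @export
ppp_weighted_costs <- function(patients_by_country, cost, ppp,
                               reference = "patient_weighted_mean") {
  stopifnot(cost >= 0)
  cn <- names(patients_by_country)
  if (is.null(cn)) stop("patients_by_country must be a named vector")
  missing_w <- setdiff(cn, names(ppp))
  if (length(missing_w))
    stop("PPP weight missing for country code(s): ",
         paste(missing_w, collapse = ", "))
  w <- ppp[cn]
  if (any(w <= 0)) stop("PPP weights must be positive")
  pat <- as.numeric(patients_by_country)
  ppp_ref <- if (identical(reference, "patient_weighted_mean")) {
    if (sum(pat) > 0) sum(pat * w) / sum(pat) else mean(w)
  } else {
    if (!reference %in% names(ppp))
      stop("reference country '", reference, "' has no PPP weight")
    unname(ppp[reference])
  }
  by_country <- stats::setNames(pat * cost * (as.numeric(w) / ppp_ref), cn)
  structure(list(by_country = by_country, total = sum(by_country),
                 per_patient_cost = cost, ppp_reference = ppp_ref),
            class = "cost_summary")
}

#' @export
print.cost_summary <- function(x, ...) {
  cat(sprintf("Annual cost summary: EUR %.3g total over %d countries (EUR %d/patient)\n",
              x$total, length(x$by_country), as.integer(x$per_patient_cost)))
  invisible(x)
}

#' Savings between a baseline and a scenario cost summary
#'
#' @param baseline,scenario `cost_summary` objects over the same country set.
#' @return A list with `by_country` differences (baseline minus scenario) and
#'   `total` savings in EUR/year; total equals the sum of per-country savings
#'   exactly.
#' @export
scenario_savings <- function(baseline, scenario) {
  b <- baseline$by_country; s <- scenario$by_country
  if (!setequal(names(b), names(s)))
    stop("baseline and scenario cover different country sets")
  s <- s[names(b)]
  diff <- b - s
  list(by_country = diff, total = sum(diff))
}
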