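#' Assemble the full synthetic input set
#'
#' Convenience wrapper running every generator off one master seed, returning
#' the inputs [run_baseline()] and [run_scenario()] consume plus all ground
#' truth.
#'
#' @param seed Master seed.
#' @param ... Overrides forwarded to [synthetic_config()].
#' @return A named list of inputs and truth objects.
#' @export
simulate_inputs <- function(seed = 1, ...) {
  cfg <- synthetic_config(seed, ...)
  pol <- gen_pollen_surface(cfg)
  sens <- gen_sensitisation_studies(cfg)
  geo <- gen_population_countries(cfg)
  comm <- gen_community_health(cfg)
  gdd <- gen_gdd_grid(cfg)
  masks <- gen_suitability_masks(cfg, pol$surface, gdd, "mean")
  list(cfg = cfg, pollen_stations = pol$stations, pollen_truth = pol$surface,
       studies_overall = sens$overall, studies_conditional = sens$conditional,
       population = geo$population, countries = geo$countries,
       clinical_rates = geo$clinical_rates, ppp = geo$ppp,
       community_records = comm$records, community_truth = comm$truth,
       gdd_grid = gdd, plant_mask = masks$plant, beetle_mask = masks$beetle)
}

#' Baseline European burden: patients and costs before beetle establishment
#'
#' Chains the spatial stages: interpolate station pollen integrals to the
#' grid, build the sensitisation map from the two study layers, multiply by
#' population and country-level clinical relevance, zero cells below the
#' pollen-exposure threshold, count patients per country, and aggregate
#' PPP-weighted annual costs.
#'
#' @param inputs A list as produced by [simulate_inputs()] (fields
#'   `pollen_stations`, `studies_overall`, `studies_conditional`,
#'   `population`, `countries`, `clinical_rates`, `ppp`). A precomputed
#'   `pollen_grid` raster may be supplied instead of stations.
#' @param spec A [grid_spec()]; defaults to the population raster's spec.
#' @param threshold Exposure threshold, grains/m3 (default 10).
#' @param cost Per-patient annual cost in EUR (default
#'   [per_patient_cost()] at the reference 565 / 18.5% inputs).
#' @param idw_power,idw_k IDW parameters.
#' @return A list of class `burden_report` with the pollen, sensitisation and
#'   patient rasters, per-country and total patients, and the cost summary.
#' @export
run_baseline <- function(inputs, spec = inputs$population$spec,
                         threshold = 10, cost = per_patient_cost(),
                         idw_power = 2, idw_k = 12) {
  pollen <- if (!is.null(inputs$pollen_grid)) inputs$pollen_grid
    else interpolate_idw(inputs$pollen_stations, spec, idw_power, idw_k)
  sens <- grid_sensitisation(inputs$studies_overall, inputs$studies_conditional,
                             spec, idw_power, idw_k)
  patients <- clinical_patients_grid(sens, inputs$population, inputs$countries,
                                     inputs$clinical_rates)
  patients <- apply_exposure_mask(patients, pollen, threshold)
  counts <- count_patients(patients, inputs$countries)
  costs <- ppp_weighted_costs(counts$by_country, cost, inputs$ppp)
  structure(list(pollen = pollen, sensitisation = sens,
                 patients_grid = patients,
                 patients_by_country = counts$by_country,
                 patients_total = counts$total,
                 costs = costs, threshold = threshold, cost_per_patient = cost),
            class = "burden_report")
}

#' @export
print.burden_report <- function(x, ...) {
  cat("Burden report\n")
  cat(sprintf("  patients: %.4g total over %d countries\n",
              x$patients_total, length(x$patients_by_country)))
  cat(sprintf("  annual cost: EUR %.4g (EUR %d/patient, PPP-weighted)\n",
              x$costs$total, as.integer(x$cost_per_patient)))
  if (!is.null(x$scenario)) {
    cat(sprintf("  scenario patients: %.4g (%.1f%% reduction)\n",
                x$scenario$patients_total, x$scenario$patient_reduction_pct))
    cat(sprintf("  scenario cost: EUR %.4g; savings EUR %.4g\n",
                x$scenario$costs$total, x$scenario$savings$total))
  }
  invisible(x)
}

#' Beetle scenario: project patients and costs under the reduction policy
#'
#' Maps beetle generations from the seasonal degree-day grid, converts them
#' to fractional pollen reductions via the [reduction_policy()] inside the
#' joint suitability masks, scales each cell's pollen and patients
#' accordingly, re-applies the exposure threshold (cells whose reduced pollen
#' falls below it contribute zero patients), and recomputes costs and
#' savings.
#'
#' @param baseline A [run_baseline()] result.
#' @param inputs The same input list (fields `gdd_grid`, `beetle_mask`,
#'   `plant_mask`, `countries`, `ppp`); alternatively supply a precomputed
#'   `reduction` raster in `inputs`.
#' @param elasticity An `elasticity_fit` or bare elasticity value (default
#'   0.84).
#' @param policy A [reduction_policy()].
#' @param params A [voltinism_params()].
#' @param projection `"powerlaw"` (default; patients scale by
#'   `(1 - r)^beta`) or `"first_order"` (linearised `1 - beta * r`, floored
#'   at 0).
#' @param reapply_threshold Re-zero cells that fall below the exposure
#'   threshold after the reduction (default TRUE).
#' @return A list of class `burden_report` carrying a `scenario` element with
#'   the projected rasters, patients, costs and savings.
#' @export
run_scenario <- function(baseline, inputs, elasticity = 0.84,
                         policy = reduction_policy(),
                         params = voltinism_params(),
                         projection = c("powerlaw", "first_order"),
                         reapply_threshold = TRUE) {
  projection <- match.arg(projection)
  beta <- if (inherits(elasticity, "elasticity_fit")) elasticity$beta
    else as.numeric(elasticity)
  red <- if (!is.null(inputs$reduction)) inputs$reduction else {
    gen_grid <- raster_grid(inputs$gdd_grid$spec,
                            matrix(as.numeric(generations(
                              pmax(inputs$gdd_grid$values, 0), params)),
                              inputs$gdd_grid$spec$n_rows,
                              inputs$gdd_grid$spec$n_cols))
    reduction_grid(gen_grid, policy, inputs$beetle_mask, inputs$plant_mask)
  }
  if (!same_spec(red$spec, baseline$patients_grid$spec))
    stop("reduction raster spec does not match the baseline grids")
  r <- red$values
  r[is.na(r)] <- 0
  pollen_new <- raster_grid(baseline$pollen$spec, baseline$pollen$values * (1 - r))
  scale <- if (projection == "powerlaw") {
    ifelse(r >= 1, 0, (1 - r)^beta)
  } else pmax(0, 1 - beta * r)
  patients_new <- raster_grid(baseline$patients_grid$spec,
                              baseline$patients_grid$values * scale)
  if (reapply_threshold)
    patients_new <- apply_exposure_mask(patients_new, pollen_new,
                                        baseline$threshold)
  counts <- count_patients(patients_new, inputs$countries)
  costs <- ppp_weighted_costs(counts$by_country, baseline$cost_per_patient,
                              inputs$ppp)
  savings <- scenario_savings(baseline$costs, costs)
  out <- baseline
  out$scenario <- list(
    reduction = red, pollen = pollen_new, patients_grid = patients_new,
    patients_by_country = counts$by_country, patients_total = counts$total,
    costs = costs, savings = savings,
    patient_reduction_pct =
      100 * (1 - counts$total / baseline$patients_total),
    projection = projection, elasticity = beta)
  out
}

#' Validate predicted patient proportions against reimbursement records
#'
#' Joins pipeline-predicted patient proportions with observed reimbursement
#' proportions per community and reports both columns' means and SDs plus the
#' mean absolute difference.
#'
#' @param predicted Data.frame with `community_id` and `proportion` (predicted
#'   patients / population).
#' @param observed Data.frame with `community_id` and `proportion` (observed
#'   reimbursed patients / population).
#' @return A list with the joined `table` and `summary` (means, SDs, mean
#'   absolute difference, n).
#' @export
validate_against_reimbursement <- function(predicted, observed) {
  stopifnot(all(c("community_id", "proportion") %in% names(predicted)),
            all(c("community_id", "proportion") %in% names(observed)))
  common <- intersect(predicted$community_id, observed$community_id)
  if (!length(common)) stop("no overlapping communities between predictions and observations")
  p <- predicted$proportion[match(common, predicted$community_id)]
  o <- observed$proportion[match(common, observed$community_id)]
  tab <- data.frame(community_id = common, predicted = p, observed = o)
  list(table = tab,
       summary = list(mean_predicted = mean(p), sd_predicted = stats::sd(p),
                      mean_observed = mean(o), sd_observed = stats::sd(o),
                      mean_abs_diff = mean(abs(p - o)), n = length(common)))
}
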