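#' Average community records over a year range
#'
#' Averages the seasonal pollen integral and the patient count per community
#' over the years present in `year_range` (communities with no record in the
#' range are dropped; missing years simply reduce the divisor).
#'
#' @param records Data.frame with columns `community_id`, `year`, `patients`,
#'   `pollen_integral`, and optionally `population`.
#' @param year_range Integer vector of years to include (e.g. `2007:2015`).
#' @return A data.frame with one row per community: `community_id`,
#'   `mean_pollen`, `mean_patients`, `n_years`, and `mean_population` when the
#'   input carries population.
#' @export
average_by_community <- function(records, year_range) {
  if (!length(year_range)) stop("year_range must be nonempty")
  need <- c("community_id", "year", "patients", "pollen_integral")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records missing columns: ", paste(miss, collapse = ", "))
  sub <- records[records$year %in% year_range, , drop = FALSE]
  if (!nrow(sub))
    return(data.frame(community_id = character(0), mean_pollen = numeric(0),
                      mean_patients = numeric(0), n_years = integer(0)))
  ids <- sort(unique(sub$community_id))
  out <- data.frame(
    community_id = ids,
    mean_pollen = as.numeric(tapply(sub$pollen_integral, sub$community_id, mean)[ids]),
    mean_patients = as.numeric(tapply(sub$patients, sub$community_id, mean)[ids]),
    n_years = as.integer(tapply(sub$year, sub$community_id, length)[ids]),
    stringsAsFactors = FALSE)
  if ("population" %in% names(records))
    out$mean_population <- as.numeric(tapply(sub$population, sub$community_id, mean)[ids])
  out
}

#' Log-log through-origin exposure-response fit
#'
#' Fits `ln(patients) = beta * ln(pollen)` by least squares without a
#' constant, on one averaged point per community. Forcing the regression
#' through the origin encodes the causal requirement that zero pollen implies
#' zero pollen-induced patients; `beta` is then the elasticity of patient
#' numbers with respect to the seasonal pollen integral. Pairs with
#' non-positive pollen or patients are excluded (the log model is undefined
#' there); the number excluded is reported on the fit.
#'
#' The closed form is `beta = sum(ln x * ln y) / sum((ln x)^2)`, with the
#' usual no-intercept standard error on n - 1 degrees of freedom and the
#' uncentred R-squared.
#'
#' @param pollen,patients Numeric vectors of community means (same length).
#' @return An object of class `elasticity_fit` with elements `beta`,
#'   `se_beta`, `n_used`, `n_excluded`, `r_squared_uncentered`, `logx`,
#'   `logy`.
#' @export
fit_loglog_origin <- function(pollen, patients) {
  stopifnot(length(pollen) == length(patients))
  keep <- is.finite(pollen) & is.finite(patients) & pollen > 0 & patients > 0
  n_excluded <- sum(!keep)
  x <- log(pollen[keep]); y <- log(patients[keep])
  if (length(x) < 2L) stop("no positive observations: fewer than 2 usable pairs")
  sxx <- sum(x^2)
  if (sxx == 0) stop("all log pollen values are zero; slope is undefined")
  beta <- sum(x * y) / sxx
  res <- y - beta * x
  n <- length(x)
  sigma2 <- sum(res^2) / (n - 1L)
  se <- sqrt(sigma2 / sxx)
  r2 <- 1 - sum(res^2) / sum(y^2)  # uncentred: no-intercept model
  structure(list(beta = beta, se_beta = se, n_used = n,
                 n_excluded = n_excluded, r_squared_uncentered = r2,
                 logx = x, logy = y),
            class = "elasticity_fit")
}

#' @export
print.elasticity_fit <- function(x, ...) {
  cat("Log-log through-origin exposure-response fit\n")
  cat(sprintf("  elasticity beta = %.4f (se %.4f), n = %d (%d excluded)\n",
              x$beta, x$se_beta, x$n_used, x$n_excluded))
  cat(sprintf("  uncentred R-squared = %.4f\n", x$r_squared_uncentered))
  cat(sprintf("  a 10%% pollen decrease implies a %.1f%% patient decrease (first order)\n",
              -percent_change_first_order(x, -10)))
  invisible(x)
}

#' @export
coef.elasticity_fit <- function(object, ...) c(beta = object$beta)

#' @export
summary.elasticity_fit <- function(object, ...) {
  z <- object$beta / object$se_beta
  out <- list(fit = object, z = z,
              p = 2 * stats::pnorm(-abs(z)),
              ci = object$beta + c(-1, 1) * stats::qnorm(0.975) * object$se_beta)
  class(out) <- "summary.elasticity_fit"
  out
}

#' @export
print.summary.elasticity_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  95%% CI [%.4f, %.4f], z = %.2f, p = %.3g\n",
              x$ci[1], x$ci[2], x$z, x$p))
  invisible(x)
}

#' Predict patient counts from pollen integrals
#'
#' @param object An `elasticity_fit`.
#' @param newdata Numeric vector of pollen integrals.
#' @param ... Unused.
#' @return Predicted patient counts `exp(beta * ln(pollen)) = pollen^beta`.
#' @export
predict.elasticity_fit <- function(object, newdata, ...) {
  newdata^object$beta
}

#' @export
residuals.elasticity_fit <- function(object, ...) {
  object$logy - object$beta * object$logx
}

#' First-order elasticity reading of a pollen change
#'
#' Returns `beta * pollen_pct_change`: the linearised percent change in
#' patient numbers for a given percent change in the seasonal pollen
#' integral. Adequate for small changes; see
#' [relative_patients_powerlaw()] for large reductions.
#'
#' @param fit An `elasticity_fit` (or a bare elasticity value).
#' @param pollen_pct_change Percent change in pollen (e.g. -10).
#' @return Percent change in patients.
#' @export
percent_change_first_order <- function(fit, pollen_pct_change) {
  beta <- if (inherits(fit, "elasticity_fit")) fit$beta else as.numeric(fit)
  beta * pollen_pct_change
}

#' Relative patient numbers under a pollen reduction, power-law form
#'
#' Applies the fitted log-log model exactly: a fractional pollen reduction
#' `r` multiplies patient numbers by `(1 - r)^beta`. Agrees with the
#' first-order reading as `r -> 0` and returns 0 at complete eradication.
#'
#' @param fit An `elasticity_fit` (or a bare elasticity value).
#' @param reduction Fractional pollen reduction in [0, 1] (vectorised).
#' @return Fraction of baseline patients remaining.
#' @export
relative_patients_powerlaw <- function(fit, reduction) {
  beta <- if (inherits(fit, "elasticity_fit")) fit$beta else as.numeric(fit)
  if (any(reduction < 0 | reduction > 1)) stop("reduction must lie in [0, 1]")
  ifelse(reduction >= 1, 0, (1 - reduction)^beta)
}
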