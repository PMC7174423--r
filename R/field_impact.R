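#' Fit the raceme-volume allometry
#'
#' Ordinary least squares of log total raceme length on log plant volume for
#' one site-treatment sample of individually measured, matured plants. The
#' fitted intercept `alpha` and slope `beta` feed the per-plot raceme
#' estimator [plot_raceme_density()].
#'
#' @param sample Data.frame with columns `log_volume` and `log_raceme`.
#' @return A list of class `allometry_fit` with `alpha`, `beta`, `n`,
#'   `sigma` (residual SD).
#' @export
fit_allometry <- function(sample) {
  stopifnot(all(c("log_volume", "log_raceme") %in% names(sample)))
  x <- sample$log_volume; y <- sample$log_raceme
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(unique(x)) < 2L)
    stop("allometry sample needs at least 2 distinct log_volume values")
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(fit)
  structure(list(alpha = unname(cf[1L]), beta = unname(cf[2L]),
                 n = length(x),
                 sigma = suppressWarnings(summary(fit)$sigma)),
            class = "allometry_fit")
}

#' @export
print.allometry_fit <- function(x, ...) {
  cat(sprintf("allometry_fit: log(raceme) = %.3f + %.3f * log(volume), n = %d\n",
              x$alpha, x$beta, x$n))
  invisible(x)
}

#' Fit allometries per site-treatment-year with year fallback
#'
#' Groups allometry samples by site, treatment and year and fits each group
#' with [fit_allometry()]. Groups with too few mature plants (fewer than
#' `min_n`) borrow the same site-treatment fit from the closest earlier year,
#' matching the field protocol where a sparse season reuses the previous
#' season's raceme-volume relationship.
#'
#' @param samples Data.frame with columns `site`, `treatment`, `year`,
#'   `log_volume`, `log_raceme`.
#' @param min_n Minimum plants per group for a group-specific fit (default 5).
#' @return A data.frame with one row per site-treatment-year: `site`,
#'   `treatment`, `year`, `alpha`, `beta`, `n`, `borrowed_from_year`.
#' @export
fit_allometry_table <- function(samples, min_n = 5) {
  need <- c("site", "treatment", "year", "log_volume", "log_raceme")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stop("allometry samples missing columns: ",
                         paste(miss, collapse = ", "))
  grp <- unique(samples[c("site", "treatment", "year")])
  grp <- grp[order(grp$site, grp$treatment, grp$year), , drop = FALSE]
  rows <- lapply(seq_len(nrow(grp)), function(i) {
    g <- grp[i, ]
    sel <- samples$site == g$site & samples$treatment == g$treatment &
      samples$year == g$year
    sub <- samples[sel, , drop = FALSE]
    from_year <- g$year
    if (nrow(sub) < min_n) {
      earlier <- samples[samples$site == g$site &
                           samples$treatment == g$treatment &
                           samples$year < g$year, , drop = FALSE]
      if (nrow(earlier)) {
        cnt <- table(earlier$year)
        ok_years <- as.integer(names(cnt)[cnt >= min_n])
        from_year <- if (length(ok_years)) max(ok_years) else max(earlier$year)
        sub <- earlier[earlier$year == from_year, , drop = FALSE]
      }
    }
    if (nrow(sub) < 2L)
      stop(sprintf("no usable allometry sample for %s/%s/%d",
                   g$site, g$treatment, g$year))
    f <- fit_allometry(sub)
    data.frame(site = g$site, treatment = g$treatment, year = g$year,
               alpha = f$alpha, beta = f$beta, n = f$n,
               borrowed_from_year = from_year, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-plot raceme density from the allometric estimator
#'
#' Estimates the total raceme length produced in a plot as
#' `r = n * m * exp(v * beta + alpha)`, where `n` is the number of plants in
#' the plot at the end of the season, `m` the fraction that matured, `v` the
#' mean log-transformed volume of the matured plants, and `(alpha, beta)` the
#' site-treatment allometry between log raceme length and log volume. The
#' length is rescaled to cm of raceme per square metre by dividing by the
#' plot area (x4 for the standard 0.5 x 0.5 m plots).
#'
#' @param n_plants Plant count in the plot (>= 0, vectorised).
#' @param frac_matured Fraction of plants that matured, in [0, 1].
#' @param mean_log_volume Mean log volume `v` of matured plants in the plot.
#' @param alpha,beta Allometry coefficients (see [fit_allometry()]).
#' @param plot_area Plot area in m2 (default 0.25).
#' @return Raceme density in cm per m2.
#' @export
plot_raceme_density <- function(n_plants, frac_matured, mean_log_volume,
                                alpha, beta, plot_area = 0.25) {
  if (any(frac_matured < 0 | frac_matured > 1, na.rm = TRUE))
    stop("frac_matured must lie in [0, 1]")
  stopifnot(all(plot_area > 0))
  r <- n_plants * frac_matured * exp(mean_log_volume * beta + alpha)
  r[n_plants == 0 | frac_matured == 0] <- 0  # empty plots: 0 even if v is NA
  r / plot_area
}

#' Estimate raceme densities for a table of plots
#'
#' Applies [plot_raceme_density()] to every non-excluded plot, matching each
#' plot to its site-treatment-year allometry from [fit_allometry_table()].
#' Plots with no measured plants (`mean_log_volume` missing) use the
#' site-treatment mean log volume of the measured plots in the same year.
#'
#' @param plots Data.frame with columns `plot`, `site`, `treatment`, `year`,
#'   `n_plants`, `frac_matured`, `mean_log_volume` (NA when unmeasured),
#'   optional `excluded_flag` (nonzero rows are dropped) and `plot_area`.
#' @param allometry Output of [fit_allometry_table()].
#' @return The retained plots with an added `density` column (cm raceme/m2).
#' @export
estimate_plot_densities <- function(plots, allometry) {
  need <- c("plot", "site", "treatment", "year", "n_plants", "frac_matured",
            "mean_log_volume")
  miss <- setdiff(need, names(plots))
  if (length(miss)) stop("plot table missing columns: ", paste(miss, collapse = ", "))
  if ("excluded_flag" %in% names(plots))
    plots <- plots[!plots$excluded_flag %in% TRUE & plots$excluded_flag != 1, ,
                   drop = FALSE]
  if (!"plot_area" %in% names(plots)) plots$plot_area <- 0.25
  key <- function(df) paste(df$site, df$treatment, df$year, sep = "\r")
  a_key <- key(allometry)
  dens <- numeric(nrow(plots))
  for (i in seq_len(nrow(plots))) {
    p <- plots[i, ]
    j <- match(key(p), a_key)
    if (is.na(j))
      stop(sprintf("no allometry fit for %s/%s/%d", p$site, p$treatment, p$year))
    v <- p$mean_log_volume
    if (is.na(v) && p$n_plants > 0 && p$frac_matured > 0) {
      same <- plots$site == p$site & plots$treatment == p$treatment &
        plots$year == p$year & !is.na(plots$mean_log_volume)
      if (!any(same))
        stop(sprintf("plot %s has no measured volume and no site-treatment mean",
                     p$plot))
      v <- mean(plots$mean_log_volume[same])
    }
    dens[i] <- plot_raceme_density(p$n_plants, p$frac_matured, v,
                                   allometry$alpha[j], allometry$beta[j],
                                   p$plot_area)
  }
  plots$density <- dens
  plots
}

# ---- Laplace-approximated GLMM with one Gaussian random intercept ----------

# Per-group log-likelihood, score and curvature in the random intercept b,
# at linear predictor eta = offset_fixed + b.
glmm_group_ll <- function(y, eta_fix, b, family) {
  eta <- eta_fix + b
  if (family == "binomial") {
    p <- stats::plogis(eta)
    list(ll = sum(y * eta - log1p(exp(eta))),
         score = sum(y - p),
         curv = sum(p * (1 - p)))
  } else {
    mu <- exp(eta)
    list(ll = sum(y * eta - mu - lgamma(y + 1)),
         score = sum(y - mu),
         curv = sum(mu))
  }
}

# Laplace-approximated marginal log-likelihood for fixed effects beta and
# random-intercept SD sigma. groups: list of index vectors into y / rows of X.
laplace_marginal_ll <- function(beta, sigma, y, X, groups, family) {
  eta_fix <- drop(X %*% beta)
  total <- 0
  for (idx in groups) {
    yg <- y[idx]; ef <- eta_fix[idx]
    if (sigma <= 0) {
      total <- total + glmm_group_ll(yg, ef, 0, family)$ll
      next
    }
    b <- 0
    for (it in 1:50) {  # damped Newton for the conditional mode
      g <- glmm_group_ll(yg, ef, b, family)
      grad <- g$score - b / sigma^2
      hess <- g$curv + 1 / sigma^2
      step <- grad / hess
      if (abs(step) > 4) step <- sign(step) * 4
      b <- b + step
      if (abs(step) < 1e-11) break
    }
    g <- glmm_group_ll(yg, ef, b, family)
    hess <- g$curv + 1 / sigma^2
    total <- total + g$ll - b^2 / (2 * sigma^2) - 0.5 * log(sigma^2 * hess)
  }
  total
}

#' Fit a one-factor random-intercept GLMM by Laplace approximation
#'
#' Maximum-likelihood fit of a generalised linear mixed model with a single
#' Gaussian random intercept (one variance component), for binomial-logit or
#' Poisson-log responses. The random effect is integrated out by the Laplace
#' approximation (a damped Newton step finds each group's conditional mode);
#' the marginal likelihood is maximised over the fixed effects and the log
#' random-effect SD by quasi-Newton optimisation. With `sigma` fixed at 0 the
#' fit reduces to an ordinary GLM maximised by the same machinery.
#'
#' @param y Response vector (0/1 for binomial, non-negative integers for
#'   Poisson).
#' @param X Fixed-effects design matrix (including intercept column).
#' @param group Grouping factor for the random intercept.
#' @param family `"binomial"` or `"poisson"`.
#' @param sigma Fix the random-intercept SD (e.g. 0 for a fixed-effects-only
#'   fit); `NULL` (default) estimates it.
#' @return A list of class `glmm_fit`: `coef`, `sigma`, `loglik`, `vcov`
#'   (fixed effects), `converged`, `boundary` (TRUE when the fit sits at a
#'   separation or variance boundary), `family`, `n`, `n_groups`.
#' @export
fit_glmm_laplace <- function(y, X, group, family = c("binomial", "poisson"),
                             sigma = NULL) {
  family <- match.arg(family)
  X <- as.matrix(X)
  stopifnot(length(y) == nrow(X))
  group <- as.factor(group)
  groups <- split(seq_along(y), group)
  p <- ncol(X)
  # starting values from a fixed-effects-only iterative fit
  beta0 <- tryCatch(
    suppressWarnings(stats::glm.fit(X, y,
      family = if (family == "binomial") stats::binomial() else stats::poisson()))$coefficients,
    error = function(e) rep(0, p))
  beta0[!is.finite(beta0)] <- 0
  beta0 <- pmin(pmax(beta0, -10), 10)
  estimate_sigma <- is.null(sigma)
  if (estimate_sigma) {
    theta_lo <- log(1e-4); theta_hi <- log(50)
    nll <- function(par) {
      -laplace_marginal_ll(par[seq_len(p)], exp(par[p + 1L]), y, X, groups, family)
    }
    par0 <- c(beta0, log(0.5))
    opt <- stats::optim(par0, nll, method = "L-BFGS-B",
                        lower = c(rep(-25, p), theta_lo),
                        upper = c(rep(25, p), theta_hi),
                        control = list(maxit = 500))
    coefs <- opt$par[seq_len(p)]
    sig <- exp(opt$par[p + 1L])
    ll <- -opt$value
    conv <- opt$convergence == 0
    at_var_boundary <- opt$par[p + 1L] <= theta_lo + 1e-6
  } else {
    sig <- sigma
    nll <- function(b) -laplace_marginal_ll(b, sig, y, X, groups, family)
    opt <- stats::optim(beta0, nll, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
    coefs <- opt$par
    ll <- -opt$value
    conv <- opt$convergence == 0
    at_var_boundary <- FALSE
  }
  sep_boundary <- family == "binomial" && any(abs(coefs) > 12)
  # fixed-effect covariance from the numerical Hessian at the optimum
  vc <- matrix(NA_real_, p, p)
  h <- tryCatch(stats::optimHess(coefs, function(b)
    -laplace_marginal_ll(b, sig, y, X, groups, family)),
    error = function(e) NULL)
  if (!is.null(h)) {
    vi <- tryCatch(solve(h), error = function(e) NULL)
    if (!is.null(vi)) vc <- vi
  }
  structure(list(coef = stats::setNames(coefs, colnames(X)), sigma = sig,
                 loglik = ll, vcov = vc, converged = conv,
                 boundary = at_var_boundary || sep_boundary,
                 family = family, n = length(y), n_groups = length(groups)),
            class = "glmm_fit")
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat(sprintf("glmm_fit (%s, Laplace): logLik %.3f, random-intercept SD %.3f%s\n",
              x$family, x$loglik, x$sigma,
              if (x$boundary) " [boundary]" else ""))
  print(round(x$coef, 4))
  invisible(x)
}

#' Hurdle model for plot raceme production
#'
#' Two-part analysis of the beetle-exclusion field experiment, on per-plot
#' raceme densities from [estimate_plot_densities()]:
#' \enumerate{
#'   \item a binomial-logit GLMM for whether a plot produces racemes at all,
#'     with treatment as fixed effect and site as a Gaussian random
#'     intercept;
#'   \item a Poisson-log GLMM on the plots with positive production, same
#'     structure, with densities rounded half-up to integer cm/m2 to form
#'     the count response.
#' }
#' Each part is compared with its null model (no treatment term) by a
#' likelihood-ratio chi-squared test on 1 df. Fitted treatment-level values
#' are reported on the response scale at random effect zero; their product is
#' the expected raceme density per treatment. Complete separation (e.g. a
#' year in which no control plot produced racemes) is reported as a flagged
#' boundary fit, not an error.
#'
#' @param plots Data.frame with columns `site`, `treatment` (levels
#'   `"control"` and `"beetle_excluded"`) and `density` (cm raceme/m2).
#' @param conf_level Confidence level for Wald intervals on the fitted
#'   probabilities (default 0.95).
#' @return An object of class `hurdle_fit`: per-treatment `p_produce` (with
#'   CI), `mean_positive_density`, random-intercept SDs, log-likelihoods and
#'   LRT statistics/p-values for both parts, and boundary flags.
#' @export
fit_hurdle <- function(plots, conf_level = 0.95) {
  need <- c("site", "treatment", "density")
  miss <- setdiff(need, names(plots))
  if (length(miss)) stop("plot table missing columns: ", paste(miss, collapse = ", "))
  tr <- factor(plots$treatment, levels = c("control", "beetle_excluded"))
  if (anyNA(tr)) stop("treatment must be 'control' or 'beetle_excluded'")
  if (nlevels(droplevels(tr)) < 2L) stop("both treatments must be present")
  site <- factor(plots$site)
  X <- cbind(`(Intercept)` = 1, treatment_excluded = as.numeric(tr == "beetle_excluded"))
  zcrit <- stats::qnorm(1 - (1 - conf_level) / 2)

  # part 1: produces racemes at all
  y_bin <- as.numeric(plots$density > 0)
  bin_alt <- fit_glmm_laplace(y_bin, X, site, "binomial")
  bin_null <- fit_glmm_laplace(y_bin, X[, 1L, drop = FALSE], site, "binomial")
  bin_lrt <- 2 * (bin_alt$loglik - bin_null$loglik)
  bin_degenerate <- length(unique(y_bin)) < 2L
  eta <- c(control = unname(bin_alt$coef[1L]),
           beetle_excluded = unname(sum(bin_alt$coef)))
  se_eta <- if (all(is.finite(bin_alt$vcov))) {
    c(control = sqrt(bin_alt$vcov[1, 1]),
      beetle_excluded = sqrt(sum(bin_alt$vcov)))
  } else c(control = NA_real_, beetle_excluded = NA_real_)
  p_produce <- stats::plogis(eta)
  p_ci <- rbind(lower = stats::plogis(eta - zcrit * se_eta),
                upper = stats::plogis(eta + zcrit * se_eta))
  if (bin_degenerate) p_ci[] <- NA_real_

  # part 2: positive densities only, rounded half-up to integer counts
  pos <- plots$density > 0
  pois_alt <- pois_null <- NULL
  mean_pos <- c(control = NA_real_, beetle_excluded = NA_real_)
  pois_lrt <- NA_real_
  pois_possible <- sum(pos) >= 2L && nlevels(droplevels(tr[pos])) == 2L
  if (pois_possible) {
    y_pos <- floor(plots$density[pos] + 0.5)
    Xp <- X[pos, , drop = FALSE]
    sp <- droplevels(site[pos])
    pois_alt <- fit_glmm_laplace(y_pos, Xp, sp, "poisson")
    pois_null <- fit_glmm_laplace(y_pos, Xp[, 1L, drop = FALSE], sp, "poisson")
    pois_lrt <- 2 * (pois_alt$loglik - pois_null$loglik)
    mean_pos <- c(control = exp(unname(pois_alt$coef[1L])),
                  beetle_excluded = exp(unname(sum(pois_alt$coef))))
  }
  structure(list(
    p_produce = p_produce, p_produce_ci = p_ci,
    mean_positive_density = mean_pos,
    sigma_site = c(binomial = bin_alt$sigma,
                   poisson = if (pois_possible) pois_alt$sigma else NA_real_),
    loglik = c(binomial = bin_alt$loglik,
               poisson = if (pois_possible) pois_alt$loglik else NA_real_),
    lrt = c(binomial = bin_lrt, poisson = pois_lrt),
    lrt_p = c(binomial = if (bin_degenerate) NA_real_ else
                stats::pchisq(bin_lrt, 1, lower.tail = FALSE),
              poisson = if (pois_possible)
                stats::pchisq(pois_lrt, 1, lower.tail = FALSE) else NA_real_),
    boundary = c(binomial = bin_alt$boundary || bin_degenerate,
                 poisson = if (pois_possible) pois_alt$boundary else NA),
    parts = list(binomial = bin_alt, binomial_null = bin_null,
                 poisson = pois_alt, poisson_null = pois_null),
    n_plots = nrow(plots)), class = "hurdle_fit")
}

#' @export
print.hurdle_fit <- function(x, ...) {
  cat("Hurdle fit for plot raceme production (site random intercept)\n")
  cat(sprintf("  P(produce): control %.3f, beetle excluded %.3f (LRT chisq = %.2f, p = %.3g)\n",
              x$p_produce["control"], x$p_produce["beetle_excluded"],
              x$lrt["binomial"], x$lrt_p["binomial"]))
  cat(sprintf("  Positive density (cm/m2): control %.1f, beetle excluded %.1f (LRT chisq = %.2f, p = %.3g)\n",
              x$mean_positive_density["control"],
              x$mean_positive_density["beetle_excluded"],
              x$lrt["poisson"], x$lrt_p["poisson"]))
  cat(sprintf("  Expected density: control %.1f, beetle excluded %.1f cm/m2\n",
              expected_density(x, "control"), expected_density(x, "beetle_excluded")))
  if (any(x$boundary, na.rm = TRUE)) cat("  [boundary fit flagged]\n")
  invisible(x)
}

#' Expected raceme density per treatment
#'
#' The unconditional hurdle expectation: probability of producing racemes
#' times the fitted positive-part mean.
#'
#' @param fit A [fit_hurdle()] object.
#' @param treatment `"control"` or `"beetle_excluded"`.
#' @return Expected density in cm raceme per m2.
#' @export
expected_density <- function(fit, treatment = c("control", "beetle_excluded")) {
  treatment <- match.arg(treatment)
  unname(fit$p_produce[treatment] * fit$mean_positive_density[treatment])
}

#' Percent reduction of pollen production by the beetle
#'
#' For each supplied year, `100 * (1 - E[control] / E[beetle_excluded])`,
#' where E is the expected raceme density from the hurdle fit; years in which
#' no control plot produced racemes while excluded plots did contribute 100%.
#' Returns the per-year values and their unweighted mean.
#'
#' @param ... One or more year results, each either a `hurdle_fit` or a named
#'   numeric vector `c(control = , beetle_excluded = )` of expected
#'   densities.
#' @return A list with `per_year` (percent) and `mean` (percent).
#' @export
percent_production_reduction <- function(...) {
  years <- list(...)
  if (!length(years)) stop("supply at least one year's fit or expectations")
  per_year <- vapply(years, function(yr) {
    e <- if (inherits(yr, "hurdle_fit")) {
      c(control = expected_density(yr, "control"),
        beetle_excluded = expected_density(yr, "beetle_excluded"))
    } else {
      stopifnot(all(c("control", "beetle_excluded") %in% names(yr)))
      yr[c("control", "beetle_excluded")]
    }
    if (!is.finite(e["beetle_excluded"]) || e["beetle_excluded"] == 0)
      stop("expected density under beetle exclusion is zero; reduction undefined")
    ec <- if (is.finite(e["control"])) e["control"] else 0
    100 * (1 - ec / e["beetle_excluded"])
  }, numeric(1))
  list(per_year = per_year, mean = mean(per_year))
}
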