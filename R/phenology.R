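#' Voltinism parameters
#'
#' Developmental base temperature and growing-degree-day requirement per
#' generation of the leaf beetle. Defaults: base 13.3 degC (the minimum
#' development threshold for all immature stages) and 288.7 degree-days from
#' egg to adult emergence, from the altitudinal field-cage study.
#'
#' @param base_temp Base temperature, degC.
#' @param gdd_per_generation Degree-days required per generation (> 0).
#' @return A list of class `voltinism_params`.
#' @export
voltinism_params <- function(base_temp = 13.3, gdd_per_generation = 288.7) {
  stopifnot(gdd_per_generation > 0)
  structure(list(base_temp = base_temp,
                 gdd_per_generation = gdd_per_generation),
            class = "voltinism_params")
}

#' Accumulate growing degree days
#'
#' Simple daily-average method: each day contributes
#' `max(0, (t_min + t_max)/2 - base_temp)` degree-days. Monotone
#' non-decreasing in every daily temperature and additive over adjacent
#' windows.
#'
#' @param series Data.frame with columns `date` (Date or coercible), `tmin`,
#'   `tmax` in degC; dates strictly increasing, `tmin <= tmax`.
#' @param params A [voltinism_params()].
#' @param from,to Window bounds (inclusive); default the full series. The
#'   window must lie within the series.
#' @return Accumulated degree-days (numeric scalar).
#' @export
gdd_accumulate <- function(series, params = voltinism_params(),
                           from = NULL, to = NULL) {
  stopifnot(all(c("date", "tmin", "tmax") %in% names(series)))
  d <- as.Date(series$date)
  if (is.unsorted(d, strictly = TRUE)) stop("dates must be strictly increasing")
  if (any(series$tmin > series$tmax)) stop("tmin must not exceed tmax")
  if (is.null(from)) from <- min(d)
  if (is.null(to)) to <- max(d)
  from <- as.Date(from); to <- as.Date(to)
  if (from < min(d) || to > max(d))
    stop("requested window extends outside the temperature series")
  sel <- d >= from & d <= to
  daily <- pmax(0, (series$tmin[sel] + series$tmax[sel]) / 2 - params$base_temp)
  sum(daily)
}

#' Number of beetle generations from accumulated degree days
#'
#' `floor(total_gdd / gdd_per_generation)`: only fully completed generations
#' count.
#'
#' @param total_gdd Accumulated degree-days (>= 0, vectorised).
#' @param params A [voltinism_params()].
#' @return Integer generation counts.
#' @export
generations <- function(total_gdd, params = voltinism_params()) {
  if (any(total_gdd < 0)) stop("total_gdd must be non-negative")
  as.integer(floor(total_gdd / params$gdd_per_generation))
}

#' Estimate degree days per generation from field cohorts
#'
#' For each cohort, accumulates degree days from oviposition to adult
#' emergence using the site's daily temperature series, then returns the
#' unweighted mean across cohorts.
#'
#' @param cohorts Data.frame with columns `site`, `oviposition_date`,
#'   `adult_emergence_date`.
#' @param series_by_site Named list of temperature data.frames (see
#'   [gdd_accumulate()]), one per site.
#' @param params A [voltinism_params()].
#' @return A list with `mean_gdd` and the per-cohort `gdd` vector.
#' @export
estimate_generation_gdd <- function(cohorts, series_by_site,
                                    params = voltinism_params()) {
  stopifnot(all(c("site", "oviposition_date", "adult_emergence_date")
                %in% names(cohorts)))
  if (any(as.Date(cohorts$adult_emergence_date) <=
          as.Date(cohorts$oviposition_date)))
    stop("adult emergence must postdate oviposition")
  g <- vapply(seq_len(nrow(cohorts)), function(i) {
    site <- as.character(cohorts$site[i])
    ser <- series_by_site[[site]]
    if (is.null(ser)) stop("no temperature series for site '", site, "'")
    gdd_accumulate(ser, params,
                   from = cohorts$oviposition_date[i],
                   to = cohorts$adult_emergence_date[i])
  }, numeric(1))
  list(mean_gdd = mean(g), gdd = g)
}

#' Mean daily pollen before and after beetle arrival
#'
#' Computes the mean daily pollen integral per station in each period,
#' averages across stations, and returns the fractional reduction
#' `1 - post/pre`.
#'
#' @param pre,post Data.frames with columns `station`, `date`,
#'   `concentration` (grains/m3, daily resolution).
#' @return A list with `pre_mean`, `post_mean`, `reduction`.
#' @export
prepost_mean_drop <- function(pre, post) {
  period_mean <- function(df) {
    stopifnot(all(c("station", "concentration") %in% names(df)))
    if (!nrow(df)) stop("daily pollen series is empty")
    mean(tapply(df$concentration, df$station, mean))
  }
  pm <- period_mean(pre)
  qm <- period_mean(post)
  if (pm == 0) stop("pre-period mean pollen is zero; reduction undefined")
  list(pre_mean = pm, post_mean = qm, reduction = 1 - qm / pm)
}

#' Empirical pollen-reduction curve against cumulative pre-arrival level
#'
#' Both periods are collapsed to a mean daily profile by day-of-season
#' (averaging over stations and years), the profiles are cumulated along the
#' season, and at each day the reduction `1 - cum_post / cum_pre` is recorded
#' against the cumulative pre-arrival level. This expresses how strongly the
#' beetle suppresses pollen at each point of the accumulating seasonal
#' exposure; empirically the impact is strongest early in the season and
#' levels out at high cumulative loads.
#'
#' @param pre,post Data.frames with columns `station`, `date`,
#'   `concentration`.
#' @return A data.frame with `doy` (day of year), `level` (cumulative mean
#'   daily pre-arrival integral) and `reduction`.
#' @export
empirical_reduction_curve <- function(pre, post) {
  profile <- function(df) {
    if (!nrow(df)) stop("daily pollen series is empty")
    doy <- as.integer(format(as.Date(df$date), "%j"))
    tapply(df$concentration, doy, mean)
  }
  p <- profile(pre)
  q <- profile(post)
  days <- sort(as.integer(intersect(names(p), names(q))))
  if (!length(days)) stop("pre and post series share no days of season")
  cp <- cumsum(p[as.character(days)])
  cq <- cumsum(q[as.character(days)])
  keep <- cp > 0
  data.frame(doy = days[keep], level = as.numeric(cp[keep]),
             reduction = as.numeric(1 - cq[keep] / cp[keep]))
}

#' Generation-dependent pollen-reduction policy
#'
#' Maps beetle generation counts to fractional reductions of the seasonal
#' pollen integral: three or more completed generations give the full
#' Milan-area reduction (default 86%), one or two generations give a partial
#' reduction via early feeding damage (default 30%), and zero generations or
#' unsuitable habitat give no effect.
#'
#' @param full,partial Reduction fractions in [0, 1] with `full >= partial`.
#' @return A list of class `reduction_policy`.
#' @export
reduction_policy <- function(full = 0.86, partial = 0.30) {
  stopifnot(full >= 0, full <= 1, partial >= 0, partial <= 1, full >= partial)
  structure(list(full = full, partial = partial), class = "reduction_policy")
}

#' Map generation counts to pollen reductions on the grid
#'
#' Applies the [reduction_policy()] lookup cellwise and zeroes cells outside
#' the joint beetle-and-host suitability (binary masks). Values are exactly
#' in {0, partial, full} and monotone in generation count.
#'
#' @param generation_grid Integer generation-count [raster_grid()].
#' @param policy A [reduction_policy()].
#' @param beetle_mask,plant_mask Binary (0/1) suitability [raster_grid()]s on
#'   the same grid spec.
#' @return A [raster_grid()] of fractional reductions.
#' @export
reduction_grid <- function(generation_grid, policy = reduction_policy(),
                           beetle_mask, plant_mask) {
  if (!same_spec(generation_grid$spec, beetle_mask$spec) ||
      !same_spec(generation_grid$spec, plant_mask$spec))
    stop("generation grid and suitability masks must share a grid spec")
  g <- generation_grid$values
  red <- matrix(0, nrow(g), ncol(g))
  red[!is.na(g) & g >= 3] <- policy$full
  red[!is.na(g) & g >= 1 & g <= 2] <- policy$partial
  suitable <- !is.na(beetle_mask$values) & beetle_mask$values > 0 &
    !is.na(plant_mask$values) & plant_mask$values > 0
  red[!suitable] <- 0
  red[is.na(g)] <- NA_real_
  raster_grid(generation_grid$spec, red)
}
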