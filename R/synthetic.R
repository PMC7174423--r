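#' Configuration for the synthetic-data generators
#'
#' Bundles the ground-truth parameters and sampling design of every
#' generator. Defaults reproduce the study conditions the pipeline is built
#' for: 296 pollen calibration stations, 50 overall and 80 ragweed-specific
#' sensitisation studies, a 313-community health panel over 2007-2015 with
#' patient elasticity 0.84 and log-normal noise sigma 0.3, a three-site
#' beetle-exclusion experiment with 14 plots per site-treatment (one site
#' without exclusion) and hurdle truth {p 0.26/0.84, positive means 260/905
#' cm/m2}, voltinism truth {base 13.3 degC, 288.7 degree-days per
#' generation}, and the {0.86, 0.30, 0} generation-dependent reduction
#' policy. The spatial domain is a 50 x 50 grid of 10 km cells.
#'
#' Each generator draws from its own stream, seeded at a fixed offset from
#' `seed`, so adding or rerunning one generator never perturbs another.
#'
#' @param seed Master integer seed.
#' @param ... Overrides for any default listed above (see the returned list
#'   for field names).
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = as.integer(seed),
    spec = grid_spec(origin_x = 4e6, origin_y = 3e6, n_rows = 50, n_cols = 50,
                     cell_size = 10000),
    # pollen surface and stations
    n_stations = 296,
    n_bumps = 4,
    background_pollen = 2,
    bump_amplitude = c(200, 2000),
    bump_width_cells = c(4, 12),
    station_noise_sdlog = 0.2,
    # sensitisation studies
    n_studies_overall = 50,
    n_studies_conditional = 80,
    overall_rate_base = 0.30,
    conditional_rate_base = 0.45,
    n_tested_range = c(100, 2000),
    # population / countries / economics
    n_countries = 42,
    clinical_rate_range = c(0.2, 0.8),
    ppp_sdlog = 0.3,
    # community health panel
    n_communities = 313,
    years = 2007:2015,
    true_elasticity = 0.84,
    noise_sigma_log = 0.3,
    community_pollen_range = c(20, 2000),
    population_sdlog = 0.5,
    patients_scale = 10,   # patients = scale * pollen^beta * (pop/1e5) * eps
    # temperatures / voltinism
    base_temp = 13.3,
    gdd_per_generation = 288.7,
    lapse_rate = -6.5,     # degC per km altitude
    temp_amplitude = 10,
    temp_mean_lowland = 14,
    temp_daily_noise_sd = 1.5,
    diurnal_range = 8,
    # field experiment
    n_sites = 3,
    n_plots = 14,
    p_control = 0.26, p_excluded = 0.84,
    mu_control = 260, mu_excluded = 905,
    site_sd_logit = 0.4, site_sd_log = 0.2,
    allometry_alpha = -2, allometry_beta = 1.3, allometry_sigma = 0.3,
    # pre/post pollen series
    n_pollen_stations = 3,
    pre_mean_target = 46.2,
    post_mean_target = 7.5,
    reduction_low = 0.90, reduction_high = 0.837,
    season_doy = 190:300,
    pollen_series_noise_sdlog = 0.15,
    reduction_policy = reduction_policy(0.86, 0.30))
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown synthetic_config fields: ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  class(cfg) <- "synthetic_config"
  cfg
}

# generator-local stream: fixed offset per generator from the master seed
with_stream <- function(cfg, offset, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((cfg$seed %% 100000L) * 17389L %% .Machine$integer.max + offset)
  force(expr)
}

#' Generate a pollen surface with hot-spots, and noisy stations reading it
#'
#' The truth surface is a positive background plus a few Gaussian bumps
#' (emulating the concentrated invasion hot-spots of real seasonal ragweed
#' pollen maps). Stations are placed at random cell centres and report the
#' true surface value times log-normal noise.
#'
#' @param cfg A [synthetic_config()].
#' @return A list with `surface` (truth [raster_grid()]) and `stations`
#'   (data.frame `id,x,y,value`).
#' @export
gen_pollen_surface <- function(cfg = synthetic_config()) {
  with_stream(cfg, 101L, {
    sp <- cfg$spec
    cc <- cell_centres(sp)
    v <- matrix(cfg$background_pollen, sp$n_rows, sp$n_cols)
    for (b in seq_len(cfg$n_bumps)) {
      bx <- stats::runif(1, min(cc$x), max(cc$x))
      by <- stats::runif(1, min(cc$y), max(cc$y))
      amp <- stats::runif(1, cfg$bump_amplitude[1], cfg$bump_amplitude[2])
      w <- stats::runif(1, cfg$bump_width_cells[1], cfg$bump_width_cells[2]) *
        sp$cell_size
      v <- v + amp * exp(-((cc$x - bx)^2 + (cc$y - by)^2) / (2 * w^2))
    }
    v <- pmax(v, 0)
    surface <- raster_grid(sp, v)
    cells <- sample.int(sp$n_rows * sp$n_cols, cfg$n_stations)
    noise <- exp(stats::rnorm(cfg$n_stations, 0, cfg$station_noise_sdlog))
    stations <- data.frame(
      id = sprintf("st%03d", seq_len(cfg$n_stations)),
      x = as.vector(cc$x)[cells], y = as.vector(cc$y)[cells],
      value = as.vector(v)[cells] * noise,
      stringsAsFactors = FALSE)
    list(surface = surface, stations = stations)
  })
}

# smooth truth rate field over the grid: base + gentle planar/sinusoid trend
rate_field <- function(spec, base, amp, phase) {
  cc <- cell_centres(spec)
  xr <- (cc$x - min(cc$x)) / max(1, diff(range(cc$x)))
  yr <- (cc$y - min(cc$y)) / max(1, diff(range(cc$y)))
  pmin(pmax(base + amp * sin(2 * pi * (xr + phase)) * 0.5 +
              amp * (yr - 0.5) * 0.5, 0.01), 0.99)
}

#' Generate sensitisation study lists from smooth truth fields
#'
#' Truth rates vary smoothly over the grid around the configured base rates.
#' Each study samples `n_tested` persons at its location and reports the
#' binomial rate estimate.
#'
#' @param cfg A [synthetic_config()].
#' @return A list with `overall` and `conditional` study data.frames
#'   (`id,x,y,rate,n_tested,kind`) and the truth fields `truth_overall`,
#'   `truth_conditional` ([raster_grid()]s).
#' @export
gen_sensitisation_studies <- function(cfg = synthetic_config()) {
  with_stream(cfg, 202L, {
    sp <- cfg$spec
    t_ov <- rate_field(sp, cfg$overall_rate_base, 0.2, 0.1)
    t_cd <- rate_field(sp, cfg$conditional_rate_base, 0.3, 0.6)
    cc <- cell_centres(sp)
    draw <- function(n, truth, kind, prefix) {
      cells <- sample.int(sp$n_rows * sp$n_cols, n)
      nt <- round(stats::runif(n, cfg$n_tested_range[1], cfg$n_tested_range[2]))
      p <- as.vector(truth)[cells]
      data.frame(id = sprintf("%s%03d", prefix, seq_len(n)),
                 x = as.vector(cc$x)[cells], y = as.vector(cc$y)[cells],
                 rate = stats::rbinom(n, nt, p) / nt,
                 n_tested = nt, kind = kind, stringsAsFactors = FALSE)
    }
    list(overall = draw(cfg$n_studies_overall, t_ov, "overall", "ov"),
         conditional = draw(cfg$n_studies_conditional, t_cd,
                            "ragweed_given_sensitised", "cd"),
         truth_overall = raster_grid(sp, t_ov),
         truth_conditional = raster_grid(sp, t_cd))
  })
}

#' Generate population, country partition and country-level tables
#'
#' Population is a log-normal field with a handful of city bumps; countries
#' are the Voronoi cells of randomly placed capitals. Clinical-relevance
#' rates and PPP health-expenditure weights are drawn per country.
#'
#' @param cfg A [synthetic_config()].
#' @return A list with `population` and `countries` ([raster_grid()]s),
#'   `clinical_rates` and `ppp` (named numeric vectors keyed by country
#'   code).
#' @export
gen_population_countries <- function(cfg = synthetic_config()) {
  with_stream(cfg, 303L, {
    sp <- cfg$spec
    cc <- cell_centres(sp)
    pop <- exp(stats::rnorm(sp$n_rows * sp$n_cols, log(500), 0.8))
    n_cities <- max(3L, cfg$n_countries %/% 6L)
    for (i in seq_len(n_cities)) {
      bx <- stats::runif(1, min(cc$x), max(cc$x))
      by <- stats::runif(1, min(cc$y), max(cc$y))
      w <- 2.5 * sp$cell_size
      pop <- pop + 5e4 * exp(-((as.vector(cc$x) - bx)^2 +
                                 (as.vector(cc$y) - by)^2) / (2 * w^2))
    }
    population <- raster_grid(sp, matrix(pop, sp$n_rows, sp$n_cols))
    capx <- stats::runif(cfg$n_countries, min(cc$x), max(cc$x))
    capy <- stats::runif(cfg$n_countries, min(cc$y), max(cc$y))
    code <- vapply(seq_along(as.vector(cc$x)), function(i)
      which.min((capx - as.vector(cc$x)[i])^2 + (capy - as.vector(cc$y)[i])^2),
      integer(1))
    countries <- raster_grid(sp, matrix(as.numeric(code), sp$n_rows, sp$n_cols))
    codes <- as.character(sort(unique(code)))
    clinical <- stats::setNames(
      stats::runif(length(codes), cfg$clinical_rate_range[1],
                   cfg$clinical_rate_range[2]), codes)
    ppp <- stats::setNames(exp(stats::rnorm(length(codes), 0, cfg$ppp_sdlog)),
                           codes)
    list(population = population, countries = countries,
         clinical_rates = clinical, ppp = ppp)
  })
}

#' Generate the community health panel
#'
#' Communities receive a fixed seasonal pollen integral (log-uniform over the
#' configured range) and a log-normal population. Yearly patient counts
#' follow `patients = scale * pollen^beta * (population / 1e5) * eps` with
#' mean-one multiplicative log-normal noise (so that averaging over years
#' stays centred on the power law), rounded to integers with floor 0 and
#' capped at the population.
#'
#' @param cfg A [synthetic_config()].
#' @return A list with `records` (data.frame `community_id,x,y,year,patients,
#'   pollen_integral,population`) and `truth` (list with `beta`, `scale`,
#'   `sigma`).
#' @export
gen_community_health <- function(cfg = synthetic_config()) {
  with_stream(cfg, 404L, {
    sp <- cfg$spec
    cc <- cell_centres(sp)
    n <- cfg$n_communities
    cells <- sample.int(sp$n_rows * sp$n_cols, n, replace = TRUE)
    pollen <- exp(stats::runif(n, log(cfg$community_pollen_range[1]),
                               log(cfg$community_pollen_range[2])))
    # population chosen so that log(scale * pop / 1e5) is mean-zero noise,
    # keeping the through-origin log-log fit centred on the true elasticity
    population <- round((1e5 / cfg$patients_scale) *
                          exp(stats::rnorm(n, 0, cfg$population_sdlog)))
    years <- cfg$years
    sig <- cfg$noise_sigma_log
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      eps <- exp(stats::rnorm(length(years), 0, sig) - sig^2 / 2)  # E[eps] = 1
      pat <- cfg$patients_scale * pollen[i]^cfg$true_elasticity *
        (population[i] / 1e5) * eps
      pat <- pmin(pmax(round(pat), 0), population[i])
      rows[[i]] <- data.frame(
        community_id = sprintf("c%03d", i),
        x = as.vector(cc$x)[cells[i]], y = as.vector(cc$y)[cells[i]],
        year = years, patients = pat,
        pollen_integral = pollen[i], population = population[i],
        stringsAsFactors = FALSE)
    }
    list(records = do.call(rbind, rows),
         truth = list(beta = cfg$true_elasticity, scale = cfg$patients_scale,
                      sigma = sig))
  })
}

#' Generate daily temperature series along an altitudinal gradient
#'
#' Sinusoidal annual cycle (peak mid-July) with an altitude lapse, symmetric
#' diurnal range about the daily mean, and Gaussian day-to-day noise applied
#' to the mean.
#'
#' @param cfg A [synthetic_config()].
#' @param sites Data.frame with columns `site` and `altitude_m`; default the
#'   five-station ladder 130-1230 m.
#' @param year Calendar year of the series (default 2016).
#' @return Named list of per-site data.frames `date,tmin,tmax`.
#' @export
gen_daily_temps <- function(cfg = synthetic_config(),
                            sites = data.frame(
                              site = paste0("alt", c(130, 250, 480, 700, 1230)),
                              altitude_m = c(130, 250, 480, 700, 1230)),
                            year = 2016) {
  with_stream(cfg, 505L, {
    dates <- seq(as.Date(sprintf("%d-01-01", year)),
                 as.Date(sprintf("%d-12-31", year)), by = "day")
    doy <- as.integer(format(dates, "%j"))
    out <- list()
    for (i in seq_len(nrow(sites))) {
      mean_t <- cfg$temp_mean_lowland +
        cfg$lapse_rate * (sites$altitude_m[i] - 130) / 1000 +
        cfg$temp_amplitude * cos(2 * pi * (doy - 197) / 365.25) +
        stats::rnorm(length(doy), 0, cfg$temp_daily_noise_sd)
      out[[as.character(sites$site[i])]] <- data.frame(
        date = dates,
        tmin = mean_t - cfg$diurnal_range / 2,
        tmax = mean_t + cfg$diurnal_range / 2)
    }
    out
  })
}

#' Generate field-cage cohorts whose development honours the GDD truth
#'
#' For each site and oviposition date, the adult-emergence date is the day at
#' which the accumulated degree-days above the configured base are closest to
#' the true per-generation requirement (weekly-visit style recording around
#' the true completion time). Sites or dates where the requirement is never
#' reached within the series are skipped.
#'
#' @param cfg A [synthetic_config()].
#' @param series_by_site Output of [gen_daily_temps()].
#' @param ovi_dates Candidate oviposition dates (defaults to the two summer
#'   cohort windows).
#' @return Data.frame `site,oviposition_date,adult_emergence_date`.
#' @export
gen_cohorts <- function(cfg = synthetic_config(),
                        series_by_site = gen_daily_temps(cfg),
                        ovi_dates = as.Date(c("2016-07-01", "2016-08-09"))) {
  params <- voltinism_params(cfg$base_temp, cfg$gdd_per_generation)
  rows <- list()
  for (site in names(series_by_site)) {
    ser <- series_by_site[[site]]
    d <- as.Date(ser$date)
    daily <- pmax(0, (ser$tmin + ser$tmax) / 2 - params$base_temp)
    for (ov in ovi_dates) {
      start <- which(d == ov)
      if (!length(start)) next
      cum <- cumsum(daily[start:length(daily)])
      if (max(cum) < cfg$gdd_per_generation) next
      k <- which.min(abs(cum - cfg$gdd_per_generation))
      if (k < 2L) next
      rows[[length(rows) + 1L]] <- data.frame(
        site = site, oviposition_date = as.Date(ov),
        adult_emergence_date = d[start + k - 1L], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Generate the beetle-exclusion plot experiment
#'
#' Three sites with 14 plots per site-treatment; the first site has no
#' exclusion treatment (no insecticide permission), mirroring the field
#' design. Plot production state is drawn at the density level: a plot
#' produces racemes with probability `plogis(logit(p_treatment) + b_site)`
#' and, conditional on producing, its density is Poisson with mean
#' `mu_treatment * exp(b2_site)` (cm raceme per m2). Allometry samples of 21
#' plants per site-treatment are drawn around the configured true intercept
#' and slope.
#'
#' @param cfg A [synthetic_config()].
#' @param year Experiment year recorded on the rows (default 2015).
#' @return A list with `plots` (data.frame `plot,site,treatment,year,density`
#'   plus descriptive `n_plants,frac_matured,mean_log_volume` columns),
#'   `allometry` (data.frame `site,treatment,year,log_volume,log_raceme`) and
#'   `truth`.
#' @export
gen_plot_data <- function(cfg = synthetic_config(), year = 2015) {
  with_stream(cfg, 606L, {
    sites <- paste0("site", seq_len(cfg$n_sites))
    b_logit <- stats::rnorm(cfg$n_sites, 0, cfg$site_sd_logit)
    b_log <- stats::rnorm(cfg$n_sites, 0, cfg$site_sd_log)
    rows <- list()
    for (s in seq_len(cfg$n_sites)) {
      treatments <- if (s == 1L) "control" else c("control", "beetle_excluded")
      for (tr in treatments) {
        p <- stats::plogis(stats::qlogis(
          if (tr == "control") cfg$p_control else cfg$p_excluded) + b_logit[s])
        mu <- (if (tr == "control") cfg$mu_control else cfg$mu_excluded) *
          exp(b_log[s])
        produce <- stats::rbinom(cfg$n_plots, 1, p)
        dens <- ifelse(produce == 1,
                       pmax(1, stats::rpois(cfg$n_plots, mu)), 0)
        n_plants <- stats::rpois(cfg$n_plots, 8)
        frac <- ifelse(produce == 1, stats::rbeta(cfg$n_plots, 4, 2), 0)
        rows[[length(rows) + 1L]] <- data.frame(
          plot = sprintf("%s_%s_%02d", sites[s], tr, seq_len(cfg$n_plots)),
          site = sites[s], treatment = tr, year = year,
          n_plants = n_plants, frac_matured = frac,
          mean_log_volume = ifelse(produce == 1,
                                   stats::rnorm(cfg$n_plots, 3, 0.6), NA),
          density = dens, stringsAsFactors = FALSE)
      }
    }
    allom <- list()
    for (s in sites) for (tr in c("control", "beetle_excluded")) {
      v <- stats::rnorm(21, 3, 0.8)
      allom[[paste(s, tr)]] <- data.frame(
        site = s, treatment = tr, year = year, log_volume = v,
        log_raceme = cfg$allometry_alpha + cfg$allometry_beta * v +
          stats::rnorm(21, 0, cfg$allometry_sigma),
        stringsAsFactors = FALSE)
    }
    list(plots = do.call(rbind, rows), allometry = do.call(rbind, allom),
         truth = list(p_control = cfg$p_control, p_excluded = cfg$p_excluded,
                      mu_control = cfg$mu_control, mu_excluded = cfg$mu_excluded,
                      allometry_alpha = cfg$allometry_alpha,
                      allometry_beta = cfg$allometry_beta))
  })
}

#' Generate pre- and post-arrival daily pollen series
#'
#' Builds a smooth seasonal pulse per station, scaled so the across-station
#' mean daily integral over the season equals `pre_mean_target` for the
#' pre-arrival period. The post-arrival series applies a level-dependent
#' reduction that is strongest early in the season (`reduction_low`) and
#' levels out at `reduction_high` for the high cumulative range; it is then
#' rescaled so the post mean equals `post_mean_target` (set
#' `post_mean_target = NULL` to keep the raw level-dependent series).
#' Multiplicative log-normal day-to-day noise is applied symmetrically
#' (mean one).
#'
#' @param cfg A [synthetic_config()].
#' @return A list with data.frames `pre` and `post`
#'   (`station,date,concentration`) and `truth`.
#' @export
gen_prepost_pollen <- function(cfg = synthetic_config()) {
  with_stream(cfg, 707L, {
    doy <- cfg$season_doy
    pulse <- exp(-((doy - stats::median(doy))^2) / (2 * (diff(range(doy)) / 6)^2))
    make <- function(scale_per_station, year, red = NULL) {
      rows <- list()
      for (st in seq_len(cfg$n_pollen_stations)) {
        base <- pulse * scale_per_station[st]
        if (!is.null(red)) base <- base * (1 - red)
        noise <- exp(stats::rnorm(length(doy), 0, cfg$pollen_series_noise_sdlog) -
                       cfg$pollen_series_noise_sdlog^2 / 2)
        rows[[st]] <- data.frame(
          station = sprintf("milan%02d", st),
          date = as.Date(doy - 1, origin = sprintf("%d-01-01", year)),
          concentration = base * noise, stringsAsFactors = FALSE)
      }
      do.call(rbind, rows)
    }
    # station scales around the pre-period target mean daily integral
    rel <- exp(stats::rnorm(cfg$n_pollen_stations, 0, 0.2))
    scale0 <- cfg$pre_mean_target / mean(pulse)
    scales <- scale0 * rel / mean(rel)
    # level-dependent reduction along the cumulative pre-season profile
    cumfrac <- cumsum(pulse) / sum(pulse)
    red <- cfg$reduction_high +
      (cfg$reduction_low - cfg$reduction_high) * exp(-6 * cumfrac)
    pre <- make(scales, 2008)
    pm0 <- mean(tapply(pre$concentration, pre$station, mean))
    pre$concentration <- pre$concentration * cfg$pre_mean_target / pm0
    post <- make(scales, 2016, red)
    if (!is.null(cfg$post_mean_target)) {
      pm <- mean(tapply(post$concentration, post$station, mean))
      post$concentration <- post$concentration * cfg$post_mean_target / pm
    }
    list(pre = pre, post = post,
         truth = list(pre_mean = cfg$pre_mean_target,
                      post_mean = cfg$post_mean_target,
                      reduction_low = cfg$reduction_low,
                      reduction_high = cfg$reduction_high))
  })
}

#' Generate a seasonal degree-day surface
#'
#' A smooth north-south gradient of total seasonal degree-days above the
#' beetle's base temperature, from which [generations()] maps voltinism.
#'
#' @param cfg A [synthetic_config()].
#' @param gdd_range Range of seasonal degree-days from the northernmost to
#'   the southernmost row.
#' @return A [raster_grid()] of seasonal degree-days.
#' @export
gen_gdd_grid <- function(cfg = synthetic_config(), gdd_range = c(100, 1600)) {
  with_stream(cfg, 808L, {
    sp <- cfg$spec
    rowval <- seq(gdd_range[1], gdd_range[2], length.out = sp$n_rows)
    v <- matrix(rowval, sp$n_rows, sp$n_cols) *
      matrix(exp(stats::rnorm(sp$n_rows * sp$n_cols, 0, 0.05)),
             sp$n_rows, sp$n_cols)
    raster_grid(sp, pmax(v, 0))
  })
}

#' Generate binary suitability masks for plant and beetle
#'
#' The plant mask covers cells with appreciable pollen; the beetle mask
#' covers the warmer (higher degree-day) part of the domain, shrunk or grown
#' for the lower/upper confidence variants.
#'
#' @param cfg A [synthetic_config()].
#' @param pollen Truth pollen [raster_grid()] (e.g. from
#'   [gen_pollen_surface()]).
#' @param gdd Seasonal degree-day [raster_grid()] from [gen_gdd_grid()].
#' @param level `"mean"`, `"lower"` or `"upper"` suitability extent.
#' @return A list with binary [raster_grid()]s `plant` and `beetle`.
#' @export
gen_suitability_masks <- function(cfg = synthetic_config(),
                                  pollen, gdd, level = c("mean", "lower", "upper")) {
  level <- match.arg(level)
  thr_gdd <- switch(level, lower = 450, mean = 300, upper = 150)
  plant <- raster_grid(pollen$spec,
                       (!is.na(pollen$values) & pollen$values >= 10) * 1)
  beetle <- raster_grid(gdd$spec,
                        (!is.na(gdd$values) & gdd$values >= thr_gdd) * 1)
  list(plant = plant, beetle = beetle)
}
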