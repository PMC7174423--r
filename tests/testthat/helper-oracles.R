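# Independent oracles used across the suite: each re-derives a result by a
# different route (brute force, exhaustive enumeration, closed-form loops)
# than the implementation under test.

# Brute-force IDW over all point-cell pairs (k = n), plain loops.
oracle_idw <- function(points, spec, power = 2) {
  cc <- cell_centres(spec)
  out <- matrix(NA_real_, spec$n_rows, spec$n_cols)
  for (i in seq_len(spec$n_rows)) {
    for (j in seq_len(spec$n_cols)) {
      num <- 0; den <- 0; exact <- NA
      for (p in seq_len(nrow(points))) {
        d <- sqrt((points$x[p] - cc$x[i, j])^2 + (points$y[p] - cc$y[i, j])^2)
        if (d < spec$cell_size / 1000) { exact <- points$value[p]; break }
        w <- d^(-power)
        num <- num + w * points$value[p]
        den <- den + w
      }
      out[i, j] <- if (!is.na(exact)) exact else num / den
    }
  }
  out
}

# Exhaustive natural-breaks search: enumerate all ways to split the sorted
# values into n_classes contiguous non-empty blocks and minimise total
# within-class SSD.
oracle_jenks <- function(values, n_classes) {
  s <- sort(values)
  n <- length(s)
  ssd <- function(v) sum((v - mean(v))^2)
  best <- Inf; best_ends <- NULL
  cut_sets <- utils::combn(n - 1L, n_classes - 1L)
  if (n_classes == 1L) return(list(objective = ssd(s), ends = n))
  for (ci in seq_len(ncol(cut_sets))) {
    cuts <- c(0L, cut_sets[, ci], n)
    obj <- 0
    for (b in seq_len(n_classes))
      obj <- obj + ssd(s[(cuts[b] + 1L):cuts[b + 1L]])
    if (obj < best) { best <- obj; best_ends <- cuts[-1L] }
  }
  list(objective = best, ends = best_ends)
}

# Closed-form no-intercept slope on logs, evaluated by an explicit loop.
oracle_loglog_slope <- function(pollen, patients) {
  num <- 0; den <- 0
  for (i in seq_along(pollen)) {
    if (pollen[i] > 0 && patients[i] > 0) {
      num <- num + log(pollen[i]) * log(patients[i])
      den <- den + log(pollen[i])^2
    }
  }
  num / den
}

# small raster fixture helpers
toy_spec <- function(n_rows = 3, n_cols = 3, cell = 10) {
  grid_spec(origin_x = 0, origin_y = n_rows * cell, n_rows = n_rows,
            n_cols = n_cols, cell_size = cell, crs = "toy")
}

toy_grid <- function(values, cell = 10) {
  values <- as.matrix(values)
  raster_grid(toy_spec(nrow(values), ncol(values), cell), values)
}
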