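#' Define a regular grid
#'
#' A `grid_spec` describes a regular lattice of square cells on an already
#' projected (planar, metres) coordinate system. The origin is the top-left
#' corner of the grid: row 1 is the northernmost row, and the centre of cell
#' (i, j) lies at `(origin_x + (j - 0.5) * cell_size,
#' origin_y - (i - 0.5) * cell_size)`. The CRS string is carried as opaque
#' metadata and never used in computation; inputs are assumed to be in metres
#' in that CRS.
#'
#' @param origin_x,origin_y Planar coordinates of the top-left grid corner
#'   (metres).
#' @param cell_size Cell edge length in metres (default 10000, i.e. the
#'   10 x 10 km lattice used throughout the pipeline).
#' @param n_rows,n_cols Grid dimensions (positive integers).
#' @param crs Opaque CRS tag (default "GCS_ETRS_1989").
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(origin_x, origin_y, n_rows, n_cols,
                      cell_size = 10000, crs = "GCS_ETRS_1989") {
  stopifnot(is.numeric(origin_x), is.numeric(origin_y),
            length(origin_x) == 1L, length(origin_y) == 1L,
            is.finite(origin_x), is.finite(origin_y))
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("cell_size must be a positive number")
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || is.na(n_cols) || n_rows < 1L || n_cols < 1L)
    stop("n_rows and n_cols must be positive integers")
  structure(list(origin_x = as.numeric(origin_x),
                 origin_y = as.numeric(origin_y),
                 cell_size = as.numeric(cell_size),
                 n_rows = n_rows, n_cols = n_cols,
                 crs = as.character(crs)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells of %.0f m, origin (%.0f, %.0f), crs '%s'\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin_x, x$origin_y, x$crs))
  invisible(x)
}

same_spec <- function(a, b) {
  isTRUE(all.equal(a$origin_x, b$origin_x)) &&
    isTRUE(all.equal(a$origin_y, b$origin_y)) &&
    isTRUE(all.equal(a$cell_size, b$cell_size)) &&
    a$n_rows == b$n_rows && a$n_cols == b$n_cols
}

#' Cell-centre coordinates of a grid
#'
#' @param spec A [grid_spec()].
#' @return A list with matrices `x` and `y` (n_rows x n_cols) of cell-centre
#'   coordinates.
#' @export
cell_centres <- function(spec) {
  xs <- spec$origin_x + (seq_len(spec$n_cols) - 0.5) * spec$cell_size
  ys <- spec$origin_y - (seq_len(spec$n_rows) - 0.5) * spec$cell_size
  list(x = matrix(xs, spec$n_rows, spec$n_cols, byrow = TRUE),
       y = matrix(ys, spec$n_rows, spec$n_cols, byrow = FALSE))
}

#' Construct a raster grid
#'
#' The raster container used by every spatial stage: a numeric matrix of cell
#' values on a [grid_spec()] lattice. Nodata cells are stored as `NA`; any
#' arithmetic involving a nodata cell yields nodata, and nodata cells are
#' excluded from all reductions.
#'
#' @param spec A [grid_spec()].
#' @param values Numeric matrix of dimension `n_rows x n_cols`, or a single
#'   number recycled to the whole grid. `NA` marks nodata.
#' @return An object of class `raster_grid` with elements `spec` and `values`.
#' @export
raster_grid <- function(spec, values) {
  stopifnot(inherits(spec, "grid_spec"))
  if (length(values) == 1L)
    values <- matrix(as.numeric(values), spec$n_rows, spec$n_cols)
  if (!is.matrix(values) ||
      nrow(values) != spec$n_rows || ncol(values) != spec$n_cols)
    stop("values must be an n_rows x n_cols matrix matching the grid_spec")
  storage.mode(values) <- "double"
  structure(list(spec = spec, values = values), class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("raster_grid: %d x %d (%d nodata cells)\n",
              x$spec$n_rows, x$spec$n_cols, sum(is.na(x$values))))
  if (length(v))
    cat(sprintf("  values: min %.4g, median %.4g, max %.4g\n",
                min(v), stats::median(v), max(v)))
  invisible(x)
}

#' Read point samples from CSV
#'
#' Expects columns `id,x,y,value`; coordinates planar metres.
#'
#' @param path CSV file path.
#' @return A data.frame with columns id, x, y, value.
#' @export
read_points <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "x", "y", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("point CSV missing columns: ", paste(miss, collapse = ", "))
  df[need]
}

#' Inverse-distance-weighted interpolation to a grid
#'
#' Interpolates point samples onto the cell centres of a regular grid using
#' inverse-distance weighting over the `k` nearest points,
#' `w_i = d_i^(-power)`. A cell whose centre coincides with a sample point
#' (distance below `cell_size / 1000`) takes that point's value exactly.
#' Output values always lie within the range of the input values.
#'
#' @param points Data.frame with columns `x`, `y`, `value` (e.g. station
#'   seasonal pollen integrals, or sensitisation study rates).
#' @param spec A [grid_spec()].
#' @param power IDW exponent (> 0), default 2.
#' @param k Number of nearest points used per cell, default 12; capped at the
#'   number of points supplied.
#' @return A [raster_grid()].
#' @export
interpolate_idw <- function(points, spec, power = 2, k = 12) {
  if (is.null(points) || nrow(points) == 0L) stop("no calibration points")
  stopifnot(power > 0, k >= 1)
  if (!all(is.finite(points$x)) || !all(is.finite(points$y)))
    stop("point coordinates must be finite")
  k <- min(as.integer(k), nrow(points))
  cc <- cell_centres(spec)
  px <- points$x; py <- points$y; pv <- points$value
  eps <- spec$cell_size / 1000
  n_cells <- spec$n_rows * spec$n_cols
  out <- numeric(n_cells)
  cx <- as.vector(cc$x); cy <- as.vector(cc$y)
  for (c_i in seq_len(n_cells)) {
    d <- sqrt((px - cx[c_i])^2 + (py - cy[c_i])^2)
    hit <- which(d < eps)
    if (length(hit)) {
      out[c_i] <- pv[hit[1L]]
      next
    }
    idx <- order(d)[seq_len(k)]
    w <- d[idx]^(-power)
    out[c_i] <- sum(w * pv[idx]) / sum(w)
  }
  raster_grid(spec, matrix(out, spec$n_rows, spec$n_cols))
}

#' Jenks natural-breaks classification
#'
#' Finds class boundaries that minimise the within-class sum of squared
#' deviations (Fisher-Jenks), by exact dynamic programming over the sorted
#' values. Ties in the dynamic programme are broken in favour of the smaller
#' left class, so the result is deterministic.
#'
#' @param values Numeric vector to classify.
#' @param n_classes Number of classes (>= 1 and <= number of distinct values).
#' @return A list with `breaks` (strictly increasing upper boundaries of the
#'   first `n_classes - 1` classes, taken as the maximum value of each class)
#'   and `assignment` (integer class index per input value, 1 = lowest class).
#' @export
natural_breaks <- function(values, n_classes) {
  v <- values[!is.na(values)]
  if (!length(v)) stop("no values to classify")
  n_classes <- as.integer(n_classes)
  if (n_classes < 1L) stop("n_classes must be >= 1")
  distinct <- sort(unique(v))
  if (n_classes > length(distinct))
    stop("n_classes exceeds the number of distinct values")
  s <- sort(v)
  n <- length(s)
  cs <- cumsum(s)
  cs2 <- cumsum(s^2)
  # ssd of s[a..b], 1-based inclusive
  ssd <- function(a, b) {
    su <- cs[b] - if (a > 1L) cs[a - 1L] else 0
    sq <- cs2[b] - if (a > 1L) cs2[a - 1L] else 0
    sq - su^2 / (b - a + 1L)
  }
  # dp[k, i]: min total ssd of first i values in k classes
  dp <- matrix(Inf, n_classes, n)
  cut <- matrix(0L, n_classes, n)
  for (i in seq_len(n)) dp[1L, i] <- ssd(1L, i)
  if (n_classes > 1L) {
    for (kk in 2L:n_classes) {
      for (i in kk:n) {
        best <- Inf; best_j <- 0L
        for (j in (kk - 1L):(i - 1L)) {
          cand <- dp[kk - 1L, j] + ssd(j + 1L, i)
          # strict '<' keeps the earliest (smallest left class) split on ties
          if (cand < best) { best <- cand; best_j <- j }
        }
        dp[kk, i] <- best
        cut[kk, i] <- best_j
      }
    }
  }
  # recover class upper boundaries
  ends <- integer(n_classes)
  i <- n
  for (kk in n_classes:1L) {
    ends[kk] <- i
    i <- if (kk > 1L) cut[kk, i] else 0L
  }
  breaks <- if (n_classes > 1L) s[ends[-n_classes]] else numeric(0)
  assignment <- rep(NA_integer_, length(values))
  ok <- !is.na(values)
  assignment[ok] <- findInterval(values[ok], breaks, left.open = TRUE) + 1L
  list(breaks = breaks, assignment = assignment,
       objective = dp[n_classes, n])
}

#' Mask a raster by country membership
#'
#' Cells whose country code (from a co-registered integer raster) is not in
#' `codes` become nodata; all other cells are unchanged.
#'
#' @param grid A [raster_grid()].
#' @param country_grid A [raster_grid()] of integer country codes on the same
#'   grid_spec.
#' @param codes Vector of country codes to retain.
#' @return A [raster_grid()].
#' @export
mask_by_country <- function(grid, country_grid, codes) {
  if (!same_spec(grid$spec, country_grid$spec))
    stop("grid and country raster have different grid specs")
  v <- grid$values
  v[!(country_grid$values %in% codes)] <- NA_real_
  raster_grid(grid$spec, v)
}

#' Read a gridded-CSV raster
#'
#' The gridded CSV dialect is the package's plain-text raster format: header
#' comment lines `#origin_x=`, `#origin_y=`, `#cell_size=`, `#crs=`,
#' optionally `#n_rows=`/`#n_cols=`, followed by `n_rows` lines of `n_cols`
#' comma-separated values with `NA` for nodata. Round-trips through
#' [write_raster()] bit-exactly.
#'
#' @param path File path.
#' @return A [raster_grid()].
#' @export
read_raster <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  get_hdr <- function(key, required = TRUE) {
    m <- grep(paste0("^#", key, "="), hdr, value = TRUE)
    if (!length(m)) {
      if (required) stop("gridded CSV missing header field '", key, "'")
      return(NA_character_)
    }
    sub(paste0("^#", key, "="), "", m[1L])
  }
  ox <- as.numeric(get_hdr("origin_x"))
  oy <- as.numeric(get_hdr("origin_y"))
  cs <- as.numeric(get_hdr("cell_size"))
  crs <- get_hdr("crs", required = FALSE)
  if (anyNA(c(ox, oy, cs)))
    stop("gridded CSV header has a non-numeric origin_x, origin_y or cell_size")
  rows <- strsplit(body, ",", fixed = TRUE)
  ncol_ <- length(rows[[1L]])
  vals <- matrix(NA_real_, length(rows), ncol_)
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    if (length(r) != ncol_)
      stop(sprintf("gridded CSV row %d has %d fields, expected %d",
                   i, length(r), ncol_))
    r <- trimws(r)
    bad <- which(r != "NA" & is.na(suppressWarnings(as.numeric(r))))
    if (length(bad))
      stop(sprintf("gridded CSV non-numeric cell at row %d, col %d: '%s'",
                   i, bad[1L], r[bad[1L]]))
    vals[i, ] <- ifelse(r == "NA", NA_real_, suppressWarnings(as.numeric(r)))
  }
  spec <- grid_spec(ox, oy, nrow(vals), ncol(vals), cell_size = cs,
                    crs = if (is.na(crs)) "" else crs)
  raster_grid(spec, vals)
}

#' Write a raster as gridded CSV
#'
#' @param grid A [raster_grid()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [read_raster()]
#' @export
write_raster <- function(grid, path) {
  stopifnot(inherits(grid, "raster_grid"))
  sp <- grid$spec
  hdr <- c(sprintf("#origin_x=%s", format(sp$origin_x, digits = 17)),
           sprintf("#origin_y=%s", format(sp$origin_y, digits = 17)),
           sprintf("#cell_size=%s", format(sp$cell_size, digits = 17)),
           sprintf("#crs=%s", sp$crs))
  body <- apply(grid$values, 1L, function(r)
    paste(ifelse(is.na(r), "NA", format(r, digits = 17, trim = TRUE,
                                        scientific = FALSE)),
          collapse = ","))
  writeLines(c(hdr, body), path)
  invisible(path)
}
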