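#' Pair a gridded hourly series with a station's observations
#'
#' Samples the cube at the cell whose center is nearest to the station
#' (ties broken towards the lowest row, then lowest column index) and
#' restricts both series to their common timestamps; 6-hourly stations are
#' matched to the exact hours they report.
#'
#' @param cube An [hourly_cube()].
#' @param station A [station_series()].
#' @return A data frame with columns `timestamp`, `grid` (cube temperature,
#'   degrees C) and `station` (observed temperature, degrees C).
#' @export
collocate <- function(cube, station) {
  g <- cube$grid
  lat <- attr(station, "lat"); lon <- attr(station, "lon")
  if (lat > g$lat_origin || lat < g$lat_origin - g$n_rows * g$lat_step ||
      lon < g$lon_origin || lon > g$lon_origin + g$n_cols * g$lon_step)
    stop("station lies outside the cube extent", call. = FALSE)
  # which.min returns the first (lowest-index) minimizer, giving the
  # documented tie-break: lowest row, then lowest column
  row <- which.min(abs(grid_lats(g) - lat))
  col <- which.min(abs(grid_lons(g) - lon))
  cube_t <- as.numeric(cube$time)
  st_t <- as.numeric(station$timestamp)
  common <- intersect(cube_t, st_t)
  if (length(common) == 0)
    stop("no common timestamps between cube and station", call. = FALSE)
  ci <- match(common, cube_t); si <- match(common, st_t)
  data.frame(timestamp = cube$time[ci],
             grid = cube$temperature[row, col, ci] - 273.15,
             station = station$temperature_C[si])
}

#' Regression and residual statistics for a collocated pair series
#'
#' Computes Pearson's correlation, an ordinary least squares fit with the
#' gridded series as the response and the station series as the predictor
#' (so a slope below 1 with a negative intercept reads "the gridded data
#' are colder"), the explained variance, and the quartiles and
#' interquartile range of the residuals (the "bias" summary), plus
#' per-calendar-month residual five-number summaries. Quantiles use linear
#' interpolation between order statistics.
#'
#' @param pairs Data frame from [collocate()] with columns `grid` and
#'   `station` (and optionally `timestamp` for monthly summaries).
#' @param response `"grid"` (default) or `"station"` -- which series is the
#'   regression response.
#' @return An object of class `comparison_stats` with fields `n`,
#'   `pearson_r`, `slope`, `intercept`, `r_squared`, `residual_q1`,
#'   `residual_q3`, `residual_iqr`, `residuals` and `per_month`.
#' @export
series_stats <- function(pairs, response = c("grid", "station")) {
  response <- match.arg(response)
  if (nrow(pairs) < 3) stop("need at least 3 pairs", call. = FALSE)
  y <- if (response == "grid") pairs$grid else pairs$station
  x <- if (response == "grid") pairs$station else pairs$grid
  if (stats::var(x) == 0)
    stop("zero variance in the predictor series", call. = FALSE)
  fit <- stats::lm(y ~ x)
  r <- stats::cor(x, y)
  res <- stats::residuals(fit)
  q <- stats::quantile(res, c(0.25, 0.75), names = FALSE, type = 7)
  per_month <- NULL
  if (!is.null(pairs$timestamp)) {
    mon <- as.POSIXlt(pairs$timestamp, tz = "UTC")$mon + 1L
    per_month <- t(vapply(1:12, function(m) {
      rm <- res[mon == m]
      if (length(rm) == 0) return(rep(NA_real_, 5))
      stats::fivenum(rm)
    }, numeric(5)))
    dimnames(per_month) <- list(month.abb,
                                c("min", "q1", "median", "q3", "max"))
  }
  structure(list(n = nrow(pairs), pearson_r = r,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r^2,
                 residual_q1 = q[1], residual_q3 = q[2],
                 residual_iqr = q[2] - q[1],
                 residuals = res, per_month = per_month,
                 response = response),
            class = "comparison_stats")
}

#' @export
print.comparison_stats <- function(x, ...) {
  cat(sprintf("<comparison_stats> n = %d\n", x$n))
  cat(sprintf("  Pearson r = %.3f  slope = %.3f  intercept = %.2f  R2 = %.3f\n",
              x$pearson_r, x$slope, x$intercept, x$r_squared))
  cat(sprintf("  residual IQR = %.2f [Q1 %.2f, Q3 %.2f]\n",
              x$residual_iqr, x$residual_q1, x$residual_q3))
  invisible(x)
}

#' @export
summary.comparison_stats <- function(object, ...) {
  print(object)
  if (!is.null(object$per_month)) {
    cat("  per-month residual five-number summaries:\n")
    print(round(object$per_month, 2))
  }
  invisible(object)
}

#' Temperature-only bioclimatic variables from a station's own records
#'
#' Forms monthly temperature extremes from the station's observations for
#' each year in `year_range`, computes the temperature-only bioclimatic
#' variables (BIO1-BIO7, BIO10, BIO11) per year, and averages the years.
#'
#' @param station A [station_series()].
#' @param year_range Integer vector of years.
#' @param min_coverage Minimum fraction of expected records per month
#'   (given the station's `step_hours`); failing months are named in the
#'   error.
#' @return Named numeric vector `BIO1, BIO2, BIO3, BIO4, BIO5, BIO6, BIO7,
#'   BIO10, BIO11`.
#' @export
station_bioclim <- function(station, year_range, min_coverage = 0.9) {
  step <- attr(station, "step_hours")
  lt <- as.POSIXlt(station$timestamp, tz = "UTC")
  yr <- lt$year + 1900L; mo <- lt$mon + 1L
  temp_vars <- c("BIO1", "BIO2", "BIO3", "BIO4", "BIO5", "BIO6", "BIO7",
                 "BIO10", "BIO11")
  annuals <- list()
  for (y in year_range) {
    tmin <- numeric(12); tmax <- numeric(12)
    short <- character(0)
    for (m in 1:12) {
      v <- station$temperature_C[yr == y & mo == m]
      expected <- days_in_month(y, m) * 24L / step
      if (length(v) / expected < min_coverage) {
        short <- c(short, sprintf("%d-%02d", y, m)); next
      }
      tmin[m] <- min(v); tmax[m] <- max(v)
    }
    if (length(short))
      stop("insufficient station coverage for month(s): ",
           paste(short, collapse = ", "), call. = FALSE)
    tab <- data.frame(tmin = tmin, tmax = tmax, hmin = 0, hmean = 0, hmax = 0)
    clim <- gen_monthly_climatology(tab, year = y)
    set <- annual_bioclim(clim, version = "mean", cv_offset = 1)
    annuals[[length(annuals) + 1L]] <- set
  }
  dec <- decadal_mean(annuals, period = paste(range(year_range), collapse = "-"))
  vapply(temp_vars, function(v) dec$layers[[v]][1, 1], numeric(1))
}

#' Square buffer zones of 1/3 square degree around stations
#'
#' Each buffer is a square in degree space centered on the station with
#' side `sqrt(1/3)` degrees, i.e. an area of exactly 1/3 square degree
#' (matching the native reanalysis cell area). Buffers crossing a pole are
#' clipped to the valid latitude range and the clipped degree-space area is
#' reported. Overlapping buffers are treated as a union when sampling
#' (cells are never counted twice).
#'
#' @param stations Data frame with columns `lat` and `lon` (degrees).
#' @return An object of class `buffer_set`: a data frame with the buffer
#'   bounds (`lat_min`, `lat_max`, `lon_min`, `lon_max`) and the
#'   degree-space `area` of each (clipped) buffer.
#' @export
buffer_zones <- function(stations) {
  side <- sqrt(1 / 3)
  lat_min <- pmax(stations$lat - side / 2, -90)
  lat_max <- pmin(stations$lat + side / 2, 90)
  out <- data.frame(lat = stations$lat, lon = stations$lon,
                    lat_min = lat_min, lat_max = lat_max,
                    lon_min = stations$lon - side / 2,
                    lon_max = stations$lon + side / 2,
                    area = (lat_max - lat_min) * side)
  class(out) <- c("buffer_set", "data.frame")
  out
}

#' @export
print.buffer_set <- function(x, ...) {
  cat(sprintf("<buffer_set> %d buffer(s), side %.4f deg, total area %.4f deg^2 (pre-union)\n",
              nrow(x), sqrt(1 / 3), sum(x$area)))
  invisible(x)
}

# logical matrix: does each cell center of grid fall inside the buffer union
buffer_mask <- function(g, buffers) {
  lat <- grid_lats(g); lon <- grid_lons(g)
  mask <- matrix(FALSE, g$n_rows, g$n_cols)
  for (i in seq_len(nrow(buffers))) {
    rs <- which(lat >= buffers$lat_min[i] & lat <= buffers$lat_max[i])
    cs <- which(lon >= buffers$lon_min[i] & lon <= buffers$lon_max[i])
    if (length(rs) && length(cs)) mask[rs, cs] <- TRUE
  }
  mask
}

#' Tukey-fence outliers of a residual vector
#'
#' Flags residuals outside `[Q1 - 1.5*IQR, Q3 + 1.5*IQR]`, with quartiles
#' by linear interpolation between order statistics. With all residuals
#' equal the fences collapse onto the common value and nothing is flagged.
#'
#' @param residuals Numeric vector, length at least 4.
#' @return Logical mask the length of `residuals`.
#' @export
iqr_outliers <- function(residuals) {
  if (length(residuals) < 4) stop("need at least 4 residuals", call. = FALSE)
  q <- stats::quantile(residuals, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  residuals < q[1] - 1.5 * iqr | residuals > q[2] + 1.5 * iqr
}

#' Compare two rasters inside station buffer zones
#'
#' Restricts both layers to cells whose centers fall inside the buffer
#' union, computes [series_stats()]-style regression statistics with `a` as
#' the response and `b` as the predictor, flags outlier cells from the OLS
#' residuals by the Tukey-fence rule, and reports the outlier area
#' fraction with latitude-weighted (cosine) cell areas.
#'
#' @param a Numeric matrix (e.g. one layer of a [bioclim_set()]).
#' @param b Numeric matrix on the same grid.
#' @param grid The shared [grid_spec()].
#' @param buffers A [buffer_zones()] result.
#' @return A list: `stats` (a `comparison_stats`), `outlier_mask` (logical
#'   matrix on the grid), `outlier_area_fraction`, and `n_cells`.
#' @export
raster_compare <- function(a, b, grid, buffers) {
  stopifnot_grid(grid)
  if (!identical(dim(a), dim(b)) ||
      !identical(dim(a), c(grid$n_rows, grid$n_cols)))
    stop("rasters must share the grid", call. = FALSE)
  mask <- buffer_mask(grid, buffers)
  sel <- which(mask & !is.na(a) & !is.na(b))
  if (length(sel) == 0)
    stop("no raster cells fall inside the buffer zones", call. = FALSE)
  pairs <- data.frame(grid = a[sel], station = b[sel])
  st <- series_stats(pairs, response = "grid")
  # residuals that are pure floating-point dust (an exact linear relation
  # between the rasters) are treated as exact fits, so identical or merely
  # shifted rasters yield zero outliers rather than flagging noise
  res <- st$residuals
  scale <- max(1e-12, stats::sd(pairs$grid))
  res[abs(res) < 1e-10 * scale] <- 0
  out_flag <- iqr_outliers(res)
  outlier_mask <- matrix(FALSE, grid$n_rows, grid$n_cols)
  outlier_mask[sel[out_flag]] <- TRUE
  cell_w <- matrix(cos(grid_lats(grid) * pi / 180), grid$n_rows, grid$n_cols)
  frac <- sum(cell_w[sel[out_flag]]) / sum(cell_w[sel])
  list(stats = st, outlier_mask = outlier_mask,
       outlier_area_fraction = frac, n_cells = length(sel))
}

#' Read and write station CSV files
#'
#' The station interchange format is a CSV with columns `station_id`,
#' `lat`, `lon`, `timestamp` (ISO 8601, UTC) and `temperature_C`.
#'
#' @param station A [station_series()].
#' @param path File path.
#' @return `write_station_csv()` returns the path invisibly;
#'   `read_station_csv()` returns a [station_series()].
#' @export
write_station_csv <- function(station, path) {
  df <- data.frame(station_id = attr(station, "station_id"),
                   lat = attr(station, "lat"), lon = attr(station, "lon"),
                   timestamp = format(station$timestamp,
                                      "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
                   temperature_C = station$temperature_C)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_station_csv
#' @export
read_station_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("station_id", "lat", "lon", "timestamp", "temperature_C")
  if (!all(need %in% names(df)))
    stop("station CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  ts <- as.POSIXct(df$timestamp, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%SZ", "%Y-%m-%d %H:%M:%S"))
  step <- if (nrow(df) > 1)
    as.integer(round(min(diff(as.numeric(ts))) / 3600)) else 1L
  station_series(df$station_id[1], df$lat[1], df$lon[1], ts,
                 df$temperature_C, step_hours = step)
}
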