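#' Metadata for the 19 bioclimatic variables
#'
#' Descriptions, units and integer scale factors of the 19 variables.
#' BIO1-BIO11 are temperature summaries in degrees C (stored as integers
#' after multiplying by 10); BIO12-BIO19 are specific-humidity summaries in
#' kg of water per kg of air (stored after multiplying by 100000), except
#' BIO15 which is a coefficient of variation in percent (stored after
#' multiplying by 100, since a percentage scaled by 100000 cannot fit a
#' 16-bit integer).
#'
#' @return A data frame with columns `variable`, `description`, `units`,
#'   `type` and `scale_factor`.
#' @export
bioclim_meta <- function() {
  data.frame(
    variable = paste0("BIO", 1:19),
    description = c(
      "Annual mean temperature",
      "Mean diurnal temperature range",
      "Isothermality (100 * BIO2 / BIO7)",
      "Temperature seasonality (SD of monthly means * 100)",
      "Max temperature of warmest month",
      "Min temperature of coldest month",
      "Temperature annual range (BIO5 - BIO6)",
      "Mean temperature of most humid quarter",
      "Mean temperature of least humid quarter",
      "Mean temperature of warmest quarter",
      "Mean temperature of coldest quarter",
      "Annual mean specific humidity",
      "Specific humidity of most humid month",
      "Specific humidity of least humid month",
      "Specific humidity seasonality (coefficient of variation)",
      "Mean specific humidity of most humid quarter",
      "Mean specific humidity of least humid quarter",
      "Mean specific humidity of warmest quarter",
      "Mean specific humidity of coldest quarter"),
    units = c(rep("degC", 11), rep("kg/kg", 3), "percent", rep("kg/kg", 4)),
    type = c(rep("temperature", 7), "combined", "combined", "temperature",
             "temperature", rep("water", 6), "combined", "combined"),
    scale_factor = c(rep(10, 11), rep(1e5, 3), 100, rep(1e5, 4)),
    stringsAsFactors = FALSE)
}

bioclim_vars <- function() paste0("BIO", 1:19)

#' Bioclimatic variable set
#'
#' Nineteen named layers (matrices on a common grid) for one humidity
#' version and one period, with a flag recording whether the ecological
#' rescaling of the moisture sums has been applied.
#'
#' @param grid A [grid_spec()].
#' @param version `"min"`, `"mean"` or `"max"` -- which monthly humidity
#'   series fed the moisture axis.
#' @param period Year or decade label (e.g. `1995` or `"90s"`).
#' @param layers Named list of 19 `n_rows x n_cols` matrices `BIO1..BIO19`.
#' @param rescaled Logical; `TRUE` once [apply_ecological_rescale()] has
#'   divided BIO12 by 12 and BIO16-BIO19 by 3.
#' @return An object of class `bioclim_set`.
#' @export
bioclim_set <- function(grid, version, period, layers, rescaled = FALSE) {
  stopifnot_grid(grid)
  version <- match.arg(version, c("min", "mean", "max"))
  if (!identical(sort(names(layers)), sort(bioclim_vars())))
    stop("layers must be named BIO1..BIO19", call. = FALSE)
  for (v in bioclim_vars()) {
    l <- layers[[v]]
    if (!is.matrix(l) || !identical(dim(l), c(grid$n_rows, grid$n_cols)))
      stop(sprintf("layer %s has wrong dimensions", v), call. = FALSE)
  }
  structure(list(grid = grid, version = version, period = period,
                 layers = layers[bioclim_vars()], rescaled = rescaled,
                 meta = bioclim_meta()),
            class = "bioclim_set")
}

#' @export
print.bioclim_set <- function(x, ...) {
  cat(sprintf("<bioclim_set> version V_%s, period %s, %d x %d cells (%s)\n",
              x$version, as.character(x$period), x$grid$n_rows,
              x$grid$n_cols, if (x$rescaled) "rescaled" else "pre-rescale"))
  b1 <- x$layers$BIO1
  cat(sprintf("  BIO1 range: %.2f .. %.2f degC\n",
              suppressWarnings(min(b1, na.rm = TRUE)),
              suppressWarnings(max(b1, na.rm = TRUE))))
  invisible(x)
}

#' Cyclic three-month window sums
#'
#' Window `i` (i = 1..12) is `values[i] + values[i+1] + values[i+2]` with
#' indices wrapping past December, so the window starting in month 12
#' covers months 12, 1 and 2. These windows are the "quarters" of the
#' bioclim convention.
#'
#' @param values Twelve monthly numbers.
#' @return Twelve window sums.
#' @export
cyclic_windows <- function(values) {
  if (length(values) != 12L) stop("need exactly 12 values", call. = FALSE)
  idx <- outer(0:11, 0:2, function(i, k) (i + k) %% 12L + 1L)
  as.numeric(values[idx[, 1]] + values[idx[, 2]] + values[idx[, 3]])
}

#' Select the extreme three-month window
#'
#' @param window_values Twelve window aggregates from [cyclic_windows()].
#' @param mode `"max"` or `"min"`.
#' @return The start month (1-12) of the extreme window; ties go to the
#'   earliest start month.
#' @export
select_window <- function(window_values, mode = c("max", "min")) {
  mode <- match.arg(mode)
  if (length(window_values) != 12L)
    stop("need exactly 12 window values", call. = FALSE)
  if (mode == "max") which.max(window_values) else which.min(window_values)
}

# cyclic 12x12 0/1 matrix: column i marks months {i, i+1, i+2} (wrapped)
window_matrix <- function() {
  W <- matrix(0, 12, 12)
  for (i in 1:12) W[((i - 1):(i + 1)) %% 12 + 1, i] <- 1
  W
}

row_max <- function(m) do.call(pmax, c(as.data.frame(m), na.rm = FALSE))
row_min <- function(m) do.call(pmin, c(as.data.frame(m), na.rm = FALSE))

#' Compute the 19 annual bioclimatic variables
#'
#' Applies the bioclim recipe to one year's monthly climatology, using the
#' monthly minimum, mean or maximum specific humidity as the moisture axis
#' according to `version`. Quarters are the 12 cyclic three-month windows;
#' humid/arid quarters are ranked by the window *sum* of moisture, warm and
#' cold quarters by the window mean temperature; ties go to the earliest
#' start month. The returned set is pre-rescale: BIO12 is still the
#' 12-month moisture sum and BIO16-BIO19 are window sums
#' (see [apply_ecological_rescale()]).
#'
#' @param clim A [monthly_climatology()].
#' @param version `"min"`, `"mean"` or `"max"`.
#' @param cv_offset Value added to the monthly moisture series before
#'   computing the BIO15 coefficient of variation. The default 0 keeps BIO15
#'   ecologically meaningful on kg/kg values; set 1 to emulate the classic
#'   precipitation-oriented implementation literally (on kg/kg inputs this
#'   collapses the CV towards zero, which is why 0 is the default).
#' @return A pre-rescale [bioclim_set()]. Cells with any missing monthly
#'   input are missing in all 19 layers; BIO3 is missing where the annual
#'   range BIO7 is zero, and BIO15 where the (offset) moisture mean is zero.
#' @export
annual_bioclim <- function(clim, version = c("mean", "min", "max"),
                           cv_offset = 0) {
  version <- match.arg(version)
  g <- clim$grid
  ncell <- g$n_rows * g$n_cols
  as_m <- function(a) matrix(a, ncell, 12L)
  tmin <- as_m(clim$tmin); tmax <- as_m(clim$tmax)
  moist <- as_m(switch(version, min = clim$hmin, mean = clim$hmean,
                       max = clim$hmax))
  bad <- rowSums(is.na(tmin) | is.na(tmax) | is.na(moist)) > 0
  tmin[bad, ] <- 0; tmax[bad, ] <- 0; moist[bad, ] <- 0

  tavg <- (tmin + tmax) / 2
  W <- window_matrix()
  wsum_m <- moist %*% W          # moisture sum per window
  wmean_t <- (tavg %*% W) / 3    # mean temperature per window

  bio1 <- rowMeans(tavg)
  bio2 <- rowMeans(tmax - tmin)
  bio4 <- 100 * sqrt(rowSums((tavg - bio1)^2) / 11)
  bio5 <- row_max(tmax)
  bio6 <- row_min(tmin)
  bio7 <- bio5 - bio6
  bio3 <- ifelse(bio7 == 0, NA_real_, 100 * bio2 / bio7)

  i_all <- seq_len(ncell)
  humid_start <- max.col(wsum_m, ties.method = "first")
  arid_start <- max.col(-wsum_m, ties.method = "first")
  warm_start <- max.col(wmean_t, ties.method = "first")
  cold_start <- max.col(-wmean_t, ties.method = "first")

  bio8 <- wmean_t[cbind(i_all, humid_start)]
  bio9 <- wmean_t[cbind(i_all, arid_start)]
  bio10 <- wmean_t[cbind(i_all, warm_start)]
  bio11 <- wmean_t[cbind(i_all, cold_start)]

  bio12 <- rowSums(moist)
  bio13 <- row_max(moist)
  bio14 <- row_min(moist)
  ms <- moist + cv_offset
  msd <- sqrt(rowSums((ms - rowMeans(ms))^2) / 11)
  mmean <- rowMeans(ms)
  bio15 <- ifelse(mmean == 0, NA_real_, 100 * msd / mmean)
  bio16 <- wsum_m[cbind(i_all, humid_start)]
  bio17 <- wsum_m[cbind(i_all, arid_start)]
  bio18 <- wsum_m[cbind(i_all, warm_start)]
  bio19 <- wsum_m[cbind(i_all, cold_start)]

  vals <- list(BIO1 = bio1, BIO2 = bio2, BIO3 = bio3, BIO4 = bio4,
               BIO5 = bio5, BIO6 = bio6, BIO7 = bio7, BIO8 = bio8,
               BIO9 = bio9, BIO10 = bio10, BIO11 = bio11, BIO12 = bio12,
               BIO13 = bio13, BIO14 = bio14, BIO15 = bio15, BIO16 = bio16,
               BIO17 = bio17, BIO18 = bio18, BIO19 = bio19)
  layers <- lapply(vals, function(v) {
    v[bad] <- NA_real_
    matrix(v, g$n_rows, g$n_cols)
  })
  bioclim_set(g, version, clim$year, layers, rescaled = FALSE)
}

#' Rescale moisture sums to ecologically meaningful means
#'
#' The bioclim recipe was designed for cumulative precipitation; on a
#' specific-humidity moisture axis the sums have no ecological meaning, so
#' the annual sum BIO12 is divided by 12 (annual *mean* humidity) and the
#' quarterly sums BIO16-BIO19 by 3 (quarterly means). Temperature variables
#' are unchanged. Applying the rescale twice is an error.
#'
#' @param raw A pre-rescale [bioclim_set()].
#' @return The rescaled [bioclim_set()].
#' @export
apply_ecological_rescale <- function(raw) {
  if (!inherits(raw, "bioclim_set")) stop("expected a bioclim_set", call. = FALSE)
  if (isTRUE(raw$rescaled))
    stop("ecological rescale already applied", call. = FALSE)
  raw$layers$BIO12 <- raw$layers$BIO12 / 12
  for (v in c("BIO16", "BIO17", "BIO18", "BIO19"))
    raw$layers[[v]] <- raw$layers[[v]] / 3
  raw$rescaled <- TRUE
  raw
}

#' Average annual bioclimatic sets into a decadal set
#'
#' @param annuals List of [bioclim_set()]s on the same grid, same version,
#'   and the same rescale state.
#' @param period Label for the result (e.g. `"80s"`).
#' @return A [bioclim_set()] whose layers are cellwise arithmetic means.
#' @export
decadal_mean <- function(annuals, period = "decade") {
  if (length(annuals) < 1) stop("need at least one annual set", call. = FALSE)
  ref <- annuals[[1]]
  for (s in annuals[-1]) {
    if (!grids_equal(ref$grid, s$grid))
      stop("annual sets are on different grids", call. = FALSE)
    if (!identical(ref$version, s$version))
      stop("annual sets mix humidity versions", call. = FALSE)
    if (!identical(ref$rescaled, s$rescaled))
      stop("annual sets mix rescaled and pre-rescale states", call. = FALSE)
  }
  n <- length(annuals)
  layers <- lapply(bioclim_vars(), function(v)
    Reduce(`+`, lapply(annuals, function(s) s$layers[[v]])) / n)
  names(layers) <- bioclim_vars()
  bioclim_set(ref$grid, ref$version, period, layers, rescaled = ref$rescaled)
}

#' Years belonging to a decade label
#'
#' The three decades partition 1981-01-01 .. 2010-12-31: `"80s"` is
#' 1981-1990, `"90s"` 1991-2000 and `"00s"` 2001-2010.
#'
#' @param decade `"80s"`, `"90s"` or `"00s"`.
#' @return Integer vector of ten years.
#' @export
decade_years <- function(decade = c("80s", "90s", "00s")) {
  decade <- match.arg(decade)
  switch(decade, "80s" = 1981:1990, "90s" = 1991:2000, "00s" = 2001:2010)
}
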