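#' Build decadal bioclimatic GeoTIFF folders from hourly NetCDF files
#'
#' End-to-end driver: reads hourly cubes, builds one monthly climatology
#' per year, computes annual bioclimatic sets for each requested humidity
#' version, applies the ecological rescale, averages years into a decadal
#' set, downscales to the requested arc-minute resolutions with the
#' regularized spline, quantizes to integers and writes the GeoTIFF folder
#' tree under the naming convention. Rescaling precedes quantization so no
#' precision is lost to integer division.
#'
#' @param paths Hourly NetCDF file path(s) covering the years.
#' @param decade `"80s"`, `"90s"` or `"00s"`.
#' @param years Years to aggregate (default [decade_years()] of `decade`).
#'   Every year must be fully covered by the input files.
#' @param versions Humidity versions to build (subset of
#'   `c("min", "mean", "max")`).
#' @param resolutions Output resolutions in arc-minutes.
#' @param out_dir Output directory.
#' @param params A [spline_params()].
#' @param cv_offset Passed to [annual_bioclim()].
#' @param temp_var,hum_var NetCDF variable names.
#' @param extent Optional target extent `c(lon_min, lon_max, lat_min,
#'   lat_max)`; defaults to the native extent.
#' @param verbose Log per-stage progress and cell counts.
#' @return Invisibly, the character vector of written folder paths.
#' @export
build_bioclim_rasters <- function(paths, decade, years = decade_years(decade),
                                  versions = c("min", "mean", "max"),
                                  resolutions = c(10, 5, 2.5),
                                  out_dir = ".", params = spline_params(),
                                  cv_offset = 0, temp_var = "T2M",
                                  hum_var = "QV2M", extent = NULL,
                                  verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()
  cube <- read_hourly_netcdf(paths, temp_var = temp_var, hum_var = hum_var)
  say("read %d hourly records on a %d x %d grid [%.1fs]",
      length(cube$time), cube$grid$n_rows, cube$grid$n_cols,
      as.numeric(Sys.time() - t0, units = "secs"))
  clims <- lapply(years, function(y) build_year_climatology(cube, y))
  say("built %d annual climatologies", length(clims))
  folders <- character(0)
  for (ver in versions) {
    annuals <- lapply(clims, function(cl)
      apply_ecological_rescale(annual_bioclim(cl, version = ver,
                                              cv_offset = cv_offset)))
    dec <- decadal_mean(annuals, period = decade)
    say("version V_%s: decadal set ready", ver)
    down <- downscale_set(dec, resolutions = resolutions, params = params,
                          extent = extent)
    for (res in names(down))
      say("version V_%s at %s arc-min: %d x %d cells", ver, res,
          down[[res]]$grid$n_rows, down[[res]]$grid$n_cols)
    folders <- c(folders,
                 package_decade(down, decade = decade, version = ver,
                                dir = out_dir))
  }
  say("wrote %d folder(s) under %s [total %.1fs]", length(folders), out_dir,
      as.numeric(Sys.time() - t0, units = "secs"))
  invisible(folders)
}
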