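#' Integer quantization rule for a bioclimatic variable
#'
#' Temperature variables (BIO1-BIO11) are stored as `value * 10`, humidity
#' variables (BIO12-BIO19) as `value * 100000`, except the dimensionless
#' BIO15 (a coefficient of variation in percent) which is stored as
#' `value * 100` so it fits a signed 16-bit integer. Rounding is
#' half-away-from-zero; missing cells map to the `nodata` sentinel.
#'
#' @param variable `"BIO1"` .. `"BIO19"`.
#' @param nodata Sentinel integer (default -32768).
#' @return An object of class `quantization_rule`.
#' @export
quantization_rule <- function(variable, nodata = -32768L) {
  meta <- bioclim_meta()
  i <- match(variable, meta$variable)
  if (is.na(i)) stop(sprintf("unknown variable '%s'", variable), call. = FALSE)
  structure(list(variable = variable, scale_factor = meta$scale_factor[i],
                 nodata = as.integer(nodata), rounding = "half-away-from-zero"),
            class = "quantization_rule")
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Quantize a float layer to 16-bit integers
#'
#' @param layer Numeric matrix (NA = missing).
#' @param rule A [quantization_rule()].
#' @return Integer matrix with an attribute `nodata`; missing cells hold
#'   the sentinel. Scaled magnitudes above 32767 raise an overflow error
#'   naming the first offending cell and value (no silent wraparound).
#' @export
quantize <- function(layer, rule) {
  if (!inherits(rule, "quantization_rule"))
    stop("expected a quantization_rule", call. = FALSE)
  scaled <- round_half_away(layer * rule$scale_factor)
  over <- which(abs(scaled) > 32767)
  if (length(over)) {
    rc <- arrayInd(over[1], dim(layer))
    stop(sprintf(
      "quantization overflow for %s at cell (%d, %d): %g x %g = %g exceeds int16",
      rule$variable, rc[1], rc[2], layer[over[1]], rule$scale_factor,
      scaled[over[1]]), call. = FALSE)
  }
  out <- matrix(as.integer(scaled), nrow(layer), ncol(layer))
  out[is.na(layer)] <- rule$nodata
  attr(out, "nodata") <- rule$nodata
  attr(out, "scale_factor") <- rule$scale_factor
  out
}

#' @rdname quantize
#' @param q Integer matrix from [quantize()].
#' @return `dequantize()` returns the float layer `q / scale_factor` with
#'   sentinel cells set to NA; the round trip error is at most half a
#'   quantum, `0.5 / scale_factor`.
#' @export
dequantize <- function(q, rule) {
  out <- q * 1.0
  out[q == rule$nodata] <- NA_real_
  out / rule$scale_factor
}

res_tags <- c(`10` = "10m", `5` = "5m", `2.5` = "2_5m")

#' Layer naming convention
#'
#' Rendered file names follow `resolution_version_decade_BIOn.tif`, e.g.
#' `10m_min_00s_BIO1.tif`; 2.5 arc-minutes renders as `2_5m`.
#'
#' @param resolution `"10m"`, `"5m"` or `"2_5m"` (numeric 10, 5, 2.5 also
#'   accepted).
#' @param version `"min"`, `"mean"` or `"max"`.
#' @param decade `"80s"`, `"90s"` or `"00s"`.
#' @param variable `"BIO1"` .. `"BIO19"`.
#' @return An object of class `layer_name`.
#' @export
layer_name <- function(resolution, version, decade, variable) {
  if (is.numeric(resolution)) {
    resolution <- res_tags[as.character(resolution)]
    if (is.na(resolution)) stop("resolution must be 10, 5 or 2.5", call. = FALSE)
  }
  resolution <- match.arg(resolution, c("10m", "5m", "2_5m"))
  version <- match.arg(version, c("min", "mean", "max"))
  decade <- match.arg(decade, c("80s", "90s", "00s"))
  variable <- match.arg(variable, bioclim_vars())
  structure(list(resolution = resolution, version = version,
                 decade = decade, variable = variable),
            class = "layer_name")
}

#' @rdname layer_name
#' @param name A `layer_name`.
#' @return `render_name()` gives the file name string.
#' @export
render_name <- function(name) {
  paste0(name$resolution, "_", name$version, "_", name$decade, "_",
         name$variable, ".tif")
}

#' @rdname layer_name
#' @param filename A rendered file name.
#' @return `parse_name()` inverts [render_name()].
#' @export
parse_name <- function(filename) {
  base <- sub("\\.tif$", "", basename(filename))
  m <- regmatches(base, regexec(
    "^(10m|5m|2_5m)_(min|mean|max)_(80s|90s|00s)_(BIO[0-9]+)$", base))[[1]]
  if (length(m) != 5 || !m[5] %in% bioclim_vars())
    stop(sprintf("'%s' does not follow the naming convention", filename),
         call. = FALSE)
  layer_name(m[2], m[3], m[4], m[5])
}

#' @export
print.layer_name <- function(x, ...) {
  cat("<layer_name>", render_name(x), "\n")
  invisible(x)
}

#' Write a quantized layer as a GeoTIFF
#'
#' Writes an uncompressed single-band signed 16-bit GeoTIFF in geographic
#' WGS 84 coordinates, north-up, with the nodata sentinel tagged. The file
#' name follows the naming convention of [layer_name()].
#'
#' @param layer Integer matrix from [quantize()].
#' @param grid The layer's [grid_spec()].
#' @param name A [layer_name()].
#' @param dir Output directory (created if needed).
#' @param nodata Sentinel (defaults to the layer's `nodata` attribute).
#' @return The file path, invisibly.
#' @export
write_geotiff <- function(layer, grid, name, dir, nodata = NULL) {
  if (!inherits(name, "layer_name")) stop("expected a layer_name", call. = FALSE)
  nodata <- as.integer(nodata %||% attr(layer, "nodata") %||% -32768L)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(dir, render_name(name))
  geotiff_write(path, layer, grid, nodata = nodata)
  invisible(path)
}

#' Read a GeoTIFF written by this package
#'
#' @param path File path.
#' @return A list with `values` (integer matrix, sentinel replaced by NA),
#'   `grid` ([grid_spec()]) and `nodata`.
#' @export
read_geotiff <- function(path) geotiff_read(path)

#' Package a decade of downscaled sets as GeoTIFF folders
#'
#' Creates one folder per resolution named `resolution_version_decade`
#' (e.g. `10m_min_00s`) containing the 19 quantized GeoTIFFs, and
#' optionally zips each folder.
#'
#' @param sets Named list mapping resolution (`"10"`, `"5"`, `"2.5"`) to a
#'   rescaled [bioclim_set()], as from [downscale_set()].
#' @param decade `"80s"`, `"90s"` or `"00s"`.
#' @param version `"min"`, `"mean"` or `"max"`.
#' @param dir Output directory.
#' @param zip Also produce `<folder>.zip` next to each folder (requires a
#'   `zip` tool on the PATH; warns and skips otherwise).
#' @return Character vector of folder paths, invisibly.
#' @export
package_decade <- function(sets, decade, version, dir, zip = FALSE) {
  folders <- character(0)
  for (res in names(sets)) {
    set <- sets[[res]]
    if (!inherits(set, "bioclim_set"))
      stop("each element of sets must be a bioclim_set", call. = FALSE)
    missing_vars <- setdiff(bioclim_vars(), names(set$layers))
    if (length(missing_vars))
      stop("incomplete set: missing ", paste(missing_vars, collapse = ", "),
           call. = FALSE)
    rtag <- res_tags[res]
    if (is.na(rtag)) stop("resolutions must be named 10, 5 or 2.5", call. = FALSE)
    folder <- file.path(dir, paste(rtag, version, decade, sep = "_"))
    dir.create(folder, recursive = TRUE, showWarnings = FALSE)
    for (v in bioclim_vars()) {
      rule <- quantization_rule(v)
      q <- quantize(set$layers[[v]], rule)
      write_geotiff(q, set$grid, layer_name(rtag, version, decade, v), folder)
    }
    if (zip) {
      if (nzchar(Sys.which("zip"))) {
        owd <- setwd(dir); on.exit(setwd(owd), add = TRUE)
        utils::zip(paste0(basename(folder), ".zip"), basename(folder),
                   flags = "-rq")
        setwd(owd)
      } else warning("no 'zip' tool on PATH; folder left unzipped")
    }
    folders <- c(folders, folder)
  }
  invisible(folders)
}
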