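#' Parameters of the regularized thin-plate-spline interpolator
#'
#' @param weight Non-negative regularization added to the spline kernel
#'   diagonal. 0 gives exact interpolation through the source cell values;
#'   larger values smooth. Affine fields (and thus constants) are
#'   reproduced exactly for any weight. Default 0.1 mirrors the documented
#'   default of the GIS regularized-spline tool this emulates.
#' @param n_neighbors Number of nearest source cells fitted per target cell
#'   (at least 4; default 12, the same tool's default).
#' @param longitude_wrap Treat longitude as periodic across the
#'   antimeridian (use `TRUE` for global grids).
#' @return An object of class `spline_params`.
#' @export
spline_params <- function(weight = 0.1, n_neighbors = 12L,
                          longitude_wrap = FALSE) {
  if (!is.finite(weight) || weight < 0)
    stop("weight must be non-negative", call. = FALSE)
  n_neighbors <- as.integer(n_neighbors)
  if (n_neighbors < 4L) stop("n_neighbors must be at least 4", call. = FALSE)
  structure(list(weight = weight, n_neighbors = n_neighbors,
                 longitude_wrap = isTRUE(longitude_wrap)),
            class = "spline_params")
}

#' Build a target grid at an arc-minute resolution
#'
#' @param resolution Cell size in arc-minutes. 10, 5 and 2.5 are the
#'   intended output resolutions; other values are allowed with a warning.
#' @param extent Numeric vector `c(lon_min, lon_max, lat_min, lat_max)` in
#'   degrees (default global).
#' @return A cell-edge registered [grid_spec()] covering the extent.
#' @export
build_target_grid <- function(resolution, extent = c(-180, 180, -90, 90)) {
  if (!resolution %in% c(10, 5, 2.5))
    warning(sprintf("non-standard resolution %s arc-minutes", resolution))
  if (length(extent) != 4 || extent[2] <= extent[1] || extent[4] <= extent[3])
    stop("extent must be c(lon_min, lon_max, lat_min, lat_max) and non-empty",
         call. = FALSE)
  step <- resolution / 60
  n_cols <- as.integer(round((extent[2] - extent[1]) / step))
  n_rows <- as.integer(round((extent[4] - extent[3]) / step))
  if (n_cols < 1 || n_rows < 1) stop("empty extent", call. = FALSE)
  grid_spec(n_rows, n_cols, lat_step = step, lon_step = step,
            lat_origin = extent[4], lon_origin = extent[1])
}

#' Interpolate a single layer to a target grid
#'
#' Fits a local regularized thin-plate spline to the `n_neighbors` nearest
#' non-missing source cell centers of every target cell center and
#' evaluates it there. Coordinates are treated in plain degrees; with
#' `longitude_wrap` the neighbor search and distances wrap across the
#' antimeridian. Degenerate neighborhoods fall back to inverse-distance
#' weighting with a warning.
#'
#' @param layer Numeric matrix on `source` (NA = missing).
#' @param source,target [grid_spec()]s.
#' @param params A [spline_params()].
#' @return Numeric matrix on `target`.
#' @export
spline_interpolate <- function(layer, source, target,
                               params = spline_params()) {
  stopifnot_grid(source); stopifnot_grid(target)
  if (!is.matrix(layer) ||
      !identical(dim(layer), c(source$n_rows, source$n_cols)))
    stop("layer dimensions do not match the source grid", call. = FALSE)
  n_valid <- sum(!is.na(layer))
  if (n_valid == 0) stop("layer is entirely missing", call. = FALSE)
  if (n_valid < params$n_neighbors)
    stop(sprintf("layer has %d non-missing cells; need at least %d",
                 n_valid, params$n_neighbors), call. = FALSE)
  res <- tps_interpolate_cpp(grid_lats(source), grid_lons(source), layer,
                             grid_lats(target), grid_lons(target),
                             params$weight, params$n_neighbors,
                             params$longitude_wrap)
  if (res$n_idw_fallback > 0)
    warning(sprintf(
      "%d degenerate spline neighborhood(s); used inverse-distance weighting",
      res$n_idw_fallback))
  res$values
}

#' Downscale a bioclimatic set to one or more resolutions
#'
#' Applies [spline_interpolate()] to each of the 19 float layers (before
#' any integer quantization) for each requested resolution.
#'
#' @param set A [bioclim_set()].
#' @param resolutions Numeric vector of arc-minute resolutions
#'   (default `c(10, 5, 2.5)`).
#' @param params A [spline_params()].
#' @param extent Target extent `c(lon_min, lon_max, lat_min, lat_max)`;
#'   defaults to the source set's own extent.
#' @return A named list (one element per resolution, e.g. `"10"`, `"5"`,
#'   `"2.5"`) of [bioclim_set()]s with metadata propagated.
#' @export
downscale_set <- function(set, resolutions = c(10, 5, 2.5),
                          params = spline_params(), extent = NULL) {
  if (!inherits(set, "bioclim_set")) stop("expected a bioclim_set", call. = FALSE)
  g <- set$grid
  if (is.null(extent))
    extent <- c(g$lon_origin, g$lon_origin + g$n_cols * g$lon_step,
                g$lat_origin - g$n_rows * g$lat_step, g$lat_origin)
  out <- lapply(resolutions, function(res) {
    tg <- build_target_grid(res, extent)
    layers <- lapply(set$layers, spline_interpolate, source = g,
                     target = tg, params = params)
    bioclim_set(tg, set$version, set$period, layers, rescaled = set$rescaled)
  })
  names(out) <- as.character(resolutions)
  out
}
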