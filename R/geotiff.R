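# Minimal single-band int16 GeoTIFF codec: baseline little-endian TIFF with
# one strip, plus the GeoTIFF tags (ModelPixelScale, ModelTiepoint,
# GeoKeyDirectory declaring geographic WGS 84, pixel-is-area) and the
# GDAL_NODATA ascii tag. Uncompressed only.

TIFF_SHORT <- 3L; TIFF_LONG <- 4L; TIFF_ASCII <- 2L; TIFF_DOUBLE <- 12L

geotiff_write <- function(path, values, grid, nodata = -32768L) {
  stopifnot_grid(grid)
  if (!is.matrix(values) ||
      !identical(dim(values), c(grid$n_rows, grid$n_cols)))
    stop("values matrix does not match the grid", call. = FALSE)
  v <- values
  v[is.na(v)] <- nodata
  v <- matrix(as.integer(round(v)), nrow(values), ncol(values))
  if (any(v < -32768 | v > 32767))
    stop("values out of int16 range", call. = FALSE)

  w <- grid$n_cols; h <- grid$n_rows
  nodata_str <- c(charToRaw(as.character(nodata)), as.raw(0))
  if (length(nodata_str) %% 2L) nodata_str <- c(nodata_str, as.raw(0))
  geokeys <- as.integer(c(1, 1, 0, 3,
                          1024, 0, 1, 2,    # geographic model
                          1025, 0, 1, 1,    # pixel is area
                          2048, 0, 1, 4326))# WGS 84
  pixscale <- c(grid$lon_step, grid$lat_step, 0)
  tiepoint <- c(0, 0, 0, grid$lon_origin, grid$lat_origin, 0)

  n_entries <- 15L
  ifd_off <- 8L
  ifd_size <- 2L + n_entries * 12L + 4L
  off_pix <- ifd_off + ifd_size
  off_tie <- off_pix + 24L
  off_geo <- off_tie + 48L
  off_nod <- off_geo + 2L * length(geokeys)
  off_data <- off_nod + length(nodata_str)
  if (off_data %% 2L) off_data <- off_data + 1L

  con <- file(path, "wb")
  on.exit(close(con))
  wr16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  wr32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  entry <- function(tag, type, count, value, inline = TRUE) {
    wr16(tag); wr16(type); wr32(count)
    if (inline && type == TIFF_SHORT) { wr16(value); wr16(0L) }
    else wr32(value)
  }
  writeBin(charToRaw("II"), con); wr16(42L); wr32(ifd_off)
  wr16(n_entries)
  entry(256L, TIFF_LONG, 1L, w)
  entry(257L, TIFF_LONG, 1L, h)
  entry(258L, TIFF_SHORT, 1L, 16L)
  entry(259L, TIFF_SHORT, 1L, 1L)
  entry(262L, TIFF_SHORT, 1L, 1L)
  entry(273L, TIFF_LONG, 1L, off_data)
  entry(277L, TIFF_SHORT, 1L, 1L)
  entry(278L, TIFF_LONG, 1L, h)
  entry(279L, TIFF_LONG, 1L, w * h * 2L)
  entry(284L, TIFF_SHORT, 1L, 1L)
  entry(339L, TIFF_SHORT, 1L, 2L)
  entry(33550L, TIFF_DOUBLE, 3L, off_pix)
  entry(33922L, TIFF_DOUBLE, 6L, off_tie)
  entry(34735L, TIFF_SHORT, length(geokeys), off_geo)
  entry(42113L, TIFF_ASCII, length(nodata_str), off_nod)
  wr32(0L)  # next IFD
  writeBin(pixscale, con, size = 8, endian = "little")
  writeBin(tiepoint, con, size = 8, endian = "little")
  wr16(geokeys)
  writeBin(nodata_str, con)
  if (seek(con, NA) < off_data) writeBin(as.raw(0), con)
  # row-major, top row first
  writeBin(as.integer(t(v)), con, size = 2, endian = "little")
  invisible(path)
}

geotiff_read <- function(path) {
  raw_all <- readBin(path, raw(), file.info(path)$size)
  con <- rawConnection(raw_all)
  on.exit(close(con))
  order_bytes <- rawToChar(readBin(con, raw(), 2))
  endian <- if (order_bytes == "II") "little" else if (order_bytes == "MM")
    "big" else stop("not a TIFF file", call. = FALSE)
  rd16 <- function(n = 1) readBin(con, integer(), n, size = 2,
                                  endian = endian, signed = FALSE)
  rd32 <- function(n = 1) readBin(con, integer(), n, size = 4, endian = endian)
  if (rd16() != 42L) stop("not a TIFF file", call. = FALSE)
  seek(con, rd32())
  n_entries <- rd16()
  tags <- list()
  for (i in seq_len(n_entries)) {
    tag <- rd16(); type <- rd16(); count <- rd32()
    value_raw <- readBin(con, raw(), 4)
    tags[[as.character(tag)]] <- list(type = type, count = count,
                                      raw = value_raw)
  }
  get_vals <- function(tag, default = NULL) {
    e <- tags[[as.character(tag)]]
    if (is.null(e)) return(default)
    type_size <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `12` = 8L)
    sz <- type_size[[as.character(e$type)]]
    vcon <- NULL
    if (e$count * sz > 4) {
      off <- readBin(e$raw, integer(), 1, size = 4, endian = endian)
      seek(con, off)
      src <- con
    } else {
      vcon <- rawConnection(e$raw)
      src <- vcon
    }
    out <- switch(as.character(e$type),
      `2` = {
        b <- readBin(src, raw(), e$count)
        nul <- which(b == as.raw(0))
        if (length(nul)) b <- b[seq_len(min(nul) - 1L)]
        rawToChar(b)
      },
      `3` = readBin(src, integer(), e$count, size = 2, endian = endian,
                    signed = FALSE),
      `4` = readBin(src, integer(), e$count, size = 4, endian = endian),
      `12` = readBin(src, numeric(), e$count, size = 8, endian = endian),
      readBin(src, integer(), e$count, size = 1, signed = FALSE))
    if (!is.null(vcon)) close(vcon)
    out
  }
  w <- get_vals(256L); h <- get_vals(257L)
  bps <- get_vals(258L, 16L); fmt <- get_vals(339L, 1L)
  if (bps != 16L || fmt != 2L)
    stop("only int16 single-band rasters are supported", call. = FALSE)
  comp <- get_vals(259L, 1L)
  if (comp != 1L) stop("compressed TIFFs are not supported", call. = FALSE)
  offsets <- get_vals(273L); counts <- get_vals(279L)
  rps <- get_vals(278L, h)
  pix <- numeric(0)
  for (s in seq_along(offsets)) {
    seek(con, offsets[s])
    pix <- c(pix, readBin(con, integer(), counts[s] / 2L, size = 2,
                          endian = endian, signed = TRUE))
  }
  m <- matrix(as.integer(pix), nrow = h, ncol = w, byrow = TRUE)
  scale <- get_vals(33550L)
  tie <- get_vals(33922L)
  if (is.null(scale) || is.null(tie))
    stop("missing georeferencing tags", call. = FALSE)
  grid <- grid_spec(h, w, lat_step = scale[2], lon_step = scale[1],
                    lat_origin = tie[5] + tie[2] * scale[2],
                    lon_origin = tie[4] - tie[1] * scale[1])
  nodata <- suppressWarnings(as.integer(get_vals(42113L, NA)))
  if (!is.na(nodata)) m[m == nodata] <- NA_integer_
  geokeys <- get_vals(34735L)
  list(values = m, grid = grid, nodata = nodata, geokeys = geokeys)
}
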