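# Minimal NetCDF-3 "classic" (CDF-1) codec.
#
# Supports exactly the subset this package needs for CF-style hourly cubes:
# fixed (non-record) dimensions, numeric and character attributes, and
# variables of type char/short/int/float/double stored contiguously in
# big-endian row-major order (last dimension varies fastest). No record
# dimension, no CDF-2/5 offsets, no HDF5-backed NetCDF-4.

NC_BYTE <- 1L; NC_CHAR <- 2L; NC_SHORT <- 3L; NC_INT <- 4L
NC_FLOAT <- 5L; NC_DOUBLE <- 6L
nc_type_size <- c(1L, 1L, 2L, 4L, 4L, 8L)

nc3_pad4 <- function(n) (4L - (n %% 4L)) %% 4L

nc3_name_raw <- function(name) {
  b <- charToRaw(name)
  c(writeBin(length(b), raw(), size = 4, endian = "big"), b,
    raw(nc3_pad4(length(b))))
}

nc3_values_raw <- function(type, values) {
  if (type == NC_CHAR) {
    b <- charToRaw(paste(values, collapse = ""))
    c(writeBin(length(b), raw(), size = 4, endian = "big"), b,
      raw(nc3_pad4(length(b))))
  } else {
    n <- length(values)
    sz <- nc_type_size[type]
    body <- if (type %in% c(NC_FLOAT, NC_DOUBLE))
      writeBin(as.numeric(values), raw(), size = sz, endian = "big")
    else
      writeBin(as.integer(values), raw(), size = sz, endian = "big")
    c(writeBin(n, raw(), size = 4, endian = "big"), body,
      raw(nc3_pad4(length(body))))
  }
}

nc3_att_list_raw <- function(atts) {
  if (length(atts) == 0)
    return(writeBin(c(0L, 0L), raw(), size = 4, endian = "big"))
  out <- writeBin(c(12L, length(atts)), raw(), size = 4, endian = "big")
  for (nm in names(atts)) {
    v <- atts[[nm]]
    type <- if (is.character(v)) NC_CHAR else NC_DOUBLE
    out <- c(out, nc3_name_raw(nm),
             writeBin(type, raw(), size = 4, endian = "big"),
             nc3_values_raw(type, v))
  }
  out
}

# dims: named integer vector of lengths; vars: list of
# list(name, type, dims = character names, data = vector in row-major
# order, atts = named list); gatts: named list.
nc3_write <- function(path, dims, vars, gatts = list()) {
  dim_names <- names(dims)
  header_for <- function(begins) {
    h <- c(charToRaw("CDF"), as.raw(1L),
           writeBin(0L, raw(), size = 4, endian = "big"))   # numrecs
    h <- c(h, writeBin(c(10L, length(dims)), raw(), size = 4, endian = "big"))
    for (i in seq_along(dims))
      h <- c(h, nc3_name_raw(dim_names[i]),
             writeBin(as.integer(dims[i]), raw(), size = 4, endian = "big"))
    h <- c(h, nc3_att_list_raw(gatts))
    h <- c(h, writeBin(c(11L, length(vars)), raw(), size = 4, endian = "big"))
    for (i in seq_along(vars)) {
      v <- vars[[i]]
      dimids <- match(v$dims, dim_names) - 1L
      if (anyNA(dimids)) stop("variable refers to unknown dimension")
      n <- prod(dims[v$dims])
      vsize <- as.integer(n * nc_type_size[v$type])
      vsize <- vsize + nc3_pad4(vsize)
      h <- c(h, nc3_name_raw(v$name),
             writeBin(length(dimids), raw(), size = 4, endian = "big"),
             writeBin(as.integer(dimids), raw(), size = 4, endian = "big"),
             nc3_att_list_raw(v$atts %||% list()),
             writeBin(c(v$type, vsize, as.integer(begins[i])), raw(),
                      size = 4, endian = "big"))
    }
    h
  }
  hlen <- length(header_for(integer(length(vars))))
  begins <- integer(length(vars))
  off <- hlen
  for (i in seq_along(vars)) {
    begins[i] <- off
    n <- prod(dims[vars[[i]]$dims])
    sz <- as.integer(n * nc_type_size[vars[[i]]$type])
    off <- off + sz + nc3_pad4(sz)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(header_for(begins), con)
  for (v in vars) {
    sz <- nc_type_size[v$type]
    if (v$type == NC_CHAR) {
      b <- charToRaw(paste(v$data, collapse = ""))
      writeBin(b, con)
      writeBin(raw(nc3_pad4(length(b))), con)
    } else if (v$type %in% c(NC_FLOAT, NC_DOUBLE)) {
      writeBin(as.numeric(v$data), con, size = sz, endian = "big")
      nb <- length(v$data) * sz
      writeBin(raw(nc3_pad4(nb)), con)
    } else {
      writeBin(as.integer(v$data), con, size = sz, endian = "big")
      nb <- length(v$data) * sz
      writeBin(raw(nc3_pad4(nb)), con)
    }
  }
  invisible(path)
}

nc3_read <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd_int <- function(n = 1) readBin(con, integer(), n, size = 4, endian = "big")
  rd_name <- function() {
    n <- rd_int()
    s <- rawToChar(readBin(con, raw(), n))
    readBin(con, raw(), nc3_pad4(n))
    s
  }
  rd_values <- function(type) {
    n <- rd_int()
    sz <- nc_type_size[type]
    v <- switch(as.character(type),
      "2" = {
        s <- rawToChar(readBin(con, raw(), n)); readBin(con, raw(), nc3_pad4(n)); s
      },
      "5" = , "6" = {
        x <- readBin(con, numeric(), n, size = sz, endian = "big")
        readBin(con, raw(), nc3_pad4(n * sz)); x
      },
      {
        x <- readBin(con, integer(), n, size = sz, endian = "big",
                     signed = TRUE)
        readBin(con, raw(), nc3_pad4(n * sz)); x
      })
    v
  }
  rd_atts <- function() {
    tag <- rd_int(); natt <- rd_int()
    if (tag == 0L && natt == 0L) return(list())
    if (tag != 12L) stop("malformed NetCDF attribute list", call. = FALSE)
    out <- list()
    for (i in seq_len(natt)) {
      nm <- rd_name(); type <- rd_int()
      out[[nm]] <- rd_values(type)
    }
    out
  }
  magic <- readBin(con, raw(), 4)
  if (!identical(magic[1:3], charToRaw("CDF")) || as.integer(magic[4]) != 1L)
    stop("not a NetCDF-3 classic (CDF-1) file", call. = FALSE)
  numrecs <- rd_int()
  tag <- rd_int(); ndims <- rd_int()
  dims <- integer(0)
  if (tag == 10L) {
    dnames <- character(ndims); dlens <- integer(ndims)
    for (i in seq_len(ndims)) { dnames[i] <- rd_name(); dlens[i] <- rd_int() }
    dims <- stats::setNames(dlens, dnames)
  } else if (!(tag == 0L && ndims == 0L))
    stop("malformed NetCDF dimension list", call. = FALSE)
  if (any(dims == 0L) && numrecs > 0L)
    stop("record (unlimited) dimensions are not supported", call. = FALSE)
  gatts <- rd_atts()
  tag <- rd_int(); nvars <- rd_int()
  if (!(tag == 11L || (tag == 0L && nvars == 0L)))
    stop("malformed NetCDF variable list", call. = FALSE)
  vars <- list()
  meta <- vector("list", nvars)
  for (i in seq_len(nvars)) {
    nm <- rd_name()
    nd <- rd_int()
    dimids <- if (nd > 0) rd_int(nd) + 1L else integer(0)
    atts <- rd_atts()
    type <- rd_int(); vsize <- rd_int(); begin <- rd_int()
    meta[[i]] <- list(name = nm, type = type, dimids = dimids,
                      atts = atts, begin = begin)
  }
  for (m in meta) {
    seek(con, m$begin)
    n <- prod(dims[m$dimids])
    sz <- nc_type_size[m$type]
    data <- switch(as.character(m$type),
      "2" = rawToChar(readBin(con, raw(), n)),
      "5" = , "6" = readBin(con, numeric(), n, size = sz, endian = "big"),
      "3" = readBin(con, integer(), n, size = 2, endian = "big",
                    signed = TRUE),
      readBin(con, integer(), n, size = sz, endian = "big"))
    vars[[m$name]] <- list(data = data, dims = names(dims)[m$dimids],
                           dimlens = unname(dims[m$dimids]), atts = m$atts,
                           type = m$type)
  }
  list(dims = dims, vars = vars, gatts = gatts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# CF time units "<unit> since <origin>" -> POSIXct
nc3_decode_time <- function(values, units) {
  m <- regmatches(units, regexec("^(seconds|minutes|hours|days) since (.+)$",
                                 units))[[1]]
  if (length(m) != 3)
    stop(sprintf("unsupported time units '%s'", units), call. = FALSE)
  mult <- c(seconds = 1, minutes = 60, hours = 3600, days = 86400)[m[2]]
  origin <- as.POSIXct(m[3], tz = "UTC",
                       tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d"))
  origin + values * mult
}

#' Write an hourly cube as CF-style NetCDF
#'
#' Emits a NetCDF-3 classic file with dimensions `time`, `lat`, `lon`,
#' coordinate variables (`time` in hours since the first timestamp, `lat`
#' and `lon` cell centers in degrees) and the data variables `T2M`
#' (temperature, K, 32-bit float) and `QV2M` (specific humidity, kg/kg,
#' 32-bit float), both dimensioned `(time, lat, lon)`.
#'
#' @param cube An [hourly_cube()].
#' @param path Output file path.
#' @param temp_var,hum_var Variable names to write.
#' @param south_up If `TRUE`, write latitudes in ascending (south-first)
#'   order, as some providers do; [read_hourly_netcdf()] normalizes either
#'   orientation.
#' @return The path, invisibly.
#' @export
write_cube_netcdf <- function(cube, path, temp_var = "T2M", hum_var = "QV2M",
                              south_up = FALSE) {
  g <- cube$grid
  lat <- grid_lats(g); lon <- grid_lons(g)
  nt <- length(cube$time)
  origin <- format(cube$time[1], "%Y-%m-%d %H:%M:%S", tz = "UTC")
  hours <- as.numeric(difftime(cube$time, cube$time[1], units = "hours"))
  row_order <- if (south_up) rev(seq_len(g$n_rows)) else seq_len(g$n_rows)

  flatten <- function(a) {
    # (time, lat, lon) with lon fastest
    out <- numeric(nt * g$n_rows * g$n_cols)
    k <- g$n_rows * g$n_cols
    for (t in seq_len(nt))
      out[((t - 1) * k + 1):(t * k)] <- c(t(a[row_order, , t]))
    out
  }
  dims <- c(time = nt, lat = g$n_rows, lon = g$n_cols)
  vars <- list(
    list(name = "time", type = NC_DOUBLE, dims = "time", data = hours,
         atts = list(units = paste("hours since", origin),
                     calendar = "standard")),
    list(name = "lat", type = NC_DOUBLE, dims = "lat", data = lat[row_order],
         atts = list(units = "degrees_north")),
    list(name = "lon", type = NC_DOUBLE, dims = "lon", data = lon,
         atts = list(units = "degrees_east")),
    list(name = temp_var, type = NC_FLOAT, dims = c("time", "lat", "lon"),
         data = flatten(cube$temperature),
         atts = list(units = "K", long_name = "2-meter air temperature")),
    list(name = hum_var, type = NC_FLOAT, dims = c("time", "lat", "lon"),
         data = flatten(cube$humidity),
         atts = list(units = "kg kg-1",
                     long_name = "2-meter specific humidity")))
  nc3_write(path, dims, vars,
            gatts = list(Conventions = "CF-1.6"))
  invisible(path)
}
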