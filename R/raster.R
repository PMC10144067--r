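#' Single-band planar raster
#'
#' Lightweight container for a georeferenced elevation or height grid in a
#' local planar coordinate system (meters). Row index increases southward,
#' column index increases eastward; `origin` is the (x, y) of the grid's
#' northwest corner. DTM/DSM pairs used together must share shape, cell
#' size and origin.
#'
#' @param values numeric matrix of cell values (meters); `NA` marks nodata.
#' @param cell_size cell edge length in meters (> 0).
#' @param origin length-2 numeric, (x, y) of the northwest corner in meters.
#' @param nodata sentinel written to disk for missing cells.
#' @return An object of class `field_raster`.
#' @export
field_raster <- function(values, cell_size, origin = c(0, 0), nodata = -9999) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("`values` must be a numeric matrix", call. = FALSE)
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("`cell_size` must be a single positive number", call. = FALSE)
  if (length(origin) != 2L || !is.numeric(origin))
    stop("`origin` must be a length-2 numeric (x, y)", call. = FALSE)
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin), nodata = as.numeric(nodata)),
    class = "field_raster"
  )
}

#' @export
print.field_raster <- function(x, ...) {
  v <- x$values
  ext <- raster_extent(x)
  cat(sprintf("<field_raster> %d rows x %d cols @ %.4g m/cell\n",
              nrow(v), ncol(v), x$cell_size))
  cat(sprintf("  extent: x [%.3f, %.3f], y [%.3f, %.3f] m\n",
              ext["xmin"], ext["xmax"], ext["ymin"], ext["ymax"]))
  fin <- v[is.finite(v)]
  if (length(fin))
    cat(sprintf("  values: [%.3f, %.3f] m, %d nodata cells\n",
                min(fin), max(fin), sum(!is.finite(v))))
  invisible(x)
}

#' @export
dim.field_raster <- function(x) dim(x$values)

#' Raster extent
#'
#' @param r a `field_raster`.
#' @return Named numeric `c(xmin, xmax, ymin, ymax)` in meters.
#' @export
raster_extent <- function(r) {
  stopifnot(inherits(r, "field_raster"))
  d <- dim(r$values)
  c(xmin = r$origin[1], xmax = r$origin[1] + d[2] * r$cell_size,
    ymin = r$origin[2] - d[1] * r$cell_size, ymax = r$origin[2])
}

# x/y coordinates of all cell centers (vectors along cols / rows)
raster_cell_centers <- function(r) {
  d <- dim(r$values)
  list(x = r$origin[1] + (seq_len(d[2]) - 0.5) * r$cell_size,
       y = r$origin[2] - (seq_len(d[1]) - 0.5) * r$cell_size)
}

# row/col of the cell containing each point; NA when outside the grid
raster_rowcol <- function(r, x, y) {
  d <- dim(r$values)
  col <- floor((x - r$origin[1]) / r$cell_size) + 1L
  row <- floor((r$origin[2] - y) / r$cell_size) + 1L
  bad <- col < 1L | col > d[2] | row < 1L | row > d[1]
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

#' Raster value at point locations
#'
#' Looks up the value of the cell containing each (x, y) point.
#'
#' @param r a `field_raster`.
#' @param x,y point coordinates in meters.
#' @return Numeric vector; `NA` for points outside the raster extent.
#' @export
raster_value_at <- function(r, x, y) {
  stopifnot(inherits(r, "field_raster"))
  rc <- raster_rowcol(r, x, y)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(rc$row)
  out[ok] <- r$values[cbind(rc$row[ok], rc$col[ok])]
  out
}

check_aligned <- function(a, b, what = "rasters") {
  if (!inherits(a, "field_raster") || !inherits(b, "field_raster"))
    stop("both inputs must be `field_raster` objects", call. = FALSE)
  if (!identical(dim(a$values), dim(b$values)) ||
      abs(a$cell_size - b$cell_size) > 1e-9 ||
      any(abs(a$origin - b$origin) > 1e-9))
    stop(sprintf("raster alignment error: %s differ in shape, cell size or origin", what),
         call. = FALSE)
  invisible(TRUE)
}

#' Write a raster as an Esri ASCII grid
#'
#' Plain-text `.asc` format (header + rows north to south), readable by
#' GDAL, QGIS and most GIS raster tools.
#'
#' @param r a `field_raster`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(r, path) {
  stopifnot(inherits(r, "field_raster"))
  d <- dim(r$values)
  ext <- raster_extent(r)
  v <- r$values
  v[!is.finite(v)] <- r$nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", d[2]),
    sprintf("nrows %d", d[1]),
    sprintf("xllcorner %.10g", ext["xmin"]),
    sprintf("yllcorner %.10g", ext["ymin"]),
    sprintf("cellsize %.10g", r$cell_size),
    sprintf("NODATA_value %.10g", r$nodata)
  ), con)
  utils::write.table(format(v, trim = TRUE, digits = 8, scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read an Esri ASCII grid
#'
#' @param path `.asc` file path.
#' @return A `field_raster`; nodata cells become `NA`.
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6L)
  kv <- strsplit(trimws(hdr), "\\s+")
  keys <- tolower(vapply(kv, `[`, "", 1L))
  vals <- as.numeric(vapply(kv, `[`, "", 2L))
  names(vals) <- keys
  req <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(req %in% keys))
    stop("not an Esri ASCII grid: missing header fields", call. = FALSE)
  nodata <- if ("nodata_value" %in% keys) vals[["nodata_value"]] else -9999
  m <- matrix(scan(path, skip = 6L, quiet = TRUE),
              nrow = vals[["nrows"]], ncol = vals[["ncols"]], byrow = TRUE)
  m[m == nodata] <- NA_real_
  field_raster(m, vals[["cellsize"]],
               origin = c(vals[["xllcorner"]],
                          vals[["yllcorner"]] + vals[["nrows"]] * vals[["cellsize"]]),
               nodata = nodata)
}
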