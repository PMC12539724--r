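# 1 m^2 = 0.000247105 acres; a 30-m pixel is 0.22239 acres.
ACRES_PER_M2 <- 0.000247105

#' Lightweight in-memory raster
#'
#' A minimal single-band raster: a numeric or integer matrix plus the grid
#' geometry needed for co-registration checks, area accounting, and text
#' serialisation. Row 1 is the northernmost row (as in ESRI ASCII grids);
#' `NA` is the nodata sentinel and is excluded from every count and area sum.
#'
#' @param values numeric or integer matrix.
#' @param pixel_size_m cell edge length in meters (default 30).
#' @param xll,yll coordinates of the lower-left corner of the grid.
#' @param legend optional character vector for categorical rasters; cell value
#'   `k` means `legend[k]`.
#' @return an object of class `grid_raster`.
#' @export
grid_raster <- function(values, pixel_size_m = 30, xll = 0, yll = 0,
                        legend = NULL) {
  if (!is.matrix(values)) stop("`values` must be a matrix", call. = FALSE)
  if (!is.numeric(pixel_size_m) || length(pixel_size_m) != 1 ||
      pixel_size_m <= 0) {
    stop("`pixel_size_m` must be a single positive number", call. = FALSE)
  }
  if (!is.null(legend)) {
    v <- values[!is.na(values)]
    if (length(v) && (any(v < 1) || any(v > length(legend)) ||
                      any(v != round(v)))) {
      stop("categorical values must index into `legend`", call. = FALSE)
    }
  }
  structure(
    list(values = values, pixel_size_m = pixel_size_m,
         xll = xll, yll = yll, legend = legend),
    class = "grid_raster"
  )
}

#' @export
dim.grid_raster <- function(x) dim(x$values)

#' @export
as.matrix.grid_raster <- function(x, ...) x$values

#' @export
print.grid_raster <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<grid_raster> %d x %d @ %gm, origin (%g, %g)\n",
              d[1], d[2], x$pixel_size_m, x$xll, x$yll))
  if (!is.null(x$legend)) {
    cat("legend:", paste(x$legend, collapse = ", "), "\n")
  }
  cat(sprintf("valid cells: %d / %d\n",
              sum(!is.na(x$values)), length(x$values)))
  invisible(x)
}

#' Area of one pixel in acres
#'
#' @param x a `grid_raster`, or a pixel edge length in meters.
#' @return acres per pixel (double precision; 30 m gives 0.22239...).
#' @export
pixel_acres <- function(x) {
  px <- if (inherits(x, "grid_raster")) x$pixel_size_m else x
  px^2 * ACRES_PER_M2
}

same_grid <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$pixel_size_m, b$pixel_size_m)) &&
    isTRUE(all.equal(a$xll, b$xll)) && isTRUE(all.equal(a$yll, b$yll))
}

stop_if_grid_mismatch <- function(..., what = "rasters") {
  rs <- list(...)
  ref <- rs[[1]]
  for (r in rs[-1]) {
    if (!same_grid(ref, r)) {
      stop(sprintf("%s are not co-registered (shape/geometry differ)", what),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Convert point coordinates to matrix cells
#'
#' Points outside the grid extent get `NA` row/col.
#'
#' @param r a `grid_raster`.
#' @param x,y point coordinates in the raster's coordinate system.
#' @return a two-column integer matrix (row, col).
#' @export
cells_from_xy <- function(r, x, y) {
  px <- r$pixel_size_m
  nr <- nrow(r$values)
  nc <- ncol(r$values)
  col <- floor((x - r$xll) / px) + 1L
  row <- nr - floor((y - r$yll) / px)
  bad <- col < 1L | col > nc | row < 1L | row > nr
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Center coordinates of matrix cells
#'
#' @param r a `grid_raster`.
#' @param row,col integer cell indices.
#' @return a two-column matrix (x, y) of cell centers.
#' @export
xy_from_cells <- function(r, row, col) {
  px <- r$pixel_size_m
  nr <- nrow(r$values)
  cbind(x = r$xll + (col - 0.5) * px,
        y = r$yll + (nr - row + 0.5) * px)
}

#' Sample raster values at point locations
#'
#' @param r a `grid_raster`.
#' @param x,y point coordinates.
#' @return vector of cell values (`NA` outside the extent).
#' @export
extract_at <- function(r, x, y) {
  rc <- cells_from_xy(r, x, y)
  out <- rep(NA_real_, nrow(rc))
  ok <- !is.na(rc[, 1])
  out[ok] <- r$values[cbind(rc[ok, 1], rc[ok, 2])]
  out
}

#' Write / read a raster as ESRI ASCII grid
#'
#' Plain-text serialisation interchangeable with standard GIS tooling.
#' Nodata is written as -9999. Categorical legends travel in a `<file>.legend.csv`
#' side file (columns `value,label`), mirroring a colormap side-file.
#'
#' @param r a `grid_raster`.
#' @param path output path (conventionally `.asc`).
#' @return `write_ascii_grid` returns `path` invisibly; `read_ascii_grid`
#'   returns a `grid_raster`.
#' @export
write_ascii_grid <- function(r, path) {
  stopifnot(inherits(r, "grid_raster"))
  v <- r$values
  nodata <- -9999
  v[is.na(v)] <- nodata
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", r$xll),
    sprintf("yllcorner %.10g", r$yll),
    sprintf("cellsize %.10g", r$pixel_size_m),
    sprintf("NODATA_value %d", nodata)
  )
  body <- apply(v, 1, function(row) paste(format(row, trim = TRUE,
                                                 scientific = FALSE),
                                          collapse = " "))
  writeLines(c(hdr, body), path)
  if (!is.null(r$legend)) {
    utils::write.csv(
      data.frame(value = seq_along(r$legend), label = r$legend),
      paste0(path, ".legend.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_ascii_grid
#' @param integer_values coerce cells to integer on read.
#' @export
read_ascii_grid <- function(path, integer_values = FALSE) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  val <- function(i) as.numeric(strsplit(trimws(hdr[i]), "\\s+")[[1]][2])
  nc <- as.integer(val(1)); nr <- as.integer(val(2))
  xll <- val(3); yll <- val(4); cs <- val(5); nodata <- val(6)
  body <- lines[-(1:6)]
  m <- matrix(as.numeric(unlist(strsplit(trimws(body), "\\s+"))),
              nrow = nr, byrow = TRUE)
  m[m == nodata] <- NA
  if (integer_values) storage.mode(m) <- "integer"
  legend <- NULL
  lp <- paste0(path, ".legend.csv")
  if (file.exists(lp)) {
    leg <- utils::read.csv(lp, stringsAsFactors = FALSE)
    legend <- leg$label[order(leg$value)]
  }
  grid_raster(m, pixel_size_m = cs, xll = xll, yll = yll, legend = legend)
}
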