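#' Planar raster grid
#'
#' Minimal north-up raster container used throughout the package: a numeric
#' (or integer) matrix with square pixels, pixel-center registration and a
#' planar coordinate origin. Row 1 is the northernmost row; column 1 the
#' westernmost column, matching the row order of ESRI ASCII grids.
#'
#' @param values numeric matrix (row 1 = north).
#' @param pixel_size pixel edge length in meters (> 0).
#' @param xmin,ymin planar coordinates of the lower-left corner of the grid.
#' @param nodata value to interpret as nodata (`NA` cells are always nodata).
#' @return an object of class `hq_grid`.
#' @export
hq_grid <- function(values, pixel_size, xmin = 0, ymin = 0, nodata = NA_real_) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number")
  structure(
    list(values = values, pixel_size = as.numeric(pixel_size),
         xmin = as.numeric(xmin), ymin = as.numeric(ymin),
         nodata = nodata),
    class = "hq_grid"
  )
}

#' @exportS3Method base::print
print.hq_grid <- function(x, ...) {
  v <- grid_values(x)
  cat(sprintf("<hq_grid> %d rows x %d cols, pixel %g m, origin (%g, %g)\n",
              nrow(v), ncol(v), x$pixel_size, x$xmin, x$ymin))
  rng <- suppressWarnings(range(v, na.rm = TRUE))
  cat(sprintf("  values in [%g, %g], %d nodata cells\n",
              rng[1], rng[2], sum(is.na(v))))
  invisible(x)
}

#' @export
dim.hq_grid <- function(x) dim(x$values)

#' Grid values with nodata as NA
#' @param g an `hq_grid`.
#' @return the value matrix with nodata cells set to `NA`.
#' @export
grid_values <- function(g) {
  stopifnot(inherits(g, "hq_grid"))
  v <- g$values
  if (!is.na(g$nodata)) v[v == g$nodata] <- NA
  v
}

#' Grid extent
#' @param g an `hq_grid`.
#' @return named numeric vector `c(xmin, xmax, ymin, ymax)`.
#' @export
grid_extent <- function(g) {
  d <- dim(g$values)
  c(xmin = g$xmin, xmax = g$xmin + d[2] * g$pixel_size,
    ymin = g$ymin, ymax = g$ymin + d[1] * g$pixel_size)
}

#' Pixel-center coordinates
#'
#' @param g an `hq_grid`.
#' @return list with `x` (length ncol, west to east) and `y` (length nrow,
#'   north to south, matching row order).
#' @export
pixel_centers <- function(g) {
  d <- dim(g$values)
  px <- g$pixel_size
  list(
    x = g$xmin + (seq_len(d[2]) - 0.5) * px,
    y = g$ymin + (d[1] - seq_len(d[1]) + 0.5) * px
  )
}

#' Row/column of the pixel containing a point
#'
#' Points on a pixel's south/west edge belong to that pixel; points exactly on
#' the grid's outer edge are clamped inward so that boundary points are usable.
#'
#' @param g an `hq_grid`.
#' @param x,y planar coordinates.
#' @return integer matrix with columns `row`, `col`; NA for points outside.
#' @export
point_to_cell <- function(g, x, y) {
  d <- dim(g$values)
  ext <- grid_extent(g)
  col <- floor((x - g$xmin) / g$pixel_size) + 1
  row <- d[1] - floor((y - g$ymin) / g$pixel_size)
  col[x == ext["xmax"]] <- d[2]
  row[y == ext["ymax"]] <- 1
  bad <- x < ext["xmin"] | x > ext["xmax"] | y < ext["ymin"] | y > ext["ymax"]
  row[bad] <- NA_integer_
  col[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

same_geometry <- function(a, b, tol = 1e-9) {
  all(dim(a$values) == dim(b$values)) &&
    abs(a$pixel_size - b$pixel_size) < tol &&
    abs(a$xmin - b$xmin) < tol && abs(a$ymin - b$ymin) < tol
}

#' Write a grid as an ESRI ASCII raster
#'
#' Plain-text `.asc` format readable by all common GIS software. Values are
#' written with 7 significant digits (float32-level precision).
#'
#' @param g an `hq_grid`.
#' @param path output file path.
#' @param nodata nodata sentinel written to the file.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(g, path, nodata = -9999) {
  stopifnot(inherits(g, "hq_grid"))
  v <- grid_values(g)
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", g$xmin),
    sprintf("yllcorner %.10g", g$ymin),
    sprintf("cellsize %.10g", g$pixel_size),
    sprintf("NODATA_value %.10g", nodata)
  ), con)
  writeLines(apply(v, 1L, function(r) paste(sprintf("%.7g", r), collapse = " ")),
             con)
  invisible(path)
}

#' Read an ESRI ASCII raster
#'
#' @param path file written by [write_ascii_grid()] or any `.asc` raster.
#' @return an `hq_grid` (nodata cells as `NA`).
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("malformed ASCII grid header in ", path)
  vals <- scan(text = lines[i:length(lines)], quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  hq_grid(m, pixel_size = hdr$cellsize, xmin = hdr$xllcorner,
          ymin = hdr$yllcorner)
}
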