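#' Lightweight georeferenced raster grid
#'
#' A `raster_grid` is a real-valued matrix with a simple geotransform:
#' square cells of size `res`, upper-left corner at (`xmin`, `ymax`),
#' row 1 = northernmost row, half-open pixel indexing. Nodata cells
#' (e.g. sea) are stored as `NA` and excluded from all statistics.
#' Point coordinates used throughout the package are cell centers.
#'
#' @param values numeric matrix (rows run north to south).
#' @param xmin x coordinate of the grid's left (west) edge.
#' @param ymax y coordinate of the grid's top (north) edge.
#' @param res cell size (same units as x/y; square cells).
#' @return an object of class `raster_grid`.
#' @export
raster_grid <- function(values, xmin = 0, ymax = nrow(values), res = 1) {
  values <- as.matrix(values)
  if (!is.numeric(values) && !is.logical(values))
    stop("raster values must be numeric or logical")
  if (nrow(values) < 1 || ncol(values) < 1) stop("empty raster")
  if (!is.finite(res) || res <= 0) stop("res must be positive")
  structure(
    list(values = values, xmin = xmin, ymax = ymax, res = res),
    class = "raster_grid"
  )
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf(
    "<raster_grid> %d x %d cells, res %g, extent x [%g, %g] y [%g, %g]\n",
    nrow(v), ncol(v), x$res,
    x$xmin, x$xmin + ncol(v) * x$res,
    x$ymax - nrow(v) * x$res, x$ymax
  ))
  ok <- is.finite(v)
  if (any(ok)) {
    cat(sprintf("  values: [%g, %g], nodata cells: %d\n",
                min(v[ok]), max(v[ok]), sum(!ok)))
  } else {
    cat("  all cells nodata\n")
  }
  invisible(x)
}

#' @export
plot.raster_grid <- function(x, main = NULL, ...) {
  v <- x$values
  # image() wants x increasing, y increasing: transpose + flip rows
  z <- t(v[nrow(v):1, , drop = FALSE])
  xs <- x$xmin + (seq_len(ncol(v)) - 0.5) * x$res
  ys <- x$ymax - (rev(seq_len(nrow(v))) - 0.5) * x$res
  graphics::image(xs, ys, z, asp = 1, xlab = "x", ylab = "y",
                  main = main, useRaster = TRUE, ...)
  invisible(x)
}

# same shape and geotransform (tolerance on the real-valued parts)
rg_same_geom <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(c(a$xmin, a$ymax, a$res), c(b$xmin, b$ymax, b$res),
                     tolerance = 1e-9))
}

# every cross-grid operation goes through this gate
rg_check_aligned <- function(grids) {
  if (length(grids) < 2) return(invisible(TRUE))
  ref <- grids[[1]]
  for (g in grids[-1]) {
    if (!inherits(g, "raster_grid")) stop("not a raster_grid")
    if (!rg_same_geom(ref, g))
      stop("raster grids are misaligned (shape or geotransform differ)")
  }
  invisible(TRUE)
}

# build a grid with the same geometry but new values
rg_like <- function(template, values) {
  raster_grid(matrix(values, nrow = nrow(template$values)),
              xmin = template$xmin, ymax = template$ymax, res = template$res)
}

#' Cell-center coordinates of a raster grid
#'
#' @param grid a `raster_grid`.
#' @param rows,cols integer row/column indices (1-based, row 1 = north).
#' @return data.frame with columns `x`, `y`.
#' @export
cell_centers <- function(grid, rows, cols) {
  data.frame(
    x = grid$xmin + (cols - 0.5) * grid$res,
    y = grid$ymax - (rows - 0.5) * grid$res
  )
}

#' Map point coordinates to raster cell indices
#'
#' Points outside the grid extent get `NA` indices.
#'
#' @param grid a `raster_grid`.
#' @param x,y point coordinates.
#' @return data.frame with integer columns `row`, `col`.
#' @export
cells_for_points <- function(grid, x, y) {
  col <- floor((x - grid$xmin) / grid$res) + 1L
  row <- floor((grid$ymax - y) / grid$res) + 1L
  bad <- row < 1L | row > nrow(grid$values) | col < 1L | col > ncol(grid$values)
  row[bad] <- NA_integer_
  col[bad] <- NA_integer_
  data.frame(row = row, col = col)
}

#' Extract raster values at point locations
#'
#' @param grid a `raster_grid`.
#' @param x,y point coordinates.
#' @return numeric vector; `NA` for points off-grid or on nodata cells.
#' @export
extract_at <- function(grid, x, y) {
  idx <- cells_for_points(grid, x, y)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(idx$row)
  out[ok] <- grid$values[cbind(idx$row[ok], idx$col[ok])]
  out
}

#' Write a raster grid as an ESRI ASCII grid (.asc)
#'
#' Plain-text interchange format readable by standard GIS software.
#' Nodata cells are written as the `nodata` sentinel.
#'
#' @param grid a `raster_grid`.
#' @param path output file path.
#' @param nodata sentinel value for nodata cells.
#' @export
write_asc <- function(grid, path, nodata = -9999) {
  v <- grid$values
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", grid$xmin),
    sprintf("yllcorner %.10g", grid$ymax - nrow(v) * grid$res),
    sprintf("cellsize %.10g", grid$res),
    sprintf("NODATA_value %.10g", nodata)
  ), con)
  v[!is.finite(v)] <- nodata
  utils::write.table(format(v, digits = 15, trim = TRUE, scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII grid written by [write_asc()]
#'
#' @param path file path.
#' @return a `raster_grid` with nodata cells as `NA`.
#' @export
read_asc <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- strsplit(trimws(hdr), "\\s+")
  key <- tolower(vapply(kv, `[`, "", 1))
  val <- as.numeric(vapply(kv, `[`, "", 2))
  names(val) <- key
  v <- as.matrix(utils::read.table(path, skip = 6))
  dimnames(v) <- NULL
  v[v == val[["nodata_value"]]] <- NA_real_
  raster_grid(v,
              xmin = val[["xllcorner"]],
              ymax = val[["yllcorner"]] + val[["nrows"]] * val[["cellsize"]],
              res = val[["cellsize"]])
}

#' Write / read occurrence points as CSV
#'
#' Occurrence sets are plain data frames with columns `x`, `y`, `species`,
#' `role` (role is one of `"presence"`, `"coppice"`, `"pseudo_absence"`).
#'
#' @param occ occurrence data frame.
#' @param path file path.
#' @export
write_occurrences <- function(occ, path) {
  stopifnot(all(c("x", "y", "species", "role") %in% names(occ)))
  utils::write.csv(occ[, c("x", "y", "species", "role")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_occurrences
#' @export
read_occurrences <- function(path) {
  occ <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("x", "y", "species", "role") %in% names(occ)))
  occ
}
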