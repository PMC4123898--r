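#' Lightweight gridded raster
#'
#' A minimal single-band raster: a numeric matrix plus a geotransform
#' (lower-left corner and square pixel size in projected metres). Row 1 is
#' the top (northernmost) row, matching image conventions; the cell centre
#' of `[i, j]` is at `x = xmin + (j - 0.5) * res`,
#' `y = ymin + (nrow - i + 0.5) * res`.
#'
#' @param values Numeric matrix of cell values (`NA` = missing/masked).
#' @param xmin,ymin Coordinates of the lower-left corner (m).
#' @param res Pixel size (m), default 30 (Landsat native).
#' @return A `bd_raster` object.
#' @export
bd_raster <- function(values, xmin = 0, ymin = 0, res = 30) {
  values <- as.matrix(values)
  stopifnot(is.numeric(values) || is.logical(values), res > 0)
  structure(
    list(values = values, xmin = xmin, ymin = ymin, res = res),
    class = "bd_raster"
  )
}

#' @export
print.bd_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf(
    "<bd_raster> %d x %d cells, %g m pixels, origin (%g, %g)\n",
    nrow(v), ncol(v), x$res, x$xmin, x$ymin
  ))
  cat(sprintf(
    "  values: min %.4g, max %.4g, NA %d\n",
    suppressWarnings(min(v, na.rm = TRUE)),
    suppressWarnings(max(v, na.rm = TRUE)), sum(is.na(v))
  ))
  invisible(x)
}

#' @export
dim.bd_raster <- function(x) dim(x$values)

raster_ymax <- function(r) r$ymin + nrow(r$values) * r$res
raster_xmax <- function(r) r$xmin + ncol(r$values) * r$res

same_grid <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(c(a$xmin, a$ymin, a$res), c(b$xmin, b$ymin, b$res)))
}

#' Locate the cell containing a point
#'
#' @param r A [bd_raster()].
#' @param x,y Point coordinates in the raster's projected metres.
#' @return Integer vector `c(row, col)`; errors if the point is off-raster.
#' @export
cell_at <- function(r, x, y) {
  col <- floor((x - r$xmin) / r$res) + 1L
  row <- floor((raster_ymax(r) - y) / r$res) + 1L
  # points exactly on the top/right edge belong to the outermost cell
  if (x == raster_xmax(r)) col <- ncol(r$values)
  if (y == r$ymin + nrow(r$values) * r$res) row <- 1L
  if (row < 1L || col < 1L || row > nrow(r$values) || col > ncol(r$values)) {
    stop("point (", x, ", ", y, ") lies outside the raster extent")
  }
  c(row = row, col = col)
}

#' Convert a raster to a long tibble
#'
#' @param r A [bd_raster()].
#' @return A tibble with columns `row`, `col`, `x`, `y` (cell centres) and
#'   `value`; one row per cell.
#' @export
raster_to_tibble <- function(r) {
  stopifnot(inherits(r, "bd_raster"))
  nr <- nrow(r$values); nc <- ncol(r$values)
  tibble::tibble(
    row = rep(seq_len(nr), times = nc),
    col = rep(seq_len(nc), each = nr),
    x = r$xmin + (rep(seq_len(nc), each = nr) - 0.5) * r$res,
    y = r$ymin + (nr - rep(seq_len(nr), times = nc) + 0.5) * r$res,
    value = as.vector(r$values)
  )
}

#' Write / read a raster as plain CSV
#'
#' Long-format CSV (`x`, `y`, `value`) keeps rasters in a text format that
#' round-trips exactly; the grid geometry is recovered from the coordinates.
#'
#' @param r A [bd_raster()].
#' @param path File path.
#' @return `write_raster_csv()` returns `path` invisibly; `read_raster_csv()`
#'   returns a [bd_raster()].
#' @export
write_raster_csv <- function(r, path) {
  df <- raster_to_tibble(r)[, c("x", "y", "value")]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_raster_csv
#' @export
read_raster_csv <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("x", "y", "value") %in% names(df)))
  xs <- sort(unique(df$x)); ys <- sort(unique(df$y))
  res <- if (length(xs) > 1) min(diff(xs)) else if (length(ys) > 1) min(diff(ys)) else 30
  nr <- length(ys); nc <- length(xs)
  m <- matrix(NA_real_, nr, nc)
  i <- nr - match(df$y, ys) + 1L
  j <- match(df$x, xs)
  m[cbind(i, j)] <- df$value
  bd_raster(m, xmin = min(xs) - res / 2, ymin = min(ys) - res / 2, res = res)
}
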