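#' Planar gridded raster
#'
#' A minimal planar raster: a numeric matrix on a square grid with a
#' lower-left origin. Row 1 of `values` is the southernmost row (y increasing
#' with row index); cell centres follow the usual half-cell offset. Point to
#' cell assignment is `floor((p - origin) / cell_size) + 1`.
#'
#' @param values numeric matrix (rows = y, cols = x), row 1 at the south edge.
#' @param origin numeric length-2, coordinates of the lower-left corner (m).
#' @param cell_size cell edge length (m), > 0.
#' @param nodata sentinel value treated as missing.
#' @param units free-text unit declaration (e.g. "m", "km/km2", "class").
#' @return object of class `grid_raster`.
#' @export
grid_raster <- function(values, origin = c(0, 0), cell_size, nodata = -9999,
                        units = "") {
  stopifnot(is.matrix(values), length(origin) == 2, cell_size > 0)
  structure(
    list(values = values, origin = as.numeric(origin),
         cell_size = as.numeric(cell_size),
         n_rows = nrow(values), n_cols = ncol(values),
         nodata = nodata, units = units),
    class = "grid_raster")
}

#' @export
print.grid_raster <- function(x, ...) {
  cat(sprintf("<grid_raster> %d x %d cells of %g m, origin (%g, %g)%s\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin[1], x$origin[2],
              if (nzchar(x$units)) paste0(", units: ", x$units) else ""))
  invisible(x)
}

raster_extent <- function(r) {
  c(r$origin[1], r$origin[1] + r$n_cols * r$cell_size,
    r$origin[2], r$origin[2] + r$n_rows * r$cell_size)
}

# row/col of the cells containing points (x, y); points on the far edge are
# pulled into the last cell so the extent is closed.
raster_cell_of <- function(r, x, y) {
  col <- floor((x - r$origin[1]) / r$cell_size) + 1L
  row <- floor((y - r$origin[2]) / r$cell_size) + 1L
  col <- pmin.int(pmax.int(col, 1L), r$n_cols)
  row <- pmin.int(pmax.int(row, 1L), r$n_rows)
  cbind(row = row, col = col)
}

# cell-centre coordinates for (row, col) index matrix
raster_cell_center <- function(r, rc) {
  cbind(x = r$origin[1] + (rc[, "col"] - 0.5) * r$cell_size,
        y = r$origin[2] + (rc[, "row"] - 0.5) * r$cell_size)
}

#' Look up raster values at planar points
#'
#' Nearest-cell lookup; points outside the raster extent or hitting the nodata
#' sentinel return `NA`.
#'
#' @param r a [grid_raster()].
#' @param x,y point coordinates (m), recycled to a common length.
#' @return numeric vector of cell values.
#' @export
raster_values_at <- function(r, x, y) {
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  ext <- raster_extent(r)
  inside <- x >= ext[1] & x <= ext[2] & y >= ext[3] & y <= ext[4]
  out <- rep(NA_real_, n)
  if (any(inside)) {
    rc <- raster_cell_of(r, x[inside], y[inside])
    v <- r$values[cbind(rc[, "row"], rc[, "col"])]
    v[!is.na(v) & v == r$nodata] <- NA_real_
    out[inside] <- v
  }
  out
}

#' Write a raster as an Esri ASCII grid
#'
#' Plain-text `.asc` format (`ncols`/`nrows`/`xllcorner`/`yllcorner`/
#' `cellsize`/`nodata_value` header, rows written north to south).
#'
#' @param r a [grid_raster()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(r, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", r$n_cols),
    sprintf("nrows %d", r$n_rows),
    sprintf("xllcorner %.10g", r$origin[1]),
    sprintf("yllcorner %.10g", r$origin[2]),
    sprintf("cellsize %.10g", r$cell_size),
    sprintf("nodata_value %.10g", r$nodata)), con)
  vals <- r$values
  vals[is.na(vals)] <- r$nodata
  for (i in seq(r$n_rows, 1L)) {
    writeLines(paste(formatC(vals[i, ], format = "g", digits = 10),
                     collapse = " "), con)
  }
  invisible(path)
}

#' Read an Esri ASCII grid
#'
#' @param path `.asc` file path.
#' @param units unit declaration to attach.
#' @return a [grid_raster()]; nodata cells become `NA`.
#' @export
read_ascii_grid <- function(path, units = "") {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  body <- lines[seq(i, length(lines))]
  vals <- lapply(body, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  m <- do.call(rbind, vals)
  m <- m[seq(nrow(m), 1L), , drop = FALSE]  # back to south-first rows
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  m[m == nodata] <- NA_real_
  grid_raster(m, origin = c(hdr$xllcorner, hdr$yllcorner),
              cell_size = hdr$cellsize, nodata = nodata, units = units)
}

# Smooth random field on a raster grid: bilinear interpolation of an
# (nk x nk) iid normal knot lattice, scaled to mean `mu`, sd `sigma`.
smooth_field <- function(n_rows, n_cols, n_knots = 8, mu = 0, sigma = 1) {
  kn <- matrix(stats::rnorm(n_knots * n_knots), n_knots, n_knots)
  ry <- seq(0, 1, length.out = n_rows) * (n_knots - 1) + 1
  rx <- seq(0, 1, length.out = n_cols) * (n_knots - 1) + 1
  iy <- pmin(floor(ry), n_knots - 1); fy <- ry - iy
  ix <- pmin(floor(rx), n_knots - 1); fx <- rx - ix
  # bilinear blend, vectorised over the full grid
  f11 <- kn[cbind(rep(iy, n_cols), rep(ix, each = n_rows))]
  f21 <- kn[cbind(rep(iy + 1, n_cols), rep(ix, each = n_rows))]
  f12 <- kn[cbind(rep(iy, n_cols), rep(ix + 1, each = n_rows))]
  f22 <- kn[cbind(rep(iy + 1, n_cols), rep(ix + 1, each = n_rows))]
  wy <- rep(fy, n_cols); wx <- rep(fx, each = n_rows)
  v <- f11 * (1 - wy) * (1 - wx) + f21 * wy * (1 - wx) +
    f12 * (1 - wy) * wx + f22 * wy * wx
  m <- matrix(v, n_rows, n_cols)
  s <- stats::sd(m)
  if (s > 0) m <- (m - mean(m)) / s
  mu + sigma * m
}
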