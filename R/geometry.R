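#' @name line-network
#' @title Line networks and their 100-m segmentation
#'
#' @description
#' A line network is a list of polylines, each an `n x 2` coordinate matrix in
#' planar metres. [segment_lines()] partitions every polyline into consecutive
#' pieces of approximately `target_length` metres — the unit to which
#' vegetation height, wetness, landcover and density are attributed. The
#' result is an edge table (class `line_segments`): one row per straight edge,
#' several edges composing one segment where a piece spans polyline vertices.
NULL

polyline_length <- function(line) {
  if (nrow(line) < 2) return(0)
  sum(sqrt(rowSums(diff(line)^2)))
}

#' Total length of a line network
#' @param lines list of polyline coordinate matrices.
#' @return total length in metres.
#' @export
network_length <- function(lines) sum(vapply(lines, polyline_length, 0))

# interpolate a point at arc length s along a polyline (s clamped)
polyline_point_at <- function(line, s) {
  seg <- sqrt(rowSums(diff(line)^2))
  cs <- c(0, cumsum(seg))
  s <- min(max(s, 0), cs[length(cs)])
  i <- findInterval(s, cs, rightmost.closed = TRUE)
  i <- min(i, length(seg))
  f <- if (seg[i] > 0) (s - cs[i]) / seg[i] else 0
  line[i, ] + f * (line[i + 1, ] - line[i, ])
}

#' Partition polylines into approximately 100-m segments
#'
#' Cuts each polyline at exact multiples of `target_length` of arc length. A
#' terminal remainder shorter than `target_length / 2` is folded into the
#' final piece (so lengths stay within `[0.5, 1.5] * target_length`); a longer
#' remainder stands as its own piece. Total length is conserved exactly.
#' Zero-length polylines are skipped with a warning.
#'
#' @param lines list of polyline coordinate matrices (metres).
#' @param target_length nominal segment length (m).
#' @return a `line_segments` data frame with one row per straight edge:
#'   `segment_id`, `x0`, `y0`, `x1`, `y1`, `length`.
#' @export
segment_lines <- function(lines, target_length = 100) {
  stopifnot(target_length > 0)
  out <- vector("list", length(lines))
  seg_counter <- 0L
  for (li in seq_along(lines)) {
    line <- lines[[li]]
    L <- polyline_length(line)
    if (L <= 0) {
      warning(sprintf("skipping zero-length polyline %d", li))
      next
    }
    cuts <- seq(0, L, by = target_length)
    if (L - cuts[length(cuts)] < target_length / 2) {
      cuts <- cuts[-length(cuts)]  # fold short remainder into final piece
    }
    cuts <- unique(c(cuts, L))
    # arc positions of polyline vertices
    vert <- c(0, cumsum(sqrt(rowSums(diff(line)^2))))
    breaks <- sort(unique(c(cuts, vert)))
    piece_of <- findInterval(breaks[-length(breaks)], cuts,
                             rightmost.closed = TRUE)
    p0 <- t(vapply(breaks[-length(breaks)],
                   function(s) polyline_point_at(line, s), numeric(2)))
    p1 <- t(vapply(breaks[-1],
                   function(s) polyline_point_at(line, s), numeric(2)))
    elen <- diff(breaks)
    keep <- elen > 1e-9
    out[[li]] <- data.frame(
      segment_id = seg_counter + piece_of[keep],
      x0 = p0[keep, 1], y0 = p0[keep, 2],
      x1 = p1[keep, 1], y1 = p1[keep, 2],
      length = elen[keep])
    seg_counter <- seg_counter + max(piece_of)
  }
  res <- do.call(rbind, out)
  if (is.null(res) || nrow(res) == 0) stop("no usable polylines")
  rownames(res) <- NULL
  class(res) <- c("line_segments", "data.frame")
  res
}

#' Per-segment summary of a segmented network
#'
#' @param edges a `line_segments` edge table from [segment_lines()].
#' @return data frame with one row per segment: `segment_id`, `length`,
#'   midpoint coordinates `mid_x`, `mid_y`.
#' @export
segment_summary <- function(edges) {
  len <- tapply(edges$length, edges$segment_id, sum)
  ids <- as.integer(names(len))
  mids <- t(vapply(ids, function(id) {
    e <- edges[edges$segment_id == id, , drop = FALSE]
    line <- rbind(as.matrix(e[, c("x0", "y0")]),
                  as.matrix(e[nrow(e), c("x1", "y1"), drop = FALSE]))
    polyline_point_at(line, sum(e$length) / 2)
  }, numeric(2)))
  data.frame(segment_id = ids, length = as.numeric(len),
             mid_x = mids[, 1], mid_y = mids[, 2])
}

# Distances from points to every edge; returns per-point minimum and the
# owning segment. Vectorised over (chunked points) x edges.
#' Nearest line segment to planar points
#'
#' Exact Euclidean point-to-polyline distance, minimised over segments.
#'
#' @param x,y point coordinates (m).
#' @param edges a `line_segments` edge table (optionally attributed).
#' @param chunk internal chunk size controlling peak memory.
#' @return data frame with `segment_id` and `distance` (m) per point.
#' @export
nearest_segment <- function(x, y, edges, chunk = 2000L) {
  stopifnot(nrow(edges) >= 1, length(x) == length(y))
  ex0 <- edges$x0; ey0 <- edges$y0
  dx <- edges$x1 - ex0; dy <- edges$y1 - ey0
  len2 <- pmax(dx^2 + dy^2, 1e-300)
  n <- length(x)
  seg_id <- integer(n); dist <- numeric(n)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    px <- x[idx]; py <- y[idx]
    # t parameter of the foot point, clamped to the edge
    tt <- (outer(px, ex0, "-") * rep(dx, each = length(idx)) +
           outer(py, ey0, "-") * rep(dy, each = length(idx))) /
      rep(len2, each = length(idx))
    tt[tt < 0] <- 0; tt[tt > 1] <- 1
    qx <- rep(ex0, each = length(idx)) + tt * rep(dx, each = length(idx))
    qy <- rep(ey0, each = length(idx)) + tt * rep(dy, each = length(idx))
    d2 <- (qx - px)^2 + (qy - py)^2
    dim(d2) <- c(length(idx), nrow(edges))
    j <- max.col(-d2, ties.method = "first")
    dist[idx] <- sqrt(d2[cbind(seq_along(idx), j)])
    seg_id[idx] <- edges$segment_id[j]
  }
  data.frame(segment_id = seg_id, distance = dist)
}

# Exact raster traversal of one straight edge: the cells crossed and the
# length of the edge inside each. Edge is clipped to the raster extent.
grid_traverse <- function(r, x0, y0, x1, y1) {
  ext <- raster_extent(r)
  dx <- x1 - x0; dy <- y1 - y0
  L <- sqrt(dx^2 + dy^2)
  if (L == 0) return(data.frame(row = integer(0), col = integer(0),
                                len = numeric(0)))
  # Liang-Barsky clip to extent
  t0 <- 0; t1 <- 1
  for (k in 1:4) {
    p <- c(-dx, dx, -dy, dy)[k]
    q <- c(x0 - ext[1], ext[2] - x0, y0 - ext[3], ext[4] - y0)[k]
    if (p == 0) { if (q < 0) return(data.frame(row = integer(0),
                                               col = integer(0),
                                               len = numeric(0))) }
    else { tq <- q / p
      if (p < 0) t0 <- max(t0, tq) else t1 <- min(t1, tq) }
  }
  if (t0 >= t1) return(data.frame(row = integer(0), col = integer(0),
                                  len = numeric(0)))
  cs <- r$cell_size
  tx <- if (dx != 0)
    (r$origin[1] + cs * seq(0, r$n_cols) - x0) / dx else numeric(0)
  ty <- if (dy != 0)
    (r$origin[2] + cs * seq(0, r$n_rows) - y0) / dy else numeric(0)
  ts <- sort(unique(c(t0, t1, tx[tx > t0 & tx < t1], ty[ty > t0 & ty < t1])))
  tm <- (ts[-length(ts)] + ts[-1]) / 2
  rc <- raster_cell_of(r, x0 + tm * dx, y0 + tm * dy)
  data.frame(row = rc[, "row"], col = rc[, "col"], len = diff(ts) * L)
}

#' Moving-window line-density raster
#'
#' Density of a line network in km per square km: for every cell, the total
#' network length inside a circular window centred on the cell divided by the
#' window area. Per-cell line lengths come from exact grid traversal; the
#' window sum is a discrete convolution with a circular kernel over cell
#' centres (a 1-km-diameter window by default).
#'
#' @param lines list of polyline coordinate matrices.
#' @param extent numeric length-4 `c(xmin, xmax, ymin, ymax)` (m).
#' @param cell_size raster resolution (m).
#' @param window_radius radius of the circular window (m).
#' @return a [grid_raster()] in km/km^2.
#' @export
line_density <- function(lines, extent, cell_size = 30, window_radius = 500) {
  n_cols <- max(1L, ceiling((extent[2] - extent[1]) / cell_size))
  n_rows <- max(1L, ceiling((extent[4] - extent[3]) / cell_size))
  r <- grid_raster(matrix(0, n_rows, n_cols),
                   origin = c(extent[1], extent[3]),
                   cell_size = cell_size, units = "km/km2")
  lenm <- matrix(0, n_rows, n_cols)
  for (line in lines) {
    if (nrow(line) < 2) next
    for (i in seq_len(nrow(line) - 1)) {
      tr <- grid_traverse(r, line[i, 1], line[i, 2],
                          line[i + 1, 1], line[i + 1, 2])
      if (nrow(tr)) {
        agg <- rowsum(tr$len, paste(tr$row, tr$col))
        rc <- do.call(rbind, strsplit(rownames(agg), " "))
        lenm[cbind(as.integer(rc[, 1]), as.integer(rc[, 2]))] <-
          lenm[cbind(as.integer(rc[, 1]), as.integer(rc[, 2]))] + agg[, 1]
      }
    }
  }
  # circular-kernel moving sum via shifted adds
  kr <- floor(window_radius / cell_size)
  off <- expand.grid(dr = -kr:kr, dc = -kr:kr)
  off <- off[(off$dr^2 + off$dc^2) * cell_size^2 <= window_radius^2, ]
  acc <- matrix(0, n_rows, n_cols)
  for (k in seq_len(nrow(off))) {
    dr <- off$dr[k]; dc <- off$dc[k]
    sr <- max(1, 1 - dr):min(n_rows, n_rows - dr)
    sc <- max(1, 1 - dc):min(n_cols, n_cols - dc)
    acc[sr, sc] <- acc[sr, sc] + lenm[sr + dr, sc + dc]
  }
  area_km2 <- pi * (window_radius / 1000)^2
  r$values <- (acc / 1000) / area_km2
  r
}

#' Majority landcover of a line segment
#'
#' The landcover class whose raster cells intersect the greatest share of the
#' segment's length (exact length-by-class intersection via grid traversal).
#' Ties break to the first class in `classes`; a tie is flagged in the result.
#'
#' @param edges edge rows (from [segment_lines()]) of one segment.
#' @param landcover_raster [grid_raster()] of integer class codes
#'   `1..length(classes)`.
#' @param classes class labels, in tie-break priority order.
#' @return list with `class` (character), `lengths` (named, m), `tie` (logical).
#' @export
majority_landcover <- function(edges, landcover_raster,
                               classes = c("Con", "Mix", "NF")) {
  lens <- stats::setNames(numeric(length(classes)), classes)
  for (i in seq_len(nrow(edges))) {
    tr <- grid_traverse(landcover_raster, edges$x0[i], edges$y0[i],
                        edges$x1[i], edges$y1[i])
    if (!nrow(tr)) next
    v <- landcover_raster$values[cbind(tr$row, tr$col)]
    ok <- !is.na(v) & v != landcover_raster$nodata
    if (any(ok)) {
      agg <- rowsum(tr$len[ok], v[ok])
      lens[as.integer(rownames(agg))] <-
        lens[as.integer(rownames(agg))] + agg[, 1]
    }
  }
  if (all(lens == 0)) stop("segment intersects no classified landcover cells")
  best <- which(lens == max(lens))
  list(class = classes[best[1]], lengths = lens, tie = length(best) > 1)
}
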