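#' Lognormal vegetation-height parameters from a mean and a sub-1-m share
#'
#' Segment vegetation heights are right-skewed; a lognormal with mean
#' `veght_mean` and `P(height < 1 m) = p_below_1m` pins both the study-wide
#' mean and the share of the footprint below 1 m. Of the two admissible
#' sigma roots the larger (more skewed) is used, giving a realistic long
#' upper tail of tall regrowth.
#'
#' @param veght_mean target mean height (m).
#' @param p_below_1m target share of segments below 1 m.
#' @return named vector `c(meanlog, sdlog)`.
#' @export
veght_lognormal_params <- function(veght_mean = 0.81, p_below_1m = 0.75) {
  z <- stats::qnorm(p_below_1m)
  disc <- z^2 + 2 * log(veght_mean)
  if (disc < 0)
    stop("incompatible veght_mean and p_below_1m (no lognormal solution)")
  sdlog <- z + sqrt(disc)
  if (sdlog <= 0) stop("incompatible veght_mean and p_below_1m")
  c(meanlog = -sdlog * z, sdlog = sdlog)
}

#' Generate a synthetic seismic-line landscape
#'
#' Builds a square study landscape with known ground truth: a line network of
#' long parallel transects (spaced unevenly so line density has spatial
#' contrast) plus random cross-lines, segmented into ~100-m pieces; per-segment
#' vegetation heights drawn from a right-skewed lognormal; smooth depth-to-water
#' and landcover fields; a moving-window density raster; and a vegetation
#' height raster in which line corridors carry their segment's height against
#' a tall forest canopy background.
#'
#' @param seed integer RNG seed; fixed seed gives an identical landscape.
#' @param extent_m side length of the square extent (m); at least 2000.
#' @param line_density target line density (km/km^2); realized total length is
#'   within a few percent of `density * area`.
#' @param veght_mean mean segment vegetation height (m).
#' @param p_below_1m share of segments with height below 1 m.
#' @param cell_size raster resolution (m).
#' @param segment_length nominal line-segment length (m).
#' @param canopy_mean,canopy_sd background forest canopy height field (m).
#' @return object of class `seismic_landscape`: extent, cell size, the line
#'   list, an attributed segment edge table (`segments`: `segment_id`, edge
#'   coordinates, `length`, `veght`, `wam`, `ewam`, `landcover`, `density`),
#'   and `veght_raster`, `wam_raster`, `landcover_raster`, `density_raster`.
#' @export
make_landscape <- function(seed, extent_m = 5000, line_density = 1.45,
                           veght_mean = 0.81, p_below_1m = 0.75,
                           cell_size = 30, segment_length = 100,
                           canopy_mean = 10, canopy_sd = 2) {
  if (extent_m < 2000) stop("extent too small to place a line network")
  if (line_density <= 0) stop("line_density must be positive")
  set.seed(as.integer(seed))
  ext <- c(0, extent_m, 0, extent_m)
  area_km2 <- (extent_m / 1000)^2
  target_m <- line_density * area_km2 * 1000

  # ~70% of the length as full-height parallel transects with a west-to-east
  # spacing gradient; the rest as random cross-lines, clipped to the extent
  n_par <- max(1L, round(0.7 * target_m / extent_m))
  xpos <- extent_m * (seq_len(n_par) / (n_par + 1))^1.4
  xpos <- pmin(pmax(xpos + stats::rnorm(n_par, 0, extent_m * 0.01), 1),
               extent_m - 1)
  lines <- lapply(xpos, function(x) cbind(c(x, x), c(0, extent_m)))
  total <- n_par * extent_m
  while (total < target_m) {
    cx <- stats::runif(1, 0, extent_m); cy <- stats::runif(1, 0, extent_m)
    ang <- stats::runif(1, 0, pi); len <- stats::runif(1, 500, 2000)
    p0 <- c(cx - cos(ang) * len / 2, cy - sin(ang) * len / 2)
    p1 <- c(cx + cos(ang) * len / 2, cy + sin(ang) * len / 2)
    p0 <- pmin(pmax(p0, 0), extent_m); p1 <- pmin(pmax(p1, 0), extent_m)
    clen <- sqrt(sum((p1 - p0)^2))
    if (clen < 100) next
    lines[[length(lines) + 1]] <- rbind(p0, p1)
    total <- total + clen
  }

  edges <- segment_lines(lines, target_length = segment_length)
  segs <- segment_summary(edges)
  lp <- veght_lognormal_params(veght_mean, p_below_1m)
  segs$veght <- stats::rlnorm(nrow(segs), lp["meanlog"], lp["sdlog"])

  n_cells <- ceiling(extent_m / cell_size)
  wam_vals <- pmax(smooth_field(n_cells, n_cells, 7, 2, 1.6), 0)
  wam_raster <- grid_raster(wam_vals, c(0, 0), cell_size, units = "m")
  lc_field <- smooth_field(n_cells, n_cells, 6, 0, 1)
  lc_vals <- matrix(3L, n_cells, n_cells)          # NF
  lc_vals[lc_field < stats::quantile(lc_field, 0.75)] <- 2L  # Mix
  lc_vals[lc_field < stats::quantile(lc_field, 0.50)] <- 1L  # Con
  landcover_raster <- grid_raster(lc_vals, c(0, 0), cell_size,
                                  units = "class")

  # canopy background, line corridors carved down to segment heights
  veght_vals <- pmax(smooth_field(n_cells, n_cells, 9, canopy_mean,
                                  canopy_sd), 0)
  veght_raster <- grid_raster(veght_vals, c(0, 0), cell_size, units = "m")
  for (i in seq_len(nrow(edges))) {
    tr <- grid_traverse(veght_raster, edges$x0[i], edges$y0[i],
                        edges$x1[i], edges$y1[i])
    if (nrow(tr)) {
      sid <- edges$segment_id[i]
      veght_raster$values[cbind(tr$row, tr$col)] <-
        segs$veght[match(sid, segs$segment_id)]
    }
  }

  density_raster <- line_density(lines, ext, cell_size = cell_size)

  segs$wam <- raster_values_at(wam_raster, segs$mid_x, segs$mid_y)
  segs$ewam <- ewam_transform(segs$wam)
  lc_code <- raster_values_at(landcover_raster, segs$mid_x, segs$mid_y)
  segs$landcover <- c("Con", "Mix", "NF")[lc_code]
  segs$density <- raster_values_at(density_raster, segs$mid_x, segs$mid_y)

  seg_edges <- merge(edges, segs[, c("segment_id", "veght", "wam", "ewam",
                                     "landcover", "density")],
                     by = "segment_id", sort = TRUE)
  class(seg_edges) <- c("line_segments", "data.frame")
  structure(
    list(extent = ext, cell_size = cell_size, lines = lines,
         segments = seg_edges, segment_summary = segs,
         veght_raster = veght_raster, wam_raster = wam_raster,
         landcover_raster = landcover_raster, density_raster = density_raster,
         seed = as.integer(seed), target_density = line_density,
         realized_length_m = total),
    class = "seismic_landscape")
}

#' @export
print.seismic_landscape <- function(x, ...) {
  area <- diff(x$extent[1:2]) * diff(x$extent[3:4]) / 1e6
  cat(sprintf(
    "<seismic_landscape> %g x %g km, %d lines (%.1f km, %.2f km/km2), %d segments\n",
    diff(x$extent[1:2]) / 1000, diff(x$extent[3:4]) / 1000,
    length(x$lines), x$realized_length_m / 1000,
    x$realized_length_m / 1000 / area,
    length(unique(x$segments$segment_id))))
  cat(sprintf("  segment veght: mean %.2f m, %.0f%% below 1 m\n",
              mean(x$segment_summary$veght),
              100 * mean(x$segment_summary$veght < 1)))
  invisible(x)
}

#' Realized line density of a landscape
#' @param landscape a [make_landscape()] result.
#' @return km of line per km^2 of extent.
#' @export
realized_density <- function(landscape) {
  area <- diff(landscape$extent[1:2]) * diff(landscape$extent[3:4]) / 1e6
  network_length(landscape$lines) / 1000 / area
}
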