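#' Write and read fix tables as CSV
#'
#' Columns: `animal_id`, `species`, `sex`, `group`, `timestamp` (ISO-8601,
#' UTC), `x`, `y`, `pfix`. On reading, the inverse fix-probability weight
#' `1 / pfix` is reconstructed; a missing `pfix` column defaults to 1.
#'
#' @param fixes fix data frame (see [simulate_ssf_track()]).
#' @param path CSV file path.
#' @return `path` invisibly (write); fix data frame (read).
#' @export
write_fixes_csv <- function(fixes, path) {
  out <- data.frame(
    animal_id = fixes$animal_id, species = fixes$species, sex = fixes$sex,
    group = fixes$group,
    timestamp = format(fixes$t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    x = fixes$x, y = fixes$y, pfix = fixes$pfix)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fixes_csv
#' @export
read_fixes_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "species", "sex", "group", "timestamp", "x", "y")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("fix CSV is missing columns: ", paste(miss, collapse = ", "))
  if (is.null(d$pfix)) d$pfix <- 1
  if (any(!is.finite(d$x)) || any(!is.finite(d$y)))
    stop("non-finite coordinates in fix CSV (rows ",
         paste(utils::head(which(!is.finite(d$x) | !is.finite(d$y))),
               collapse = ", "), ")")
  if (any(d$pfix <= 0 | d$pfix > 1)) stop("pfix must be in (0, 1]")
  data.frame(animal_id = d$animal_id, species = d$species, sex = d$sex,
             group = d$group,
             t = as.POSIXct(d$timestamp, format = "%Y-%m-%dT%H:%M:%SZ",
                            tz = "UTC"),
             x = d$x, y = d$y, pfix = d$pfix, weight = 1 / d$pfix)
}

#' Write and read a line network as GeoJSON
#'
#' One `LineString` feature per polyline; when an attributed segment table is
#' supplied, one feature per segment with properties `veght_m`, `wam_m`,
#' `landcover`.
#'
#' @param lines list of polyline coordinate matrices, or `NULL` when writing
#'   `segments`.
#' @param path GeoJSON file path.
#' @param segments optional attributed `line_segments` table.
#' @return `path` invisibly (write); for reading, a list with `lines` and,
#'   when present, a `properties` data frame.
#' @export
write_lines_geojson <- function(lines, path, segments = NULL) {
  feats <- list()
  if (!is.null(segments)) {
    for (id in unique(segments$segment_id)) {
      e <- segments[segments$segment_id == id, , drop = FALSE]
      coords <- rbind(as.matrix(e[, c("x0", "y0")]),
                      as.matrix(e[nrow(e), c("x1", "y1"), drop = FALSE]))
      dimnames(coords) <- NULL
      props <- list(segment_id = id)
      if (!is.null(e$veght)) props$veght_m <- e$veght[1]
      if (!is.null(e$wam)) props$wam_m <- e$wam[1]
      if (!is.null(e$landcover)) props$landcover <- e$landcover[1]
      feats[[length(feats) + 1]] <- list(
        type = "Feature", properties = props,
        geometry = list(type = "LineString", coordinates = coords))
    }
  } else {
    for (line in lines) {
      dimnames(line) <- NULL
      feats[[length(feats) + 1]] <- list(
        type = "Feature", properties = stats::setNames(list(), character(0)),
        geometry = list(type = "LineString", coordinates = line))
    }
  }
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_lines_geojson
#' @export
read_lines_geojson <- function(path) {
  g <- jsonlite::read_json(path)
  if (is.null(g$features)) stop("not a GeoJSON FeatureCollection")
  lines <- list()
  props <- list()
  for (f in g$features) {
    if (!identical(f$geometry$type, "LineString")) next
    m <- do.call(rbind, lapply(f$geometry$coordinates,
                               function(p) as.numeric(unlist(p))))
    lines[[length(lines) + 1]] <- m
    props[[length(props) + 1]] <-
      as.data.frame(f$properties[lengths(f$properties) == 1])
  }
  keep <- vapply(props, ncol, 0L) > 0
  list(lines = lines,
       properties = if (any(keep)) do.call(rbind, props[keep]) else NULL)
}
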