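#' Exponential-decay transform of depth-to-water (eWAM)
#'
#' Maps depth-to-water (m) into `[0, 1)` via `1 - exp(-rate * depth)`. With the
#' default rate of 1.55 per metre the transform saturates rapidly beyond 2 m
#' and is effectively constant past 3 m, mirroring the rooting depth of boreal
#' vegetation: water deeper than roots can reach no longer limits regrowth.
#'
#' @param depth depth to water, metres (vector); must be non-negative.
#' @param rate decay rate, per metre.
#' @return numeric vector in `[0, 1)`.
#' @seealso [edist_transform()]
#' @export
#' @examples
#' ewam_transform(c(0, 1, 3))
ewam_transform <- function(depth, rate = 1.55) {
  if (any(depth < 0, na.rm = TRUE)) stop("depth-to-water must be >= 0")
  1 - exp(-rate * depth)
}

#' Exponential-decay transform of distance-to-line (eDist)
#'
#' Maps distance to the nearest seismic-line segment (m) into `[0, 1)` via
#' `1 - exp(-rate * distance)`. With the default rate of 0.002 per metre the
#' influence of a line decays rapidly beyond 500 m and is effectively constant
#' past 2 km; a point on a line maps to exactly 0.
#'
#' @param distance distance, metres (vector); must be non-negative.
#' @param rate decay rate, per metre.
#' @return numeric vector in `[0, 1)`.
#' @export
#' @examples
#' edist_transform(c(0, 500, 2000))
edist_transform <- function(distance, rate = 0.002) {
  if (any(distance < 0, na.rm = TRUE)) stop("distance must be >= 0")
  1 - exp(-rate * distance)
}
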