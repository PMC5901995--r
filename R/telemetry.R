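#' Rarefy a track to a nominal fix interval
#'
#' Greedy schedule walk: starting from the first fix, the next retained fix is
#' the one closest to (last retained time + `interval`), provided it falls
#' within `tolerance_min` minutes of that target. If no fix does (a gap), the
#' first fix after the gap restarts the schedule — no synthetic fixes are ever
#' invented. Rarefaction is idempotent at a fixed interval.
#'
#' @param track fix data frame ordered in time (column `t`, POSIXct).
#' @param interval target interval (h).
#' @param tolerance_min schedule tolerance (min).
#' @return the retained fixes.
#' @export
rarefy <- function(track, interval = 2, tolerance_min = 5) {
  stopifnot(interval > 0, nrow(track) >= 1)
  t <- as.numeric(track$t)
  if (is.unsorted(t, strictly = TRUE)) stop("timestamps must be increasing")
  tol <- tolerance_min * 60
  step <- interval * 3600
  keep <- 1L
  last <- 1L
  repeat {
    target <- t[last] + step
    cand <- which(t >= target - tol & t <= target + tol)
    cand <- cand[cand > last]
    if (length(cand)) {
      nxt <- cand[which.min(abs(t[cand] - target))]
    } else {
      nxt <- which(t > target + tol)[1]  # gap: restart at first later fix
      if (is.na(nxt)) break
    }
    keep <- c(keep, nxt)
    last <- nxt
  }
  out <- track[keep, , drop = FALSE]
  if (nrow(out) == 0) stop("rarefaction removed all fixes")
  rownames(out) <- NULL
  out
}

#' Classify fixes into movement and stationary states
#'
#' A maximal run of consecutive fixes is labelled stationary when its time
#' span strictly exceeds `min_duration` hours and every fix lies within
#' `radius` metres of the run centroid (resting and feeding-on-a-kill
#' behaviour); all other fixes are movement. The run is grown greedily from
#' its first fix, re-testing the centroid condition at each extension, which
#' makes the labels deterministic. Typical thresholds: wolves 6 h within
#' 300 m, grizzly bears 7 h within 100 m.
#'
#' @param track fix data frame ordered in time.
#' @param radius run radius (m).
#' @param min_duration minimum run time span (h).
#' @return character vector of `"movement"` / `"stationary"` labels, one per
#'   fix.
#' @export
classify_stationary <- function(track, radius = 300, min_duration = 6) {
  stopifnot(radius > 0)
  n <- nrow(track)
  t <- as.numeric(track$t) / 3600
  labels <- rep("movement", n)
  i <- 1L
  while (i <= n) {
    j <- i
    sx <- track$x[i]; sy <- track$y[i]
    while (j < n) {
      nx <- sx + track$x[j + 1]; ny <- sy + track$y[j + 1]
      k <- j + 1L - i + 1L
      cx <- nx / k; cy <- ny / k
      d <- sqrt((track$x[i:(j + 1)] - cx)^2 + (track$y[i:(j + 1)] - cy)^2)
      if (all(d <= radius)) { j <- j + 1L; sx <- nx; sy <- ny } else break
    }
    if (j > i && (t[j] - t[i]) > min_duration) {
      labels[i:j] <- "stationary"
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  labels
}

#' Biological season of a timestamp
#'
#' Wolf seasons partition the whole year: denning 20 Apr - 30 Jun, rendezvous
#' 1 Jul - 20 Sep, nomadic 21 Sep - 19 Apr. Grizzly bear seasons cover the
#' active period only: spring 1 May - 15 Jun, summer 16 Jun - 31 Jul, fall
#' 1 Aug - 15 Oct; dates outside these windows return
#' `"outside-study-season"`.
#'
#' @param t POSIXct timestamps.
#' @param species `"wolf"` or `"bear"` (recycled).
#' @return character vector of season labels.
#' @export
assign_season <- function(t, species) {
  n <- max(length(t), length(species))
  species <- rep_len(species, n)
  if (!all(species %in% c("wolf", "bear"))) stop("unknown species")
  md <- as.integer(format(t, "%m")) * 100 + as.integer(format(t, "%d"))
  md <- rep_len(md, n)
  out <- character(n)
  w <- species == "wolf"
  out[w & md >= 420 & md <= 630] <- "denning"
  out[w & md >= 701 & md <= 920] <- "rendezvous"
  out[w & (md >= 921 | md <= 419)] <- "nomadic"
  b <- species == "bear"
  out[b] <- "outside-study-season"
  out[b & md >= 501 & md <= 615] <- "spring"
  out[b & md >= 616 & md <= 731] <- "summer"
  out[b & md >= 801 & md <= 1015] <- "fall"
  out
}

#' Build movement steps from a state-labelled track
#'
#' One step per consecutive pair of movement fixes whose spacing matches the
#' nominal interval (within tolerance). Rates are in m/h — a 2-h 1000-m step
#' is 500 m/h. The turn angle is the signed bearing change from the previous
#' contiguous step in (-pi, pi], `NA` where no previous step exists. The step
#' takes the season of its start fix and the weight of its end fix (whose
#' covariates enter the selection likelihood).
#'
#' @param track fix data frame ordered in time for one animal.
#' @param states per-fix labels from [classify_stationary()]; default treats
#'   every fix as movement.
#' @param nominal_interval expected spacing (h); default is the median
#'   observed spacing.
#' @param tolerance_min spacing tolerance (min).
#' @return step data frame: identifiers, start/end coordinates and times,
#'   `length` (m), `duration` (h), `rate` (m/h), `bearing`, `turn_angle`,
#'   `season`, `weight`.
#' @export
build_steps <- function(track, states = NULL, nominal_interval = NULL,
                        tolerance_min = 5) {
  n <- nrow(track)
  if (n < 2) return(empty_steps())
  if (is.null(states)) states <- rep("movement", n)
  t <- as.numeric(track$t) / 3600
  dt <- diff(t)
  if (is.null(nominal_interval)) nominal_interval <- stats::median(dt)
  ok <- states[-n] == "movement" & states[-1] == "movement" &
    abs(dt - nominal_interval) <= tolerance_min / 60
  idx <- which(ok)
  if (!length(idx)) return(empty_steps())
  dx <- track$x[idx + 1] - track$x[idx]
  dy <- track$y[idx + 1] - track$y[idx]
  len <- sqrt(dx^2 + dy^2)
  bearing <- atan2(dy, dx)
  # previous contiguous step: the one ending at this step's start fix
  prev <- match(idx - 1L, idx)
  turn <- wrap_angle(bearing - bearing[prev])
  turn[is.na(prev)] <- NA_real_
  steps <- data.frame(
    animal_id = track$animal_id[idx],
    species = track$species[idx], sex = track$sex[idx],
    group = track$group[idx],
    t_start = track$t[idx], t_end = track$t[idx + 1],
    x_start = track$x[idx], y_start = track$y[idx],
    x_end = track$x[idx + 1], y_end = track$y[idx + 1],
    length = len, duration = dt[idx], rate = len / dt[idx],
    bearing = bearing, turn_angle = turn,
    season = assign_season(track$t[idx], track$species[idx]),
    weight = track$weight[idx + 1])
  rownames(steps) <- NULL
  steps
}

empty_steps <- function() {
  data.frame(animal_id = character(0), species = character(0),
             sex = character(0), group = character(0),
             t_start = as.POSIXct(character(0), tz = "UTC"),
             t_end = as.POSIXct(character(0), tz = "UTC"),
             x_start = numeric(0), y_start = numeric(0),
             x_end = numeric(0), y_end = numeric(0),
             length = numeric(0), duration = numeric(0), rate = numeric(0),
             bearing = numeric(0), turn_angle = numeric(0),
             season = character(0), weight = numeric(0))
}

#' Apply per-animal-per-season inclusion filters
#'
#' Animals with fewer than `min_per_season` steps in a season are dropped for
#' that season (broad-scale default 40 movement locations; the fine-scale
#' near-line dataset uses 20).
#'
#' @param steps step data frame with `animal_id` and `season` columns.
#' @param min_per_season inclusion threshold (a count of exactly
#'   `min_per_season` is retained).
#' @return list: `steps` (retained rows) and `report` (per animal-season
#'   counts with a `retained` flag).
#' @export
apply_inclusion_filters <- function(steps, min_per_season = 40) {
  key <- interaction(steps$animal_id, steps$season, drop = TRUE)
  counts <- as.data.frame(table(key))
  parts <- do.call(rbind, strsplit(as.character(counts$key), ".",
                                   fixed = TRUE))
  report <- data.frame(animal_id = parts[, 1], season = parts[, 2],
                       n = counts$Freq,
                       retained = counts$Freq >= min_per_season)
  keep <- report$retained[match(key, counts$key)]
  out <- steps[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    print(report)
    stop("all data excluded by the inclusion filter")
  }
  rownames(out) <- NULL
  list(steps = out, report = report)
}
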