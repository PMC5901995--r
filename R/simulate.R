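#' Ground truth for simulation
#'
#' Bundles the generative selection coefficients, the movement kernel and the
#' movement-rate breakpoint so downstream parameter-recovery tests can compare
#' estimates to truth. Coefficient names are products over the step-end
#' covariates (`eDist`, `Veght`, `eWAM`, `Density`, and landcover indicators
#' `fLandCon`/`fLandMix`), e.g. `c(eDist = -1, "eDist:Veght" = 0.5)`. A
#' negative `eDist` coefficient is attraction: steps ending nearer lines are
#' preferred.
#'
#' @param beta named numeric vector of selection coefficients.
#' @param kernel list: `shape`, `scale` of the gamma step-length kernel (m per
#'   fix interval) and `kappa` of the von Mises turn-angle kernel (centred at
#'   0; `kappa = 0` is a uniform turn).
#' @param breakpoint vegetation height (m) at which the movement-rate slope
#'   changes in rate simulations.
#' @param seed default RNG seed for simulators using this truth.
#' @return object of class `simulation_truth`.
#' @export
simulation_truth <- function(beta = c(eDist = -1),
                             kernel = list(shape = 2, scale = 250,
                                           kappa = 0.5),
                             breakpoint = 0.7, seed = 1L) {
  stopifnot(!is.null(names(beta)), all(nzchar(names(beta))))
  structure(list(beta = beta, kernel = kernel, breakpoint = breakpoint,
                 seed = as.integer(seed)),
            class = "simulation_truth")
}

# von Mises sampler (Best & Fisher 1979 rejection method, batched)
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(16L, ceiling(1.3 * (n - length(out))))
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    acc <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    out <- c(out, (sign(u3 - 0.5) * acos(pmin(pmax(f, -1), 1)))[acc])
  }
  wrap_angle(mu + out[seq_len(n)])
}

#' Precompute a gridded covariate lookup for a landscape
#'
#' Evaluates distance-to-nearest-segment and the nearest segment's attributes
#' at every cell centre of a regular grid (default: the landscape's 30-m
#' resolution, mirroring the resolution at which the study-area covariates
#' are mapped). Point lookups then cost O(1), which makes the step simulator
#' and large stratum builds fast while keeping the generative and inferential
#' covariate definitions identical.
#'
#' @param landscape a [make_landscape()] result.
#' @param cell_size lookup resolution (m).
#' @param edist_rate decay rate for [edist_transform()].
#' @return object of class `covariate_index`.
#' @export
covariate_index <- function(landscape, cell_size = landscape$cell_size,
                            edist_rate = 0.002) {
  ext <- landscape$extent
  segs <- landscape$segments
  n_cols <- ceiling((ext[2] - ext[1]) / cell_size)
  n_rows <- ceiling((ext[4] - ext[3]) / cell_size)
  cx <- ext[1] + (seq_len(n_cols) - 0.5) * cell_size
  cy <- ext[3] + (seq_len(n_rows) - 0.5) * cell_size
  pts_x <- rep(cx, each = n_rows)
  pts_y <- rep(cy, times = n_cols)
  nd <- nearest_segment(pts_x, pts_y, segs, chunk = 4000L)
  i <- match(nd$segment_id, segs$segment_id)
  dim_ <- c(n_rows, n_cols)
  structure(list(
    origin = c(ext[1], ext[3]), cell_size = cell_size,
    n_rows = n_rows, n_cols = n_cols, edist_rate = edist_rate,
    distance = matrix(nd$distance, n_rows, n_cols),
    edist = matrix(edist_transform(nd$distance, edist_rate), dim_[1]),
    veght = matrix(segs$veght[i], dim_[1]),
    ewam = matrix(segs$ewam[i], dim_[1]),
    density = matrix(segs$density[i], dim_[1]),
    landcover = matrix(segs$landcover[i], dim_[1]),
    segment_id = matrix(nd$segment_id, dim_[1])),
    class = "covariate_index")
}

# O(1) covariate lookup at points (clamped to the index extent)
lookup_covariates <- function(ci, x, y) {
  col <- pmin.int(pmax.int(floor((x - ci$origin[1]) / ci$cell_size) + 1L, 1L),
                  ci$n_cols)
  row <- pmin.int(pmax.int(floor((y - ci$origin[2]) / ci$cell_size) + 1L, 1L),
                  ci$n_rows)
  k <- cbind(row, col)
  list(eDist = ci$edist[k], Veght = ci$veght[k], eWAM = ci$ewam[k],
       Density = ci$density[k],
       fLand = factor(ci$landcover[k], levels = c("NF", "Con", "Mix")),
       distance = ci$distance[k], segment_id = ci$segment_id[k])
}

wrap_angle <- function(a) {
  a <- (a + pi) %% (2 * pi) - pi
  a[a <= -pi] <- pi
  a
}

# step-end covariates at points: eDist plus attributes of the nearest segment
step_covariates <- function(x, y, segments, edist_rate = 0.002) {
  nd <- nearest_segment(x, y, segments)
  i <- match(nd$segment_id, segments$segment_id)
  data.frame(
    eDist = edist_transform(nd$distance, edist_rate),
    Veght = segments$veght[i],
    eWAM = segments$ewam[i],
    Density = segments$density[i],
    fLand = factor(segments$landcover[i], levels = c("NF", "Con", "Mix")),
    distance = nd$distance,
    segment_id = nd$segment_id)
}

# linear predictor from a named coefficient vector; names are ":"-joined
# products of covariate columns (landcover indicators as fLandCon etc.)
lp_from_beta <- function(cov, beta) {
  lp <- rep(0, length(cov[["eDist"]]))
  base <- function(nm) {
    if (nm %in% c("fLandCon", "fLandMix", "fLandNF"))
      return(as.numeric(cov$fLand == sub("^fLand", "", nm)))
    if (!nm %in% names(cov)) stop(sprintf("unknown covariate '%s'", nm))
    cov[[nm]]
  }
  for (term in names(beta)) {
    parts <- strsplit(term, ":", fixed = TRUE)[[1]]
    col <- Reduce(`*`, lapply(parts, base))
    lp <- lp + beta[[term]] * col
  }
  lp
}

#' Simulate a GPS track under a known step-selection kernel
#'
#' A biased correlated random walk: at every fix, `m_candidates` candidate
#' endpoints are proposed from the gamma/von Mises movement kernel and one is
#' chosen with probability proportional to `exp(beta' x)` of its step-end
#' covariates. A large candidate set (default 50, well above the 10 used in
#' fitting) makes the discrete choice a close approximation of the continuous
#' selection kernel. Candidates falling outside the extent are reflected at
#' the boundary; the number of reflections is recorded as an attribute.
#'
#' @param landscape a [make_landscape()] result.
#' @param truth a [simulation_truth()].
#' @param n_steps number of steps (the track has `n_steps + 1` fixes).
#' @param fix_interval hours between fixes.
#' @param animal_id,species,sex,group identifiers stamped on every fix.
#' @param start_time first timestamp (POSIXct, UTC).
#' @param start_xy optional start coordinates; default is the extent centre.
#' @param m_candidates candidate endpoints per step.
#' @param cov_index optional [covariate_index()]; built on the fly when
#'   absent. Pass one explicitly when simulating many tracks on the same
#'   landscape.
#' @param seed RNG seed; defaults to `truth$seed`.
#' @return fix data frame (`animal_id`, `species`, `sex`, `group`, `t`, `x`,
#'   `y`, `pfix`, `weight`) ordered in time.
#' @export
simulate_ssf_track <- function(landscape, truth, n_steps = 300,
                               fix_interval = 2, animal_id = "A01",
                               species = "wolf", sex = "F", group = "P1",
                               start_time = as.POSIXct("2006-07-02 00:00:00",
                                                       tz = "UTC"),
                               start_xy = NULL, m_candidates = 50,
                               cov_index = NULL, seed = truth$seed) {
  if (is.null(cov_index)) cov_index <- covariate_index(landscape)
  set.seed(as.integer(seed))
  ext <- landscape$extent
  if (is.null(start_xy))
    start_xy <- c(mean(ext[1:2]), mean(ext[3:4]))
  pos <- start_xy
  bearing <- stats::runif(1, -pi, pi)
  kern <- truth$kernel
  xs <- numeric(n_steps + 1); ys <- numeric(n_steps + 1)
  xs[1] <- pos[1]; ys[1] <- pos[2]
  n_reflect <- 0L
  # pre-draw all candidate kernels in one batch
  len_all <- stats::rgamma(n_steps * m_candidates, shape = kern$shape,
                           scale = kern$scale)
  ang_all <- rvonmises(n_steps * m_candidates, 0, kern$kappa)
  for (i in seq_len(n_steps)) {
    j <- (i - 1L) * m_candidates + seq_len(m_candidates)
    len <- len_all[j]
    ang <- ang_all[j]
    br <- bearing + ang
    exx <- pos[1] + len * cos(br)
    eyy <- pos[2] + len * sin(br)
    refl <- exx < ext[1] | exx > ext[2] | eyy < ext[3] | eyy > ext[4]
    exx <- reflect_into(exx, ext[1], ext[2])
    eyy <- reflect_into(eyy, ext[3], ext[4])
    n_reflect <- n_reflect + sum(refl)
    cov <- lookup_covariates(cov_index, exx, eyy)
    lp <- lp_from_beta(cov, truth$beta)
    w <- exp(lp - max(lp))
    pick <- sample.int(m_candidates, 1, prob = w)
    new_pos <- c(exx[pick], eyy[pick])
    bearing <- atan2(new_pos[2] - pos[2], new_pos[1] - pos[1])
    pos <- new_pos
    xs[i + 1] <- pos[1]; ys[i + 1] <- pos[2]
  }
  out <- data.frame(
    animal_id = animal_id, species = species, sex = sex, group = group,
    t = start_time + 3600 * fix_interval * (0:n_steps),
    x = xs, y = ys, pfix = 1, weight = 1)
  attr(out, "n_reflected") <- n_reflect
  out
}

reflect_into <- function(v, lo, hi) {
  span <- hi - lo
  v <- (v - lo) %% (2 * span)
  v <- ifelse(v > span, 2 * span - v, v)
  v + lo
}

#' Inject stationary bouts into a track
#'
#' Inserts resting/feeding bouts: at `n_bouts` anchor fixes, extra fixes at
#' the track's fix interval are inserted for `bout_duration` hours, jittered
#' uniformly within `bout_radius` of the anchor location; later timestamps
#' shift by the bout duration. The anchor and inserted fixes carry a `bout_id`
#' column (NA elsewhere) as ground truth for the stationary classifier.
#'
#' @param track fix data frame from [simulate_ssf_track()].
#' @param bout_duration bout length (h); at least two fix intervals.
#' @param bout_radius jitter radius (m).
#' @param n_bouts number of bouts; 0 returns the track unchanged (with an
#'   all-NA `bout_id` column).
#' @param seed RNG seed.
#' @return the track with inserted fixes and a `bout_id` column.
#' @export
inject_stationary_bouts <- function(track, bout_duration = 10,
                                    bout_radius = 50, n_bouts = 3,
                                    seed = 1L) {
  set.seed(as.integer(seed))
  track$bout_id <- NA_integer_
  if (n_bouts == 0) return(track)
  dt <- as.numeric(difftime(track$t[2], track$t[1], units = "hours"))
  if (bout_duration < 2 * dt)
    stop("bout_duration must span at least two fix intervals")
  n_ins <- floor(bout_duration / dt)
  # spaced anchors, away from the track ends
  anchors <- sort(sample(seq(5L, nrow(track) - 5L),
                         n_bouts, replace = FALSE))
  pieces <- list(); prev <- 1L
  for (b in seq_along(anchors)) {
    a <- anchors[b]
    pre <- track[prev:a, , drop = FALSE]
    pre$bout_id[nrow(pre)] <- b  # anchor is part of the bout
    th <- stats::runif(n_ins, 0, 2 * pi)
    rr <- bout_radius * sqrt(stats::runif(n_ins))
    ins <- data.frame(
      animal_id = track$animal_id[a], species = track$species[a],
      sex = track$sex[a], group = track$group[a],
      t = track$t[a] + 3600 * dt * seq_len(n_ins),
      x = track$x[a] + rr * cos(th), y = track$y[a] + rr * sin(th),
      pfix = track$pfix[a], weight = track$weight[a],
      bout_id = b)
    pieces[[length(pieces) + 1]] <- pre
    pieces[[length(pieces) + 1]] <- ins
    prev <- a + 1L
  }
  pieces[[length(pieces) + 1]] <- track[prev:nrow(track), , drop = FALSE]
  out <- do.call(rbind, pieces)
  # shift timestamps after each insertion so the schedule stays strict
  out$t <- track$t[1] + 3600 * dt * (seq_len(nrow(out)) - 1L)
  rownames(out) <- NULL
  out
}

#' Thin a track by fix-success probability
#'
#' Each fix is retained independently with probability `pfix`; retained fixes
#' carry weight `1 / pfix`, the inverse-probability weight correcting
#' habitat-induced fix bias in downstream likelihoods.
#'
#' @param track fix data frame.
#' @param pfix per-fix success probability in (0, 1].
#' @param seed RNG seed.
#' @return thinned track with updated `pfix` and `weight` columns.
#' @export
thin_fixes <- function(track, pfix, seed = 1L) {
  if (pfix <= 0 || pfix > 1) stop("pfix must be in (0, 1]")
  set.seed(as.integer(seed))
  keep <- stats::runif(nrow(track)) <= pfix
  out <- track[keep, , drop = FALSE]
  out$pfix <- pfix
  out$weight <- 1 / pfix
  rownames(out) <- NULL
  out
}

#' Simulate a movement-rate dataset with a known breakpoint
#'
#' Generates near-line movement-rate observations: log movement rate follows a
#' continuous hinge in `log(Veght + 1)` with the kink at `truth$breakpoint`
#' metres of vegetation height, plus season and forest offsets, a Gaussian
#' per-individual random intercept and residual noise. Because the transform
#' is monotone, the kink location in metres is exactly `truth$breakpoint`.
#'
#' @param truth a [simulation_truth()]; `truth$breakpoint` is the hinge
#'   location (m).
#' @param n_obs observations to draw.
#' @param noise_sd residual standard deviation (log m/h units).
#' @param seed RNG seed.
#' @param n_individuals number of animals (random-intercept levels).
#' @param sd_individual random-intercept standard deviation.
#' @param intercept,slope_left,slope_right hinge parameters on the
#'   `log(Veght + 1)` scale (left slope below the kink, right above).
#' @param season_effects named offsets for seasons beyond the first.
#' @param forest_effect additive offset for observations in forest.
#' @param hinge_forest_only if TRUE the hinge applies only in forest
#'   (non-forest rates are flat in height), mimicking a
#'   height-by-season-by-forest interaction.
#' @param veght_meanlog,veght_sdlog lognormal draw for segment heights.
#' @return data frame: `animal_id`, `group`, `fSeason`, `fFor`, `veght`,
#'   `log_veght`, `log_rate`, plus the true random intercepts as an attribute.
#' @export
simulate_rate_data <- function(truth, n_obs = 300, noise_sd = 0.3, seed = 1L,
                               n_individuals = 10, sd_individual = 0.3,
                               intercept = 6, slope_left = 0.8,
                               slope_right = -1.5,
                               season_effects = c(rendezvous = 0.2,
                                                  nomadic = -0.1),
                               forest_effect = 0.15,
                               hinge_forest_only = FALSE,
                               veght_meanlog = NULL, veght_sdlog = NULL) {
  set.seed(as.integer(seed))
  if (is.null(veght_meanlog)) {
    lp <- veght_lognormal_params()
    veght_meanlog <- lp["meanlog"]; veght_sdlog <- lp["sdlog"]
  }
  bp <- truth$breakpoint
  veght <- stats::rlnorm(n_obs, veght_meanlog, veght_sdlog)
  x <- log1p(veght)
  cx <- log1p(bp)
  if (bp <= 0 || cx >= max(x))
    stop("breakpoint must lie within the simulated vegetation-height range")
  id <- sprintf("A%02d", sample.int(n_individuals, n_obs, replace = TRUE))
  u <- stats::rnorm(n_individuals, 0, sd_individual)
  names(u) <- sprintf("A%02d", seq_len(n_individuals))
  seasons <- c("denning", names(season_effects))
  fSeason <- factor(sample(seasons, n_obs, replace = TRUE), levels = seasons)
  fFor <- stats::rbinom(n_obs, 1, 0.6)
  hinge <- slope_left * pmin(x - cx, 0) + slope_right * pmax(x - cx, 0)
  if (hinge_forest_only) hinge <- hinge * fFor
  lp_fixed <- intercept + hinge +
    c(0, season_effects)[as.integer(fSeason)] + forest_effect * fFor
  y <- lp_fixed + u[id] + stats::rnorm(n_obs, 0, noise_sd)
  out <- data.frame(animal_id = id, group = "G1", fSeason = fSeason,
                    fFor = fFor, veght = veght, log_veght = x, log_rate = y)
  attr(out, "random_intercepts") <- u
  attr(out, "lp_fixed") <- lp_fixed
  out
}
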