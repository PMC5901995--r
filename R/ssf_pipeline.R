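#' Candidate step-selection model set
#'
#' The five-model broad-scale candidate set: distance only (null), then
#' distance crossed with vegetation height, with height and wetness, with
#' height and line density, and with height and landcover. Interactions
#' always carry their main effects.
#'
#' @return named list of model formulas (response `used`).
#' @export
ssf_model_set <- function() {
  list(M1 = used ~ eDist,
       M2 = used ~ eDist * Veght,
       M3 = used ~ eDist * Veght * eWAM,
       M4 = used ~ eDist * Veght * Density,
       M5 = used ~ eDist * Veght * fLand)
}

#' Step length / turn angle independence check
#'
#' Spearman rank correlation between step length and absolute turn angle.
#' Available steps are sampled by drawing the two independently, which is
#' defensible only when the observed correlation is weak; a warning is issued
#' above `threshold`.
#'
#' @param steps step data frame with `length` and `turn_angle`.
#' @param threshold warning threshold on `|rho|`.
#' @return Spearman rho (invisibly also attached attribute `n`).
#' @export
check_lt_ta_correlation <- function(steps, threshold = 0.115) {
  ok <- !is.na(steps$turn_angle)
  if (sum(ok) < 10) stop("need at least 10 steps with defined turn angles")
  rho <- stats::cor(steps$length[ok], abs(steps$turn_angle[ok]),
                    method = "spearman")
  if (abs(rho) > threshold)
    warning(sprintf(
      "step length and |turn angle| correlate (rho = %.3f > %.3f)",
      rho, threshold))
  attr(rho, "n") <- sum(ok)
  rho
}

#' Sample available steps for one used step
#'
#' Draws `K` step lengths and turn angles independently, with replacement,
#' from the empirical pools of the animal's species-sex-season group, and
#' projects endpoints from the used step's start point and the previous
#' step's bearing.
#'
#' @param x_start,y_start start coordinates (m).
#' @param prev_bearing absolute bearing of the previous step (radians); `NA`
#'   means the stratum cannot be formed.
#' @param length_pool,angle_pool empirical samples to draw from.
#' @param K number of available steps.
#' @return data frame of `K` endpoint rows (`x_end`, `y_end`, `length`,
#'   `turn_angle`), or `NULL` when `prev_bearing` is missing.
#' @export
sample_available <- function(x_start, y_start, prev_bearing,
                             length_pool, angle_pool, K = 10) {
  stopifnot(K >= 1, length(length_pool) >= 1, length(angle_pool) >= 1)
  if (is.na(prev_bearing)) return(NULL)
  len <- length_pool[sample.int(length(length_pool), K, replace = TRUE)]
  ang <- angle_pool[sample.int(length(angle_pool), K, replace = TRUE)]
  br <- prev_bearing + ang
  data.frame(x_end = x_start + len * cos(br),
             y_end = y_start + len * sin(br),
             length = len, turn_angle = ang)
}

#' Build used/available strata with step-end covariates
#'
#' For every used step with a defined previous bearing, samples `K` available
#' steps from the empirical length/angle pools of the step's
#' species-sex-season group (pool minimum 30, else the pool falls back to all
#' steps of the animal's species-sex), attaches step-end covariates from the
#' nearest attributed line segment, and stacks everything in long format.
#' Strata whose used step lacks a previous bearing are skipped and counted.
#'
#' @param steps step data frame (see [build_steps()]), with `cluster` column
#'   if robust errors are wanted.
#' @param segments attributed `line_segments` edge table.
#' @param K available steps per stratum.
#' @param seed RNG seed for the pool draws.
#' @param edist_rate decay rate for [edist_transform()].
#' @param cov_index optional [covariate_index()] for O(1) covariate lookups
#'   at the mapped resolution; exact point-to-segment distances are used when
#'   absent.
#' @param extent optional study-area rectangle `c(xmin, xmax, ymin, ymax)`;
#'   available endpoints are reflected at its boundary so the availability
#'   domain matches the domain movement is confined to (otherwise availables
#'   projected past the boundary would sit artificially far from any line,
#'   inflating apparent selection).
#' @return long data frame, `K + 1` rows per stratum: `stratum`, `used`,
#'   `animal_id`, `cluster`, `weight`, covariates `eDist`, `Veght`, `eWAM`,
#'   `Density`, `fLand`. Attribute `n_skipped` counts skipped strata.
#' @export
build_strata <- function(steps, segments, K = 10, seed = 1L,
                         edist_rate = 0.002, extent = NULL,
                         cov_index = NULL) {
  set.seed(as.integer(seed))
  grp <- interaction(steps$species, steps$sex, steps$season, drop = TRUE)
  has_angle <- !is.na(steps$turn_angle)
  prev_bearing <- steps$bearing - steps$turn_angle
  ok <- !is.na(prev_bearing)
  n_skipped <- sum(!ok)
  idx <- which(ok)
  if (!length(idx)) stop("no strata could be formed")
  nstr <- length(idx)
  # group-wise pool draws, vectorised over strata x K
  len_draw <- matrix(0, nstr, K)
  ang_draw <- matrix(0, nstr, K)
  all_pool <- which(has_angle)
  for (g in levels(grp)) {
    in_g <- which(grp[idx] == g)
    if (!length(in_g)) next
    pool <- which(grp == g & has_angle)
    if (length(pool) < 30) pool <- all_pool
    draws <- pool[sample.int(length(pool), length(in_g) * K, replace = TRUE)]
    len_draw[in_g, ] <- steps$length[draws]
    ang_draw[in_g, ] <- steps$turn_angle[draws]
  }
  br <- prev_bearing[idx] + ang_draw          # nstr x K
  ax <- steps$x_start[idx] + len_draw * cos(br)
  ay <- steps$y_start[idx] + len_draw * sin(br)
  if (!is.null(extent)) {
    ax <- reflect_into(ax, extent[1], extent[2])
    ay <- reflect_into(ay, extent[3], extent[4])
  }
  # member order: used step first, then its K availables, stratum by stratum
  ex <- as.vector(rbind(steps$x_end[idx], t(ax)))
  ey <- as.vector(rbind(steps$y_end[idx], t(ay)))
  cv <- if (is.null(cov_index))
    step_covariates(ex, ey, segments, edist_rate)
  else as.data.frame(lookup_covariates(cov_index, ex, ey)[
    c("eDist", "Veght", "eWAM", "Density", "fLand")])
  out <- data.frame(
    stratum = rep(idx, each = K + 1),
    used = rep(c(1, rep(0, K)), nstr),
    animal_id = rep(steps$animal_id[idx], each = K + 1),
    cluster = if ("cluster" %in% names(steps))
      rep(steps$cluster[idx], each = K + 1)
    else rep(steps$animal_id[idx], each = K + 1),
    weight = rep(steps$weight[idx], each = K + 1),
    cv[, c("eDist", "Veght", "eWAM", "Density", "fLand")])
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Drop pack-correlated contemporaneous steps
#'
#' When animals of the same pack take steps at the same nominal timestamp and
#' their start points form a group in which each member is within `radius` of
#' another (transitive closure), exactly one step of the group is retained,
#' chosen uniformly at random.
#'
#' @param steps step data frame with `group` and `t_start`.
#' @param radius proximity radius (m).
#' @param seed RNG seed for the uniform choice.
#' @return retained steps; attribute `n_removed` counts drops.
#' @export
filter_pack_correlated <- function(steps, radius = 200, seed = 1L) {
  set.seed(as.integer(seed))
  key <- paste(steps$group, as.numeric(steps$t_start))
  drop <- logical(nrow(steps))
  for (k in unique(key[duplicated(key)])) {
    idx <- which(key == k)
    d <- as.matrix(stats::dist(cbind(steps$x_start[idx],
                                     steps$y_start[idx])))
    # connected components under the within-radius relation
    comp <- seq_along(idx)
    repeat {
      changed <- FALSE
      for (a in seq_along(idx)) for (b in seq_along(idx)) {
        if (d[a, b] <= radius && comp[b] != comp[a]) {
          comp[comp == comp[b]] <- comp[a]; changed <- TRUE
        }
      }
      if (!changed) break
    }
    for (cc in unique(comp)) {
      members <- idx[comp == cc]
      if (length(members) > 1) {
        keep <- members[sample.int(length(members), 1)]
        drop[setdiff(members, keep)] <- TRUE
      }
    }
  }
  out <- steps[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(drop)
  out
}

#' Assign independence clusters to time-ordered steps
#'
#' Rolling-span rule: a new cluster starts whenever the time since the
#' current cluster's first step exceeds `gap_hours` (wolves 120 h = 5 days,
#' grizzly bears 24 h). Successive steps inside a span share a cluster for
#' the cluster-robust sandwich covariance.
#'
#' @param times POSIXct step start times, non-decreasing.
#' @param gap_hours span threshold (h).
#' @return integer cluster ids.
#' @export
assign_clusters <- function(times, gap_hours = 120) {
  t <- as.numeric(times) / 3600
  if (is.unsorted(t)) stop("steps must be time-ordered")
  n <- length(t)
  id <- integer(n)
  cur <- 1L; t0 <- t[1]
  for (i in seq_len(n)) {
    if (t[i] - t0 > gap_hours) { cur <- cur + 1L; t0 <- t[i] }
    id[i] <- cur
  }
  id
}

#' QIC_U model competition table
#'
#' Ranks conditional-logistic fits of the same strata by
#' `QIC_U = -2 loglik + 2 p` and attaches Akaike-style model weights
#' `w_i = exp(-delta_i / 2) / sum_j exp(-delta_j / 2)`.
#'
#' @param fits named list of [fit_clogit()] results on identical strata.
#' @return data frame ordered by QIC_U: `model`, `n_params`, `loglik`,
#'   `qicu`, `delta`, `weight`.
#' @export
qicu_select <- function(fits) {
  stopifnot(length(fits) >= 1)
  ns <- vapply(fits, function(f) f$n_strata, 0)
  if (length(unique(ns)) != 1)
    stop("fits were not computed on identical strata")
  tab <- data.frame(
    model = names(fits),
    n_params = vapply(fits, function(f) f$n_params, 0),
    loglik = vapply(fits, function(f) f$loglik, 0),
    qicu = vapply(fits, function(f) f$qicu, 0))
  tab$delta <- tab$qicu - min(tab$qicu)
  tab$weight <- exp(-tab$delta / 2) / sum(exp(-tab$delta / 2))
  tab <- tab[order(tab$qicu), ]
  rownames(tab) <- NULL
  tab
}

#' Pool individual coefficients by inverse-variance weighting
#'
#' Two-stage population inference: the selected model is refit per
#' individual; each coefficient is pooled as
#' `sum_i (beta_i / v_i) / sum_i (1 / v_i)` with `v_i` the individual's
#' (robust, when available) variance, and the 95% CI half-width is
#' `1.96 * (sum_i 1 / v_i)^(-1/2)`. Non-converged fits are excluded with a
#' note.
#'
#' @param fits named list (by animal) of [fit_clogit()] results of one model.
#' @return object of class `ssf_population`: a coefficient table plus the
#'   per-individual inputs.
#' @export
population_average <- function(fits) {
  conv <- vapply(fits, function(f) isTRUE(f$converged), TRUE)
  excluded <- names(fits)[!conv]
  if (length(excluded))
    message("excluding non-converged individual fits: ",
            paste(excluded, collapse = ", "))
  fits <- fits[conv]
  if (length(fits) < 2) stop("need at least 2 converged individual fits")
  terms <- fits[[1]]$terms
  betas <- do.call(rbind, lapply(fits, function(f) f$coefficients[terms]))
  vars <- do.call(rbind, lapply(fits, function(f) {
    V <- as.matrix(vcov(f))
    stats::setNames(diag(V), colnames(V))[terms]
  }))
  wsum <- colSums(1 / vars)
  pooled <- colSums(betas / vars) / wsum
  tab <- data.frame(term = terms, beta = pooled,
                    ci_halfwidth = 1.96 / sqrt(wsum),
                    n_individuals = nrow(betas))
  rownames(tab) <- NULL
  structure(list(table = tab, individual_beta = betas,
                 individual_var = vars, excluded = excluded),
            class = "ssf_population")
}

#' @export
print.ssf_population <- function(x, ...) {
  cat(sprintf("Population-averaged SSF coefficients (%d individuals)\n",
              x$table$n_individuals[1]))
  print(transform(x$table, beta = round(beta, 4),
                  ci_halfwidth = round(ci_halfwidth, 4)))
  invisible(x)
}

#' Rank-frequency k-fold cross-validation of an SSF
#'
#' Repeatedly partitions strata into training (80%) and testing (20%) sets;
#' the model is refit on the training strata, each test stratum's `K + 1`
#' member scores are ranked (average ranks on ties, rounded to bins), and the
#' frequency of each rank among used steps is correlated (Spearman) with the
#' rank index: `r_s1`. The same tally with one randomly chosen available step
#' standing in for the used step gives the null statistic `r_s0`. A
#' discriminating model has mean `r_s1` near 1 and mean `r_s0` near 0.
#'
#' @param formula model formula (response `used`).
#' @param data long strata data frame (see [build_strata()]).
#' @param strata stratum column name.
#' @param reps repetitions.
#' @param train_frac training fraction of strata.
#' @param seed RNG seed.
#' @param weights optional weight column passed to the training fits.
#' @return list: `rs1_mean`, `rs1_range`, `rs0_mean`, `rs0_range`, per-rep
#'   vectors `rs1`, `rs0`, and `n_skipped` reps.
#' @export
kfold_cv <- function(formula, data, strata = "stratum", reps = 100,
                     train_frac = 0.8, seed = 1L, weights = NULL) {
  set.seed(as.integer(seed))
  sid <- data[[strata]]
  ids <- unique(sid)
  if (length(ids) < 25) stop("need at least 25 strata for cross-validation")
  rs1 <- rs0 <- rep(NA_real_, reps)
  n_skipped <- 0L
  for (r in seq_len(reps)) {
    train_ids <- sample(ids, floor(train_frac * length(ids)))
    test_ids <- setdiff(ids, train_ids)
    if (!length(test_ids) || !length(train_ids)) {
      n_skipped <- n_skipped + 1L; next
    }
    train <- data[sid %in% train_ids, , drop = FALSE]
    fit <- tryCatch(
      fit_clogit(formula, train, strata = strata, weights = weights),
      error = function(e) NULL)
    if (is.null(fit)) { n_skipped <- n_skipped + 1L; next }
    test <- data[sid %in% test_ids, , drop = FALSE]
    lp <- predict(fit, test, type = "lp")
    ranks <- stats::ave(lp, test[[strata]], FUN = rank)
    Kp1 <- max(table(test[[strata]]))
    used_ranks <- round(ranks[test$used == 1])
    f1 <- tabulate(used_ranks, nbins = Kp1)
    rs1[r] <- suppressWarnings(
      stats::cor(seq_len(Kp1), f1, method = "spearman"))
    # pseudo-used: one random available step per test stratum
    avail_idx <- which(test$used == 0)
    pick <- vapply(split(avail_idx, test[[strata]][avail_idx]),
                   function(v) v[sample.int(length(v), 1)], 0L)
    f0 <- tabulate(round(ranks[pick]), nbins = Kp1)
    rs0[r] <- suppressWarnings(
      stats::cor(seq_len(Kp1), f0, method = "spearman"))
  }
  list(rs1_mean = mean(rs1, na.rm = TRUE), rs1_range = range(rs1, na.rm = TRUE),
       rs0_mean = mean(rs0, na.rm = TRUE), rs0_range = range(rs0, na.rm = TRUE),
       rs1 = rs1, rs0 = rs0, n_skipped = n_skipped)
}

#' Screen covariates for collinearity
#'
#' Flags covariate pairs with `|r| > r_max` (dropping the later-listed
#' member) and then, iteratively, columns with variance inflation factors
#' above `vif_max` (dropping the later-listed worst offender), so the
#' surviving design is stable for conditional logistic fitting.
#'
#' @param covariates data frame of numeric covariates.
#' @param r_max pairwise correlation threshold.
#' @param vif_max variance-inflation threshold.
#' @return list: `keep` (surviving column names), `dropped`, and a `report`
#'   data frame of every decision.
#' @export
screen_collinearity <- function(covariates, r_max = 0.6, vif_max = 3) {
  num <- covariates[vapply(covariates, is.numeric, TRUE)]
  keep <- names(num)
  report <- data.frame(column = character(0), reason = character(0),
                       value = numeric(0))
  if (length(keep) >= 2) {
    cm <- abs(stats::cor(num))
    for (a in seq_len(ncol(cm) - 1)) for (b in (a + 1):ncol(cm)) {
      ca <- colnames(cm)[a]; cb <- colnames(cm)[b]
      if (ca %in% keep && cb %in% keep && cm[a, b] > r_max) {
        keep <- setdiff(keep, cb)
        report <- rbind(report, data.frame(
          column = cb, reason = sprintf("|r| with %s", ca),
          value = cm[a, b]))
      }
    }
  }
  repeat {
    if (length(keep) < 2) break
    vifs <- vapply(keep, function(cn) {
      r2 <- summary(stats::lm(
        stats::reformulate(setdiff(keep, cn), response = cn),
        data = num))$r.squared
      1 / max(1 - r2, 1e-12)
    }, 0)
    bad <- which(vifs > vif_max)
    if (!length(bad)) break
    worst <- keep[max(bad)]  # later-listed offender
    report <- rbind(report, data.frame(column = worst, reason = "VIF",
                                       value = vifs[max(bad)]))
    keep <- setdiff(keep, worst)
  }
  list(keep = keep, dropped = setdiff(names(num), keep), report = report)
}
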