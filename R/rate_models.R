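#' Candidate movement-rate model set
#'
#' Fine-scale candidates: season only (null), vegetation height crossed with
#' season, and height crossed with season and forest/non-forest. Response is
#' log movement rate (m/h); the height covariate is `log(Veght + 1)`.
#'
#' @return named list of fixed-effect formulas.
#' @export
rate_model_set <- function() {
  list(M6 = log_rate ~ fSeason,
       M7 = log_rate ~ log_veght * fSeason,
       M8 = log_rate ~ log_veght * fSeason * fFor)
}

#' Assemble the near-line movement-rate dataset
#'
#' Retains movement steps whose end fix lies within `max_distance` of a line
#' segment, attaches the nearest segment's attributes, log-transforms rate
#' and height, and applies the per-animal-per-season minimum (default 20
#' qualifying locations). Wolf steps at 2-h intervals have already been
#' converted to m/h by [build_steps()] (distance divided by the 2-h
#' duration).
#'
#' @param steps movement step data frame (see [build_steps()]).
#' @param segments attributed `line_segments` edge table.
#' @param max_distance buffer distance (m).
#' @param min_per_season inclusion threshold per animal-season.
#' @return list: `data` (columns `animal_id`, `group`, `fSeason`, `fFor`,
#'   `veght`, `log_veght`, `log_rate`, `distance`), `report` from the
#'   inclusion filter, and `n_within_buffer`.
#' @export
build_rate_dataset <- function(steps, segments, max_distance = 100,
                               min_per_season = 20) {
  if (!nrow(steps)) stop("no steps supplied")
  nd <- nearest_segment(steps$x_end, steps$y_end, segments)
  within <- nd$distance <= max_distance & steps$rate > 0
  if (!any(within)) stop("no steps within the line buffer")
  i <- match(nd$segment_id[within], segments$segment_id)
  d <- data.frame(
    animal_id = steps$animal_id[within],
    group = steps$group[within],
    season = steps$season[within],
    veght = segments$veght[i],
    fFor = as.integer(segments$landcover[i] != "NF"),
    log_rate = log(steps$rate[within]),
    distance = nd$distance[within])
  d$log_veght <- log1p(d$veght)
  filt <- apply_inclusion_filters(d, min_per_season = min_per_season)
  out <- filt$steps
  out$fSeason <- factor(out$season)
  list(data = out, report = filt$report, n_within_buffer = sum(within))
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 loglik + 2 p + 2 p (p + 1) / (n - p - 1)`; approaches AIC as
#' `n` grows.
#'
#' @param loglik model log-likelihood.
#' @param n observations.
#' @param p parameter count.
#' @return AICc value.
#' @export
aicc <- function(loglik, n, p) {
  if (n <= p + 1) stop("AICc undefined: n must exceed p + 1")
  -2 * loglik + 2 * p + 2 * p * (p + 1) / (n - p - 1)
}

#' Fit a Gaussian random-intercept movement-rate model
#'
#' Wraps a linear mixed model (REML for reported estimates and variance
#' components; a maximum-likelihood refit supplies the log-likelihood used by
#' AICc so fixed-effect structures are comparable). Fixed-effect confidence
#' intervals are normal-approximation half-widths `1.96 * SE`. A singular
#' random structure is reported with the variance pinned at zero, not an
#' error.
#'
#' @param fixed fixed-effects formula, response `log_rate`.
#' @param data rate dataset (see [build_rate_dataset()]).
#' @param random `"individual"` for `(1 | animal_id)` or
#'   `"individual_in_group"` for `(1 | group / animal_id)`.
#' @return object of class `rate_lmm`: the underlying fits, a coefficient
#'   table with CI half-widths and a CI-excludes-zero flag, variance
#'   components, `aicc`, `r2_marginal`, `r2_conditional`.
#' @export
fit_rate_lmm <- function(fixed, data,
                         random = c("individual", "individual_in_group")) {
  random <- match.arg(random)
  fixed <- drop_constant_terms(fixed, data)
  re <- switch(random, individual = "(1 | animal_id)",
               individual_in_group = "(1 | group) + (1 | group:animal_id)")
  form <- stats::as.formula(paste(deparse(fixed), "+", re))
  fit <- suppressMessages(lme4::lmer(form, data = data, REML = TRUE))
  fit_ml <- suppressMessages(lme4::lmer(form, data = data, REML = FALSE))
  n <- nrow(data)
  p <- attr(stats::logLik(fit_ml), "df")
  ic <- aicc(as.numeric(stats::logLik(fit_ml)), n, p)
  be <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  tab <- data.frame(term = names(be), beta = as.numeric(be), se = se,
                    ci_halfwidth = 1.96 * se,
                    significant = abs(be) > 1.96 * se)
  rownames(tab) <- NULL
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_random <- sum(vc$vcov[vc$grp != "Residual"])
  var_resid <- vc$vcov[vc$grp == "Residual"]
  r2 <- r2_components(stats::var(stats::predict(fit, re.form = NA)),
                      var_random, var_resid)
  structure(list(
    fit = fit, fit_ml = fit_ml, fixed = fixed, random = random,
    coefficients = tab, var_random = var_random, var_resid = var_resid,
    varcorr = vc, n = n, p = p, aicc = ic,
    r2_marginal = unname(r2[1]), r2_conditional = unname(r2[2]),
    singular = lme4::isSingular(fit)),
    class = "rate_lmm")
}

# drop fixed-effect terms involving factors with a single observed level
# (e.g. a one-season dataset), keeping the model estimable
drop_constant_terms <- function(fixed, data) {
  vars <- all.vars(fixed[[3]])
  constant <- vars[vapply(vars, function(v) {
    x <- data[[v]]
    !is.null(x) && !is.numeric(x) && length(unique(as.character(x))) < 2
  }, TRUE)]
  if (!length(constant)) return(fixed)
  labs <- attr(stats::terms(fixed), "term.labels")
  keep <- labs[!vapply(labs, function(l)
    any(constant %in% all.vars(stats::reformulate(l))), TRUE)]
  resp <- deparse(fixed[[2]])
  message("dropping constant-factor terms: ",
          paste(setdiff(labs, keep), collapse = ", "))
  if (!length(keep)) return(stats::as.formula(paste(resp, "~ 1")))
  stats::reformulate(keep, response = resp)
}

# variance-decomposition R2 for a Gaussian identity-link mixed model
r2_components <- function(var_fixed, var_random, var_resid) {
  total <- var_fixed + var_random + var_resid
  if (total <= 0) stop("zero total variance")
  c(marginal = var_fixed / total,
    conditional = (var_fixed + var_random) / total)
}

#' Marginal and conditional R-squared of a mixed model
#'
#' Variance-decomposition R2: the marginal value is the share of total
#' variance (fixed predictor + random intercepts + residual) explained by the
#' fixed effects; the conditional value adds the random-effect variance.
#' Always `r2_marginal <= r2_conditional`, with equality iff the random
#' variance is zero.
#'
#' @param fit a [fit_rate_lmm()] result.
#' @return named numeric `c(marginal, conditional)`.
#' @export
r2_nakagawa <- function(fit) {
  stopifnot(inherits(fit, "rate_lmm"))
  c(marginal = unname(fit$r2_marginal),
    conditional = unname(fit$r2_conditional))
}

#' @export
print.rate_lmm <- function(x, ...) {
  cat(sprintf(
    "Movement-rate mixed model (random: %s%s)\n  n = %d, AICc = %.3f, R2m = %.3f, R2c = %.3f\n",
    x$random, if (x$singular) ", singular" else "", x$n, x$aicc,
    x$r2_marginal, x$r2_conditional))
  print(transform(x$coefficients, beta = round(beta, 3),
                  se = round(se, 3), ci_halfwidth = round(ci_halfwidth, 3)))
  invisible(x)
}

#' @export
coef.rate_lmm <- function(object, ...) {
  stats::setNames(object$coefficients$beta, object$coefficients$term)
}

#' Compare movement-rate models by AICc
#'
#' @param data rate dataset.
#' @param models named list of fixed-effect formulas
#'   (default [rate_model_set()]).
#' @param random random-intercept structure passed to [fit_rate_lmm()].
#' @return list: `table` (AICc ranking with delta and Akaike weights) and
#'   `fits`.
#' @export
select_rate_model <- function(data, models = rate_model_set(),
                              random = "individual") {
  fits <- lapply(models, fit_rate_lmm, data = data, random = random)
  tab <- data.frame(
    model = names(fits),
    p = vapply(fits, function(f) f$p, 0),
    loglik_ml = vapply(fits, function(f)
      as.numeric(stats::logLik(f$fit_ml)), 0),
    aicc = vapply(fits, function(f) f$aicc, 0))
  tab$delta <- tab$aicc - min(tab$aicc)
  tab$weight <- exp(-tab$delta / 2) / sum(exp(-tab$delta / 2))
  tab <- tab[order(tab$aicc), ]
  rownames(tab) <- NULL
  list(table = tab, fits = fits)
}

#' Two-segment continuous (hinge) piecewise regression
#'
#' Least-squares fit of `y = a + b_left * min(x - c, 0) +
#' b_right * max(x - c, 0)` with the breakpoint `c` chosen by an exhaustive
#' scan over observed `x` values inside the central 90% of the range. The two
#' hinge arms are orthogonal pointwise, so each candidate's normal equations
#' collapse to closed-form sums over sorted data and the full scan runs in
#' O(n) after sorting. Ties in SSE break to the smallest candidate.
#'
#' @param x,y numeric vectors (at least 20 points; `x` must span an
#'   interval).
#' @param trim tail fraction of the x-range excluded from candidates on each
#'   side.
#' @return object of class `piecewise_fit`: `breakpoint`, `coefficients`
#'   (`intercept`, `slope_left`, `slope_right`), `sse`, `sse_linear`, data.
#' @export
piecewise_fit <- function(x, y, trim = 0.05) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 20) stop("need at least 20 points")
  rng <- range(x)
  if (diff(rng) <= 0) stop("x must span an interval")
  lo <- rng[1] + trim * diff(rng)
  hi <- rng[2] - trim * diff(rng)
  ord <- order(x)
  xs <- x[ord]; ys <- y[ord]
  cand <- unique(xs[xs >= lo & xs <= hi])
  # candidates must leave points strictly on both sides
  cand <- cand[cand > xs[1] & cand < xs[n]]
  if (!length(cand)) stop("no interior breakpoint candidates")
  cx <- cumsum(xs); cy <- cumsum(ys); cxy <- cumsum(xs * ys)
  cxx <- cumsum(xs^2)
  Sy <- cy[n]; Syy <- sum(ys^2)
  k <- findInterval(cand, xs)           # points with x <= cand
  # u = min(x - c, 0): nonzero for the first k points (x < c contributes; at
  # x == c the term is zero so including it is harmless)
  Su <- cx[k] - k * cand
  Suu <- cxx[k] - 2 * cand * cx[k] + k * cand^2
  Suy <- cxy[k] - cand * cy[k]
  # v = max(x - c, 0): nonzero for the remaining points
  Sv <- (cx[n] - cx[k]) - (n - k) * cand
  Svv <- (cxx[n] - cxx[k]) - 2 * cand * (cx[n] - cx[k]) + (n - k) * cand^2
  Svy <- (cxy[n] - cxy[k]) - cand * (cy[n] - cy[k])
  denom_a <- n - ifelse(Suu > 0, Su^2 / Suu, 0) -
    ifelse(Svv > 0, Sv^2 / Svv, 0)
  num_a <- Sy - ifelse(Suu > 0, Su * Suy / Suu, 0) -
    ifelse(Svv > 0, Sv * Svy / Svv, 0)
  a <- num_a / denom_a
  b1 <- ifelse(Suu > 0, (Suy - a * Su) / Suu, 0)
  b2 <- ifelse(Svv > 0, (Svy - a * Sv) / Svv, 0)
  sse <- Syy - (a * Sy + b1 * Suy + b2 * Svy)
  best <- which.min(sse)  # first minimum = smallest candidate
  bp <- cand[best]
  lin <- stats::lm.fit(cbind(1, xs), ys)
  structure(list(
    breakpoint = bp,
    coefficients = c(intercept = a[best], slope_left = b1[best],
                     slope_right = b2[best]),
    sse = sse[best], sse_linear = sum(lin$residuals^2),
    n = n, x = x, y = y, trim = trim,
    candidates = cand, sse_profile = sse),
    class = "piecewise_fit")
}

#' @export
print.piecewise_fit <- function(x, ...) {
  cat(sprintf(
    "Hinge regression: breakpoint %.4g (slopes %.3g -> %.3g, n = %d)\n",
    x$breakpoint, x$coefficients["slope_left"],
    x$coefficients["slope_right"], x$n))
  invisible(x)
}

#' @export
fitted.piecewise_fit <- function(object, ...) {
  co <- object$coefficients
  co["intercept"] + co["slope_left"] * pmin(object$x - object$breakpoint, 0) +
    co["slope_right"] * pmax(object$x - object$breakpoint, 0)
}

#' @export
residuals.piecewise_fit <- function(object, ...) {
  object$y - fitted(object)
}

#' @export
plot.piecewise_fit <- function(x, ...) {
  ord <- order(x$x)
  graphics::plot(x$x, x$y, pch = 16, col = "grey50",
                 xlab = "x", ylab = "y", ...)
  graphics::lines(x$x[ord], fitted(x)[ord], lwd = 2)
  graphics::abline(v = x$breakpoint, lty = 2)
  invisible(x)
}

#' Case-resampling bootstrap confidence interval for a breakpoint
#'
#' Refits the hinge regression on `n_boot` case resamples and returns the
#' percentile interval at `alpha`, reported both as bounds and as a
#' half-width around the point estimate (the conventional
#' "breakpoint (95% CI = h)" display). Fails if more than 20% of replicates
#' cannot be fit.
#'
#' @param fit a [piecewise_fit()] result.
#' @param n_boot bootstrap replicates.
#' @param alpha two-sided level (0.05 for a 95% interval).
#' @param seed RNG seed.
#' @return list: `breakpoint`, `ci` (bounds), `ci_halfwidth`, `n_boot`,
#'   `n_failed`, `boot` (replicate breakpoints).
#' @export
bootstrap_breakpoint_ci <- function(fit, n_boot = 1000, alpha = 0.05,
                                    seed = 1L) {
  stopifnot(inherits(fit, "piecewise_fit"))
  set.seed(as.integer(seed))
  n <- fit$n
  bps <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    i <- sample.int(n, n, replace = TRUE)
    bps[b] <- tryCatch(
      piecewise_fit(fit$x[i], fit$y[i], trim = fit$trim)$breakpoint,
      error = function(e) NA_real_)
  }
  n_failed <- sum(is.na(bps))
  if (n_failed > 0.2 * n_boot)
    stop(sprintf("bootstrap failed in %d of %d replicates",
                 n_failed, n_boot))
  ci <- stats::quantile(bps, c(alpha / 2, 1 - alpha / 2), na.rm = TRUE,
                        names = FALSE)
  list(breakpoint = fit$breakpoint, ci = ci,
       ci_halfwidth = diff(ci) / 2, n_boot = n_boot, n_failed = n_failed,
       boot = bps)
}
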