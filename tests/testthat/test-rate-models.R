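test_that("AICc matches its closed form and collapses to AIC as n grows", {
  expect_equal(aicc(-100, 100, 5), 210 + 60 / 94, tolerance = 1e-12)
  expect_equal(aicc(-100, 1e9, 5), 210, tolerance = 1e-6)
  expect_error(aicc(-100, 6, 5), "n must exceed")
  # AICc > AIC for finite n, difference shrinking in n
  aic <- 210
  diffs <- vapply(c(20, 50, 200, 1000), function(n)
    aicc(-100, n, 5) - aic, 0)
  expect_true(all(diffs > 0))
  expect_true(all(diff(diffs) < 0))
})

test_that("R2 decomposition follows plug-in arithmetic", {
  expect_equal(seismicmove:::r2_components(1, 1, 2), c(marginal = 0.25,
                                                       conditional = 0.5))
  expect_equal(seismicmove:::r2_components(0, 1, 1)[["marginal"]], 0)
  r0 <- seismicmove:::r2_components(2, 0, 1)
  expect_equal(unname(r0["marginal"]), unname(r0["conditional"]))
  expect_error(seismicmove:::r2_components(0, 0, 0), "zero total")
})

test_that("with no between-animal variance the LMM collapses to OLS", {
  truth <- simulation_truth(breakpoint = 0.7)
  d <- simulate_rate_data(truth, n_obs = 400, noise_sd = 0.4, seed = 4,
                          sd_individual = 0, n_individuals = 6,
                          slope_left = 0.5, slope_right = 0.5)
  fit <- suppressWarnings(fit_rate_lmm(log_rate ~ log_veght + fSeason, d))
  ols <- lm(log_rate ~ log_veght + fSeason, d)
  expect_true(fit$singular)
  expect_equal(unname(coef(fit)), unname(coef(ols)), tolerance = 1e-6)
  expect_equal(fit$r2_marginal, fit$r2_conditional, tolerance = 1e-6)
})

test_that("variance components and fixed effects are recovered", {
  truth <- simulation_truth(breakpoint = 0.7)
  d <- simulate_rate_data(truth, n_obs = 2000, noise_sd = 1, seed = 10,
                          sd_individual = sqrt(0.5), n_individuals = 40,
                          slope_left = 0.8, slope_right = 0.8,
                          season_effects = c(rendezvous = 0.2,
                                             nomadic = -0.1))
  fit <- fit_rate_lmm(log_rate ~ log_veght + fSeason, d)
  expect_equal(fit$var_random, 0.5, tolerance = 0.25)
  expect_equal(fit$var_resid, 1, tolerance = 0.25)
  tab <- fit$coefficients
  expect_lt(abs(tab$beta[tab$term == "log_veght"] - 0.8) /
              tab$se[tab$term == "log_veght"], 2)
  expect_lte(fit$r2_marginal, fit$r2_conditional)
  # positive between-animal variance separates conditional from marginal
  expect_gt(fit$r2_conditional, fit$r2_marginal)
})

test_that("a balanced two-group mixed design matches the closed-form BLUE", {
  # balanced one-way design: the fixed-effect GLS estimate of a group
  # contrast equals the OLS group means regardless of the variance split
  set.seed(11)
  d <- data.frame(animal_id = rep(sprintf("A%02d", 1:10), each = 20),
                  group = "G1")
  d$fFor <- rep(rep(0:1, each = 10), 10)
  u <- rnorm(10, 0, 0.5)
  d$log_rate <- 2 + 1.5 * d$fFor + u[as.integer(factor(d$animal_id))] +
    rnorm(200, 0, 0.3)
  fit <- fit_rate_lmm(log_rate ~ fFor, d)
  means <- tapply(d$log_rate, d$fFor, mean)
  expect_equal(unname(coef(fit)["fFor"]), unname(means[2] - means[1]),
               tolerance = 1e-8)
})

test_that("AICc competition prefers the generating structure", {
  truth <- simulation_truth(breakpoint = 0.7)
  d <- simulate_rate_data(truth, n_obs = 1200, noise_sd = 0.3, seed = 12,
                          sd_individual = 0.3, n_individuals = 12,
                          slope_left = 1, slope_right = -2,
                          hinge_forest_only = TRUE)
  sel <- select_rate_model(d)
  expect_equal(sel$table$model[1], "M8")
  expect_true(all(abs(sum(sel$table$weight) - 1) < 1e-12))
})

test_that("a noiseless hinge is recovered at grid resolution", {
  set.seed(13)
  x <- runif(300, 0, 3)
  y <- 2 + 0.5 * pmin(x - 0.7, 0) - 1.5 * pmax(x - 0.7, 0)
  pw <- piecewise_fit(x, y)
  # the optimum lies at the observed x nearest 0.7 from below/above
  expect_lt(abs(pw$breakpoint - 0.7), max(diff(sort(x))) + 1e-9)
  expect_equal(unname(pw$coefficients["slope_left"]), 0.5, tolerance = 1e-2)
  expect_equal(unname(pw$coefficients["slope_right"]), -1.5,
               tolerance = 1e-2)
  expect_lt(pw$sse, 1e-3)
})

test_that("a pure line gains nothing from the hinge", {
  set.seed(14)
  x <- runif(100, 0, 2)
  y <- 1 + 2 * x
  pw <- piecewise_fit(x, y)
  expect_equal(unname(pw$coefficients["slope_left"]),
               unname(pw$coefficients["slope_right"]), tolerance = 1e-6)
  # the hinge buys essentially nothing over the straight line
  expect_lt(pw$sse_linear - pw$sse, 1e-8)
  expect_lte(pw$sse, pw$sse_linear + 1e-12)
})

test_that("the O(n) scan equals an explicit per-candidate lm fit", {
  set.seed(15)
  x <- runif(120, 0, 3)
  y <- 1 + 0.8 * pmin(x - 1.2, 0) - 0.6 * pmax(x - 1.2, 0) + rnorm(120, 0, 0.4)
  pw <- piecewise_fit(x, y)
  sse_lm <- vapply(pw$candidates, function(cc) {
    sum(resid(lm(y ~ I(pmin(x - cc, 0)) + I(pmax(x - cc, 0))))^2)
  }, 0)
  expect_equal(pw$sse_profile, sse_lm, tolerance = 1e-9)
  expect_equal(pw$breakpoint, pw$candidates[which.min(sse_lm)])
  # hinge SSE never exceeds the straight-line SSE
  expect_lte(pw$sse, pw$sse_linear + 1e-12)
})

test_that("bootstrap breakpoint CIs are tight when noiseless, and seeded", {
  set.seed(16)
  x <- runif(200, 0, 3)
  y <- 2 + 1 * pmin(x - 0.7, 0) - 2 * pmax(x - 0.7, 0)
  pw <- piecewise_fit(x, y)
  ci <- bootstrap_breakpoint_ci(pw, n_boot = 200, seed = 5)
  expect_lt(ci$ci_halfwidth, 0.05)
  ci2 <- bootstrap_breakpoint_ci(pw, n_boot = 200, seed = 5)
  expect_identical(ci, ci2)
})

test_that("the near-line dataset applies buffer and count rules exactly", {
  segs <- toy_segments(1000, veght = 0.4)
  t0 <- as.POSIXct("2006-07-02 00:00:00", tz = "UTC")
  mk_steps <- function(id, n, dist_y) data.frame(
    animal_id = id, group = "P1", season = "rendezvous",
    x_end = seq_len(n) * 10, y_end = dist_y,
    rate = exp(rnorm(n, 6, 0.3)), t_start = t0 + 7200 * seq_len(n))
  set.seed(17)
  steps <- rbind(mk_steps("A", 25, 99),   # within buffer, enough locations
                 mk_steps("B", 25, 101),  # 101 m away: excluded entirely
                 mk_steps("C", 19, 50))   # within buffer, too few
  got <- build_rate_dataset(steps, segs, max_distance = 100,
                            min_per_season = 20)
  expect_equal(unique(got$data$animal_id), "A")
  expect_equal(got$n_within_buffer, 25 + 19)
  expect_equal(nrow(got$data), 25)
  # zero vegetation height maps to log_veght 0
  segs0 <- toy_segments(1000, veght = 0)
  got0 <- build_rate_dataset(mk_steps("A", 25, 10), segs0,
                             min_per_season = 20)
  expect_true(all(got0$data$log_veght == 0))
})
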