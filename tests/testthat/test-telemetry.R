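test_that("rarefying a 1-h track to 2 h keeps every second fix", {
  tr <- toy_track(n = 20, dt_h = 1)
  r <- rarefy(tr, interval = 2)
  expect_equal(r$t, tr$t[seq(1, 20, by = 2)])
})

test_that("gaps are preserved, never interpolated", {
  tr <- toy_track(n = 12, dt_h = 2)
  tr <- tr[-(4:6), ]  # 6-h hole
  r <- rarefy(tr, interval = 2)
  expect_equal(nrow(r), nrow(tr))
  gaps <- diff(as.numeric(r$t)) / 3600
  expect_equal(sort(unique(gaps)), c(2, 8))
})

test_that("rarefying a 10-min schedule to 2 h lands in the tolerance window", {
  tr <- toy_track(n = 400, dt_h = 1 / 6)
  set.seed(2)
  tr$t <- tr$t + runif(400, -60, 60)  # a minute of clock jitter
  tr <- tr[order(tr$t), ]
  r <- rarefy(tr, interval = 2, tolerance_min = 5)
  spacing <- diff(as.numeric(r$t)) / 60
  expect_true(all(spacing >= 115 & spacing <= 125))
})

test_that("rarefaction is idempotent", {
  tr <- toy_track(n = 50, dt_h = 1)
  once <- rarefy(tr, interval = 2)
  twice <- rarefy(once, interval = 2)
  expect_equal(twice$t, once$t)
})

test_that("a jittered run is stationary, straight travel is not", {
  set.seed(7)
  tr <- toy_track(n = 20, dt_h = 1, speed = 500)
  # fixes 5..13: an 8-h run jittered within 50 m of a point
  tr$x[5:13] <- tr$x[5] + runif(9, -50, 50)
  tr$y[5:13] <- tr$y[5] + runif(9, -50, 50)
  lab <- classify_stationary(tr, radius = 300, min_duration = 6)
  expect_true(all(lab[6:12] == "stationary"))
  expect_true(all(lab %in% c("movement", "stationary")))  # partition
  fast <- classify_stationary(toy_track(n = 30, dt_h = 1, speed = 500),
                              radius = 300, min_duration = 6)
  expect_true(all(fast == "movement"))
})

test_that("bout recall and movement precision beat 95% on synthetic tracks", {
  L <- test_landscape(); ci <- test_cov_index()
  truth <- simulation_truth(beta = c(eDist = -0.5),
                            kernel = list(shape = 2, scale = 400,
                                          kappa = 0.5), seed = 31)
  tr <- simulate_ssf_track(L, truth, n_steps = 400, fix_interval = 1,
                           cov_index = ci)
  tb <- inject_stationary_bouts(tr, bout_duration = 10, bout_radius = 50,
                                n_bouts = 6, seed = 32)
  lab <- classify_stationary(tb, radius = 100, min_duration = 7)
  truth_stat <- !is.na(tb$bout_id)
  recall <- mean(lab[truth_stat] == "stationary")
  precision_mov <- mean(!truth_stat[lab == "movement"])
  expect_gte(recall, 0.95)
  expect_gte(precision_mov, 0.95)
})

test_that("stationary labels shrink when the rule tightens", {
  L <- test_landscape(); ci <- test_cov_index()
  truth <- simulation_truth(beta = c(eDist = 0), seed = 33)
  tr <- simulate_ssf_track(L, truth, n_steps = 300, fix_interval = 1,
                           cov_index = ci)
  tb <- inject_stationary_bouts(tr, bout_duration = 9, bout_radius = 80,
                                n_bouts = 4, seed = 34)
  n_stat <- function(radius, dur)
    sum(classify_stationary(tb, radius, dur) == "stationary")
  expect_lte(n_stat(100, 7), n_stat(300, 7))
  expect_lte(n_stat(300, 12), n_stat(300, 7))
})

test_that("season calendars match the study design, including boundaries", {
  d <- function(x) as.POSIXct(x, tz = "UTC")
  expect_equal(assign_season(d("2006-07-01"), "wolf"), "rendezvous")
  expect_equal(assign_season(d("2006-04-19"), "wolf"), "nomadic")
  expect_equal(assign_season(d("2006-04-20"), "wolf"), "denning")
  expect_equal(assign_season(d("2006-09-20"), "wolf"), "rendezvous")
  expect_equal(assign_season(d("2006-09-21"), "wolf"), "nomadic")
  expect_equal(assign_season(d("2006-06-16"), "bear"), "summer")
  expect_equal(assign_season(d("2006-06-15"), "bear"), "spring")
  expect_equal(assign_season(d("2006-10-16"), "bear"),
               "outside-study-season")
  # the wolf calendar covers all 365 days
  days <- seq(d("2006-01-01"), d("2006-12-31"), by = "day")
  expect_true(all(nzchar(assign_season(days, "wolf"))))
  expect_error(assign_season(d("2006-01-01"), "lynx"), "species")
})

test_that("step geometry: rates, collinear and right-angle turns", {
  tr <- toy_track(n = 4, dt_h = 2, speed = 500)
  st <- build_steps(tr)
  expect_equal(st$rate, rep(500, 3))
  expect_equal(st$length, rep(1000, 3))
  expect_true(is.na(st$turn_angle[1]))
  expect_equal(st$turn_angle[2:3], c(0, 0))
  # right-angle turn
  tr2 <- toy_track(n = 2, dt_h = 2, speed = 500)
  tr2 <- rbind(tr2, within(tr2[2, ], {
    t <- t + 7200; y <- y + 1000
  }))
  st2 <- build_steps(tr2)
  expect_equal(abs(st2$turn_angle[2]), pi / 2)
})

test_that("steps are only built between matching-interval movement fixes", {
  tr <- toy_track(n = 8, dt_h = 2)
  lab <- rep("movement", 8)
  lab[4] <- "stationary"
  st <- build_steps(tr, states = lab)
  expect_equal(nrow(st), 5)  # pairs (1,2)(2,3)(5,6)(6,7)(7,8)
  # the step after the break has no turn angle
  expect_true(is.na(st$turn_angle[st$t_start == tr$t[5]]))
})

test_that("inclusion filters drop below-threshold animal-seasons exactly", {
  mk <- function(id, n) data.frame(animal_id = id, season = "denning",
                                   n_row = seq_len(n))
  steps <- rbind(mk("A", 39), mk("B", 40), mk("C", 120))
  got <- apply_inclusion_filters(steps, min_per_season = 40)
  expect_equal(sort(unique(got$steps$animal_id)), c("B", "C"))
  # report equals a brute-force tally
  tallies <- table(steps$animal_id)
  expect_equal(got$report$n[order(got$report$animal_id)],
               as.integer(tallies))
  expect_equal(got$report$retained[order(got$report$animal_id)],
               as.integer(tallies) >= 40)
  expect_error(apply_inclusion_filters(mk("A", 5), 40), "excluded")
})
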