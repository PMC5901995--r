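# brute-force conditional log-likelihood for oracle checks
cl_loglik <- function(beta, X, y, stratum, w = NULL) {
  eta <- drop(X %*% beta)
  if (is.null(w)) w <- rep(1, length(unique(stratum)))
  sum(vapply(unique(stratum), function(s) {
    i <- stratum == s
    w[match(s, unique(stratum))] *
      (eta[i][y[i] == 1] - log(sum(exp(eta[i]))))
  }, 0))
}

toy_strata <- function() {
  # 2 strata x (1 used + 3 available), one covariate; the used step is the
  # largest value in one stratum but not the other, so the MLE is finite
  data.frame(
    stratum = rep(1:2, each = 4),
    used = rep(c(1, 0, 0, 0), 2),
    x = c(0.9, 0.1, 0.4, 0.2, 0.2, 0.6, 0.1, 0.3))
}

test_that("the null log-likelihood is exactly -N log(K + 1)", {
  ch <- recovery_cohort()
  f <- fit_clogit(used ~ eDist, ch$strata, strata = "stratum",
                  init = c(eDist = 0), max_iter = 0)
  expect_equal(f$loglik_null, -f$n_strata * log(11), tolerance = 1e-12)
})

test_that("Newton MLE matches a dense grid search on toy strata", {
  d <- toy_strata()
  f <- fit_clogit(used ~ x, d, strata = "stratum")
  grid <- seq(-10, 10, by = 1e-4)
  ll <- vapply(grid, function(b)
    cl_loglik(b, cbind(d$x), d$used, d$stratum), 0)
  expect_equal(unname(coef(f)), grid[which.max(ll)], tolerance = 1e-3)
  # refine around the optimum to 1e-6
  g2 <- seq(grid[which.max(ll)] - 2e-4, grid[which.max(ll)] + 2e-4,
            by = 1e-7)
  ll2 <- vapply(g2, function(b)
    cl_loglik(b, cbind(d$x), d$used, d$stratum), 0)
  expect_equal(unname(coef(f)), g2[which.max(ll2)], tolerance = 1e-6)
})

test_that("estimates and naive covariance match survival::clogit", {
  skip_if_not_installed("survival")
  withr::local_package("survival")
  ch <- recovery_cohort()
  d <- ch$strata[ch$strata$stratum %in% unique(ch$strata$stratum)[1:400], ]
  f <- fit_clogit(used ~ eDist * Veght, d, strata = "stratum")
  cf <- survival::clogit(used ~ eDist * Veght + strata(stratum), data = d)
  expect_equal(unname(coef(f)), unname(coef(cf)), tolerance = 1e-6)
  expect_equal(unname(f$naive_cov), unname(stats::vcov(cf)),
               tolerance = 1e-5)
  expect_equal(f$loglik, as.numeric(stats::logLik(cf)), tolerance = 1e-8)
})

test_that("within-stratum selection probabilities sum to one at any beta", {
  d <- toy_strata()
  for (b in c(-3, 0, 2.5)) {
    eta <- exp(b * d$x)
    p <- ave(eta, d$stratum, FUN = function(v) v / sum(v))
    expect_equal(as.numeric(tapply(p, d$stratum, sum)), c(1, 1))
  }
})

test_that("adding a stratum-constant shift leaves the fit unchanged", {
  ch <- recovery_cohort()
  d <- ch$strata[ch$strata$stratum %in% unique(ch$strata$stratum)[1:200], ]
  f0 <- fit_clogit(used ~ eDist + Veght, d, strata = "stratum")
  d2 <- d
  d2$eDist <- d2$eDist + 5  # same constant in every member of every stratum
  f1 <- fit_clogit(used ~ eDist + Veght, d2, strata = "stratum")
  expect_equal(coef(f0), coef(f1), tolerance = 1e-7)
  expect_equal(f0$loglik, f1$loglik, tolerance = 1e-9)
})

test_that("perfect separation is reported with the covariate name", {
  d <- data.frame(stratum = rep(1:30, each = 3),
                  used = rep(c(1, 0, 0), 30),
                  good = rep(c(1, 0, 0), 30) + 0.001 * seq_len(90))
  expect_error(fit_clogit(used ~ good, d, strata = "stratum"),
               "separation.*good")
})

test_that("duplicating strata shrinks naive and robust SEs by sqrt(2)", {
  ch <- recovery_cohort()
  d <- ch$strata[ch$strata$stratum %in% unique(ch$strata$stratum)[1:150], ]
  d$cl <- d$cluster
  f1 <- fit_clogit(used ~ eDist, d, strata = "stratum", cluster = "cl")
  d2 <- d
  d2$stratum <- d2$stratum + 1e6
  d2$cl <- paste0(d2$cl, "_dup")
  dd <- rbind(d, d2)
  f2 <- fit_clogit(used ~ eDist, dd, strata = "stratum", cluster = "cl")
  expect_equal(coef(f2), coef(f1), tolerance = 1e-8)
  expect_equal(sqrt(diag(f1$naive_cov)) / sqrt(diag(f2$naive_cov)),
               c(eDist = sqrt(2)), tolerance = 1e-6)
  expect_equal(sqrt(diag(f1$robust_cov)) / sqrt(diag(f2$robust_cov)),
               c(eDist = sqrt(2)), tolerance = 1e-6)
})

test_that("robust covariance is symmetric PSD and near naive for iid strata", {
  ch <- recovery_cohort()
  d <- ch$strata
  d$cl_singleton <- d$stratum  # one stratum per cluster
  f <- fit_clogit(used ~ eDist * Veght, d, strata = "stratum",
                  cluster = "cl_singleton")
  V <- f$robust_cov
  expect_equal(V, t(V))
  expect_true(all(eigen(V, symmetric = TRUE)$values > -1e-12))
  ratio <- sqrt(diag(V)) / sqrt(diag(f$naive_cov))
  expect_true(all(ratio > 0.8 & ratio < 1.25))
  expect_error(robust_cov(f, rep("c1", f$n_strata)), "clusters")
})

test_that("QIC_U weights follow the closed form and sum to one", {
  mk <- function(ll, p, n = 100) structure(
    list(loglik = ll, n_params = p, qicu = -2 * ll + 2 * p, n_strata = n),
    class = "clogit_fit")
  # equal QIC -> equal weights
  t1 <- qicu_select(list(A = mk(-100, 2), B = mk(-101, 1)))
  expect_equal(t1$weight, c(0.5, 0.5))
  # delta = (0, 2) -> (0.731, 0.269)
  t2 <- qicu_select(list(A = mk(-100, 2), B = mk(-100, 3)))
  expect_equal(t2$delta, c(0, 2))
  expect_equal(t2$weight, c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-9)
  expect_equal(sum(t2$weight), 1)
  expect_error(qicu_select(list(A = mk(-1, 1, 10), B = mk(-1, 1, 20))),
               "identical strata")
})

test_that("a pure-noise covariate raises QIC_U in expectation under the null", {
  set.seed(40)
  deltas <- replicate(20, {
    n <- 60
    d <- data.frame(stratum = rep(1:n, each = 4),
                    used = rep(c(1, 0, 0, 0), n),
                    x = rnorm(4 * n), junk = rnorm(4 * n))
    f1 <- fit_clogit(used ~ x, d, strata = "stratum")
    f2 <- fit_clogit(used ~ x + junk, d, strata = "stratum")
    f2$qicu - f1$qicu
  })
  expect_gt(mean(deltas), 0)
})

test_that("inverse-variance pooling reproduces hand-computed values", {
  mk <- function(beta, v) structure(
    list(coefficients = c(b = beta), naive_cov = matrix(v, 1, 1,
      dimnames = list("b", "b")), robust_cov = NULL, terms = "b",
      converged = TRUE), class = "clogit_fit")
  p1 <- population_average(list(A = mk(1, 1), B = mk(3, 1)))
  expect_equal(p1$table$beta, 2)
  p2 <- population_average(list(A = mk(1, 0.25), B = mk(3, 1)))
  expect_equal(p2$table$beta, 1.4)
  expect_equal(p2$table$ci_halfwidth, 1.96 / sqrt(1 / 0.25 + 1))
  # equal betas pool to themselves
  p3 <- population_average(list(A = mk(2, 0.5), B = mk(2, 0.5)))
  expect_equal(p3$table$beta, 2)
  # pooled beta lies in the convex hull of the individual betas
  expect_true(p2$table$beta >= 1 && p2$table$beta <= 3)
})

test_that("relative selection probability is the inverse logit", {
  expect_equal(predict_relative_prob(c(eDist = 0), data.frame(eDist = 1)),
               0.5)
  # a -0.33 distance coefficient at eDist = 1 gives 0.418
  expect_equal(
    predict_relative_prob(c(eDist = -0.33), data.frame(eDist = 1)),
    plogis(-0.33), tolerance = 1e-12)
  expect_equal(round(plogis(-0.33), 3), 0.418)
  p <- predict_relative_prob(c(eDist = -0.33),
                             data.frame(eDist = seq(0, 1, 0.1)))
  expect_true(all(diff(p) < 0))
  expect_error(predict_relative_prob(c(eDist = 1, Veght = 1),
                                     data.frame(eDist = 1)), "Veght")
})
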