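#' Fit a conditional logistic step selection function
#'
#' Maximises the (optionally weighted) stratified conditional log-likelihood
#' \deqn{\ell(\beta) = \sum_s w_s \left[\beta^\top x_{us} -
#'   \log \sum_{j \in s} \exp(\beta^\top x_j)\right]}
#' over strata of one used and K available steps, by Newton-Raphson with
#' step-halving from `beta = 0`, declaring convergence when the gradient
#' max-norm falls below `tol`. The naive covariance is the inverse observed
#' information; when a cluster id is supplied a cluster-robust sandwich
#' covariance is added (see [robust_cov()]). `QIC_U = -2 loglik + 2 p` is
#' reported for model competition.
#'
#' @param formula model formula, e.g. `used ~ eDist * Veght`; the intercept
#'   is dropped (it cancels in the conditional likelihood).
#' @param data long data frame: one row per stratum member.
#' @param strata name of the stratum-id column (or a vector).
#' @param weights optional per-stratum weight column name (or vector); the
#'   used row's value is taken for the stratum (inverse fix-probability
#'   weights).
#' @param cluster optional independence-cluster column name (or vector),
#'   constant within stratum.
#' @param init starting coefficients (default 0).
#' @param max_iter,tol Newton controls.
#' @return object of class `clogit_fit`: coefficients, `naive_cov`,
#'   `robust_cov` (if clustered), `loglik`, `loglik_null`, `qicu`,
#'   `n_strata`, `converged`, per-stratum scores.
#' @seealso [qicu_select()], [population_average()], [kfold_cv()]
#' @export
fit_clogit <- function(formula, data, strata = "stratum", weights = NULL,
                       cluster = NULL, init = NULL, max_iter = 50,
                       tol = 1e-8) {
  resolve <- function(arg) {
    if (is.null(arg)) return(NULL)
    if (is.character(arg) && length(arg) == 1) data[[arg]] else arg
  }
  s <- resolve(strata)
  if (is.null(s)) stop("strata not found")
  w_row <- resolve(weights)
  cl_row <- resolve(cluster)
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  y <- as.numeric(stats::model.response(mf))
  X <- stats::model.matrix(stats::terms(formula), mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  if (ncol(X) == 0) stop("no covariates in formula")
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  s <- factor(s)
  ord <- order(s)
  X <- X[ord, , drop = FALSE]; y <- y[ord]; s <- s[ord]
  if (!is.null(w_row)) w_row <- w_row[ord]
  if (!is.null(cl_row)) cl_row <- cl_row[ord]
  used_per <- tapply(y, s, sum)
  if (any(used_per != 1))
    stop("every stratum must contain exactly one used step")
  n_strata <- nlevels(s)
  si <- as.integer(s)
  # per-stratum weight = weight on the used row
  w_s <- rep(1, n_strata)
  if (!is.null(w_row)) w_s <- w_row[y == 1][order(si[y == 1])]
  w_i <- w_s[si]
  p <- ncol(X)
  beta <- if (is.null(init)) rep(0, p) else init
  ll_fun <- function(b) {
    eta <- drop(X %*% b)
    mx <- as.numeric(tapply(eta, si, max))
    lse <- log(as.numeric(rowsum(exp(eta - mx[si]), si))) + mx
    sum(w_s * (eta[y == 1] - lse))
  }
  score_info <- function(b) {
    eta <- drop(X %*% b)
    m <- ave(eta, si, FUN = max)
    ex <- exp(eta - m)
    denom <- rowsum(ex, si)[si]
    pr <- ex / denom
    grad <- colSums(w_i * (y - pr) * X)
    xbar <- rowsum(pr * X, si)
    info <- crossprod(X, (w_i * pr) * X) - crossprod(xbar, w_s * xbar)
    U <- w_s * (X[y == 1, , drop = FALSE][order(si[y == 1]), , drop = FALSE] -
                  xbar)
    list(grad = grad, info = info, scores = U)
  }
  ll <- ll_fun(beta)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    gi <- score_info(beta)
    if (max(abs(gi$grad)) < tol) { converged <- TRUE; break }
    step <- tryCatch(solve(gi$info, gi$grad), error = function(e) NULL)
    if (is.null(step)) stop("information matrix is singular")
    # step-halving
    ok <- FALSE
    for (h in 0:30) {
      cand <- beta + step / 2^h
      ll_new <- ll_fun(cand)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) {
        beta <- cand; ll <- ll_new; ok <- TRUE; break
      }
    }
    if (!ok) break
    if (max(abs(beta)) > 50) {
      worst <- colnames(X)[which.max(abs(beta))]
      stop(sprintf(
        "separation detected: covariate '%s' perfectly ranks used steps",
        worst))
    }
  }
  gi <- score_info(beta)
  if (max(abs(gi$grad)) < tol) converged <- TRUE
  if (ll > -1e-5) {
    # every used step has conditional probability ~1: a covariate (or
    # combination) perfectly ranks used steps and the MLE diverges
    scale <- apply(X, 2, stats::sd)
    worst <- colnames(X)[which.max(abs(beta) * scale)]
    stop(sprintf(
      "separation detected: covariate '%s' perfectly ranks used steps",
      worst))
  }
  naive_cov <- tryCatch(solve(gi$info), error = function(e) {
    stop("information matrix is singular at the optimum")
  })
  dimnames(naive_cov) <- list(colnames(X), colnames(X))
  names(beta) <- colnames(X)
  stratum_cluster <- NULL
  if (!is.null(cl_row))
    stratum_cluster <- cl_row[y == 1][order(si[y == 1])]
  fit <- structure(list(
    coefficients = beta, naive_cov = naive_cov, robust_cov = NULL,
    loglik = ll, loglik_null = ll_fun(rep(0, p)),
    qicu = -2 * ll + 2 * p, n_strata = n_strata, n_params = p,
    converged = converged, iterations = iter,
    scores = gi$scores, stratum_cluster = stratum_cluster,
    formula = formula, terms = colnames(X), call = match.call()),
    class = "clogit_fit")
  if (!is.null(stratum_cluster)) {
    if (length(unique(stratum_cluster)) >= 2) {
      fit$robust_cov <- robust_cov(fit, stratum_cluster)
    } else {
      warning("fewer than 2 independence clusters; using naive covariance")
    }
  }
  fit
}

#' Cluster-robust sandwich covariance for a conditional logistic fit
#'
#' Sandwich estimator `A^-1 B A^-1` with `A` the observed information and `B`
#' the outer-product sum, over independence clusters, of per-cluster summed
#' stratum scores. With one stratum per cluster and a well-specified model it
#' approaches the naive covariance; with serially correlated steps sharing a
#' cluster it inflates the standard errors accordingly.
#'
#' @param fit a [fit_clogit()] result.
#' @param cluster cluster id per stratum (in stratum order).
#' @return symmetric positive semi-definite covariance matrix.
#' @export
robust_cov <- function(fit, cluster) {
  if (!fit$converged) stop("fit did not converge")
  cluster <- factor(cluster)
  if (nlevels(cluster) < 2) stop("need at least 2 independence clusters")
  Uc <- rowsum(fit$scores, cluster)
  B <- crossprod(Uc)
  V <- fit$naive_cov %*% B %*% fit$naive_cov
  (V + t(V)) / 2
}

#' @export
coef.clogit_fit <- function(object, ...) object$coefficients

#' @export
logLik.clogit_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_params, class = "logLik")
}

#' @export
vcov.clogit_fit <- function(object, type = c("robust", "naive"), ...) {
  type <- match.arg(type)
  if (type == "robust" && !is.null(object$robust_cov))
    return(object$robust_cov)
  object$naive_cov
}

#' @export
print.clogit_fit <- function(x, ...) {
  cat(sprintf(
    "Conditional logistic step selection fit (%d strata%s)\n",
    x$n_strata,
    if (x$converged) "" else ", NOT CONVERGED"))
  print(round(x$coefficients, 4))
  cat(sprintf("logLik %.3f  QIC_U %.3f\n", x$loglik, x$qicu))
  invisible(x)
}

#' @export
summary.clogit_fit <- function(object, ...) {
  V <- vcov(object)
  se <- sqrt(diag(V))
  tab <- data.frame(
    beta = object$coefficients, se = se,
    ci_halfwidth = 1.96 * se,
    z = object$coefficients / se,
    p = 2 * stats::pnorm(-abs(object$coefficients / se)))
  out <- list(table = tab, n_strata = object$n_strata,
              loglik = object$loglik, qicu = object$qicu,
              converged = object$converged,
              robust = !is.null(object$robust_cov))
  class(out) <- "summary.clogit_fit"
  out
}

#' @export
print.summary.clogit_fit <- function(x, ...) {
  cat(sprintf("Conditional logistic SSF: %d strata, logLik %.3f, QIC_U %.3f\n",
              x$n_strata, x$loglik, x$qicu))
  cat(sprintf("Standard errors: %s\n",
              if (x$robust) "cluster-robust sandwich" else "naive"))
  print(round(x$table, 4))
  invisible(x)
}

#' @export
predict.clogit_fit <- function(object, newdata,
                               type = c("lp", "relative_prob"), ...) {
  type <- match.arg(type)
  f <- stats::reformulate(attr(stats::delete.response(
    stats::terms(object$formula)), "term.labels"))
  X <- stats::model.matrix(f, newdata)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  lp <- drop(X[, names(object$coefficients), drop = FALSE] %*%
               object$coefficients)
  if (type == "lp") lp else stats::plogis(lp)
}

#' Relative probability of step selection
#'
#' The inverse-logit reporting scale `exp(lp) / (1 + exp(lp))` of a linear
#' predictor built from named coefficients and matching covariates (the
#' conventional display scale for selection surfaces; the likelihood itself
#' is conditional and has no absolute probability).
#'
#' @param beta named coefficient vector.
#' @param covariates data frame or named list with a column per coefficient
#'   (interaction names `a:b` are formed as products).
#' @return numeric vector in (0, 1).
#' @export
predict_relative_prob <- function(beta, covariates) {
  covariates <- as.data.frame(covariates)
  lp <- rep(0, nrow(covariates))
  for (term in names(beta)) {
    parts <- strsplit(term, ":", fixed = TRUE)[[1]]
    miss <- setdiff(parts, names(covariates))
    if (length(miss))
      stop(sprintf("covariate '%s' not supplied", miss[1]))
    lp <- lp + beta[[term]] * Reduce(`*`, covariates[parts])
  }
  stats::plogis(lp)
}
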