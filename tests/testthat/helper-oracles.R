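# Independent oracles shared across test files.

# exhaustive path enumeration: minimum-total-height 8-connected path between
# two cells of a small grid (branch and bound over simple paths)
enumerate_least_cost <- function(h, start, end, eps = 1e-6, cell = 1) {
  nr <- nrow(h); nc <- ncol(h)
  best <- list(cost = Inf, path = NULL)
  visited <- matrix(FALSE, nr, nc)
  offs <- cbind(dr = rep(c(-1, 0, 1), times = 3),
                dc = rep(c(-1, 0, 1), each = 3))
  offs <- offs[!(offs[, 1] == 0 & offs[, 2] == 0), ]
  recurse <- function(r, c, cost, path) {
    if (cost >= best$cost) return()
    if (r == end[1] && c == end[2]) {
      best <<- list(cost = cost, path = path)
      return()
    }
    visited[r, c] <<- TRUE
    for (k in seq_len(nrow(offs))) {
      r2 <- r + offs[k, 1]; c2 <- c + offs[k, 2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc || visited[r2, c2]) next
      step <- cell * sqrt(sum(offs[k, ]^2))
      recurse(r2, c2, cost + h[r2, c2] + eps * step,
              rbind(path, c(r2, c2)))
    }
    visited[r, c] <<- FALSE
  }
  recurse(start[1], start[2], h[start[1], start[2]], rbind(start))
  best
}

# zooming dense grid search for a 2-covariate conditional logistic MLE:
# successive grid refinements down to the requested resolution
grid_search_clogit2 <- function(X, y, stratum, lo = c(-10, -10),
                                hi = c(10, 10), resolution = 1e-6) {
  ll <- function(b) {
    eta <- drop(X %*% b)
    sum(vapply(unique(stratum), function(s) {
      i <- stratum == s
      eta[i][y[i] == 1] - log(sum(exp(eta[i])))
    }, 0))
  }
  centre <- (lo + hi) / 2
  span <- (hi - lo) / 2
  repeat {
    g1 <- seq(centre[1] - span[1], centre[1] + span[1], length.out = 41)
    g2 <- seq(centre[2] - span[2], centre[2] + span[2], length.out = 41)
    vals <- outer(g1, g2, Vectorize(function(a, b) ll(c(a, b))))
    k <- arrayInd(which.max(vals), dim(vals))
    centre <- c(g1[k[1]], g2[k[2]])
    step <- c(g1[2] - g1[1], g2[2] - g2[1])
    if (all(step <= resolution)) break
    span <- step * 1.5
  }
  list(beta = centre, loglik = ll(centre))
}
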