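# Independent oracles used across the suite.  Each is a deliberately
# brute-force or closed-form computation that shares no code with the
# package implementation it checks.

# Cox partial log-likelihood for a single covariate, written out directly
# (Breslow risk sets; the fixtures have no tied event times, where Efron
# and Breslow coincide).  Vectorized over beta.
partial_loglik_1d <- function(beta, time, event, x) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; x <- x[ord]
  sapply(beta, function(b) {
    eta <- x * b
    ll <- 0
    for (i in which(event == 1)) {
      risk <- time >= time[i]
      ll <- ll + eta[i] - log(sum(exp(eta[risk])))
    }
    ll
  })
}

# argmax of the 1-D partial likelihood by grid search
grid_search_cox <- function(time, event, x, lower = -5, upper = 5,
                            step = 1e-4) {
  grid <- seq(lower, upper, by = step)
  grid[which.max(partial_loglik_1d(grid, time, event, x))]
}

# 2-D partial log-likelihood (covariates x1, x2), for the 2SRI fixture
partial_loglik_2d <- function(b1, b2, time, event, x1, x2) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  x1 <- x1[ord]; x2 <- x2[ord]
  eta <- x1 * b1 + x2 * b2
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + eta[i] - log(sum(exp(eta[risk])))
  }
  ll
}

# brute-force maximizer of the 2-D partial likelihood: full grid, zoomed
# (final resolution ~2.5e-5)
grid_search_cox_2d <- function(time, event, x1, x2,
                               lower = c(-5, -5), upper = c(5, 5)) {
  lo <- lower; hi <- upper
  best <- c(0, 0)
  for (round in 1:4) {
    g1 <- seq(lo[1], hi[1], length.out = 41)
    g2 <- seq(lo[2], hi[2], length.out = 41)
    ll <- outer(g1, g2, Vectorize(function(a, b)
      partial_loglik_2d(a, b, time, event, x1, x2)))
    idx <- arrayInd(which.max(ll), dim(ll))
    best <- c(g1[idx[1]], g2[idx[2]])
    span <- c(g1[2] - g1[1], g2[2] - g2[1])
    lo <- best - 2 * span
    hi <- best + 2 * span
  }
  best
}

# order-statistic percentile with linear interpolation (quantile type 7),
# computed from first principles
percentile_oracle <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  sapply(p, function(pp) {
    h <- (n - 1) * pp + 1
    lo <- floor(h)
    if (lo >= n) return(s[n])
    s[lo] + (h - lo) * (s[lo + 1] - s[lo])
  })
}

# the six-row cohort fixture shipped with the package
toy_cohort <- function() {
  read.csv(system.file("extdata", "toy_cohort.csv", package = "ivcoxsim"))
}

# hand-constructed parameter sets for generator-level tests
make_params <- function(alpha0 = 0, alpha_z = 0, alpha_c1 = 0, alpha_c2 = 0,
                        lambda0 = 0.02, beta_x = 0, gamma_c1 = 0,
                        gamma_c2 = 0) {
  structure(list(alpha0 = alpha0, alpha_z = alpha_z, alpha_c1 = alpha_c1,
                 alpha_c2 = alpha_c2, lambda0 = lambda0, beta_x = beta_x,
                 gamma_c1 = gamma_c1, gamma_c2 = gamma_c2),
            class = "calibrated_params")
}
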