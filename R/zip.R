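# Fixed-effects zero-inflated Poisson fitter.
#
# Used inside the year-cluster bootstrap where refitting the full
# random-intercept GLMM hundreds of times would be prohibitive; the
# resampling over whole years already carries the between-year variance.
# Mixture with an intercept-only inflation component:
#   P(y = 0) = pi + (1 - pi) exp(-lambda),  lambda = exp(X beta),
#   pi = plogis(gamma0).

zip_loglik <- function(beta, gamma0, X, y) {
  eta <- drop(X %*% beta)
  lambda <- exp(eta)
  pi <- stats::plogis(gamma0)
  z <- y == 0L
  ll <- numeric(length(y))
  ll[z] <- log(pi + (1 - pi) * exp(-lambda[z]))
  ll[!z] <- log1p(-pi) + stats::dpois(y[!z], lambda[!z], log = TRUE)
  sum(ll)
}

zip_fit <- function(X, y, maxit = 300L) {
  X <- as.matrix(X); y <- as.integer(y)
  start_beta <- tryCatch(
    stats::glm.fit(X, y, family = stats::poisson())$coefficients,
    error = function(e) c(log(mean(y) + 0.1), rep(0, ncol(X) - 1L)))
  start_beta[!is.finite(start_beta)] <- 0
  p0 <- mean(y == 0L)
  start <- c(start_beta, stats::qlogis(min(max(p0 / 2, 0.02), 0.9)))
  negll <- function(par) {
    -zip_loglik(par[-length(par)], par[length(par)], X, y)
  }
  grad <- function(par) {
    beta <- par[-length(par)]; g0 <- par[length(par)]
    lambda <- exp(drop(X %*% beta))
    pi <- stats::plogis(g0)
    z <- y == 0L
    db <- numeric(length(y)); dg <- numeric(length(y))
    if (any(z)) {
      denom <- pi + (1 - pi) * exp(-lambda[z])
      db[z] <- -(1 - pi) * exp(-lambda[z]) * lambda[z] / denom
      dg[z] <- pi * (1 - pi) * (1 - exp(-lambda[z])) / denom
    }
    db[!z] <- y[!z] - lambda[!z]
    dg[!z] <- -pi
    -c(drop(crossprod(X, db)), sum(dg))
  }
  opt <- stats::optim(start, negll, grad, method = "BFGS",
                      control = list(maxit = maxit))
  k <- length(opt$par)
  list(beta = opt$par[-k], gamma0 = opt$par[k],
       pi = stats::plogis(opt$par[k]),
       loglik = -opt$value, converged = opt$convergence == 0L)
}
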