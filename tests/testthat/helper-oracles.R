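# Independent oracles used to cross-check the package's model fits.
# These deliberately avoid the code paths under test (stats::glm,
# MASS::polr, the package's own likelihood).

# logistic regression by hand-written iteratively-reweighted least squares
irls_logistic <- function(X, y, maxit = 100L, tol = 1e-12) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-12)
    z <- eta + (y - mu) / w
    new <- solve(crossprod(X, X * w), crossprod(X, w * z))
    if (max(abs(new - beta)) < tol) { beta <- drop(new); break }
    beta <- drop(new)
  }
  stats::setNames(drop(beta), colnames(X))
}

# cumulative-logit log-likelihood written independently (loop form),
# same parameterization: logit P(Y <= k) = th[k] - eta
po_loglik_oracle <- function(th, eta, y) {
  K <- length(th) + 1L
  Fl <- function(x) 1 / (1 + exp(-x))
  ll <- 0
  for (i in seq_along(y)) {
    k <- y[i]
    pu <- if (k == K) 1 else Fl(th[k] - eta[i])
    pl <- if (k == 1L) 0 else Fl(th[k - 1L] - eta[i])
    ll <- ll + log(pu - pl)
  }
  ll
}

# brute-force ML for a 3-level, hospital-dummy-only proportional-odds model:
# coarse grid over (t1, gap, beta) followed by Nelder-Mead refinement of the
# oracle likelihood
po_fit_oracle <- function(y, hospital_dummy) {
  obj <- function(par) {
    if (par[2] <= 0) return(1e10)
    th <- c(par[1], par[1] + par[2])
    -po_loglik_oracle(th, par[3] * hospital_dummy, y)
  }
  grid <- expand.grid(t1 = seq(-3, 3, 0.5), gap = seq(0.25, 4, 0.25),
                      beta = seq(-3, 3, 0.5))
  vals <- apply(grid, 1, obj)
  st <- as.numeric(grid[which.min(vals), ])
  opt <- stats::optim(st, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
  opt <- stats::optim(opt$par, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
  list(thresholds = c(opt$par[1], opt$par[1] + opt$par[2]),
       beta = opt$par[3], loglik = -opt$value)
}
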