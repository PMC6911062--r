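# Independent oracles used across the suite. These deliberately avoid the
# package's computational paths: covariance matrices by double loops,
# conditional Gaussians by dense solves, marginal likelihoods by adaptive
# Gauss-Hermite quadrature with its own mode finder, Bessel functions by
# numerical integration.

# Modified Bessel function of the second kind through its integral
# representation K_nu(x) = int_0^inf exp(-x cosh t) cosh(nu t) dt.
bessel_k_oracle <- function(x, nu) {
  stats::integrate(function(t) exp(-x * cosh(t)) * cosh(nu * t),
                   0, 30, rel.tol = 1e-12)$value
}

# Brute-force covariance matrix: element-wise double loop.
brute_cov <- function(xy, corr_fun, variance, nugget = 0) {
  n <- nrow(xy)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (k in seq_len(n)) {
      u <- sqrt(sum((xy[i, ] - xy[k, ])^2))
      S[i, k] <- variance * corr_fun(u) + (i == k) * nugget
    }
  }
  S
}

# Conditional Gaussian by dense joint covariance and solve().
cond_gauss_oracle <- function(xy_obs, v_obs, xy_tgt, corr_fun, variance,
                              nugget = 0) {
  n <- nrow(xy_obs); m <- nrow(xy_tgt)
  xy <- rbind(xy_obs, xy_tgt)
  S <- brute_cov(xy, corr_fun, variance)
  S[seq_len(n), seq_len(n)] <- S[seq_len(n), seq_len(n)] +
    diag(nugget, n)
  S_oo <- S[seq_len(n), seq_len(n), drop = FALSE]
  S_to <- S[n + seq_len(m), seq_len(n), drop = FALSE]
  S_tt <- S[n + seq_len(m), n + seq_len(m), drop = FALSE]
  list(mean = as.vector(S_to %*% solve(S_oo, v_obs)),
       var = diag(S_tt - S_to %*% solve(S_oo, t(S_to))))
}

# Adaptive Gauss-Hermite quadrature for the marginal log-likelihood of a
# Poisson log-Gaussian model with latent dimension <= 4 (without factorial
# constants, matching the package's convention). Own mode finder via optim.
aghq_loglik <- function(y, eta, a, Sigma, k = 25) {
  d <- length(y)
  Q <- solve(Sigma)
  negj <- function(b) {
    lam <- a * exp(eta + b)
    -(sum(y * (eta + b) - lam) - 0.5 * sum(b * (Q %*% b)))
  }
  opt <- stats::optim(rep(0, d), negj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  b_hat <- opt$par
  lam <- a * exp(eta + b_hat)
  H <- Q + diag(lam, d)
  L <- t(chol(solve(H)))                      # H^{-1} = L L'
  gh <- pracma::gaussHermite(k)
  grids <- do.call(expand.grid, rep(list(seq_len(k)), d))
  z <- matrix(gh$x[as.matrix(grids)], ncol = d)
  logw <- matrix(log(gh$w)[as.matrix(grids)], ncol = d)
  wsum <- rowSums(logw)
  terms <- vapply(seq_len(nrow(z)), function(i) {
    b <- b_hat + sqrt(2) * as.vector(L %*% z[i, ])
    lamb <- a * exp(eta + b)
    h <- sum(y * (eta + b) - lamb) -
      0.5 * sum(b * (Q %*% b))
    wsum[i] + h + sum(z[i, ]^2)
  }, numeric(1))
  mx <- max(terms)
  # log prior normalising constant of N(0, Sigma)
  log_prior_const <- -0.5 * d * log(2 * pi) -
    0.5 * determinant(Sigma)$modulus[1]
  0.5 * d * log(2) + sum(log(diag(L))) + mx + log(sum(exp(terms - mx))) +
    log_prior_const
}
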