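#' Matérn correlation parameters
#'
#' Bundles the variance, scale and smoothness of a Matérn spatial correlation
#' model. The smoothness is fixed at construction and never estimated: under
#' fixed-domain asymptotics variance, scale and smoothness cannot all be
#' estimated consistently, so the smoothness is pinned (default `1`) and only
#' variance and scale are treated as free parameters downstream.
#'
#' @param variance Marginal variance of the field (sigma^2, > 0).
#' @param scale Correlation scale phi in km (> 0).
#' @param smoothness Matérn smoothness kappa (> 0, default 1; fixed).
#'
#' @return An object of class `matern_params`.
#' @seealso [matern_correlation()], [exponential_params()]
#' @export
#' @examples
#' matern_params(variance = 0.5, scale = 3)
matern_params <- function(variance, scale, smoothness = 1) {
  stop_if_not_positive(variance = variance, scale = scale, smoothness = smoothness)
  structure(
    list(variance = variance, scale = scale, smoothness = smoothness),
    class = c("matern_params", "cov_params")
  )
}

#' Exponential correlation parameters
#'
#' Parameters of the exponential correlation model `exp(-u / scale)`, used for
#' the latent fields of the species-richness models. In the richness models the
#' variance is often written nu^2 and the scale psi; model summaries report
#' them as `log(sigma2)` and `log(phi)` — both notations name the same
#' (variance, scale) pair held here.
#'
#' @param variance Marginal variance of the field (> 0).
#' @param scale Correlation scale psi in km (> 0).
#'
#' @return An object of class `exponential_params`.
#' @export
#' @examples
#' exponential_params(variance = 0.1, scale = 13)
exponential_params <- function(variance, scale) {
  stop_if_not_positive(variance = variance, scale = scale)
  structure(
    list(variance = variance, scale = scale),
    class = c("exponential_params", "cov_params")
  )
}

stop_if_not_positive <- function(...) {
  vals <- list(...)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("`", nm, "` must be a single finite positive number", call. = FALSE)
    }
  }
  invisible(NULL)
}

#' Matérn correlation function
#'
#' Evaluates the Matérn correlation
#' \deqn{\rho(u; \phi, \kappa) = \{2^{\kappa-1}\Gamma(\kappa)\}^{-1}
#'   (u/\phi)^\kappa K_\kappa(u/\phi),}
#' where \eqn{K_\kappa} is the modified Bessel function of the second kind.
#' The limit at `u = 0` is 1. With `smoothness = 0.5` this reduces to the
#' exponential correlation `exp(-u/scale)`.
#'
#' @param u Non-negative distances (km); vectorised.
#' @param params A [matern_params()] object.
#'
#' @return Correlations in (0, 1], same length as `u`.
#' @export
#' @examples
#' p <- matern_params(1, scale = 2, smoothness = 0.5)
#' matern_correlation(2, p)  # exp(-1)
matern_correlation <- function(u, params) {
  stopifnot(inherits(params, "matern_params"))
  if (any(!is.finite(u)) || any(u < 0)) {
    stop("distances `u` must be finite and non-negative", call. = FALSE)
  }
  kappa <- params$smoothness
  s <- u / params$scale
  out <- numeric(length(u))
  zero <- s < .Machine$double.eps^0.75
  out[zero] <- 1
  if (any(!zero)) {
    sz <- s[!zero]
    # exponentially scaled Bessel avoids underflow at large u/phi
    lr <- -(kappa - 1) * log(2) - lgamma(kappa) + kappa * log(sz) +
      log(besselK(sz, kappa, expon.scaled = TRUE)) - sz
    out[!zero] <- exp(lr)
  }
  pmin(out, 1)
}

#' Exponential correlation function
#'
#' Evaluates `exp(-u / scale)`. This is the correlation model of the latent
#' fields in the richness models and drives the comparison-region rule: the
#' distance at which the correlation drops to a threshold `c` is
#' `-scale * log(c)`.
#'
#' @param u Non-negative distances (km); vectorised.
#' @param params An [exponential_params()] object.
#'
#' @return Correlations in (0, 1], same length as `u`.
#' @export
exponential_correlation <- function(u, params) {
  stopifnot(inherits(params, "exponential_params"))
  if (any(!is.finite(u)) || any(u < 0)) {
    stop("distances `u` must be finite and non-negative", call. = FALSE)
  }
  exp(-u / params$scale)
}

correlation_fun <- function(params) {
  if (inherits(params, "matern_params")) {
    function(u) matern_correlation(u, params)
  } else if (inherits(params, "exponential_params")) {
    function(u) exponential_correlation(u, params)
  } else {
    stop("`params` must be matern_params or exponential_params", call. = FALSE)
  }
}

# Euclidean distance matrix of a set of planar points (km).
dist_matrix <- function(x, y = NULL) {
  a <- as.matrix(x)
  b <- if (is.null(y)) a else as.matrix(y)
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  sqrt(pmax(d2, 0))
}

# Correlation matrix evaluated through the unique distances only; on regular
# grids this cuts the number of special-function evaluations by orders of
# magnitude.
corr_matrix <- function(D, params) {
  f <- correlation_fun(params)
  dv <- round(as.vector(D), 12)
  ud <- unique(dv)
  r <- f(ud)
  matrix(r[match(dv, ud)], nrow(D), ncol(D))
}

coords_matrix <- function(locations) {
  if (is.data.frame(locations)) {
    if (all(c("x", "y") %in% names(locations))) {
      return(cbind(locations$x, locations$y))
    }
    stopifnot(ncol(locations) == 2)
    cbind(locations[[1]], locations[[2]])
  } else {
    m <- as.matrix(locations)
    stopifnot(ncol(m) == 2)
    m
  }
}

#' Build a spatial covariance matrix
#'
#' Assembles `variance * rho(||x_i - x_k||) + nugget * 1{i = k}` over a set of
#' planar locations, with `rho` either Matérn or exponential. Distances are
#' Euclidean in km; coordinates must already be projected.
#'
#' @param locations Data frame with columns `x`, `y` (km), or a two-column
#'   matrix.
#' @param params A [matern_params()] or [exponential_params()] object.
#' @param nugget Non-negative nugget variance added to the diagonal.
#'
#' @return A symmetric positive-definite matrix.
#' @details Duplicate locations are only admissible with a positive nugget
#'   (or when the caller deliberately shares one latent value); with a zero
#'   nugget the matrix is singular and Cholesky-based consumers will apply the
#'   jitter policy of [chol_jitter()] and then fail if it does not help.
#' @export
build_covariance <- function(locations, params, nugget = 0) {
  stopifnot(is.numeric(nugget), length(nugget) == 1L, nugget >= 0)
  xy <- coords_matrix(locations)
  if (nrow(xy) < 1L) stop("need at least one location", call. = FALSE)
  D <- dist_matrix(xy)
  params$variance * corr_matrix(D, params) + diag(nugget, nrow(xy))
}

# Cholesky with a single retry after adding 1e-8 * variance jitter to the
# diagonal; failure after the retry is an error. `scale` is the marginal
# variance used to size the jitter.
chol_jitter <- function(S, scale = mean(diag(S))) {
  R <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(R)) {
    R <- tryCatch(chol(S + diag(1e-8 * scale, nrow(S))), error = function(e) NULL)
    if (is.null(R)) {
      stop("covariance matrix is not positive definite (even after 1e-8 jitter)",
           call. = FALSE)
    }
  }
  R
}

#' Simulate a zero-mean Gaussian random field
#'
#' Draws one or more realizations of a zero-mean multivariate Gaussian vector
#' with the spatial covariance of [build_covariance()], by Cholesky
#' factorization. Identical seeds give identical draws.
#'
#' @inheritParams build_covariance
#' @param n Number of independent realizations.
#' @param seed Optional integer seed; the caller's RNG state is untouched.
#'
#' @return A tibble with columns `x`, `y`, `sim` (realization index) and
#'   `value`.
#' @export
simulate_field <- function(locations, params, nugget = 0, n = 1, seed = NULL) {
  xy <- coords_matrix(locations)
  S <- build_covariance(xy, params, nugget)
  R <- chol_jitter(S, params$variance)
  draw <- function() {
    Z <- matrix(stats::rnorm(nrow(xy) * n), nrow(xy), n)
    crossprod(R, Z)
  }
  V <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  tibble::tibble(
    x = rep(xy[, 1], times = n),
    y = rep(xy[, 2], times = n),
    sim = rep(seq_len(n), each = nrow(xy)),
    value = as.vector(V)
  )
}

#' Conditional (kriging) mean and variance of a Gaussian field
#'
#' Given values of a zero-mean Gaussian field at observed locations — either
#' exact observations or a posterior summary (mean and, optionally, a
#' covariance) — returns the conditional mean and variance of the field at
#' target locations under the standard conditional-Gaussian formulae. With a
#' zero nugget the conditional mean interpolates observed values exactly; far
#' from all observations it relaxes to the prior mean 0.
#'
#' @param observed Data frame with columns `x`, `y`, `value` (posterior or
#'   observed field mean at each location).
#' @param targets Data frame with columns `x`, `y`, or two-column matrix.
#' @param params Correlation parameters ([matern_params()] or
#'   [exponential_params()]).
#' @param nugget Nugget variance at the observed locations (default 0).
#' @param observed_cov Optional posterior covariance matrix of the observed
#'   values; when supplied, the conditional variance accounts for it via
#'   `c' S^-1 V S^-1 c` instead of treating the values as exact.
#'
#' @return A tibble with columns `x`, `y`, `value` (conditional mean) and
#'   `var` (conditional variance).
#' @export
conditional_mean_field <- function(observed, targets, params, nugget = 0,
                                   observed_cov = NULL) {
  stopifnot(is.data.frame(observed), all(c("x", "y", "value") %in% names(observed)))
  obs_xy <- coords_matrix(observed[c("x", "y")])
  tgt_xy <- coords_matrix(targets)
  S_oo <- build_covariance(obs_xy, params, nugget)
  R <- chol_jitter(S_oo, params$variance)
  D_to <- dist_matrix(tgt_xy, obs_xy)
  C_to <- params$variance * corr_matrix(D_to, params)    # targets x observed
  # S_oo^-1 v and S_oo^-1 t(C_to) through the Cholesky factor
  a <- backsolve(R, backsolve(R, observed$value, transpose = TRUE))
  W <- backsolve(R, backsolve(R, t(C_to), transpose = TRUE))  # obs x targets
  cond_mean <- as.vector(C_to %*% a)
  cond_var <- params$variance - colSums(t(C_to) * W)
  if (!is.null(observed_cov)) {
    cond_var <- cond_var + colSums(W * (observed_cov %*% W))
  }
  tibble::tibble(
    x = tgt_xy[, 1], y = tgt_xy[, 2],
    value = cond_mean, var = pmax(cond_var, 0)
  )
}
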