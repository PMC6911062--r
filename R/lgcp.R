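# Log-Gaussian Cox process model of the opportunistic sampling locations.
#
# The point pattern of citizen-science sampling events is modelled as an
# inhomogeneous Poisson process with intensity
#   Lambda(x) = exp{alpha0 + alpha1 * D(x) + alpha2 * V(x) + S(x)},
# where D is distance to the collectors' home, V the value-of-nature
# covariate, and S a zero-mean Gaussian field with Matérn correlation
# (smoothness fixed at 1). The latent field is discretized to one value per
# grid cell and the process reduced to conditionally Poisson cell counts with
# mean area * Lambda(cell); estimation is by Monte Carlo maximum likelihood.

#' Bin a point pattern into grid-cell counts
#'
#' @param pattern Tibble with columns `x`, `y` (and optionally `year`).
#' @param grid A `rich_grid`.
#' @return The grid tibble with a `count` column; counts sum to the number of
#'   points and empty cells carry 0.
#' @export
bin_points <- function(pattern, grid) {
  idx <- locate_cell(pattern, grid)
  out <- grid
  out$count <- tabulate(idx, nbins = nrow(grid))
  out
}

#' Conditional Poisson log-likelihood of the discretized sampling model
#'
#' Evaluates, conditionally on the latent field, the cell-count
#' log-likelihood: each cell contributes
#' `count * log(area * Lambda) - area * Lambda` with
#' `log Lambda = alpha0 + alpha1 * D + alpha2 * V + S`. Factorial constants
#' are dropped, consistently with every other likelihood in the package.
#'
#' @param cells Tibble with columns `count`, `D`, `V`, `S` and `area`.
#' @param alpha0,alpha1,alpha2 Intensity coefficients (intercept,
#'   distance-to-home, value-of-nature).
#' @return Scalar log-likelihood (without factorial constants).
#' @export
lgcp_loglik <- function(cells, alpha0, alpha1, alpha2) {
  need <- c("count", "D", "V", "S", "area")
  stopifnot(all(need %in% names(cells)))
  eta <- alpha0 + alpha1 * cells$D + alpha2 * cells$V + cells$S
  lam <- cells$area * exp(eta)
  if (any(!is.finite(lam))) {
    stop("non-finite intensity in lgcp_loglik; check parameters", call. = FALSE)
  }
  sum(cells$count * (log(cells$area) + eta) - lam)
}

#' Fit the log-Gaussian Cox process to a sampling point pattern
#'
#' Discretizes the pattern to cell counts on `grid`, then maximizes the
#' Monte Carlo likelihood of the Poisson log-Gaussian cell-count model with a
#' Matérn (smoothness 1) latent field. Confidence intervals are Wald
#' intervals from the observed information at the optimum (Louis' identity
#' on a Monte Carlo sample of the latent field); the spatial variance and
#' scale are estimated and reported on the log scale.
#'
#' @param pattern Tibble of sampling locations with columns `x`, `y`.
#' @param grid A `rich_grid` carrying the value-of-nature column `V`.
#' @param home Length-2 numeric, the collectors' home `c(x, y)` in km.
#' @param smoothness Matérn smoothness, fixed (default 1; never estimated).
#' @param init Optional initial values: list with `alpha` (length 3) and
#'   `log_theta` (`log(sigma2)`, `log(phi)`).
#' @param control An [mcml_control()].
#' @param seed Integer seed for the Monte Carlo sampler.
#'
#' @return An object of class `lgcp_fit` with a tidy coefficient table
#'   (see [generics::tidy()]), a per-cell latent summary, the Monte Carlo
#'   log-likelihood and the settings used.
#' @export
fit_lgcp <- function(pattern, grid, home, smoothness = 1, init = NULL,
                     control = mcml_control(), seed = NULL) {
  if (!"V" %in% names(grid)) {
    stop("grid must carry the value-of-nature column `V`", call. = FALSE)
  }
  binned <- bin_points(pattern, grid)
  if (any(binned$count > 0 & !binned$inside)) {
    rlang::abort("point pattern has events in masked cells",
                 class = "prefrich_masked_points")
  }
  if (nrow(pattern) < 30) {
    warning("fewer than 30 events; LGCP estimates will be unstable",
            call. = FALSE)
  }
  cells <- binned[binned$inside, ]
  D <- distance_to_home(cells[c("x", "y")], home)
  X <- cbind(intercept = 1, D = D, V = cells$V)
  area <- rep(cell_area(grid), nrow(cells))
  model <- cov_model("matern", smoothness = smoothness, nugget = FALSE)
  eng <- mcml_fit(
    y = cells$count, X = X, coords = cells[c("x", "y")], model = model,
    a = area,
    init_beta = init$alpha, init_log_theta = init$log_theta,
    control = control, seed = seed
  )
  terms <- c("alpha0", "alpha1", "alpha2", "log_sigma2", "log_phi")
  structure(list(
    coefficients = wald_table(eng$par, eng$vcov, terms),
    field = matern_params(exp(eng$log_theta[1]), exp(eng$log_theta[2]),
                          smoothness),
    latent_summary = tibble::tibble(
      cell = cells$cell, x = cells$x, y = cells$y,
      mean = eng$latent_mean, var = diag(eng$latent_cov)
    ),
    latent_cov = eng$latent_cov,
    grid = grid, home = home, counts = binned$count,
    loglik = eng$loglik, loglik_se = eng$loglik_se, ess = eng$ess,
    converged = eng$converged,
    vcov = eng$vcov,
    settings = list(
      smoothness = smoothness, n_sim = control$n_sim,
      refreshes_used = eng$refreshes, max_refresh = control$refresh,
      seed = eng$seed, n_events = nrow(pattern), n_cells = nrow(cells),
      discretization = "regular grid, one latent value per cell"
    ),
    engine = eng
  ), class = "lgcp_fit")
}

#' @export
print.lgcp_fit <- function(x, ...) {
  cat("Log-Gaussian Cox process fit (MCML)\n")
  cat("  events:", x$settings$n_events, " cells:", x$settings$n_cells, "\n")
  cat("  log-likelihood (Laplace evaluation):",
      format(x$loglik, digits = 6), "\n\n")
  print(as.data.frame(x$coefficients), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Predictive mean surface of the latent sampling field
#'
#' Returns the predictive (conditional) mean of the latent field S — the
#' quantity plugged into the citizen-science richness model as the
#' preferential-sampling adjustment covariate. At the fit's own grid cells
#' this is the Laplace posterior mean; at other target locations it is the
#' conditional-Gaussian (kriging) mean computed from the per-cell posterior
#' summary under the fitted Matérn model.
#'
#' @param fit An [fit_lgcp()] result.
#' @param targets Optional data frame of target locations `x`, `y`; default
#'   is the fit's own grid.
#' @return A tibble with columns `x`, `y`, `shat` and `shat_var` (and `cell`
#'   when predicting on the fit's grid).
#' @export
predict_shat <- function(fit, targets = NULL) {
  stopifnot(inherits(fit, "lgcp_fit"))
  ls <- fit$latent_summary
  if (is.null(targets)) {
    return(tibble::tibble(cell = ls$cell, x = ls$x, y = ls$y,
                          shat = ls$mean, shat_var = ls$var))
  }
  obs <- tibble::tibble(x = ls$x, y = ls$y, value = ls$mean)
  out <- conditional_mean_field(obs, targets, fit$field,
                                observed_cov = fit$latent_cov)
  tibble::tibble(x = out$x, y = out$y, shat = out$value, shat_var = out$var)
}

#' Multiplicative change in sampling intensity for a covariate change
#'
#' For a log-linear intensity model, a coefficient `coef` and covariate
#' change `delta` multiply the intensity by `exp(coef * delta)`; e.g. a
#' value-of-nature coefficient of 2.778 means a fully valuable cell is
#' sampled about 16 times more intensely than a worthless one.
#'
#' @param coef Intensity coefficient.
#' @param delta Covariate change (default 1).
#' @return The multiplicative intensity factor `exp(coef * delta)`.
#' @export
#' @examples
#' intensity_ratio(2.778)  # ~16
intensity_ratio <- function(coef, delta = 1) exp(coef * delta)
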