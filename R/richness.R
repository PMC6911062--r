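# Geostatistical Poisson models of species richness.
#
# Conditionally on a spatial Gaussian field U_j (exponential correlation) and
# per-record Gaussian noise Z_j (nugget), richness counts are independent
# Poisson with log-mean
#
#   CSD: beta0 + beta1*W + beta2*V + beta3*F + beta4*log(C) + f(t)
#        + gamma*Shat(x) + U(x) + Z
#   RSD: beta0 + beta1*W + beta2*V + beta3*F + beta5*(t - 1997) + U(x) + Z
#
# Shat is the predictive mean of the sampling model's latent field, plugged
# in as a fixed covariate: its coefficient gamma measures residual
# preferential sampling. Records sharing a cell share the cell's U value
# (the field is purely spatial); each record has its own nugget draw.

richness_terms <- function(model, n_spline) {
  if (model == "CSD") {
    c("beta0", "beta1_W", "beta2_V", "beta3_F", "beta4_logC",
      paste0("f", seq_len(n_spline)), "gamma")
  } else {
    c("beta0", "beta1_W", "beta2_V", "beta3_F", "beta5_t")
  }
}

# Shared design-matrix builder so fitting and prediction can never disagree.
# `df` needs W, V, F plus (CSD) collectors, year, shat or (RSD) year.
richness_design <- function(df, model, spline) {
  stopifnot(all(c("W", "V", "F") %in% names(df)))
  if (model == "CSD") {
    if (any(df$collectors < 1)) {
      stop("collector counts must be >= 1", call. = FALSE)
    }
    B <- spline_basis(df$year, spline, intercept = FALSE)
    X <- cbind(1, df$W, df$V, df$F, log(df$collectors), B, df$shat)
  } else {
    X <- cbind(1, df$W, df$V, df$F, df$year - 1997)
  }
  colnames(X) <- richness_terms(model, if (model == "CSD") ncol(B) else 0L)
  X
}

#' Linear predictor of the citizen-science richness model
#'
#' Evaluates `beta0 + beta1*W + beta2*V + beta3*F + beta4*log(C) + f(t) +
#' gamma*Shat` for each record; the latent field and nugget are added by the
#' likelihood layer, not here.
#'
#' @param records Tibble with columns `W`, `V`, `F`, `collectors`, `year`,
#'   `shat`.
#' @param beta Coefficients `c(beta0, beta1, beta2, beta3, beta4)`.
#' @param spline_coefs Coefficients of the (intercept-free) spline basis.
#' @param gamma Preferential-sampling adjustment coefficient.
#' @param spline A [spline_spec()].
#' @return Numeric vector of linear predictors.
#' @export
linear_predictor_csd <- function(records, beta, spline_coefs, gamma,
                                 spline = spline_spec()) {
  X <- richness_design(records, "CSD", spline)
  stopifnot(length(beta) == 5L, length(spline_coefs) == ncol(X) - 6L)
  as.vector(X %*% c(beta, spline_coefs, gamma))
}

#' Linear predictor of the randomised-survey richness model
#'
#' Evaluates `beta0 + beta1*W + beta2*V + beta3*F + beta5*(t - 1997)`.
#'
#' @param records Tibble with columns `W`, `V`, `F`, `year`.
#' @param beta Coefficients `c(beta0, beta1, beta2, beta3, beta5)`.
#' @return Numeric vector of linear predictors.
#' @export
linear_predictor_rsd <- function(records, beta) {
  X <- richness_design(records, "RSD", NULL)
  stopifnot(length(beta) == 5L)
  as.vector(X %*% beta)
}

#' Fit a geostatistical Poisson species-richness model
#'
#' Fits the citizen-science (`"CSD"`) or randomised-survey (`"RSD"`) richness
#' model by Monte Carlo maximum likelihood. The latent structure is a
#' zero-mean Gaussian field with exponential correlation evaluated between
#' record locations plus an independent nugget per record; covariance
#' parameters are estimated on the log scale and reported as `log_sigma2`,
#' `log_phi`, `log_tau2`.
#'
#' @param records Tibble with columns `x`, `y`, `year`, `richness` and, for
#'   CSD, `collectors`.
#' @param grid A `rich_grid` carrying covariate columns `W`, `V`, `F`.
#' @param model `"CSD"` or `"RSD"`.
#' @param shat For CSD: the preferential-sampling adjustment surface, a
#'   tibble with columns `cell` and `shat` on the cells of `grid` (as
#'   returned by [predict_shat()]); pass a zero column to fit without
#'   adjustment. Ignored for RSD.
#' @param spline A [spline_spec()] for the CSD temporal effect.
#' @param init Optional list with `beta` and `log_theta`
#'   (`log(sigma2), log(phi), log(tau2)`).
#' @param control An [mcml_control()].
#' @param seed Integer seed for the Monte Carlo sampler.
#'
#' @return An object of class `richness_fit`.
#' @export
fit_richness <- function(records, grid, model = c("CSD", "RSD"), shat = NULL,
                         spline = spline_spec(), init = NULL,
                         control = mcml_control(), seed = NULL) {
  model <- match.arg(model)
  if (nrow(records) < 30) {
    warning("fewer than 30 records; estimates will be unstable", call. = FALSE)
  }
  df <- covariate_at(records, grid, c("W", "V", "F"))
  if (anyNA(df[c("W", "V", "F")])) {
    stop("records fall in masked cells without covariate values", call. = FALSE)
  }
  if (model == "CSD") {
    if (is.null(shat)) {
      stop("CSD model needs `shat` (use predict_shat(); a zero surface fits ",
           "without adjustment)", call. = FALSE)
    }
    stopifnot(all(c("cell", "shat") %in% names(shat)))
    idx <- locate_cell(df, grid)
    df$shat <- shat$shat[match(idx, shat$cell)]
    if (anyNA(df$shat)) {
      stop("`shat` does not cover every cell containing a record", call. = FALSE)
    }
  }
  X <- richness_design(df, model, spline)
  sds <- apply(X[, -1, drop = FALSE], 2, stats::sd)
  if (any(sds < 1e-12)) {
    rlang::warn(paste("constant design column(s):",
                      paste(colnames(X)[-1][sds < 1e-12], collapse = ", ")),
                class = "prefrich_collinear_design")
  }
  # the latent field is spatial at cell resolution: records in one cell
  # share the cell's U value (the nugget separates them), so the covariance
  # is built from the containing cells' centers
  idx_cell <- locate_cell(df, grid)
  df$cx <- grid$x[idx_cell]
  df$cy <- grid$y[idx_cell]
  cv <- cov_model("exponential", nugget = TRUE)
  eng <- mcml_fit(
    y = records$richness, X = X, coords = df[c("cx", "cy")], model = cv,
    init_beta = init$beta, init_log_theta = init$log_theta,
    control = control, seed = seed
  )
  terms <- c(colnames(X), cov_par_names(cv))
  structure(list(
    coefficients = wald_table(eng$par, eng$vcov, terms),
    model = model,
    field = exponential_params(exp(eng$log_theta[1]), exp(eng$log_theta[2])),
    nugget = exp(eng$log_theta[3]),
    spline = if (model == "CSD") spline,
    records = df,
    grid = grid,
    loglik = eng$loglik, loglik_se = eng$loglik_se, ess = eng$ess,
    converged = eng$converged,
    vcov = eng$vcov,
    settings = list(
      model = model, n_sim = control$n_sim,
      refreshes_used = eng$refreshes, max_refresh = control$refresh,
      seed = eng$seed, n_records = nrow(records)
    ),
    engine = eng
  ), class = "richness_fit")
}

#' @export
print.richness_fit <- function(x, ...) {
  cat("Geostatistical Poisson richness fit (", x$model, ", MCML)\n", sep = "")
  cat("  records:", x$settings$n_records, "\n")
  cat("  log-likelihood (Laplace evaluation):",
      format(x$loglik, digits = 6), "\n\n")
  print(as.data.frame(x$coefficients), row.names = FALSE, digits = 4)
  invisible(x)
}

beta_block <- function(fit) {
  cov_terms <- c("log_sigma2", "log_phi", "log_tau2")
  !fit$coefficients$term %in% cov_terms
}

#' Predict the species-richness surface
#'
#' Computes the predictive mean, standard error and coefficient of variation
#' of `mu(x, t) = exp(eta(x, t) + U(x))` over grid cells, for a fixed
#' prediction year and (CSD) number of collectors. The latent field `U` at a
#' cell is obtained by conditional-Gaussian prediction from the fit's latent
#' posterior summary; the nugget is record-level noise and is excluded from
#' the prediction target by default. Under the lognormal formula the mean is
#' `exp(eta + m + v/2)` and the standard error `mean * sqrt(exp(v) - 1)`,
#' where `v` is the latent conditional variance plus (by default) the Wald
#' parameter-uncertainty term of the linear predictor.
#'
#' @param fit A [fit_richness()] result.
#' @param grid Prediction grid carrying `W`, `V`, `F` (default: the fit's
#'   grid).
#' @param year Prediction year (default 1998).
#' @param collectors Number of collectors at prediction, CSD only
#'   (default 2).
#' @param shat CSD only: adjustment surface (`cell`, `shat`) on the
#'   prediction grid; defaults to the values stored at fitting time when the
#'   grids coincide.
#' @param include_param_unc Add the Wald parameter-uncertainty term to the
#'   predictive variance (default `TRUE`).
#' @param include_nugget Add the nugget variance to the prediction target
#'   (default `FALSE`).
#'
#' @return The grid tibble restricted to unmasked cells with complete
#'   covariates, with columns `mu`, `se` and `cov` (se/mu) appended; the
#'   prediction year and collectors are attached as attributes.
#' @export
predict_mu <- function(fit, grid = fit$grid, year = 1998, collectors = 2,
                       shat = NULL, include_param_unc = TRUE,
                       include_nugget = FALSE) {
  stopifnot(inherits(fit, "richness_fit"))
  cells <- grid[grid$inside, ]
  ok <- stats::complete.cases(cells[, c("W", "V", "F")])
  cells <- cells[ok, ]
  df <- cells
  df$year <- year
  if (fit$model == "CSD") {
    df$collectors <- collectors
    if (is.null(shat)) {
      df$shat <- fit$records$shat[match(locate_cell(df, grid),
                                        locate_cell(fit$records, fit$grid))]
      if (anyNA(df$shat)) {
        stop("no stored `shat` for some prediction cells; pass `shat` ",
             "covering the prediction grid", call. = FALSE)
      }
    } else {
      idx <- locate_cell(df, grid)
      df$shat <- shat$shat[match(idx, shat$cell)]
      if (anyNA(df$shat)) stop("`shat` does not cover the prediction grid",
                               call. = FALSE)
    }
  }
  X <- richness_design(df, fit$model, fit$spline)
  beta <- fit$coefficients$estimate[beta_block(fit)]
  eta <- as.vector(X %*% beta)

  # conditional mean and variance of U at the prediction cells, from the
  # latent posterior over the record-level effects b = U + Z
  eng <- fit$engine
  nu2 <- fit$field$variance
  if (nu2 > 1e-12) {
    Dc <- dist_matrix(coords_matrix(df[c("x", "y")]),
                      coords_matrix(fit$records[c("cx", "cy")]))
    Cc <- nu2 * exp(-Dc / fit$field$scale)       # cells x records, U vs b
    R <- chol_jitter(eng$Sigma, nu2)
    W <- backsolve(R, backsolve(R, t(Cc), transpose = TRUE)) # records x cells
    m <- as.vector(Cc %*% backsolve(R, backsolve(R, eng$latent_mean,
                                                 transpose = TRUE)))
    v <- pmax(nu2 - colSums(t(Cc) * W) +
                colSums(W * (eng$latent_cov %*% W)), 0)
  } else {
    m <- rep(0, nrow(df)); v <- rep(0, nrow(df))
  }
  if (include_param_unc) {
    Vb <- fit$vcov[beta_block(fit), beta_block(fit), drop = FALSE]
    v <- v + rowSums((X %*% Vb) * X)
  }
  if (include_nugget) v <- v + fit$nugget

  out <- cells
  out$mu <- exp(eta + m + v / 2)
  out$se <- out$mu * sqrt(pmax(exp(v) - 1, 0))
  out$cov <- ifelse(out$mu > 0, out$se / out$mu, NA_real_)
  attr(out, "year") <- year
  attr(out, "collectors") <- if (fit$model == "CSD") collectors
  attr(out, "model") <- fit$model
  out
}

#' Fitted temporal effect of the citizen-science model
#'
#' Returns the fitted spline `f(t)` with pointwise Wald confidence limits,
#' centred on its 1997-1999 mean so the level is identified next to the model
#' intercept.
#'
#' @param fit A CSD [fit_richness()] result.
#' @param years Years at which to evaluate (default a fine grid over the
#'   spline boundary).
#' @param level Confidence level (default 0.95).
#' @return A tibble with `year`, `effect`, `conf.low`, `conf.high`.
#' @export
spline_effect <- function(fit, years = NULL, level = 0.95) {
  stopifnot(inherits(fit, "richness_fit"), fit$model == "CSD")
  if (is.null(years)) {
    years <- seq(fit$spline$boundary[1], fit$spline$boundary[2], by = 0.25)
  }
  B <- spline_basis(years, fit$spline, intercept = FALSE)
  Bref <- colMeans(spline_basis(1997:1999, fit$spline, intercept = FALSE))
  Bc <- sweep(B, 2, Bref)
  is_spline <- grepl("^f[0-9]+$", fit$coefficients$term)
  theta <- fit$coefficients$estimate[is_spline]
  Vs <- fit$vcov[is_spline, is_spline, drop = FALSE]
  eff <- as.vector(Bc %*% theta)
  se <- sqrt(pmax(rowSums((Bc %*% Vs) * Bc), 0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  tibble::tibble(year = years, effect = eff,
                 conf.low = eff - z * se, conf.high = eff + z * se)
}
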