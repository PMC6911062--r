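# Shared fixtures: light Monte Carlo settings and one small fitted study,
# built once per test run and reused across files.

fast_ctl <- function(n_sim = 120, refresh = 2) {
  mcml_control(n_sim = n_sim, refresh = refresh, burn = 200, thin = 3,
               trust = 1)
}

# one small synthetic study + fits, memoised across test files
small_study <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- scenario_preset("preferential", grid_dim = 15)
    bundle <- gen_scenario(cfg, seed = 7)
    lgcp <- fit_lgcp(bundle$csd$pattern, bundle$grid, cfg$home,
                     control = fast_ctl(), seed = 71)
    shat <- predict_shat(lgcp)
    fit_csd <- fit_richness(bundle$csd$records, bundle$grid, "CSD",
                            shat = shat, control = fast_ctl(), seed = 72)
    fit_rsd <- fit_richness(bundle$rsd$records, bundle$grid, "RSD",
                            control = fast_ctl(), seed = 73)
    cache <<- list(cfg = cfg, bundle = bundle, lgcp = lgcp, shat = shat,
                   fit_csd = fit_csd, fit_rsd = fit_rsd)
    cache
  }
})

# hand-made degenerate richness fit (no latent field, no parameter
# uncertainty) for closed-form prediction checks
manual_rsd_fit <- function(grid, beta = c(1, 0.5, -0.3, 0.2, -0.1)) {
  terms <- c("beta0", "beta1_W", "beta2_V", "beta3_F", "beta5_t",
             "log_sigma2", "log_phi", "log_tau2")
  par <- c(beta, log(1e-14), log(5), log(1e-14))
  k <- length(par)
  rec <- tibble::tibble(x = grid$x[1], y = grid$y[1],
                        cx = grid$x[1], cy = grid$y[1],
                        year = 1998, richness = 1,
                        W = 0.5, V = 0.5, F = 0.5)
  structure(list(
    coefficients = tibble::tibble(term = terms, estimate = par,
                                  std.error = 0, conf.low = par,
                                  conf.high = par),
    model = "RSD",
    field = exponential_params(1e-14, 5),
    nugget = 1e-14,
    spline = NULL,
    records = rec,
    grid = grid,
    vcov = matrix(0, k, k),
    engine = list(Sigma = matrix(1e-14 * 2, 1, 1),
                  latent_mean = 0,
                  latent_cov = matrix(0, 1, 1)),
    loglik = NA_real_, loglik_se = NA_real_, ess = NA_real_,
    converged = TRUE,
    settings = list(model = "RSD", n_records = 1)
  ), class = "richness_fit")
}
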