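# Simulation studies behind the acceptance checks: parameter recovery under
# known truth and the preferential-sampling discrimination study. Problem
# sizes (Monte Carlo size, refresh count) are the package's reduced-size
# study settings; the replicate counts follow the study design.

study_ctl <- function() {
  mcml_control(n_sim = 150, refresh = 4, burn = 250, thin = 3, trust = 1)
}

# recovery runs many replicates; a slightly lighter engine keeps the study
# at reduced Monte Carlo size
recovery_ctl <- function() {
  mcml_control(n_sim = 120, refresh = 3, burn = 200, thin = 3, trust = 1)
}

# Sampling-process model recovery: events drawn from a known intensity on a
# 20 x 20 km region, home at the centre.
lgcp_recovery_config <- function() {
  scenario_config(grid_dim = c(20, 20), home = c(10, 10),
                  lgcp = list(alpha = c(-2, -0.1, 1.5), sigma2 = 0.5,
                              phi = 3, kappa = 1))
}

run_lgcp_recovery <- function(n_rep, seed0 = 300) {
  cfg <- lgcp_recovery_config()
  truth <- c(-2, -0.1, 1.5, log(0.5), log(3))
  out <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    b <- gen_scenario(cfg, seed = seed0 + r)
    f <- suppressWarnings(
      fit_lgcp(b$csd$pattern, b$grid, cfg$home, control = recovery_ctl(),
               seed = seed0 + 1000 + r))
    tt <- generics::tidy(f)
    out[[r]] <- dplyr::mutate(tt, truth = truth, rep = r,
                              covers = .data$conf.low <= truth &
                                truth <= .data$conf.high)
  }
  dplyr::bind_rows(out)
}

# Survey richness model recovery: forest-restricted lattice (threshold
# 0.25, about 300 of the 400 intersections) on a 20 x 20 km region with the
# linear-time model truth.
rsd_recovery_config <- function() {
  cfg <- scenario_config(grid_dim = c(20, 20))
  cfg$rsd$forest_threshold <- 0.25
  cfg
}

run_rsd_recovery <- function(n_rep, seed0 = 100) {
  cfg <- rsd_recovery_config()
  truth <- c(1.5, -0.3, 0.4, 0.2, -0.08, log(0.1), log(13), log(0.04))
  out <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    b <- gen_scenario(cfg, seed = seed0 + r)
    f <- suppressWarnings(
      fit_richness(b$rsd$records, b$grid, "RSD", control = recovery_ctl(),
                   seed = seed0 + 1000 + r))
    tt <- generics::tidy(f)
    out[[r]] <- dplyr::mutate(tt, truth = truth, rep = r,
                              covers = .data$conf.low <= truth &
                                truth <= .data$conf.high)
  }
  dplyr::bind_rows(out)
}

recovery_summary <- function(res) {
  dplyr::summarise(dplyr::group_by(res, .data$term),
                   truth = .data$truth[1],
                   mean_est = mean(.data$estimate),
                   rel_bias = (mean(.data$estimate) - .data$truth[1]) /
                     abs(.data$truth[1]),
                   coverage = mean(.data$covers),
                   .groups = "drop")
}

is_regression_coef <- function(term) {
  grepl("^(alpha|beta)", term)
}

# One full-pipeline replicate of a preset; returns the adjustment
# coefficient's estimate and whether its CI covers / excludes zero.
run_gamma_study <- function(preset, n_rep, seed0) {
  out <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    res <- suppressWarnings(
      run_full_analysis(scenario_preset(preset, grid_dim = 20),
                        seed = seed0 + r, control = study_ctl()))
    g <- dplyr::filter(generics::tidy(res$fit_csd), .data$term == "gamma")
    out[[r]] <- tibble::tibble(preset = preset, rep = r,
                               estimate = g$estimate,
                               covers0 = g$conf.low <= 0 & 0 <= g$conf.high)
  }
  dplyr::bind_rows(out)
}
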