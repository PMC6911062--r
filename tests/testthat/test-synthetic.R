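test_that("covariate surfaces are smooth fields in [0, 1]", {
  g <- make_grid(c(0, 0, 20, 20), 1)
  cov1 <- gen_covariates(g, seed = 31, scale = 6)
  for (v in c("W", "V", "F")) {
    expect_true(all(cov1[[v]] >= 0 & cov1[[v]] <= 1))
  }
  expect_identical(gen_covariates(g, seed = 31, scale = 6), cov1)
  # positive spatial autocorrelation at one-cell lag (Moran-style check on
  # horizontal neighbours)
  left <- cov1$W[cov1$col < attr(g, "n_col")]
  right <- cov1$W[cov1$col > 1]
  expect_gt(stats::cor(left, right), 0.3)
})

test_that("the opportunistic generator respects the intensity truth", {
  cfg <- scenario_config(grid_dim = c(15, 15))
  g <- make_grid(c(0, 0, 15, 15), 1)
  covs <- gen_covariates(g, seed = 5, scale = 6,
                         cross_cor = cfg$covariates$cross_cor)
  # Poisson concentration: realized counts stay within 4 sd of the
  # conditional expectation, replicate-wise
  ok <- 0L
  for (r in 1:10) {
    csd <- gen_csd(cfg, covs, seed = 50 + r)
    lam_tot <- sum(cell_area(g) * csd$truth$lambda)
    if (abs(nrow(csd$pattern) - lam_tot) <= 4 * sqrt(lam_tot)) ok <- ok + 1L
  }
  expect_gte(ok, 9L)
  expect_identical(gen_csd(cfg, covs, seed = 99)$records,
                   gen_csd(cfg, covs, seed = 99)$records)
})

test_that("distance-to-home preference shows up in the pattern", {
  cfg_near <- scenario_config(grid_dim = c(15, 15), home = c(7.5, 7.5))
  cfg_near$lgcp$alpha <- c(-1, -0.4, 0)
  cfg_flat <- scenario_config(grid_dim = c(15, 15), home = c(7.5, 7.5))
  cfg_flat$lgcp$alpha <- c(-1, 0, 0)
  cfg_flat$lgcp$sigma2 <- cfg_near$lgcp$sigma2 <- 1e-6
  g <- make_grid(c(0, 0, 15, 15), 1)
  covs <- gen_covariates(g, seed = 5)
  d_near <- d_flat <- numeric(0)
  for (r in 1:5) {
    d_near <- c(d_near, distance_to_home(
      gen_csd(cfg_near, covs, seed = 700 + r)$pattern, c(7.5, 7.5)))
    d_flat <- c(d_flat, distance_to_home(
      gen_csd(cfg_flat, covs, seed = 800 + r)$pattern, c(7.5, 7.5)))
  }
  expect_lt(median(d_near), median(d_flat))
})

test_that("without preferential dependence, counts are unlinked to the field", {
  cfg <- scenario_config(grid_dim = c(15, 15))
  cfg$csd$gamma <- 0
  g <- make_grid(c(0, 0, 15, 15), 1)
  covs <- gen_covariates(g, seed = 5, cross_cor = cfg$covariates$cross_cor)
  cors <- vapply(1:10, function(r) {
    csd <- gen_csd(cfg, covs, seed = 900 + r)
    d <- covariate_at(csd$records, covs, c("W", "V", "F"))
    glm0 <- stats::glm(csd$records$richness ~ d$W + d$V + d$F +
                         log(csd$records$collectors),
                       family = stats::poisson())
    s_at <- csd$truth$S$S[match(locate_cell(csd$records, g),
                                csd$truth$S$cell)]
    stats::cor(stats::residuals(glm0, type = "pearson"), s_at)
  }, numeric(1))
  expect_lt(abs(mean(cors)), 0.1)
})

test_that("the lattice survey is forest-restricted with expected geometry", {
  cfg <- scenario_config(grid_dim = c(30, 30))
  g <- make_grid(c(0, 0, 30, 30), 1)
  covs <- gen_covariates(g, seed = 8, cross_cor = cfg$covariates$cross_cor)
  rsd <- gen_rsd(cfg, covs, seed = 3)
  at <- covariate_at(rsd$records, covs, "F")
  expect_true(all(at$F >= cfg$rsd$forest_threshold))
  expect_true(all(rsd$records$year %in% 1997:1999))
  # threshold zero on a 30 x 30 km region with 1 km spacing: exactly 900
  cfg0 <- cfg; cfg0$rsd$forest_threshold <- 0
  expect_equal(nrow(gen_rsd(cfg0, covs, seed = 3)$records), 900L)
  expect_identical(gen_rsd(cfg, covs, seed = 4)$records,
                   gen_rsd(cfg, covs, seed = 4)$records)
  cfg1 <- cfg; cfg1$rsd$forest_threshold <- 1.1
  expect_error(gen_rsd(cfg1, covs, seed = 3), "forest threshold")
})

test_that("a written scenario bundle round-trips through the readers", {
  dir <- file.path(tempdir(), "bundle-rt")
  on.exit(unlink(dir, recursive = TRUE))
  cfg <- scenario_preset("preferential", grid_dim = 12)
  bundle <- gen_scenario(cfg, seed = 21, dir = dir)
  rec <- read_records(file.path(dir, "records.csv"))
  expect_equal(nrow(rec),
               nrow(bundle$csd$records) + nrow(bundle$rsd$records))
  expect_equal(rec$richness[rec$source == "CSD"],
               bundle$csd$records$richness)
  W <- read_ascii_grid(file.path(dir, "W.asc"), "W")
  expect_equal(W$W, bundle$grid$W, tolerance = 1e-9)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$csd$gamma, 0.5)
  expect_equal(truth$lgcp$alpha, cfg$lgcp$alpha)
  expect_setequal(names(truth$rsd),
                  c("beta", "beta5", "sigma2", "phi", "tau2", "period",
                    "spacing", "forest_threshold"))
  # presets differ only in the preferential coefficient
  expect_equal(scenario_preset("nonpreferential")$csd$gamma, 0)
  expect_equal(scenario_preset("preferential")$csd$gamma, 0.5)
})
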