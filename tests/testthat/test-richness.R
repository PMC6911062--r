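test_that("linear predictors match term-by-term hand sums", {
  rec <- tibble::tibble(W = 0.3, V = 0.6, F = 0.1, collectors = 2,
                        year = 1998, shat = 0.4)
  beta <- c(1.2, 0.5, -0.4, 0.9, 1.8)
  theta <- seq(0.05, 0.45, 0.05)
  gam <- -0.2
  got <- linear_predictor_csd(rec, beta, theta, gam)
  B <- spline_basis(1998, spline_spec())
  hand <- beta[1] + beta[2] * 0.3 + beta[3] * 0.6 + beta[4] * 0.1 +
    beta[5] * log(2) + sum(B * theta) + gam * 0.4
  expect_equal(got, hand, tolerance = 1e-12)
  # collectors scaling: doubling C adds beta4 log 2
  rec4 <- dplyr::mutate(rec, collectors = 4)
  expect_equal(linear_predictor_csd(rec4, beta, theta, gam) - got,
               beta[5] * log(2), tolerance = 1e-12)
  expect_error(linear_predictor_csd(dplyr::mutate(rec, collectors = 0),
                                    beta, theta, gam), ">= 1")

  rsd <- tibble::tibble(W = 0.3, V = 0.6, F = 0.1, year = 1999)
  b5 <- c(0.7, -0.3, 0.4, 0.2, -0.1)
  expect_equal(linear_predictor_rsd(rsd, b5),
               0.7 - 0.3 * 0.3 + 0.4 * 0.6 + 0.2 * 0.1 - 0.1 * 2,
               tolerance = 1e-12)
  # centring convention: 1997 has zero time effect
  rsd97 <- dplyr::mutate(rsd, year = 1997)
  expect_equal(linear_predictor_rsd(rsd97, b5) -
                 linear_predictor_rsd(dplyr::mutate(rsd, year = 1997),
                                      replace(b5, 5, 99)), 0)
})

test_that("a zero adjustment surface neutralises gamma exactly", {
  rec <- tibble::tibble(W = 0.2, V = 0.2, F = 0.2, collectors = 2,
                        year = 2000, shat = 0)
  beta <- c(1, 0, 0, 0, 0); theta <- rep(0, 9)
  expect_equal(linear_predictor_csd(rec, beta, theta, gamma = 5),
               linear_predictor_csd(rec, beta, theta, gamma = 0))
})

test_that("predict_mu reduces to exp(eta) without a latent field", {
  g <- make_grid(c(0, 0, 4, 4), 1)
  set.seed(6)
  g$W <- runif(16); g$V <- runif(16); g$F <- runif(16)
  fit <- manual_rsd_fit(g, beta = c(1, 0.5, -0.3, 0.2, -0.1))
  pred <- predict_mu(fit, g, year = 1999, include_param_unc = FALSE)
  eta <- 1 + 0.5 * g$W - 0.3 * g$V + 0.2 * g$F - 0.1 * (1999 - 1997)
  expect_equal(pred$mu, exp(eta), tolerance = 1e-6)
  expect_true(all(pred$se < 1e-5))
})

test_that("predict_mu is monotone in each covariate per its coefficient sign", {
  g <- make_grid(c(0, 0, 4, 4), 1)
  g$W <- 0.5; g$V <- 0.5; g$F <- 0.5
  fit <- manual_rsd_fit(g, beta = c(1, 0.5, -0.3, 0.2, -0.1))
  base <- predict_mu(fit, g, year = 1998, include_param_unc = FALSE)$mu
  for (v in c("W", "V", "F")) {
    g2 <- g; g2[[v]] <- g2[[v]] + 0.2
    shifted <- predict_mu(fit, g2, year = 1998,
                          include_param_unc = FALSE)$mu
    b <- fit$coefficients$estimate[match(paste0("beta", match(v, c("W", "V", "F")), "_", v),
                                         fit$coefficients$term)]
    if (b > 0) expect_true(all(shifted > base)) else
      expect_true(all(shifted < base))
  }
})

test_that("the collector ratio between C = 2 and C = 1 is 2^beta4", {
  st <- small_study()
  fit <- st$fit_csd
  p2 <- predict_mu(fit, st$bundle$grid, year = 1998, collectors = 2,
                   shat = st$shat, include_param_unc = FALSE)
  p1 <- predict_mu(fit, st$bundle$grid, year = 1998, collectors = 1,
                   shat = st$shat, include_param_unc = FALSE)
  b4 <- tidy(fit)$estimate[tidy(fit)$term == "beta4_logC"]
  expect_equal(p2$mu / p1$mu, rep(2^b4, nrow(p2)), ignore_attr = TRUE,
               tolerance = 1e-6)
})

test_that("single-cell lognormal prediction matches a sampling oracle", {
  g <- make_grid(c(0, 0, 1, 1), 1)
  g$W <- 0.4; g$V <- 0.2; g$F <- 0.6
  fit <- manual_rsd_fit(g, beta = c(0.8, 0.3, -0.2, 0.1, -0.05))
  # inject a genuine latent posterior N(m, v) at one record location
  m <- 0.3; v <- 0.2; nu2 <- 0.25
  fit$field <- exponential_params(nu2, 5)
  fit$engine <- list(Sigma = matrix(nu2 + 0.01, 1, 1),
                     latent_mean = m, latent_cov = matrix(0.001, 1, 1))
  pred <- predict_mu(fit, g, year = 1997, include_param_unc = FALSE)
  # oracle: Monte Carlo over U draws with the implied conditional moments
  cc <- nu2 / (nu2 + 0.01)
  m_u <- cc * m
  v_u <- nu2 - cc * nu2 + cc^2 * 0.001
  eta <- 0.8 + 0.3 * 0.4 - 0.2 * 0.2 + 0.1 * 0.6
  set.seed(3)
  draws <- exp(eta + rnorm(2e5, m_u, sqrt(v_u)))
  expect_equal(pred$mu, mean(draws), tolerance = 0.01)
  expect_equal(pred$se, stats::sd(draws), tolerance = 0.03)
  expect_equal(pred$cov, pred$se / pred$mu)
})

test_that("fit_richness validates inputs", {
  st <- small_study()
  expect_error(fit_richness(st$bundle$csd$records, st$bundle$grid, "CSD"),
               "shat")
  g <- st$bundle$grid
  recs <- st$bundle$rsd$records
  const <- dplyr::mutate(g, V = 0.5)
  expect_warning(
    try(fit_richness(recs[1:31, ], const, "RSD",
                     control = mcml_control(n_sim = 20, refresh = 0,
                                            burn = 10, prefit = FALSE)),
        silent = TRUE),
    class = "prefrich_collinear_design")
})

test_that("the fitted temporal effect is centred on 1997-1999", {
  st <- small_study()
  eff <- spline_effect(st$fit_csd, years = 1997:1999)
  expect_lt(abs(mean(eff$effect)), 1e-9)
  expect_true(all(eff$conf.low <= eff$effect & eff$effect <= eff$conf.high))
})
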