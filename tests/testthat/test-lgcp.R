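test_that("bin_points conserves events and places them correctly", {
  g <- make_grid(c(0, 0, 5, 5), 1)
  empty <- bin_points(tibble::tibble(x = numeric(), y = numeric()), g)
  expect_true(all(empty$count == 0))
  three <- bin_points(tibble::tibble(x = rep(2.3, 3), y = rep(4.2, 3)), g)
  expect_equal(sum(three$count), 3L)
  expect_equal(max(three$count), 3L)
  set.seed(14)
  pts <- tibble::tibble(x = runif(40, 0, 5), y = runif(40, 0, 5))
  expect_equal(sum(bin_points(pts, g)$count), 40L)
  expect_error(bin_points(tibble::tibble(x = 9, y = 1), g), "outside")
})

test_that("the conditional cell-count log-likelihood has its closed forms", {
  g <- make_grid(c(0, 0, 3, 4), 1)
  cells <- tibble::tibble(count = 0, D = runif(12), V = runif(12), S = 0,
                          area = 1)
  a0 <- -1; a1 <- -0.2; a2 <- 1.1
  # all counts zero: minus the summed intensity
  expect_equal(lgcp_loglik(cells, a0, a1, a2),
               -sum(exp(a0 + a1 * cells$D + a2 * cells$V)))
  # single cell, count 2, unit area, linear predictor 0
  one <- tibble::tibble(count = 2, D = 0, V = 0, S = 0, area = 1)
  expect_equal(lgcp_loglik(one, 0, 5, 5), 2 * 0 - 1)
  # 12-cell instance against a brute-force per-cell sum
  set.seed(9)
  cells$count <- rpois(12, 1)
  cells$S <- rnorm(12, 0, 0.5)
  cells$area <- 0.25
  brute <- 0
  for (i in 1:12) {
    lam <- cells$area[i] * exp(a0 + a1 * cells$D[i] + a2 * cells$V[i] +
                                 cells$S[i])
    brute <- brute + cells$count[i] * log(lam) - lam
  }
  expect_equal(lgcp_loglik(cells, a0, a1, a2), brute, tolerance = 1e-10)
  expect_error(lgcp_loglik(dplyr::mutate(one, D = Inf), 1, 1, 1),
               "non-finite")
})

test_that("intensity_ratio exponentiates coefficient times change", {
  expect_equal(intensity_ratio(0, 5), 1)
  expect_equal(intensity_ratio(-0.031, 10), exp(-0.31))
  expect_equal(round(intensity_ratio(2.778)), 16)
})

test_that("events in masked cells are rejected with a named error", {
  g <- make_grid(c(0, 0, 6, 6), 1, mask_rule = function(x, y) x < 5)
  g$V <- 0.5
  pts <- tibble::tibble(x = c(1.5, 5.5), y = c(1.5, 1.5))
  expect_error(fit_lgcp(pts, g, c(0, 0)), class = "prefrich_masked_points")
})

test_that("the fitted latent surface highlights a known hotspot", {
  st <- small_study()
  fit <- st$lgcp
  # predictive mean at cells, compared with the generator's true field:
  # positive correlation demonstrates the surface tracks real structure
  truth <- st$bundle$truth$S
  sh <- predict_shat(fit)
  m <- merge(as.data.frame(sh), as.data.frame(truth), by = "cell")
  expect_gt(stats::cor(m$shat, m$S), 0.2)
  # far from every event the conditional mean relaxes to the prior mean 0
  far <- predict_shat(fit, targets = data.frame(x = 1e4, y = 1e4))
  expect_lt(abs(far$shat), 1e-6)
})

test_that("predict_shat at held-out targets matches the dense oracle", {
  st <- small_study()
  fit <- st$lgcp
  ls <- fit$latent_summary
  keep <- ls[1:8, ]
  sub <- fit
  sub$latent_summary <- keep
  sub$latent_cov <- fit$latent_cov[1:8, 1:8]
  tgt <- data.frame(x = c(2.2, 7.7), y = c(3.3, 8.1))
  got <- predict_shat(sub, targets = tgt)
  oracle <- cond_gauss_oracle(
    cbind(keep$x, keep$y), keep$mean, as.matrix(tgt),
    function(u) matern_correlation(u, fit$field),
    fit$field$variance)
  expect_equal(got$shat, oracle$mean, tolerance = 1e-8)
})

test_that("expected count under the fitted model is near the observed count", {
  st <- small_study()
  fit <- st$lgcp
  al <- tidy(fit)$estimate[1:3]
  cells <- fit$latent_summary
  grid_cells <- fit$grid[fit$grid$inside, ]
  D <- distance_to_home(cells[c("x", "y")], st$cfg$home)
  lam <- cell_area(fit$grid) *
    exp(al[1] + al[2] * D + al[3] * grid_cells$V + cells$mean +
          cells$var / 2)
  n_obs <- nrow(st$bundle$csd$pattern)
  expect_lt(abs(sum(lam) - n_obs) / n_obs, 0.15)
})
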