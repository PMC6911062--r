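test_that("Matérn correlation matches closed forms and the Bessel oracle", {
  # limiting value at zero distance
  expect_equal(matern_correlation(0, matern_params(1, 2)), 1)
  # smoothness 1/2 reduces to the exponential correlation
  p_half <- matern_params(1, scale = 2, smoothness = 0.5)
  expect_equal(matern_correlation(2, p_half), exp(-1), tolerance = 1e-12)
  # smoothness 1 at u = phi equals K_1(1), checked against the integral
  # representation of the Bessel function
  k1 <- bessel_k_oracle(1, 1)
  expect_equal(matern_correlation(1, matern_params(1, 1, 1)), k1,
               tolerance = 1e-9)
  expect_equal(round(k1, 4), 0.6019)
  # invalid inputs
  expect_error(matern_correlation(-1, p_half), "non-negative")
  expect_error(matern_params(-1, 2), "positive")
})

test_that("exponential correlation has the stated closed form", {
  p <- exponential_params(1, scale = 3)
  expect_equal(exponential_correlation(0, p), 1)
  expect_equal(exponential_correlation(3, p), exp(-1))
  # inverse form used by the comparison-region rule
  expect_equal(exponential_correlation(-3 * log(0.75), p), 0.75)
})

test_that("Matérn with smoothness 1/2 equals exponential on a distance grid", {
  u <- seq(0, 20, length.out = 100)
  pm <- matern_params(1, scale = 2.5, smoothness = 0.5)
  pe <- exponential_params(1, scale = 2.5)
  expect_equal(matern_correlation(u, pm), exponential_correlation(u, pe),
               tolerance = 1e-10)
})

test_that("correlation functions are non-increasing and in (0, 1]", {
  u <- seq(0, 15, length.out = 120)
  for (p in list(matern_params(1, 2, 1), matern_params(1, 0.5, 2.5),
                 exponential_params(1, 4))) {
    r <- if (inherits(p, "matern_params")) {
      matern_correlation(u, p)
    } else {
      exponential_correlation(u, p)
    }
    expect_true(all(diff(r) <= 1e-12))
    expect_true(all(r > 0 & r <= 1))
  }
})

test_that("build_covariance matches the brute-force double loop", {
  expect_equal(build_covariance(data.frame(x = 1, y = 2),
                                exponential_params(2, 3)),
               matrix(2, 1, 1))
  xy2 <- data.frame(x = c(0, 3), y = c(0, 4))
  S2 <- build_covariance(xy2, exponential_params(1.5, 2))
  expect_equal(S2[1, 2], 1.5 * exp(-5 / 2))
  set.seed(11)
  xy <- data.frame(x = runif(5, 0, 10), y = runif(5, 0, 10))
  pm <- matern_params(0.8, 2.2, 1)
  S <- build_covariance(xy, pm, nugget = 0.3)
  S_oracle <- brute_cov(as.matrix(xy), function(u) matern_correlation(u, pm),
                        0.8, nugget = 0.3)
  expect_equal(S, S_oracle, tolerance = 1e-12)
})

test_that("simulate_field is reproducible and has the target moments", {
  p <- exponential_params(1.5, 2)
  one <- data.frame(x = 0, y = 0)
  sims <- simulate_field(one, p, n = 2000, seed = 4)
  v <- stats::var(sims$value)
  se_v <- 1.5 * sqrt(2 / 1999)          # sd of a chi-square variance estimate
  expect_lt(abs(v - 1.5), 3 * se_v)
  expect_lt(abs(mean(sims$value)), 3 * sqrt(1.5 / 2000))
  expect_identical(simulate_field(one, p, n = 5, seed = 9),
                   simulate_field(one, p, n = 5, seed = 9))
})

test_that("simulate_field empirical covariance converges with replicates", {
  set.seed(5)
  xy <- data.frame(x = runif(4, 0, 6), y = runif(4, 0, 6))
  p <- exponential_params(1, 2)
  S <- build_covariance(xy, p)
  frob <- function(n) {
    V <- matrix(simulate_field(xy, p, n = n, seed = 21)$value, nrow = 4)
    norm(tcrossprod(V) / n - S, "F")
  }
  expect_lt(frob(8000), frob(300))
})

test_that("duplicate locations are handled through the jitter policy", {
  xy <- data.frame(x = c(1, 1), y = c(2, 2))
  p <- exponential_params(1, 2)
  sims <- simulate_field(xy, p, seed = 3)   # jitter rescues the factorization
  expect_lt(abs(diff(sims$value)), 1e-3)
  expect_error(chol_jitter(matrix(c(1, 2, 2, 1), 2)), "positive definite")
})

test_that("conditional_mean_field interpolates, decays, and matches the dense oracle", {
  p <- exponential_params(1, 2)
  obs <- data.frame(x = c(0, 2, 5), y = c(0, 1, 3),
                    value = c(0.5, -0.2, 1.1))
  # exact interpolation at an observed location with zero nugget
  at_obs <- conditional_mean_field(obs, obs[2, c("x", "y")], p)
  expect_equal(at_obs$value, -0.2, tolerance = 1e-8)
  # prior-mean limit far away
  far <- conditional_mean_field(obs, data.frame(x = 500, y = 500), p)
  expect_lt(abs(far$value), 1e-10)
  expect_equal(far$var, 1, tolerance = 1e-8)
  # dense joint-Gaussian oracle on 3 observed + 2 targets
  tgt <- data.frame(x = c(1, 4), y = c(0.5, 2))
  got <- conditional_mean_field(obs, tgt, p, nugget = 0.1)
  oracle <- cond_gauss_oracle(as.matrix(obs[, c("x", "y")]), obs$value,
                              as.matrix(tgt),
                              function(u) exponential_correlation(u, p),
                              1, nugget = 0.1)
  expect_equal(got$value, oracle$mean, tolerance = 1e-9)
  expect_equal(got$var, oracle$var, tolerance = 1e-9)
})
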