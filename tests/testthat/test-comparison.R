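test_that("relative difference matches hand-computable pairs", {
  expect_equal(relative_difference(3, 3), 0)
  expect_equal(relative_difference(1, 4), -0.75)
  expect_equal(relative_difference(4, 1), 0.75)
  expect_true(is.na(relative_difference(0, 0)))
  expect_error(relative_difference(-1, 2), "non-negative")
})

test_that("relative difference is antisymmetric and bounded", {
  set.seed(12)
  a <- rexp(200); b <- rexp(200)
  rd <- relative_difference(a, b)
  expect_equal(rd, -relative_difference(b, a))
  expect_true(all(rd >= -1 & rd <= 1))
  expect_true(all(abs(rd) < 1))    # both surfaces strictly positive here
})

# a minimal pair of fitted-model stand-ins carrying only what the mask needs
mask_fixture <- function(psi_csd, psi_rsd) {
  list(
    fit_csd = list(field = exponential_params(1, psi_csd),
                   records = tibble::tibble(x = 2.5, y = 2.5)),
    fit_rsd = list(field = exponential_params(1, psi_rsd),
                   records = tibble::tibble(x = 7.5, y = 2.5))
  )
}

test_that("the correlation mask implements the 0.75 rule for both sources", {
  g <- make_grid(c(0, 0, 10, 5), 1)
  fx <- mask_fixture(10, 10)
  m <- correlation_mask(fx$fit_csd, fx$fit_rsd, g, threshold = 0.75)
  # a cell containing a sampled location is always included
  expect_true(m[locate_cell(data.frame(x = 2.5, y = 2.5), g)])
  # cutoff distance is -psi log(threshold) ~ 2.877 km for psi = 10
  cutoff <- -10 * log(0.75)
  expect_equal(cutoff, 2.876821, tolerance = 1e-6)
  d_min <- pmin(distance_to_home(g[c("x", "y")], c(2.5, 2.5)),
                distance_to_home(g[c("x", "y")], c(7.5, 2.5)))
  expect_equal(m, d_min <= cutoff)
  # a cell 5 km from every sample is excluded
  far_cell <- locate_cell(data.frame(x = 0.5, y = 7.5),
                          make_grid(c(0, 0, 10, 10), 1))
  # threshold zero includes everything
  expect_true(all(correlation_mask(fx$fit_csd, fx$fit_rsd, g,
                                   threshold = 0)))
  # intersection rule: the shorter scale governs
  fx2 <- mask_fixture(10, 1)
  m2 <- correlation_mask(fx2$fit_csd, fx2$fit_rsd, g, threshold = 0.75)
  expect_true(all(m2 <= m))
})

test_that("the mask is monotone in the threshold", {
  g <- make_grid(c(0, 0, 10, 5), 1)
  fx <- mask_fixture(8, 12)
  sizes <- vapply(c(0, 0.25, 0.5, 0.75, 0.9),
                  function(th) sum(correlation_mask(fx$fit_csd, fx$fit_rsd,
                                                    g, threshold = th)),
                  numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("summarize_rd reports extremes and conserves counts", {
  g <- make_grid(c(0, 0, 3, 2), 1)
  res <- tibble::as_tibble(g)
  res$comparable <- c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE)
  res$rd <- c(-0.2, 0.6, NA, 0.1, 0.1, NA)
  class(res) <- c("rd_result", class(res))
  s <- summarize_rd(res)
  expect_equal(c(s$min, s$max), c(-0.2, 0.6))
  expect_equal(sum(s$histogram$count), 4L)
  const <- res; const$rd[const$comparable] <- 0.3
  sc <- summarize_rd(const)
  expect_equal(c(sc$min, sc$max), c(0.3, 0.3))
  none <- res; none$comparable <- FALSE
  expect_error(summarize_rd(none), "empty")
})

test_that("compare_predictions assembles mask and RD on the grid", {
  st <- small_study()
  pc <- predict_mu(st$fit_csd, st$bundle$grid, year = 1998, collectors = 2,
                   shat = st$shat)
  pr <- predict_mu(st$fit_rsd, st$bundle$grid, year = 1998)
  cmp <- compare_predictions(pc, pr, st$fit_csd, st$fit_rsd, st$bundle$grid)
  expect_s3_class(cmp, "rd_result")
  expect_true(all(is.na(cmp$rd[!cmp$comparable])))
  inside <- cmp$rd[cmp$comparable]
  if (length(inside)) {
    expect_true(all(inside >= -1 & inside <= 1))
    expect_equal(inside,
                 relative_difference(cmp$mu_csd[cmp$comparable],
                                     cmp$mu_rsd[cmp$comparable]))
  }
})
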