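# Comparison of the two prediction surfaces on the region where both data
# sources are informative.

#' Comparison-region mask from the fitted spatial correlations
#'
#' A grid cell enters the comparison region when, for each source's fitted
#' latent field, the correlation between the cell and the nearest sampled
#' location is at least `threshold` (default 0.75). The nearest sampled
#' location is taken over the union of both sources' locations; with an
#' exponential correlation the rule is equivalent to the nearest-sample
#' distance not exceeding `-scale * log(threshold)` for both fitted scales.
#'
#' @param fit_csd,fit_rsd The two [fit_richness()] results.
#' @param grid Prediction grid.
#' @param locations_csd,locations_rsd Sampled locations per source (tibbles
#'   with `x`, `y`); default the locations stored in the fits.
#' @param threshold Correlation threshold in `[0, 1)` (default 0.75).
#' @return Logical vector, one entry per grid row (masked cells are `FALSE`).
#' @export
correlation_mask <- function(fit_csd, fit_rsd, grid,
                             locations_csd = fit_csd$records,
                             locations_rsd = fit_rsd$records,
                             threshold = 0.75) {
  stopifnot(threshold >= 0, threshold < 1)
  sampled <- rbind(coords_matrix(locations_csd[c("x", "y")]),
                   coords_matrix(locations_rsd[c("x", "y")]))
  if (nrow(sampled) == 0) stop("no sampled locations", call. = FALSE)
  D <- dist_matrix(coords_matrix(grid[c("x", "y")]), sampled)
  d_min <- apply(D, 1, min)
  rho_csd <- exponential_correlation(d_min, fit_csd$field)
  rho_rsd <- exponential_correlation(d_min, fit_rsd$field)
  grid$inside & rho_csd >= threshold & rho_rsd >= threshold
}

#' Relative difference between two prediction surfaces
#'
#' `RD = (mu_csd - mu_rsd) / max(mu_csd, mu_rsd)`, element-wise; positive
#' where the citizen-science surface predicts more. Bounded in `[-1, 1]`,
#' with `|RD| = 1` only when one of the two means is zero; cells where both
#' means are zero get `NA`.
#'
#' @param mu_csd,mu_rsd Non-negative per-cell prediction means.
#' @return Numeric vector of relative differences.
#' @export
relative_difference <- function(mu_csd, mu_rsd) {
  stopifnot(length(mu_csd) == length(mu_rsd))
  if (any(mu_csd < 0, na.rm = TRUE) || any(mu_rsd < 0, na.rm = TRUE)) {
    stop("prediction means must be non-negative", call. = FALSE)
  }
  denom <- pmax(mu_csd, mu_rsd)
  out <- ifelse(denom > 0, (mu_csd - mu_rsd) / denom, NA_real_)
  out
}

#' Compare the two richness prediction surfaces
#'
#' Builds the 0.75-correlation comparison region and the relative-difference
#' surface between the citizen-science and randomised-survey predictions.
#'
#' @param pred_csd,pred_rsd [predict_mu()] surfaces on the same grid.
#' @param fit_csd,fit_rsd The corresponding fits (for the correlation rule).
#' @param grid The prediction grid.
#' @param threshold Correlation threshold (default 0.75).
#' @return A tibble of class `rd_result`: the grid with columns `mu_csd`,
#'   `mu_rsd`, `comparable` (mask) and `rd` (defined only on the mask).
#' @export
compare_predictions <- function(pred_csd, pred_rsd, fit_csd, fit_rsd, grid,
                                threshold = 0.75) {
  out <- tibble::as_tibble(grid[c("cell", "col", "row", "x", "y", "inside")])
  out$mu_csd <- pred_csd$mu[match(out$cell, pred_csd$cell)]
  out$mu_rsd <- pred_rsd$mu[match(out$cell, pred_rsd$cell)]
  out$comparable <- correlation_mask(fit_csd, fit_rsd, grid,
                                     threshold = threshold) &
    !is.na(out$mu_csd) & !is.na(out$mu_rsd)
  out$rd <- NA_real_
  out$rd[out$comparable] <- relative_difference(out$mu_csd[out$comparable],
                                                out$mu_rsd[out$comparable])
  attr(out, "threshold") <- threshold
  attr(out, "grid_meta") <- grid_meta(grid)
  class(out) <- c("rd_result", class(out))
  out
}

#' Summarise a relative-difference surface
#'
#' Minimum, maximum and histogram counts of `RD` over the comparable cells.
#'
#' @param result An `rd_result` from [compare_predictions()].
#' @param breaks Histogram bin edges (default 18 equal bins on
#'   `[-0.9, 0.9]`, widened if values fall outside).
#' @return A list with `n`, `min`, `max`, `mean` and a `histogram` tibble of
#'   bin edges and counts.
#' @export
summarize_rd <- function(result, breaks = seq(-0.9, 0.9, length.out = 19)) {
  rd <- result$rd[result$comparable & !is.na(result$rd)]
  if (length(rd) == 0) stop("comparison region is empty", call. = FALSE)
  if (min(rd) < min(breaks)) breaks <- c(-1, breaks)
  if (max(rd) > max(breaks)) breaks <- c(breaks, 1)
  h <- graphics::hist(rd, breaks = breaks, plot = FALSE)
  list(
    n = length(rd), min = min(rd), max = max(rd), mean = mean(rd),
    histogram = tibble::tibble(lower = utils::head(h$breaks, -1),
                               upper = h$breaks[-1], count = h$counts)
  )
}
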