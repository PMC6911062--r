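# broom-style tidiers and ggplot2 visualisations for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted sampling-process model
#'
#' One row per parameter: the intensity coefficients on the natural scale,
#' the spatial variance and scale on the log scale, with Wald confidence
#' limits.
#'
#' @param x An `lgcp_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`.
#' @export
tidy.lgcp_fit <- function(x, ...) x$coefficients

#' @rdname tidy.lgcp_fit
#' @export
tidy.richness_fit <- function(x, ...) x$coefficients

#' One-row fit summary
#'
#' @param x An `lgcp_fit` or `richness_fit`.
#' @param ... Unused.
#' @return A one-row tibble: Monte Carlo log-likelihood and its standard
#'   error, importance-sampling effective sample size, observation count and
#'   convergence flag.
#' @export
glance.lgcp_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, logLik_se = x$loglik_se, ess = x$ess,
                 nobs = x$settings$n_events, converged = x$converged)
}

#' @rdname glance.lgcp_fit
#' @export
glance.richness_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, logLik_se = x$loglik_se, ess = x$ess,
                 nobs = x$settings$n_records, converged = x$converged)
}

#' Map a per-cell variable of a grid tibble
#'
#' @param grid A `rich_grid` (or any tibble with `x`, `y` and the variable).
#' @param var Column to map (string).
#' @return A ggplot.
#' @export
plot_surface <- function(grid, var) {
  stopifnot(var %in% names(grid))
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$x, y = .data$y,
                                     fill = .data[[var]])) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(x = "easting (km)", y = "northing (km)", fill = var)
}

#' @export
autoplot.lgcp_fit <- function(object, ...) {
  plot_surface(object$latent_summary, "mean") +
    ggplot2::labs(fill = "S-hat",
                  title = "Predictive mean of the latent sampling field")
}

#' @export
autoplot.richness_fit <- function(object, ...) {
  tt <- object$coefficients
  ggplot2::ggplot(tt, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf.low,
                                         xmax = .data$conf.high),
                            height = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "estimate (95% CI)", y = NULL,
                  title = paste(object$model, "richness model"))
}

#' @export
autoplot.rd_result <- function(object, ...) {
  df <- object[object$comparable, ]
  plot_surface(df, "rd") +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), na.value = "grey90") +
    ggplot2::labs(fill = "RD",
                  title = "Relative difference (CSD - RSD) / max")
}
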