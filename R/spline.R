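#' Temporal spline specification
#'
#' The citizen-science richness model carries a smooth temporal effect
#' `f(t)`, a cubic B-spline with interior knots at 1990, 1995, 2000, 2002,
#' 2004 and 2006 and boundary knots at the survey period limits
#' (1985, 2009). Years outside the boundary are refused — no extrapolation.
#'
#' @param knots Strictly increasing interior knot years.
#' @param degree Spline degree (default 3, cubic).
#' @param boundary Length-2 boundary knots (default `c(1985, 2009)`).
#' @return A list of class `spline_spec`.
#' @export
spline_spec <- function(knots = c(1990, 1995, 2000, 2002, 2004, 2006),
                        degree = 3, boundary = c(1985, 2009)) {
  stopifnot(length(boundary) == 2L, boundary[1] < boundary[2],
            all(diff(knots) > 0),
            all(knots > boundary[1]), all(knots < boundary[2]))
  structure(list(knots = knots, degree = degree, boundary = boundary),
            class = "spline_spec")
}

#' Cubic B-spline basis over survey years
#'
#' Evaluates the B-spline basis of a [spline_spec()] at integer (or
#' fractional) years. With `intercept = TRUE` the full basis is returned and
#' its rows sum to 1 (partition of unity); the model fits use
#' `intercept = FALSE`, dropping the first basis function so the temporal
#' effect is identified next to the model intercept.
#'
#' @param years Numeric years within the boundary knots.
#' @param spec A [spline_spec()].
#' @param intercept Keep the full basis? (default `FALSE`).
#' @return A matrix with one row per year.
#' @export
spline_basis <- function(years, spec = spline_spec(), intercept = FALSE) {
  stopifnot(inherits(spec, "spline_spec"))
  if (any(years < spec$boundary[1] | years > spec$boundary[2])) {
    stop("years outside the spline boundary [", spec$boundary[1], ", ",
         spec$boundary[2], "]; no extrapolation", call. = FALSE)
  }
  B <- splines::bs(years, knots = spec$knots, degree = spec$degree,
                   Boundary.knots = spec$boundary, intercept = intercept)
  unname(B[, , drop = FALSE])
}
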