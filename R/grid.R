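#' Create a regular analysis grid
#'
#' Builds the regular square grid on which covariates, the discretized latent
#' field of the point-process model, and all prediction surfaces live. The
#' study design registers everything on a 1 x 1 km reference grid; the cell
#' size defaults accordingly. Cells are indexed column-major from the
#' lower-left corner; each cell is the half-open square
#' `[left, right) x [bottom, top)`.
#'
#' @param bbox Numeric vector `c(xmin, ymin, xmax, ymax)` in km.
#' @param cell_size Cell edge length in km (default 1).
#' @param mask_rule Optional predicate `function(x, y)` returning `TRUE` for
#'   cell centers inside the study region; cells failing it are masked.
#'
#' @return A tibble of class `rich_grid` with columns `cell`, `col`, `row`,
#'   `x`, `y` (cell centers) and `inside`, and attributes `origin`,
#'   `cell_size`, `n_col`, `n_row`.
#' @export
#' @examples
#' g <- make_grid(c(0, 0, 10, 10), cell_size = 1)
#' nrow(g)  # 100 cells
make_grid <- function(bbox, cell_size = 1, mask_rule = NULL) {
  stopifnot(is.numeric(bbox), length(bbox) == 4L, is.numeric(cell_size),
            length(cell_size) == 1L, cell_size > 0)
  if (bbox[3] <= bbox[1] || bbox[4] <= bbox[2]) {
    stop("degenerate bounding box: need xmax > xmin and ymax > ymin", call. = FALSE)
  }
  n_col <- as.integer(ceiling((bbox[3] - bbox[1]) / cell_size - 1e-9))
  n_row <- as.integer(ceiling((bbox[4] - bbox[2]) / cell_size - 1e-9))
  df <- tidyr::expand_grid(row = seq_len(n_row), col = seq_len(n_col))
  df <- dplyr::arrange(df, .data$col, .data$row)
  df <- dplyr::mutate(
    df,
    cell = dplyr::row_number(),
    x = bbox[1] + (.data$col - 0.5) * cell_size,
    y = bbox[2] + (.data$row - 0.5) * cell_size,
    inside = TRUE
  )
  df <- df[, c("cell", "col", "row", "x", "y", "inside")]
  if (!is.null(mask_rule)) df$inside <- mask_rule(df$x, df$y)
  new_grid(df, origin = bbox[1:2], cell_size = cell_size,
           n_col = n_col, n_row = n_row)
}

new_grid <- function(df, origin, cell_size, n_col, n_row) {
  out <- tibble::as_tibble(df)
  attr(out, "origin") <- as.numeric(origin)
  attr(out, "cell_size") <- cell_size
  attr(out, "n_col") <- as.integer(n_col)
  attr(out, "n_row") <- as.integer(n_row)
  class(out) <- c("rich_grid", class(out))
  out
}

grid_meta <- function(grid) {
  m <- list(origin = attr(grid, "origin"), cell_size = attr(grid, "cell_size"),
            n_col = attr(grid, "n_col"), n_row = attr(grid, "n_row"))
  if (any(vapply(m, is.null, logical(1)))) {
    stop("grid is missing metadata; build it with make_grid()/read_ascii_grid()",
         call. = FALSE)
  }
  m
}

#' Cell area of a grid, km^2
#' @param grid A `rich_grid`.
#' @return Scalar cell area.
#' @export
cell_area <- function(grid) grid_meta(grid)$cell_size^2

#' Locate points in grid cells
#'
#' Maps planar points to cell indices under the half-open convention
#' `[left, right) x [bottom, top)`: a point on a cell's lower-left corner
#' belongs to that cell; a point on an interior right or top edge belongs to
#' the neighbouring cell.
#'
#' @param points Data frame with columns `x`, `y`, or two-column matrix.
#' @param grid A `rich_grid`.
#'
#' @return Integer vector of cell indices (rows of `grid`).
#' @export
locate_cell <- function(points, grid) {
  m <- grid_meta(grid)
  xy <- coords_matrix(points)
  col <- floor((xy[, 1] - m$origin[1]) / m$cell_size) + 1
  row <- floor((xy[, 2] - m$origin[2]) / m$cell_size) + 1
  bad <- col < 1 | col > m$n_col | row < 1 | row > m$n_row
  if (any(bad)) {
    stop("points outside the grid extent at indices: ",
         paste(utils::head(which(bad), 10L), collapse = ", "), call. = FALSE)
  }
  as.integer((col - 1) * m$n_row + row)
}

#' Distance from points to the collectors' home location
#'
#' Euclidean distance in km between each point and a single reference point,
#' the central point of the collectors' residential municipality. This is the
#' `D(x)` covariate of the sampling-intensity model.
#'
#' @param points Data frame with columns `x`, `y`, or two-column matrix.
#' @param home Length-2 numeric `c(x, y)` in km.
#'
#' @return Non-negative numeric vector of distances.
#' @export
distance_to_home <- function(points, home) {
  stopifnot(is.numeric(home), length(home) == 2L)
  xy <- coords_matrix(points)
  sqrt((xy[, 1] - home[1])^2 + (xy[, 2] - home[2])^2)
}

#' Look up cell-level covariate values at point locations
#'
#' Covariates are defined per grid cell; points inherit the value of their
#' containing cell (no interpolation). Points in masked cells get `NA`.
#'
#' @param points Data frame with columns `x`, `y`.
#' @param grid A `rich_grid` carrying the covariate columns.
#' @param vars Character vector of covariate column names (e.g. `c("W", "V",
#'   "F")`).
#'
#' @return A tibble: `points` with the covariate columns appended.
#' @export
covariate_at <- function(points, grid, vars) {
  missing_vars <- setdiff(vars, names(grid))
  if (length(missing_vars)) {
    stop("grid has no covariate column(s): ", paste(missing_vars, collapse = ", "),
         call. = FALSE)
  }
  idx <- locate_cell(points, grid)
  out <- tibble::as_tibble(points)
  for (v in vars) {
    val <- grid[[v]][idx]
    val[!grid$inside[idx]] <- NA_real_
    out[[v]] <- val
  }
  out
}
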