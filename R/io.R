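#' Write a grid variable as an ESRI ASCII grid
#'
#' Serialises one per-cell variable of a `rich_grid` in the plain-text `.asc`
#' raster format (header of `ncols`, `nrows`, `xllcorner`, `yllcorner`,
#' `cellsize`, `NODATA_value`, then rows from north to south). Masked cells
#' and `NA` values are written as the nodata value.
#'
#' @param grid A `rich_grid`.
#' @param var Name of the column to write.
#' @param path Output file path.
#' @param nodata Nodata sentinel (default -9999).
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(grid, var, path, nodata = -9999) {
  m <- grid_meta(grid)
  stopifnot(var %in% names(grid))
  vals <- grid[[var]]
  vals[!grid$inside] <- NA_real_
  M <- matrix(vals[order(grid$col, grid$row)], nrow = m$n_row, ncol = m$n_col)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", m$n_col), paste("nrows", m$n_row),
    paste("xllcorner", format(m$origin[1], digits = 15)),
    paste("yllcorner", format(m$origin[2], digits = 15)),
    paste("cellsize", format(m$cell_size, digits = 15)),
    paste("NODATA_value", nodata)
  ), con)
  for (r in seq(m$n_row, 1)) {   # north to south
    row_vals <- M[r, ]
    row_vals[is.na(row_vals)] <- nodata
    writeLines(paste(format(row_vals, digits = 10, trim = TRUE, scientific = FALSE),
                     collapse = " "), con)
  }
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path Path to a `.asc` file written by [write_ascii_grid()] or any
#'   conforming writer.
#' @param var Column name to store the values under (default `"value"`).
#' @return A `rich_grid` tibble; nodata cells have `inside = FALSE` and `NA`
#'   values.
#' @export
read_ascii_grid <- function(path, var = "value") {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  n_col <- as.integer(hdr$ncols); n_row <- as.integer(hdr$nrows)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  stopifnot(length(vals) == n_col * n_row)
  M <- matrix(vals, nrow = n_row, ncol = n_col, byrow = TRUE)
  M <- M[seq(n_row, 1), , drop = FALSE]   # back to south-up
  bbox <- c(hdr$xllcorner, hdr$yllcorner,
            hdr$xllcorner + n_col * hdr$cellsize,
            hdr$yllcorner + n_row * hdr$cellsize)
  g <- make_grid(bbox, hdr$cellsize)
  v <- M[cbind(g$row, g$col)]
  v[v == nodata] <- NA_real_
  g[[var]] <- v
  g$inside <- !is.na(v)
  g
}

#' Read survey records from delimited text
#'
#' Reads point-referenced richness records with header columns
#' `x, y, year, collectors, richness, source` (comma- or whitespace-
#' delimited). Coordinates are km in a projected system; `meters = TRUE`
#' divides `x`, `y` by 1000 on the way in.
#'
#' @param path File path.
#' @param meters Are coordinates in meters? (default `FALSE`, i.e. km).
#' @return A tibble of records.
#' @export
read_records <- function(path, meters = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x", "y", "year", "richness", "source")
  if (!all(need %in% names(df))) {
    stop("records file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (meters) {
    df$x <- df$x / 1000; df$y <- df$y / 1000
  }
  tibble::as_tibble(df)
}

#' Write survey records to delimited text
#' @param records Tibble of records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a point pattern (sampling locations) from delimited text
#'
#' Expects header columns `x, y, year`.
#' @inheritParams read_records
#' @return A tibble with columns `x`, `y`, `year`.
#' @export
read_point_pattern <- function(path, meters = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("x", "y") %in% names(df))) {
    stop("point-pattern file must have columns x, y", call. = FALSE)
  }
  if (meters) {
    df$x <- df$x / 1000; df$y <- df$y / 1000
  }
  tibble::as_tibble(df)
}

#' Write a model-fit summary as JSON
#'
#' Writes the tidy coefficient table of a fitted model (estimates and 95%
#' confidence limits; covariance parameters on the log scale, regression
#' coefficients on the natural scale) plus fitting metadata.
#'
#' @param fit An `lgcp_fit` or `richness_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  tt <- generics::tidy(fit)
  out <- list(
    model = class(fit)[1],
    parameters = lapply(seq_len(nrow(tt)), function(i) {
      list(term = tt$term[i], estimate = tt$estimate[i],
           ci_low = tt$conf.low[i], ci_high = tt$conf.high[i])
    }),
    loglik = fit$loglik,
    settings = fit$settings
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
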