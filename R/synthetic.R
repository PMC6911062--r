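# Synthetic study generator.
#
# Emulates the statistical structure of the study design at desk scale: a
# square region on a 1 km grid with smooth correlated covariate fields; an
# opportunistic point pattern drawn from the log-Gaussian Cox process,
# concentrated near the collectors' home and in high-value cells; a
# forest-restricted randomly-offset lattice survey; and conditionally Poisson
# richness counts. Preferential dependence is injected through the TRUE
# latent sampling field (coefficient `gamma`), while the analysis pipeline
# can only ever use its estimate — exactly the attenuation the adjustment
# faces on real data. The generators build their fields through the plain
# simulation backend and never touch the model-fitting code paths.

#' Configuration of a synthetic study scenario
#'
#' Collects every generative parameter of the synthetic study: the grid, the
#' collectors' home, the truth of the sampling-intensity model, of both
#' richness models, and the survey-design settings. Defaults give a 30 x 30
#' km region at 1 km resolution with roughly 150-250 opportunistic events
#' and a forest-restricted lattice survey of a few hundred locations.
#'
#' @param grid_dim Length-2 integer, cells per side (default `c(30, 30)`).
#' @param cell_size Cell size in km (default 1).
#' @param home Collectors' home `c(x, y)` in km.
#' @param lgcp Truth of the sampling model: `alpha` (intercept,
#'   distance-to-home, value-of-nature), `sigma2`, `phi`, `kappa`.
#' @param csd Truth of the citizen-science richness model: `beta`
#'   (intercept, W, V, F, log-collectors), `gamma`, `spline_coefs`,
#'   `sigma2`, `phi`, `tau2`, `period`, `collector_probs` (on 1, 2, 3
#'   collectors).
#' @param rsd Truth of the randomised-survey model: `beta` (intercept, W, V,
#'   F), `beta5` (linear time), `sigma2`, `phi`, `tau2`, `period`,
#'   `spacing` (lattice spacing, km), `forest_threshold` (minimum F for
#'   eligibility).
#' @param covariates Covariate-field settings: `scale` (correlation scale,
#'   km) and `cross_cor` (3 x 3 correlation matrix of the underlying
#'   Gaussian fields, order W, V, F).
#'
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(
    grid_dim = c(30, 30), cell_size = 1, home = c(6, 15),
    lgcp = list(alpha = c(-1.5, -0.1, 1.5), sigma2 = 0.5, phi = 3, kappa = 1),
    csd = list(beta = c(1.0, 0.6, -0.35, 0.95, 1.9), gamma = 0,
               spline_coefs = c(0.1, 0.25, 0.2, 0, -0.1, -0.05, 0.1, 0.2, 0.15),
               sigma2 = 0.35, phi = 5.4, tau2 = 0.1,
               period = c(1985, 2009), collector_probs = c(0.1, 0.8, 0.1)),
    rsd = list(beta = c(1.5, -0.3, 0.4, 0.2), beta5 = -0.08,
               sigma2 = 0.1, phi = 13, tau2 = 0.04,
               period = c(1997, 1999), spacing = 1, forest_threshold = 0.6),
    covariates = list(scale = 6,
                      cross_cor = matrix(c(1, 0.3, 0.2,
                                           0.3, 1, 0.4,
                                           0.2, 0.4, 1), 3, 3))) {
  stopifnot(length(grid_dim) == 2L, all(grid_dim >= 2),
            lgcp$sigma2 >= 0, csd$sigma2 >= 0, csd$tau2 >= 0,
            rsd$sigma2 >= 0, rsd$tau2 >= 0,
            length(csd$collector_probs) == 3L,
            abs(sum(csd$collector_probs) - 1) < 1e-8)
  structure(list(grid_dim = grid_dim, cell_size = cell_size, home = home,
                 lgcp = lgcp, csd = csd, rsd = rsd, covariates = covariates),
            class = "scenario_config")
}

#' Packaged scenario presets
#'
#' Two ready-made scenarios differing only in the preferential-sampling
#' coefficient of the generator: `"nonpreferential"` has `gamma = 0` (the
#' sampling field does not enter the richness counts) and `"preferential"`
#' has `gamma = 0.5`.
#'
#' @param name `"nonpreferential"` or `"preferential"`.
#' @param grid_dim Cells per side (default 30; smaller values give faster,
#'   noisier studies).
#' @return A [scenario_config()].
#' @export
scenario_preset <- function(name = c("nonpreferential", "preferential"),
                            grid_dim = 30) {
  name <- match.arg(name)
  cfg <- scenario_config(grid_dim = c(grid_dim, grid_dim))
  cfg$csd$gamma <- if (name == "preferential") 0.5 else 0
  cfg$preset <- name
  cfg
}

# Documented seed-splitting rule: stage k of a run seeded with `seed` uses
# seed * 8 + k, so any stage can be rerun in isolation.
stage_seed <- function(seed, k) as.integer(seed) * 8L + as.integer(k)

#' Generate smooth correlated covariate surfaces
#'
#' Builds the wetness (`W`), value-of-nature (`V`) and forest-cover (`F`)
#' surfaces by drawing three cross-correlated Gaussian fields with
#' exponential spatial correlation and pushing them through the standard
#' normal CDF, giving smooth fields with uniform margins on `[0, 1]`.
#'
#' @param grid A `rich_grid`.
#' @param seed Integer seed.
#' @param scale Spatial correlation scale in km (default 6).
#' @param cross_cor 3 x 3 cross-correlation matrix (order W, V, F).
#' @return The grid with columns `W`, `V`, `F` appended.
#' @export
gen_covariates <- function(grid, seed, scale = 6,
                           cross_cor = diag(3)) {
  p <- exponential_params(variance = 1, scale = scale)
  sims <- simulate_field(grid[c("x", "y")], p, n = 3, seed = seed)
  E <- matrix(sims$value, ncol = 3)
  E <- E %*% chol(cross_cor)
  out <- grid
  out$W <- stats::pnorm(E[, 1])
  out$V <- stats::pnorm(E[, 2])
  out$F <- stats::pnorm(E[, 3])
  out$W[!out$inside] <- NA_real_
  out$V[!out$inside] <- NA_real_
  out$F[!out$inside] <- NA_real_
  out
}

sample_years <- function(n, period) {
  sample(seq(period[1], period[2]), n, replace = TRUE)
}

# Poisson richness counts given a linear predictor plus latent field U
# (shared within cells) and per-record nugget Z.
draw_counts <- function(eta_fixed, cells, coords_by_cell, sigma2, phi, tau2) {
  n <- length(eta_fixed)
  ucell <- sort(unique(cells))
  U <- if (sigma2 > 0) {
    p <- exponential_params(sigma2, phi)
    f <- simulate_field(coords_by_cell[match(ucell, coords_by_cell$cell),
                                       c("x", "y")], p)
    f$value
  } else rep(0, length(ucell))
  Z <- if (tau2 > 0) stats::rnorm(n, 0, sqrt(tau2)) else numeric(n)
  U_rec <- U[match(cells, ucell)]
  y <- stats::rpois(n, exp(eta_fixed + U_rec + Z))
  list(y = y, U = tibble::tibble(cell = ucell, U = U), Z = Z)
}

#' Generate an opportunistic (citizen-science) data set
#'
#' Draws sampling locations from the log-Gaussian Cox process truth —
#' cell-wise Poisson event counts with mean `area * Lambda(cell)`, positions
#' uniform within cells — then richness counts from the citizen-science
#' model truth, using the TRUE latent sampling field (times `gamma`) so that
#' genuine preferential dependence is present when `gamma != 0`.
#'
#' @param config A [scenario_config()].
#' @param covars Grid with covariates from [gen_covariates()].
#' @param seed Integer seed.
#' @return A list: `pattern` (tibble `x`, `y`, `year`), `records` (tibble
#'   `x`, `y`, `year`, `collectors`, `richness`, `source`), and `truth`
#'   (latent fields and intensity actually used).
#' @export
gen_csd <- function(config, covars, seed) {
  grid <- covars
  cells <- grid[grid$inside, ]
  area <- cell_area(grid)
  withr::with_seed(seed, {
    S <- simulate_field(cells[c("x", "y")],
                        matern_params(config$lgcp$sigma2, config$lgcp$phi,
                                      config$lgcp$kappa))$value
    D <- distance_to_home(cells[c("x", "y")], config$home)
    lam <- exp(config$lgcp$alpha[1] + config$lgcp$alpha[2] * D +
                 config$lgcp$alpha[3] * cells$V + S)
    if (sum(area * lam) > 1e6) {
      stop("expected event count exceeds 1e6; lower the intensity truth",
           call. = FALSE)
    }
    n_ev <- stats::rpois(nrow(cells), area * lam)
    idx <- rep(seq_len(nrow(cells)), n_ev)
    n <- length(idx)
    half <- grid_meta(grid)$cell_size / 2
    pattern <- tibble::tibble(
      x = cells$x[idx] + stats::runif(n, -half, half),
      y = cells$y[idx] + stats::runif(n, -half, half),
      year = sample_years(n, config$csd$period)
    )
    collectors <- sample(1:3, n, replace = TRUE,
                         prob = config$csd$collector_probs)
    B <- spline_basis(pattern$year, spline_spec(
      boundary = config$csd$period))
    b <- config$csd$beta
    eta <- b[1] + b[2] * cells$W[idx] + b[3] * cells$V[idx] +
      b[4] * cells$F[idx] + b[5] * log(collectors) +
      as.vector(B %*% config$csd$spline_coefs) +
      config$csd$gamma * S[idx]
    cnt <- draw_counts(eta, cells$cell[idx],
                       tibble::tibble(cell = cells$cell, x = cells$x,
                                      y = cells$y),
                       config$csd$sigma2, config$csd$phi, config$csd$tau2)
    records <- tibble::tibble(
      x = pattern$x, y = pattern$y, year = pattern$year,
      collectors = collectors, richness = cnt$y, source = "CSD"
    )
  })
  list(pattern = pattern, records = records,
       truth = list(S = tibble::tibble(cell = cells$cell, x = cells$x,
                                       y = cells$y, S = S),
                    lambda = lam, U = cnt$U))
}

#' Generate a randomised-survey data set
#'
#' Places a randomly offset regular lattice over the region, keeps the
#' intersections whose cell passes the forest-cover threshold, assigns
#' survey years uniformly over the survey period, and draws richness counts
#' from the randomised-survey model truth.
#'
#' @inheritParams gen_csd
#' @return A list: `records` tibble and `truth` (latent field used).
#' @export
gen_rsd <- function(config, covars, seed) {
  grid <- covars
  m <- grid_meta(grid)
  sp <- config$rsd$spacing
  withr::with_seed(seed, {
    off <- stats::runif(2, 0, sp)
    xs <- seq(m$origin[1] + off[1], m$origin[1] + m$n_col * m$cell_size - 1e-9,
              by = sp)
    ys <- seq(m$origin[2] + off[2], m$origin[2] + m$n_row * m$cell_size - 1e-9,
              by = sp)
    pts <- tidyr::expand_grid(x = xs, y = ys)
    pts <- covariate_at(pts, grid, c("W", "V", "F"))
    keep <- !is.na(pts$F) & pts$F >= config$rsd$forest_threshold
    pts <- pts[keep, ]
    if (nrow(pts) == 0) {
      stop("no lattice point passes the forest threshold", call. = FALSE)
    }
    n <- nrow(pts)
    year <- sample_years(n, config$rsd$period)
    b <- config$rsd$beta
    eta <- b[1] + b[2] * pts$W + b[3] * pts$V + b[4] * pts$F +
      config$rsd$beta5 * (year - 1997)
    cnt <- draw_counts(eta, locate_cell(pts, grid),
                       tibble::tibble(cell = grid$cell, x = grid$x,
                                      y = grid$y),
                       config$rsd$sigma2, config$rsd$phi, config$rsd$tau2)
    records <- tibble::tibble(
      x = pts$x, y = pts$y, year = year,
      collectors = NA_integer_, richness = cnt$y, source = "RSD"
    )
  })
  list(records = records, truth = list(U = cnt$U))
}

#' Generate a complete synthetic study
#'
#' Runs [gen_covariates()], [gen_csd()] and [gen_rsd()] with per-stage seeds
#' derived from one global seed (stage `k` uses `seed * 8 + k`), and
#' optionally writes the whole bundle — records, point pattern, covariate
#' rasters, truth and resolved configuration — to a directory in the
#' package's plain-text formats.
#'
#' @param config A [scenario_config()].
#' @param seed Global integer seed.
#' @param dir Optional output directory.
#' @return A list (`config`, `seed`, `grid` with covariates, `csd`, `rsd`,
#'   `truth`), invisibly carrying paths when `dir` is given.
#' @export
gen_scenario <- function(config = scenario_config(), seed = 1, dir = NULL) {
  grid <- make_grid(c(0, 0, config$grid_dim[1] * config$cell_size,
                      config$grid_dim[2] * config$cell_size),
                    config$cell_size)
  covars <- gen_covariates(grid, seed = stage_seed(seed, 1),
                           scale = config$covariates$scale,
                           cross_cor = config$covariates$cross_cor)
  csd <- gen_csd(config, covars, seed = stage_seed(seed, 2))
  rsd <- gen_rsd(config, covars, seed = stage_seed(seed, 3))
  bundle <- list(config = config, seed = seed, grid = covars,
                 csd = csd, rsd = rsd,
                 truth = list(S = csd$truth$S, U_csd = csd$truth$U,
                              U_rsd = rsd$truth$U))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    ok <- FALSE
    on.exit(if (!ok) unlink(dir, recursive = TRUE), add = TRUE)
    write_records(rbind(csd$records, rsd$records),
                  file.path(dir, "records.csv"))
    utils::write.csv(as.data.frame(csd$pattern),
                     file.path(dir, "csd_pattern.csv"),
                     row.names = FALSE, quote = FALSE)
    for (v in c("W", "V", "F")) {
      write_ascii_grid(covars, v, file.path(dir, paste0(v, ".asc")))
    }
    truth <- list(
      seed = seed,
      home = config$home,
      lgcp = config$lgcp,
      csd = config$csd[c("beta", "gamma", "spline_coefs", "sigma2", "phi",
                         "tau2", "period", "collector_probs")],
      rsd = config$rsd[c("beta", "beta5", "sigma2", "phi", "tau2", "period",
                         "spacing", "forest_threshold")]
    )
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(unclass(config), file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         matrix = "columnmajor")
    ok <- TRUE
    bundle$dir <- dir
  }
  bundle
}
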