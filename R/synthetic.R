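#' Configuration for the synthetic panel generator
#'
#' The generator emulates the statistical structure the analysis assumes: a
#' complete regions x years x indicators panel of nonnegative levels with
#' region scale effects, smooth temporal growth, multiplicative noise, and a
#' tunable latent correlation between a region's supply capacity and its
#' demand pressure. Defaults mirror the study conditions: 31 regions
#' observed 2010-2019 on the 14-indicator elderly-care index system.
#'
#' @param m_regions Number of regions (>= 4). Default 31.
#' @param years Integer vector of consecutive calendar years (>= 4).
#'   Default 2010:2019.
#' @param seed Integer RNG seed; the generator is deterministic given it.
#' @param region_scale_sd Log-scale standard deviation of the latent region
#'   size factors (default 0.6: large provinces roughly 3-10x small ones,
#'   as in province-level counts of people, beds and spending).
#' @param trend_rate Mean multiplicative growth per year (default 0.08,
#'   the order of magnitude of 2010s elderly-care capacity growth).
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   noise (> 0; default 0.1).
#' @param coupling_rho Correlation in \[-1, 1\] between latent supply
#'   capacity u and demand pressure v (default 0.6: supply broadly follows
#'   demand but imperfectly).
#' @param n_negative_indicators Number of demand-side indicators flagged
#'   negative orientation (default 0; the 14-indicator system is all
#'   positive).
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(m_regions = 31, years = 2010:2019, seed = 1L,
                             region_scale_sd = 0.6, trend_rate = 0.08,
                             noise_cv = 0.1, coupling_rho = 0.6,
                             n_negative_indicators = 0L) {
  stopifnot(is.numeric(m_regions), length(m_regions) == 1L)
  if (m_regions < 4) stop("m_regions must be at least 4")
  years <- as.integer(years)
  if (length(years) < 4) stop("at least 4 years are required")
  if (!is.numeric(noise_cv) || noise_cv <= 0) stop("noise_cv must be > 0")
  if (abs(coupling_rho) > 1) stop("coupling_rho must lie in [-1, 1]")
  if (region_scale_sd <= 0) stop("region_scale_sd must be > 0")
  if (n_negative_indicators < 0 || n_negative_indicators > 4)
    stop("n_negative_indicators must be between 0 and 4")
  structure(list(m_regions = as.integer(m_regions), years = years,
                 seed = as.integer(seed),
                 region_scale_sd = region_scale_sd, trend_rate = trend_rate,
                 noise_cv = noise_cv, coupling_rho = coupling_rho,
                 n_negative_indicators = as.integer(n_negative_indicators)),
            class = "synthetic_config")
}

# typical province-level magnitudes per indicator, in the units of the
# 14-indicator system; these set the scale, not the statistics
.indicator_base_levels <- function() {
  c(X1 = 2e4, X2 = 1.5e4, X3 = 1.5e3, X4 = 1.5e5, X5 = 5e6, X6 = 3e3,
    X7 = 2e4, X8 = 5e5, X9 = 2e3, X10 = 1e3,
    Y1 = 5e6, Y2 = 14, Y3 = 2.5e4, Y4 = 1e5)
}

#' Generate a synthetic indicator panel with known ground truth
#'
#' Multiplicative lognormal model. Region p carries latent supply capacity
#' u_p and demand pressure v_p, bivariate normal with standard deviation
#' `region_scale_sd` and correlation `coupling_rho`. The level of indicator
#' j in region p at year t is
#' \deqn{base_j \cdot \exp(loading_j \cdot u_p) \cdot
#'       (1 + trend)^{t - t_0} \cdot \epsilon_{pjt},}
#' with v_p in place of u_p for demand indicators and lognormal noise
#' epsilon of unit mean and coefficient of variation `noise_cv`. All values
#' are strictly positive and the draw is deterministic given the seed.
#'
#' @param config A [synthetic_config()].
#' @param loadings Optional named numeric vector of per-indicator loadings
#'   overriding the defaults (drawn once, uniform on \[0.5, 1.5\]); useful
#'   for constructing a dominant-variance indicator.
#' @return List with `panel` (an `indicator_panel`) and `truth` (list with
#'   `u`, `v`, `loadings`, `base_levels`, `config`).
#' @examples
#' sim <- generate_panel(synthetic_config(m_regions = 6, years = 2010:2014,
#'                                        seed = 42))
#' sim$panel
#' cor(sim$truth$u, sim$truth$v)
#' @export
generate_panel <- function(config, loadings = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  spec <- elderly_care_indicators()
  if (config$n_negative_indicators > 0) {
    dem <- which(spec$subsystem == "demand")
    flip <- utils::tail(dem, config$n_negative_indicators)
    spec$orientation[flip] <- "negative"
  }
  m <- config$m_regions
  regions <- sprintf("R%02d", seq_len(m))
  years <- config$years
  base <- .indicator_base_levels()

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  # latent bivariate-normal (u, v), corr coupling_rho, sd region_scale_sd
  z1 <- stats::rnorm(m)
  z2 <- stats::rnorm(m)
  rho <- config$coupling_rho
  u <- config$region_scale_sd * z1
  v <- config$region_scale_sd * (rho * z1 + sqrt(1 - rho^2) * z2)

  if (is.null(loadings)) {
    loadings <- stats::setNames(stats::runif(nrow(spec), 0.5, 1.5), spec$id)
  } else {
    stopifnot(all(spec$id %in% names(loadings)))
    loadings <- loadings[spec$id]
  }

  sigma <- sqrt(log(1 + config$noise_cv^2))  # lognormal, unit mean
  t0 <- years[1L]
  grid <- expand.grid(region = regions, year = years, indicator = spec$id,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  latent <- ifelse(spec$subsystem[match(grid$indicator, spec$id)] == "supply",
                   u[match(grid$region, regions)],
                   v[match(grid$region, regions)])
  lj <- loadings[grid$indicator]
  bj <- base[grid$indicator]
  eps <- exp(stats::rnorm(nrow(grid), -sigma^2 / 2, sigma))
  grid$value <- bj * exp(lj * latent) *
    (1 + config$trend_rate)^(grid$year - t0) * eps

  panel <- as_indicator_panel(grid, spec = spec)
  truth <- list(u = stats::setNames(u, regions),
                v = stats::setNames(v, regions),
                loadings = loadings, base_levels = base, config = config)
  list(panel = panel, truth = truth)
}

#' Generate a simple adjacency structure
#'
#' @param m_regions Number of regions: >= 3 for a ring, a perfect square for
#'   a grid.
#' @param topology `"ring"` (each region has exactly two neighbours) or
#'   `"grid"` (rook contiguity on a sqrt(m) x sqrt(m) lattice).
#' @return An `adjacency_map` over regions `R01 ... Rmm`.
#' @examples
#' adjacency_degrees(generate_adjacency(9, "grid"))
#' @export
generate_adjacency <- function(m_regions, topology = c("ring", "grid")) {
  topology <- match.arg(topology)
  m <- as.integer(m_regions)
  regions <- sprintf("R%02d", seq_len(m))
  if (topology == "ring") {
    if (m < 3) stop("a ring needs at least 3 regions")
    from <- regions
    to <- regions[c(2:m, 1L)]
  } else {
    k <- as.integer(round(sqrt(m)))
    if (k * k != m) stop("grid topology needs a perfect-square m_regions")
    idx <- function(r, c) (r - 1L) * k + c
    from <- character(0); to <- character(0)
    for (r in seq_len(k)) for (c in seq_len(k)) {
      if (c < k) { from <- c(from, regions[idx(r, c)])
                   to <- c(to, regions[idx(r, c + 1L)]) }
      if (r < k) { from <- c(from, regions[idx(r, c)])
                   to <- c(to, regions[idx(r + 1L, c)]) }
    }
  }
  adjacency_map(from, to, regions = regions)
}

# save/restore the global RNG state so generators do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
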