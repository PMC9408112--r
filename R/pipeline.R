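#' Published coupling-coordination reference tables
#'
#' The package ships, as plain-text fixtures, the published region x year
#' coupling coordination degrees for the 31 mainland Chinese regions: the
#' 2010-2019 table computed from observed yearbook data and the 2020-2024
#' table computed from forecast data. The underlying raw indicator panel was
#' never published, so these tables are reference output, not reproducible
#' input; the package uses them for arithmetic cross-checks (row means,
#' classification) and as a mappable series for spatial analysis.
#'
#' @param period `"2010_2019"` (observed-data table) or `"2020_2024"`
#'   (forecast-data table).
#' @return Data frame: `region`, one column per year, and the published
#'   `Average` column.
#' @export
reference_coupling_table <- function(period = c("2010_2019", "2020_2024")) {
  period <- match.arg(period)
  path <- system.file("extdata",
                      sprintf("coupling_reference_%s.csv", period),
                      package = "couplecoord", mustWork = TRUE)
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Published indicator-weight spot values
#'
#' The weight trajectory of the building-area indicator X5 is the one
#' supply-side weight pair quoted numerically in the source analysis:
#' 0.1302 in 2010 falling to 0.0946 in 2014.
#'
#' @return Named numeric vector with elements `w_2010` and `w_2014`.
#' @export
reference_x5_weights <- function() {
  c(w_2010 = 0.1302, w_2014 = 0.0946)
}

#' Arithmetic cross-checks against the published tables
#'
#' Recomputes, from the printed yearly cells of the reference tables: every
#' region's period-mean coordination degree (compared at 4 decimals to the
#' published Average column), the classification label of every published
#' row average, and the relative decline of the X5 weight between 2010 and
#' 2014 (compared to 27.3% at one decimal). These are checks of the
#' package's arithmetic against the published arithmetic; they do not touch
#' the unpublished raw panel.
#'
#' @return Data frame with columns `check`, `expected`, `computed`, `pass`.
#' @export
fixture_check <- function() {
  rows <- list()
  for (period in c("2010_2019", "2020_2024")) {
    tab <- reference_coupling_table(period)
    ycols <- setdiff(names(tab), c("region", "Average"))
    for (i in seq_len(nrow(tab))) {
      m <- period_mean(as.numeric(tab[i, ycols]), digits = 4)
      rows[[length(rows) + 1L]] <- data.frame(
        check = sprintf("row_mean_%s_%s", period, tab$region[i]),
        expected = tab$Average[i], computed = m,
        pass = abs(m - tab$Average[i]) < 5e-5,
        stringsAsFactors = FALSE)
    }
  }
  # classification of the published period means for the regions whose
  # balance level the source analysis states in words
  named_levels <- c(Jiangsu = "Good balance", Shandong = "Good balance",
                    Sichuan = "Moderate balance", Zhejiang = "Moderate balance",
                    Beijing = "Primary balance", Tibet = "Serious imbalance")
  tab4 <- reference_coupling_table("2010_2019")
  for (rg in names(named_levels)) {
    lab <- classify_coordination(tab4$Average[tab4$region == rg])$level
    rows[[length(rows) + 1L]] <- data.frame(
      check = sprintf("classification_2010_2019_%s", rg),
      expected = NA_real_, computed = NA_real_,
      pass = identical(lab, named_levels[[rg]]), stringsAsFactors = FALSE)
  }
  x5 <- reference_x5_weights()
  decline <- round_half_up(
    100 * (x5[["w_2010"]] - x5[["w_2014"]]) / x5[["w_2010"]], 1)
  rows[[length(rows) + 1L]] <- data.frame(
    check = "x5_weight_decline_pct", expected = 27.3, computed = decline,
    pass = decline == 27.3, stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pipeline run configuration
#'
#' Bundles every tunable of the end-to-end analysis; the defaults are the
#' method-faithful settings (alpha = 0.4, beta = 0.6, plain-product
#' coordination, per-year standardization, binary contiguity weights).
#'
#' @param alpha,beta Subsystem importance weights, summing to 1.
#' @param sqrt_variant Square-root coordination form (default `FALSE`).
#' @param scope Standardization scope, `"per_year"` or `"pooled"`.
#' @param weights_scheme Spatial weight scheme, `"binary"` or
#'   `"row_standardized"`.
#' @param forecast A [forecast_config()].
#' @param n_perm Permutations for the yearly Moran tests (0 to skip).
#' @param seed Master seed for every stochastic stage.
#' @param digits Display rounding for written report tables (default 4).
#' @return A `run_config` list.
#' @export
run_config <- function(alpha = 0.4, beta = 0.6, sqrt_variant = FALSE,
                       scope = c("per_year", "pooled"),
                       weights_scheme = c("binary", "row_standardized"),
                       forecast = forecast_config(), n_perm = 999L,
                       seed = 1L, digits = 4L) {
  scope <- match.arg(scope)
  weights_scheme <- match.arg(weights_scheme)
  if (abs(alpha + beta - 1) > 1e-12 || alpha < 0 || beta < 0)
    stop("alpha and beta must be nonnegative and sum to 1")
  structure(list(alpha = alpha, beta = beta, sqrt_variant = sqrt_variant,
                 scope = scope, weights_scheme = weights_scheme,
                 forecast = forecast, n_perm = as.integer(n_perm),
                 seed = as.integer(seed), digits = as.integer(digits)),
            class = "run_config")
}

#' Run the end-to-end coupling-coordination analysis
#'
#' Standardize -> entropy weights -> composite scores -> coupling /
#' coordination with classification -> yearly global Moran's I -> forecast
#' the panel `horizon` years ahead -> re-run coupling and Moran's I on the
#' forecast panel. Deterministic given the configuration seed.
#'
#' @param panel A complete `indicator_panel`.
#' @param adjacency An `adjacency_map` covering the panel regions, or
#'   `NULL` to skip the spatial stage.
#' @param config A [run_config()].
#' @param output_dir Directory for CSV artifacts and the run manifest, or
#'   `NULL` (default) for in-memory results only.
#' @return List with `weights` (per year/subsystem table), `coupling`,
#'   `coordination_matrix`, `moran`, `forecast_panel`,
#'   `forecast_coupling`, `forecast_moran`, and (when writing) `manifest`.
#' @export
run_pipeline <- function(panel, adjacency = NULL, config = run_config(),
                         output_dir = NULL) {
  stopifnot(inherits(panel, "indicator_panel"), inherits(config, "run_config"))

  wt <- rbind(weight_table(panel, "supply", config$scope),
              weight_table(panel, "demand", config$scope))
  cp <- couple_panel(panel, config$alpha, config$beta, config$sqrt_variant,
                     config$scope)
  cm <- coordination_matrix(cp)

  sw <- NULL; mo <- NULL
  if (!is.null(adjacency)) {
    sw <- build_weights(adjacency, config$weights_scheme)
    mo <- moran_by_year(cp, sw, n_perm = config$n_perm, seed = config$seed)
  }

  fcfg <- config$forecast
  fcfg$seed <- config$seed
  fp <- forecast_panel(panel, fcfg)
  fcp <- couple_panel(fp, config$alpha, config$beta, config$sqrt_variant,
                      config$scope)
  fmo <- if (!is.null(sw))
    moran_by_year(fcp, sw, n_perm = config$n_perm, seed = config$seed)
  else NULL

  out <- list(weights = wt, coupling = cp, coordination_matrix = cm,
              moran = mo, forecast_panel = fp, forecast_coupling = fcp,
              forecast_moran = fmo, config = config)

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    files <- c(weights = "weights.csv", coupling = "coupling.csv",
               coordination_matrix = "coordination_matrix.csv",
               moran = "moran.csv", forecast_panel = "forecast_panel.csv",
               forecast_coupling = "forecast_coupling.csv",
               forecast_moran = "forecast_moran.csv")
    written <- character(0)
    for (nm in names(files)) {
      obj <- out[[nm]]
      if (is.null(obj)) next
      path <- file.path(output_dir, files[[nm]])
      digits <- if (nm %in% c("coordination_matrix")) config$digits else NULL
      if (nm == "forecast_panel") {
        df <- as.data.frame(obj)
        df$source <- "forecast"
        write_results(df, path)
      } else {
        write_results(as.data.frame(obj), path, digits = digits)
      }
      written <- c(written, path)
    }
    manifest <- data.frame(file = basename(written),
                           md5 = unname(tools::md5sum(written)),
                           stringsAsFactors = FALSE)
    cfgflat <- utils::capture.output(utils::str(config))
    manifest_path <- file.path(output_dir, "manifest.csv")
    write_results(manifest, manifest_path)
    writeLines(c(sprintf("seed: %d", config$seed), cfgflat),
               file.path(output_dir, "config.txt"))
    out$manifest <- manifest
  }
  out
}
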