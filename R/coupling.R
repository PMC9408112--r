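#' Comprehensive evaluation score of one subsystem
#'
#' Linear weighting of a region's standardized indicator row:
#' T = sum_j W_j Z'_j, which lies in \[0, 1\] because the weights sum to 1
#' and every Z' is in \[0, 1\].
#'
#' @param std A `standardized_matrix`.
#' @param w A `weight_vector` for the same year and subsystem.
#' @param region Region name, or `NULL` (default) for all regions.
#' @return Named numeric vector of scores (length 1 if `region` given).
#' @export
composite_score <- function(std, w, region = NULL) {
  stopifnot(inherits(std, "standardized_matrix"), inherits(w, "weight_vector"))
  if (std$year != w$year || std$subsystem != w$subsystem)
    stop(sprintf("year/subsystem mismatch: matrix is %s/%d, weights are %s/%d",
                 std$subsystem, std$year, w$subsystem, w$year))
  if (!identical(colnames(std$matrix), names(w$weights)))
    stop("indicator sets differ between matrix and weights")
  scores <- drop(std$matrix %*% w$weights)
  if (!is.null(region)) {
    if (!region %in% names(scores)) stop("unknown region: ", region)
    scores <- scores[region]
  }
  scores
}

#' Coupling degree of two subsystem scores
#'
#' C = 2 sqrt(T1 T2) / (T1 + T2): a symmetric balance measure in \[0, 1\],
#' equal to 1 exactly when the two scores coincide and 0 when either is 0.
#' Defined as 0 when both scores are 0.
#'
#' @param t1,t2 Subsystem scores in \[0, 1\] (vectorized).
#' @return Coupling degree in \[0, 1\].
#' @examples
#' coupling_degree(0.5, 0.5)  # 1
#' coupling_degree(0.9, 0.1)  # 0.6
#' @export
coupling_degree <- function(t1, t2) {
  if (any(t1 < 0) || any(t2 < 0)) stop("subsystem scores must be nonnegative")
  if (any(t1 > 1 + 1e-9) || any(t2 > 1 + 1e-9))
    stop("subsystem scores must lie in [0, 1]")
  # clamp floating-point overshoot from weight-dot-products
  t1 <- pmin(t1, 1); t2 <- pmin(t2, 1)
  s <- t1 + t2
  out <- ifelse(s > 0, 2 * sqrt(t1 * t2) / ifelse(s > 0, s, 1), 0)
  pmin(out, 1)
}

#' Coupling coordination degree
#'
#' D = C(T1, T2) * (alpha T1 + beta T2): the coupling degree weighted by the
#' combined development level of the two subsystems, so that two equally
#' undeveloped systems do not score as "coordinated". With alpha + beta = 1
#' and scores in \[0, 1\], D lies in \[0, 1\]. The default weighting
#' alpha = 0.4 (supply) / beta = 0.6 (demand) treats demand pressure as the
#' slightly more load-bearing side.
#'
#' Some of the coupling-coordination literature instead uses
#' D = sqrt(C * (alpha T1 + beta T2)); `sqrt_variant = TRUE` selects that
#' form for sensitivity analysis. The default is the plain product.
#'
#' @inheritParams coupling_degree
#' @param alpha,beta Nonnegative subsystem importance weights summing to 1.
#' @param sqrt_variant Use the square-root form (default `FALSE`).
#' @return Coordination degree in \[0, 1\].
#' @examples
#' coordination_degree(0.64, 0.64)      # 0.64
#' coordination_degree(0.9, 0.1)        # 0.252
#' @export
coordination_degree <- function(t1, t2, alpha = 0.4, beta = 0.6,
                                sqrt_variant = FALSE) {
  if (abs(alpha + beta - 1) > 1e-12 || alpha < 0 || beta < 0)
    stop("alpha and beta must be nonnegative and sum to 1")
  cc <- coupling_degree(t1, t2)
  t <- alpha * t1 + beta * t2
  if (sqrt_variant) sqrt(cc * t) else cc * t
}

#' The ten-level coordination classification
#'
#' @return Data frame with columns `lower`, `upper`, `level`, `category`:
#'   ten bins of width 0.1, half-open \[a, a + 0.1) with the top bin closed
#'   at 1. Category thresholds: poor below 0.4, medium in \[0.4, 0.6),
#'   excellent at and above 0.6.
#' @export
coordination_levels <- function() {
  data.frame(
    lower = (0:9) / 10,
    upper = (1:10) / 10,
    level = c("Extreme imbalance", "Serious imbalance", "Moderate imbalance",
              "Mild imbalance", "Close to imbalance", "Barely balance",
              "Primary balance", "Moderate balance", "Good balance",
              "Excellent balance"),
    category = rep(c("poor", "medium", "excellent"), times = c(4, 2, 4)),
    stringsAsFactors = FALSE
  )
}

#' Classify coordination degrees
#'
#' @param d Numeric vector of coordination degrees in \[0, 1\].
#' @return Data frame with columns `D`, `level`, `category`.
#' @examples
#' classify_coordination(c(0.8632, 0.1216, 0.4))
#' @export
classify_coordination <- function(d) {
  if (any(!is.finite(d)) || any(d < 0) || any(d > 1))
    stop("coordination degree must lie in [0, 1]")
  lv <- coordination_levels()
  idx <- pmin(findInterval(d, lv$lower), nrow(lv))  # top bin closed at 1
  data.frame(D = d, level = lv$level[idx], category = lv$category[idx],
             stringsAsFactors = FALSE)
}

#' Decimal rounding, halves away from zero
#'
#' Reporting rounding matching published tables, which round decimal halves
#' up (0.42795 -> 0.4280), unlike base [round()]'s round-half-even. A tiny
#' tolerance absorbs binary representation error in values that are exact
#' decimal halves.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return `x` rounded to `digits` places, halves away from zero.
#' @export
round_half_up <- function(x, digits = 4L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Mean coordination degree over a period
#'
#' @param d Nonempty numeric vector of yearly coordination degrees for one
#'   region.
#' @param digits Decimal places for reporting (halves rounded up, as in the
#'   published tables); `NULL` for full precision.
#' @return The arithmetic mean, rounded if `digits` is given.
#' @export
period_mean <- function(d, digits = NULL) {
  if (length(d) == 0L) stop("empty coordination series")
  m <- mean(d)
  if (!is.null(digits)) m <- round_half_up(m, digits)
  m
}

#' Coupling coordination analysis of a full panel
#'
#' Runs, for every year of the panel: per-year min-max standardization of
#' both subsystems, entropy weighting, linear-weighted composite scores, and
#' the coupling / coordination degrees with classification.
#'
#' @inheritParams standardize_year
#' @param alpha,beta Subsystem importance weights (see
#'   [coordination_degree()]).
#' @param sqrt_variant Use the square-root coordination form.
#' @return A `coupling_result`: data frame with one row per region-year and
#'   columns `region`, `year`, `T_supply`, `T_demand`, `C`, `D`, `level`,
#'   `category`.
#' @examples
#' p <- generate_panel(synthetic_config(m_regions = 6, years = 2010:2013))$panel
#' head(couple_panel(p))
#' @export
couple_panel <- function(panel, alpha = 0.4, beta = 0.6,
                         sqrt_variant = FALSE,
                         scope = c("per_year", "pooled")) {
  scope <- match.arg(scope)
  years <- attr(panel, "years")
  rows <- lapply(years, function(y) {
    ss <- standardize_year(panel, y, "supply", scope)
    sd <- standardize_year(panel, y, "demand", scope)
    t1 <- composite_score(ss, compute_weights(ss))
    t2 <- composite_score(sd, compute_weights(sd))
    cc <- coupling_degree(t1, t2)
    dd <- coordination_degree(t1, t2, alpha, beta, sqrt_variant)
    cls <- classify_coordination(dd)
    data.frame(region = names(t1), year = y,
               T_supply = unname(t1), T_demand = unname(t2),
               C = unname(cc), D = unname(dd),
               level = cls$level, category = cls$category,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$region, out$year), ]
  rownames(out) <- NULL
  class(out) <- c("coupling_result", "data.frame")
  out
}

#' Wide region x year matrix of coordination degrees
#'
#' @param results A `coupling_result` from [couple_panel()].
#' @param value Column to spread, default `"D"`.
#' @return Data frame: one row per region, one column per year, plus an
#'   `Average` column (the period mean).
#' @export
coordination_matrix <- function(results, value = "D") {
  stopifnot(value %in% names(results))
  regions <- unique(results$region)
  years <- sort(unique(results$year))
  m <- matrix(NA_real_, length(regions), length(years),
              dimnames = list(regions, years))
  m[cbind(match(results$region, regions), match(results$year, years))] <-
    results[[value]]
  out <- data.frame(region = regions, m, Average = rowMeans(m),
                    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
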