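#' Entropy weights for a standardized indicator matrix
#'
#' Objective indicator weighting: each indicator's weight is proportional to
#' one minus the Shannon entropy of its cross-region proportion
#' distribution, so indicators that discriminate more between regions weigh
#' more. For indicator j over the n regions p:
#' \deqn{S_{pj} = Z'_{pj} / \sum_p Z'_{pj}, \quad
#'       K_j = -\frac{1}{\ln n} \sum_p S_{pj} \ln S_{pj}, \quad
#'       D_j = 1 - K_j, \quad W_j = D_j / \sum_j D_j,}
#' with the continuity convention 0 ln 0 = 0 (exact zeros always occur after
#' min-max standardization). A degenerate indicator (all entries 0.5) has
#' equal proportions, hence entropy exactly 1 and weight exactly 0.
#'
#' @param std A `standardized_matrix` from [standardize_year()].
#' @return A `weight_vector`: list with `year`, `subsystem`, `weights`
#'   (named, summing to 1), `entropy` (K_j), `difference_coefficient`
#'   (D_j = 1 - K_j; distinct from the coupling coordination degree D), and
#'   `proportions` (the S matrix, regions x indicators).
#' @examples
#' p <- generate_panel(synthetic_config(m_regions = 6, years = 2010:2013))$panel
#' w <- compute_weights(standardize_year(p, 2011, "demand"))
#' sum(w$weights)
#' @export
compute_weights <- function(std) {
  stopifnot(inherits(std, "standardized_matrix"))
  z <- std$matrix
  n <- nrow(z)
  if (n < 2L) stop("entropy weighting needs at least 2 regions")
  csum <- colSums(z)
  # a zero column is impossible: degenerate columns are all 0.5, others
  # contain an exact 1 by construction
  stopifnot(all(csum > 0))
  s <- sweep(z, 2L, csum, "/")
  plogp <- s * log(s)
  plogp[s == 0] <- 0
  k <- -colSums(plogp) / log(n)
  # guard tiny negative drift
  k <- pmin(pmax(k, 0), 1)
  # equal proportions (degenerate 0.5-columns) have entropy exactly 1;
  # snap past the last floating-point ulp of log()
  flat <- apply(z, 2L, function(col) diff(range(col)) == 0)
  k[flat] <- 1
  d <- 1 - k
  if (sum(d) == 0)
    stop("no discriminating indicator: all indicators are degenerate")
  w <- d / sum(d)
  structure(list(year = std$year, subsystem = std$subsystem,
                 weights = w, entropy = k, difference_coefficient = d,
                 proportions = s),
            class = "weight_vector")
}

#' @export
print.weight_vector <- function(x, ...) {
  cat(sprintf("entropy weights, %s subsystem, year %d:\n",
              x$subsystem, x$year))
  print(round(x$weights, 4), ...)
  invisible(x)
}

#' Weight table across years
#'
#' Convenience wrapper: standardizes and entropy-weights every year of a
#' panel for one subsystem and stacks the results.
#'
#' @inheritParams standardize_year
#' @return Data frame with columns `year`, `subsystem`, `indicator`,
#'   `weight`, `entropy`, `difference_coefficient`.
#' @export
weight_table <- function(panel, subsystem = c("supply", "demand"),
                         scope = c("per_year", "pooled")) {
  subsystem <- match.arg(subsystem)
  scope <- match.arg(scope)
  rows <- lapply(attr(panel, "years"), function(y) {
    w <- compute_weights(standardize_year(panel, y, subsystem, scope))
    data.frame(year = y, subsystem = subsystem,
               indicator = names(w$weights), weight = unname(w$weights),
               entropy = unname(w$entropy),
               difference_coefficient = unname(w$difference_coefficient),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
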