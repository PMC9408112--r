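#' Min-max standardization of one year/subsystem slice
#'
#' Rescales each indicator to \[0, 1\] across regions within one year.
#' Positive-orientation indicators use (z - min) / (max - min); negative
#' orientation uses (max - z) / (max - min), so that after standardization
#' larger is always "more" of what the subsystem measures. An indicator
#' whose cross-region range is zero carries no ordering information: every
#' entry is set to 0.5 and the id is recorded, which drives its entropy
#' weight to exactly zero downstream.
#'
#' @param panel An `indicator_panel`, complete for the requested year.
#' @param year Calendar year to standardize.
#' @param subsystem `"supply"` or `"demand"`.
#' @param scope `"per_year"` (default): min/max taken across regions within
#'   the requested year, which is what per-year entropy weighting requires.
#'   `"pooled"`: min/max taken across all region-years of the panel, for
#'   sensitivity analysis.
#' @return A `standardized_matrix`: list with `year`, `subsystem`,
#'   `matrix` (regions x indicators, entries in \[0, 1\]),
#'   `degenerate_indicators` (ids with zero range), and `scope`.
#' @examples
#' p <- generate_panel(synthetic_config(m_regions = 5, years = 2010:2013))$panel
#' s <- standardize_year(p, 2010, "supply")
#' range(s$matrix)
#' @export
standardize_year <- function(panel, year, subsystem = c("supply", "demand"),
                             scope = c("per_year", "pooled")) {
  subsystem <- match.arg(subsystem)
  scope <- match.arg(scope)
  z <- panel_matrix(panel, year, subsystem)
  if (nrow(z) < 2L)
    stop("standardization needs at least 2 regions, got ", nrow(z))

  if (scope == "per_year") {
    lo <- apply(z, 2L, min)
    hi <- apply(z, 2L, max)
  } else {
    all_years <- attr(panel, "years")
    stacked <- do.call(rbind, lapply(all_years, panel_matrix,
                                     panel = panel, subsystem = subsystem))
    lo <- apply(stacked, 2L, min)
    hi <- apply(stacked, 2L, max)
  }

  rng <- hi - lo
  degen <- colnames(z)[rng == 0]
  out <- z
  for (j in seq_len(ncol(z))) {
    if (rng[j] == 0) {
      out[, j] <- 0.5
    } else {
      out[, j] <- (z[, j] - lo[j]) / rng[j]
    }
  }

  spec <- attr(panel, "spec")
  neg <- spec$id[spec$orientation == "negative"]
  flip <- colnames(out) %in% neg & !(colnames(out) %in% degen)
  out[, flip] <- 1 - out[, flip]
  # clamp pooled-scope values that still lie inside [0,1] numerically
  out[out < 0] <- 0
  out[out > 1] <- 1

  structure(list(year = as.integer(year), subsystem = subsystem,
                 matrix = out, degenerate_indicators = degen, scope = scope),
            class = "standardized_matrix")
}

#' @export
print.standardized_matrix <- function(x, ...) {
  cat(sprintf("standardized %s matrix, year %d: %d regions x %d indicators",
              x$subsystem, x$year, nrow(x$matrix), ncol(x$matrix)))
  if (length(x$degenerate_indicators))
    cat(" (degenerate: ", paste(x$degenerate_indicators, collapse = ", "),
        ")", sep = "")
  cat("\n")
  invisible(x)
}
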