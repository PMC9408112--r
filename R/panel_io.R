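#' Construct and validate an indicator panel
#'
#' An indicator panel holds the observed level of every indicator for every
#' region and year, in long format. The analysis assumes a complete panel:
#' every (region, year, indicator) cell present, values finite and
#' nonnegative.
#'
#' @param df Data frame with columns `region`, `year`, `indicator`, `value`.
#' @param spec Indicator specification table (see [indicator_spec()]);
#'   defaults to the 14-indicator elderly-care system.
#' @param complete If `TRUE` (default), error when any cell of the
#'   region x year x indicator grid is missing.
#' @return An `indicator_panel`: the long data frame, sorted by
#'   (region, year, indicator), with the specification attached as the
#'   `"spec"` attribute and `regions` / `years` attributes giving the sorted
#'   axes.
#' @export
as_indicator_panel <- function(df, spec = elderly_care_indicators(),
                               complete = TRUE) {
  need <- c("region", "year", "indicator", "value")
  if (!all(need %in% names(df)))
    stop("panel must have columns: ", paste(need, collapse = ", "))
  df <- df[need]
  df$region <- as.character(df$region)
  df$indicator <- as.character(df$indicator)
  if (!is.numeric(df$year) || any(df$year != round(df$year)))
    stop("year must be integer-valued")
  df$year <- as.integer(df$year)

  unknown <- setdiff(unique(df$indicator), spec$id)
  if (length(unknown))
    stop("unknown indicator id(s): ", paste(unknown, collapse = ", "))
  if (!is.numeric(df$value) || anyNA(df$value) || any(!is.finite(df$value)))
    stop("panel values must be finite numbers")
  if (any(df$value < 0)) {
    bad <- which(df$value < 0)[1L]
    stop(sprintf("negative value %g at row %d (%s, %d, %s)", df$value[bad],
                 bad, df$region[bad], df$year[bad], df$indicator[bad]))
  }

  key <- paste(df$region, df$year, df$indicator, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (region, year, indicator) key(s): ",
         paste(utils::head(gsub("\r", "/", key[duplicated(key)]), 5),
               collapse = ", "))

  regions <- sort(unique(df$region))
  years <- sort(unique(df$year))
  inds <- spec$id[spec$id %in% df$indicator]
  if (complete) {
    grid <- expand.grid(region = regions, year = years, indicator = inds,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    gkey <- paste(grid$region, grid$year, grid$indicator, sep = "\r")
    miss <- setdiff(gkey, key)
    if (length(miss))
      stop("incomplete panel; missing (region, year, indicator): ",
           paste(utils::head(gsub("\r", "/", miss), 10), collapse = ", "),
           if (length(miss) > 10) sprintf(" ... and %d more", length(miss) - 10))
  }

  df <- df[order(df$region, df$year, match(df$indicator, spec$id)), ]
  rownames(df) <- NULL
  structure(df, spec = spec[spec$id %in% inds, , drop = FALSE],
            regions = regions, years = years,
            class = c("indicator_panel", "data.frame"))
}

#' Read an indicator panel from CSV
#'
#' Expects long-format delimited text with header
#' `region,year,indicator,value`, UTF-8, "." decimal separator.
#'
#' @inheritParams as_indicator_panel
#' @param path Path to the CSV file.
#' @return An `indicator_panel`.
#' @export
read_panel <- function(path, spec = elderly_care_indicators(),
                       complete = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(value = "character"))
  val <- suppressWarnings(as.numeric(df$value))
  if (anyNA(val)) {
    bad <- which(is.na(val))[1L]
    stop(sprintf("non-numeric value '%s' at data row %d of %s",
                 df$value[bad], bad, path))
  }
  if (any(val < 0)) {
    bad <- which(val < 0)[1L]
    stop(sprintf("negative value %s at data row %d of %s",
                 df$value[bad], bad, path))
  }
  df$value <- val
  as_indicator_panel(df, spec = spec, complete = complete)
}

#' @export
print.indicator_panel <- function(x, ...) {
  spec <- attr(x, "spec")
  cat(sprintf("indicator panel: %d regions x %d years x %d indicators (%d supply, %d demand)\n",
              length(attr(x, "regions")), length(attr(x, "years")),
              nrow(spec), sum(spec$subsystem == "supply"),
              sum(spec$subsystem == "demand")))
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6L) cat(sprintf("... %d rows total\n", nrow(x)))
  invisible(x)
}

#' Extract one year/subsystem slice of a panel as a region x indicator matrix
#'
#' @param panel An `indicator_panel`.
#' @param year Calendar year present in the panel.
#' @param subsystem `"supply"` or `"demand"`.
#' @return Numeric matrix, rows = regions (sorted), cols = indicators in
#'   specification order.
#' @export
panel_matrix <- function(panel, year, subsystem = c("supply", "demand")) {
  subsystem <- match.arg(subsystem)
  stopifnot(inherits(panel, "indicator_panel"))
  if (!year %in% attr(panel, "years"))
    stop("year ", year, " not present in panel")
  spec <- attr(panel, "spec")
  inds <- spec$id[spec$subsystem == subsystem]
  if (!length(inds)) stop("panel has no ", subsystem, " indicators")
  sub <- panel[panel$year == year & panel$indicator %in% inds, ]
  regions <- attr(panel, "regions")
  m <- matrix(NA_real_, length(regions), length(inds),
              dimnames = list(regions, inds))
  m[cbind(match(sub$region, regions), match(sub$indicator, inds))] <- sub$value
  if (anyNA(m)) stop("panel slice incomplete for year ", year)
  m
}

#' Read a region adjacency list
#'
#' Header-less two-column text, one neighbour pair per line, whitespace- or
#' comma-delimited. Pairs are unordered: duplicates and reversed duplicates
#' collapse to a single edge.
#'
#' @param path Path to the adjacency file.
#' @param regions Optional character vector of known region names; any edge
#'   naming a region outside it is an error, and the returned map covers all
#'   of `regions` (possibly leaving some isolated).
#' @return An `adjacency_map`: list with `regions` (character) and `edges`
#'   (two-column character matrix, one unordered pair per row,
#'   lexicographically ordered within row).
#' @export
read_adjacency <- function(path, regions = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  # comma-delimited lines may contain region names with internal spaces;
  # whitespace-delimited lines may not
  parts <- lapply(lines, function(l) {
    if (grepl(",", l, fixed = TRUE)) trimws(strsplit(l, ",")[[1L]])
    else strsplit(l, "[[:space:]]+")[[1L]]
  })
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop("malformed adjacency line ", bad[1L], ": '", lines[bad[1L]], "'")
  a <- vapply(parts, `[`, "", 1L)
  b <- vapply(parts, `[`, "", 2L)
  adjacency_map(a, b, regions = regions)
}

#' Build an adjacency map from neighbour pairs
#'
#' @param from,to Character vectors of equal length naming the two ends of
#'   each neighbour pair.
#' @inheritParams read_adjacency
#' @return An `adjacency_map`.
#' @export
adjacency_map <- function(from, to, regions = NULL) {
  stopifnot(length(from) == length(to))
  from <- as.character(from); to <- as.character(to)
  loops <- from == to
  if (any(loops))
    stop("self-loop edge(s): ", paste(unique(from[loops]), collapse = ", "))
  if (!is.null(regions)) {
    unknown <- setdiff(c(from, to), regions)
    if (length(unknown))
      stop("edge references unknown region(s): ",
           paste(unknown, collapse = ", "))
  } else {
    regions <- sort(unique(c(from, to)))
  }
  lo <- pmin(from, to); hi <- pmax(from, to)
  edges <- unique(cbind(lo, hi))
  dimnames(edges) <- list(NULL, c("from", "to"))
  edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  structure(list(regions = regions, edges = edges), class = "adjacency_map")
}

#' @export
print.adjacency_map <- function(x, ...) {
  cat(sprintf("adjacency map: %d regions, %d edges\n",
              length(x$regions), nrow(x$edges)))
  invisible(x)
}

#' Neighbour counts of an adjacency map
#'
#' @param adj An `adjacency_map`.
#' @return Named integer vector of region degrees (0 for isolated regions).
#' @export
adjacency_degrees <- function(adj) {
  stopifnot(inherits(adj, "adjacency_map"))
  deg <- table(factor(c(adj$edges[, 1L], adj$edges[, 2L]),
                      levels = adj$regions))
  stats::setNames(as.integer(deg), adj$regions)
}

#' Write a result table to delimited text
#'
#' Values round-trip through [utils::read.csv()] at better than
#' 10-significant-digit precision by default; set `digits` (e.g. 4) for
#' display rounding matching published tables.
#'
#' @param table Nonempty data frame or matrix.
#' @param path Output file path.
#' @param digits Optional number of decimal places for display rounding of
#'   numeric columns; `NULL` (default) writes full precision.
#' @return Invisibly, the path.
#' @export
write_results <- function(table, path, digits = NULL) {
  if (is.matrix(table)) table <- as.data.frame(table)
  if (!is.data.frame(table) || nrow(table) == 0L)
    stop("result table must be a nonempty data frame")
  table <- as.data.frame(table)
  if (!is.null(digits)) {
    num <- vapply(table, is.numeric, TRUE)
    table[num] <- lapply(table[num], round, digits = digits)
  }
  ok <- tryCatch({
    utils::write.csv(table, path, row.names = FALSE, quote = TRUE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop("cannot write results to '", path, "': ",
                        conditionMessage(ok))
  invisible(path)
}
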