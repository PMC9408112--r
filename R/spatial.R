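#' Build a spatial weight matrix from an adjacency map
#'
#' @param adj An `adjacency_map`.
#' @param scheme `"binary"` (default; W_pq = 1 iff p and q are neighbours,
#'   the form the global autocorrelation statistic here normalizes by its
#'   own total weight) or `"row_standardized"` (each nonzero row rescaled to
#'   sum to 1).
#' @param allow_islands Permit regions with no neighbours (default `FALSE`:
#'   an isolated region is an error, since it contributes no spatial
#'   information and usually signals a broken adjacency file).
#' @return A `spatial_weights`: list with `regions` and `matrix` (m x m,
#'   zero diagonal, symmetric for the binary scheme).
#' @export
build_weights <- function(adj, scheme = c("binary", "row_standardized"),
                          allow_islands = FALSE) {
  stopifnot(inherits(adj, "adjacency_map"))
  scheme <- match.arg(scheme)
  regions <- adj$regions
  m <- length(regions)
  w <- matrix(0, m, m, dimnames = list(regions, regions))
  i <- match(adj$edges[, 1L], regions)
  j <- match(adj$edges[, 2L], regions)
  w[cbind(i, j)] <- 1
  w[cbind(j, i)] <- 1
  deg <- rowSums(w)
  if (!allow_islands && any(deg == 0))
    stop("island region(s) with no neighbours: ",
         paste(regions[deg == 0], collapse = ", "),
         " (set allow_islands = TRUE to override)")
  if (scheme == "row_standardized") {
    nz <- deg > 0
    w[nz, ] <- w[nz, , drop = FALSE] / deg[nz]
  }
  structure(list(regions = regions, matrix = w, scheme = scheme),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat(sprintf("spatial weights (%s): %d regions, total weight %g\n",
              x$scheme, length(x$regions), sum(x$matrix)))
  invisible(x)
}

#' Global Moran's I
#'
#' \deqn{I = \frac{\sum_p \sum_q W_{pq}(x_p - \bar x)(x_q - \bar x)}
#'                {\sum_p \sum_q W_{pq}}
#'       \cdot \frac{n}{\sum_p (x_p - \bar x)^2}.}
#' Positive values indicate spatial clustering of similar values, negative
#' values spatial alternation; the null expectation under random labelling
#' is -1/(n - 1). The statistic is invariant to adding a constant to `x`
#' and to positive rescaling of the weights.
#'
#' @param x Numeric vector of one value per region. If named, names must
#'   match the weight regions (any order); unnamed vectors are taken in
#'   weight-matrix order.
#' @param w A `spatial_weights`.
#' @return A `moran_result`: list with `I`, `n_used`, `expectation`
#'   (-1/(n-1)) and `scheme`.
#' @examples
#' w <- build_weights(generate_adjacency(4, "ring"))
#' morans_i(c(1, 0, 1, 0), w)$I  # -1: perfect alternation
#' @export
morans_i <- function(x, w) {
  stopifnot(inherits(w, "spatial_weights"))
  wm <- w$matrix
  n <- length(w$regions)
  if (length(x) != n)
    stop("x has length ", length(x), " but weights cover ", n, " regions")
  if (!is.null(names(x))) {
    if (!setequal(names(x), w$regions))
      stop("names of x do not match the weight regions")
    x <- x[w$regions]
  }
  if (any(!is.finite(x))) stop("x must be finite")
  xc <- x - mean(x)
  ss <- sum(xc^2)
  if (ss == 0) stop("zero variance: x is constant across regions")
  s0 <- sum(wm)
  i <- as.numeric(t(xc) %*% wm %*% xc) / s0 * n / ss
  structure(list(I = i, n_used = n, expectation = -1 / (n - 1),
                 scheme = w$scheme),
            class = "moran_result")
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("Moran's I = %.4f (n = %d, E[I] = %.4f)\n",
              x$I, x$n_used, x$expectation))
  invisible(x)
}

#' Permutation test for positive spatial autocorrelation
#'
#' One-sided (greater) test by random labelling: region values are permuted
#' `n_perm` times and p = (1 + #\{I_perm >= I_obs\}) / (n_perm + 1).
#'
#' @inheritParams morans_i
#' @param n_perm Number of permutations (>= 99).
#' @param seed Integer seed; the test is deterministic given it.
#' @return List with `I` (observed), `p_value`, `n_perm`, `n_used`.
#' @export
moran_permutation_test <- function(x, w, n_perm = 999L, seed = 1L) {
  if (n_perm < 99) stop("use at least 99 permutations")
  obs <- morans_i(x, w)
  if (!is.null(names(x))) x <- x[w$regions]
  xc <- x - mean(x)
  ss <- sum(xc^2)
  n <- length(x)
  # edge list form: permuted I needs only the nonzero weights
  nz <- which(w$matrix != 0, arr.ind = TRUE)
  wv <- w$matrix[nz]
  s0 <- sum(wv)
  scale <- n / (s0 * ss)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  iperm <- vapply(seq_len(n_perm), function(k) {
    p <- sample.int(n)
    sum(wv * xc[p[nz[, 1L]]] * xc[p[nz[, 2L]]]) * scale
  }, 0)
  p <- (1 + sum(iperm >= obs$I)) / (n_perm + 1)
  list(I = obs$I, p_value = p, n_perm = as.integer(n_perm), n_used = n)
}

#' Yearly Moran's I of the coordination degree
#'
#' @param results A `coupling_result` from [couple_panel()].
#' @param w A `spatial_weights` covering the result regions.
#' @param n_perm Permutations for the significance test; 0 to skip.
#' @param seed Seed for the permutation test.
#' @return Data frame with columns `year`, `I`, `p_value` (NA if skipped),
#'   `n_used`, `scheme`.
#' @export
moran_by_year <- function(results, w, n_perm = 999L, seed = 1L) {
  years <- sort(unique(results$year))
  rows <- lapply(years, function(y) {
    sub <- results[results$year == y, ]
    x <- stats::setNames(sub$D, sub$region)
    if (n_perm > 0) {
      mt <- moran_permutation_test(x, w, n_perm = n_perm, seed = seed + y)
      data.frame(year = y, I = mt$I, p_value = mt$p_value,
                 n_used = mt$n_used, scheme = w$scheme)
    } else {
      mi <- morans_i(x, w)
      data.frame(year = y, I = mi$I, p_value = NA_real_,
                 n_used = mi$n_used, scheme = w$scheme)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
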