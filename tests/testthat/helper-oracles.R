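# Independent brute-force oracles: literal loop transcriptions of the
# method's formulas, kept deliberately naive and separate from the package
# implementation they check.

# min-max standardization across regions (rows) per indicator (column)
oracle_standardize <- function(z, orientation = rep("positive", ncol(z))) {
  out <- z
  for (j in seq_len(ncol(z))) {
    lo <- min(z[, j]); hi <- max(z[, j])
    for (i in seq_len(nrow(z))) {
      if (hi == lo) {
        out[i, j] <- 0.5
      } else if (orientation[j] == "positive") {
        out[i, j] <- (z[i, j] - lo) / (hi - lo)
      } else {
        out[i, j] <- (hi - z[i, j]) / (hi - lo)
      }
    }
  }
  out
}

# entropy weights from a standardized matrix: proportions over regions,
# entropy, difference coefficient, normalized weight
oracle_weights <- function(zs) {
  n <- nrow(zs); k <- ncol(zs)
  w <- numeric(k); kj <- numeric(k)
  for (j in seq_len(k)) {
    tot <- 0
    for (i in seq_len(n)) tot <- tot + zs[i, j]
    acc <- 0
    for (i in seq_len(n)) {
      s <- zs[i, j] / tot
      if (s > 0) acc <- acc + s * log(s)
    }
    kj[j] <- -acc / log(n)
  }
  dj <- 1 - kj
  dj / sum(dj)
}

# full single-year pipeline: raw supply and demand matrices -> per-region
# coordination degree
oracle_pipeline_d <- function(zsup, zdem, alpha = 0.4, beta = 0.6) {
  ss <- oracle_standardize(zsup)
  sd <- oracle_standardize(zdem)
  ws <- oracle_weights(ss)
  wd <- oracle_weights(sd)
  n <- nrow(zsup)
  d <- numeric(n)
  for (i in seq_len(n)) {
    t1 <- 0; for (j in seq_len(ncol(ss))) t1 <- t1 + ws[j] * ss[i, j]
    t2 <- 0; for (j in seq_len(ncol(sd))) t2 <- t2 + wd[j] * sd[i, j]
    cc <- if (t1 + t2 > 0) 2 * sqrt(t1 * t2) / (t1 + t2) else 0
    d[i] <- cc * (alpha * t1 + beta * t2)
  }
  d
}

# global Moran's I by direct double-loop substitution
oracle_moran <- function(x, wm) {
  n <- length(x)
  xbar <- mean(x)
  num <- 0; s0 <- 0; ss <- 0
  for (p in seq_len(n)) {
    for (q in seq_len(n)) {
      num <- num + wm[p, q] * (x[p] - xbar) * (x[q] - xbar)
      s0 <- s0 + wm[p, q]
    }
    ss <- ss + (x[p] - xbar)^2
  }
  (num / s0) * (n / ss)
}

# small complete panel with custom indicator counts, values supplied or
# drawn from the given sampler
make_test_panel <- function(m = 5, n_sup = 2, n_dem = 2, years = 2020,
                            values = NULL, sampler = function(n) runif(n, 1, 100)) {
  ids_s <- paste0("S", seq_len(n_sup))
  ids_d <- paste0("Dm", seq_len(n_dem))
  spec <- do.call(indicator_set, c(
    lapply(ids_s, indicator_spec, subsystem = "supply"),
    lapply(ids_d, indicator_spec, subsystem = "demand")))
  regions <- paste0("r", seq_len(m))
  grid <- expand.grid(region = regions, year = years,
                      indicator = c(ids_s, ids_d),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$value <- if (is.null(values)) sampler(nrow(grid)) else values
  as_indicator_panel(grid, spec = spec)
}
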