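test_that("weight matrices honour scheme, symmetry and island detection", {
  ring <- generate_adjacency(4, "ring")
  wb <- build_weights(ring, "binary")
  expect_true(all(rowSums(wb$matrix) == 2))
  expect_identical(wb$matrix, t(wb$matrix))
  expect_true(all(diag(wb$matrix) == 0))

  wr <- build_weights(ring, "row_standardized")
  expect_true(all(wr$matrix[wr$matrix > 0] == 0.5))
  expect_equal(unname(rowSums(wr$matrix)), rep(1, 4))

  iso <- adjacency_map("A", "B", regions = c("A", "B", "C"))
  expect_error(build_weights(iso), "island region")
  expect_silent(build_weights(iso, allow_islands = TRUE))
})

test_that("Moran's I reproduces hand-evaluated ring patterns", {
  w <- build_weights(generate_adjacency(4, "ring"))
  expect_equal(morans_i(c(1, 0, 1, 0), w)$I, -1)   # perfect alternation
  expect_equal(morans_i(c(1, 1, 0, 0), w)$I, 0)    # two-block split
  expect_error(morans_i(c(2, 2, 2, 2), w), "zero variance")
  expect_error(morans_i(c(1, 2, 3), w), "length")
})

test_that("Moran's I is location/scale invariant and matches the double-loop oracle", {
  set.seed(81)
  for (k in 1:20) {
    m <- sample(c(9, 16, 25), 1)
    adj <- generate_adjacency(m, sample(c("ring", "grid"), 1))
    w <- build_weights(adj, sample(c("binary", "row_standardized"), 1))
    x <- rnorm(m)
    got <- morans_i(x, w)$I
    expect_equal(got, oracle_moran(x, w$matrix), tolerance = 1e-12)
    # adding a constant and rescaling W leave I unchanged
    expect_equal(morans_i(x + 5, w)$I, got, tolerance = 1e-12)
    w2 <- w; w2$matrix <- 3.7 * w$matrix
    expect_equal(morans_i(x, w2)$I, got, tolerance = 1e-12)
  }
})

test_that("Moran's I agrees with the ape reference implementation", {
  skip_if_not_installed("ape")
  set.seed(82)
  # ape row-normalizes the supplied weights internally, so compare on the
  # row-standardized scheme where that normalization is the identity
  w <- build_weights(china_adjacency(), "row_standardized")
  x <- rnorm(31)
  ref <- ape::Moran.I(x, w$matrix, scaled = FALSE)
  expect_equal(morans_i(x, w)$I, ref$observed, tolerance = 1e-12)
})

test_that("named region values are aligned to the weight ordering", {
  w <- build_weights(generate_adjacency(4, "ring"))
  x <- c(R01 = 1, R02 = 0, R03 = 1, R04 = 0)
  shuffled <- x[c(3, 1, 4, 2)]
  expect_equal(morans_i(shuffled, w)$I, morans_i(x, w)$I)
  names(shuffled)[1] <- "nope"
  expect_error(morans_i(shuffled, w), "names")
})

test_that("the permutation test is deterministic, detects clustering, and is calibrated", {
  grid <- generate_adjacency(16, "grid")
  w <- build_weights(grid)
  # two-colour split of the lattice: strong positive autocorrelation
  x <- rep(c(1, 1, 0, 0), each = 4) + rnorm(16, sd = 0.01)
  p1 <- moran_permutation_test(x, w, n_perm = 999, seed = 7)
  p2 <- moran_permutation_test(x, w, n_perm = 999, seed = 7)
  expect_identical(p1$p_value, p2$p_value)
  expect_lte(p1$p_value, 0.05)

  # null calibration: p-values approximately uniform over replicate draws
  set.seed(83)
  ps <- vapply(1:200, function(k)
    moran_permutation_test(rnorm(16), w, n_perm = 99, seed = k)$p_value, 0)
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_error(moran_permutation_test(rnorm(16), w, n_perm = 10), "99")
})

test_that("yearly Moran tables cover every panel year", {
  sim <- generate_panel(synthetic_config(m_regions = 16, years = 2010:2013,
                                        seed = 10))
  cp <- couple_panel(sim$panel)
  # synthetic regions R01.. match the generated grid regions
  w <- build_weights(generate_adjacency(16, "grid"))
  mo <- moran_by_year(cp, w, n_perm = 99, seed = 2)
  expect_equal(mo$year, 2010:2013)
  expect_true(all(is.finite(mo$I)))
  expect_true(all(mo$p_value > 0 & mo$p_value <= 1))
  mo0 <- moran_by_year(cp, w, n_perm = 0)
  expect_true(all(is.na(mo0$p_value)))
  expect_equal(mo0$I, mo$I)
})
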