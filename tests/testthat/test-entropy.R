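test_that("hand-computed weights: informative indicator takes all the weight", {
  # S1 standardized to (0, 1/3, 2/3, 1); S2 constant -> degenerate 0.5s.
  # Equal proportions give S2 entropy exactly 1, so W = (1, 0).
  p <- make_test_panel(m = 4, n_sup = 2, n_dem = 1, years = 2020,
                       values = c(0, 1, 2, 3, 5, 5, 5, 5, 1, 2, 3, 4))
  s <- standardize_year(p, 2020, "supply")
  w <- compute_weights(s)
  expect_identical(unname(w$weights), c(1, 0))
  expect_identical(unname(w$entropy[["S2"]]), 1)
  # K for S1 by hand: proportions (0, 1/6, 1/3, 1/2)
  k1 <- -(1/6 * log(1/6) + 1/3 * log(1/3) + 1/2 * log(1/2)) / log(4)
  expect_equal(unname(w$entropy[["S1"]]), k1, tolerance = 1e-14)
})

test_that("identical columns share weight equally; a single indicator gets 1", {
  p <- make_test_panel(m = 4, n_sup = 2, n_dem = 1, years = 2020,
                       values = c(1, 2, 3, 9, 1, 2, 3, 9, 1, 1, 2, 2))
  w <- compute_weights(standardize_year(p, 2020, "supply"))
  expect_equal(unname(w$weights), c(0.5, 0.5), tolerance = 1e-14)

  w1 <- compute_weights(standardize_year(p, 2020, "demand"))
  expect_identical(unname(w1$weights), 1)
})

test_that("weights match the brute-force loop oracle on random matrices", {
  set.seed(41)
  for (k in 1:30) {
    p <- make_test_panel(m = 5, n_sup = 4, n_dem = 1, years = 2020)
    s <- standardize_year(p, 2020, "supply")
    got <- compute_weights(s)
    want <- oracle_weights(s$matrix)
    expect_equal(unname(got$weights), want, tolerance = 1e-12)
    expect_equal(sum(got$weights), 1, tolerance = 1e-10)
    expect_true(all(got$entropy >= 0 & got$entropy <= 1))
    expect_equal(unname(got$difference_coefficient),
                 unname(1 - got$entropy))
  }
})

test_that("weights are invariant to region order and equivariant to column order", {
  set.seed(51)
  vals <- runif(5 * 3, 1, 10)
  p <- make_test_panel(m = 5, n_sup = 3, n_dem = 1, years = 2020,
                       values = c(vals, runif(5, 1, 2)))
  w <- compute_weights(standardize_year(p, 2020, "supply"))

  # permute region labels: same multiset of rows, same weights
  df <- as.data.frame(p)
  perm <- c(r1 = "r3", r2 = "r5", r3 = "r1", r4 = "r2", r5 = "r4")
  df$region <- unname(perm[df$region])
  wp <- compute_weights(standardize_year(
    as_indicator_panel(df, spec = attr(p, "spec")), 2020, "supply"))
  expect_equal(sort(unname(wp$weights)), sort(unname(w$weights)),
               tolerance = 1e-12)
  expect_equal(unname(wp$weights[names(w$weights)]), unname(w$weights),
               tolerance = 1e-12)

  # relabel columns S1<->S2: weights follow their columns
  df2 <- as.data.frame(p)
  df2$indicator[df2$indicator == "S1"] <- "tmp"
  df2$indicator[df2$indicator == "S2"] <- "S1"
  df2$indicator[df2$indicator == "tmp"] <- "S2"
  wq <- compute_weights(standardize_year(
    as_indicator_panel(df2, spec = attr(p, "spec")), 2020, "supply"))
  expect_equal(unname(wq$weights[c("S2", "S1", "S3")]),
               unname(w$weights[c("S1", "S2", "S3")]), tolerance = 1e-12)
})

test_that("more cross-region dispersion earns more weight", {
  # S1 spreads evenly; S2 concentrates nearly all mass in one region, a
  # lower-entropy proportion profile, so S2 must outweigh S1
  p <- make_test_panel(m = 5, n_sup = 2, n_dem = 1, years = 2020,
                       values = c(1, 2, 3, 4, 5,
                                  1, 1.05, 1.1, 1.15, 100,
                                  1, 2, 3, 4, 5))
  w <- compute_weights(standardize_year(p, 2020, "supply"))
  expect_gt(w$weights[["S2"]], w$weights[["S1"]])
})

test_that("an all-degenerate matrix is refused", {
  p <- make_test_panel(m = 3, n_sup = 2, n_dem = 1, years = 2020,
                       values = c(7, 7, 7, 4, 4, 4, 1, 2, 3))
  s <- standardize_year(p, 2020, "supply")
  expect_error(compute_weights(s), "no discriminating indicator")
})

test_that("weight_table stacks one weight vector per year and sums to 1", {
  sim <- generate_panel(synthetic_config(m_regions = 6, years = 2010:2013,
                                         seed = 8))
  wt <- weight_table(sim$panel, "supply")
  expect_equal(nrow(wt), 4L * 10L)
  sums <- tapply(wt$weight, wt$year, sum)
  expect_equal(as.numeric(sums), rep(1, 4), tolerance = 1e-10)
})
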