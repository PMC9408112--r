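test_that("composite scores reproduce hand dot-products and enforce matching", {
  p <- make_test_panel(m = 4, n_sup = 2, n_dem = 2, years = 2020)
  ss <- standardize_year(p, 2020, "supply")
  ws <- compute_weights(ss)
  expect_equal(composite_score(ss, ws),
               drop(ss$matrix %*% ws$weights), tolerance = 1e-14)

  wd <- compute_weights(standardize_year(p, 2020, "demand"))
  expect_error(composite_score(ss, wd), "mismatch")
  expect_error(composite_score(ss, ws, region = "nowhere"), "unknown region")

  # selector weight, uniform average, and a hand dot-product
  mk <- function(w, row) sum(w * row)
  expect_equal(mk(c(1, 0), c(0.3, 0.9)), 0.3)
  expect_equal(mk(c(0.5, 0.5), c(0.2, 0.8)), 0.5)
  expect_equal(mk(c(0.25, 0.75), c(0.4, 0.8)), 0.7)
})

test_that("coupling degree matches closed forms and is symmetric, bounded", {
  expect_equal(coupling_degree(0.5, 0.5), 1)
  expect_equal(coupling_degree(0.8, 0), 0)
  expect_equal(coupling_degree(0, 0), 0)
  expect_equal(coupling_degree(0.9, 0.1), 0.6)
  expect_error(coupling_degree(-0.1, 0.5), "nonnegative")

  set.seed(61)
  t1 <- runif(200); t2 <- runif(200)
  cc <- coupling_degree(t1, t2)
  expect_equal(cc, coupling_degree(t2, t1))
  expect_true(all(cc >= 0 & cc <= 1))
  # equality attained iff the scores coincide (for positive totals)
  expect_true(all((cc == 1) == (t1 == t2) | (t1 + t2 == 0)))
})

test_that("coordination degree collapses and bounds correctly", {
  expect_equal(coordination_degree(0.64, 0.64), 0.64)
  expect_equal(coordination_degree(0, 0), 0)
  expect_equal(coordination_degree(0.9, 0.1), 0.6 * (0.4 * 0.9 + 0.6 * 0.1))
  expect_error(coordination_degree(0.5, 0.5, alpha = 0.5, beta = 0.6),
               "sum to 1")

  set.seed(62)
  t1 <- runif(200); t2 <- runif(200)
  d <- coordination_degree(t1, t2)
  expect_true(all(d >= 0 & d <= pmax(t1, t2) + 1e-12))

  # strict monotonicity in the demand score for positive supply
  d1 <- coordination_degree(0.3, 0.4); d2 <- coordination_degree(0.3, 0.5)
  expect_gt(d2, d1)
  grid2 <- seq(0.05, 0.95, by = 0.05)
  dd <- coordination_degree(rep(0.3, length(grid2)), grid2)
  expect_true(all(diff(dd) > 0))

  # square-root variant for sensitivity analysis
  expect_equal(coordination_degree(0.64, 0.64, sqrt_variant = TRUE),
               sqrt(1 * 0.64))
})

test_that("classification covers [0,1] in ten exclusive bins with prose categories", {
  lv <- coordination_levels()
  expect_equal(nrow(lv), 10L)

  expect_equal(classify_coordination(0.8632)$level, "Good balance")
  expect_equal(classify_coordination(0.8632)$category, "excellent")
  expect_equal(classify_coordination(0.1216)$level, "Serious imbalance")
  expect_equal(classify_coordination(0.1216)$category, "poor")
  # half-open bins: boundary values belong to the upper bin
  expect_equal(classify_coordination(0.4)$level, "Close to imbalance")
  expect_equal(classify_coordination(0.4)$category, "medium")
  expect_equal(classify_coordination(1)$level, "Excellent balance")
  expect_equal(classify_coordination(0)$level, "Extreme imbalance")
  expect_error(classify_coordination(1.2), "\\[0, 1\\]")

  # every D lands in exactly one bin, and the bin brackets it
  d <- seq(0, 1, by = 0.001)
  cls <- classify_coordination(d)
  idx <- match(cls$level, lv$level)
  expect_true(all(d >= lv$lower[idx]))
  expect_true(all(d < lv$upper[idx] | idx == 10L))
  # category thresholds at 0.4 and 0.6
  expect_true(all(cls$category[d < 0.4] == "poor"))
  expect_true(all(cls$category[d >= 0.4 & d < 0.6] == "medium"))
  expect_true(all(cls$category[d >= 0.6] == "excellent"))
})

test_that("period means reproduce the published Average column", {
  tab4 <- reference_coupling_table("2010_2019")
  ycols <- as.character(2010:2019)
  bj <- as.numeric(tab4[tab4$region == "Beijing", ycols])
  expect_equal(period_mean(bj, digits = 4), 0.6142)
  js <- as.numeric(tab4[tab4$region == "Jiangsu", ycols])
  expect_equal(period_mean(js, digits = 4), 0.8632)
  expect_equal(period_mean(rep(0.5, 10)), 0.5)
  expect_error(period_mean(numeric(0)), "empty")
})

test_that("couple_panel agrees with the literal formula-chain oracle", {
  set.seed(71)
  for (k in 1:25) {
    p <- make_test_panel(m = 5, n_sup = 2, n_dem = 2, years = 2020)
    got <- couple_panel(p)
    zsup <- panel_matrix(p, 2020, "supply")
    zdem <- panel_matrix(p, 2020, "demand")
    want <- oracle_pipeline_d(zsup, zdem)
    expect_equal(got$D[match(rownames(zsup), got$region)], want,
                 tolerance = 1e-12)
  }
})

test_that("the wide coordination matrix mirrors the long results", {
  sim <- generate_panel(synthetic_config(m_regions = 5, years = 2010:2013,
                                         seed = 9))
  cp <- couple_panel(sim$panel)
  cm <- coordination_matrix(cp)
  expect_equal(names(cm), c("region", as.character(2010:2013), "Average"))
  r3 <- cp[cp$region == "R03", ]
  expect_equal(as.numeric(cm[cm$region == "R03", as.character(2010:2013)]),
               r3$D[order(r3$year)])
  expect_equal(cm$Average[cm$region == "R03"], mean(r3$D))
})
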