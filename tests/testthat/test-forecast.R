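test_that("window construction counts and contents are exact", {
  w <- make_windows(1:10, 3)
  expect_equal(nrow(w$x), 7L)
  expect_equal(w$x[1, ], c(1, 2, 3))
  expect_equal(w$y, 4:10)
  expect_equal(nrow(make_windows(1:4, 3)$x), 1L)
  expect_error(make_windows(1:3, 3), "too short")

  # no look-ahead: the windows feeding y_t never contain values from t on
  s <- rnorm(10)
  w1 <- make_windows(s, 3)
  s2 <- s; s2[8:10] <- 99
  w2 <- make_windows(s2, 3)
  expect_equal(w1$x[1:4, ], w2$x[1:4, ])  # targets y_4..y_7 untouched
})

test_that("constant series bypass the network exactly and fits are deterministic", {
  fr <- fit_and_forecast(rep(5, 8), forecast_config(horizon = 5))
  expect_identical(fr$forecasts, rep(5, 5))
  expect_identical(fr$loss, 0)

  set.seed(91)
  s <- cumsum(runif(10, 0.5, 1.5))
  cfg <- forecast_config(seed = 123)
  a <- fit_and_forecast(s, cfg)
  b <- fit_and_forecast(s, cfg)
  expect_equal(a$forecasts, b$forecasts, tolerance = 1e-9)
  expect_equal(a$loss, b$loss, tolerance = 1e-9)

  expect_error(fit_and_forecast(c(1, NA, 3, 4, 5), cfg), "finite")
  expect_error(fit_and_forecast(c(1, -2, 3, 4, 5), cfg), "nonnegative")
  expect_error(fit_and_forecast(c(1, 2, 3), cfg), "too short")
})

test_that("a noiseless linear trend is continued within 10% one step ahead", {
  s <- 2 + 0.5 * (1:10)
  errs <- vapply(1:20, function(seed) {
    fr <- fit_and_forecast(s, forecast_config(seed = seed))
    abs(fr$forecasts[1] - 7.5) / 7.5
  }, 0)
  expect_lt(max(errs), 0.10)
})

test_that("the network beats persistence on noiseless trending series", {
  lin <- 2 + 0.5 * (1:10)
  expo <- 2 * 1.1^(1:10)
  for (s in list(lin, expo)) {
    fr <- fit_and_forecast(s[1:9], forecast_config(seed = 2, horizon = 1))
    nn_err <- abs(fr$forecasts[1] - s[10])
    persist_err <- abs(s[9] - s[10])
    expect_lte(nn_err, persist_err)
  }
})

test_that("forecasts are nonnegative even for decaying series", {
  s <- pmax(10 - 2 * (1:10), 0.2)
  fr <- fit_and_forecast(s, forecast_config(seed = 3, horizon = 5))
  expect_true(all(fr$forecasts >= 0))
})

test_that("panel forecasting keeps shape, completeness and downstream compatibility", {
  sim <- generate_panel(synthetic_config(m_regions = 5, years = 2010:2017,
                                         seed = 12, noise_cv = 0.05))
  fcfg <- forecast_config(horizon = 3, n_restarts = 2, max_iter = 200)
  fp <- forecast_panel(sim$panel, fcfg)
  expect_equal(attr(fp, "years"), 2018:2020)
  expect_equal(attr(fp, "regions"), attr(sim$panel, "regions"))
  expect_equal(nrow(fp), 5L * 3L * 14L)
  expect_true(all(fp$value >= 0))

  # identical seed, identical panel forecast
  fp2 <- forecast_panel(sim$panel, fcfg)
  expect_equal(fp$value, fp2$value, tolerance = 1e-9)

  # the coupling stage runs unchanged on the forecast panel
  cp <- couple_panel(fp)
  expect_equal(sort(unique(cp$year)), 2018:2020)
  expect_true(all(cp$D >= 0 & cp$D <= 1))
})

test_that("trendless noisy panels forecast near the training means", {
  # per indicator: mean of the forecast panel stays within 3 SD of the
  # training values (Monte-Carlo over generator seeds)
  devs <- vapply(1:6, function(s) {
    sim <- generate_panel(synthetic_config(m_regions = 6, years = 2010:2017,
                                           seed = s, trend_rate = 0))
    fp <- forecast_panel(sim$panel,
                         forecast_config(seed = s, horizon = 3,
                                         n_restarts = 3, max_iter = 300))
    p <- sim$panel
    max(vapply(unique(p$indicator), function(ind) {
      tr <- p$value[p$indicator == ind]
      abs(mean(fp$value[fp$indicator == ind]) - mean(tr)) / stats::sd(tr)
    }, 0))
  }, 0)
  expect_lt(max(devs), 3)
})
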