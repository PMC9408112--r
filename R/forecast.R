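#' Configuration for sliding-window neural-network forecasting
#'
#' A small one-hidden-layer feed-forward network maps a lag window of past
#' values to the next value (the nonlinear input-output scheme), then rolls
#' forward recursively for multi-step forecasts. Defaults are sized for
#' ten-point yearly series: with lag 3 a decade yields 7 training windows,
#' and more capacity than 8 hidden units would be unidentifiable.
#'
#' @param lag Window length (>= 1, default 3).
#' @param hidden_units Hidden layer width (default 8).
#' @param activation Hidden activation: `"tanh"` (default) or `"logistic"`.
#' @param max_iter Optimizer iteration cap per restart (default 500).
#' @param seed Integer seed; fitting is deterministic given it.
#' @param horizon Years ahead to forecast (default 5).
#' @param n_restarts Random initializations; best training loss wins
#'   (default 5).
#' @param weight_decay L2 penalty on the network weights (default 1e-4),
#'   a mild regularizer that stabilizes extrapolation from tiny samples.
#' @return A `forecast_config` list.
#' @export
forecast_config <- function(lag = 3L, hidden_units = 8L,
                            activation = c("tanh", "logistic"),
                            max_iter = 500L, seed = 1L, horizon = 5L,
                            n_restarts = 5L, weight_decay = 1e-4) {
  activation <- match.arg(activation)
  if (lag < 1) stop("lag must be >= 1")
  if (horizon < 1) stop("horizon must be >= 1")
  if (hidden_units < 1) stop("hidden_units must be >= 1")
  if (n_restarts < 1) stop("n_restarts must be >= 1")
  structure(list(lag = as.integer(lag),
                 hidden_units = as.integer(hidden_units),
                 activation = activation, max_iter = as.integer(max_iter),
                 seed = as.integer(seed), horizon = as.integer(horizon),
                 n_restarts = as.integer(n_restarts),
                 weight_decay = weight_decay),
            class = "forecast_config")
}

#' Sliding training windows of a series
#'
#' @param series Ordered numeric vector of yearly values.
#' @param lag Window length.
#' @return List with `x` (matrix, one window per row, oldest value first)
#'   and `y` (the next value after each window); `length(series) - lag`
#'   pairs in total.
#' @examples
#' make_windows(1:5, 2)
#' @export
make_windows <- function(series, lag) {
  n <- length(series)
  if (n < lag + 1)
    stop("series of length ", n, " is too short for lag ", lag,
         " (need at least ", lag + 1, ")")
  k <- n - lag
  x <- matrix(0, k, lag)
  for (t in seq_len(k)) x[t, ] <- series[t:(t + lag - 1L)]
  list(x = x, y = series[(lag + 1L):n])
}

# flat parameter vector <-> network; forward pass and loss gradient for a
# 1-hidden-layer net with linear output
.nn_unpack <- function(theta, lag, h) {
  n1 <- (lag + 1L) * h
  list(w1 = matrix(theta[seq_len(n1)], lag + 1L, h),
       w2 = theta[(n1 + 1L):(n1 + h + 1L)])
}

.nn_predict <- function(theta, x, lag, h, act) {
  p <- .nn_unpack(theta, lag, h)
  a <- cbind(1, x) %*% p$w1
  hid <- if (act == "tanh") tanh(a) else 1 / (1 + exp(-a))
  drop(cbind(1, hid) %*% p$w2)
}

.nn_obj <- function(theta, x, y, lag, h, act, lambda) {
  p <- .nn_unpack(theta, lag, h)
  xb <- cbind(1, x)
  a <- xb %*% p$w1
  hid <- if (act == "tanh") tanh(a) else 1 / (1 + exp(-a))
  hb <- cbind(1, hid)
  pred <- drop(hb %*% p$w2)
  r <- pred - y
  list(value = mean(r^2) + lambda * sum(theta^2),
       r = r, xb = xb, a = a, hid = hid, hb = hb)
}

.nn_loss <- function(theta, x, y, lag, h, act, lambda)
  .nn_obj(theta, x, y, lag, h, act, lambda)$value

.nn_grad <- function(theta, x, y, lag, h, act, lambda) {
  o <- .nn_obj(theta, x, y, lag, h, act, lambda)
  k <- length(y)
  dpred <- 2 * o$r / k
  g_w2 <- drop(crossprod(o$hb, dpred))
  p <- .nn_unpack(theta, lag, h)
  dhid <- outer(dpred, p$w2[-1L])
  da <- if (act == "tanh") dhid * (1 - o$hid^2) else dhid * o$hid * (1 - o$hid)
  g_w1 <- crossprod(o$xb, da)
  c(as.vector(g_w1), g_w2) + 2 * lambda * theta
}

#' Fit a sliding-window network and forecast a series
#'
#' The series is min-max scaled to \[0, 1\], the network is trained by
#' full-batch quasi-Newton optimization (BFGS with analytic gradients) from
#' `n_restarts` seeded random initializations keeping the best training
#' loss, and forecasts are produced recursively, each prediction feeding
#' back into the next input window. Outputs are inverse-scaled and clipped
#' at 0 (indicator levels are nonnegative). A constant series bypasses the
#' network entirely: its forecast is the constant.
#'
#' @param series Ordered numeric vector of nonnegative yearly values, of
#'   length at least `lag + 2`.
#' @param config A [forecast_config()].
#' @return A `forecast_result`: list with `fitted` (one value per training
#'   window, on the original scale), `forecasts` (length `horizon`),
#'   `loss` (best scaled-space training MSE) and `config`.
#' @examples
#' fit_and_forecast(c(5, 5, 5, 5, 5, 5), forecast_config(horizon = 3))$forecasts
#' @export
fit_and_forecast <- function(series, config = forecast_config()) {
  stopifnot(inherits(config, "forecast_config"))
  if (any(!is.finite(series))) stop("series must be finite")
  if (any(series < 0)) stop("series values must be nonnegative")
  lag <- config$lag
  if (length(series) < lag + 2)
    stop("series of length ", length(series),
         " is too short (need at least ", lag + 2, ")")

  lo <- min(series); hi <- max(series)
  if (hi == lo) {
    return(structure(list(
      fitted = rep(lo, length(series) - lag),
      forecasts = rep(lo, config$horizon), loss = 0, config = config),
      class = "forecast_result"))
  }
  s <- (series - lo) / (hi - lo)
  win <- make_windows(s, lag)
  h <- config$hidden_units
  npar <- (lag + 1L) * h + h + 1L

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  inits <- matrix(stats::runif(npar * config$n_restarts, -0.5, 0.5),
                  npar, config$n_restarts)

  best <- NULL
  for (r in seq_len(config$n_restarts)) {
    fit <- stats::optim(inits[, r], fn = .nn_loss, gr = .nn_grad,
                        x = win$x, y = win$y, lag = lag, h = h,
                        act = config$activation,
                        lambda = config$weight_decay,
                        method = "BFGS",
                        control = list(maxit = config$max_iter,
                                       reltol = 1e-12))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  theta <- best$par

  fitted_s <- .nn_predict(theta, win$x, lag, h, config$activation)
  buf <- s
  fc_s <- numeric(config$horizon)
  for (step in seq_len(config$horizon)) {
    xin <- matrix(utils::tail(buf, lag), 1L)
    fc_s[step] <- .nn_predict(theta, xin, lag, h, config$activation)
    buf <- c(buf, fc_s[step])
  }
  inv <- function(v) pmax(v * (hi - lo) + lo, 0)
  structure(list(fitted = inv(fitted_s), forecasts = inv(fc_s),
                 loss = best$value, config = config),
            class = "forecast_result")
}

#' Forecast every series of a panel
#'
#' Fits one sliding-window network per (region, indicator) series and
#' returns a panel covering only the horizon years, on which the
#' standardization / weighting / coupling stages can run unchanged.
#'
#' @param panel A complete `indicator_panel`.
#' @param config A [forecast_config()]. Each series gets its own
#'   deterministic seed derived from `config$seed`.
#' @return An `indicator_panel` for the `horizon` years following the last
#'   panel year, with the same regions and indicators.
#' @export
forecast_panel <- function(panel, config = forecast_config()) {
  stopifnot(inherits(panel, "indicator_panel"))
  spec <- attr(panel, "spec")
  regions <- attr(panel, "regions")
  years <- attr(panel, "years")
  new_years <- utils::tail(years, 1L) + seq_len(config$horizon)
  rows <- vector("list", length(regions) * nrow(spec))
  k <- 0L
  for (rg in regions) {
    for (ind in spec$id) {
      sub <- panel[panel$region == rg & panel$indicator == ind, ]
      sub <- sub[order(sub$year), ]
      cfg <- config
      # per-series seed: stable under region/indicator ordering
      cfg$seed <- (config$seed + 7919L * match(rg, regions) +
                     104729L * match(ind, spec$id)) %% .Machine$integer.max
      fr <- tryCatch(fit_and_forecast(sub$value, cfg), error = function(e)
        stop("forecast failed for (", rg, ", ", ind, "): ",
             conditionMessage(e), call. = FALSE))
      k <- k + 1L
      rows[[k]] <- data.frame(region = rg, year = new_years,
                              indicator = ind, value = fr$forecasts,
                              stringsAsFactors = FALSE)
    }
  }
  as_indicator_panel(do.call(rbind, rows), spec = spec)
}
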