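# GM(1,1) grey model: a first-order, one-variable grey forecasting model
# for short, strictly positive annual series.

#' Fit a GM(1,1) grey model
#'
#' The original sequence `x0` is accumulated once (1-AGO) into `x1`; the
#' model postulates the whitened differential equation
#' `dx1/dt + a*x1 = b`. The developing coefficient `a` and grey input `b`
#' are estimated by least squares on the discretized form
#' `x0(k+1) = b - a*z(k)` with `z(k) = (x1(k) + x1(k+1))/2` (consecutive-
#' neighbor means), i.e. `[a, b]' = (P'P)^{-1} P'Q` with rows
#' `P[k, ] = (-z(k), 1)` and `Q[k] = x0(k+1)`. Fitted values come from the
#' time-response function
#' `x1hat(i) = (x0(1) - b/a) * exp(-a*(i-1)) + b/a` differenced back to the
#' original scale (`x0hat(1) = x0(1)` by construction, so the first
#' residual is structurally zero).
#'
#' @param x strictly positive numeric series, length at least 4.
#' @param start_year optional calendar year of the first observation; used
#'   to label fitted values and forecasts. Defaults to the integer names of
#'   `x` when present.
#' @return object of class `gm11`: coefficients `a` and `b`, the original
#'   and accumulated sequences `x0` and `x1`, `fitted` (length of `x`),
#'   `residuals`, `years` (or `NULL`), `mean_relative_error` (excluding the
#'   structural first point; see [mean_relative_error()]) and the
#'   class-ratio diagnostic `class_ratio`.
#' @examples
#' th <- load_fixture("table4_theil_series")
#' m <- fit_gm11(th)
#' round(c(m$a, m$b), 4)
#' predict(m, horizon = 10)
#' @export
fit_gm11 <- function(x, start_year = NULL) {
  x0 <- as.numeric(x)
  n <- length(x0)
  if (n < 4) stop("GM(1,1) needs at least 4 points")
  if (any(!is.finite(x0)) || any(x0 <= 0))
    stop("all values must be finite and strictly positive")
  if (is.null(start_year) && !is.null(names(x))) {
    yrs <- suppressWarnings(as.integer(names(x)))
    if (!anyNA(yrs)) start_year <- yrs[1]
  }
  x1 <- cumsum(x0)
  z <- (x1[-n] + x1[-1]) / 2
  P <- cbind(-z, 1)
  qrP <- qr(P)
  if (qrP$rank < 2) stop("singular normal equations: degenerate sequence")
  ab <- qr.coef(qrP, x0[-1])
  a <- ab[[1]]; b <- ab[[2]]
  fitted <- gm11_reconstruct(a, b, x0[1], n)
  model <- structure(list(
    a = a, b = b, x0 = x0, x1 = x1, fitted = fitted,
    residuals = x0 - fitted,
    years = if (is.null(start_year)) NULL else start_year + seq_len(n) - 1L,
    class_ratio = if (n >= 2) range(x0[-n] / x0[-1]) else NULL),
    class = "gm11")
  model$mean_relative_error <- mean_relative_error(model)
  model
}

# x0hat(i) from the time-response function; a = 0 falls back to the
# analytic limit (constant sequence).
gm11_reconstruct <- function(a, b, x_first, idx_max, idx = seq_len(idx_max)) {
  if (abs(a) < 1e-14) return(rep(x_first, length(idx)))
  x1hat <- function(i) (x_first - b / a) * exp(-a * (i - 1)) + b / a
  out <- ifelse(idx == 1, x_first, x1hat(idx) - x1hat(idx - 1))
  as.numeric(out)
}

#' @export
print.gm11 <- function(x, ...) {
  cat(sprintf("GM(1,1): a = %.6f, b = %.6f, n = %d\n", x$a, x$b,
              length(x$x0)))
  cat(sprintf("  mean relative fit error: %.2f%% (%s)\n",
              100 * x$mean_relative_error,
              if (x$mean_relative_error < 0.20) "acceptable" else
                "NOT acceptable"))
  invisible(x)
}

#' Forecast from a fitted GM(1,1) model
#'
#' Extends the fitted time-response function `horizon` steps beyond the
#' sample. Forecasts are strictly decreasing when `a > 0` and strictly
#' increasing when `a < 0` (constant when `a = 0`).
#'
#' @param object a [fit_gm11()] model.
#' @param horizon number of steps ahead (>= 1).
#' @param ... unused.
#' @return data frame with columns `index` (sequence index, 1-based from
#'   the first observation), `year` (when the model carries year labels)
#'   and `value`.
#' @export
predict.gm11 <- function(object, horizon = 10, ...) {
  horizon <- as.integer(horizon)
  if (is.na(horizon) || horizon < 1) stop("horizon must be a positive integer")
  n <- length(object$x0)
  idx <- n + seq_len(horizon)
  val <- gm11_reconstruct(object$a, object$b, object$x0[1], max(idx),
                          idx = idx)
  out <- data.frame(index = idx, value = val)
  if (!is.null(object$years))
    out <- data.frame(index = idx,
                      year = object$years[n] + seq_len(horizon),
                      value = val)
  out
}

#' Mean relative fit error of a GM(1,1) model
#'
#' Averages `|x0hat(i) - x0(i)| / x0(i)` over the in-sample points. The
#' first point is excluded by default because its residual is structurally
#' zero (the reconstruction anchors `x0hat(1) = x0(1)`); including it only
#' dilutes the average.
#'
#' @param model a [fit_gm11()] model.
#' @param include_first also average over the structural first point.
#' @return the error as a fraction, with attribute `acceptable` (`TRUE`
#'   when below 0.20, the conventional adequacy cut-off for grey models).
#' @export
mean_relative_error <- function(model, include_first = FALSE) {
  stopifnot(inherits(model, "gm11"))
  rel <- abs(model$residuals) / model$x0
  if (!include_first) rel <- rel[-1]
  err <- mean(rel)
  attr(err, "acceptable") <- err < 0.20
  err
}
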