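#' Modified Gompertz curve for cumulative methane production
#'
#' \deqn{y(t) = A \exp\!\left[-\exp\!\left(\frac{\mu_m e}{A}(\lambda - t)
#'   + 1\right)\right]}
#' where `A` is the methane potential (asymptotic cumulative yield), `mu_m`
#' the maximum production rate (the slope at the inflection point, where
#' \eqn{y = A/e}) and `lambda` the lag time.
#'
#' @param t Time (days); vectorized.
#' @param A Asymptotic yield, same units as `y` (must be > 0).
#' @param mu_m Maximum rate (units of y per day).
#' @param lambda Lag time (days).
#' @return Predicted cumulative methane at `t`.
#' @examples
#' gompertz(0:10 * 10, A = 1000, mu_m = 50, lambda = 10)
#' @export
gompertz <- function(t, A, mu_m, lambda) {
  stopifnot(all(A > 0))
  A * exp(-exp((mu_m * exp(1) / A) * (lambda - t) + 1))
}

.gompertz_start <- function(t, y) {
  A0 <- max(y)
  low <- y < 0.05 * A0
  lam0 <- if (any(low)) max(t[low]) else 0
  # steepest finite-difference slope on the replicate-averaged series
  ybar <- tapply(y, t, mean)
  tu <- sort(unique(t))
  mu0 <- if (length(tu) > 1) max(diff(ybar) / diff(tu)) else A0 / max(max(t), 1)
  if (!is.finite(mu0) || mu0 <= 0) mu0 <- A0 / max(max(t), 1)
  list(A = A0, mu_m = mu0, lambda = lam0)
}

#' Fit the modified Gompertz model to a cumulative methane series
#'
#' Box-constrained nonlinear least squares (Levenberg–Marquardt, via
#' \pkg{minpack.lm}) of [gompertz()] to observed cumulative methane.
#' Replicate bottles may be pooled by passing repeated time points. Starting
#' values (unless supplied): `A` from the series maximum, `lambda` from the
#' latest time still below 5% of the maximum, `mu_m` from the steepest
#' finite-difference slope. Bounds: `A` in (0, 10 max(y)], `mu_m` > 0,
#' `lambda` in \[0, max(t)\].
#'
#' @param formula A two-sided formula, response ~ time, e.g. `ch4 ~ day`.
#' @param data A data frame containing the formula variables; at least 5
#'   distinct rows, response not all zero.
#' @param start Optional named list with `A`, `mu_m`, `lambda` starting
#'   values.
#' @param control A [minpack.lm::nls.lm.control()] list; the default runs
#'   the optimizer close to machine precision.
#' @return An object of class `"gompertz_fit"` with components
#'   `coefficients` (named: A, mu_m, lambda), `stderr`, `r_squared`,
#'   `sigma`, `residuals`, `fitted`, `converged`, `data`, `call`.
#' @examples
#' d <- data.frame(day = seq(0, 128, 8))
#' d$ch4 <- gompertz(d$day, 5000, 300, 35)
#' fit <- fit_gompertz(ch4 ~ day, d)
#' coef(fit)
#' @seealso [fit_linear()], [fit_methane()], [predict.gompertz_fit()]
#' @export
fit_gompertz <- function(formula, data, start = NULL,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 1024, ftol = 1e-15, ptol = 1e-15)) {
  stopifnot(inherits(formula, "formula"), length(formula) == 3L)
  mf <- stats::model.frame(formula, data)
  y <- mf[[1L]]
  t <- mf[[2L]]
  if (anyNA(y) || anyNA(t)) stop("series contains missing values")
  if (any(t < 0)) stop("times must be non-negative")
  if (length(y) < 5L) stop("need at least 5 points to fit the Gompertz model")
  if (max(y) <= 0)
    stop("no methane production: series is all zero, nothing to fit")
  if (is.null(start)) start <- .gompertz_start(t, y)
  start$A <- max(start$A, 1e-8)
  df <- data.frame(.t = t, .y = y)
  upperA <- 10 * max(y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      .y ~ gompertz(.t, A, mu_m, lambda),
      data = df,
      start = start,
      lower = c(A = 1e-12, mu_m = 1e-12, lambda = 0),
      upper = c(A = upperA, mu_m = Inf, lambda = max(t)),
      control = control),
    error = function(e) e)
  if (inherits(fit, "error")) {
    out <- list(coefficients = c(A = NA_real_, mu_m = NA_real_, lambda = NA_real_),
                stderr = c(A = NA_real_, mu_m = NA_real_, lambda = NA_real_),
                r_squared = NA_real_, sigma = NA_real_,
                residuals = rep(NA_real_, length(y)), fitted = rep(NA_real_, length(y)),
                converged = FALSE, message = conditionMessage(fit),
                data = df, call = match.call())
    class(out) <- "gompertz_fit"
    return(out)
  }
  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) stats::setNames(rep(NA_real_, 3), names(est)))
  pred <- gompertz(t, est[["A"]], est[["mu_m"]], est[["lambda"]])
  ssr <- sum((y - pred)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - ssr / sst else NA_real_
  out <- list(
    coefficients = est,
    stderr = se[names(est)],
    r_squared = r2,
    sigma = sqrt(ssr / max(length(y) - 3L, 1L)),
    residuals = y - pred,
    fitted = pred,
    converged = isTRUE(fit$convInfo$isConv),
    message = fit$convInfo$stopMessage,
    data = df,
    call = match.call()
  )
  class(out) <- "gompertz_fit"
  out
}

#' @export
print.gompertz_fit <- function(x, digits = 4, ...) {
  cat("Modified Gompertz fit\n")
  if (all(is.na(x$coefficients))) {
    cat("  fit failed:", x$message, "\n")
    return(invisible(x))
  }
  cat(sprintf("  A = %s, mu_m = %s, lambda = %s; R^2 = %s%s\n",
              format(x$coefficients[["A"]], digits = digits),
              format(x$coefficients[["mu_m"]], digits = digits),
              format(x$coefficients[["lambda"]], digits = digits),
              format(x$r_squared, digits = 3),
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' @export
summary.gompertz_fit <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$stderr)
  structure(list(coefficients = tab, r_squared = object$r_squared,
                 sigma = object$sigma, converged = object$converged,
                 n = nrow(object$data), message = object$message),
            class = "summary.gompertz_fit")
}

#' @export
print.summary.gompertz_fit <- function(x, digits = 4, ...) {
  cat("Modified Gompertz fit:", x$n, "points;",
      if (x$converged) "converged" else "NOT converged", "\n")
  stats::printCoefmat(x$coefficients, digits = digits)
  cat(sprintf("R^2 = %s, residual sigma = %s\n",
              format(x$r_squared, digits = 3), format(x$sigma, digits = 4)))
  invisible(x)
}

#' @export
coef.gompertz_fit <- function(object, ...) object$coefficients

#' @export
fitted.gompertz_fit <- function(object, ...) object$fitted

#' @export
residuals.gompertz_fit <- function(object, ...) object$residuals

#' Predict cumulative methane from a Gompertz fit
#'
#' @param object A [fit_gompertz()] object.
#' @param newdata Optional: numeric vector of times, or a data frame with a
#'   time column named as in the original call (the first matching numeric
#'   column is used). Defaults to the fitted times.
#' @param ... Unused.
#' @return Predicted cumulative methane.
#' @export
predict.gompertz_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$.t
  else if (is.numeric(newdata)) newdata
  else if (is.data.frame(newdata)) newdata[[1L]]
  else stop("newdata must be a numeric vector or a data frame of times")
  est <- object$coefficients
  gompertz(t, est[["A"]], est[["mu_m"]], est[["lambda"]])
}

#' Simulate new noisy series from a fitted Gompertz model
#'
#' Draws Gaussian residuals with the fit's residual standard deviation
#' around the fitted curve, at the fitted time points.
#'
#' @param object A [fit_gompertz()] object.
#' @param nsim Number of simulated series.
#' @param seed Optional RNG seed.
#' @param ... Unused.
#' @return A data frame with one column per simulation, rows matching the
#'   fitted time points.
#' @export
simulate.gompertz_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(object$data)
  out <- as.data.frame(replicate(nsim, object$fitted + stats::rnorm(n, 0, object$sigma)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
plot.gompertz_fit <- function(x, ...,
                              xlab = "time (days)",
                              ylab = "cumulative CH4") {
  graphics::plot(x$data$.t, x$data$.y, xlab = xlab, ylab = ylab, ...)
  tt <- seq(min(x$data$.t), max(x$data$.t), length.out = 200)
  graphics::lines(tt, predict(x, tt))
  invisible(x)
}

#' Fit a linear methane-production model
#'
#' Ordinary least squares of cumulative methane on time, the model used for
#' slowly producing treatments (e.g. disaccharides and gas-fed controls)
#' whose curves never leave the quasi-linear regime.
#'
#' @inheritParams fit_gompertz
#' @return An object of class `"linear_fit"` with `coefficients`
#'   (intercept, slope), `r_squared`, `residuals`, `fitted`, `data`. A
#'   constant response yields slope 0 and `r_squared` 0 with a warning.
#' @examples
#' fit_linear(ch4 ~ day, data.frame(day = 0:10, ch4 = 4 * (0:10)))
#' @export
fit_linear <- function(formula, data) {
  stopifnot(inherits(formula, "formula"), length(formula) == 3L)
  mf <- stats::model.frame(formula, data)
  y <- mf[[1L]]; t <- mf[[2L]]
  if (length(y) < 3L) stop("need at least 3 points for a linear fit")
  if (stats::var(y) == 0) {
    warning("constant series: slope 0, R^2 reported as 0")
    out <- list(coefficients = c(intercept = y[1L], slope = 0),
                r_squared = 0, residuals = rep(0, length(y)),
                fitted = y, data = data.frame(.t = t, .y = y))
    class(out) <- "linear_fit"
    return(out)
  }
  lmfit <- stats::lm(y ~ t)
  out <- list(
    coefficients = c(intercept = unname(stats::coef(lmfit)[1L]),
                     slope = unname(stats::coef(lmfit)[2L])),
    r_squared = 1 - sum(stats::residuals(lmfit)^2) / sum((y - mean(y))^2),
    residuals = unname(stats::residuals(lmfit)),
    fitted = unname(stats::fitted(lmfit)),
    data = data.frame(.t = t, .y = y)
  )
  class(out) <- "linear_fit"
  out
}

#' @export
print.linear_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Linear methane-rate fit: slope = %s per day, R^2 = %s\n",
              format(x$coefficients[["slope"]], digits = digits),
              format(x$r_squared, digits = 3)))
  invisible(x)
}

#' @export
coef.linear_fit <- function(object, ...) object$coefficients

#' @export
residuals.linear_fit <- function(object, ...) object$residuals

#' @export
predict.linear_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$.t
  else if (is.numeric(newdata)) newdata else newdata[[1L]]
  object$coefficients[["intercept"]] + object$coefficients[["slope"]] * t
}

#' Fit a methane curve with automatic model choice
#'
#' Fits the Gompertz model and falls back to the linear model when the
#' sigmoid is not supported by the data. The default rule accepts the
#' Gompertz fit when it converged with \eqn{R^2 \ge} `r2_min` and the
#' standard error of `A` is smaller than `A` itself; otherwise the linear
#' fit is returned. This mirrors the usual sigmoid-for-sugars /
#' linear-for-recalcitrant-substrates split in microcosm studies.
#'
#' @inheritParams fit_gompertz
#' @param model `"auto"` (default), `"gompertz"` or `"linear"`.
#' @param r2_min Minimum Gompertz R^2 accepted under `"auto"`.
#' @return A `"gompertz_fit"` or `"linear_fit"` object, with attribute
#'   `"model"` set to the model used.
#' @export
fit_methane <- function(formula, data, model = c("auto", "gompertz", "linear"),
                        r2_min = 0.6) {
  model <- match.arg(model)
  if (model == "linear") {
    fit <- fit_linear(formula, data)
    attr(fit, "model") <- "linear"
    return(fit)
  }
  gfit <- fit_gompertz(formula, data)
  ok <- gfit$converged && !is.na(gfit$r_squared) && gfit$r_squared >= r2_min &&
    is.finite(gfit$stderr[["A"]]) && gfit$stderr[["A"]] < gfit$coefficients[["A"]]
  if (model == "gompertz" || ok) {
    attr(gfit, "model") <- "gompertz"
    return(gfit)
  }
  fit <- fit_linear(formula, data)
  attr(fit, "model") <- "linear"
  fit
}

#' Consolidate several methane series into a group mean series
#'
#' Averages replicate or treatment series pointwise on a common time grid
#' (the grid of the first series, restricted to the overlap of all series;
#' other series are linearly interpolated onto it), attaching the pointwise
#' standard deviation.
#'
#' @param series_list A non-empty list of data frames, each with columns
#'   `day` and `ch4`.
#' @return A data frame with columns `day`, `ch4` (mean), `sd` and `n`.
#' @export
consolidate_group <- function(series_list) {
  if (!is.list(series_list) || length(series_list) == 0L)
    stop("series_list must be a non-empty list of series")
  series_list <- lapply(series_list, function(s) {
    stopifnot(is.data.frame(s), all(c("day", "ch4") %in% names(s)))
    s[order(s$day), c("day", "ch4")]
  })
  lo <- max(vapply(series_list, function(s) min(s$day), numeric(1)))
  hi <- min(vapply(series_list, function(s) max(s$day), numeric(1)))
  if (lo > hi) stop("series have no overlapping time range")
  grid <- series_list[[1L]]$day
  grid <- grid[grid >= lo & grid <= hi]
  if (length(grid) == 0L) stop("no grid points in the overlapping time range")
  mat <- vapply(series_list,
                function(s) stats::approx(s$day, s$ch4, xout = grid)$y,
                numeric(length(grid)))
  mat <- matrix(mat, nrow = length(grid))
  data.frame(
    day = grid,
    ch4 = rowMeans(mat),
    sd = apply(mat, 1L, stats::sd),
    n = ncol(mat)
  )
}

#' Group production rate over the rise phase
#'
#' Linear rate of a (typically consolidated) cumulative methane series over
#' its production window — the points between 5% and 95% of the series
#' maximum, extended one point on each side. Cumulative curves with long
#' lags and plateaus would otherwise dilute the rate estimate.
#'
#' @param series A data frame with columns `day` and `ch4`.
#' @return A `"linear_fit"` object for the rise window.
#' @export
rise_rate <- function(series) {
  stopifnot(is.data.frame(series), all(c("day", "ch4") %in% names(series)))
  y <- series$ch4
  top <- max(y)
  if (top <= 0) stop("no methane production: cannot estimate a rise rate")
  w <- which(y > 0.05 * top & y < 0.95 * top)
  if (length(w) == 0L) w <- seq_along(y)
  w <- unique(c(max(min(w) - 1L, 1L), w, min(max(w) + 1L, length(y))))
  fit_linear(ch4 ~ day, series[w, ])
}
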