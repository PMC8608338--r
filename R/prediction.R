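#' Mean prediction interval for an OLS fit
#'
#' \eqn{100(1-\alpha)\%} interval for the mean response at a new predictor
#' point \eqn{x_0}:
#' \deqn{\hat y_0 \pm t_{1-\alpha/2,\,v}\sqrt{\hat\sigma^2\,
#'       x_0'(X'X)^{-1}x_0},}
#' with \eqn{v} the residual degrees of freedom (\eqn{n - p} without an
#' intercept). When the fit carries an intercept, \eqn{x_0} is supplied on
#' the raw predictor scale; it is centered internally, the point estimate
#' includes the intercept, \eqn{v = n - p - 1}, and the variance gains the
#' \eqn{1/n} term contributed by the estimated mean.
#'
#' @param fit an \code{"ols_fit"}.
#' @param x0 numeric vector of length p (raw predictor scale).
#' @param level coverage probability, default 0.95.
#' @param data the \code{"design_response"}; defaults to the one in the fit.
#' @return object of class \code{"interval_result"}: list with
#'   \code{point_estimate}, \code{lower}, \code{upper}, \code{level},
#'   \code{width}, \code{se}, \code{df}.
#' @export
predict_interval_ols <- function(fit, x0, level = 0.95, data = fit$data) {
  stopifnot(inherits(fit, "ols_fit"))
  mean_interval(fit, d = NULL, x0 = x0, level = level, data = data,
                beta = fit$beta_hat, b0 = fit$intercept_estimate)
}

#' Mean prediction interval for a Liu fit
#'
#' \deqn{\tilde y_0 \pm t_{1-\alpha/2,\,v}\sqrt{\hat\sigma^2\,
#'       x_0' Q_d (X'X)^{-1} Q_d' x_0}, \qquad
#'       Q_d = (X'X + I)^{-1}(X'X + dI).}
#' Because \eqn{Q_d} contracts every eigendirection by
#' \eqn{(\lambda + d)/(\lambda + 1) \le 1}, the Liu interval is never wider
#' than the OLS interval at the same point, with equality iff \eqn{d = 1}.
#' Intercept handling, degrees of freedom and the \eqn{1/n} term follow
#' [predict_interval_ols()].
#'
#' @param lfit a \code{"liu_fit"}.
#' @param ols the underlying \code{"ols_fit"}.
#' @param x0 numeric vector of length p (raw predictor scale).
#' @param level coverage probability, default 0.95.
#' @param data the \code{"design_response"}; defaults to the one in the fit.
#' @return an \code{"interval_result"} (see [predict_interval_ols()]).
#' @export
predict_interval_liu <- function(lfit, ols, x0, level = 0.95, data = ols$data) {
  stopifnot(inherits(lfit, "liu_fit"), inherits(ols, "ols_fit"))
  mean_interval(ols, d = lfit$d, x0 = x0, level = level, data = data,
                beta = lfit$beta_liu, b0 = lfit$intercept_estimate)
}

# shared interval engine. d = NULL -> OLS variance; otherwise Liu variance
# via the spectral contraction (lam + d)/(lam + 1) in canonical coordinates:
# x0' Qd (X'X)^{-1} Qd' x0 = sum_j ((lam_j + d)/(lam_j + 1))^2 u_j^2 / lam_j,
# u = D'x0.
mean_interval <- function(ols, d, x0, level, data, beta, b0) {
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)", call. = FALSE)
  x0 <- as.numeric(x0)
  p <- length(ols$beta_hat)
  if (length(x0) != p) stop(sprintf("x0 must have length %d", p), call. = FALSE)
  sp <- ols$spectral
  lam <- sp$eigenvalues
  has_int <- !is.null(data) && isTRUE(data$intercept)
  x0c <- if (has_int) x0 - colMeans(data$X) else x0
  u <- drop(crossprod(sp$D, x0c))
  mult2 <- if (is.null(d)) rep(1, p) else ((lam + d) / (lam + 1))^2
  quad <- sum(mult2 * u^2 / lam)
  if (has_int) quad <- quad + 1 / data$n
  point <- sum(x0 * beta) + if (has_int) b0 else 0
  se <- sqrt(ols$sigma2_hat * quad)
  tq <- stats::qt(1 - (1 - level) / 2, df = ols$df_resid)
  structure(list(point_estimate = point, lower = point - tq * se,
                 upper = point + tq * se, level = level,
                 width = 2 * tq * se, se = se, df = ols$df_resid),
            class = "interval_result")
}

#' @export
print.interval_result <- function(x, ...) {
  cat(sprintf("%g%% mean prediction interval (df = %d)\n", 100 * x$level, x$df))
  cat(sprintf("  point %.6g  [%.6g, %.6g]  width %.6g\n",
              x$point_estimate, x$lower, x$upper, x$width))
  invisible(x)
}
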