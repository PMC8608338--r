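#' Liu estimator for a given shrinkage parameter
#'
#' Computes the Liu fit
#' \deqn{\hat\beta_{LIU}(d) = (X'X + I)^{-1}(X'X + dI)\,\hat\beta_{OLS},}
#' evaluated componentwise in the canonical form:
#' \eqn{\hat\alpha_{LIU,j} = \frac{\lambda_j + d}{\lambda_j + 1}\hat\alpha_j},
#' then rotated back with \eqn{\hat\beta_{LIU} = D\,\hat\alpha_{LIU}}.
#' At \eqn{d = 1} the Liu fit equals OLS exactly; for \eqn{d < 1} every
#' canonical component is shrunk toward zero.
#'
#' @param fit an \code{"ols_fit"} from [fit_ols()].
#' @param d shrinkage parameter in \eqn{[0, 1]}. Values outside raise an
#'   error unless \code{allow_out_of_range = TRUE} (research use).
#' @param spectral the \code{"spectral_form"}; defaults to the one stored in
#'   \code{fit}.
#' @param rule_name label recorded on the result (a rule token or
#'   \code{"fixed"}).
#' @param allow_out_of_range logical, permit d outside \eqn{[0,1]}.
#' @return object of class \code{"liu_fit"}: list with \code{d},
#'   \code{alpha_liu}, \code{beta_liu}, \code{rule_name},
#'   \code{intercept_estimate} (\code{NA} when the fit has no intercept).
#' @examples
#' d <- design_response(cbind(c(1, 0, 1), c(0, 1, 1)), c(1, 2, 4),
#'                      intercept = FALSE)
#' fit <- fit_ols(d)
#' liu_fit(fit, d = 0.5)$beta_liu
#' @export
liu_fit <- function(fit, d, spectral = fit$spectral, rule_name = "fixed",
                    allow_out_of_range = FALSE) {
  stopifnot(inherits(fit, "ols_fit"), inherits(spectral, "spectral_form"))
  if (!is.finite(d)) stop("d must be finite", call. = FALSE)
  if (!allow_out_of_range && (d < 0 || d > 1))
    stop(sprintf("d = %g outside [0, 1]; set allow_out_of_range = TRUE to override", d),
         call. = FALSE)
  lam <- spectral$eigenvalues
  alpha_liu <- (lam + d) / (lam + 1) * spectral$alpha_hat
  beta_liu <- drop(spectral$D %*% alpha_liu)
  names(beta_liu) <- names(fit$beta_hat)
  b0 <- NA_real_
  if (!is.null(fit$data) && fit$data$intercept) {
    b0 <- mean(fit$data$y) - sum(colMeans(fit$data$X) * beta_liu)
  }
  structure(list(d = d, alpha_liu = alpha_liu, beta_liu = beta_liu,
                 rule_name = rule_name, intercept_estimate = b0),
            class = "liu_fit")
}

#' @export
print.liu_fit <- function(x, ...) {
  cat(sprintf("Liu fit (%s): d = %.6g\n", x$rule_name, x$d))
  if (!is.na(x$intercept_estimate))
    cat(sprintf("intercept: %.6g\n", x$intercept_estimate))
  print(x$beta_liu)
  invisible(x)
}

#' Closed-form MSE of the OLS estimator
#'
#' \deqn{MSE(\hat\alpha) = \sigma^2 \sum_j 1/\lambda_j,}
#' the total mean squared error of the (canonical) least-squares coefficients,
#' which equals that of \eqn{\hat\beta} by rotation invariance.
#'
#' @param eigenvalues strictly positive numeric vector.
#' @param sigma2 positive error variance (an estimate may be plugged in).
#' @return positive scalar.
#' @export
mse_ols_analytic <- function(eigenvalues, sigma2) {
  stopifnot(all(eigenvalues > 0), sigma2 >= 0)
  sigma2 * sum(1 / eigenvalues)
}

#' Closed-form MSE of the Liu estimator
#'
#' \deqn{MSE(\hat\alpha(d)) = \sigma^2 \sum_j
#'   \frac{(\lambda_j + d)^2}{\lambda_j(\lambda_j + 1)^2}
#'   + (d - 1)^2 \sum_j \frac{\hat\alpha_j^2}{(\lambda_j + 1)^2},}
#' a variance term plus a plug-in squared-bias term (the unknown
#' \eqn{\alpha_j^2} replaced by \eqn{\hat\alpha_j^2}, with no bias
#' correction). At \eqn{d = 1} it reduces exactly to [mse_ols_analytic()].
#' As a function of d it is a convex quadratic.
#'
#' @param eigenvalues strictly positive numeric vector.
#' @param alpha_hat numeric vector, same length.
#' @param sigma2 positive error variance (estimate).
#' @param d shrinkage parameter.
#' @return positive scalar.
#' @export
mse_liu_analytic <- function(eigenvalues, alpha_hat, sigma2, d) {
  stopifnot(length(eigenvalues) == length(alpha_hat),
            all(eigenvalues > 0), sigma2 >= 0, is.finite(d))
  lam <- eigenvalues
  sigma2 * sum((lam + d)^2 / (lam * (lam + 1)^2)) +
    (d - 1)^2 * sum(alpha_hat^2 / (lam + 1)^2)
}
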