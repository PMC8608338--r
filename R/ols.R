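#' Eigen (canonical) decomposition of a design
#'
#' Rotates the model \eqn{y = X\beta + \varepsilon} into its canonical form
#' \eqn{y = Z\alpha + \varepsilon} with \eqn{Z = XD}, where the columns of the
#' orthogonal matrix \eqn{D} are the eigenvectors of \eqn{X'X} and
#' \eqn{Z'Z = \Lambda = diag(\lambda_1 \ge \dots \ge \lambda_p)}. The
#' canonical least-squares coefficients are \eqn{\hat\alpha = \Lambda^{-1}Z'y}.
#' Per-component shrinkage rules are formulated on this scale.
#'
#' Eigenvector signs are fixed by making each column's entry of largest
#' magnitude positive (ties broken at the lowest index), so decompositions
#' are reproducible. Signs never affect any shrinkage rule (they depend on
#' \eqn{\hat\alpha_j^2} only) nor any fitted value.
#'
#' @param data a [design_response()] object. When the design carries an
#'   intercept, the decomposition is of the centered predictor matrix.
#' @return An object of class \code{"spectral_form"}: list with
#'   \code{eigenvalues} (descending), \code{D}, \code{Z}, \code{alpha_hat}.
#' @export
spectral_decompose <- function(data) {
  stopifnot(inherits(data, "design_response"))
  Xc <- centered_X(data)
  yc <- centered_y(data)
  e <- eigen(crossprod(Xc), symmetric = TRUE)
  lam <- e$values
  if (min(lam) <= 1e-12 * max(lam)) {
    stop(sprintf("singular design: smallest eigenvalue %.3e", min(lam)),
         call. = FALSE)
  }
  D <- fix_eigen_signs(e$vectors)
  Z <- Xc %*% D
  alpha_hat <- drop(crossprod(Z, yc)) / lam
  structure(list(eigenvalues = lam, D = D, Z = Z, alpha_hat = alpha_hat),
            class = "spectral_form")
}

# sign convention: largest-|entry| of each eigenvector made positive,
# ties broken by lowest row index (which.max does exactly that)
fix_eigen_signs <- function(V) {
  for (j in seq_len(ncol(V))) {
    k <- which.max(abs(V[, j]))
    if (V[k, j] < 0) V[, j] <- -V[, j]
  }
  V
}

#' Ordinary least squares via the canonical form
#'
#' Fits \eqn{\hat\beta = (X'X)^{-1}X'y} (after centering when an intercept is
#' requested), together with the canonical coefficients
#' \eqn{\hat\alpha = D'\hat\beta}, residuals, the unbiased error-variance
#' estimate \eqn{\hat\sigma^2 = RSS / df} and the residual degrees of freedom
#' (\eqn{n - p} without an intercept, \eqn{n - p - 1} with one).
#'
#' @param data a [design_response()] object.
#' @return Object of class \code{"ols_fit"}: list with \code{beta_hat},
#'   \code{intercept_estimate} (or \code{NA} when no intercept is fitted),
#'   \code{alpha_hat}, \code{sigma2_hat}, \code{df_resid}, \code{residuals},
#'   \code{fitted}, and the underlying \code{spectral} form and \code{data}.
#' @examples
#' d <- design_response(cbind(c(1, 0, 1), c(0, 1, 1)), c(1, 2, 4),
#'                      intercept = FALSE)
#' fit_ols(d)$beta_hat  # (4/3, 7/3)
#' @export
fit_ols <- function(data) {
  stopifnot(inherits(data, "design_response"))
  sp <- spectral_decompose(data)
  beta_hat <- drop(sp$D %*% sp$alpha_hat)
  names(beta_hat) <- data$column_names
  b0 <- NA_real_
  if (data$intercept) {
    b0 <- mean(data$y) - sum(colMeans(data$X) * beta_hat)
  }
  fitted <- drop(data$X %*% beta_hat) + if (data$intercept) b0 else 0
  resid <- data$y - fitted
  df <- data$n - data$p - if (data$intercept) 1L else 0L
  structure(
    list(beta_hat = beta_hat, intercept_estimate = b0,
         alpha_hat = sp$alpha_hat,
         sigma2_hat = sum(resid^2) / df, df_resid = df,
         residuals = resid, fitted = fitted,
         spectral = sp, data = data),
    class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("OLS fit: p = %d, df_resid = %d, sigma2_hat = %.6g\n",
              length(x$beta_hat), x$df_resid, x$sigma2_hat))
  if (!is.na(x$intercept_estimate))
    cat(sprintf("intercept: %.6g\n", x$intercept_estimate))
  print(x$beta_hat)
  invisible(x)
}

#' Condition number of a design
#'
#' Measures the severity of multicollinearity from the eigenvalue spread of
#' \eqn{X'X}. \code{mode = "ratio"} returns \eqn{\lambda_{max}/\lambda_{min}};
#' \code{mode = "sqrt"} (the default) returns its square root, the
#' singular-value-ratio convention that matches the usual 10/30/100
#' rule-of-thumb thresholds.
#'
#' @param data a [design_response()] object.
#' @param mode \code{"sqrt"} (default) or \code{"ratio"}.
#' @return positive scalar.
#' @seealso [classify_collinearity()]
#' @export
condition_number <- function(data, mode = c("sqrt", "ratio")) {
  mode <- match.arg(mode)
  lam <- spectral_decompose(data)$eigenvalues
  r <- max(lam) / min(lam)
  if (mode == "sqrt") sqrt(r) else r
}

#' Classify a condition number into multicollinearity bands
#'
#' Rule of thumb: moderate when \eqn{10 \le CN \le 30}, high when
#' \eqn{30 < CN \le 100}, severe when \eqn{CN > 100}, otherwise none/low.
#' Boundary values 10 and 30 belong to "moderate", 100 to "high".
#'
#' @param cn positive condition number (\eqn{\ge 1}).
#' @return one of \code{"none/low"}, \code{"moderate"}, \code{"high"},
#'   \code{"severe"}.
#' @export
classify_collinearity <- function(cn) {
  if (!is.finite(cn) || cn < 1) stop("cn must be a finite number >= 1", call. = FALSE)
  if (cn > 100) "severe"
  else if (cn > 30) "high"
  else if (cn >= 10) "moderate"
  else "none/low"
}
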