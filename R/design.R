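#' Bundle a design matrix and response for regression
#'
#' Container for a fixed design matrix \code{X} and response \code{y},
#' validated for use with ordinary least squares and Liu shrinkage fits.
#' When \code{intercept = TRUE}, downstream fits center \code{y} and the
#' columns of \code{X}, estimate the slope system on the centered data and
#' recover the intercept as \eqn{\bar y - \bar x' \hat\beta}.
#'
#' @param X numeric matrix (n rows, p columns) of predictors, or an object
#'   coercible to one. Must have full column rank and n > p (n > p + 1 when
#'   an intercept is fitted).
#' @param y numeric response vector of length n.
#' @param intercept logical; fit (and center out) an intercept. Default
#'   \code{TRUE} for user data; the simulation engine uses \code{FALSE}.
#' @param column_names optional character vector of predictor names.
#' @param response_name optional name for the response.
#' @return An object of class \code{"design_response"}: a list with elements
#'   \code{X}, \code{y}, \code{n}, \code{p}, \code{intercept},
#'   \code{column_names}, \code{response_name}.
#' @seealso [fit_ols()], [spectral_decompose()], [condition_number()]
#' @export
design_response <- function(X, y, intercept = TRUE,
                            column_names = NULL, response_name = "y") {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (!all(is.finite(X))) stop("X contains non-finite entries", call. = FALSE)
  if (!all(is.finite(y))) stop("y contains non-finite entries", call. = FALSE)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)", call. = FALSE)
  if (p < 1L) stop("X must have at least one column", call. = FALSE)
  min_n <- p + if (isTRUE(intercept)) 1L else 0L
  if (n <= min_n) {
    stop(sprintf(
      "insufficient degrees of freedom: n = %d, p = %d%s requires n > %d",
      n, p, if (intercept) " (+ intercept)" else "", min_n), call. = FALSE)
  }
  if (is.null(column_names)) {
    column_names <- colnames(X)
    if (is.null(column_names)) column_names <- paste0("x", seq_len(p))
  }
  colnames(X) <- column_names
  obj <- structure(
    list(X = X, y = y, n = n, p = p, intercept = isTRUE(intercept),
         column_names = column_names, response_name = response_name),
    class = "design_response")
  # full-rank check via the spectrum of the (centered) cross-product
  ev <- eigen(crossprod(centered_X(obj)), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12 * max(ev)) {
    stop(sprintf(
      "singular design: smallest eigenvalue of X'X is %.3e (largest %.3e)",
      min(ev), max(ev)), call. = FALSE)
  }
  obj
}

# centered predictor matrix (identity when no intercept is fitted)
centered_X <- function(data) {
  if (data$intercept) scale(data$X, center = TRUE, scale = FALSE) else data$X
}

# centered response
centered_y <- function(data) {
  if (data$intercept) data$y - mean(data$y) else data$y
}

#' @export
print.design_response <- function(x, ...) {
  cat(sprintf("design_response: n = %d, p = %d, intercept = %s\n",
              x$n, x$p, x$intercept))
  cat("predictors:", paste(x$column_names, collapse = ", "),
      " response:", x$response_name, "\n")
  invisible(x)
}

#' Read a regression dataset from CSV
#'
#' Reads a CSV file with a header row, a decimal point \code{"."} and comma
#' separators, selects the response column by name and uses all remaining
#' numeric columns (or an explicit list) as predictors.
#'
#' @param path path to the CSV file.
#' @param response name of the response column.
#' @param predictors optional character vector of predictor column names;
#'   by default every column other than the response.
#' @param intercept logical, passed to [design_response()].
#' @return A [design_response()] object.
#' @export
read_design_csv <- function(path, response, predictors = NULL, intercept = TRUE) {
  df <- utils::read.csv(path, header = TRUE, fileEncoding = "UTF-8")
  if (!response %in% names(df)) {
    stop(sprintf("response column '%s' not found in %s", response, path),
         call. = FALSE)
  }
  if (is.null(predictors)) predictors <- setdiff(names(df), response)
  missing_cols <- setdiff(predictors, names(df))
  if (length(missing_cols)) {
    stop(sprintf("predictor column(s) not found: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  X <- as.matrix(df[predictors])
  if (!is.numeric(X)) stop("predictor columns must be numeric", call. = FALSE)
  design_response(X, df[[response]], intercept = intercept,
                  column_names = predictors, response_name = response)
}
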