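# full-precision CSV writer: numbers serialized with %.17g so read-back is
# exact to double precision
write_csv_full_precision <- function(df, path) {
  fmt <- function(col) {
    if (is.double(col)) sprintf("%.17g", col) else as.character(col)
  }
  out <- vapply(df, fmt, character(nrow(df)))
  if (nrow(df) == 1L) out <- matrix(out, nrow = 1L, dimnames = list(NULL, names(df)))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = ","), con)
  writeLines(apply(out, 1, paste, collapse = ","), con)
  invisible(path)
}

#' Write a synthetic high-collinearity example dataset
#'
#' Generates a small regression CSV (header \code{y, x1, ..., xp}) with the
#' package's simulation generator, emulating the shape of the classic
#' 30-blend tobacco heat dataset: n = 30 observations, 4 collinear predictor
#' concentrations and one response. The dataset is entirely synthetic. The
#' design is regenerated (advancing the seeded RNG) until its condition
#' number falls in the "high" band (30, 100] under the default square-root
#' mode; the number of attempts is reported via \code{message()}.
#'
#' @param out_path path of the CSV file to write.
#' @param n,p,rho shape of the design (defaults 30, 4, 0.97).
#' @param sigma error standard deviation for the response.
#' @param seed integer seed; a fixed seed gives a byte-identical file.
#' @param quiet suppress the attempts message.
#' @return the path, invisibly. Attributes of the written data (condition
#'   number, attempts) are attached to the return value.
#' @export
make_fixture <- function(out_path, n = 30, p = 4, rho = 0.97, sigma = 1,
                         seed = 1L, quiet = FALSE) {
  set.seed(seed)
  attempts <- 0L
  rho_try <- rho
  repeat {
    attempts <- attempts + 1L
    X <- generate_X(n, p, rho_try)
    d <- tryCatch(
      design_response(X, rep(0, n), intercept = FALSE,
                      column_names = paste0("x", seq_len(p))),
      error = function(e) NULL)
    if (!is.null(d)) {
      cn <- condition_number(d, mode = "sqrt")
      if (cn > 30 && cn <= 100) break
    }
    if (attempts >= 1000L)
      stop("could not hit the high-collinearity band in 1000 attempts",
           call. = FALSE)
    # steer the collinearity level toward the band every 25 misses
    if (attempts %% 25L == 0L) {
      rho_try <- if (!is.null(d) && cn <= 30) 1 - (1 - rho_try) / 2
                 else (rho_try + rho) / 2
    }
  }
  beta <- generate_beta(X)
  y <- generate_y(X, beta, sigma)
  df <- data.frame(y = y, X)
  names(df) <- c("y", paste0("x", seq_len(p)))
  write_csv_full_precision(df, out_path)
  if (!quiet)
    message(sprintf("fixture written to %s (CN = %.4f, %d attempt%s)",
                    out_path, cn, attempts, if (attempts == 1L) "" else "s"))
  out <- out_path
  attr(out, "condition_number") <- cn
  attr(out, "attempts") <- attempts
  invisible(out)
}
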