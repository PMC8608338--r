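#' Inputs for shrinkage-parameter rules
#'
#' Bundles the canonical coefficients \eqn{\hat\alpha_j}, the eigenvalues
#' \eqn{\lambda_j} of \eqn{X'X} and the unbiased error-variance estimate
#' \eqn{\hat\sigma^2} — the only quantities any of the d-selection rules use.
#'
#' @param alpha_hat numeric vector of canonical OLS coefficients, or an
#'   \code{"ols_fit"} object (from which all three fields are extracted).
#' @param eigenvalues strictly positive numeric vector, same length.
#' @param sigma2_hat strictly positive scalar. A value of exactly zero is
#'   rejected: it signals an exactly interpolating fit upstream, for which
#'   shrinkage selection is statistically degenerate.
#' @return object of class \code{"shrinkage_inputs"}.
#' @export
shrinkage_inputs <- function(alpha_hat, eigenvalues = NULL, sigma2_hat = NULL) {
  if (inherits(alpha_hat, "ols_fit")) {
    fit <- alpha_hat
    alpha_hat <- fit$alpha_hat
    eigenvalues <- fit$spectral$eigenvalues
    sigma2_hat <- fit$sigma2_hat
  }
  alpha_hat <- as.numeric(alpha_hat)
  eigenvalues <- as.numeric(eigenvalues)
  p <- length(alpha_hat)
  if (p == 0L) stop("alpha_hat has length zero", call. = FALSE)
  if (length(eigenvalues) != p)
    stop("alpha_hat and eigenvalues must have the same length", call. = FALSE)
  if (any(!is.finite(alpha_hat)) || any(!is.finite(eigenvalues)))
    stop("non-finite shrinkage inputs", call. = FALSE)
  if (any(eigenvalues <= 0)) stop("eigenvalues must be strictly positive", call. = FALSE)
  if (!is.finite(sigma2_hat) || sigma2_hat <= 0)
    stop("sigma2_hat must be strictly positive (zero indicates an exact fit)",
         call. = FALSE)
  structure(list(alpha_hat = alpha_hat, eigenvalues = eigenvalues,
                 sigma2_hat = sigma2_hat),
            class = "shrinkage_inputs")
}

as_shrinkage_inputs <- function(x) {
  if (inherits(x, "shrinkage_inputs")) x else shrinkage_inputs(x)
}

#' Per-component shrinkage quantities d-hat
#'
#' Componentwise optimal shrinkage values
#' \deqn{\hat d_j = \frac{\hat\alpha_j^2 - \hat\sigma^2}
#'                       {\hat\sigma^2/\lambda_j + \hat\alpha_j^2}.}
#' Values may be negative; clipping to zero happens only in the aggregated
#' rules ([estimate_d()]).
#'
#' @param inp a [shrinkage_inputs()] object or an \code{"ols_fit"}.
#' @return numeric vector of length p.
#' @export
d_components <- function(inp) {
  inp <- as_shrinkage_inputs(inp)
  a2 <- inp$alpha_hat^2
  (a2 - inp$sigma2_hat) / (inp$sigma2_hat / inp$eigenvalues + a2)
}

#' Per-component quantities q-hat
#'
#' \deqn{\hat q_j = \frac{\hat\alpha_j^2 - 1}
#'                       {1/\lambda_{min} + \hat\alpha_j^2},}
#' the variant family whose denominator uses the worst-case (smallest)
#' eigenvalue for every component and whose numerator subtracts the constant
#' one rather than \eqn{\hat\sigma^2}.
#'
#' @inheritParams d_components
#' @return numeric vector of length p.
#' @export
q_components <- function(inp) {
  inp <- as_shrinkage_inputs(inp)
  a2 <- inp$alpha_hat^2
  (a2 - 1) / (1 / min(inp$eigenvalues) + a2)
}

#' All supported rule names
#' @return character vector \code{c("D1", ..., "D10", "Dgamma")}.
#' @export
shrinkage_rules <- function() c(paste0("D", 1:10), "Dgamma")

#' Estimate the Liu shrinkage parameter d by a named rule
#'
#' Aggregated rules for the Liu parameter \eqn{d \in [0,1]}:
#' \itemize{
#' \item \code{D1}: \eqn{\max(0, (\hat\alpha_{max}^2 - \hat\sigma^2) /
#'       (\hat\sigma^2/\lambda_{max} + \hat\alpha_{max}^2))}, where
#'       \eqn{\hat\alpha_{max}^2 = \max_j \hat\alpha_j^2} is paired with
#'       \eqn{\lambda_{max} = \max_j \lambda_j} regardless of which component
#'       attains each maximum.
#' \item \code{D2}/\code{D3}/\code{D4}: \eqn{\max(0, \cdot)} of the median /
#'       mean / max of [d_components()].
#' \item \code{D5}/\code{D6}/\code{D7}: the same aggregates of
#'       [q_components()].
#' \item \code{Dgamma}: \eqn{\max(0, (Q_\gamma - \hat\sigma^2) /
#'       (\hat\sigma^2/\lambda_{min} + \max_j \hat\alpha_j^2))} where
#'       \eqn{Q_\gamma} is the empirical \eqn{\gamma}-quantile (linear
#'       interpolation, type 7) of \eqn{\{\hat\alpha_j^2\}} under the default
#'       \code{quantile_base = "alpha_squared"}. \code{D8}, \code{D9},
#'       \code{D10} are \code{Dgamma} at \eqn{\gamma} = 0 (minimum), 0.25
#'       (first quartile) and 0.50 (median).
#' }
#' With \code{quantile_base = "alpha_squared"} every rule provably lies in
#' \eqn{[0,1]}. The literal signed reading
#' (\code{quantile_base = "alpha"}, quantile of \eqn{\hat\alpha_j}) is
#' available for sensitivity analysis; it does not guarantee the upper bound,
#' so its result is clipped to \eqn{[0,1]}.
#'
#' @param inp a [shrinkage_inputs()] object or an \code{"ols_fit"}.
#' @param rule case-insensitive rule token, one of [shrinkage_rules()].
#' @param gamma quantile probability in \eqn{[0,1]}; required iff
#'   \code{rule = "Dgamma"}.
#' @param quantile_base \code{"alpha_squared"} (default) or \code{"alpha"}.
#' @return object of class \code{"shrinkage_result"}: list with \code{name},
#'   \code{d}, \code{gamma} (or \code{NA}), and \code{components} (the
#'   per-component \eqn{\hat d_j} or \eqn{\hat q_j} for D2--D7, the
#'   \eqn{\hat\alpha_j^2} pool for the quantile family, \code{NULL} for D1).
#' @examples
#' inp <- shrinkage_inputs(c(2, 1), c(10, 0.1), 1)
#' estimate_d(inp, "D1")$d   # 0.7317073
#' estimate_d(inp, "D10")$d  # 0.1071429
#' @export
estimate_d <- function(inp, rule, gamma = NULL,
                       quantile_base = c("alpha_squared", "alpha")) {
  inp <- as_shrinkage_inputs(inp)
  quantile_base <- match.arg(quantile_base)
  rule_uc <- toupper(as.character(rule))
  if (rule_uc == "DGAMMA") {
    if (is.null(gamma)) stop("rule 'Dgamma' requires gamma", call. = FALSE)
    if (!is.finite(gamma) || gamma < 0 || gamma > 1)
      stop("gamma must lie in [0, 1]", call. = FALSE)
  } else if (rule_uc %in% paste0("D", 1:10)) {
    if (!is.null(gamma))
      stop("gamma is only accepted with rule 'Dgamma'", call. = FALSE)
  } else {
    stop(sprintf("unknown shrinkage rule '%s'", rule), call. = FALSE)
  }

  a2 <- inp$alpha_hat^2
  lam <- inp$eigenvalues
  s2 <- inp$sigma2_hat

  quantile_rule <- function(g) {
    base <- if (quantile_base == "alpha_squared") a2 else inp$alpha_hat
    q <- unname(stats::quantile(base, probs = g, type = 7))
    d <- max(0, (q - s2) / (s2 / min(lam) + max(a2)))
    if (quantile_base == "alpha") d <- min(d, 1)
    list(d = d, comp = base)
  }

  comp <- NULL
  g <- NA_real_
  d <- switch(rule_uc,
    D1 = max(0, (max(a2) - s2) / (s2 / max(lam) + max(a2))),
    D2 = { comp <- d_components(inp); max(0, stats::median(comp)) },
    D3 = { comp <- d_components(inp); max(0, mean(comp)) },
    D4 = { comp <- d_components(inp); max(0, max(comp)) },
    D5 = { comp <- q_components(inp); max(0, stats::median(comp)) },
    D6 = { comp <- q_components(inp); max(0, mean(comp)) },
    D7 = { comp <- q_components(inp); max(0, max(comp)) },
    D8 = { g <- 0;    r <- quantile_rule(g); comp <- r$comp; r$d },
    D9 = { g <- 0.25; r <- quantile_rule(g); comp <- r$comp; r$d },
    D10 = { g <- 0.5; r <- quantile_rule(g); comp <- r$comp; r$d },
    DGAMMA = { g <- gamma; r <- quantile_rule(g); comp <- r$comp; r$d }
  )
  structure(list(name = if (rule_uc == "DGAMMA") "Dgamma" else rule_uc,
                 d = d, gamma = g, components = comp),
            class = "shrinkage_result")
}

#' @export
print.shrinkage_result <- function(x, ...) {
  cat(sprintf("%s: d = %.6g%s\n", x$name, x$d,
              if (!is.na(x$gamma)) sprintf(" (gamma = %g)", x$gamma) else ""))
  invisible(x)
}

# d for every rule in `rules` at once; used by the simulation engine where
# per-replication dispatch overhead matters. "OLS" maps to d = 1.
all_rule_d <- function(alpha_hat, eigenvalues, sigma2_hat, rules) {
  a2 <- alpha_hat^2
  lam <- eigenvalues
  s2 <- sigma2_hat
  dj <- (a2 - s2) / (s2 / lam + a2)
  qj <- (a2 - 1) / (1 / min(lam) + a2)
  den_g <- s2 / min(lam) + max(a2)
  qgamma_d <- function(g)
    max(0, (unname(stats::quantile(a2, probs = g, type = 7)) - s2) / den_g)
  vapply(rules, function(r) switch(toupper(r),
    OLS = 1,
    D1 = max(0, (max(a2) - s2) / (s2 / max(lam) + max(a2))),
    D2 = max(0, stats::median(dj)),
    D3 = max(0, mean(dj)),
    D4 = max(0, max(dj)),
    D5 = max(0, stats::median(qj)),
    D6 = max(0, mean(qj)),
    D7 = max(0, max(qj)),
    D8 = qgamma_d(0),
    D9 = qgamma_d(0.25),
    D10 = qgamma_d(0.5),
    stop(sprintf("unknown rule '%s'", r), call. = FALSE)
  ), numeric(1))
}
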