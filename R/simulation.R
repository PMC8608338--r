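#' Configuration for one Monte Carlo simulation cell
#'
#' One cell of the factorial evaluation design: sample size \code{n},
#' dimension \code{p}, collinearity level \code{rho}, error standard
#' deviation \code{sigma}, and \code{M} replications. Per replication the
#' engine draws a collinear design, takes the true coefficient vector as the
#' unit principal eigenvector of \eqn{X'X}, draws
#' \eqn{y = X\beta + \varepsilon}, fits OLS, estimates d by every requested
#' rule and fits the corresponding Liu estimators.
#'
#' @param n sample size (n > p).
#' @param p number of predictors.
#' @param rho collinearity level in \eqn{[0, 1)}.
#' @param sigma error standard deviation (> 0).
#' @param M number of Monte Carlo replications (default 5000).
#' @param seed integer seed for the cell.
#' @param rules character vector of estimators to evaluate; \code{"OLS"}
#'   plus any of \code{"D1"}...\code{"D10"}.
#' @param corr_mode \code{"target_rho"} (default): predictors built so the
#'   pairwise population correlation is exactly \code{rho};
#'   \code{"literal_rho_squared"}: the classical weighting
#'   \eqn{(1-\rho^2)^{1/2} z_j + \rho z_{p+1}}, whose pairwise correlation is
#'   \eqn{\rho^2}.
#' @param redraw_X logical; redraw the design every replication (default
#'   \code{TRUE}) or fix one design per cell.
#' @return object of class \code{"simulation_config"}.
#' @export
simulation_config <- function(n, p, rho, sigma, M = 5000, seed = 1L,
                              rules = c("OLS", paste0("D", 1:10)),
                              corr_mode = c("target_rho", "literal_rho_squared"),
                              redraw_X = TRUE) {
  corr_mode <- match.arg(corr_mode)
  # n > p is enforced when the cell is run, so that factorial enumeration
  # can list every combination of the factor levels
  stopifnot(p >= 1, M >= 1, sigma > 0, rho >= 0, rho < 1)
  rules <- toupper(rules)
  bad <- setdiff(rules, c("OLS", paste0("D", 1:10)))
  if (length(bad)) stop(sprintf("unknown rule(s): %s", paste(bad, collapse = ", ")),
                        call. = FALSE)
  structure(list(n = as.integer(n), p = as.integer(p), rho = rho,
                 sigma = sigma, M = as.integer(M), seed = as.integer(seed),
                 rules = rules, corr_mode = corr_mode,
                 redraw_X = isTRUE(redraw_X)),
            class = "simulation_config")
}

#' Generate a collinear Gaussian design matrix
#'
#' Common-factor construction: p + 1 independent standard normal columns
#' \eqn{z_1, ..., z_{p+1}} are drawn and combined as
#' \deqn{x_j = \sqrt{1-\rho}\, z_j + \sqrt{\rho}\, z_{p+1}
#'   \quad (\code{corr\_mode = "target\_rho"}, pairwise correlation \rho)}
#' or
#' \deqn{x_j = \sqrt{1-\rho^2}\, z_j + \rho\, z_{p+1}
#'   \quad (\code{corr\_mode = "literal\_rho\_squared"}, correlation \rho^2).}
#' No centering or standardization is applied afterwards. Uses the current
#' RNG state; seed beforehand for reproducibility.
#'
#' @param n,p dimensions.
#' @param rho collinearity level in \eqn{[0, 1)}.
#' @param corr_mode see [simulation_config()].
#' @return n x p numeric matrix.
#' @export
generate_X <- function(n, p, rho,
                       corr_mode = c("target_rho", "literal_rho_squared")) {
  corr_mode <- match.arg(corr_mode)
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)", call. = FALSE)
  Z <- matrix(stats::rnorm(n * (p + 1L)), n, p + 1L)
  if (corr_mode == "target_rho") {
    sqrt(1 - rho) * Z[, seq_len(p), drop = FALSE] + sqrt(rho) * Z[, p + 1L]
  } else {
    sqrt(1 - rho^2) * Z[, seq_len(p), drop = FALSE] + rho * Z[, p + 1L]
  }
}

#' True coefficient vector for the simulation
#'
#' The unit-norm eigenvector of \eqn{X'X} belonging to its largest
#' eigenvalue, sign-fixed by the package's eigenvector convention. This
#' choice makes \eqn{\beta'\beta = 1} and concentrates the signal in the
#' strongest principal direction.
#'
#' @param X numeric design matrix with full column rank.
#' @return unit-norm numeric vector of length \code{ncol(X)}.
#' @export
generate_beta <- function(X) {
  e <- eigen(crossprod(as.matrix(X)), symmetric = TRUE)
  if (min(e$values) <= 1e-12 * max(e$values))
    stop("rank-deficient X", call. = FALSE)
  drop(fix_eigen_signs(e$vectors[, 1, drop = FALSE]))
}

#' Generate responses for the simulation model
#'
#' \eqn{y = X\beta + \varepsilon} with
#' \eqn{\varepsilon_i \sim N(0, \sigma^2)} i.i.d. and no intercept term.
#' Uses the current RNG state.
#'
#' @param X design matrix.
#' @param beta coefficient vector of length \code{ncol(X)}.
#' @param sigma error standard deviation (> 0).
#' @return numeric vector of length \code{nrow(X)}.
#' @export
generate_y <- function(X, beta, sigma) {
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  X <- as.matrix(X)
  if (length(beta) != ncol(X)) stop("length(beta) must equal ncol(X)", call. = FALSE)
  drop(X %*% beta) + stats::rnorm(nrow(X), 0, sigma)
}

#' Run one Monte Carlo cell
#'
#' For i = 1...M: draw (or reuse) a design, set \eqn{\beta} to the unit
#' principal eigenvector of the current \eqn{X'X}, draw y, fit OLS, estimate
#' every rule's d and fit the Liu estimator, and accumulate the squared
#' \eqn{L_2} error \eqn{(\hat\beta_i - \beta)'(\hat\beta_i - \beta)} and the
#' \eqn{L_1} error \eqn{\sum_j |\hat\beta_{ij} - \beta_j|}. EMSE and EMAE are
#' their means over M, reported with Monte Carlo standard errors. The
#' replication-averaged closed form \eqn{\sigma^2\sum_j 1/\lambda_j(X_i)} is
#' also accumulated as an analytic cross-check of the OLS EMSE.
#'
#' Replications whose drawn design is numerically singular are retried with a
#' fresh draw and counted; more than 1\% retries raises a warning.
#'
#' @param cfg a [simulation_config()].
#' @return object of class \code{"simulation_cell"}: list with
#'   \code{config}, \code{summary} (data frame: rule, emse, emse_se, emae,
#'   emae_se, mean_d), \code{ols_emse_analytic}, \code{retries}.
#' @export
run_cell <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (cfg$n <= cfg$p)
    stop(sprintf("infeasible cell: n = %d must exceed p = %d", cfg$n, cfg$p),
         call. = FALSE)
  set.seed(cfg$seed)
  n <- cfg$n; p <- cfg$p; rho <- cfg$rho; sigma <- cfg$sigma; M <- cfg$M
  rules <- cfg$rules
  R <- length(rules)
  sq_sum <- numeric(R); sq_sum2 <- numeric(R)
  ab_sum <- numeric(R); ab_sum2 <- numeric(R)
  d_sum <- numeric(R)
  analytic_sum <- 0
  retries <- 0L

  draw_design <- function() {
    repeat {
      X <- generate_X(n, p, rho, cfg$corr_mode)
      e <- eigen(crossprod(X), symmetric = TRUE)
      if (min(e$values) > 1e-12 * max(e$values)) {
        return(list(X = X, lam = e$values,
                    D = fix_eigen_signs(e$vectors)))
      }
      retries <<- retries + 1L
    }
  }
  fixed <- if (!cfg$redraw_X) draw_design() else NULL
  invariance_checked <- FALSE

  for (i in seq_len(M)) {
    dd <- if (cfg$redraw_X) draw_design() else fixed
    lam <- dd$lam; D <- dd$D; X <- dd$X
    beta <- D[, 1]
    y <- generate_y(X, beta, sigma)
    alpha_hat <- drop(crossprod(X %*% D, y)) / lam
    beta_hat <- drop(D %*% alpha_hat)
    s2 <- sum((y - X %*% beta_hat)^2) / (n - p)
    analytic_sum <- analytic_sum + sigma^2 * sum(1 / lam)
    dvec <- all_rule_d(alpha_hat, lam, s2, rules)
    alpha_true <- drop(crossprod(D, beta))
    for (r in seq_len(R)) {
      alpha_liu <- (lam + dvec[r]) / (lam + 1) * alpha_hat
      beta_liu <- drop(D %*% alpha_liu)
      se <- sum((beta_liu - beta)^2)
      ae <- sum(abs(beta_liu - beta))
      if (!invariance_checked) {
        # rotation invariance of the squared error, asserted once per cell
        se_canon <- sum((alpha_liu - alpha_true)^2)
        stopifnot(abs(se - se_canon) <= 1e-8 * (1 + se))
        invariance_checked <- TRUE
      }
      sq_sum[r] <- sq_sum[r] + se; sq_sum2[r] <- sq_sum2[r] + se^2
      ab_sum[r] <- ab_sum[r] + ae; ab_sum2[r] <- ab_sum2[r] + ae^2
      d_sum[r] <- d_sum[r] + dvec[r]
    }
  }
  if (retries > 0.01 * M)
    warning(sprintf("%d singular design redraws in %d replications", retries, M))

  emse <- sq_sum / M
  emae <- ab_sum / M
  mc_se <- function(s, s2v) if (M > 1) sqrt(pmax(0, s2v / M - (s / M)^2) / (M - 1)) else rep(NA_real_, R)
  summary <- data.frame(
    rule = rules,
    emse = emse, emse_se = mc_se(sq_sum, sq_sum2),
    emae = emae, emae_se = mc_se(ab_sum, ab_sum2),
    mean_d = d_sum / M,
    stringsAsFactors = FALSE)
  structure(list(config = cfg, summary = summary,
                 ols_emse_analytic = analytic_sum / M,
                 retries = retries),
            class = "simulation_cell")
}

#' @export
print.simulation_cell <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("simulation cell: n=%d p=%d rho=%g sigma=%g M=%d seed=%d\n",
              cfg$n, cfg$p, cfg$rho, cfg$sigma, cfg$M, cfg$seed))
  print(x$summary, row.names = FALSE, digits = 5)
  invisible(x)
}

#' @export
as.data.frame.simulation_cell <- function(x, ...) {
  cfg <- x$config
  cbind(data.frame(n = cfg$n, p = cfg$p, rho = cfg$rho, sigma = cfg$sigma,
                   M = cfg$M, seed = cfg$seed), x$summary)
}

#' Expand factor lists into a list of cell configurations
#'
#' Full factorial over the supplied factor levels, one
#' [simulation_config()] per combination. Each cell's seed is derived from
#' the master seed and the cell's identity (not its position), so permuting
#' levels never changes any cell's result.
#'
#' @param n,p,rho,sigma numeric vectors of factor levels.
#' @param M replications per cell.
#' @param seed master seed.
#' @param ... passed to [simulation_config()] (rules, corr_mode, redraw_X).
#' @return list of \code{"simulation_config"} objects.
#' @export
expand_configs <- function(n, p, rho, sigma, M = 5000, seed = 1L, ...) {
  grid <- expand.grid(n = n, p = p, rho = rho, sigma = sigma,
                      KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    simulation_config(n = g$n, p = g$p, rho = g$rho, sigma = g$sigma, M = M,
                      seed = cell_seed(seed, g$n, g$p, g$rho, g$sigma, M), ...)
  })
}

# deterministic per-cell seed: master seed plus a small hash of the cell
# identity, kept below 2^31 - 1. Tied to the factor values, not the cell's
# position in the grid.
cell_seed <- function(master, n, p, rho, sigma, M) {
  key <- sprintf("n%d|p%d|rho%.10g|sigma%.10g|M%d",
                 as.integer(n), as.integer(p), rho, sigma, as.integer(M))
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 131 + ch) %% 1000000007
  as.integer((as.numeric(master) + h) %% 2147483647)
}

#' Run a grid of simulation cells
#'
#' Runs [run_cell()] on each configuration. Duplicate cells (identical
#' factors) trigger a warning but both are kept. Results are deterministic
#' given each cell's seed.
#'
#' @param configs nonempty list of [simulation_config()] objects.
#' @return object of class \code{"simulation_table"}: list of cells plus a
#'   combined long-format data frame \code{results}.
#' @export
run_grid <- function(configs) {
  if (!length(configs)) stop("empty configuration list", call. = FALSE)
  keys <- vapply(configs, function(cfg)
    sprintf("%d|%d|%g|%g|%d", cfg$n, cfg$p, cfg$rho, cfg$sigma, cfg$M), "")
  if (anyDuplicated(keys))
    warning("duplicate simulation cells in grid; all are run and kept")
  cells <- lapply(configs, run_cell)
  results <- do.call(rbind, lapply(cells, as.data.frame))
  structure(list(cells = cells, results = results), class = "simulation_table")
}

#' @export
print.simulation_table <- function(x, ...) {
  cat(sprintf("simulation table: %d cell(s)\n", length(x$cells)))
  print(x$results, row.names = FALSE, digits = 5)
  invisible(x)
}

#' Write simulation results as long-format CSV
#'
#' Columns: n, p, rho, sigma, M, seed, rule, emse, emse_se, emae, emae_se,
#' mean_d. Numbers are serialized at full precision so round-trips are
#' lossless.
#'
#' @param table a \code{"simulation_table"} or \code{"simulation_cell"}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_results_csv <- function(table, path) {
  df <- if (inherits(table, "simulation_cell")) as.data.frame(table)
        else table$results
  write_csv_full_precision(df, path)
  invisible(path)
}

#' Reshape long results into a wide per-rule table
#'
#' One row per rule, one column per (rho) level within fixed n, p, sigma —
#' the layout used to eyeball EMSE/EMAE across collinearity levels.
#'
#' @param table a \code{"simulation_table"}.
#' @param measure \code{"emse"} or \code{"emae"}.
#' @return data frame with rule rows and one column per cell.
#' @export
wide_table <- function(table, measure = c("emse", "emae")) {
  measure <- match.arg(measure)
  df <- table$results
  df$cell <- sprintf("n%d.p%d.rho%g.sigma%g", df$n, df$p, df$rho, df$sigma)
  out <- stats::reshape(df[c("rule", "cell", measure)],
                        idvar = "rule", timevar = "cell", direction = "wide")
  names(out) <- sub(paste0("^", measure, "\\."), "", names(out))
  rownames(out) <- NULL
  out
}
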