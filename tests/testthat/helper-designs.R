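# small reproducible random designs used across test files
random_design <- function(n, p, seed, intercept = FALSE, rho = 0.5) {
  set.seed(seed)
  X <- generate_X(n, p, rho)
  beta <- stats::rnorm(p)
  y <- drop(X %*% beta) + stats::rnorm(n)
  design_response(X, y, intercept = intercept)
}

# random inputs for the shrinkage rules
random_inputs <- function(seed) {
  set.seed(seed)
  p <- sample(2:10, 1)
  shrinkage_inputs(
    alpha_hat = stats::rnorm(p, sd = stats::runif(1, 0.1, 5)),
    eigenvalues = stats::rexp(p, rate = stats::runif(1, 0.01, 10)) + 1e-6,
    sigma2_hat = stats::rexp(1) + 1e-8)
}

all_d_rules <- paste0("D", 1:10)
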