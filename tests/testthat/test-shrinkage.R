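hand_inp <- shrinkage_inputs(alpha_hat = c(2, 1), eigenvalues = c(10, 0.1),
                             sigma2_hat = 1)

test_that("d components match hand evaluation", {
  # (4-1)/(1/10+4) = 3/4.1 ; (1-1)/(1/0.1+1) = 0
  expect_equal(d_components(hand_inp), c(3 / 4.1, 0), tolerance = 1e-12)
  # zero-coefficient limit: each component (0 - 1)/(1/lambda_j) = -lambda_j
  inp0 <- shrinkage_inputs(c(0, 0), c(10, 0.1), 1)
  expect_equal(d_components(inp0), c(-10, -0.1), tolerance = 1e-12)
})

test_that("q components match hand evaluation", {
  # max(1/lambda) = 10: (4-1)/(10+4) = 3/14 ; (1-1)/(10+1) = 0
  expect_equal(q_components(hand_inp), c(3 / 14, 0), tolerance = 1e-12)
  inp1 <- shrinkage_inputs(c(1, -1, 1), c(5, 2, 0.5), 0.3)
  expect_equal(q_components(inp1), c(0, 0, 0))
})

test_that("aggregated rules match hand evaluation to 1e-6", {
  # hand fractions: d components (3/4.1, 0); q components (3/14, 0)
  expect_equal(estimate_d(hand_inp, "D1")$d, 3 / 4.1, tolerance = 1e-6)  # 0.731707
  expect_equal(estimate_d(hand_inp, "D2")$d, 3 / 8.2, tolerance = 1e-6)  # 0.365854
  expect_equal(estimate_d(hand_inp, "D3")$d, mean(c(3 / 4.1, 0)), tolerance = 1e-12)
  expect_equal(estimate_d(hand_inp, "D4")$d, 3 / 4.1, tolerance = 1e-6)
  expect_equal(estimate_d(hand_inp, "D5")$d, 3 / 28, tolerance = 1e-6)   # 0.107143
  expect_equal(estimate_d(hand_inp, "D6")$d, 3 / 28, tolerance = 1e-6)
  expect_equal(estimate_d(hand_inp, "D7")$d, 3 / 14, tolerance = 1e-6)   # 0.214286
  # quantile family: denominator 1/0.1 + 4 = 14; quantiles of {1, 4}
  expect_equal(estimate_d(hand_inp, "D8")$d, 0, tolerance = 1e-12)
  expect_equal(estimate_d(hand_inp, "D9")$d, 0.75 / 14, tolerance = 1e-6)  # 0.053571
  expect_equal(estimate_d(hand_inp, "D10")$d, 1.5 / 14, tolerance = 1e-6)  # 0.107143
  expect_equal(estimate_d(hand_inp, "Dgamma", gamma = 0.5)$d,
               estimate_d(hand_inp, "D10")$d, tolerance = 1e-12)
})

test_that("rule tokens are case-insensitive and validated", {
  expect_equal(estimate_d(hand_inp, "d1")$d, estimate_d(hand_inp, "D1")$d)
  expect_error(estimate_d(hand_inp, "D11"), "unknown")
  expect_error(estimate_d(hand_inp, "Dgamma"), "gamma")
  expect_error(estimate_d(hand_inp, "Dgamma", gamma = 1.5), "\\[0, 1\\]")
  expect_error(estimate_d(hand_inp, "D2", gamma = 0.5), "only accepted")
})

test_that("all rules return 0 when coefficients vanish", {
  inp0 <- shrinkage_inputs(rep(0, 4), c(4, 3, 2, 1), 1)
  for (r in all_d_rules) expect_equal(estimate_d(inp0, r)$d, 0)
})

test_that("degenerate inputs are rejected", {
  expect_error(shrinkage_inputs(numeric(0), numeric(0), 1), "length zero")
  expect_error(shrinkage_inputs(c(1, 2), c(1, -1), 1), "strictly positive")
  expect_error(shrinkage_inputs(c(1, 2), c(1, 1), 0), "strictly positive")
  expect_error(shrinkage_inputs(c(1, 2), c(1, 2, 3), 1), "same length")
})

test_that("every rule stays in [0,1] and obeys the orderings (property sweep)", {
  n_cases <- 2500
  for (i in seq_len(n_cases)) {
    inp <- random_inputs(seed = i)
    d <- liushrink:::all_rule_d(inp$alpha_hat, inp$eigenvalues,
                                inp$sigma2_hat, all_d_rules)
    expect_true(all(is.finite(d)))
    if (any(d < 0) || any(d > 1)) {
      fail(sprintf("rule outside [0,1] at seed %d: %s", i,
                   paste(sprintf("%s=%.17g", names(d), d), collapse = " ")))
    }
    # quantile family monotone in gamma
    if (!(d["D8"] <= d["D9"] + 1e-12 && d["D9"] <= d["D10"] + 1e-12))
      fail(sprintf("D8<=D9<=D10 violated at seed %d", i))
    # median/mean <= max within each family
    if (!(d["D2"] <= d["D4"] + 1e-12 && d["D3"] <= d["D4"] + 1e-12))
      fail(sprintf("D2,D3<=D4 violated at seed %d", i))
    if (!(d["D5"] <= d["D7"] + 1e-12 && d["D6"] <= d["D7"] + 1e-12))
      fail(sprintf("D5,D6<=D7 violated at seed %d", i))
  }
  succeed()
})

test_that("Dgamma is nondecreasing in gamma", {
  for (i in 1:50) {
    inp <- random_inputs(seed = 1000 + i)
    g <- sort(runif(6))
    dg <- vapply(g, function(gg) estimate_d(inp, "Dgamma", gamma = gg)$d, 0)
    expect_true(all(diff(dg) >= -1e-12))
  }
})

test_that("rules are invariant to permuting (alpha_j, lambda_j) pairs", {
  set.seed(77)
  for (i in 1:20) {
    inp <- random_inputs(seed = 2000 + i)
    perm <- sample(length(inp$alpha_hat))
    inp_p <- shrinkage_inputs(inp$alpha_hat[perm], inp$eigenvalues[perm],
                              inp$sigma2_hat)
    for (r in all_d_rules) {
      expect_equal(estimate_d(inp_p, r)$d, estimate_d(inp, r)$d,
                   tolerance = 1e-12)
    }
  }
})

test_that("D1 pairs the max alpha^2 with the max eigenvalue independently", {
  # argmax alpha^2 (j=2) differs from argmax lambda (j=1)
  inp <- shrinkage_inputs(c(0.5, 3), c(10, 0.1), 1)
  expect_equal(estimate_d(inp, "D1")$d, (9 - 1) / (1 / 10 + 9), tolerance = 1e-12)
})

test_that("signed quantile base is available and clipped to [0,1]", {
  # literal signed reading can exceed 1 before the clip
  inp <- shrinkage_inputs(0.5, 1, 0.01)
  raw <- (0.5 - 0.01) / (0.01 / 1 + 0.25)
  expect_gt(raw, 1)
  expect_equal(estimate_d(inp, "Dgamma", gamma = 0.5,
                          quantile_base = "alpha")$d, 1)
  d_sq <- estimate_d(inp, "Dgamma", gamma = 0.5)$d
  expect_lte(d_sq, 1)
})

test_that("vectorized rules equal a naive per-index loop to 1e-12", {
  naive_d <- function(a, lam, s2) {
    p <- length(a)
    dj <- numeric(p); qj <- numeric(p)
    for (j in seq_len(p)) {
      dj[j] <- (a[j]^2 - s2) / (s2 / lam[j] + a[j]^2)
      qj[j] <- (a[j]^2 - 1) / (max(1 / lam) + a[j]^2)
    }
    a2s <- sort(a^2)
    qn <- function(g) unname(quantile(a2s, g, type = 7))
    den <- max(s2 / lam) + max(a^2)
    c(D1 = max(0, (max(a^2) - s2) / (s2 / max(lam) + max(a^2))),
      D2 = max(0, median(dj)), D3 = max(0, sum(dj) / p), D4 = max(0, max(dj)),
      D5 = max(0, median(qj)), D6 = max(0, sum(qj) / p), D7 = max(0, max(qj)),
      D8 = max(0, (qn(0) - s2) / den), D9 = max(0, (qn(0.25) - s2) / den),
      D10 = max(0, (qn(0.5) - s2) / den))
  }
  for (i in seq_len(1000)) {
    inp <- random_inputs(seed = 5000 + i)
    d_pkg <- liushrink:::all_rule_d(inp$alpha_hat, inp$eigenvalues,
                                    inp$sigma2_hat, all_d_rules)
    d_ref <- naive_d(inp$alpha_hat, inp$eigenvalues, inp$sigma2_hat)
    expect_equal(unname(d_pkg), unname(d_ref), tolerance = 1e-12)
  }
})
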