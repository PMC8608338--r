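Package: liushrink
Title: Liu Regression with Quantile-Based Shrinkage-Parameter Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Liu regression for multicollinear linear models, with the full
    family of data-driven rules for choosing the shrinkage parameter d,
    including a quantile-based family designed for high to severe
    multicollinearity. Provides ordinary least squares and canonical
    (eigen) form estimation, condition-number diagnostics, closed-form
    mean-squared-error expressions, mean prediction intervals for both
    ordinary least squares and Liu fits, and a Monte Carlo engine that
    evaluates estimated mean squared error and mean absolute error of all
    rules over factorial designs of sample size, dimension, collinearity
    level and error variance. Includes a command-line interface for fitting,
    diagnostics, interval estimation and simulation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
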