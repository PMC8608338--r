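# liushrink

Liu regression for multicollinear linear models, with a full family of
data-driven rules for choosing the shrinkage parameter — including a
quantile-based family built for **high to severe multicollinearity** — plus
condition-number diagnostics, closed-form risk expressions, mean prediction
intervals, and a Monte Carlo engine for comparing estimators by estimated
mean squared error (EMSE) and mean absolute error (EMAE).

## Who this is for

Analysts fitting linear models `y = Xβ + ε` whose predictors are strongly
correlated — a routine situation in biostatistics and epidemiological
modelling (e.g. chemical concentrations, collinear exposure measures). OLS
is unbiased there but its total variance `σ² Σⱼ 1/λⱼ` blows up as the
smallest eigenvalue of `X′X` approaches zero. The **Liu estimator**

```
β̂_LIU(d) = (X′X + I)⁻¹ (X′X + d·I) β̂_OLS ,   0 ≤ d ≤ 1
```

shrinks OLS linearly in `d` (`d = 1` recovers OLS) and dominates it on mean
squared error for well-chosen `d`. The package implements the rule family
D1–D7 (componentwise optimum aggregates and their worst-case-eigenvalue
variants) and the quantile family

```
Dγ = max(0, (Qγ − σ̂²) / (σ̂²/λ_min + max_j α̂ⱼ²))
```

where `Qγ` is the empirical γ-quantile of the squared canonical coefficients
`α̂ⱼ²`; `D8`, `D9`, `D10` are `Dγ` at γ = 0 (minimum), 0.25 and 0.5. At
severe collinearity the trailing `α̂ⱼ²` are pure noise and their low
quantiles fall below `σ̂²`, so the rule drives `d` toward 0 exactly where
hard shrinkage is optimal — `D8` attains the lowest EMSE/EMAE of the whole
family in the Monte Carlo comparisons.

## Worked example

Create a synthetic high-collinearity dataset (30 rows, 4 predictors, shaped
like the classic tobacco-blend heat data), diagnose it, fit all estimators,
and compare prediction intervals — from R or the CLI
(`Rscript inst/cli/liushrink.R <subcommand> ...`):

```r
library(liushrink)
make_fixture("blends.csv", seed = 2026)
#> fixture written to blends.csv (CN = 32.2863, 35 attempts)

d <- read_design_csv("blends.csv", response = "y")
condition_number(d)                      # sqrt mode, centered design
#> [1] 34.25571
classify_collinearity(condition_number(d))
#> [1] "high"

cli_main(c("fit", "blends.csv", "--response", "y", "--rules", "D1,D5,D8", "--quiet"))
#> estimator,d,mse,x1,x2,x3,x4
#> OLS,NA,9.14815,1.400723,-0.265304,2.719537,-1.60204
#> D1,0.935606,8.23737,1.352613,-0.221621,2.599092,-1.48001
#> D5,0.000000,8.44508,0.653616,0.413059,0.849089,0.29296
#> D8,0.000000,8.44508,0.653616,0.413059,0.849089,0.29296

cli_main(c("interval", "blends.csv", "--response", "y",
           "--x0", "0.2,0.1,0.3,0.4", "--rules", "OLS,D8", "--quiet"))
#> estimator,d,lower,upper,difference
#> OLS,NA,-0.420183,1.016831,1.437014
#> D8,0,0.130158,0.871996,0.741837
```

Reading the output: the `fit` table lists each rule's estimated `d`, the
plug-in analytic MSE `σ̂²Σ(λⱼ+d)²/(λⱼ(λⱼ+1)²) + (d−1)²Σα̂ⱼ²/(λⱼ+1)²`
(every Liu rule beats the OLS value 9.15 here), and the shrunken
coefficients. The `interval` table shows that the Liu mean-prediction
interval at `x0` is roughly half the OLS width (0.74 vs 1.44) — `Q_d`
contracts every eigendirection, so Liu intervals are never wider than OLS.

A Monte Carlo comparison at one design point:

```r
cfg <- simulation_config(n = 25, p = 4, rho = 0.999, sigma = 1, M = 2000, seed = 7)
run_cell(cfg)
#> simulation cell: n=25 p=4 rho=0.999 sigma=1 M=2000 seed=7
#>  rule       emse   emse_se     emae   emae_se    mean_d
#>   OLS 145.774838 3.1024488 18.95981 0.1975468 1.0000000
#>   D1  142.844883 3.1034105 18.65055 0.2010443 0.9687525
#>   ...
#>   D8    0.080838 0.0014326  0.45094 0.0041385 0.0008427
#>   D9    1.126429 0.0950260  1.13002 0.0320926 0.0329851
#>   D10   5.122580 0.3013590  2.65376 0.0639495 0.1049260
```

At this severe collinearity level OLS has EMSE ≈ 146 while the γ = 0
quantile rule `D8` reaches ≈ 0.08 — three orders of magnitude smaller — with
the other rules in between. `expand_configs()` + `run_grid()` (or the `grid`
CLI subcommand with a config file) run full factorials over
`n ∈ {25,...,200}`, `p ∈ {4,...,32}`, `ρ ∈ {0.90,...,0.9999}`,
`σ ∈ {0.5, 1, 2}` with per-cell seeds derived from the cell identity, and
`write_results_csv()` / `wide_table()` export long and per-rule wide tables.

See the methods vignette (`vignettes/liu-shrinkage-methods.Rmd`) for the
model, the definitional choices behind the quantile rules, the simulation
design and its conventions, and known limitations.

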