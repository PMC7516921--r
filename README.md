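# gofselect

Model selection criteria upgraded with goodness-of-fit tests, for data with
additive noise of **known, possibly non-zero-mean distribution**.

## The problem

The residual forms of the two standard selection criteria,

    AIC = n·ln(MSE) + 2k          BIC = n·ln(σ²(ε)) + k·ln(n)

(with MSE the mean squared residual, σ²(ε) the residual variance, k the
parameter count and n the sample size) are only valid surrogates of the
likelihood forms under zero-mean Gaussian noise. Under noise that is not
symmetric about zero — Poisson or gamma-distributed errors are the common
cases in counting and sensing applications — a least-squares fit wins the
MSE contest by driving the residual mean to zero, which is precisely what
the residuals of the *true* model should not do. Classic AIC then
systematically prefers an over-adapted competitor to the generating model.

`gofselect` implements the upgraded criteria

    AIC_H  = n·ln(MSE/H) + 2k                 BIC_H  = n·ln(σ²/H) + k·ln(n)
    AIC_GF = n·ln(MSE·(1+Z²)/H) + 2k          BIC_GF = n·ln(σ²·(1+Z²)/H) + k·ln(n)

where H is the Shannon entropy of the binned residual distribution
(rewarding residuals without leftover structure) and Z is a
goodness-of-fit discrepancy — Kolmogorov–Smirnov, Anderson–Darling or
Pearson chi-squared — between the residual sample and the known noise
distribution. The better the model, the more its residuals resemble the
noise, the smaller Z, the smaller the criterion. The package is aimed at
anyone comparing parametric surface fits (exponential, polynomial, power
law, or custom models) when the noise statistics are known or measurable.

It ships with the four reference noise families (Gaussian, uniform,
Poisson, gamma), Levenberg–Marquardt fitting with deterministic
multi-start initialization, and a fully seeded simulation benchmark that
pits the generating model ("Correct") against a least-squares competitor
("Alternative") over scans of sample size and noise intensity.

## Worked example

Power-law data `z = x³/y` on 0 < x < 10, 0.5 < y < 10 with Poisson(λ = 10)
noise added *uncentered*; the Alternative is the same power-law family
refit to the data, so it absorbs part of the noise mean:

```r
library(gofselect)
ref <- noise_spec("poisson", lambda = 10)
cfg <- benchmark_config("power_law", ref, n_grid = c(200, 1000),
                        reps = 5, seed = 1)
run_comparison(cfg, n = 1000, rep_seed = 3)[, c(1:3, 6:9)]
#>    model_label criterion value    mse variance entropy z_score
#> 1      Correct       aic  4693 108.50    10.53   2.608  0.1281
#> 2      Correct       bic  2375 108.50    10.53   2.608  0.1281
#> ...
#> 7  Alternative       aic  3967  52.51    35.16   3.101  0.5429
#> ...
#> 12 Alternative    bic_gf  2707  52.51    35.16   3.101  0.5429
```

Read it like this: the Correct model's residuals *are* the Poisson draws,
so their MSE (≈ 110 = variance 10 + mean² 100) looks bad and classic AIC
picks the Alternative (3967 < 4693), whose fit has soaked up half the
noise mean (MSE ≈ 53). But the Alternative's residuals no longer resemble
the noise: its KS discrepancy is 0.54 versus 0.13, and BIC_GF — built on
the variance, inflated for the distorted fit, and scaled by (1 + Z²) —
correctly ranks the generating model first (1433 < 2707). Over the scan:

```r
selection_rates(scan_sample_size(cfg))
#>    n_or_intensity criterion correct_rate  reps
#>  1            200 aic                  0     5
#>  4            200 bic                  1     5
#>  5            200 bic_gf               1     5
#>  7           1000 aic                  0     5
#> 10           1000 bic                  1     5
#> 11           1000 bic_gf               1     5
#> ...
```

`autoplot()` on any scan draws the criterion-vs-n curves per model;
`tidy()`/`glance()` expose fitted models in broom style. A thin CLI over
the same functions lives at `inst/cli/gofselect.R`
(`Rscript .../gofselect.R bench --case power_law --noise poisson ...`);
identical invocations produce byte-identical CSVs.

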