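# pmgflow

Quantifying **pollen-mediated gene flow (PMGF)** from concentric field
experiments: a central block of herbicide-resistant pollen donors, eight
compass arms of susceptible receptor stations, and progeny screened with a
discriminating herbicide rate so that survivor fractions estimate the
gene-flow frequency per (year, direction, distance) cell.

For weed scientists and quantitative ecologists who need to estimate how
far resistance alleles travel on pollen, how anisotropic that dispersal is,
and how many seedlings must be screened to detect rare gene flow at all.

## The model

Grouped binomial screening counts are fitted with a **double exponential
decay** on the logit of the gene-flow frequency *p* at distance *d*:

    logit(p) = β0 + exp(β1 + γ1·d) + exp(β2(dir:yr) + γ2(dir:yr)·d)

The steep first term (γ1) captures the sharp near-source peak of
wind-pollination kernels; the shallow second term (γ2) carries the fat,
leptokurtic tail, with its intercept and rate coded by direction, year and
their interaction. `inv_logit(β0)` is the far-field asymptote. The model is
fitted by direct maximum likelihood (multi-start BFGS with analytic
gradients plus Newton polishing), ranked against 37 simpler and
wind-covariate alternatives by AIC = −2LL + 2K, and post-processed into:

- **O50 / O90** — distances where the predicted frequency falls to 50% /
  10% of its value at the closest analyzed distance, with
  parametric-bootstrap confidence intervals;
- **Pearson χ²** goodness of fit for grouped binomial data;
- **detection power** `1 − (1 − p)^n` and the minimum screening sample
  size for a target power;
- descriptive stages: pooled frequency-by-distance tables, flowering
  synchrony (both published conventions), wind roses (sector frequency,
  mean speed, wind run), and PMGF–wind correlations.

A seeded synthetic-data generator reproduces the statistical structure of
the field study (kernel-driven binomial counts over the concentric design,
S/SE-prevailing hourly winds, logistic flowering curves), so every stage is
testable without the original raw data.

## Worked example

```r
library(pmgflow)

# published per-distance screening counts, pooled over directions
pooled_frequency_by_distance(published_counts(), year = 2014)[1:4, ]
#>   year distance_m total_screened total_resistant frequency
#> 1 2014        0.5           2591            1546 0.5966808
#> 2 2014        1.0           2157            1154 0.5350023
#> 3 2014        2.0           3201            1281 0.4001874
#> 4 2014        4.0           2456             781 0.3179967

# the packaged reference kernel: ~94% survival at the donor edge decaying
# to the ~3% far-field asymptote
cf <- reference_coefficients(full = FALSE)
round(predict_frequency(cf, c(0, 1, 10, 50)), 4)
#> [1] 0.9371 0.7799 0.5331 0.0827

# simulate a two-year study from the full published coefficient set and
# refit the direction-by-year model
truth <- generator_truth(n_per_cell = 5000, seed = 42)
rec   <- generate_screening(truth)
fit   <- fit_decay(rec, model_spec(2, "direction:year", "direction:year"),
                   seed = 42)
fit
#> PMGF decay model fit: dexp|b2:direction:year|g2:direction:year
#>   cells: 152   K: 35   logLik: -644.426   AIC: 1358.851
#>   converged: TRUE (scaled gradient 6.89e-13)

summary(fit)[1:3, ]
#>     term   estimate  std_error    z_value      p_value
#> 1  beta0 -3.5068797 0.02112369 -166.01643 0.000000e+00
#> 2  beta1  0.2470723 0.02767341    8.92815 4.332004e-19
#> 3 gamma1 -5.2842250 0.27999903  -18.87230 1.927324e-79

# distance at which gene flow halves along the East arm, with bootstrap CI
o50 <- reduction_distance(fit, "E", "2014", 0.5, reference_distance_m = 0.5)
ci  <- reduction_ci(fit, "E", "2014", 0.5, reference_distance_m = 0.5,
                    n_boot = 1000, seed = 42)
sprintf("O50 East 2014: %.2f m (95%% CI %.2f-%.2f)", o50, ci[1], ci[2])
#> "O50 East 2014: 15.16 m (95% CI 14.82-15.52)"

# screening effort needed to detect gene flow at frequency 0.001
min_sample_size(0.001, power_target = 0.8)
#> [1] 1609
```

The estimates recover the generating coefficients (β0 = −3.50, β1 = 0.26,
γ1 = −5.35, ...) within sampling error, and the fitted kernel's O50 follows
from the *printed two-decimal* coefficient table — reference computations,
not reproductions of the original full-precision fit.

`run_pipeline(pipeline_config(...))` chains every stage
(simulate/load → summarize → select → fit → predict) into tidy CSV report
tables plus a JSON manifest that fully re-executes the run.

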