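# bznmf

Automatic decomposition of composite decay signals by
Boltzmann-constrained non-negative matrix factorization.

## What it is for

Time-resolved spectroscopy and fluorescence correlation spectroscopy
produce sets of non-negative signal curves, each a sum of a few
exponential relaxation components `h_r * exp(-t / tau_r)` whose time
constants carry the physics (diffusion times, energy-transfer times).
Given an `M x N` matrix `I` of `N` such curves sampled at `M` common time
points, `bznmf` fits the factorization

```
I ~ W H,   w_jr = exp(-t_j / tau_r),   h_ri >= 0
```

by multiplicative updates under either a least-squares or a generalized
Kullback-Leibler objective, and selects the number of components `R`
automatically by minimizing

```
AIC(R)  = N ln(D_LSE(R) / N) + 2R          (Gaussian / least squares)
AIC(R)  = 2 D_KL(R) + 2R                   (Poisson / generalized KL)
AICc(R) = AIC(R) + 2R(R+1) / (N - R - 1)   (finite-sample correction)
```

over a rank sweep (default `1..20`), with a k-fold cross-validation
selector as baseline.  A generator for ground-truthed synthetic
multi-exponential data and parameter-recovery error-rate summaries
(`D_tau`, `D_h`: mean relative absolute deviations of time constants and
existence ratios) are included, so the whole simulation study behind the
method can be rerun.

It is aimed at experimentalists who have many curves from one sample and
want rank and parameters decided by the data rather than by hand.

## Worked example

```r
library(bznmf)

# three-component decays: tau = 10, 100, 1000, equal weights,
# 50 sequences at 145 log-spaced time points, +/-10% relative noise
sim <- simulate_signals(sim_config(sim_rank = 3, dims = 145, seed = 21))

report <- run_decompose(sim$signal, criterion = "aic",
                        rank_range = c(1, 8),
                        config = fit_config(seed = 1))
report
#> <bz_report> criterion aic_lse selected rank 3 (rmse 0.0245)
#>        tau ratio_mean ratio_sd
#>    10.0343     0.3303   0.0250
#>   101.9860     0.3383   0.0250
#>  1004.0000     0.3314   0.0081

ev <- error_rates(list(report$fit$factorization),
                  taus_true = c(10, 100, 1000),
                  ratios_true = rep(1/3, 3))
ev
#> <bz_evaluation> 1 set(s), 50 sequences: D_tau = 0.910%, D_h = 4.714%
```

The selected rank is 3; the fitted time constants land within a percent
or two of the simulation truth, each sequence's existence ratios recover
the equal 1/3 weights, and the error-rate summary condenses that into
the mean relative deviations of the time constants (0.91%) and of the
per-sequence existence ratios (4.7%).

The same pipeline runs from a shell on delimited text (first column the
times, one column per sequence):

```sh
Rscript inst/cli/bznmf.R simulate --sim-rank 2 --dims 75 --seed 1 --out curves.tsv
Rscript inst/cli/bznmf.R decompose curves.tsv --criterion aic --rank-max 20 --out results/
```

See `vignettes/bznmf-methods.Rmd` for the model, the selection criteria,
the initialization/stopping choices and known limitations.

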