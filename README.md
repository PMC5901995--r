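# seismicmove

Predator movement analysis along regenerating seismic lines.

Seismic lines — narrow (~8 m) linear clearings cut through boreal forest for
oil and gas exploration — act as travel corridors for wolves and grizzly
bears, increasing their overlap with threatened woodland caribou. As
vegetation regrows, the management question is whether regeneration ever
erases the predator response, and which lines to prioritise for active
restoration. `seismicmove` implements a two-scale answer for researchers and
restoration planners working with GPS telemetry and mapped line networks:

**Broad scale — step selection functions.** Each observed movement step is
matched with K = 10 available steps sharing its start point, and selection
is estimated by conditional logistic regression,

    l(b) = sum_s w_s [ b'x_used(s) - log sum_{j in s} exp(b'x_j) ],

with inverse fix-probability weights `w_s`, cluster-robust sandwich standard
errors over independence clusters (5-day span for wolves, 24 h for bears),
QIC_U = -2l + 2p model competition across M1–M5, inverse-variance pooling of
per-individual coefficients, and rank-frequency k-fold cross-validation
(mean r_s1 vs r_s0 over 100 80/20 splits). Line covariates are
exponential-decay distance `eDist = 1 - exp(-0.002 d)`, least-cost mean
vegetation height `Veght` per 100-m segment, wetness decay
`eWAM = 1 - exp(-1.55 w)`, moving-window line density, and majority
landcover.

**Fine scale — movement rates.** Steps ending within 100 m of a line enter
Gaussian random-intercept mixed models of log rate (m/h) in
`log(Veght + 1)`, season and forest cover, compared by AICc and summarised
by marginal/conditional R². Where height matters, a two-segment continuous
hinge regression locates the breakpoint, with a 1,000-replicate bootstrap
percentile CI (reported as a half-width).

A synthetic landscape/telemetry generator with known ground truth (selection
coefficients, stationary bouts, movement-rate breakpoints) stands in for the
proprietary GPS and LiDAR inputs, so the entire pipeline is testable by
parameter recovery. See the methods vignette
(`vignettes/seismic-line-movement.Rmd`) for the models, assumptions and
design choices.

## Worked example

```r
library(seismicmove)

# a 4 x 4 km landscape at the study's line density and height structure
L <- make_landscape(seed = 7, extent_m = 4000)
L
#> <seismic_landscape> 4 x 4 km, 11 lines (23.7 km, 1.48 km/km2), 237 segments
#>   segment veght: mean 0.79 m, 72% below 1 m

ci <- covariate_index(L)

# eight wolves attracted to low-vegetation lines:
# beta_eDist = -1 (attraction), beta_eDist:Veght = +0.5 (weaker at regrowth)
truth <- simulation_truth(beta = c(eDist = -1, "eDist:Veght" = 0.5), seed = 7)
fixes <- do.call(rbind, lapply(1:8, function(i)
  simulate_ssf_track(L, truth, n_steps = 200, seed = 700 + i,
                     animal_id = sprintf("W%02d", i),
                     group = sprintf("P%d", (i %% 2) + 1), cov_index = ci)))

res <- run_ssf_analysis(fixes, L, default_config(cv_reps = 30, seed = 7),
                        cov_index = ci)
res
#> Step-selection analysis
#>   best model: M2 (QIC_U weight 0.645)
#> Population-averaged SSF coefficients (8 individuals)
#>          term    beta ci_halfwidth n_individuals
#> 1       eDist -0.9968       0.3535             8
#> 2       Veght -0.0290       0.0551             8
#> 3 eDist:Veght  0.4588       0.2251             8
#>   k-fold CV: mean r_s1 0.590, mean r_s0 -0.080
```

QIC_U picks the generating structure (M2: `eDist * Veght`), the pooled
coefficients recover the simulated truth (-1 and +0.5) within their 95%
half-widths, and cross-validation ranks used steps far better than random
available steps (r_s1 >> r_s0 ~ 0).

```r
# fine scale: a movement-rate dataset with a 0.7-m breakpoint
rt <- simulation_truth(breakpoint = 0.7, seed = 7)
rd <- simulate_rate_data(rt, n_obs = 250, noise_sd = 0.25, seed = 8,
                         sd_individual = 0.15, n_individuals = 10,
                         slope_left = 0.8, slope_right = -1.5)
pw <- piecewise_fit(rd$log_veght, rd$log_rate)
ci_bp <- bootstrap_breakpoint_ci(pw, n_boot = 1000, seed = 9)
sprintf("breakpoint %.2f m (95%% CI half-width %.2f m)",
        expm1(pw$breakpoint), diff(expm1(ci_bp$ci)) / 2)
#> "breakpoint 0.71 m (95% CI half-width 0.05 m)"
```

Movement rate rises with height up to ~0.7 m of regrowth and falls beyond
it — the estimated hinge recovers the simulated kink to within the
bootstrap interval.

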