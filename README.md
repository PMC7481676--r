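# boarest

Joint Bayesian estimation of **seasonal animal density, habitat
preference and trap catchability** from camera-trap data and municipal
harvest records, built around the random encounter and staying time
(REST) model. The package targets wildlife managers and quantitative
ecologists working with cryptic, individually unrecognisable species —
wild boar being the motivating case — who have (a) passage counts and
staying times from cameras watching a fixed focal area and (b) monthly
counts of active traps and captures per management unit.

## The model

Density at camera *i* in month *m* follows the REST equation

    D[i,m] = N[i,m] / A  ×  E[T_m] / S_m

(*N* passages through the focal area *A* = √3/4·1.9² m²; *E[T]* the
expected staying time, fitted by WAIC-selected parametric distribution;
*S* the active time = deployment × daily activity proportion from a von
Mises circular kernel density of detection times). Habitat enters
through a log-linear model on the first four principal components of
six standardised land-use percentages,

    D[i,m] = exp(α0[m] + Σₑ αₑ[m]·PCₑ[i]),      αₑ ~ U(−3, 3)

with passage counts negative binomial around the implied mean. The same
coefficients evaluated on every 1 km² grid cell, averaged per
management unit with forest-area weights, connect to the harvest data
through a Poisson catch-effort model

    C[u,m,t] ~ Poisson( q[m,t] · R[u,m] · D[u,m] ),   q ~ U(0, 1)

whose proportionality constant *q* is the catchability of trap type *t*
(box or snare). Everything is sampled jointly by an adaptive
Metropolis-within-Gibbs sampler (50 000 iterations, 10 000 burn-in,
thinning 20, 3 chains by default) with split-chain Rhat < 1.1 as the
convergence criterion. See `vignettes/boarest-methods.Rmd` for the full
specification, priors and design rationale.

## Worked example

Simulate a complete synthetic study with known truth, fit it, and read
off the posteriors:

```r
library(boarest)

study <- simulate_study("small", seed = 1)   # 30 cameras, 100 cells,
                                             # 6 units, Jun-Aug
data  <- prepare_joint_data(study)
model <- build_joint_model(data, study$config)
fit   <- run_mcmc(model, iterations = 5000, burn_in = 1000, thin = 5,
                  chains = 3, seed = 1)
fit
#> <boarest_fit> 74 quantities, 3 chains x 800 draws (lognormal staying times)
#>   max Rhat = 1.015 (converged, < 1.1)

fit_summary(fit, "density")   # animals per km² per management unit
#> # A tibble: 18 × 11
#>   unit_id month term             mean    sd  q2.5   q25 median   q75 q97.5  rhat
#> 1 u01     Jun   density[u01,Ju…  23.1  6.11  14.3  18.8   22.0  26.2  37.9  1.00
#> 2 u02     Jun   density[u02,Ju…  20.8  5.45  12.8  17.1   19.9  23.6  33.8  1.00
#> ...

fit_summary(fit, "catchability")[, c("month", "trap_type", "median", "q25", "q75")]
#> # A tibble: 6 × 5
#>   month trap_type  median     q25    q75
#> 1 Jun   box       0.0169  0.0140  0.0198
#> 2 Jun   snare     0.00969 0.00818 0.0115
#> 3 Jul   box       0.0221  0.0187  0.0258
#> 4 Jul   snare     0.0167  0.0141  0.0199
#> 5 Aug   box       0.0161  0.0120  0.0213
#> 6 Aug   snare     0.00991 0.00712 0.0134
```

The generating truth here was box catchability 0.02 and snare 0.012:
each monthly 50% interval brackets or sits near its truth, and unit
densities, habitat coefficients (`fit_summary(fit, "alpha")`) and
staying-time means are recovered the same way. `autoplot(fit,
"density")`, `autoplot(fit, "alpha")` and `autoplot(fit,
"catchability")` draw the posterior-median seasonal series with 50%
credible whiskers; `tidy(fit)` returns every quantity as a tibble.

A command-line interface wraps the same pipeline for file-based work:

```sh
inst/cli/boarest simulate --out data/ --preset full --seed 1
inst/cli/boarest fit --data data/ --out results/ --family auto
inst/cli/boarest summarize --draws results/
```

`fit` writes posterior summary CSVs (densities per unit/month, habitat
coefficients per month/age, catchability per month/trap type), an Rhat
report, per-chain draws and a run log with the seed, and exits non-zero
if any Rhat ≥ 1.1 (override with `--allow-nonconverged`).

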