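# dimrmax

Demographic-invariant estimation of the annual maximum population growth
rate for long-lived, late-maturing populations, with northwest Atlantic
loggerhead turtles (*Caretta caretta*) as the packaged, fully reproducible
worked system.

## Who this is for

Conservation and protected-species scientists who need a defensible
distribution of the maximum population growth rate — the quantity behind
removal limits (e.g. Potential Biological Removal) and recovery targets —
for populations where trend data cannot identify it. The method needs only
two life-history parameters: age-at-first-reproduction and constant adult
survival.

## The method

The core is the demographic invariant `r_max * T_op ≈ a_raT`, with `a_raT`
a dimensionless allometric constant close to 1 across taxa (body-mass
scalings of the growth rate and generation time cancel). With adult
survival `s` constant after maturation at age `α`, the optimal generation
time is `T_op = α + s / (λ_max − s)`, yielding a fixed-point equation for
the finite annual maximum growth rate:

    λ_max = exp{ a_raT · [ α + s / (λ_max − s) ]⁻¹ }

so that `λ_max^T_op = exp(a_raT)`: a population can no more than ~triple
per generation. The package reports `R_max = λ_max − 1`.

The pipeline (all stages independently usable):

1. **Projection-matrix demography** (`eigen_analysis`, `generation_time`,
   `filter_optimal`) and a **Bayesian log-log regression**
   (`fit_allometry`) verifying `a_raT ≈ 1` from `(r_max, T_op)` pairs of
   turtle matrix population models (slope fixed at −1; free-slope check
   included).
2. **Growth meta-analysis** (`fit_growth_meta`): Gibbs-sampled bivariate
   normal–lognormal hierarchy over nine published von Bertalanffy
   parameter pairs `(L_inf, ln k)` (vague normal priors on the means,
   Wishart prior on the precision matrix).
3. **Age slicing** (`slice_ages`): inverts the growth curve to turn the
   neophyte-nester size distribution (Normal, 91.2 ± 4.72 cm SCL) into an
   age-at-first-reproduction distribution, anchoring `t0` at a 4.5 cm
   hatchling and filtering lengths ≥ `L_inf` and ages > 100 years.
4. **Monte Carlo propagation** (`run_monte_carlo`): 10⁶ draws of
   `a_raT ~ lognormal(mean 1, sd 0.4)`, `s ~ truncated Beta(mean 0.841,
   sd 0.035, bounds 0.770–0.925)` and resampled `α`, each solved through
   the fixed point; summaries by mean/median/KDE mode and 95%
   highest-density interval.

`rmax_dim()` runs 2–4 end-to-end; `run_pipeline()` does the same from a
YAML/JSON config and writes draws, summaries and a seeded run manifest.

## Worked example

```r
library(dimrmax)
fit <- rmax_dim(n = 1e6, seed = 1)   # packaged loggerhead inputs
print(fit)
```

```
Demographic-invariant maximum population growth rate
  growth meta-analysis: 9 studies; age slicing + Monte Carlo: n = 1000000
  R_max (/year): mean 0.02359  median 0.0212  mode 0.01762  95% HDI [0.006148, 0.0464]  (n = 1000000)
```

```r
summary(fit)
```

```
L_inf_bar: mean 101.1  median 101.2  mode 101.2  95% HDI [96.3, 105.8]  (n = 32000)
ln_k_bar:  mean -2.829  median -2.831  mode -2.823  95% HDI [-3.165, -2.441]  (n = 32000)
alpha (years): mean 40.84  median 38.72  mode 35.96  95% HDI [21.64, 64.85]  (n = 964865)
R_max (/year): mean 0.02359  median 0.0212  mode 0.01762  95% HDI [0.006148, 0.0464]  (n = 1000000)
```

Reading: pooled growth curves give an asymptotic length of ~101 cm SCL and
growth coefficient ~0.06/yr; a 91 cm first-time nester is therefore ~39–41
years old; propagating all uncertainty, the population's best-case annual
growth is ~2.1% (median), almost surely between ~0.6% and ~4.6%. Roughly
3.5% of proposed nester sizes were unsliceable (at or beyond the asymptote)
or implied ages over 100 years and were filtered, per the age-slicing
rules.

`plot(fit)` draws the `R_max` density; `simulate(fit)` re-runs the Monte
Carlo stage under fresh seeds; `fit$mc$draws` holds the joint draws
`(a_raT, alpha, s, lambda_max, top, r_max, R_max)`.

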