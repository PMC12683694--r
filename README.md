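# growsurv

Integrated growth–survival capture-mark-recapture (CMR) models with
distance-weighted landscape covariates, for asking how the landscape around
a study site shapes the demography of a size-structured animal population —
the motivating case being a semi-aquatic snake in irrigation canals whose
growth and survival may depend on how much rice is cultivated nearby, with
drought a confounder of both.

## What it fits

**Growth.** Consecutive-year recaptures feed a hierarchical von Bertalanffy
model: `EL = a − (a − L) e^{−(k/a)Δt}`, with sex-specific asymptotes
(`a = ε_a,sex + λ_a,sex,s`) and a log-linear growth coefficient

    log k = μ_k,sex + β_rice · R_w(s,t) + β_drought · SPEI(s,t) + α_k,sex,s + ζ_k,t + ι_k,i

**Survival.** A robust-design CMR model (annual primary periods, daily
secondary occasions) conditioned on first capture, with random temporary
emigration γ, sex-specific daily detection p carrying nested
site/year/day random effects, and apparent survival

    logit φ = μ_φ,sex + θ_rice · R_w(s,t) + θ_drought · SPEI(s,t) + f_φ(size) + η_φ,s,t

where `f_φ` is a penalized cubic B-spline evaluated at latent sizes imputed
through the growth chain — the two models are fit jointly.

**Landscape covariate.** Rice cover is summarized in 100 rings of 0.1 km
around each site; `R_w = Σ w_i x_i` weights standardized ring values by a
Gaussian per-unit-area kernel `w_i ∝ A_i exp(−m_i²/2σ²)` whose scale σ is
*estimated* with the demographic parameters.  Derived summaries:
`scale_max` (modal-weight distance) and `scale_90` (90% cumulative weight).

**Causal step.** `causal_dag()` / `minimal_adjustment_sets()` apply the
backdoor criterion to the working DAGs; drought is the unique minimal
adjustment set for the total rice effect, which is why SPEI sits in both
linear predictors.

Models are fit by MCMC in JAGS (via rjags).  Companion tools simulate
complete synthetic studies with a known truth record
(`simulate_study()`), and validate the whole chain by simulate-and-refit
(`run_recovery_study()`, `shape_recovery()`), plus posterior-predictive
checks (`growth_gof()`, `freeman_tukey_gof()`).

## Worked example

Simulate a growth study with known truth (landscape effect 0.34, kernel
scale 0.8 km), fit the hierarchical growth model, and check fit:

```r
library(growsurv)

gs <- simulate_growth_study(n_intervals = 260, seed = 7)
fit <- fit_growth(gs$intervals, gs$rings, gs$spei,
                  mcmc = mcmc_profile("test"), seed = 1)
subset(fit$summary, parameter %in% c("eps_a[1]", "eps_a[2]", "b_rice",
                                     "b_dr", "sig_rice", "sd_err"))
#>  parameter    mean      sd      q2.5   q97.5
#>   eps_a[1] 902.038 18.5133 866.87933 940.554
#>   eps_a[2] 656.740 11.4905 632.76646 678.016
#>     b_rice   0.299  0.0810   0.14052   0.454
#>       b_dr   0.131  0.0689  -0.00771   0.268
#>   sig_rice   0.902  0.5001   0.25391   2.068
#>     sd_err  32.654  2.2845  28.35607  37.359

fit$scales$summary     # derived spatial scale of the landscape effect
#>   parameter  mean  q2.5 q97.5
#> 1     sigma 0.902 0.254  2.07
#> 2 scale_max 0.903 0.250  2.05
#> 3  scale_90 1.984 0.600  4.50

growth_gof(fit, seed = 1)
#> Posterior-predictive check (RSS): Bayesian p-value = 0.472
```

The landscape effect on growth (truth 0.34) is estimated at 0.30 with a
95% credible interval of 0.14-0.45; the kernel scale (truth 0.8 km) at
0.90 km (0.25-2.07), with 90% of the cumulative landscape weight inside
2.0 km; sex-specific asymptotes (truth 881/645 mm) are covered; and the
RSS check's Bayesian p-value near 0.5 signals no lack of fit.  The
causal step that justifies the drought covariate:

```r
dag <- read_dag(system.file("extdata", "dag_growth.dag",
                            package = "growsurv"),
                exposure = "rice", outcome = "growth")
minimal_adjustment_sets(dag)
#> [[1]]
#> [1] "drought"
```

The integrated survival model fits the same way from capture histories
(`build_capture_histories()` + `fit_cmr()`), returning sex-specific
daily detection, availability and apparent survival, the survival
kernel's `scale_max`/`scale_90`, the size-survival spline
(`plot(fit)`), Freeman-Tukey goodness of fit
(`freeman_tukey_gof()`), and the cumulative annual recapture
probability (`annual_recapture_draws()`).  Single short-profile fits of
the survival model carry wide intervals; its operating characteristics
are best seen through `run_recovery_study()`, which is what the
reproduction script below does.

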