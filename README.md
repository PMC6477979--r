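# dlnafilter

Filtering and Bayesian inference for stochastic biochemical oscillators
whose reaction hazards depend on a **distributed delay** of past states —
the situation that arises when a transcriptional–translational negative
feedback loop (such as the circadian *Cry1* circuit) is reduced to a single
mRNA species whose transcription is repressed by its own expression level a
Gamma-distributed lag ago.

## Who this is for

Systems biologists and statisticians who record univariate reporter
time series (bioluminescence imaging at fixed exposures) and want
likelihood-based estimates of kinetic rates, delay moments and measurement
parameters from a stochastic — not deterministic — feedback model, together
with filtered and smoothed reconstructions of the unobserved molecular
state.

## The model and the method

State: mRNA count $X(t)$ with reactions

$$\emptyset \xrightarrow{\nu(u)} X, \quad X \xrightarrow{\mu} \emptyset,
\qquad
\nu(u) = \frac{R_{\max}}{1 + (u/K_{pc})^{n}}, \qquad
u(t) = \int_{t-\tau_m}^{t} X(s) K(t-s)\,ds,$$

with $K$ a truncated Gamma delay density (mean $E[\tau]$, SD $SD[\tau]$,
truncation $\tau_m = 30$ h). Observations integrate light over the camera
exposure: $Y_t = \kappa \int_{t-\Delta_t}^{t} X(s) ds + \epsilon_t$,
$\epsilon_t \sim N(0, \sigma_\epsilon^2)$.

Because the dynamics look back up to $\tau_m$, the filter propagates the
joint Gaussian law (linear noise approximation) of the **entire delay
window** $X_{t-\tau_m:t}$ on a $\delta_t$ lattice and revises the whole
window at every observation with a Kalman-type update
$C = P F^\top (F P F^\top + \sigma_\epsilon^2)^{-1}$. This yields a
closed-form marginal likelihood, one-step predictive moments, and a
"partial smoothing" density (each state's law when it last left the
window). Parameters are sampled by two-stage **delayed-acceptance MCMC**:
a cheap coarse-lattice likelihood ($\delta_t = 0.5$ h) screens proposals,
the fine lattice ($\delta_t = 0.1$ h) decides, and the fine posterior is
exactly invariant.

## Worked example

```r
library(dlnafilter)

params <- ttfl_params()                       # reference circadian setting
sims   <- generate_dataset(params, n_rep = 3, snr = 100, seed = 42,
                           horizon = 120)     # delayed SSA + camera model
series <- sims[[1]]
series
#> <observed_series> 240 obs, exposure 0.5 h, t in [0.5, 120] h

truth <- ttfl_params(kappa = series$meta$kappa,
                     sigma_eps = series$meta$sigma_eps)
fit <- filter_loglik(series, truth, dt = 0.1)
fit$loglik
#> [1] -771.27
head(subset(fit$predictive, phase == "filter"), 3)
#>    time     mean sd_signal   sd_obs  phase
#> 61 30.5 40.07657  2.696724 2.714849 filter
#> 62 31.0 52.71952  3.018822 3.035024 filter
#> 63 31.5 60.03943  3.209940 3.225183 filter

coverage(sims, params, level = 0.95, dt = 0.1)
#> <coverage_report> nominal 95%: predictive 95.6% (n=540),
#>                   smoothing 95.6% (n=540), pooled 95.6%
```

The log-likelihood is the filter's closed-form marginal likelihood of the
240 observations at the generating parameters; the predictive table gives,
per observation, the one-step-ahead mean and SD of the noise-free
integrated signal (`sd_signal`) and of the observation (`sd_obs`). The
coverage report shows that nominal 95% predictive and partial-smoothing
intervals cover the simulated noise-free signal at close to the nominal
rate — the filter is calibrated under the model.

For parameter inference:

```r
pri <- default_priors(sigma_eps_center = series$meta$sigma_eps)
chains <- lapply(1:4, function(i)
  delayed_acceptance_mcmc(series, pri, n_iter = 30000, seed = 100 + i,
                          dt_coarse = 0.5, dt_fine = 0.1,
                          init_pilot_iters = 5000))
posterior_summaries(chains)   # screens non-convergent chains, pools, HPDIs
```

A command-line surface wrapping the same functions is installed as
`exec/dlnafilter` (`simulate`, `filter`, `fit`, `diagnose` subcommands);
see `run_cli()`.

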