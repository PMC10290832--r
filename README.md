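# weibullcm

Interval estimation for the **common mean of several Weibull
distributions**.

Many environmental and reliability datasets arrive as several independent
samples — monthly wind speeds from different weather stations, failure
times from different production lots — each well described by a
two-parameter Weibull distribution with its own scale *c<sub>i</sub>* and
shape *k<sub>i</sub>*, but sharing one mean
µ = c<sub>i</sub> Γ(1 + 1/k<sub>i</sub>). This package is for analysts who
need a defensible confidence or credible interval for that shared mean. It
provides:

* **Weibull MLEs** from the profile score equation
  1/k̂ − Σx<sup>k̂</sup>log x / Σx<sup>k̂</sup> + mean(log x) = 0, with the
  closed profile scale ĉ = (Σx<sup>k̂</sup>/n)<sup>1/k̂</sup>, the observed
  information matrix, and the delta-method variance of the fitted mean
  (`fit_weibull_mle()`, `mean_estimate()`);
* the **inverse-variance pooled common mean**
  µ̂ = Σ(µ̂ᵢ/v̂ᵢ) / Σ(1/v̂ᵢ) (`pool_common_mean()`);
* four interval estimators for µ:
  * **GCI** — generalized confidence interval from generalized pivotal
    quantities R<sub>k</sub> = k̂₀/k̂\*, R<sub>c</sub> =
    (1/ĉ\*)<sup>k̂\*/k̂₀</sup>ĉ₀ obtained by refitting Weibull(1,1) star
    samples (`gci_interval()`);
  * **adjusted MOVER** — method of variance estimates recovery applied to
    per-group log-Wald limits, fully deterministic
    (`adjusted_mover_interval()`);
  * **Bayesian equitailed** and **HPD** credible intervals from a Gibbs
    sampler with a conjugate gamma step for c′ = (1/c)<sup>k</sup> and
    random-walk Metropolis updates of k under gamma priors
    (`bayes_common_mean()`);
* an **AIC comparison** of six candidate families (Weibull, gamma,
  lognormal, normal, exponential, Cauchy) to justify the Weibull margin
  (`compare_distributions()`);
* a **Monte Carlo engine** for coverage probability and expected length
  under configurable scenarios (`evaluate_scenario()`, `run_study()`);
* the bundled **Surat Thani wind-speed dataset** — 50 monthly wind speeds
  (m/s) from each of three districts of Surat Thani province, Thailand
  (`surat_thani_wind()`) — and a thin command-line interface
  (`inst/cli/weibullcm.R`).

## Worked example

```r
library(weibullcm)
wind <- surat_thani_wind()

ests <- mapply(mean_estimate, wind, names(wind), SIMPLIFY = FALSE)
ests[["Kanchanadit"]]$fit
#> Weibull MLE fit (Kanchanadit)
#>   n = 50, scale = 0.7564, shape = 2.2178, logLik = -12.3979
#>   mean = 0.6699

pool_common_mean(ests)
#> Common mean of 3 groups: 0.8446
#>   weights: 0.566 0.213 0.221

adjusted_mover_interval(wind, level = 0.95)
#> 95% interval (adjusted_mover): [0.8048, 0.8879], length 0.0831

gci_interval(wind, level = 0.95, m = 2500, seed = 1)
#> 95% interval (gci): [0.7957, 0.8946], length 0.0990

bc <- bayes_common_mean(wind, iters = 20000, burn_in = 1000, seed = 1)
bc$equitailed
#> 95% interval (bayes_equitailed): [0.7964, 0.8968], length 0.1005
bc$hpd
#> 95% interval (bayes_hpd): [0.7955, 0.8956], length 0.1001

head(compare_distributions(wind[["Kanchanadit"]]), 3)
#>    family n_params    loglik      aic   ok
#> 1 weibull        2 -12.39788 28.79577 TRUE
#> 2   gamma        2 -13.51388 31.02776 TRUE
#> 3  normal        2 -14.30160 32.60319 TRUE
```

Reading: each district's wind speeds are fitted as Weibull (the AIC table
confirms Weibull beats five competitors for these data); the three fitted
means (0.830, 1.064, 0.670 m/s) pool to a common mean of 0.845 m/s, with
the precise group (Khiri Rat Nikhom) carrying 57% of the weight. The
deterministic MOVER interval is the narrowest; the GCI and the two Bayesian
intervals agree closely with each other (≈[0.796, 0.896]), the HPD interval
being, by construction, never longer than the equitailed one.

The command-line front end wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","weibullcm.R",package="weibullcm"))')" \
  ci --method gci --level 0.95 --gpq-draws 2500 --seed 1 --fixture surat_thani
```

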