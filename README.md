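# weibullrelease

Statistical analysis of in-vitro cumulative drug-release profiles with the
non-normalized Weibull distribution.

## The problem

Controlled-release formulations — drug-loaded nanoparticle colloids,
electrospun polymer nanofibers, matrix tablets — are characterized by the
fraction of payload they release over time. Practitioners need to (i) fit a
flexible empirical model to the whole release curve, (ii) read a transport
mechanism off the fitted shape, and (iii) summarize the curve into
regulatory metrics such as the dissolution efficiency. This package does
all three for the Weibull model

```
M(t) = M∞ (1 − exp(−(t/τK)^β))
```

where `M(t)` is the cumulative release in percent of the loaded drug at
time `t` (hours), `M∞` is the saturation release, `τK` the characteristic
time (63.2 % of `M∞` released at `t = τK`) and `β` the dimensionless shape
(stretching) exponent. The survival complement `exp(−(t/τK)^β)` is the
Kohlrausch stretched exponential; the small-time Taylor limit
`M∞ (t/τK)^β` is the Korsmeyer–Peppas power law (the Higuchi √t law at
β = ½). Derived time statistics follow from the Gamma function:
`⟨τ⟩ = τK Γ(1 + 1/β)` and
`σ = τK √(Γ(1 + 2/β) − Γ(1 + 1/β)²)`.

Shape exponents map to mechanisms: `β ≤ 0.75` Fickian diffusion,
`0.75 < β < 1` combined diffusion + swelling, `β = 1` first-order
(exponential) kinetics, `β > 1` complex sigmoidal release with an
inflection. The dissolution efficiency at a final time `t_f` is

```
DE(%) = (1/t_f) ∫₀^{t_f} M(t) dt
```

the area under the release curve relative to the 100 %-release rectangle.

## What the package provides

- **Model functions** (`weibull_cdf`, `weibull_pdf`, `weibull_inverse`,
  `powerlaw_limit`, `kohlrausch`, `mean_release_time`,
  `std_release_time`, `derived_stats`) and the classical comparison
  models (`mech_model`, `model_value`: zero-order, first-order, Higuchi,
  power law).
- **Fitting** (`fit_weibull_cdf`, `weibull_plot_fit`,
  `loglog_powerlaw_fit`, `compare_models`): Weibull-plot linearization
  for initial values, nonlinear least squares with standard errors, AICc
  model ranking.
- **Interpretation** (`classify_beta`, `classify_powerlaw_slope`).
- **Metrics** (`dissolution_efficiency`, `time_to_release`,
  `build_release_table`, `drug_loading`, `encapsulation_efficiency`).
- **Synthetic data** (`generate_profile`, `sampling_schedule`,
  `noise_model`, `recovery_experiment`): seeded noisy profiles with known
  ground truth for estimator validation.
- **I/O and CLI** (`read_profile_csv`, `write_report`, `run_cli`): CSV
  profiles in, JSON/CSV reports out, plus `fit`/`de`/`table`/`simulate`
  subcommands (see `exec/release-kinetics`).

## Worked example

Three fitted parameter presets ship with the package
(`release_presets()`); the irradiated-colloid system is
`(M∞, τK, β) = (15.1 %, 27.90 h, 2.67)`:

```r
library(weibullrelease)
p <- release_presets()$colloids

mean_release_time(p)
#> mean release time: 24.8 h

dissolution_efficiency(p, 80)
#> DE(t_f = 80 h) = 10.42 %  (release at t_f: 15.1 %)

build_release_table(p, fixed_times = c(40, 80), release_targets = c(5, 10))
#>  time_h release_pct de_pct
#>    19.8           5    1.5
#>    28.8          10    3.4
#>    40.0          14    5.9
#>    80.0          15   10.4
```

Reading the table: 5 % of the drug is out after ~20 h, the model releases
14 % by 40 h, and by 80 h the dissolution efficiency has reached 10.4 % —
a slow sigmoidal release (`β = 2.67 > 1`, an inflection near 23 h).

Simulate a noisy assay and recover the parameters:

```r
prof <- generate_profile(p, sampling_schedule("paperlike", 20),
                         noise_model(sd = 0.3, seed = 42))
fit <- fit_weibull_cdf(prof, m_inf = 15.1)
#> Weibull fit (M_inf fixed): M_inf = 15.1 %, tau_K = 28.38 h, beta = 2.482
#>   RMSE = 0.371 %, R2 = 0.99528, AICc = -32.2
classify_beta(fit$params$beta)
#> Mechanism: complex_sigmoidal (beta = 2.48156)
```

The same pipeline from the shell:

```sh
exec/release-kinetics simulate --preset colloids --seed 42 --out prof.csv
exec/release-kinetics fit --input prof.csv --m-inf 15.1 --out report.json
exec/release-kinetics de --m-inf 15.1 --tau-k 27.90 --beta 2.67 --tf 80
```

## Documentation

The methods vignette (`vignettes/weibull-release-kinetics.Rmd`) describes
the model, its assumptions, the fitting and classification defaults, what
the synthetic generator does and does not emulate, and known limitations —
including a documented discrepancy between the closed-form release-time
standard deviation and previously printed values.
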