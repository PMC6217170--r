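# pulselag

Division timing of carbon-starved *Escherichia coli* under pulsed
nutrient feeding.

Starved bacteria fed glucose in sporadic, minuscule pulses resume
division only after a lag that depends on the pulse frequency. `pulselag`
implements the quantitative analysis behind that observation: a
threshold-accumulation model of the division protein FtsZ, plus every
supporting stage from raw optical-density curves to flow-cytometry
subpopulation counts and real-time metabolomics traces. It is aimed at
researchers analyzing pulse-feeding (or more generally
famine-and-feast) experiments and at modelers who want a tested,
reproducible implementation of the threshold-division model.

## The model

FtsZ abundance $Z$ (copies/cell) under a time-integrated (TI) feedrate
$f$ (mmol glucose · g DCW⁻¹ · h⁻¹) follows

$$\frac{dZ}{dt} = \alpha_0 + \alpha_1 f - \frac{V_{max}\,Z}{K_m + Z}$$

— basal synthesis, feedrate-coupled synthesis, and Michaelis–Menten
(ClpXP-mediated) degradation. Division is triggered when $Z$ rises from
its starved level $Z_0$ to a threshold $Z^*$; the lag time is the
transit time, available in closed form (`lag_time_analytic()`) and by
independent ODE integration (`lag_time_numeric()`). Synthesis and
degradation balance at the threshold at a **critical feedrate**
$f_{crit} = (V_{max} Z^*/(K_m+Z^*) - \alpha_0)/\alpha_1$: below it the
lag is infinite, above it the lag falls off steeply with $f$. A single
parameter — the synthesis gain $\alpha_1$ — is fitted to observed
lag-versus-feedrate data by least squares on $\log_{10}$ lag
(`fit_alpha1()`).

Around the model sit the empirical stages:

| stage | functions |
|---|---|
| OD lag/growth changepoint fit | `exclude_outliers()`, `fit_threshold_linear()`, `division_rate()` |
| feedrate arithmetic | `pulse_schedule()`, `ti_feedrate()`, `od_to_dcw()` |
| empirical lag curve and maintenance | `fit_lag_vs_feedrate()`, `decompose_maintenance()` |
| flow cytometry | `calibrate_expected_events()`, `absolute_count()`, `fit_dna_mixture()`, `subpopulation_counts()`, `check_2n_to_1n()` |
| real-time metabolomics | `z_normalize()`, `moving_average()`, `pulse_response_features()` |
| synthetic data with ground truth | `synth_config()`, `gen_all()` and per-stage generators |
| orchestration | `run_pipeline()`, `read_pulselag_config()` |

All fitting functions return classed S3 objects with `print`, `coef`,
`predict`, `residuals`, `plot` (and for the model fit, `simulate`)
methods. See `vignette("pulselag-methods")` for the full methods
account.

## Worked example

Generate a synthetic 18-experiment pulse-feeding campaign with known
ground truth, then run the full analysis:

```r
library(pulselag)

cfg <- synth_config(seed = 42)           # study-conditions generator
gen_all(cfg, "demo_in")                  # OD, lags, cytometry, ion CSVs
res <- run_pipeline("demo_in", "demo_out", ftsz_params_study(), seed = 42)

res$model_fit
#> FtsZ threshold model: single-parameter fit
#>   alpha1 = 99.9778 copies/cell/min per (mmol/g/h)
#>   R^2 (log10 lag) = 0.9685 on 16 points (0 excluded)
#>   implied critical feedrate = 0.2 mmol/g/h

res$lag_curve
#> Threshold exponential-decay lag curve
#>   breakpoint p0 = 0.18 mmol/g/h (2 censored experiments)
#>   p1 = 90.61 min, p2 = 2.816 (mmol/g/h)^-1

res$maintenance
#> Feedrate decomposition f = (1/Y_xs) Psi + m_s
#>   yield Y_xs = 0.05149 g DCW/mmol (slope 19.42 +/- 0.4)
#>   maintenance m_s = 0.01064 +/- 0.014 mmol/g/h
```

Reading the output: the fitted synthesis gain recovers the generating
value (100) to 0.02%; the two sub-critical experiments (no division
within the record) pin the empirical breakpoint at 0.18 mmol/g/h, just
below the model's critical feedrate of 0.2; and the maintenance
intercept is statistically indistinguishable from zero — pulsed carbon
is stored for division, not burned. `demo_out/` holds per-experiment
fits, model predictions, cytometry subpopulation counts, ion-trace
classes, a JSON summary, and a manifest with input digests and the seed
for exact replay.

Single quantities are just as direct:

```r
p <- ftsz_params_study()
critical_feedrate(p)                  # 0.2
lag_time_analytic(p, c(0.25, 0.4, 0.8))
#> 125.644 42.78714 15.74347          # minutes
predict_titration(p, scale_vmax = 0.5, f = 0.25)  # protease inhibition halves...
```

A thin command-line wrapper for the synth/run/lag operations is
installed at `inst/scripts/pulselag.R`.

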