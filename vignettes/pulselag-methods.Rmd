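---
title: "Methods: a threshold-accumulation model of division timing under pulsed feeding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a threshold-accumulation model of division timing under pulsed feeding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulselag)
```

## The scientific problem

Carbon-starved *Escherichia coli* stop dividing. When glucose returns only
as sporadic, minuscule pulses, cultures resume division after a lag that
depends on the pulse *frequency*, not simply on the total glucose fed. The
working hypothesis implemented here is that a single division-limiting
protein — FtsZ, the tubulin homolog that polymerizes into the division
ring — is synthesized briefly after each pulse and degraded continuously
by the ClpXP protease. Division triggers when FtsZ abundance reaches a
threshold, so the lag is the time the pulse train needs to push FtsZ from
its starved level up to that threshold.

## The model

FtsZ abundance $Z$ (copies/cell) under a time-integrated feedrate $f$
(mmol glucose · g DCW⁻¹ · h⁻¹) follows

$$\frac{dZ}{dt} = \alpha_0 + \alpha_1 f - \frac{V_{max} Z}{K_m + Z},$$

with basal synthesis $\alpha_0$, feed-coupled synthesis $\alpha_1 f$, and
Michaelis–Menten degradation. Division occurs when $Z$ first reaches
$Z^\*$ starting from the starved level $Z_0 \le Z^\*$. Time is in minutes
internally; feedrates stay in per-hour units with explicit 60× conversions
at the boundaries, matching how the quantities are conventionally
reported.

Writing $a = \alpha_0 + \alpha_1 f$, $b = a - V_{max}$, $c = a K_m$,
separation of variables gives the exact lag

$$t_{lag} = \frac{Z^\* - Z_0}{b}
  + \frac{K_m - c/b}{b}\,
    \ln\!\frac{c + b Z^\*}{c + b Z_0},$$

implemented in `lag_time_analytic()`. Three regimes matter:

* **Sub-critical feeding.** If $a (K_m + Z^\*) \le V_{max} Z^\*$ the
  steady state sits at or below the threshold and the lag is infinite.
  The boundary defines the critical feedrate
  $f_{crit} = (V_{max} Z^\*/(K_m+Z^\*) - \alpha_0)/\alpha_1$
  (`critical_feedrate()`, clamped at zero). The finiteness test is done
  on the products $a(K_m+Z^\*)$ vs. $V_{max} Z^\*$ rather than on the
  steady-state quotient, so rounding at the boundary cannot flip the
  verdict.
* **The removable singularity $a = V_{max}$** ($b = 0$). The two terms of
  the closed form cancel catastrophically; whenever
  $|b| Z_{max} / c < 10^{-7}$ the implementation switches to the exact
  series of $\int (K_m + Z)/(c + bZ)\,dZ$ truncated at first order in
  $b$, whose relative truncation error is below $10^{-14}$ in that
  region. The limit $b \to 0$ itself is exact.
* **Degradation knocked out** ($V_{max}=0$, the *clpX* deletion
  scenario): the flow is linear, $t = (Z^\*-Z_0)/a$, and the general
  formula reduces to it identically.

`lag_time_numeric()` is the independent check: it integrates the ODE with
`deSolve::lsodar` (tolerances $10^{-12}$) and takes the solver's root
finder's threshold crossing. The two routes agree to better than
$10^{-6}$ relative over wide random parameter grids; the test suite and
the acceptance script re-verify this at every run (200 random sets).

### Discrete pulses versus the smoothed model

Real feeding is discrete: a pulse every $T$ minutes delivering `dose`
mmol/g DCW. `simulate_pulse_train()` models each pulse as an
instantaneous jump $\Delta Z = \alpha_1 \cdot dose \cdot 60$ — the
smoothed synthesis $\alpha_1 f$ integrated over one period — followed by
the starvation flow (basal synthesis vs. degradation) until the next
pulse. Pulses in the experiments lasted ~10 s against periods of minutes,
so the instantaneous-jump idealization is a good approximation. Between
pulses the state is advanced *exactly*: the starvation flow's
time-of-flight $t(Z)$ is the same closed form, and the abundance after a
period is found by inverting it with `uniroot` on a bracket that stops
just short of the attractor (where the transit time diverges). As
$T \to 0$ at fixed $f$ the discrete trajectory converges to the smoothed
model; the tests require agreement within 1% at $T = t_{lag}/1000$.

### Fitting a single parameter

`fit_alpha1()` fits only $\alpha_1$; all other constants are held fixed.
The objective is least squares on $\log_{10}$ lag: lags span orders of
magnitude and multiplicative error is the natural scale. Zero-lag
observations are excluded (they only say the threshold was already met).
Points predicted *non-dividing* at a trial $\alpha_1$ enter with
$\log_{10}(t_{max,fit})$, default $10^4$ min: a large finite penalty that
keeps the objective smooth and pushes the gain upward instead of silently
dropping the point. The objective is one-dimensional in $\log \alpha_1$;
it is minimized by `stats::optimize()` over three abutting brackets
spanning $[10^{-6}, 10^8]$ (a cheap multistart that guards against the
penalty plateau), ties broken toward the lowest $\alpha_1$, followed by a
local polish. $R^2$ is reported on the $\log_{10}$ scale over the points
used; a single point is exactly interpolated and given $R^2 = 1$ by
convention.

### Reference parameterizations

The literature-derived kinetic constants behind the original analysis are
not reproduced here; instead the package ships two labeled synthetic
sets. `ftsz_params_ref()` ($\alpha_0{=}5$, $\alpha_1{=}100$,
$V_{max}{=}50$, $K_m{=}1000$, $Z^\*{=}2000$, $Z_0{=}1000$) is a
round-number set for tests and examples — explicitly non-biological.
`ftsz_params_study()` keeps that shape but re-solves $\alpha_0$ so the
critical feedrate equals 0.2 mmol/g/h, the reported critical rate for
glucose pulsing; it parameterizes the synthetic study-conditions data.
Real analyses must supply an explicit configuration
(`read_pulselag_config()`).

## Empirical stages

**OD changepoint fit.** `fit_threshold_linear()` fits
$OD(t) = OD_i$ for $t < t_{lag}$, then $OD_i + \mu (t - t_{lag})$, by
profiling $t_{lag}$: for fixed $t_{lag}$ the model is linear in
$(OD_i, \mu)$ and solved in closed form with $\mu \ge 0$; the profile is
evaluated at every observed time and refined by golden-section search
between the bracketing neighbours, ties toward the earliest changepoint
(deterministic, resolution-independent). Censoring — "no division within
the record" — is declared when the fitted slope is numerically zero or
the total fitted rise $\mu(t_{end}-t_{lag})$ is under 5 residual standard
deviations. That cutoff separates cleanly: on flat noisy series the rise
statistic stays below ~2.5 sd (99th percentile), while genuine growth
records sit above 25. High outliers are removed first by the one-sided,
single-pass rule (`exclude_outliers()`): values more than 3 sample sd
above the whole-series mean; a zero-variance series is left untouched.

**Feedrate arithmetic.** `ti_feedrate()` converts a dispense schedule
(e.g. 22 µl of 2.5 g/l glucose into 32 ml of culture every few minutes)
into mmol glucose per g DCW per hour, using the strain calibration
1 OD = 0.4 g DCW/l (`od_to_dcw()`). It is exactly linear in dose and
inversely proportional to period and to initial OD.

**Lag-versus-feedrate decay.** The empirical curve
$t_{lag}(f) = p_1 e^{-p_2 (f - p_0)}$ for $f \ge p_0$, indeterminate
below, has a rank-deficient parameterization: on dividing points alone,
$(p_0, p_1)$ trade off exactly through $p_1 e^{p_2 p_0}$. The package's
convention: censored (non-dividing) experiments bound $p_0$ from below
and the largest censored feedrate is the breakpoint estimate; given
$p_0$, $\log p_1$ and $p_2$ come from OLS of log lag on feedrate. With no
censored points $p_0$ must be supplied (e.g. the model's critical
feedrate). Whether the original empirical fit used censored points at all
is not documented; using them as the breakpoint constraint extracts
information from the sub-critical experiments instead of discarding them.

**Maintenance decomposition.** `decompose_maintenance()` fits
$f = (1/Y_{x/s}) \Psi + m_s$ by OLS of feedrate on division rate
$\Psi = 60\,\mu/OD_i$ (per hour, normalized to the initial amount of
cells, as the quantity is defined relative to existing cells at lag end).
The slope gives the inverse yield, the intercept the maintenance rate,
both with standard errors.

## Flow cytometry

Progressive clogging of the injection port depresses recorded events.
`calibrate_expected_events()` averages the total events of the first
three (pre-clogging) time points into $E_i$;
`absolute_count()` corrects each sample as
$C_s = E_{cells}/E_{total} \cdot E_i$, which cancels attenuation that
suppresses cells and debris alike.

`fit_dna_mixture()` separates the 1N and 2N DNA-content subpopulations by
a two-component Gaussian EM written for this purpose, because the
initialization encodes the biology: the 2N mean starts at the highest
density mode of the fluorescence distribution and the 1N mean at half of
it. No 2:1 mean constraint is imposed during iteration (stain
nonlinearity can break exact doubling). Five deterministic restarts
perturb the initial means by ±10–20%; the best likelihood wins, the
lower-mean component is labeled 1N, and a collapse (weight < 0.02 or
means closer than half a pooled sd) is flagged degenerate rather than
silently reported. A standard-deviation floor keeps point-mass inputs
finite.

`check_2n_to_1n()` audits the division bookkeeping: if every division is
one 2N cell becoming two 1N cells and nothing else moves,
$n_1(t) = n_1(0) + 2\,(n_2(0) - n_2(t))$. Residuals beyond a tolerance
(default 5% of the per-time total — a package choice, the original
consistency call being visual) or a growing 2N pool flag the hypothesis.
Note the prediction anchors on the time-zero estimates, doubling their
error: at $10^4$ events per injection with three replicate injections per
time point, propagated counting noise alone produces residuals of up to
~13% of the total, so estimator-level audits need a correspondingly wider
band than count-level ones.

## Real-time metabolomics

`z_normalize()` rescales raw ion counts against a pre-perturbation
reference window, $Z = (S - \bar S_{ref})/\sigma_{ref}$ (default window
0–300 s), making traces invariant to positive affine rescaling.
`moving_average()` is a centered running mean (default 5 points, the
figure-style smoothing; the original window length is not documented)
with shrinking edge windows. `pulse_response_features()` summarizes each
inter-pulse interval — peak $Z$, time to peak, return-to-baseline — and
classifies the trace: *spike* (peak above $z_{peak,min}=3$ returning
within the interval), *accumulate–deplete* (Kendall rank trend > 0.5
between pulses with a post-pulse drop), else *flat*. The thresholds are
package defaults, configurable; the original classification was visual.
Because a flat ion's Z-scores have unit variance by construction, the
pipeline smooths lightly (3-point window) before classifying so that
noise maxima do not brush the spike threshold.

## Synthetic data: what it emulates and what it does not

Every input has a seeded generator with returned ground truth, making
each analysis stage a closed loop (`gen_od_experiment()`,
`gen_lag_dataset()`, `gen_cytometry_timecourse()`, `gen_ion_traces()`,
`gen_all()`). Default noise levels are the study-scale conditions: OD
noise sd 0.005, multiplicative lag noise $\sigma_{\log_{10}} = 0.05$,
$10^4$ events per injection with clogging attenuation drawn from
$[0.6, 1]$ (unity during calibration), FL1 components
$N(100, 15^2)$/$N(200, 15^2)$, ion noise sd 0.3 Z-units. Growth slopes
follow the yield decomposition $\Psi = Y(f - m_s)$ with $Y = 0.05$
g/mmol and $m_s = 0$ (maintenance being empirically indistinguishable
from zero). The default lag/OD design covers 18 feedrates from 0.1 to
1.0 mmol/g/h, including one just below the critical rate, mirroring the
experimental series. One master seed fans out to per-generator child
seeds via $(1009\,s + 9973\,k) \bmod (2^{31}-1)$, giving independent yet
reproducible streams, and all generator RNG use restores the caller's
`.Random.seed`.

What the generators deliberately do **not** emulate — and hence what
passing closed-loop tests cannot certify about real data: per-cell
heterogeneity (the observed partial dividing fraction is not modeled),
non-Gaussian OD drift and plate effects, stain nonlinearity between the
1N and 2N means, mass-spectrometric ion suppression, finite pulse
duration, and any real calibration between plate-reader and
spectrophotometer OD scales (a user-supplied monotone table is accepted;
the default is identity because the original calibration is
unpublished).

## Problem sizes and numerical conventions

The shipped tests run the oracle equivalence on 200 random parameter
sets, gain recovery on 50 replicates, changepoint recovery on 100
replicates, mixture recovery at $10^4$ events, and classifier recovery on
200 traces — sizes chosen so the whole suite completes in well under a
minute while keeping Monte-Carlo medians stable. Tolerances: $10^{-6}$
relative for analytic-vs-numeric lag agreement, 1% for the
discrete-to-continuous limit, and the recovery bands stated above. All
fits are deterministic given their inputs; the only randomness flows
through the generator seeds and, in the pipeline, the manifest seed.

## Known limitations

* The model is a smoothed, deterministic caricature: no Z-ring assembly,
  localization, or per-cell stochasticity; predictions are
  population-level lag times only.
* $\alpha_1$ is the only fitted kinetic constant; conclusions are
  conditional on the fixed $(\alpha_0, V_{max}, K_m, Z^\*, Z_0)$, and the
  shipped parameterizations are synthetic stand-ins, not literature
  values.
* The breakpoint of the empirical decay fit is identified only through
  censored experiments (or supplied externally); its uncertainty is not
  propagated.
* The EM mixture fit assumes exactly two normal components; higher
  ploidy classes or sub-1N debris would bias the weights.
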