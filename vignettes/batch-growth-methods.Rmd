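---
title: "Methods: batch growth-curve analysis for multicultivator experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: batch growth-curve analysis for multicultivator experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phycobatch)
```

`phycobatch` analyses batch growth curves of green microalgae logged by
multicultivator turbidity sensors, in two cultivation modes: light-limited
(CO~2~-sufficient) photoautotrophy and heterotrophy on an organic carbon
substrate (glucose or acetate). This vignette documents the models, the
tunable parameters, the numerical choices, and what the bundled synthetic
data generator does and does not emulate.

## Sensor correction

Multicultivator turbidity sensors (apparent OD at 720 nm, written
`od_sensor`) under-read dense cultures relative to a bench
spectrophotometer (750 nm, `od_reference`). The ratio of true to apparent
OD is well described by an exponential in the apparent signal,

$$\frac{\mathrm{OD}_{750}}{\mathrm{OD}_{sensor}} = a\,e^{b\,\mathrm{OD}_{sensor}},$$

with species- and condition-dependent constants $a$ (dimensionless; the
low-density correction factor) and $b$ (per apparent-OD unit). The
corrected value is therefore $\mathrm{OD}_{sensor}\,a\,e^{b\,\mathrm{OD}_{sensor}}$,
strictly increasing and convex for $a, b > 0$.

**Fitting.** `fit_calibration()` works in the exactly linearised space
$\ln(\mathrm{OD}_{750}/\mathrm{OD}_{sensor}) = \ln a + b\,\mathrm{OD}_{sensor}$
by ordinary least squares. The linearisation is exact, so the fit is
deterministic, has no starting-value sensitivity, and recovers generating
constants from noiseless model-consistent pairs to machine precision.
Whether the original analysis fitted in ratio space or by direct nonlinear
least squares is not documented anywhere we know of; the linearised fit is
this package's choice. Pairs with `od_sensor < 0.01` are excluded by
default — the ratio amplifies noise near zero — and the floor is
configurable. $b$ is not constrained in sign; $a \le 0$ is impossible by
construction of the log fit.

**Inversion.** The simulator needs the map from corrected to apparent OD.
For $b \ne 0$ the inverse has the closed form
$x = W_0(b\,y/a)/b$ with $W_0$ the principal Lambert-W branch
(`pracma::lambertWp`); for $b = 0$ it is $y/a$. The argument of $W_0$ is
non-negative for $b > 0$, so the inversion is defined for every
physically possible corrected OD.

**One model per condition.** Calibrations are fitted per species and
condition, not per growth phase. `compare_calibrations()` fits a common
linearised model with a group interaction so users can verify, on their
own dilution series, that exponential- and deceleration-phase constants do
not differ.

## Growth-curve analysis

A light-limited photoautotrophic batch shows a short exponential phase
(15–30 h) followed by a long deceleration ("linear") phase in which
self-shading pins volumetric productivity near a constant. Two parameters
summarise the curve:

* the **specific growth rate** $\mu$ (h^-1^), the OLS slope of
  $\ln \mathrm{OD}$ against time on the exponential window, with doubling
  time $\ln 2/\mu$;
* the **maximum volumetric biomass productivity** $V_{max}$
  (g L^-1^ day^-1^), $24\,k$ times the steepest sustained OD slope in the
  deceleration phase, where $k$ (g L^-1^ per corrected-OD unit) is the
  species-specific, time-stable OD-to-dry-weight conversion.

**Segmentation.** `segment_phases()` selects as exponential window the
*longest* window of duration at least `min_exp_hours` (default 5 h),
starting no earlier than `lag_skip` (default 2 h), whose log-OD linear fit
reaches `r2_threshold`. Ties on length go to the higher R², then the
earlier start. The deceleration window runs from the end of the
exponential window to the end of the series.

The R² default is 0.9996. This was calibrated on simulated batches at the
package's standard conditions (30-min sampling, 1% multiplicative sensor
noise, three replicates): because R² rises with window length for a fixed
noise level, a lenient threshold such as 0.995 admits windows that reach
~30 h into the deceleration phase and drag the fitted slope down by more
than 10%, while 0.9996 reproduces the 5–30 h log-linear region seen in
real corrected curves and recovers the generating rate to within ~3%.
Even so, the selected window genuinely extends several hours past the
point where the depth-averaged growth rate first drops below 95% of its
inoculum value — gentle curvature hides below the noise floor — which is
why recovered $\mu$ sits 2–4% under the generating initial rate rather
than exactly on it.

**V~max~.** The original procedure reads "the linear part" of the
deceleration curve off a plot. `estimate_vmax()` replaces that visual
choice with a deterministic surrogate: the maximum OLS slope over sliding
windows of `vmax_window_hours` within the deceleration phase. The window
default is 12 h. Short windows make the max-over-windows rule an extreme
value statistic of noise — with 6 h windows and percent-level sensor noise
the estimate runs ~20% hot, because the exponential correction amplifies
relative noise at high OD by a factor $1 + b\,\mathrm{OD}_{sensor}$ —
while 12 h matches the long near-linear stretch of real deceleration
phases and is unbiased on noiseless curves (recovery is exact to 1e-9).
For the same reason the recommended practice, used by the analysis
scripts, is to estimate $V_{max}$ on the point-wise mean of the replicate
curves (`average_series()`), mirroring how replicate curves are averaged
before visual analysis; $\mu$ is estimated per replicate and averaged.

**Degenerate inputs.** OD values ≤ 0 inside the exponential window are
rejected, not clipped; no baseline subtraction is applied. A constant
series has no exponential window and raises an error reporting the best
R² found. Series must be strictly increasing in time with a sampling
interval constant to 1%.

## Substrate yields

The biomass yield on substrate $Y_{X/S}$ (g dry weight per g substrate) is
estimated two ways:

* **endpoint** — $(X_{final} - X_0)/S_0$, valid when the substrate is
  exhausted at growth arrest; if a final substrate concentration is
  supplied and exceeds 5% of $S_0$ the function warns rather than errors,
  because the assumption, not the arithmetic, fails;
* **consumption** — OLS regression of cumulative biomass increments on
  cumulative substrate consumed, through the origin (the mass-balance line
  passes through (0, 0) by definition), with the substrate series linearly
  interpolated to the biomass sampling grid.

Whether a consumption-based yield should use endpoint pairs or the full
series is an open choice; the package implements the full-series
regression and leaves endpoint pairs to `yield_endpoint()`. Yields are
invariant to time-unit rescaling, and on noiseless simulator output both
methods return the generating yield exactly because the generator enforces
the mass balance by construction.

## Pigment statistics

Pigment contents (chlorophyll *a*+*b*, lutein, total carotene) are
expressed as percent of dry weight; `percent_dw()` converts µg pigment per
mg dry weight. Replicate groups (typically n = 3) are compared with
two-sided Welch $t$-tests at $\alpha = 0.05$; `effect_table()` builds the
standard contrast families: each light intensity against the
300 µmol m^-2^ s^-1^ reference, deceleration against exponential phase,
weak light against darkness, and acetate against glucose in darkness.
`reference_percentage()` expresses a heterotrophic condition as a
percentage of the mean deceleration-phase photoautotrophic content,
averaging per-intensity means with equal weight over whichever intensities
are present (recorded in the output for transparency).

Two statistical choices deserve a note. First, the Welch (unequal
variance) form was chosen as the robust default for n = 3 groups; with
such small samples the Welch–Satterthwaite approximation is conservative —
its true level under equal variances is about 0.035 at nominal 0.05 — so
null-calibration checks in the test-suite assert control at (not equality
with) the nominal level. Second, no multiple-testing correction is applied
by default, matching per-comparison testing at $\alpha = 0.05$; a
Benjamini–Hochberg option (`p_adjust = "BH"`) is available.

Degenerate replicate groups with zero variance are reported with
$p = 1$ when identical (and $p = 0$ when different) and flagged, rather
than erroring.

## The synthetic-data generator

The generator exists so that every stage is testable by parameter
recovery; its defaults are the package's standard study conditions and
are not re-tuned per analysis.

**Photoautotrophy.** Light attenuates across the culture depth by
Beer–Lambert, $I(z) = I_0 e^{-\sigma X z}$, and the local growth rate
saturates with irradiance in Monod form with half-saturation $K_I$. The
depth-averaged specific rate has the closed form

$$\bar\mu(X) = \frac{\mu_{max}}{\sigma X L}
  \ln\!\frac{K_I + I_0}{K_I + I_0 e^{-\sigma X L}},$$

and the trajectory integrates $dX/dt = (\bar\mu(X) - m)X$. This
reproduces the defining phenomenology: exponential growth while the
culture is optically thin, then a deceleration phase whose volumetric
productivity approaches the constant
$\mu_{max}\ln((K_I+I_0)/K_I)/(\sigma L)$ (for maintenance $m = 0$). The
closed form is validated against a 1000-point Simpson quadrature to 1e-8.

Defaults: light path $L = 0.03$ m (the tube diameter), absorption
cross-section $\sigma = 150$ m² per kg dry weight (mid-range for green
microalgae; note 1 g L^-1^ ≡ 1 kg m^-3^, so $\sigma X z$ is
dimensionless without unit juggling), $K_I = 150$ µmol m^-2^ s^-1^
(placing ~73% saturation at 400 µmol m^-2^ s^-1^, where photosynthetic
light curves typically saturate), inoculum $X_0 = 0.005$ g L^-1^ (a
dilute start that leaves a 15–30 h exponential phase before self-shading,
as observed), zero maintenance, 72 h duration, 30-min sampling, three
replicates, 1% multiplicative sensor noise. `photo_spec()` solves
$\mu_{max}$ from either a target initial specific rate (default
0.15 h^-1^, the highest exponential-phase rate seen in such batches), a
target dense-culture productivity (e.g. 1.8 g L^-1^ day^-1^, the
strongest observed case), or takes it directly for light-scan studies
where $\mu_{max}$ is a species property shared across intensities.

**Heterotrophy.** Monod kinetics on the substrate with yield $Y$;
substrate is eliminated through the exact mass balance
$S = S_0 - (X - X_0)/Y$, so $Y(S_0 - S) = X - X_0$ holds to the
integrator's precision at every sample by construction. Presets:
glucose at $S_0 = 15$ g L^-1^ with $Y = 0.55$, acetate at 2 g L^-1^ with
$Y = 0.32$, $\mu_{max} = 0.10$ h^-1^ (the 0.08–0.13 h^-1^ range of fast
heterotrophic growers), $K_S = 0.1$ g L^-1^, $X_0 = 0.1$ g L^-1^. An
optional dark-decay factor $e^{-r\max(0, t - t_{on})}$ slows growth late
in complete darkness and is suppressed under weak light; it is a declared
phenomenological stand-in for the (mechanistically unexplained)
weak-light growth stimulation of slow strains, not a claim about
mechanism.

**Sensor model and noise.** Corrected OD is biomass divided by $k$
(default 0.4 g L^-1^ per OD unit); the apparent-OD trace is the Lambert-W
inversion of the calibration (default $a = 1.795$, $b = 0.934$, the
worked dense-culture example), and each replicate gets multiplicative
Gaussian noise. All randomness flows from the single integer seed in the
spec, so one seed yields one dataset, byte-identical across runs.

**Pigment tables.** Cell means follow
base × acclim(I) × phase × substrate × weak-light × suppression, with the
photoacclimation curve $acclim(I) = c_{min} + (c_{max}-c_{min})
K_A/(K_A+I)$, strictly decreasing in irradiance. The suppression factor
expresses heterotrophic content as a fraction of the photoautotrophic
deceleration reference, so a factor of 0.23 makes
`reference_percentage()` return 23% by construction. Photoacclimation is
generated statically per phase — not as lagged ODE state — which is
sufficient for testing the statistics stage but does not emulate
photoacclimation kinetics.

**What passing tests do not show.** The generator draws i.i.d. Gaussian
multiplicative noise; real sensor logs show autocorrelated drift, bubble
artefacts, and occasional dropouts. It models neither CO₂/pH chemistry,
acetate alkalinisation, photoinhibition, flashing-light perception, nor
secondary carotenoid induction. Parameter recovery on this generator
therefore demonstrates the correctness of the estimators under the
model's assumptions, not robustness to every failure mode of real
hardware.

## Numerical choices

* ODE integration: `deSolve::ode` (lsoda) at `rtol 1e-10`, `atol 1e-12`,
  solved on a grid five times finer than the 30-min sampling and
  subsampled, validated against the closed-form limits (pure exponential
  as $\sigma \to 0$; asymptotic productivity in dense cultures).
* Windowed regressions use cumulative-sum OLS, O(1) per window.
* Rates are computed in hours throughout and converted to per-day only at
  reporting (×24).
* Problem sizes: analyses and tests run 72–143 h batches at 30-min
  sampling (145–287 points), three replicates, and 200–1000 replicate
  null/power simulations for the contrast stage — sizes chosen to match
  the multicultivator experiments the package emulates.

## Reproducing the headline numbers

`scripts/acceptance.R --seed <int> --out <path>` regenerates the
synthetic inputs and recomputes, from scratch: the calibration constants
recovered from a noiseless dilution series; the specific growth rate
recovered by the full pipeline from a photoautotrophic batch generated at
0.15 h^-1^; and the three substrate yields (glucose endpoint 0.55,
acetate endpoint 0.32, acetate consumption-regression 0.30). The numbered
scripts under `analysis/` run the same machinery as a narrated workflow
and write their tables under `results/`.
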