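# phycobatch

Batch growth-curve analysis for multicultivator experiments with green
microalgae, in both light-limited (CO₂-sufficient) photoautotrophy and
heterotrophy on glucose or acetate.

Multicultivators log an apparent optical density that under-reads dense
cultures, and light-limited batches do not follow a single growth law:
a short exponential phase gives way to a long deceleration ("linear")
phase as self-shading sets in. Analysing such experiments therefore
takes a pipeline, and `phycobatch` implements each stage as a tested
function:

1. **Sensor correction.** The true-to-apparent OD ratio follows
   `OD750/ODmc = a·exp(b·ODmc)`; `fit_calibration()` estimates `(a, b)`
   from a dilution series by exact linearisation
   (`ln(OD750/ODmc) = ln a + b·ODmc`), `correct_od()` applies the
   correction, and `invert_od()` inverts it in closed form via the
   principal Lambert-W branch.
2. **Phase segmentation and growth parameters.** `segment_phases()`
   finds the log-linear exponential window; `estimate_mu()` returns the
   specific growth rate µ (h⁻¹, slope of ln OD vs time) and
   `doubling_time()` its generation time ln 2/µ; `estimate_vmax()`
   returns the maximum volumetric biomass productivity V_max
   (g L⁻¹ day⁻¹, 24·k times the steepest sliding-window OD slope of the
   deceleration phase, with k the OD-to-dry-weight factor).
3. **Substrate yields.** Y_X/S (g DW per g substrate) by the endpoint
   method `(X_final − X0)/S0` and by regression of biomass increments on
   substrate consumed, through the origin (`yield_endpoint()`,
   `yield_consumption()`).
4. **Pigment statistics.** Contents in % of dry weight compared by Welch
   t-tests across light intensities, growth phases, carbon sources and
   weak-light treatments (`contrast()`, `effect_table()`), plus
   heterotrophic content expressed against the photoautotrophic
   deceleration-phase reference (`reference_percentage()`).
5. **Mechanistic synthetic data.** `simulate_photoautotrophic()`
   integrates Beer–Lambert self-shading with a Monod irradiance response
   (closed-form depth-averaged rate), `simulate_heterotrophic()`
   integrates Monod substrate kinetics with an exact mass balance, and
   `apply_sensor_model()` distorts the result into noisy sensor-space
   replicate logs — so every estimator above is testable by parameter
   recovery against known ground truth.

## Worked example

Simulate a photoautotrophic batch at 500 µmol m⁻² s⁻¹ whose generating
initial specific growth rate is 0.15 h⁻¹, distort it through the sensor
model (1% noise, 3 replicates), then recover everything from the sensor
logs alone:

```r
library(phycobatch)

spec  <- photo_spec(I0 = 500, initial_rate = 0.15, seed = 42)
batch <- apply_sensor_model(simulate_photoautotrophic(spec))

# calibrate from a (noisy) dilution series, as one would in the lab
cal <- fit_calibration(
  simulate_dilution_series(spec$calibration, noise_sd = 0.01, seed = 42))
print(cal)
#> Sensor calibration: a = 1.813, b = 0.9261 per OD unit
#>   fitted on 20 dilution pairs, R^2 (linearised) = 0.9995

corrected <- lapply(batch$od_sensor, correct_series, model = cal)
est <- analyze_growth(average_series(corrected), biomass_conversion(0.4))
print(est)
#> Growth estimate [mean]
#>   mu     = 0.1448 h^-1 (R^2 = 0.9997), doubling time 4.79 h
#>   V_max  = 1.612 g L^-1 day^-1 (window 59.0-71.0 h)
#> Phases: exponential 2.0-28.0 h (R^2 = 0.9997), deceleration 28.0-72.0 h
```

The recovered µ (0.145 h⁻¹) sits within 4% of the generating rate even
after the full sensor detour; the exponential window reproduces the
5–30 h log-linear region such batches show, and V_max is read off the
deceleration phase of the replicate-averaged curve.

## The analysis workflow

Numbered drivers under `analysis/` narrate the full study and write
their tables under `results/`:

| script | what it does |
| --- | --- |
| `01_simulate_datasets.R` | generates the photoautotrophic light scan (100–700 µmol m⁻² s⁻¹), glucose/acetate batches, the weak-light pair, and pigment tables |
| `02_fit_calibration.R` | calibration fits (noiseless and 1% noise) and the exponential-vs-deceleration phase contrast |
| `03_growth_rates.R` | µ and V_max per intensity; shows µ saturating with light while V_max keeps rising (the two parameters decouple) |
| `04_substrate_yields.R` | endpoint and consumption-regression yields on glucose and acetate |
| `05_pigment_contrasts.R` | the four contrast families and the heterotrophic-vs-photoautotrophic reference percentages |

Run them in order from the repository root, e.g.
`Rscript analysis/01_simulate_datasets.R`.

## Further reading

The methods vignette (`vignettes/batch-growth-methods.Rmd`) documents
the models and their assumptions, every tunable threshold with its
default and rationale, the numerical choices, and what the synthetic
generator does and does not emulate about real sensor logs.
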