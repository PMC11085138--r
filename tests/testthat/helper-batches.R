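# Shared fixtures, all generated in code.

fig8_model <- function() calibration_model(1.795, 0.934, label = "fig8")

default_conv <- function() biomass_conversion(0.4)

# A sensor-distorted photoautotrophic batch at the standard conditions:
# 500 umol m^-2 s^-1, initial specific rate 0.15 h^-1, 1% noise, n = 3.
photo_batch <- function(seed = 1, ...) {
  sp <- photo_spec(I0 = 500, initial_rate = 0.15, seed = seed, ...)
  apply_sensor_model(simulate_photoautotrophic(sp))
}

het_batch <- function(substrate = "glucose", seed = 1, substrate_noise_sd = 0,
                      ...) {
  sp <- het_spec(substrate, seed = seed, ...)
  apply_sensor_model(simulate_heterotrophic(sp), substrate_noise_sd)
}

# Corrected replicate series of a sensor-distorted batch.
corrected_reps <- function(batch) {
  lapply(batch$od_sensor, correct_series, model = batch$spec$calibration)
}

# Welch two-sample t-test recomputed from the textbook formulas,
# independent of stats::t.test.
welch_oracle_p <- function(x, y) {
  vx <- stats::var(x) / length(x)
  vy <- stats::var(y) / length(y)
  tstat <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  2 * stats::pt(-abs(tstat), df)
}

# Composite-Simpson depth average of the Monod irradiance response,
# independent of the closed form used by the simulator.
simpson_depth_avg <- function(X, mu_max, I0, K_I, sigma, L, n = 1000) {
  z <- seq(0, L, length.out = n + 1)
  f <- mu_max * I0 * exp(-sigma * X * z) / (K_I + I0 * exp(-sigma * X * z))
  h <- L / n
  w <- c(1, rep(c(4, 2), length.out = n - 1), 1)
  sum(w * f) * h / 3 / L
}
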