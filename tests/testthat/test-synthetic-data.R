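test_that("culture_spec validates parameters", {
  expect_error(culture_spec(mu_max = -1), "non-negative")
  expect_error(culture_spec(L = 0), "positive")
  expect_error(culture_spec(I0 = Inf), "finite")
  sp <- culture_spec()
  expect_s3_class(sp, "culture_spec")
  expect_identical(sp$n_replicates, 3L)
  expect_equal(sp$sample_interval, 0.5)
  expect_equal(sp$duration, 72)
})

test_that("closed-form depth average matches a Simpson quadrature oracle", {
  for (X in c(0.01, 0.05, 0.2, 1, 3, 10)) {
    expect_equal(
      depth_avg_rate(X, mu_max = 0.2, I0 = 500, K_I = 150, sigma = 150,
                     L = 0.03),
      simpson_depth_avg(X, mu_max = 0.2, I0 = 500, K_I = 150, sigma = 150,
                        L = 0.03),
      tolerance = 1e-8)
  }
})

test_that("vanishing absorption reduces to a pure exponential", {
  sp <- culture_spec(mode = "photoautotrophic", I0 = 500, mu_max = 0.2,
                     sigma = 1e-8, noise_sd = 0)
  b <- simulate_photoautotrophic(sp)
  rate <- 0.2 * 500 / (150 + 500)
  expect_equal(b$biomass, sp$X0 * exp(rate * b$times), tolerance = 1e-6)
})

test_that("dense cultures approach a constant volumetric productivity", {
  sp <- photo_spec(I0 = 500, initial_rate = 0.15, noise_sd = 0)
  b <- simulate_photoautotrophic(sp)
  dX <- diff(b$biomass) / diff(b$times)
  last24 <- dX[b$times[-1] > max(b$times) - 24]
  asymptote <- sp$mu_max * log((sp$K_I + sp$I0) / sp$K_I) / (sp$sigma * sp$L)
  expect_true(all(abs(last24 / asymptote - 1) < 0.05))
})

test_that("the photoautotrophic truth reports rate and onset consistently", {
  sp <- photo_spec(I0 = 500, initial_rate = 0.15, seed = 1)
  b <- simulate_photoautotrophic(sp)
  expect_equal(b$truth$initial_rate, 0.15, tolerance = 1e-9)
  mu_at <- function(X) depth_avg_rate(X, sp$mu_max, sp$I0, sp$K_I,
                                      sp$sigma, sp$L)
  X_onset <- b$biomass[which.min(abs(b$times - b$truth$onset_h))]
  expect_equal(mu_at(X_onset) / mu_at(sp$X0), 0.95, tolerance = 0.01)
})

test_that("heterotrophic batches conserve the substrate mass balance", {
  sp <- het_spec("glucose", noise_sd = 0)
  b <- simulate_heterotrophic(sp)
  lhs <- b$biomass - sp$X0
  rhs <- sp$Y_true * (sp$S0 - b$substrate$concentration)
  expect_equal(lhs, rhs, tolerance = 1e-8)
  # final biomass approaches X0 + Y * S0 = 8.35 g/L
  expect_equal(b$biomass[length(b$biomass)], 8.35, tolerance = 0.01)
})

test_that("weak light and darkness diverge only after the decay onset", {
  base <- list(substrate = "glucose", mu_max = 0.03, X0 = 0.02,
               dark_decay_rate = 0.05, dark_decay_onset = 50,
               duration = 143, noise_sd = 0)
  dark <- do.call(het_spec, c(base, weak_light = FALSE))
  wl <- do.call(het_spec, c(base, weak_light = TRUE))
  bd <- simulate_heterotrophic(dark)
  bw <- simulate_heterotrophic(wl)
  pre <- bd$times <= 50
  expect_equal(bd$biomass[pre], bw$biomass[pre], tolerance = 1e-8)
  expect_lt(bd$biomass[length(bd$biomass)],
            bw$biomass[length(bw$biomass)])
})

test_that("the sensor model is exact without noise and seeded with it", {
  sp <- photo_spec(I0 = 300, noise_sd = 0, seed = 1)
  b <- apply_sensor_model(simulate_photoautotrophic(sp))
  for (s in b$od_sensor)
    expect_equal(correct_od(s$values, sp$calibration),
                 b$od_corrected$values, tolerance = 1e-9)
  # identity calibration: sensor equals corrected before noise
  sp_id <- photo_spec(I0 = 300, noise_sd = 0,
                      calibration = calibration_model(1, 0), seed = 1)
  b_id <- apply_sensor_model(simulate_photoautotrophic(sp_id))
  expect_equal(b_id$od_sensor[[1]]$values, b_id$od_corrected$values,
               tolerance = 1e-12)
  # determinism: one seed, one dataset
  spn <- photo_spec(I0 = 300, seed = 77)
  b1 <- apply_sensor_model(simulate_photoautotrophic(spn))
  b2 <- apply_sensor_model(simulate_photoautotrophic(spn))
  expect_identical(lapply(b1$od_sensor, `[[`, "values"),
                   lapply(b2$od_sensor, `[[`, "values"))
})

test_that("pigment generator collapses to the base values without effects", {
  tab <- generate_pigment_tables(pigment_base = c(chl_ab = 3),
                                 intensities = c(100, 300),
                                 phase_mult = 1, c_min = 1, c_max = 1,
                                 het_substrates = NULL, noise_sd = 0)
  expect_true(all(tab$percent_dw == 3))
})

test_that("the photoacclimation curve decreases with light intensity", {
  tab <- generate_pigment_tables(pigment_base = c(chl_ab = 3),
                                 intensities = c(100, 300, 500, 700),
                                 phases = "exponential",
                                 het_substrates = NULL, noise_sd = 0)
  means <- tapply(tab$percent_dw, tab$light, mean)
  expect_true(all(diff(means[order(as.numeric(names(means)))]) < 0))
})

test_that("full pipeline closure recovers mu and yield from generated logs", {
  # calibration fitted from generator-emitted dilution pairs, then the
  # sensor logs are corrected, segmented, and estimated
  gen <- fig8_model()
  pairs <- simulate_dilution_series(gen, noise_sd = 0.01, seed = 21)
  fitted <- fit_calibration(pairs)

  pb <- photo_batch(seed = 13)
  mus <- vapply(pb$od_sensor, function(s) {
    cs <- correct_series(s, fitted)
    estimate_mu(cs, segment_phases(cs))$mu
  }, numeric(1))
  expect_equal(mean(mus), 0.15, tolerance = 0.05)

  hb <- het_batch("glucose", seed = 13)
  conv <- biomass_conversion(hb$spec$conversion_k)
  finals <- vapply(hb$od_sensor, function(s)
    od_to_biomass(correct_od(s$values[length(s$values)], fitted), conv),
    numeric(1))
  y <- yield_endpoint(mean(finals), hb$spec$X0, hb$spec$S0)$y
  expect_equal(y, hb$spec$Y_true, tolerance = 0.10)
})
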