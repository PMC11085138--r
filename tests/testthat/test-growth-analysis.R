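test_that("od_series validates its invariants", {
  expect_error(od_series(c(0, 1, 1), c(1, 2, 3)), "strictly increasing")
  expect_error(od_series(0:2, c(1, -1, 2)), "non-negative")
  expect_error(od_series(c(0, 0.5, 1.2), c(1, 2, 3)), "constant")
  s <- od_series(seq(0, 5, 0.5), rep(1, 11), space = "sensor")
  expect_s3_class(s, "od_series")
})

test_that("segmentation finds the whole window on a pure exponential", {
  t <- seq(0, 39.5, by = 0.5)  # 80 points
  s <- od_series(t, 0.1 * exp(0.15 * t))
  seg <- segment_phases(s)
  span_after_lag <- max(t) - 2
  expect_gte(seg$exp_end - seg$exp_start, 0.9 * span_after_lag)
  expect_gte(seg$exp_r_squared, 1 - 1e-10)
})

test_that("segmentation refuses a constant series", {
  t <- seq(0, 35.5, by = 0.5)
  s <- od_series(t, rep(0.5, length(t)))
  expect_error(segment_phases(s), "no exponential phase")
})

test_that("segmentation cuts near the light-limitation onset of a simulated batch", {
  b <- photo_batch(seed = 3)
  onset <- b$truth$onset_h
  for (cs in corrected_reps(b)) {
    seg <- segment_phases(cs)
    # the log-linear window genuinely extends several hours past the 95%
    # onset before curvature exceeds the noise floor
    expect_gte(seg$exp_end, onset - 3)
    expect_lte(seg$exp_end, onset + 10)
  }
})

test_that("mu equals the generating rate on noiseless exponentials", {
  t <- seq(0, 30, by = 0.5)
  s <- od_series(t, 0.1 * exp(0.15 * t))
  seg <- segment_phases(s)
  expect_equal(estimate_mu(s, seg)$mu, 0.15, tolerance = 1e-9)
  # window independence: any sub-window gives the same slope
  for (w in list(c(2, 10), c(5, 20), c(12, 28))) {
    sub_seg <- phase_segmentation(w[1], w[2], w[2], max(t))
    expect_equal(estimate_mu(s, sub_seg)$mu, 0.15, tolerance = 1e-9)
  }
})

test_that("mu survives a round trip through sensor space", {
  m <- fig8_model()
  t <- seq(0, 30, by = 0.5)
  corrected <- 0.1 * exp(0.15 * t)
  sensor <- od_series(t, invert_od(corrected, m), space = "sensor")
  back <- correct_series(sensor, m)
  seg <- segment_phases(back)
  expect_equal(estimate_mu(back, seg)$mu, 0.15, tolerance = 1e-6)
})

test_that("mu is recovered within 5% from noisy replicated batches", {
  b <- photo_batch(seed = 7)
  mus <- vapply(corrected_reps(b), function(cs)
    estimate_mu(cs, segment_phases(cs))$mu, numeric(1))
  expect_equal(mean(mus), 0.15, tolerance = 0.05)
})

test_that("estimate_mu rejects degenerate windows", {
  t <- seq(0, 30, by = 0.5)
  s <- od_series(t, 0.1 * exp(0.15 * t))
  expect_error(estimate_mu(s, phase_segmentation(0, 1, 1, 30)),
               "fewer than 5")
})

test_that("doubling time inverts the specific growth rate", {
  expect_equal(round(doubling_time(0.15), 1), 4.6)
  expect_equal(doubling_time(log(2)), 1)
  expect_equal(doubling_time(log(2) / 20), 20)
  expect_error(doubling_time(0), "mu > 0")
  expect_error(doubling_time(-0.1), "mu > 0")
})

test_that("V_max is 24 k times the slope of a linear deceleration segment", {
  # exponential rise to 15 h, then a linear ramp of slope 0.05 OD/h
  t <- seq(0, 60, by = 0.5)
  rate <- 0.2
  v <- ifelse(t <= 15, 0.1 * exp(rate * t),
              0.1 * exp(rate * 15) + 0.05 * (t - 15))
  s <- od_series(t, v)
  seg <- phase_segmentation(2, 15, 15, 60)
  est <- estimate_vmax(s, seg, biomass_conversion(1))
  expect_equal(est$vmax, 24 * 0.05, tolerance = 1e-9)

  # units consistency: rescaling OD by c with k/c leaves V_max unchanged
  for (c_scale in c(0.2, 5)) {
    s2 <- od_series(t, v * c_scale)
    est2 <- estimate_vmax(s2, seg, biomass_conversion(1 / c_scale))
    expect_equal(est2$vmax, est$vmax, tolerance = 1e-9)
  }
})

test_that("estimate_vmax needs a long enough deceleration window", {
  t <- seq(0, 30, by = 0.5)
  s <- od_series(t, 0.1 * exp(0.1 * t))
  seg <- phase_segmentation(2, 25, 25, 30)
  expect_error(estimate_vmax(s, seg, default_conv()), "shorter than")
})

test_that("V_max recovery lands within 10% of the generating productivity", {
  sp <- photo_spec(I0 = 700, target_vmax = 1.8, seed = 5)
  b <- apply_sensor_model(simulate_photoautotrophic(sp))
  ms <- average_series(corrected_reps(b))
  est <- estimate_vmax(ms, segment_phases(ms), default_conv())
  expect_equal(est$vmax, 1.8, tolerance = 0.10)
  # and the generator's own dense-culture truth is the tuned value
  expect_equal(b$truth$vmax_true, 1.8, tolerance = 0.01)
})

test_that("estimation on corrected sensor series equals direct corrected series", {
  # zero noise: the sensor detour must be analytically transparent
  sp <- photo_spec(I0 = 500, initial_rate = 0.15, noise_sd = 0, seed = 1)
  b <- apply_sensor_model(simulate_photoautotrophic(sp))
  via_sensor <- correct_series(b$od_sensor[[1]], sp$calibration)
  direct <- b$od_corrected
  expect_equal(via_sensor$values, direct$values, tolerance = 1e-6)
  seg_a <- segment_phases(via_sensor); seg_b <- segment_phases(direct)
  expect_equal(estimate_mu(via_sensor, seg_a)$mu,
               estimate_mu(direct, seg_b)$mu, tolerance = 1e-6)
})

test_that("od_to_biomass is linear and recoverable from simulator output", {
  conv <- biomass_conversion(0.5)
  expect_equal(od_to_biomass(0, conv), 0)
  expect_equal(od_to_biomass(2, conv), 1.0)
  b <- simulate_photoautotrophic(photo_spec(I0 = 300, seed = 2))
  k_hat <- unname(coef(lm(b$biomass ~ 0 + b$od_corrected$values)))
  expect_equal(k_hat, b$spec$conversion_k, tolerance = 0.01)
})

test_that("V_max rises with light intensity while mu saturates", {
  mu_shared <- photo_spec(I0 = 500, initial_rate = 0.15)$mu_max
  I0s <- c(100, 300, 500, 700)
  res <- t(vapply(I0s, function(I0) {
    sp <- photo_spec(I0 = I0, mu_max = mu_shared, seed = 11)
    b <- apply_sensor_model(simulate_photoautotrophic(sp))
    cs <- corrected_reps(b)
    mus <- vapply(cs, function(s) estimate_mu(s, segment_phases(s))$mu,
                  numeric(1))
    ms <- average_series(cs)
    c(mu = mean(mus),
      vmax = estimate_vmax(ms, segment_phases(ms), default_conv())$vmax)
  }, numeric(2)))
  expect_true(all(diff(res[, "vmax"]) > 0))
  # decoupling: the light response of mu flattens, that of V_max does not
  expect_lt(res[4, "mu"] / res[3, "mu"], 1.1)
  expect_gt(res[4, "vmax"] / res[3, "vmax"], 1.15)
  # V_max is closer to linear in light intensity than mu
  r2_mu <- summary(lm(res[, "mu"] ~ I0s))$r.squared
  r2_vmax <- summary(lm(res[, "vmax"] ~ I0s))$r.squared
  expect_gt(r2_vmax, r2_mu)
})
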