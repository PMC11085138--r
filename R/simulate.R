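# Mechanistic generator of synthetic batch cultures.
#
# Photoautotrophic mode: Beer-Lambert attenuation across the light path
# gives I(z) = I0 * exp(-sigma * X * z); the local growth rate saturates
# with irradiance in Monod form, and the depth-averaged specific rate has
# the closed form
#   mu_bar(X) = mu_max / (sigma X L) * ln[(K_I + I0) / (K_I + I0 e^{-sigma X L})].
# Self-shading thus turns an initial exponential phase into a long
# deceleration phase with near-constant volumetric productivity.
#
# Heterotrophic mode: Monod kinetics on the organic substrate with yield
# Y_true; substrate is eliminated through the mass balance
# S = S0 - (X - X0)/Y_true, so conservation holds exactly by construction.
# An optional dark-decay factor d(t) = exp(-r * max(0, t - onset)) slows
# growth late in complete darkness; weak light suppresses the decay.
#
# Units: X in g DW L^-1 (numerically equal to kg m^-3), z and L in m,
# sigma in m^2 per kg DW, irradiance in umol m^-2 s^-1, rates in h^-1.

#' Full parameterisation of a simulated batch culture
#'
#' Defaults mirror a multicultivator batch: 3 cm light path, 72 h
#' duration, one sample every 30 min, 3 replicates, 1% multiplicative
#' sensor noise, and the exponential sensor distortion of a dense
#' *C. sorokiniana* culture.
#'
#' @param mode `"photoautotrophic"` or `"heterotrophic"`.
#' @param I0 Incident light intensity, umol m^-2 s^-1 (photoautotrophic).
#' @param L Light-path depth, m (default 0.03, the tube diameter).
#' @param sigma Biomass absorption cross-section, m^2 per kg DW
#'   (default 150).
#' @param mu_max Maximum specific growth rate, h^-1.
#' @param K_I Half-saturation irradiance, umol m^-2 s^-1 (default 150,
#'   placing ~73% saturation at 400 umol m^-2 s^-1).
#' @param maintenance Maintenance (decay) rate, h^-1 (default 0).
#' @param X0 Inoculum biomass density, g L^-1 (default 0.005, a dilute
#'   inoculum leaving a 15-30 h exponential phase before self-shading).
#' @param S0 Initial substrate concentration, g L^-1 (heterotrophic; 15
#'   for glucose, 2 for acetate).
#' @param K_S Substrate half-saturation constant, g L^-1.
#' @param Y_true Generating biomass yield, g DW per g substrate.
#' @param dark_decay_rate Dark-decay rate, h^-1 (0 disables).
#' @param dark_decay_onset Hours after which dark decay sets in.
#' @param weak_light Logical; weak light (a few umol m^-2 s^-1, no net
#'   photosynthesis) suppresses the dark decay.
#' @param conversion_k Biomass per corrected-OD unit, g L^-1 (default 0.4).
#' @param calibration A [calibration_model()] used to distort corrected OD
#'   into sensor space.
#' @param noise_sd Relative SD of multiplicative replicate noise.
#' @param n_replicates Number of replicate tubes (default 3).
#' @param sample_interval Sampling interval, h (default 0.5).
#' @param duration Batch duration, h (default 72).
#' @param seed Integer seed governing all randomness of the batch.
#' @param label Free-text tag.
#' @return An object of class `culture_spec`.
#' @export
culture_spec <- function(mode = c("photoautotrophic", "heterotrophic"),
                         I0 = 500, L = 0.03, sigma = 150, mu_max = 0.2,
                         K_I = 150, maintenance = 0,
                         X0 = 0.005, S0 = 15, K_S = 0.1, Y_true = 0.55,
                         dark_decay_rate = 0, dark_decay_onset = 50,
                         weak_light = FALSE,
                         conversion_k = 0.4,
                         calibration = calibration_model(1.795, 0.934),
                         noise_sd = 0.01, n_replicates = 3,
                         sample_interval = 0.5, duration = 72, seed = 1,
                         label = "") {
  mode <- match.arg(mode)
  num <- c(I0 = I0, L = L, sigma = sigma, mu_max = mu_max, K_I = K_I,
           maintenance = maintenance, X0 = X0, S0 = S0, K_S = K_S,
           Y_true = Y_true, dark_decay_rate = dark_decay_rate,
           dark_decay_onset = dark_decay_onset, conversion_k = conversion_k,
           noise_sd = noise_sd, sample_interval = sample_interval,
           duration = duration)
  if (any(!is.finite(num)))
    stop("all culture parameters must be finite", call. = FALSE)
  if (any(num[c("mu_max", "maintenance", "dark_decay_rate", "noise_sd",
                "I0", "K_I", "K_S", "S0", "X0")] < 0))
    stop("rates and concentrations must be non-negative", call. = FALSE)
  if (L <= 0 || sigma <= 0 || conversion_k <= 0 || duration <= 0 ||
      sample_interval <= 0)
    stop("L, sigma, conversion_k, duration, sample_interval must be positive",
         call. = FALSE)
  stopifnot(inherits(calibration, "calibration_model"))
  structure(c(as.list(num),
              list(mode = mode, weak_light = isTRUE(weak_light),
                   calibration = calibration,
                   n_replicates = as.integer(n_replicates),
                   seed = as.integer(seed), label = label)),
            class = "culture_spec")
}

#' Depth-averaged specific growth rate under self-shading
#'
#' Closed form of the Beer-Lambert / Monod depth average
#' `(1/L) * integral of mu_max I(z) / (K_I + I(z)) dz` with
#' `I(z) = I0 exp(-sigma X z)`. Reduces to the unshaded Monod rate
#' `mu_max I0/(K_I + I0)` as the optical depth `sigma X L -> 0`.
#'
#' @param X Biomass density, g L^-1 (vectorised).
#' @param mu_max,I0,K_I,sigma,L As in [culture_spec()].
#' @return Depth-averaged specific growth rate, h^-1.
#' @export
depth_avg_rate <- function(X, mu_max, I0, K_I, sigma, L) {
  tau <- sigma * X * L
  out <- numeric(length(tau))
  small <- tau < 1e-10
  out[small] <- mu_max * I0 / (K_I + I0)
  if (any(!small)) {
    tb <- tau[!small]
    out[!small] <- mu_max / tb *
      log((K_I + I0) / (K_I + I0 * exp(-tb)))
  }
  out
}

.solve_trajectory <- function(deriv, X0, duration, sample_interval, parms) {
  fine <- sample_interval / 5
  times <- seq(0, duration, by = fine)
  sol <- deSolve::ode(y = c(X = X0), times = times, func = deriv,
                      parms = parms, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  X <- sol[, "X"]
  keep <- seq(1, length(times), by = 5L)
  list(fine_times = times, fine_X = X,
       times = times[keep], X = X[keep])
}

#' Simulate a light-limited photoautotrophic batch
#'
#' Integrates `dX/dt = (mu_bar(X) - maintenance) * X` with the
#' depth-averaged rate of [depth_avg_rate()] and samples the trajectory at
#' the configured interval. Ground truths exposed in `$truth`: the initial
#' specific growth rate, the light-limitation onset (first time the
#' depth-averaged rate falls below 95% of its inoculum value), and the
#' maximum volumetric productivity along the dense trajectory.
#'
#' @param spec A [culture_spec()] with mode `"photoautotrophic"`.
#' @return An object of class `simulated_batch`: list with `spec`,
#'   `truth`, `times`, `biomass`, and `od_corrected` (an [od_series()]);
#'   pass through [apply_sensor_model()] for sensor-space replicates.
#' @export
simulate_photoautotrophic <- function(spec) {
  stopifnot(inherits(spec, "culture_spec"))
  if (spec$mode != "photoautotrophic")
    stop("spec mode must be photoautotrophic", call. = FALSE)
  deriv <- function(t, y, p) {
    mu <- depth_avg_rate(y[1], p$mu_max, p$I0, p$K_I, p$sigma, p$L)
    list((mu - p$maintenance) * y[1])
  }
  tr <- .solve_trajectory(deriv, spec$X0, spec$duration,
                          spec$sample_interval, spec)
  mu_fine <- depth_avg_rate(tr$fine_X, spec$mu_max, spec$I0, spec$K_I,
                            spec$sigma, spec$L)
  mu0 <- mu_fine[1]
  below <- which(mu_fine < 0.95 * mu0)
  onset <- if (length(below)) tr$fine_times[below[1]] else NA_real_
  dXdt <- (mu_fine - spec$maintenance) * tr$fine_X
  truth <- list(initial_rate = mu0 - spec$maintenance,
                onset_h = onset,
                vmax_true = 24 * max(dXdt),
                Y_true = NA_real_)
  od <- od_series(tr$times, tr$X / spec$conversion_k, space = "corrected",
                  channel = paste0(spec$label, "corrected"))
  structure(list(spec = spec, truth = truth, times = tr$times,
                 biomass = tr$X, od_corrected = od,
                 substrate = NULL, od_sensor = NULL),
            class = "simulated_batch")
}

#' Simulate a heterotrophic (Monod) batch on glucose or acetate
#'
#' Integrates `dX/dt = mu_eff * X` with
#' `mu_eff = mu_max * S/(K_S + S) * d(t)`, where the substrate follows the
#' exact mass balance `S = S0 - (X - X0)/Y_true` and
#' `d(t) = exp(-dark_decay_rate * max(0, t - dark_decay_onset))` in
#' complete darkness (`d = 1` under weak light). With
#' `dark_decay_rate = 0` the final biomass approaches `X0 + Y_true * S0`.
#'
#' @param spec A [culture_spec()] with mode `"heterotrophic"` and `S0 > 0`.
#' @return A `simulated_batch` whose `substrate` field is a
#'   [substrate_series()]; `$truth` carries `Y_true`, the initial specific
#'   rate, and the asymptotic final biomass.
#' @export
simulate_heterotrophic <- function(spec) {
  stopifnot(inherits(spec, "culture_spec"))
  if (spec$mode != "heterotrophic")
    stop("spec mode must be heterotrophic", call. = FALSE)
  if (spec$S0 <= 0)
    stop("heterotrophic simulation needs S0 > 0", call. = FALSE)
  deriv <- function(t, y, p) {
    S <- max(p$S0 - (y[1] - p$X0) / p$Y_true, 0)
    d <- if (p$weak_light) 1 else
      exp(-p$dark_decay_rate * max(0, t - p$dark_decay_onset))
    list(p$mu_max * S / (p$K_S + S) * d * y[1])
  }
  tr <- .solve_trajectory(deriv, spec$X0, spec$duration,
                          spec$sample_interval, spec)
  S <- pmax(spec$S0 - (tr$X - spec$X0) / spec$Y_true, 0)
  truth <- list(initial_rate = spec$mu_max * spec$S0 / (spec$K_S + spec$S0),
                onset_h = NA_real_,
                vmax_true = NA_real_,
                Y_true = spec$Y_true,
                X_final_asymptote = spec$X0 + spec$Y_true * spec$S0)
  od <- od_series(tr$times, tr$X / spec$conversion_k, space = "corrected",
                  channel = paste0(spec$label, "corrected"))
  structure(list(spec = spec, truth = truth, times = tr$times,
                 biomass = tr$X,
                 od_corrected = od,
                 substrate = substrate_series(tr$times, S),
                 od_sensor = NULL),
            class = "simulated_batch")
}

#' @export
print.simulated_batch <- function(x, ...) {
  cat(sprintf("Simulated %s batch: %d samples over %g h, X %.3g -> %.3g g/L\n",
              x$spec$mode, length(x$times), x$spec$duration,
              x$biomass[1], x$biomass[length(x$biomass)]))
  invisible(x)
}

#' Distort a simulated batch into sensor space with replicate noise
#'
#' Inverts the calibration to produce the apparent-OD trace the
#' multicultivator would log, then adds multiplicative Gaussian noise per
#' replicate. All randomness derives from the spec's seed, so identical
#' seeds reproduce identical series.
#'
#' @param batch A `simulated_batch`.
#' @param substrate_noise_sd Relative SD of multiplicative noise applied
#'   to the substrate series (default 0, i.e. the substrate assay is
#'   treated as exact).
#' @return The batch with `od_sensor` set to a list of `n_replicates`
#'   sensor-space [od_series()] objects (and, when requested, a noisy
#'   substrate series).
#' @export
apply_sensor_model <- function(batch, substrate_noise_sd = 0) {
  stopifnot(inherits(batch, "simulated_batch"))
  spec <- batch$spec
  clean <- invert_od(batch$od_corrected$values, spec$calibration)
  set.seed(spec$seed)
  batch$od_sensor <- lapply(seq_len(spec$n_replicates), function(r) {
    noisy <- clean
    if (spec$noise_sd > 0)
      noisy <- clean * (1 + stats::rnorm(length(clean), 0, spec$noise_sd))
    od_series(batch$times, pmax(noisy, 0), space = "sensor",
              channel = sprintf("%srep%d", spec$label, r))
  })
  if (!is.null(batch$substrate) && substrate_noise_sd > 0) {
    s <- batch$substrate
    noisy <- pmax(s$concentration *
                    (1 + stats::rnorm(length(s$concentration), 0,
                                      substrate_noise_sd)), 0)
    batch$substrate <- substrate_series(s$times, noisy, s$substrate)
  }
  batch
}

#' Photoautotrophic preset anchored to the observed growth magnitudes
#'
#' Builds a [culture_spec()] whose `mu_max` is solved from one of three
#' anchors: a target initial specific growth rate (default 0.15 h^-1, the
#' highest exponential-phase rate seen in the multicultivator batches), a
#' target dense-culture volumetric productivity (`target_vmax`, g L^-1
#' day^-1, using the closed-form dense limit
#' `dX/dt -> mu_max ln((K_I + I0)/K_I) / (sigma L)`), or `mu_max`
#' directly.
#'
#' @param I0 Incident light intensity, umol m^-2 s^-1.
#' @param initial_rate Target initial specific growth rate, h^-1.
#' @param target_vmax Target dense-culture productivity, g L^-1 day^-1
#'   (requires zero maintenance).
#' @param mu_max Explicit maximum specific rate (overrides the anchors).
#' @param ... Further arguments to [culture_spec()].
#' @return A photoautotrophic [culture_spec()].
#' @export
photo_spec <- function(I0 = 500, initial_rate = 0.15, target_vmax = NULL,
                       mu_max = NULL, ...) {
  base <- culture_spec(mode = "photoautotrophic", I0 = I0, mu_max = 1, ...)
  if (is.null(mu_max)) {
    if (!is.null(target_vmax)) {
      if (base$maintenance != 0)
        stop("target_vmax preset assumes zero maintenance", call. = FALSE)
      mu_max <- (target_vmax / 24) * base$sigma * base$L /
        log((base$K_I + I0) / base$K_I)
    } else {
      g0 <- depth_avg_rate(base$X0, 1, I0, base$K_I, base$sigma, base$L)
      mu_max <- (initial_rate + base$maintenance) / g0
    }
  }
  culture_spec(mode = "photoautotrophic", I0 = I0, mu_max = mu_max, ...)
}

#' Heterotrophic preset for glucose or acetate batches
#'
#' Glucose batches start at 15 g L^-1 with a generating yield of 0.55
#' g/g; acetate batches at 2 g L^-1 with 0.32 g/g — the magnitudes
#' observed for the fast-growing strains. `mu_max` defaults to 0.10 h^-1,
#' within the 0.08-0.13 h^-1 range of the fast heterotrophic growers.
#'
#' @param substrate `"glucose"` or `"acetate"`.
#' @param Y_true Generating yield (defaults per substrate).
#' @param mu_max Maximum specific growth rate, h^-1.
#' @param X0 Inoculum density, g L^-1 (default 0.1).
#' @param ... Further arguments to [culture_spec()].
#' @return A heterotrophic [culture_spec()].
#' @export
het_spec <- function(substrate = c("glucose", "acetate"), Y_true = NULL,
                     mu_max = 0.10, X0 = 0.1, ...) {
  substrate <- match.arg(substrate)
  S0 <- switch(substrate, glucose = 15, acetate = 2)
  if (is.null(Y_true)) Y_true <- switch(substrate, glucose = 0.55,
                                        acetate = 0.32)
  culture_spec(mode = "heterotrophic", S0 = S0, Y_true = Y_true,
               mu_max = mu_max, X0 = X0, ...)
}

#' Generate synthetic pigment tables with a known effect structure
#'
#' Mean content per cell (percent of dry weight) is
#' `base * acclim(I) * phase_mult^[deceleration] ` for photoautotrophic
#' cells, with the photoacclimation curve
#' `acclim(I) = c_min + (c_max - c_min) * K_A / (K_A + I)` (strictly
#' decreasing in irradiance when `c_max > c_min`). Heterotrophic cells are
#' expressed relative to the photoautotrophic deceleration reference
#' (the mean of the deceleration-phase means over `intensities`):
#' `suppression * substrate_mult * weaklight_mult^[weak light] * reference`.
#' Replicates get multiplicative Gaussian noise.
#'
#' @param species Species label.
#' @param pigment_base Named vector of base contents, %DW, at the
#'   exponential phase and `acclim = 1`.
#' @param intensities Photoautotrophic light intensities, umol m^-2 s^-1.
#' @param phases Photoautotrophic phases to emit.
#' @param phase_mult Deceleration-phase multiplier (photoacclimation to
#'   self-shading; 1 = no phase effect).
#' @param c_min,c_max,K_A Photoacclimation curve parameters.
#' @param het_substrates Heterotrophic substrates to emit (`NULL` for a
#'   photoautotrophic-only table).
#' @param weak_light_levels Logical vector of weak-light states to emit
#'   for each heterotrophic substrate.
#' @param suppression Heterotrophic content as a fraction of the
#'   photoautotrophic deceleration reference.
#' @param substrate_mult Named multipliers per substrate.
#' @param weaklight_mult Multiplier applied under weak light.
#' @param noise_sd Relative replicate noise SD.
#' @param n_replicates Replicates per cell (default 3).
#' @param seed Integer seed.
#' @param weak_light_intensity Intensity recorded for weak-light rows.
#' @return A [pigment_records()] data frame.
#' @export
generate_pigment_tables <- function(species = "C. sorokiniana",
                                    pigment_base = c(chl_ab = 3, lutein = 0.4,
                                                     carotene = 0.15),
                                    intensities = c(100, 300, 500, 700),
                                    phases = c("exponential", "deceleration"),
                                    phase_mult = 1.5,
                                    c_min = 0.6, c_max = 1.4, K_A = 200,
                                    het_substrates = c("glucose", "acetate"),
                                    weak_light_levels = c(FALSE, TRUE),
                                    suppression = 0.23,
                                    substrate_mult = c(glucose = 1, acetate = 1),
                                    weaklight_mult = 1,
                                    noise_sd = 0.05, n_replicates = 3,
                                    seed = 1,
                                    weak_light_intensity = 5) {
  stopifnot(all(c(phase_mult, suppression, substrate_mult,
                  weaklight_mult) >= 0),
            all(is.finite(c(phase_mult, suppression, weaklight_mult))))
  acclim <- function(I) c_min + (c_max - c_min) * K_A / (K_A + I)
  set.seed(seed)
  rows <- list()
  draw <- function(mean_val) {
    if (noise_sd > 0)
      pmax(mean_val * (1 + stats::rnorm(n_replicates, 0, noise_sd)), 0)
    else rep(mean_val, n_replicates)
  }
  for (pg in names(pigment_base)) {
    base <- pigment_base[[pg]]
    for (ph in phases) {
      pm <- if (ph == "deceleration") phase_mult else 1
      for (I in intensities) {
        rows[[length(rows) + 1L]] <- pigment_records(
          species, "photoautotrophic", I, "none", ph, pg,
          seq_len(n_replicates), draw(base * acclim(I) * pm))
      }
    }
    if (!is.null(het_substrates)) {
      ref <- base * phase_mult * mean(acclim(intensities))
      for (s in het_substrates) {
        sm <- if (s %in% names(substrate_mult)) substrate_mult[[s]] else 1
        for (wl in weak_light_levels) {
          m <- suppression * sm * (if (wl) weaklight_mult else 1) * ref
          rows[[length(rows) + 1L]] <- pigment_records(
            species, "heterotrophic",
            if (wl) weak_light_intensity else 0, s,
            "heterotrophic-sample", pg, seq_len(n_replicates), draw(m))
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("pigment_records", "data.frame")
  out
}
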