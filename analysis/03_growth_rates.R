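#!/usr/bin/env Rscript
# Growth analysis of the simulated photoautotrophic light scan: correct
# the sensor logs, segment phases, and estimate mu and V_max per
# intensity. The headline pattern: mu saturates with incident light while
# V_max keeps rising, so the two parameters decouple across intensities.

suppressMessages(library(phycobatch))
data_dir <- "results/data"
if (!dir.exists(data_dir))
  stop("run analysis/01_simulate_datasets.R first")
dir.create("results", showWarnings = FALSE)

rows <- list()
for (I0 in c(100, 300, 500, 700)) {
  dir <- file.path(data_dir, sprintf("photo_I%03d", I0))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  model <- calibration_model(truth$spec$calibration$a,
                             truth$spec$calibration$b)
  conv <- biomass_conversion(truth$spec$conversion_k)
  logs <- read_od_log(file.path(dir, "sensor_log.csv"))
  corrected <- lapply(logs, correct_series, model = model)
  mus <- vapply(corrected, function(s)
    estimate_mu(s, segment_phases(s))$mu, numeric(1))
  ms <- average_series(corrected)
  vmax <- estimate_vmax(ms, segment_phases(ms), conv)$vmax
  rows[[as.character(I0)]] <- data.frame(
    I0 = I0, mu = mean(mus), mu_sd = sd(mus),
    doubling_time = doubling_time(mean(mus)), vmax = vmax,
    mu_true = truth$truth$initial_rate)
  cat(sprintf("I0 = %3d: mu = %.4f /h (true %.3f), t_d = %.1f h, V_max = %.2f g/L/day\n",
              I0, mean(mus), truth$truth$initial_rate,
              doubling_time(mean(mus)), vmax))
}
tab <- do.call(rbind, rows)

fit_mu <- summary(lm(mu ~ I0, data = tab))$r.squared
fit_v <- summary(lm(vmax ~ I0, data = tab))$r.squared
cat(sprintf("\nmu(700)/mu(500)     = %.3f (saturating)\n",
            tab$mu[4] / tab$mu[3]))
cat(sprintf("Vmax(700)/Vmax(500) = %.3f (still rising)\n",
            tab$vmax[4] / tab$vmax[3]))
cat(sprintf("linear R^2: V_max %.3f vs mu %.3f -> V_max responds more\n",
            fit_v, fit_mu))
cat("linearly to incident light than mu: the two parameters decouple.\n")

utils::write.table(tab, "results/growth_rates_by_intensity.csv", sep = ",",
                   row.names = FALSE, quote = FALSE)
cat("written: results/growth_rates_by_intensity.csv\n")
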