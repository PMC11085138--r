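#!/usr/bin/env Rscript
# Generate the synthetic multicultivator datasets every later step
# consumes: photoautotrophic batches across 100-700 umol m^-2 s^-1, Monod
# heterotrophic batches on glucose (15 g/L) and acetate (2 g/L), the
# long weak-light-vs-darkness pair, and replicate pigment tables.
# Everything lands under results/data/.

suppressMessages(library(phycobatch))
seed <- 20260927L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cat("== Photoautotrophic light scan ==\n")
mu_shared <- photo_spec(I0 = 500, initial_rate = 0.15)$mu_max
for (I0 in c(100, 300, 500, 700)) {
  sp <- photo_spec(I0 = I0, mu_max = mu_shared, seed = seed + I0)
  b <- apply_sensor_model(simulate_photoautotrophic(sp))
  write_batch_dataset(b, file.path(out, sprintf("photo_I%03d", I0)))
  cat(sprintf("  I0 = %3d: initial rate %.4f /h, onset %.1f h, final %.2f g/L\n",
              I0, b$truth$initial_rate, b$truth$onset_h,
              b$biomass[length(b$biomass)]))
}

cat("== Heterotrophic batches ==\n")
for (sub in c("glucose", "acetate")) {
  sp <- het_spec(sub, seed = seed + nchar(sub))
  b <- apply_sensor_model(simulate_heterotrophic(sp), substrate_noise_sd = 0.02)
  write_batch_dataset(b, file.path(out, paste0("het_", sub)))
  cat(sprintf("  %s: Y_true %.2f, final biomass %.2f g/L (asymptote %.2f)\n",
              sub, sp$Y_true, b$biomass[length(b$biomass)],
              b$truth$X_final_asymptote))
}

cat("== Weak-light stimulation pair (slow grower, 143 h) ==\n")
for (wl in c(FALSE, TRUE)) {
  sp <- het_spec("glucose", mu_max = 0.03, X0 = 0.02,
                 dark_decay_rate = 0.05, dark_decay_onset = 50,
                 duration = 143, weak_light = wl, seed = seed + 7)
  b <- apply_sensor_model(simulate_heterotrophic(sp))
  write_batch_dataset(b, file.path(out,
                                   if (wl) "weaklight_on" else "weaklight_off"))
  cat(sprintf("  weak light %-5s: final biomass %.3f g/L\n",
              wl, b$biomass[length(b$biomass)]))
}

cat("== Pigment tables ==\n")
tab <- generate_pigment_tables(phase_mult = 1.5, weaklight_mult = 2,
                               substrate_mult = c(glucose = 0.5, acetate = 1),
                               suppression = 0.23, noise_sd = 0.05,
                               seed = seed)
utils::write.table(tab, file.path(out, "pigments.csv"), sep = ",",
                   row.names = FALSE, quote = FALSE)
cat(sprintf("  %d replicate measurements written\n", nrow(tab)))

cat("Datasets written under", out, "\n")
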