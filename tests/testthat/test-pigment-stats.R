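test_that("percent_dw converts micrograms per milligram to %DW", {
  expect_equal(percent_dw(50, 1), 5)
  expect_equal(percent_dw(0, 1), 0)
  expect_equal(percent_dw(6, 1), 0.6)
  expect_error(percent_dw(10, 0), "positive")
})

test_that("reference percentage relates heterotrophic content to the photo reference", {
  mk <- function(vals, mode, light, phase) pigment_records(
    "sp", mode, light, "acetate", phase, "lutein",
    seq_along(vals), vals)
  photo <- rbind(mk(c(2, 2, 2), "photoautotrophic", 100, "deceleration"),
                 mk(c(4, 4, 4), "photoautotrophic", 700, "deceleration"))
  # het mean equal to the reference mean (3) -> 100%
  expect_equal(reference_percentage(
    mk(c(3, 3, 3), "heterotrophic", 0, "heterotrophic-sample"), photo)$percentage,
    100)
  expect_equal(reference_percentage(
    mk(c(1.5, 1.5, 1.5), "heterotrophic", 0, "heterotrophic-sample"),
    photo)$percentage, 50)
  # scale invariance
  photo_scaled <- photo; photo_scaled$percent_dw <- photo$percent_dw * 7
  het <- mk(c(1.2, 1.5, 1.3), "heterotrophic", 0, "heterotrophic-sample")
  het_scaled <- het; het_scaled$percent_dw <- het$percent_dw * 7
  expect_equal(reference_percentage(het, photo)$percentage,
               reference_percentage(het_scaled, photo_scaled)$percentage,
               tolerance = 1e-12)
})

test_that("reference percentage enforces record consistency", {
  a <- pigment_records("sp1", "heterotrophic", 0, "acetate",
                       "heterotrophic-sample", "lutein", 1:3, c(1, 1, 1))
  b <- pigment_records("sp2", "photoautotrophic", c(100, 100, 700, 700), "none",
                       "deceleration", "lutein", c(1:2, 1:2), rep(2, 4))
  expect_error(reference_percentage(a, b), "mismatch")
  one_int <- b[b$light == 100, ]
  class(one_int) <- class(b)
  one_int$species <- "sp1"
  expect_error(reference_percentage(a, one_int), "2 light intensities")
})

test_that("a generator suppression factor of 0.23 yields a 23% reference value", {
  tab <- generate_pigment_tables(suppression = 0.23, noise_sd = 0,
                                 substrate_mult = c(glucose = 1, acetate = 1),
                                 weaklight_mult = 1)
  het <- tab[tab$mode == "heterotrophic" & tab$substrate == "acetate" &
               tab$light == 0 & tab$pigment == "carotene", ]
  photo <- tab[tab$mode == "photoautotrophic" & tab$phase == "deceleration" &
                 tab$pigment == "carotene", ]
  expect_equal(reference_percentage(het, photo)$percentage, 23,
               tolerance = 1e-9)
})

test_that("contrast implements the Welch test with degenerate conventions", {
  # identical groups: estimate 0, not significant, flagged degenerate
  ct <- contrast(c(2, 2, 2), c(2, 2, 2))
  expect_equal(ct$estimate, 0)
  expect_equal(ct$p_value, 1)
  expect_false(ct$significant)
  expect_true(ct$degenerate)
  # a +10 shift with the same spread is significant
  ct2 <- contrast(c(1, 2, 3) + 10, c(1, 2, 3))
  expect_true(ct2$significant)
  expect_equal(ct2$p_value, welch_oracle_p(c(11, 12, 13), c(1, 2, 3)),
               tolerance = 1e-12)
  # near-identical textbook pair: clearly non-significant
  g1 <- c(2.1, 2.2, 2.0); g2 <- c(2.1, 2.0, 2.2)
  ct3 <- contrast(g1, g2)
  expect_gt(ct3$p_value, 0.9)
  expect_equal(ct3$p_value, welch_oracle_p(g1, g2), tolerance = 1e-12)
})

test_that("effect_table covers the four contrast families", {
  tab <- generate_pigment_tables(phase_mult = 2, weaklight_mult = 2,
                                 substrate_mult = c(glucose = 0.5, acetate = 1),
                                 noise_sd = 0.05, seed = 3)
  et <- effect_table(tab)
  expect_setequal(unique(et$design),
                  c("light", "phase", "weaklight", "substrate"))
  # strong generated effects are detected
  expect_true(all(et$significant[et$design == "phase"]))
  expect_true(all(et$significant[et$design == "weaklight"]))
  expect_true(all(et$significant[et$design == "substrate"]))
  expect_true(all(et$p_value >= 0 & et$p_value <= 1))
})

test_that("effect_table on an empty table returns an empty report", {
  et <- effect_table(NULL)
  expect_identical(nrow(et), 0L)
  et2 <- effect_table(generate_pigment_tables()[0, ])
  expect_identical(nrow(et2), 0L)
})

test_that("missing design cells are listed, not fatal", {
  tab <- generate_pigment_tables(het_substrates = "glucose",
                                 weak_light_levels = FALSE, seed = 1)
  et <- effect_table(tab, design = c("weaklight", "substrate"))
  expect_identical(nrow(et), 0L)
  expect_gt(length(attr(et, "missing_cells")), 0)
})

test_that("null phase contrasts control the type-I error at alpha", {
  # 1000 null replicates of a two-phase, one-intensity, one-pigment table.
  # The Welch test is conservative at n = 3 (true level ~0.035 under equal
  # variances), so the rejection rate must not exceed the nominal level
  # but is allowed to fall below it.
  hits <- 0L; n_rep <- 1000L
  for (r in seq_len(n_rep)) {
    tab <- generate_pigment_tables(pigment_base = c(chl_ab = 3),
                                   intensities = 300, phase_mult = 1,
                                   het_substrates = NULL,
                                   noise_sd = 0.05, seed = 20000 + r)
    et <- effect_table(tab, design = "phase")
    hits <- hits + sum(et$significant)
  }
  rate <- hits / n_rep
  band <- 2.576 * sqrt(0.05 * 0.95 / n_rep)
  expect_lt(rate, 0.05 + band)
  expect_gt(rate, 0.01)
})

test_that("a doubled weak-light effect is detected in almost all replicates", {
  n_rep <- 200L
  sig <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    tab <- generate_pigment_tables(pigment_base = c(lutein = 0.4),
                                   intensities = c(100, 300),
                                   het_substrates = "glucose",
                                   weaklight_mult = 2, noise_sd = 0.05,
                                   seed = 31000 + r)
    et <- effect_table(tab, design = "weaklight")
    sig[r] <- all(et$significant)
  }
  expect_gte(mean(sig), 0.95)
})

test_that("Benjamini-Hochberg adjustment is available but off by default", {
  tab <- generate_pigment_tables(noise_sd = 0.08, seed = 9)
  raw <- effect_table(tab)
  adj <- effect_table(tab, p_adjust = "BH")
  expect_true(all(adj$p_value >= raw$p_value - 1e-12))
})

test_that("pigment records reject impossible contents", {
  expect_error(pigment_records("s", "heterotrophic", 0, "glucose",
                               "heterotrophic-sample", "chl_ab", 1, -1),
               "non-negative")
  expect_error(pigment_records("s", "heterotrophic", 0, "glucose",
                               "heterotrophic-sample", "chl_ab", 1, 150),
               "below 100")
})
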