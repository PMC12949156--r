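test_that("default cohort has the study's group sizes and focal 32 kHz loss
          in the acute group", {
  co <- generate_cohort(seed = 1)
  expect_equal(nrow(co$ears), 57)
  expect_equal(as.integer(table(co$ears$group)[c("young", "acute_noise",
                                                 "aged", "aged_noise")]),
               c(17, 13, 14, 13))
  expect_equal(sum(co$ears$sex == "F"), 32)
  mean_syn <- function(g, f) {
    mean(co$truth$synapses_per_ihc[co$truth$group == g &
                                     co$truth$frequency_hz == f])
  }
  # acute noise: ~50% loss at 32 kHz, 16 kHz near baseline
  expect_lt(abs(mean_syn("acute_noise", 32000) /
                  mean_syn("young", 32000) - 0.5), 0.1)
  expect_gt(mean_syn("acute_noise", 16000) / mean_syn("young", 16000), 0.9)
  # aged groups: broad loss at both frequencies
  for (f in c(16000, 32000)) {
    expect_lt(mean_syn("aged", f), 0.85 * mean_syn("young", f))
    expect_lt(mean_syn("aged_noise", f), mean_syn("aged", f))
  }
  expect_true(all(co$truth$synapses_per_ihc >= 0))
})

test_that("cohorts are reproducible under a fixed seed and differ across
          seeds", {
  a <- generate_cohort(seed = 5)
  b <- generate_cohort(seed = 5)
  expect_identical(a$truth, b$truth)
  expect_identical(a$scatter, b$scatter)
  c_ <- generate_cohort(seed = 6)
  expect_false(identical(a$truth, c_$truth))
})

test_that("EFR trial simulation is linear in synapse count and alternates
          polarity", {
  cfg <- test_config()
  co <- generate_cohort(cfg, seed = 2)
  spec <- efr_stimulus("ram", 16000, 1000)
  ts <- simulate_efr_trials(co, "ear_01", spec, seed = 3, noise_sd_uv = 0,
                            artifact_amp_uv = 0)
  expect_equal(nrow(ts$trials), 128)
  expect_equal(sum(ts$polarity > 0), 64)
  expect_equal(ts$polarity[1:4], c(1, -1, 1, -1))
  # noiseless, artifact-free: every trial identical, bootstrap variance 0
  expect_equal(max(abs(sweep(ts$trials, 2, ts$trials[1, ]))), 0)
  b <- bootstrap_spectrum(ts, n_draws = 10, seed = 4)
  expect_equal(sd(b$mags[, 1]), 0, tolerance = 1e-12)
  # doubling every synapse doubles each harmonic component
  co2 <- co
  co2$truth$synapses_per_ihc <- co$truth$synapses_per_ihc * 2
  ts2 <- simulate_efr_trials(co2, "ear_01", spec, seed = 3,
                             noise_sd_uv = 0, artifact_amp_uv = 0)
  b2 <- bootstrap_spectrum(ts2, n_draws = 10, seed = 4)
  expect_equal(unname(colMeans(b2$mags)), unname(colMeans(b$mags)) * 2,
               tolerance = 1e-9)
  expect_error(simulate_efr_trials(co, "ear_01",
                                   efr_stimulus("ram", 24000, 110)),
               "synapse map")
})

test_that("a polarity-inverting artifact cancels in balanced averages", {
  # sub-Nyquist carrier so the artifact bin is directly inspectable
  cfg <- test_config(frequencies = c(3000, 32000))
  co <- generate_cohort(cfg, seed = 3)
  spec <- efr_stimulus("sam", 3000, 110)
  ts <- simulate_efr_trials(co, "ear_01", spec, seed = 4,
                            sample_rate_hz = 8000, noise_sd_uv = 0,
                            artifact_amp_uv = 2)
  sp_bal <- amplitude_spectrum(colMeans(ts$trials), 8000)
  carrier_bin <- round(3000 / sp_bal$bin_hz) + 1
  expect_lt(sp_bal$amplitude[carrier_bin], 1e-10)
  # single-polarity average retains the artifact at full amplitude
  sp_pos <- amplitude_spectrum(colMeans(ts$trials[ts$polarity > 0, ]), 8000)
  expect_gt(sp_pos$amplitude[carrier_bin], 1.9)
})

test_that("evoked amplitude increases with synapse count and anticorrelates
          with DPOAE threshold across the cohort", {
  co <- generate_cohort(seed = 7)
  # noiseless f0 amplitude for every ear at 16 kHz
  spec <- efr_stimulus("ram", 16000, 1000)
  amps <- sapply(co$ears$ear_id, function(e) {
    ts <- simulate_efr_trials(co, e, spec, seed = 1, noise_sd_uv = 0,
                              artifact_amp_uv = 0)
    bootstrap_spectrum(ts, n_draws = 2, seed = 1)$mags[1, 1]
  })
  syn <- co$truth$synapses_per_ihc[co$truth$frequency_hz == 16000]
  ohc <- co$truth$ohc_loss_db[co$truth$frequency_hz == 16000]
  fit <- lm(amps ~ syn + ohc)
  expect_gt(coef(fit)[["syn"]], 0)
  thr <- sapply(co$ears$ear_id, function(e) {
    dpoae_threshold(simulate_dpoae_io(co, e, 16000, seed = 1,
                                      noise_sd_db = 0))
  })
  ct <- pearson_with_ci(thr, amps, 95)
  expect_lt(ct$r, 0)
  expect_true(ct$significant)
})

test_that("ABR growth saturates, shifts with OHC loss, and scales with
          synapses", {
  cfg <- test_config()
  co <- generate_cohort(cfg, seed = 9)
  g <- simulate_abr_growth(co, "ear_01", 16000, seed = 1, noise_sd_uv = 0)
  expect_true(all(diff(g$wave1_uv) >= 0))
  # amplitude at 80 dB SPL proportional to synapse count when noiseless
  co2 <- co
  co2$truth$synapses_per_ihc <- co$truth$synapses_per_ihc * 3
  g3 <- simulate_abr_growth(co2, "ear_01", 16000, seed = 1, noise_sd_uv = 0)
  expect_equal(g3$wave1_uv, g$wave1_uv * 3, tolerance = 1e-9)
  # zero synapses leave nothing but noise
  co0 <- co
  co0$truth$synapses_per_ihc <- 0
  g0 <- simulate_abr_growth(co0, "ear_01", 16000, seed = 1, noise_sd_uv = 0)
  expect_equal(max(abs(g0$wave1_uv)), 0)
  # a 20 dB OHC loss shifts the level where growth begins by 20 dB
  coh <- co
  coh$truth$ohc_loss_db <- 0
  base <- synapredict:::abr_expected_curve(coh, "ear_01", 16000,
                                           levels = seq(10, 120, 5))
  coh$truth$ohc_loss_db <- 20
  shifted <- synapredict:::abr_expected_curve(coh, "ear_01", 16000,
                                              levels = seq(10, 120, 5))
  # the OHC attenuation also scales the plateau; compare shapes after
  # normalizing
  expect_equal(shifted[-(1:4)] / max(shifted), (base / max(base))[
    seq_len(length(base) - 4)], tolerance = 1e-3)
})

test_that("DPOAE I/O crosses 0 dB SPL at baseline threshold plus OHC loss", {
  co <- generate_cohort(seed = 11)
  for (e in c("ear_01", "ear_40")) {
    io <- simulate_dpoae_io(co, e, 32000, seed = 1, noise_sd_db = 0)
    truth <- co$truth[co$truth$ear_id == e &
                        co$truth$frequency_hz == 32000, ]
    expected <- co$config$dpoae_threshold_db + truth$ohc_loss_db
    thr <- dpoae_threshold(io)
    if (expected <= max(io$l2_levels)) {
      expect_equal(thr, expected, tolerance = 1e-9)
    } else {
      expect_true(is.na(thr))
    }
    expect_equal(io$f2_f1_ratio, 1.2)
    expect_equal(io$l1_rule, "L2 + 10 dB")
  }
})
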