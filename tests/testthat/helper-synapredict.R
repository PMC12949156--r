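# Shared fixture builders (everything is generated in code at test time).

# A cohort config with arbitrary analysis frequencies, keeping the default
# group structure. Useful when tests need a sub-Nyquist carrier.
test_config <- function(frequencies = c(16000, 32000), ...) {
  fl <- as.character(frequencies)
  base <- c(17, 15)[seq_along(frequencies)]
  gl <- rbind(young = c(0, 0), acute_noise = c(0, 0.5),
              aged = c(0.30, 0.35), aged_noise = c(0.45, 0.50))
  colnames(gl) <- fl
  cohort_config(frequencies = frequencies,
                baseline_synapses = stats::setNames(base, fl),
                group_loss = gl[, seq_along(frequencies), drop = FALSE],
                ...)
}

# Hand-built EFR trial set: deterministic harmonic components plus optional
# white noise and polarity-inverting artifact.
make_trial_set <- function(amps = c(1, 0, 0, 0, 0), fm_hz = 110,
                           sample_rate_hz = 2000, duration_s = 0.5,
                           n_trials = 128, noise_sd = 0,
                           artifact_amp = 0, artifact_hz = 700,
                           phase = 0, seed = 42) {
  n_samp <- round(duration_s * sample_rate_hz)
  t <- (seq_len(n_samp) - 1) / sample_rate_hz
  response <- numeric(n_samp)
  for (k in seq_along(amps)) {
    response <- response + amps[k] * sin(2 * pi * k * fm_hz * t + phase)
  }
  artifact <- artifact_amp * sin(2 * pi * artifact_hz * t)
  polarity <- rep(c(1, -1), length.out = n_trials)
  trials <- withr::with_seed(seed, {
    rep(1, n_trials) %o% response + polarity %o% artifact +
      matrix(stats::rnorm(n_trials * n_samp, 0, noise_sd), n_trials)
  })
  structure(list(trials = trials, sample_rate_hz = sample_rate_hz,
                 polarity = polarity, fm_hz = fm_hz,
                 carrier_hz = NA_real_, ear_id = "test",
                 measure = "test"),
            class = "efr_trial_set")
}

# Hand-built growth / IO objects for metric unit tests.
make_abr_growth <- function(levels = seq(10, 80, 5), wave1_uv,
                            noise_sd_uv = 0.05) {
  structure(list(ear_id = "test", frequency_hz = 16000, levels = levels,
                 wave1_uv = wave1_uv, noise_sd_uv = noise_sd_uv),
            class = "abr_growth")
}

make_dpoae_io <- function(l2 = seq(10, 80, 5), dp) {
  structure(list(ear_id = "test", f2_hz = 16000, l2_levels = l2,
                 dp_level_db_spl = dp, l1_rule = "L2 + 10 dB",
                 f2_f1_ratio = 1.2),
            class = "dpoae_io")
}

# Minimal analysis-style table for model/CV tests: one ear per `ears` id,
# `rows_per_ear` rows each, predictors drawn once.
make_model_table <- function(n_ears, rows_per_ear = 2, beta0 = 2,
                             beta = c(M = 0.3), sigma = 1, seed = 7,
                             group = "young") {
  withr::with_seed(seed, {
    n <- n_ears * rows_per_ear
    tab <- tibble::tibble(
      ear_id = rep(sprintf("e%03d", seq_len(n_ears)), each = rows_per_ear),
      group = group,
      sex = sample(c("F", "M"), n, replace = TRUE),
      frequency_hz = rep_len(c(16000, 32000), n)
    )
    y <- rep(beta0, n)
    for (nm in names(beta)) {
      tab[[nm]] <- stats::rnorm(n, 0, 10)
      y <- y + beta[[nm]] * tab[[nm]]
    }
    tab$synapses_per_ihc <- y + stats::rnorm(n, 0, sigma)
    tab
  })
}
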