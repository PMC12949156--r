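#' Synthetic cohort configuration
#'
#' Defaults encode the statistical structure the analysis assumes, for a
#' cohort of four groups of mice: young (n = 17), acute noise exposed
#' (n = 13), aged (n = 14), and aged after noise exposure (n = 13), with
#' measurements at the 16 and 32 kHz cochlear regions.
#'
#' Group synapse-loss patterns: acute noise is focal (~50% loss at 32 kHz,
#' none at 16 kHz); aged and aged+noise groups show broad loss at both
#' frequencies. Outer-hair-cell (OHC) threshold elevation is collinear with
#' group membership, inducing the evoked/DPOAE collinearity the analysis
#' has to cope with.
#'
#' Each evoked measure has a linear link to synapse count (`link_gain`, uV
#' per synapse/IHC), an OHC sensitivity (dB of evoked attenuation per dB of
#' OHC loss; smaller for RAM than SAM stimuli, encoding the premise that
#' the sharp RAM onset is less vulnerable to OHC dysfunction), an
#' off-frequency spread (fraction of the response driven by cochlear
#' regions away from the nominal place, which makes evoked potentials
#' under-report focal lesions), and a per-ear multiplicative scatter
#' (electrode placement, head size, ...).
#'
#' @param group_sizes named integer vector of ears per group.
#' @param frequencies cochlear/stimulus frequencies analyzed (Hz).
#' @param baseline_synapses named (by frequency) mean synapses/IHC in young
#'   ears.
#' @param baseline_synapse_sd between-ear SD of the baseline.
#' @param group_loss matrix `group x frequency` of mean fractional synapse
#'   loss.
#' @param loss_sd between-ear SD of the loss fraction.
#' @param ohc_loss_db matrix `group x c(mean, sd)` of OHC threshold
#'   elevation (dB), truncated at 0.
#' @param ohc_freq_jitter_sd per-frequency jitter of OHC loss (dB).
#' @param link_gain named vector, uV of f0 response (or wave-1 amplitude at
#'   80 dB SPL for `abr`) per synapse/IHC.
#' @param ohc_sensitivity named vector, dB attenuation per dB OHC loss.
#' @param off_freq_spread named vector in `[0, 1]`: weight of the
#'   off-frequency region in the effective synapse count driving a measure.
#' @param ear_scatter_sd_log named vector, SD of the log-normal per-ear
#'   scatter of each measure.
#' @param harmonic_weights list with `sam` and `ram` relative amplitudes at
#'   the modulation frequency and its first four harmonics.
#' @param eeg_noise_sd_uv per-sample EEG noise SD (uV) for EFR trials.
#' @param artifact_amp_uv stimulus-artifact amplitude (uV); inverts with
#'   stimulus polarity and cancels in balanced averages.
#' @param efr_trials trials per polarity.
#' @param efr_n_draws bootstrap draws used when extracting EFR measures.
#' @param abr_levels,abr_l50_db,abr_slope_scale_db,abr_noise_uv ABR growth:
#'   level grid (dB SPL), sigmoid midpoint at zero OHC loss, sigmoid scale,
#'   and amplitude measurement noise.
#' @param dpoae_levels,dpoae_threshold_db,dpoae_slope,dpoae_noise_db DPOAE
#'   I/O: L2 grid, baseline threshold (level where the emission crosses
#'   0 dB SPL with healthy OHCs), growth slope (dB/dB), and per-point noise.
#' @param missing_1khz_32k_rate fraction of ears lacking the 1 kHz
#'   modulated EFRs at the 32 kHz carrier (exercises complete-case
#'   filtering).
#' @param n_female number of female ears (sex has no effect on any
#'   generated signal).
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(
    group_sizes = c(young = 17, acute_noise = 13, aged = 14, aged_noise = 13),
    frequencies = c(16000, 32000),
    baseline_synapses = c("16000" = 17, "32000" = 15),
    baseline_synapse_sd = 1.2,
    group_loss = rbind(young      = c("16000" = 0.00, "32000" = 0.00),
                       acute_noise = c(0.00, 0.50),
                       aged        = c(0.30, 0.35),
                       aged_noise  = c(0.45, 0.50)),
    loss_sd = 0.06,
    ohc_loss_db = rbind(young      = c(mean = 1,  sd = 2),
                        acute_noise = c(5,  3),
                        aged        = c(16, 6),
                        aged_noise  = c(26, 8)),
    ohc_freq_jitter_sd = 2,
    link_gain = c(sam_110 = 0.08, sam_1000 = 0.10,
                  ram_110 = 0.16, ram_1000 = 0.20, abr = 0.10),
    ohc_sensitivity = c(sam_110 = 0.80, sam_1000 = 0.70,
                        ram_110 = 0.35, ram_1000 = 0.25, abr = 0.12),
    off_freq_spread = c(sam_110 = 0.65, sam_1000 = 0.60,
                        ram_110 = 0.65, ram_1000 = 0.60, abr = 0.20),
    ear_scatter_sd_log = c(sam_110 = 0.45, sam_1000 = 0.30,
                           ram_110 = 0.40, ram_1000 = 0.15, abr = 0.25),
    harmonic_weights = list(sam = c(1, 0.15, 0.05, 0.02, 0.01),
                            ram = c(1, 0.80, 0.55, 0.35, 0.20)),
    eeg_noise_sd_uv = 10,
    artifact_amp_uv = 0.5,
    efr_trials = 64,
    efr_n_draws = 100,
    abr_levels = seq(10, 80, by = 5),
    abr_l50_db = 45,
    abr_slope_scale_db = 6,
    abr_noise_uv = 0.05,
    dpoae_levels = seq(10, 80, by = 5),
    dpoae_threshold_db = 25,
    dpoae_slope = 0.6,
    dpoae_noise_db = 1.5,
    missing_1khz_32k_rate = 0.35,
    n_female = 32) {
  stopifnot(all(group_sizes >= 0), all(group_loss >= 0 & group_loss <= 1))
  if (ohc_sensitivity[["ram_1000"]] >= ohc_sensitivity[["sam_1000"]] ||
      ohc_sensitivity[["ram_110"]] >= ohc_sensitivity[["sam_110"]]) {
    stop("default premise violated: RAM measures must be less ",
         "OHC-sensitive than SAM measures", call. = FALSE)
  }
  structure(as.list(environment()), class = "cohort_config")
}

#' EFR stimulus specs matching the study design
#'
#' SAM and RAM tones (depth 100%, RAM duty cycle 25% with 2.5% tapers),
#' 500 ms, 70 dB SPL, at the requested carrier and modulation frequencies.
#'
#' @param carrier_hz carrier frequency (Hz).
#' @param fm_hz modulation frequency (Hz).
#' @param kind `"sam"` or `"ram"`.
#' @return a [stimulus_spec()].
#' @export
efr_stimulus <- function(kind, carrier_hz, fm_hz) {
  stimulus_spec(kind = kind, carrier_hz = carrier_hz, fm_hz = fm_hz,
                depth = 1, duty_cycle = 0.25, edge_fraction = 0.025,
                duration_s = 0.5, level_db_spl = 70)
}

#' Generate a synthetic cohort
#'
#' Deterministic given `seed`. Returns ear-level metadata, the ground-truth
#' synapse/OHC table, and the latent per-ear measure scatter used by the
#' response simulators.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed.
#' @return a `cohort` list with elements `ears` (tibble: ear_id, group,
#'   sex, missing_1khz_32k), `truth` (tibble: ear_id, group, frequency_hz,
#'   synapses_per_ihc, ohc_loss_db), `scatter` (tibble: ear_id, measure,
#'   factor), `config`, `seed`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1) {
  withr::with_seed(seed, {
    groups <- rep(names(config$group_sizes), config$group_sizes)
    n <- length(groups)
    ear_id <- sprintf("ear_%02d", seq_len(n))
    n_f <- min(config$n_female, n)
    sex <- sample(rep(c("F", "M"), c(n_f, n - n_f)))
    ears <- tibble::tibble(
      ear_id = ear_id, group = groups, sex = sex,
      missing_1khz_32k = stats::runif(n) < config$missing_1khz_32k_rate
    )

    freqs <- config$frequencies
    truth <- do.call(rbind, lapply(seq_len(n), function(i) {
      g <- groups[i]
      base <- config$baseline_synapses[as.character(freqs)] +
        stats::rnorm(length(freqs), 0, config$baseline_synapse_sd)
      loss <- pmin(1, pmax(0, config$group_loss[g, as.character(freqs)] +
                             stats::rnorm(length(freqs), 0, config$loss_sd)))
      ohc_base <- max(0, stats::rnorm(1, config$ohc_loss_db[g, "mean"],
                                      config$ohc_loss_db[g, "sd"]))
      ohc <- pmax(0, ohc_base +
                    stats::rnorm(length(freqs), 0, config$ohc_freq_jitter_sd))
      data.frame(ear_id = ear_id[i], group = g, frequency_hz = freqs,
                 synapses_per_ihc = pmax(0, base * (1 - loss)),
                 ohc_loss_db = ohc)
    }))
    truth <- tibble::as_tibble(truth)

    measures <- names(config$link_gain)
    scatter <- tidyr::expand_grid(ear_id = ear_id, measure = measures)
    sds <- config$ear_scatter_sd_log[scatter$measure]
    scatter$factor <- exp(stats::rnorm(nrow(scatter), 0, sds))

    structure(list(ears = ears, truth = truth,
                   scatter = tibble::as_tibble(scatter),
                   config = config, seed = seed),
              class = "cohort")
  })
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d ears (%s), seed %d\n", nrow(x$ears),
              paste(sprintf("%s=%d", names(table(x$ears$group)),
                            table(x$ears$group)), collapse = ", "),
              x$seed))
  invisible(x)
}

cohort_lookup <- function(cohort, ear, frequency_hz) {
  row <- cohort$truth[cohort$truth$ear_id == ear &
                        cohort$truth$frequency_hz == frequency_hz, ]
  if (nrow(row) != 1) {
    stop("frequency ", frequency_hz, " not in ear ", ear, "'s synapse map",
         call. = FALSE)
  }
  row
}

# Effective synapse count driving a measure at a nominal frequency:
# a (1 - spread) : spread mix of the on-frequency count and the mean count
# over the other cochlear regions. This is what makes evoked potentials
# under-report focal lesions.
effective_synapses <- function(cohort, ear, frequency_hz, measure) {
  cfg <- cohort$config
  on <- cohort_lookup(cohort, ear, frequency_hz)$synapses_per_ihc
  others <- cohort$truth[cohort$truth$ear_id == ear &
                           cohort$truth$frequency_hz != frequency_hz, ]
  off <- if (nrow(others)) mean(others$synapses_per_ihc) else on
  sp <- cfg$off_freq_spread[[measure]]
  (1 - sp) * on + sp * off
}

measure_scatter <- function(cohort, ear, measure) {
  cohort$scatter$factor[cohort$scatter$ear_id == ear &
                          cohort$scatter$measure == measure]
}

# Response digitization rate for an EFR epoch: the full 500 ms epoch gives
# 2 Hz DFT bins; the rate only needs to clear the 5th envelope harmonic
# plus the 7-bin noise window.
efr_sample_rate <- function(fm_hz) if (fm_hz <= 200) 2000 else 10240

#' Simulate trial-level EFR responses for one ear
#'
#' Each trial is `response + noise + polarity * artifact` (uV). The
#' response holds components at the modulation frequency and its first four
#' harmonics with the SAM/RAM harmonic series, amplitude
#' `link_gain * effective synapses * 10^(-ohc_sensitivity * ohc_loss / 20)`
#' times the ear's scatter factor. Trials alternate polarity with equal
#' counts per polarity; the artifact is a carrier-frequency sinusoid that
#' inverts with polarity.
#'
#' @param cohort a [generate_cohort()] result.
#' @param ear ear id.
#' @param spec an [efr_stimulus()] (kind `"sam"` or `"ram"`).
#' @param seed integer seed for the trial noise.
#' @param sample_rate_hz response digitization rate; default chosen from
#'   the modulation frequency.
#' @param noise_sd_uv,artifact_amp_uv overrides of the config values.
#' @return an `efr_trial_set`: `trials` (n_trials x n_samples, uV),
#'   `sample_rate_hz`, `polarity`, `fm_hz`, `carrier_hz`, `ear_id`,
#'   `measure`.
#' @export
simulate_efr_trials <- function(cohort, ear, spec, seed = 1,
                                sample_rate_hz = efr_sample_rate(spec$fm_hz),
                                noise_sd_uv = cohort$config$eeg_noise_sd_uv,
                                artifact_amp_uv =
                                  cohort$config$artifact_amp_uv) {
  stopifnot(spec$kind %in% c("sam", "ram"))
  cfg <- cohort$config
  measure <- paste0(spec$kind, "_", spec$fm_hz)
  truth <- cohort_lookup(cohort, ear, spec$carrier_hz)
  s_eff <- effective_synapses(cohort, ear, spec$carrier_hz, measure)
  atten <- 10^(-cfg$ohc_sensitivity[[measure]] * truth$ohc_loss_db / 20)
  amp0 <- cfg$link_gain[[measure]] * s_eff * atten *
    measure_scatter(cohort, ear, measure)
  weights <- cfg$harmonic_weights[[spec$kind]]

  n_samp <- round(spec$duration_s * sample_rate_hz)
  t <- (seq_len(n_samp) - 1) / sample_rate_hz
  response <- numeric(n_samp)
  for (k in seq_along(weights)) {
    response <- response +
      amp0 * weights[k] * sin(2 * pi * k * spec$fm_hz * t)
  }
  artifact <- artifact_amp_uv * sin(2 * pi * spec$carrier_hz * t)

  n_trials <- 2 * cfg$efr_trials
  polarity <- rep(c(1, -1), length.out = n_trials)
  trials <- withr::with_seed(seed, {
    noise <- matrix(stats::rnorm(n_trials * n_samp, 0, noise_sd_uv),
                    nrow = n_trials)
    base <- rep(1, n_trials) %o% response + polarity %o% artifact
    base + noise
  })
  structure(list(trials = trials, sample_rate_hz = sample_rate_hz,
                 polarity = polarity, fm_hz = spec$fm_hz,
                 carrier_hz = spec$carrier_hz, ear_id = ear,
                 measure = measure),
            class = "efr_trial_set")
}

# Noiseless expected wave-1 amplitude curve for an ear x frequency.
abr_expected_curve <- function(cohort, ear, frequency_hz,
                               levels = cohort$config$abr_levels) {
  cfg <- cohort$config
  truth <- cohort_lookup(cohort, ear, frequency_hz)
  s_eff <- effective_synapses(cohort, ear, frequency_hz, "abr")
  atten <- 10^(-cfg$ohc_sensitivity[["abr"]] * truth$ohc_loss_db / 20)
  amp_max <- cfg$link_gain[["abr"]] * s_eff * atten *
    measure_scatter(cohort, ear, "abr")
  amp_max * stats::plogis((levels - cfg$abr_l50_db - truth$ohc_loss_db) /
                            cfg$abr_slope_scale_db)
}

#' Simulate an ABR wave-1 amplitude growth function
#'
#' Wave-1 amplitude is a saturating (logistic) function of stimulus level,
#' shifted rightward by the ear's OHC loss and scaled by its effective
#' synapse count; measurement noise is added per level. The attached
#' `true_threshold_db` is the lowest grid level at which the noiseless
#' curve exceeds three times the measurement noise.
#'
#' @param cohort a [generate_cohort()] result.
#' @param ear ear id.
#' @param frequency_hz tone-pip frequency (Hz).
#' @param seed integer seed for the amplitude noise.
#' @param noise_sd_uv override of the config measurement noise.
#' @return an `abr_growth` list: `ear_id`, `frequency_hz`, `levels`,
#'   `wave1_uv`, `true_threshold_db`, `noise_sd_uv`.
#' @export
simulate_abr_growth <- function(cohort, ear, frequency_hz, seed = 1,
                                noise_sd_uv = cohort$config$abr_noise_uv) {
  levels <- cohort$config$abr_levels
  clean <- abr_expected_curve(cohort, ear, frequency_hz, levels)
  above <- clean > 3 * cohort$config$abr_noise_uv
  true_thr <- if (any(above)) levels[which(above)[1]] else NA_real_
  wave1 <- withr::with_seed(seed, {
    clean + stats::rnorm(length(levels), 0, noise_sd_uv)
  })
  structure(list(ear_id = ear, frequency_hz = frequency_hz, levels = levels,
                 wave1_uv = wave1, true_threshold_db = true_thr,
                 noise_sd_uv = noise_sd_uv),
            class = "abr_growth")
}

#' Simulate a DPOAE input-output function
#'
#' The emission level grows linearly with the f2 level (L2) and is shifted
#' rightward by the ear's OHC loss, crossing 0 dB SPL at
#' `baseline threshold + ohc_loss`. Primary levels follow the study design:
#' L1 = L2 + 10 dB, f2/f1 = 1.2 (recorded as provenance).
#'
#' @param cohort a [generate_cohort()] result.
#' @param ear ear id.
#' @param f2_hz probe frequency (Hz).
#' @param seed integer seed for the per-point noise.
#' @param noise_sd_db override of the config noise.
#' @return a `dpoae_io` list: `ear_id`, `f2_hz`, `l2_levels`,
#'   `dp_level_db_spl`, `l1_rule`, `f2_f1_ratio`.
#' @export
simulate_dpoae_io <- function(cohort, ear, f2_hz, seed = 1,
                              noise_sd_db = cohort$config$dpoae_noise_db) {
  cfg <- cohort$config
  truth <- cohort_lookup(cohort, ear, f2_hz)
  thr <- cfg$dpoae_threshold_db + truth$ohc_loss_db
  clean <- cfg$dpoae_slope * (cfg$dpoae_levels - thr)
  dp <- withr::with_seed(seed, {
    clean + stats::rnorm(length(clean), 0, noise_sd_db)
  })
  structure(list(ear_id = ear, f2_hz = f2_hz, l2_levels = cfg$dpoae_levels,
                 dp_level_db_spl = dp, l1_rule = "L2 + 10 dB",
                 f2_f1_ratio = 1.2),
            class = "dpoae_io")
}

#' Ground-truth synapse table
#' @param cohort a [generate_cohort()] result.
#' @return tibble (ear_id, frequency_hz, synapses_per_ihc).
#' @export
ground_truth_table <- function(cohort) {
  cohort$truth[, c("ear_id", "frequency_hz", "synapses_per_ihc")]
}
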