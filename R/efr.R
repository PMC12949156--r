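#' Single-sided DFT amplitude spectrum
#'
#' Amplitudes are scaled so that a sinusoid of amplitude `a` whose
#' frequency falls exactly on a bin contributes `a` at that bin
#' (`2 |X_k| / n` for k > 0). No window is applied: the analysis epoch is
#' chosen so that the modulation frequency and its harmonics are exact bin
#' frequencies.
#'
#' @param x waveform (uV).
#' @param sample_rate_hz sampling rate (Hz).
#' @return list: `amplitude` (uV, bins 1..n/2+1 with bin 1 = DC),
#'   `phase` (radians), `bin_hz` spacing.
#' @export
amplitude_spectrum <- function(x, sample_rate_hz) {
  n <- length(x)
  X <- stats::fft(x)[seq_len(floor(n / 2) + 1)]
  amp <- Mod(X) * 2 / n
  amp[1] <- amp[1] / 2
  list(amplitude = amp, phase = Arg(X), bin_hz = sample_rate_hz / n)
}

freq_to_bin <- function(freq_hz, bin_hz) {
  b <- freq_hz / bin_hz
  if (abs(b - round(b)) > 1e-9) {
    stop("frequency ", freq_hz, " Hz does not fall on a DFT bin (spacing ",
         bin_hz, " Hz)", call. = FALSE)
  }
  as.integer(round(b)) + 1L  # 1-based, bin 1 = DC
}

#' Noise floor around a harmonic
#'
#' The arithmetic mean of the spectrum magnitude in the 4th to 7th DFT bin
#' on either side of the harmonic bin (eight bins in total).
#'
#' @param amplitude full magnitude spectrum (uV), 1-based with bin 1 = DC.
#' @param harmonic_bin index of the harmonic of interest.
#' @return noise-floor amplitude (uV).
#' @export
estimate_noise_floor <- function(amplitude, harmonic_bin) {
  offs <- noise_bin_offsets()
  bins <- harmonic_bin + offs
  if (any(bins < 1) || any(bins > length(amplitude))) {
    stop("harmonic bin too close to the spectrum edge for the 8-bin ",
         "noise estimate", call. = FALSE)
  }
  mean(amplitude[bins])
}

noise_bin_offsets <- function() c(-7:-4, 4:7)

#' Balanced bootstrap of the EFR magnitude spectrum
#'
#' Each draw samples `draw_size / 2` trials with replacement from each
#' polarity, averages the waveforms, and computes the magnitude spectrum of
#' the average. Per draw, the amplitudes at the modulation frequency and
#' its first four harmonics (f0..f4), the 8-bin noise floors around each
#' (n0..n4), and the phase at f0 are recorded. The estimator of record for
#' every quantity is the mean over draws.
#'
#' Per-trial DFTs are computed once and averaged per draw in the complex
#' domain, which by linearity of the DFT equals averaging the waveforms
#' first.
#'
#' @param tset an `efr_trial_set` (see [simulate_efr_trials()]), or any
#'   list with `trials` (n_trials x n_samples, uV), `polarity` (+1/-1 per
#'   trial), `sample_rate_hz`, `fm_hz`.
#' @param n_draws number of bootstrap draws (default 100).
#' @param draw_size trials per draw (default: all trials); must be even.
#' @param seed integer seed for the draw indices.
#' @return a `bootstrap_spectrum`: `mags` and `noise` (n_draws x 5, uV),
#'   `phase_f0` (radians per draw), `harmonic_hz`, `bin_hz`, `n_draws`,
#'   `draw_size`, `draw_indices` (n_draws x draw_size), `polarity`.
#' @export
bootstrap_spectrum <- function(tset, n_draws = 100,
                               draw_size = nrow(tset$trials), seed = 1) {
  trials <- tset$trials
  pol <- tset$polarity
  pos <- which(pol > 0)
  neg <- which(pol < 0)
  if (length(pos) == 0 || length(neg) == 0) {
    stop("both stimulus polarities are required for balanced draws",
         call. = FALSE)
  }
  if (draw_size %% 2 != 0) stop("draw_size must be even", call. = FALSE)

  n_samp <- ncol(trials)
  bin_hz <- tset$sample_rate_hz / n_samp
  harmonic_hz <- tset$fm_hz * (1:5)
  if (max(harmonic_hz) >= tset$sample_rate_hz / 2) {
    stop("sample rate too low to resolve the 5th envelope harmonic",
         call. = FALSE)
  }
  hbins <- vapply(harmonic_hz, freq_to_bin, integer(1), bin_hz = bin_hz)
  nbins <- outer(hbins, noise_bin_offsets(), "+")  # 5 x 8
  if (any(nbins < 2) || any(nbins > floor(n_samp / 2) + 1)) {
    stop("harmonic bins too close to the spectrum edge", call. = FALSE)
  }
  bins <- sort(unique(c(hbins, as.vector(nbins))))

  # per-trial complex spectra at the bins of interest (trials x bins)
  spec <- stats::mvfft(t(trials))[bins, , drop = FALSE] * (2 / n_samp)
  half <- draw_size / 2

  idx <- withr::with_seed(seed, {
    t(vapply(seq_len(n_draws), function(d) {
      c(sample(pos, half, replace = TRUE),
        sample(neg, half, replace = TRUE))
    }, integer(draw_size)))
  })

  mags <- matrix(NA_real_, n_draws, 5,
                 dimnames = list(NULL, paste0("f", 0:4)))
  noise <- matrix(NA_real_, n_draws, 5,
                  dimnames = list(NULL, paste0("n", 0:4)))
  phase_f0 <- numeric(n_draws)
  h_at <- match(hbins, bins)
  n_at <- matrix(match(as.vector(nbins), bins), nrow = 5)
  for (d in seq_len(n_draws)) {
    avg <- rowMeans(spec[, idx[d, ], drop = FALSE])
    m <- Mod(avg)
    mags[d, ] <- m[h_at]
    noise[d, ] <- rowMeans(matrix(m[n_at], nrow = 5))
    phase_f0[d] <- Arg(avg[h_at[1]])
  }
  structure(list(mags = mags, noise = noise, phase_f0 = phase_f0,
                 harmonic_hz = harmonic_hz, bin_hz = bin_hz,
                 n_draws = n_draws, draw_size = draw_size,
                 draw_indices = idx, polarity = pol),
            class = "bootstrap_spectrum")
}

efr_methods <- function() {
  c("f0", "f0_4", "f0_snr", "f0_4_snr", "plv", "f0_4_power")
}

#' EFR magnitude / phase-locking measures from a bootstrap spectrum
#'
#' All magnitude measures are computed on the across-draw mean amplitudes
#' `f_i` (uV) and noise floors `n_i` (uV):
#' \itemize{
#'   \item `f0`: `20 log10(f_0)`, dB re 1 uV
#'   \item `f0_4`: `20 log10(sum_i f_i)`, dB re 1 uV
#'   \item `f0_snr`: `20 log10(f_0 / n_0)`, dB
#'   \item `f0_4_snr`: `20 log10(sum_i f_i / n_i)`, dB
#'   \item `f0_4_power`: `10 log10(sum_i f_i^2)`, dB re 1 uV^2
#'   \item `plv`: phase-locking value across draws, unitless in [0, 1]
#' }
#'
#' @param b a [bootstrap_spectrum()].
#' @param method one of `"f0"`, `"f0_4"`, `"f0_snr"`, `"f0_4_snr"`,
#'   `"plv"`, `"f0_4_power"`.
#' @return a single numeric value.
#' @export
compute_efr_measure <- function(b, method = efr_methods()) {
  method <- match.arg(method)
  f <- colMeans(b$mags)
  n <- colMeans(b$noise)
  if (grepl("snr", method) && any(n == 0)) {
    stop("zero noise floor: SNR measures are undefined for noiseless input",
         call. = FALSE)
  }
  switch(method,
    f0        = 20 * log10(f[[1]]),
    f0_4      = 20 * log10(sum(f)),
    f0_snr    = 20 * log10(f[[1]] / n[[1]]),
    f0_4_snr  = 20 * log10(sum(f / n)),
    f0_4_power = 10 * log10(sum(f^2)),
    plv       = compute_plv(b)
  )
}

#' Phase-locking value across bootstrap draws
#'
#' Magnitude of the mean unit phasor of the f0 phase over draws; 1 for
#' perfectly reproducible phase, near 0 for uniformly scattered phase.
#'
#' @param b a [bootstrap_spectrum()].
#' @return PLV in `[0, 1]`.
#' @export
compute_plv <- function(b) {
  Mod(mean(exp(1i * b$phase_f0)))
}

#' All EFR measures for one trial set, tidily
#'
#' @param tset an `efr_trial_set`.
#' @param methods which measures to compute.
#' @param n_draws,seed passed to [bootstrap_spectrum()].
#' @return tibble (ear_id, carrier_hz, fm_hz, measure, method, value).
#' @export
efr_measures <- function(tset, methods = efr_methods(), n_draws = 100,
                         seed = 1) {
  b <- bootstrap_spectrum(tset, n_draws = n_draws, seed = seed)
  tibble::tibble(
    ear_id = tset$ear_id %||% NA_character_,
    carrier_hz = tset$carrier_hz,
    fm_hz = tset$fm_hz,
    measure = tset$measure %||% paste0("fm_", tset$fm_hz),
    method = methods,
    value = vapply(methods, function(m) compute_efr_measure(b, m),
                   numeric(1))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
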