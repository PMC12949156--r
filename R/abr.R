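#' Zero-phase band-pass filter for averaged ABR traces
#'
#' 4th-order Butterworth, 300-3000 Hz, applied forward and backward
#' (zero phase) via \code{signal::filtfilt}.
#'
#' @param x averaged ABR trace (uV).
#' @param sample_rate_hz sampling rate (Hz); must exceed 6 kHz.
#' @param band passband edges (Hz).
#' @return filtered trace (uV).
#' @export
bandpass_abr <- function(x, sample_rate_hz, band = c(300, 3000)) {
  if (sample_rate_hz <= 2 * band[2]) {
    stop("sample rate must exceed twice the upper band edge", call. = FALSE)
  }
  bf <- signal::butter(4, band / (sample_rate_hz / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Wave-1 peak picking (peak-to-following-trough)
#'
#' Finds the first prominent positive local maximum inside the latency
#' window and takes its amplitude relative to the following trough. A
#' simple documented procedure standing in for rater-reviewed
#' semi-automated picking.
#'
#' @param trace filtered trace (uV).
#' @param sample_rate_hz sampling rate (Hz).
#' @param window_s latency window `c(min, max)` (s) to search for the peak.
#' @param noise_uv noise scale; peaks below `3 * noise_uv` are flagged and
#'   the amplitude is reported at noise level.
#' @param convention `"peak_to_trough"` (default) or `"baseline_to_peak"`.
#' @return list: `latency_s`, `amplitude_uv`, `flagged`.
#' @export
pick_wave1 <- function(trace, sample_rate_hz, window_s,
                       noise_uv = 0,
                       convention = c("peak_to_trough",
                                      "baseline_to_peak")) {
  convention <- match.arg(convention)
  n <- length(trace)
  i0 <- max(1L, floor(window_s[1] * sample_rate_hz) + 1L)
  i1 <- min(n, ceiling(window_s[2] * sample_rate_hz) + 1L)
  if (i0 >= i1) stop("latency window outside the trace", call. = FALSE)
  seg <- trace[i0:i1]

  # local maxima inside the window
  d <- diff(seg)
  pk <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  if (length(pk) == 0) pk <- which.max(seg)
  # first peak within 1 dB of the window maximum counts as prominent
  big <- pk[seg[pk] >= max(seg[pk]) * 0.9]
  ip <- big[1]
  peak_val <- seg[ip]

  # following trough: minimum after the peak, up to the window end
  trough_val <- if (ip < length(seg)) min(seg[(ip + 1):length(seg)]) else
    peak_val
  amp <- switch(convention,
                peak_to_trough = peak_val - trough_val,
                baseline_to_peak = peak_val)
  flagged <- peak_val < 3 * noise_uv
  if (flagged) amp <- min(amp, 3 * noise_uv)
  list(latency_s = (i0 + ip - 2) / sample_rate_hz,
       amplitude_uv = amp, flagged = flagged)
}

#' Wave-1 amplitude growth slope
#'
#' Ordinary least-squares slope of wave-1 amplitude against stimulus level
#' over the two highest levels (75 and 80 dB SPL), the four highest (65-80
#' dB SPL), or all collected levels.
#'
#' @param g an `abr_growth` (see [simulate_abr_growth()]) or any list with
#'   `levels` (dB SPL) and `wave1_uv`.
#' @param which `"top2"`, `"top4"`, or `"all"`.
#' @return slope (uV/dB).
#' @export
wave1_slope <- function(g, which = c("top2", "top4", "all")) {
  which <- match.arg(which)
  keep <- switch(which,
    top2 = g$levels %in% c(75, 80),
    top4 = g$levels %in% c(65, 70, 75, 80),
    all = rep(TRUE, length(g$levels))
  )
  lv <- g$levels[keep]
  amp <- g$wave1_uv[keep]
  need <- switch(which, top2 = 2L, top4 = 4L, all = 2L)
  if (length(lv) < need) {
    stop("required levels for slope_", which, " not present", call. = FALSE)
  }
  unname(stats::cov(lv, amp) / stats::var(lv))
}

#' ABR threshold from a growth function
#'
#' The lowest level whose amplitude exceeds `k * noise_uv` with all higher
#' levels also exceeding it; `NA` ("not reached") otherwise. A simple
#' documented criterion standing in for the automated threshold algorithm.
#'
#' @param g an `abr_growth`.
#' @param noise_uv amplitude noise scale (uV).
#' @param k criterion multiple (default 3).
#' @return threshold (dB SPL) or `NA`.
#' @export
estimate_abr_threshold <- function(g, noise_uv, k = 3) {
  if (length(g$levels) < 3) {
    stop("need amplitudes at three or more levels", call. = FALSE)
  }
  above <- g$wave1_uv > k * noise_uv
  ok <- rev(cumprod(rev(above))) == 1  # above here and at all higher levels
  if (any(ok)) g$levels[which(ok)[1]] else NA_real_
}

#' Summary metrics of one ABR growth function
#'
#' @param g an `abr_growth`.
#' @param noise_uv noise scale for the threshold criterion; defaults to the
#'   growth object's own if present.
#' @return tibble: ear_id, frequency_hz, abr_80, abr_70, abr_60 (uV),
#'   slope_2, slope_4, slope_all (uV/dB), abr_threshold_db.
#' @export
abr_summary <- function(g, noise_uv = g$noise_sd_uv %||% 0.05) {
  at <- function(lv) {
    i <- match(lv, g$levels)
    if (is.na(i)) NA_real_ else g$wave1_uv[i]
  }
  tibble::tibble(
    ear_id = g$ear_id %||% NA_character_,
    frequency_hz = g$frequency_hz %||% NA_real_,
    abr_80 = at(80), abr_70 = at(70), abr_60 = at(60),
    slope_2 = wave1_slope(g, "top2"),
    slope_4 = wave1_slope(g, "top4"),
    slope_all = wave1_slope(g, "all"),
    abr_threshold_db = estimate_abr_threshold(g, noise_uv)
  )
}
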