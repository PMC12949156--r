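#' Stimulus specification
#'
#' Parametric description of the acoustic stimuli used throughout the
#' analysis: sinusoidally amplitude-modulated (SAM) tones, rectangularly
#' amplitude-modulated (RAM) tones with a flat "on" portion and tapered
#' edges, and short tone pips for ABR level series.
#'
#' For SAM/RAM stimuli `fm_hz * duration_s` must be a positive integer so
#' that the modulation frequency lands exactly on a DFT bin of the full
#' epoch.
#'
#' @param kind one of `"sam"`, `"ram"`, `"tone_pip"`.
#' @param carrier_hz carrier frequency (Hz); must be below Nyquist.
#' @param fm_hz modulation frequency (Hz); 0 for tone pips.
#' @param depth modulation depth in `[0, 1]`.
#' @param duty_cycle RAM only: fraction of each modulation period at full
#'   envelope, in `(0, 1]`.
#' @param edge_fraction RAM only: fraction of the modulation period spanned
#'   by the raised-cosine taper at each on/off edge, in `[0, 0.5)`.
#' @param rise_fall_ms tone pip only: cosine-squared ramp duration (ms).
#' @param duration_s total stimulus duration (s).
#' @param level_db_spl overall RMS level (dB SPL re 20 uPa).
#' @param sample_rate_hz synthesis rate (Hz); default 100 kHz.
#' @return a `stimulus_spec` list.
#' @export
stimulus_spec <- function(kind = c("sam", "ram", "tone_pip"),
                          carrier_hz,
                          fm_hz = 0,
                          depth = 1,
                          duty_cycle = 0.25,
                          edge_fraction = 0.025,
                          rise_fall_ms = 0.5,
                          duration_s = 0.5,
                          level_db_spl = 70,
                          sample_rate_hz = 1e5) {
  kind <- match.arg(kind)
  if (depth < 0 || depth > 1) {
    stop("modulation depth must lie in [0, 1]", call. = FALSE)
  }
  if (carrier_hz >= sample_rate_hz / 2) {
    stop("carrier frequency must be below Nyquist (sample_rate_hz / 2)",
         call. = FALSE)
  }
  if (kind %in% c("sam", "ram")) {
    ncyc <- fm_hz * duration_s
    if (fm_hz <= 0 || abs(ncyc - round(ncyc)) > 1e-9) {
      stop("fm_hz * duration_s must be a positive integer ",
           "(modulation frequency must fall on a DFT bin)", call. = FALSE)
    }
  }
  if (kind == "ram") {
    if (duty_cycle <= 0 || duty_cycle > 1) {
      stop("duty_cycle must lie in (0, 1]", call. = FALSE)
    }
    if (edge_fraction < 0 || edge_fraction >= 0.5) {
      stop("edge_fraction must lie in [0, 0.5)", call. = FALSE)
    }
    if (duty_cycle < 2 * edge_fraction) {
      stop("duty_cycle shorter than the two taper spans", call. = FALSE)
    }
  }
  if (kind == "tone_pip" && duration_s < 2 * rise_fall_ms / 1000) {
    stop("duration shorter than the rise plus fall ramps", call. = FALSE)
  }
  structure(
    list(kind = kind, carrier_hz = carrier_hz, fm_hz = fm_hz, depth = depth,
         duty_cycle = duty_cycle, edge_fraction = edge_fraction,
         rise_fall_ms = rise_fall_ms, duration_s = duration_s,
         level_db_spl = level_db_spl, sample_rate_hz = sample_rate_hz),
    class = "stimulus_spec"
  )
}

#' @export
print.stimulus_spec <- function(x, ...) {
  cat(sprintf("<stimulus_spec> %s: carrier %g Hz, fm %g Hz, %g s @ %g dB SPL\n",
              toupper(x$kind), x$carrier_hz, x$fm_hz, x$duration_s,
              x$level_db_spl))
  invisible(x)
}

ref_pressure_pa <- 20e-6

time_axis <- function(spec) {
  n <- round(spec$duration_s * spec$sample_rate_hz)
  (seq_len(n) - 1) / spec$sample_rate_hz
}

#' Modulation envelope of a SAM or RAM stimulus
#'
#' The SAM envelope is `1 + depth * sin(2 pi fm t)`. The RAM envelope is a
#' rectangular gate that is "on" for `duty_cycle` of each modulation period,
#' with a raised-cosine (Tukey-style) taper of `edge_fraction` of the period
#' at each edge, the tapers lying inside the on-window.
#'
#' @param spec a [stimulus_spec()] of kind `"sam"` or `"ram"`.
#' @param t time points (s); defaults to the spec's full sample grid.
#' @return numeric envelope values (unscaled).
#' @export
stimulus_envelope <- function(spec, t = time_axis(spec)) {
  switch(spec$kind,
    sam = 1 + spec$depth * sin(2 * pi * spec$fm_hz * t),
    ram = ram_envelope(t * spec$fm_hz, spec$duty_cycle, spec$edge_fraction,
                       spec$depth),
    stop("no envelope for kind ", spec$kind, call. = FALSE)
  )
}

# u: time in modulation-period units; envelope per cycle: raised-cosine ramp
# over [0, e], flat 1 over [e, d - e], ramp down over [d - e, d], 0 elsewhere.
ram_envelope <- function(u, duty, edge, depth = 1) {
  ph <- u - floor(u)
  env <- numeric(length(ph))
  if (edge > 0) {
    up <- ph < edge
    env[up] <- 0.5 * (1 - cos(pi * ph[up] / edge))
    dn <- ph >= (duty - edge) & ph < duty
    env[dn] <- 0.5 * (1 + cos(pi * (ph[dn] - (duty - edge)) / edge))
    flat <- ph >= edge & ph < (duty - edge)
    env[flat] <- 1
  } else {
    env[ph < duty] <- 1
  }
  (1 - depth) + depth * env
}

#' Synthesize a stimulus waveform
#'
#' Builds the pressure waveform for a stimulus spec and scales it to the
#' requested overall RMS level. Tone pips get cosine-squared onset/offset
#' ramps with a steady state in between.
#'
#' @param spec a [stimulus_spec()].
#' @return a `waveform` list: `samples` (Pa), `sample_rate_hz`, `spec`.
#' @export
synthesize_stimulus <- function(spec) {
  t <- time_axis(spec)
  carrier <- sin(2 * pi * spec$carrier_hz * t)
  env <- switch(spec$kind,
    sam = ,
    ram = stimulus_envelope(spec, t),
    tone_pip = pip_envelope(t, spec$rise_fall_ms / 1000, spec$duration_s)
  )
  w <- structure(
    list(samples = env * carrier, sample_rate_hz = spec$sample_rate_hz,
         spec = spec),
    class = "waveform"
  )
  scale_to_spl(w, spec$level_db_spl)
}

pip_envelope <- function(t, ramp_s, duration_s) {
  env <- rep(1, length(t))
  if (ramp_s > 0) {
    on <- t < ramp_s
    env[on] <- sin(pi * t[on] / (2 * ramp_s))^2
    off <- t > (duration_s - ramp_s)
    env[off] <- sin(pi * (duration_s - t[off]) / (2 * ramp_s))^2
    env[t > duration_s] <- 0
  }
  env
}

#' Scale a waveform to a target sound pressure level
#'
#' @param w a `waveform`.
#' @param level_db_spl target overall RMS level (dB SPL re 20 uPa).
#' @return the waveform with `samples` rescaled so that their RMS equals
#'   `20e-6 * 10^(level/20)` Pa.
#' @export
scale_to_spl <- function(w, level_db_spl) {
  rms <- sqrt(mean(w$samples^2))
  if (rms == 0) stop("cannot scale an all-zero waveform", call. = FALSE)
  target <- ref_pressure_pa * 10^(level_db_spl / 20)
  w$samples <- w$samples * (target / rms)
  w$spec$level_db_spl <- level_db_spl
  w
}

#' Overall RMS level of a waveform in dB SPL
#' @param w a `waveform`.
#' @return dB SPL re 20 uPa.
#' @export
waveform_spl <- function(w) {
  20 * log10(sqrt(mean(w$samples^2)) / ref_pressure_pa)
}

#' Interleaved tone-pip presentation schedule
#'
#' Arranges one presentation of every (frequency, level) pair per train
#' cycle with frequencies rotating fastest, so consecutive stimuli always
#' differ in frequency (the interleaved-ramp design that minimizes
#' auditory-nerve adaptation). The effective per-frequency rate is the
#' overall rate divided by the number of distinct frequencies.
#'
#' @param frequencies distinct stimulus frequencies (Hz).
#' @param levels stimulus levels (dB SPL).
#' @param overall_rate_hz stimuli per second across the whole train.
#' @return a list with `entries` (tibble: frequency_hz, level_db_spl,
#'   onset_s), `overall_rate_hz`, `per_frequency_rate_hz`.
#' @export
build_interleaved_train <- function(frequencies, levels, overall_rate_hz) {
  if (length(frequencies) < 1 || length(levels) < 1) {
    stop("need at least one frequency and one level", call. = FALSE)
  }
  grid <- expand.grid(frequency_hz = frequencies, level_db_spl = levels,
                      KEEP.OUT.ATTRS = FALSE)
  grid$onset_s <- (seq_len(nrow(grid)) - 1) / overall_rate_hz
  list(
    entries = tibble::as_tibble(grid),
    overall_rate_hz = overall_rate_hz,
    per_frequency_rate_hz = overall_rate_hz / length(unique(frequencies))
  )
}

#' Average presentation rate of a jittered stimulus train
#'
#' For stimuli of fixed duration separated by an inter-stimulus interval
#' drawn uniformly from `[isi_min_s, isi_max_s]`, the average rate is the
#' reciprocal of the mean period.
#'
#' @param duration_s stimulus duration (s).
#' @param isi_min_s,isi_max_s inter-stimulus interval bounds (s).
#' @return stimuli per second.
#' @export
presentation_rate <- function(duration_s, isi_min_s, isi_max_s) {
  1 / (duration_s + (isi_min_s + isi_max_s) / 2)
}

#' Write a waveform as a two-column CSV (time_s, pressure_pa)
#' @param w a `waveform`.
#' @param path output file.
#' @export
write_waveform_csv <- function(w, path) {
  t <- (seq_along(w$samples) - 1) / w$sample_rate_hz
  utils::write.csv(data.frame(time_s = t, pressure_pa = w$samples),
                   path, row.names = FALSE)
  invisible(path)
}
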