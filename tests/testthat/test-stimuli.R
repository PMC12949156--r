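test_that("scaled waveforms hit the requested SPL for every stimulus kind", {
  specs <- list(
    stimulus_spec("sam", carrier_hz = 16000, fm_hz = 110),
    stimulus_spec("ram", carrier_hz = 16000, fm_hz = 110),
    stimulus_spec("tone_pip", carrier_hz = 16000, duration_s = 0.005,
                  rise_fall_ms = 0.5)
  )
  for (spec in specs) {
    w <- synthesize_stimulus(spec)
    expect_lt(abs(waveform_spl(w) - 70), 0.01)
  }
  # 70 dB SPL is 0.0632 Pa RMS (20 uPa * 10^3.5)
  w <- synthesize_stimulus(specs[[1]])
  expect_equal(sqrt(mean(w$samples^2)), 20e-6 * 10^3.5, tolerance = 1e-6)
  # idempotence and the +20 dB = x10 identity
  w2 <- scale_to_spl(w, 70)
  expect_equal(w$samples, w2$samples)
  w3 <- scale_to_spl(w, 90)
  expect_equal(w3$samples, w$samples * 10, tolerance = 1e-12)
  expect_error(scale_to_spl(list(samples = rep(0, 10)), 70), "all-zero")
})

test_that("SAM envelope has the analytic number of zero minima and a flat
          depth-0 limit", {
  spec <- stimulus_spec("sam", carrier_hz = 16000, fm_hz = 110,
                        duration_s = 0.5, depth = 1)
  env <- stimulus_envelope(spec)
  # 1 + sin reaches 0 once per modulation cycle: fm * duration = 55 times
  d <- diff(env)
  minima <- which(d[-length(d)] < 0 & d[-1] >= 0) + 1L
  deep <- env[minima] < 1e-4
  expect_equal(sum(deep), 55)
  # depth 0: constant envelope, single spectral component at the carrier
  spec0 <- stimulus_spec("sam", carrier_hz = 16000, fm_hz = 110, depth = 0)
  expect_equal(diff(range(stimulus_envelope(spec0))), 0)
  w0 <- synthesize_stimulus(spec0)
  sp <- amplitude_spectrum(w0$samples, w0$sample_rate_hz)
  peak <- which.max(sp$amplitude)
  expect_equal((peak - 1) * sp$bin_hz, 16000)
  expect_lt(max(sp$amplitude[-peak]) / sp$amplitude[peak], 1e-6)
})

test_that("RAM envelope honours the duty cycle, tapers, and degenerate
          limits", {
  spec <- stimulus_spec("ram", carrier_hz = 16000, fm_hz = 110,
                        duty_cycle = 0.25, edge_fraction = 0.025)
  env <- stimulus_envelope(spec)
  frac_on <- mean(env > 0.5)
  # above-half-maximum fraction = duty - edge; allow +/- two taper spans
  expect_lt(abs(frac_on - 0.25), 2 * 0.025)
  expect_equal(max(env), 1)
  expect_equal(min(env), 0)
  # duty 1 with no taper degenerates to a pure tone
  pure <- stimulus_spec("ram", carrier_hz = 16000, fm_hz = 110,
                        duty_cycle = 1, edge_fraction = 0)
  expect_equal(diff(range(stimulus_envelope(pure))), 0)
  # taper spans must fit inside the on-portion
  expect_error(stimulus_spec("ram", carrier_hz = 16000, fm_hz = 110,
                             duty_cycle = 0.04, edge_fraction = 0.025),
               "taper")
})

test_that("SAM and RAM at the same level have equal RMS but RAM has the
          larger peak pressure", {
  sam <- synthesize_stimulus(stimulus_spec("sam", 16000, 110))
  ram <- synthesize_stimulus(stimulus_spec("ram", 16000, 110))
  expect_lt(abs(waveform_spl(sam) - waveform_spl(ram)), 0.01)
  # RAM's envelope is off 75% of the time, so its unscaled RMS is lower and
  # equal-RMS scaling pushes its peak above SAM's
  expect_gt(max(abs(ram$samples)), max(abs(sam$samples)))
})

test_that("SAM/RAM envelopes are periodic with period 1/fm and carry the
          expected sidebands", {
  for (kind in c("sam", "ram")) {
    spec <- stimulus_spec(kind, carrier_hz = 16000, fm_hz = 200,
                          sample_rate_hz = 1e5)
    env <- stimulus_envelope(spec)
    per <- spec$sample_rate_hz / spec$fm_hz  # 500 samples, integer
    expect_equal(env[seq_len(per)], env[seq_len(per) + per],
                 tolerance = 1e-12)
    w <- synthesize_stimulus(spec)
    sp <- amplitude_spectrum(w$samples, w$sample_rate_hz)
    bin_of <- function(f) round(f / sp$bin_hz) + 1
    carrier_amp <- sp$amplitude[bin_of(16000)]
    side <- sapply(1:5, function(k) {
      max(sp$amplitude[bin_of(16000 + k * 200)],
          sp$amplitude[bin_of(16000 - k * 200)]) / carrier_amp
    })
    if (kind == "sam") {
      expect_gt(side[1], 0.1)          # single pair of sidebands
      expect_lt(max(side[2:5]), 1e-8)  # nothing beyond carrier +/- fm
    } else {
      expect_true(all(side[1:4] > 1e-6))  # harmonics out to k = 4
    }
  }
})

test_that("tone pips have the specified steady state and cos^2 ramps", {
  spec <- stimulus_spec("tone_pip", carrier_hz = 16000, duration_s = 0.005,
                        rise_fall_ms = 0.5)
  fs <- spec$sample_rate_hz
  t <- (seq_len(round(0.005 * fs)) - 1) / fs
  env <- synapredict:::pip_envelope(t, 0.0005, 0.005)
  steady <- sum(env > 1 - 1e-9) / fs
  expect_lt(abs(steady - 0.004), 2 / fs)
  # mid-ramp sits at half the steady amplitude (cos^2 at a quarter period)
  mid <- which.min(abs(t - 0.00025))
  expect_equal(env[mid], 0.5, tolerance = 1e-3)
  # zero ramp degenerates to a rectangular gate
  expect_true(all(synapredict:::pip_envelope(t, 0, 0.005) == 1))
  expect_error(stimulus_spec("tone_pip", carrier_hz = 16000,
                             duration_s = 0.0005, rise_fall_ms = 0.5),
               "duration")
})

test_that("the interleaved train rotates frequencies fastest and divides the
          rate", {
  sched <- build_interleaved_train(
    frequencies = 5600 * 2^(0:6 / 2), levels = seq(10, 80, 5),
    overall_rate_hz = 81
  )
  expect_equal(nrow(sched$entries), 7 * 15)
  expect_equal(sched$per_frequency_rate_hz, 81 / 7)
  # consecutive stimuli always differ in frequency
  expect_true(all(diff(sched$entries$frequency_hz) != 0))
  expect_equal(diff(sched$entries$onset_s),
               rep(1 / 81, nrow(sched$entries) - 1))
  one <- build_interleaved_train(1000, c(60, 70), 50)
  expect_equal(one$per_frequency_rate_hz, 50)
  expect_error(build_interleaved_train(numeric(), 70, 81), "at least")
})

test_that("spec validation rejects unusable configurations", {
  expect_error(stimulus_spec("sam", carrier_hz = 16000, fm_hz = 110,
                             depth = 1.2), "depth")
  expect_error(stimulus_spec("sam", carrier_hz = 16000, fm_hz = 113,
                             duration_s = 0.5), "DFT bin")
  expect_error(stimulus_spec("sam", carrier_hz = 6e4, fm_hz = 110,
                             sample_rate_hz = 1e5), "Nyquist")
})
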