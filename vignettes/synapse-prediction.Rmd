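---
title: "Predicting cochlear synapse counts from evoked potentials: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting cochlear synapse counts from evoked potentials: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Cochlear synaptopathy -- the loss of synapses between inner hair cells
(IHCs) and auditory-nerve fibers -- cannot be observed in a living ear.
Candidate non-invasive proxies are the amplitude of wave 1 of the auditory
brainstem response (ABR), the magnitude of the envelope following response
(EFR) to amplitude-modulated tones, and, as a covariate for outer hair
cell (OHC) function, distortion-product otoacoustic emissions (DPOAEs).
The difficulty is that OHC dysfunction usually co-occurs with synapse loss
and attenuates the very same evoked potentials, so a useful biomarker must
either be insensitive to OHC status or be adjustable for it.

`synapredict` implements the full evaluation pipeline for such biomarkers:
stimulus synthesis, bootstrapped EFR spectral metrics, ABR growth metrics,
DPOAE summaries, correlation screening, cross-validated linear
synapse-prediction models, and AICc model ranking -- together with a
seeded synthetic mouse-cohort generator so the whole analysis runs
end-to-end with no external data.

## The prediction model

For ear $i$ and cochlear frequency $f \in \{16, 32\}$ kHz, synapses per
IHC $y_{f,i}$ are modeled by ordinary least squares as

$$y_{f,i} = \beta_0 + \sum_j \beta_{1,j}\, M_{j,f,i} +
\beta_2\, \xi_{f,i} + \epsilon_{f,i},$$

where $M_{j,f,i}$ are evoked-potential measures (ABR wave-1 amplitude at
60/70/80 dB SPL, wave-1 growth slopes, or SAM/RAM EFR magnitudes at 110 or
1000 Hz modulation) and $\xi_{f,i}$ is an optional DPOAE adjustment (the
DPOAE threshold, or the emission level at L2 = 40 or 55 dB SPL). The two
frequencies are pooled with no frequency term. The empty model
($y = \beta_0 + \epsilon$, predicting the sample mean) and DPOAE-only
models are the baselines any genuine synaptopathy metric has to beat.
Predictors are used on their native scales; OLS prediction is invariant to
linear rescaling, and collinearity between evoked measures and DPOAEs --
which the cohort deliberately exhibits -- affects coefficient
interpretability, not predictive performance.

Performance is estimated two complementary ways:

* **Repeated ear-grouped cross-validation** (`repeated_grouped_cv()`).
  The acute-noise group is set aside entirely as an independent test set
  for focal synaptopathy. The remaining ears are partitioned into 10 folds
  (all rows of an ear share a fold; fold sizes differ by at most one ear),
  each fold is held out in turn, and the whole procedure is repeated 10
  times with reshuffled ears. Root-mean-squared error
  $\sqrt{\tfrac1N\sum_k (y_k - \hat y_k)^2}$ is computed per (repeat,
  fold) on the held-out fold and on the full acute test set; the mean and
  SEM pool all repeats x folds. The SEM pools without a between-repeat
  correction, which understates variance slightly since repeats reuse the
  same ears; it is reported for display, never for testing.
* **AICc ranking** (`compare_models_aicc()`). Every model in the grid is
  fit to one common complete-case observation set (rows missing any
  column used by any model are dropped first), and
  $\mathrm{AICc} = 2k - 2\ell + \tfrac{2k(k+1)}{n-k-1}$ is compared to the
  best model. $\ell$ is the Gaussian maximum-likelihood value from the
  residual sum of squares, and $k$ counts the intercept, slopes, and the
  residual variance (the convention under which `stats::logLik` can serve
  as an independent cross-check). $\Delta\mathrm{AICc} \le 2$ marks
  comparable models, 2--10 ambiguous evidence, $> 10$ a clear preference.
  Cross-validation and AICc intentionally use different observation sets
  (per-model complete cases versus one common set), mirroring how the two
  analyses answer different questions.

## Stimuli

EFR stimuli are 500 ms, 70 dB SPL amplitude-modulated carriers at 16 or
32 kHz, modulated at 110 or 1000 Hz:

* **SAM**: envelope $1 + d\,\sin(2\pi f_m t)$ with depth $d = 1$.
* **RAM**: a rectangular gate that is "on" for a 25% duty cycle, with
  raised-cosine (Tukey-style) tapers at each on/off edge. The taper span
  is 2.5% *of the modulation period* at each edge; the source stimulus
  definition leaves the taper's base ambiguous, so this choice is pinned
  down here and in `stimulus_spec()`. Tapers lie inside the on-window, so
  the above-half-maximum fraction is duty minus one taper span.

Both are scaled to identical overall RMS (70 dB SPL re 20 uPa), which
makes the RAM peak pressure higher than SAM's. ABR stimuli are 5 ms tone
pips (0.5 ms cosine-squared ramps, 4 ms steady state) presented in an
interleaved train: one presentation of each of 7 frequencies x 15 levels
at 81 stimuli/s overall, frequencies rotating fastest, giving an
effective per-frequency rate of 81/7 = 11.6/s. EFR epochs repeat at
1/(0.5 s + mean jitter 0.11 s) = 1.64/s. Default synthesis rate is
100 kHz; `fm_hz * duration_s` must be an integer so the modulation
frequency falls exactly on a DFT bin.

## EFR magnitude estimation

`bootstrap_spectrum()` draws, 100 times, 64 trials with replacement from
each polarity (128 per draw), averages the waveforms, and computes the
magnitude spectrum of the average; per-trial DFTs are computed once and
averaged in the complex domain, which is identical by linearity. The
noise floor around each harmonic is the mean magnitude in the 4th--7th
bins on either side (eight bins). The estimator of record is the mean
over draws. With the full 500 ms epoch and no onset exclusion the bin
spacing is 2 Hz; no window is applied, so harmonic bins are exact.
Magnitudes are single-sided spectral amplitudes in uV (dB re 1 uV where a
reference is needed; the SNR measures are reference-free):

* `f0` $= 20\log_{10} f_0$, `f0_4` $= 20\log_{10}\sum_{i=0}^4 f_i$
* `f0_snr` $= 20\log_{10}(f_0/n_0)$,
  `f0_4_snr` $= 20\log_{10}\sum_{i=0}^4 f_i/n_i$
* `f0_4_power` $= 10\log_{10}\sum_{i=0}^4 f_i^2$ (power-sum variant)
* `plv` $= \left|\,\overline{e^{i\phi_0}}\,\right|$ across draws.

The PLV definition is a documented choice: the phase is taken at $f_0$ of
each draw's average, and the mean phasor is across bootstrap draws.
Because draws resample the *same* trials, draw phases are correlated, and
the PLV of pure noise concentrates well above zero (median about 0.6 at
default settings) rather than near zero as a per-trial PLV would. The
estimator is kept because all statistics in this pipeline are defined on
the bootstrap distribution; its `[0, 1]` bounds, perfect-locking value of
1, and decline under phase scatter all hold and are tested.

## ABR and DPOAE summaries

Averaged ABR traces are band-passed 300--3000 Hz (4th-order Butterworth,
zero-phase `signal::filtfilt`). Wave-1 amplitude is peak-to-following-
trough (configurable to baseline-to-peak); the growth metrics are the
amplitudes at 60/70/80 dB SPL and OLS slopes over the top two levels
(75/80), top four (65--80), or all collected levels (`Slope_all` uses all
collected levels by default -- whether subthreshold levels should be
excluded is ambiguous in the source description, and a flag exposes the
choice). The threshold criterion (lowest level exceeding 3x the noise
scale with all higher levels also exceeding it) is a deliberately simple,
documented stand-in for rater-reviewed algorithms; it is used only for
synthetic validation.

DPOAE input--output functions are summarized by the threshold -- the L2
at which the emission crosses 0 dB SPL, linearly interpolated in dB--dB
coordinates (a step-readout option exists for sensitivity checks) -- and
the emission levels at L2 = 40 and 55 dB SPL. "Not reached" propagates as
a missing covariate into complete-case filtering.

## The synthetic cohort generator

`generate_cohort()` encodes the *statistical* structure the analysis
assumes; it is not a biophysical cochlear model. Four groups (young
n = 17, acute noise n = 13, aged n = 14, aged+noise n = 13; 32 F / 25 M)
with:

* **Synapse loss**: baselines of 17 (16 kHz) and 15 (32 kHz) synapses/IHC
  in young ears (about 15/IHC at the synaptogram peak), focal ~50% loss
  at 32 kHz only for acute noise, broad ~30--35% (aged) and ~45--50%
  (aged+noise) loss at both frequencies.
* **OHC loss** collinear with group (means 1/5/16/26 dB), driving both
  the DPOAE covariates (linear I/O, slope 0.6 dB/dB, baseline threshold
  25 dB) and the attenuation of evoked responses.
* **Measure links**: each evoked measure is linear in the ear's
  *effective* synapse count with measure-specific gain, OHC sensitivity
  (dB per dB; RAM < SAM, encoding the premise that the sharp RAM onset is
  less vulnerable to OHC dysfunction; ABR at 80 dB SPL least sensitive),
  off-frequency spread (the fraction of the response driven by cochlear
  regions away from the nominal place -- high for EFRs, low for ABR --
  which is what makes every model overpredict focal 32 kHz loss while ABR
  degrades least), and a per-ear log-normal scatter (electrode placement,
  head size; smallest for RAM at 1 kHz, largest for the 110 Hz EFRs,
  whose generators are partly central). These four knobs are free
  generator parameters for sensitivity analyses, not estimates of any
  real quantity; their defaults were chosen to realize the qualitative
  structure just described and are deliberately not tuned further.
* **Trial-level EFRs**: each trial is response + white EEG noise (10 uV
  per sample) + a polarity-inverting carrier artifact (0.5 uV); 64 trials
  per polarity, alternating. Responses carry the modulation frequency and
  its first four harmonics with SAM- or RAM-appropriate weights. The
  response is digitized at 2 kHz (110 Hz stimuli) or 10.24 kHz (1 kHz
  stimuli): the full 500 ms epoch keeps 2 Hz bins while Nyquist clears
  the 5th harmonic plus the 7-bin noise window. ABR amplitudes follow a
  saturating logistic growth in level (midpoint 45 dB SPL + OHC loss,
  scale 6 dB) -- the growth form is a generator choice, as no functional
  form is prescribed by the data being emulated. Synthetic mode supplies
  ABR amplitudes directly; the waveform path (filtering, peak picking)
  shares the same summary type and is validated on constructed traces.
* **Missingness**: 35% of ears lack the 1 kHz EFRs at the 32 kHz carrier,
  exercising complete-case machinery.
* **Sex** is assigned but has no effect on any generated signal (matching
  the finding that sex adjustment did not improve predictions).

What the generator does *not* emulate: cochlear nonlinearity and
compression, adaptation, off-frequency listening beyond the static spread
mixture, latency structure, non-Gaussian EEG noise, or any
frequency-place map. Tests that pass on this cohort therefore validate
the *pipeline* (estimators, resampling, selection machinery) and the
qualitative orderings it is designed to exhibit -- not quantitative
agreement with any real dataset.

## Numerical choices and degenerate inputs

* SPL reference 20 uPa RMS; all levels are overall RMS levels.
* Waveforms scaled to within 0.01 dB of the requested level; all-zero
  input is an error.
* Bootstrap draws must be even-sized and both polarities present; a
  modulation frequency off the DFT grid is an error, as is a harmonic too
  close to the spectrum edge for the 8-bin floor.
* SNR measures error on a zero noise floor (degenerate noiseless input).
* `|r| = 1` correlations are flagged degenerate (the Fisher interval
  collapses); screens report pairs with fewer than 4 complete
  observations as missing instead of failing.
* Rank-deficient fits error with the collinear columns named; AICc
  requires $n > k + 1$.
* CV requires at least as many non-test ears as folds; identical seeds
  give bit-identical fold assignments and results.

## Problem sizes

The shipped analyses and tests use the study-sized cohort (57 ears, two
frequencies, 128 EFR trials per ear x stimulus, 100 bootstrap draws,
10 x 10 CV). One full cohort's EFR extraction takes roughly half a minute;
the qualitative-ordering check runs ten independent cohorts. Estimator
property tests run on purpose-built small fixtures (for example 200-ear
tables for the CV noise-floor checks, averaged over four data
realizations so the realized noise SD's sampling wobble stays below the
tolerance being tested).

## Limitations

* The generator's linear measure links and static spread mixture are the
  simplest structure that produces the intended orderings; effect sizes
  on real data will differ, and reproducing printed table values requires
  the real per-ear dataset in `build_analysis_table()` format.
* The bootstrap-based PLV is a reproducibility measure of the f0 phase
  estimate, not a per-trial phase-locking statistic.
* The simple ABR threshold criterion is not a substitute for validated
  threshold algorithms on real waveforms.
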