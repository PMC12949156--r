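# synapredict

Cochlear synaptopathy — the loss of synapses between inner hair cells
(IHCs) and auditory-nerve fibers — can today be confirmed only by
post-mortem histology. `synapredict` is an R package and analysis
workflow for evaluating non-invasive electrophysiological predictors of
synapse counts in a mouse model: ABR wave-1 amplitude and growth slope,
envelope following responses (EFR) to sinusoidally (SAM) and
rectangularly (RAM) amplitude-modulated tones at 110 and 1000 Hz
modulation, and DPOAE covariates for outer-hair-cell (OHC) function,
which is collinear with synapse loss and confounds every evoked measure.

For ear *i* and cochlear frequency *f* ∈ {16, 32} kHz, synapses per IHC
are modeled as

> y<sub>f,i</sub> = β₀ + Σ<sub>j</sub> β<sub>1,j</sub>·M<sub>j,f,i</sub> + β₂·ξ<sub>f,i</sub> + ε<sub>f,i</sub>

where M are evoked-potential measures and ξ an optional DPOAE adjustment
(threshold, DPOAE₄₀, or DPOAE₅₅). Models are compared by repeated
(10×) ten-fold **ear-grouped cross-validation** — with the acute-noise
group held out entirely as a focal-synaptopathy test set — and by
**AICc** on a common complete-case observation set. EFR magnitude is
estimated by a balanced bootstrap: 100 draws of 64 + 64
alternating-polarity trials, averaged, with harmonic amplitudes f₀…f₄
and an 8-bin noise floor (±4th–7th DFT bins) per harmonic; measures
include f₀, f₀₋₄ = 20·log₁₀ Σfᵢ, the SNR variants, the power sum
10·log₁₀ Σfᵢ², and a phase-locking value.

A seeded synthetic cohort generator (young n = 17, acute noise n = 13,
aged n = 14, aged + noise n = 13; focal ~50% loss at 32 kHz for acute
noise, broad loss for the aged groups; OHC loss collinear with group)
makes the entire analysis reproducible with no external data. Real
per-ear tables in the same long format can be fed directly to
`build_analysis_table()` → `repeated_grouped_cv()` /
`compare_models_aicc()`.

## Worked example

```r
library(synapredict)

cohort <- generate_cohort(cohort_config(), seed = 1)
spec   <- efr_stimulus("ram", carrier_hz = 16000, fm_hz = 1000)
trials <- simulate_efr_trials(cohort, "ear_01", spec, seed = 42)
boot   <- bootstrap_spectrum(trials, seed = 43)    # 100 draws of 64+64

round(colMeans(boot$mags), 3)
#>    f0    f1    f2    f3    f4
#> 3.353 2.671 1.806 1.144 0.650
compute_efr_measure(boot, "f0")    #> 10.51  (dB re 1 uV)
compute_efr_measure(boot, "f0_4")  #> 19.67  (dB re 1 uV)
compute_plv(boot)                  #> 1

io <- simulate_dpoae_io(cohort, "ear_01", 16000, seed = 7)
dpoae_threshold(io)                #> 27.4   (dB SPL)
```

The harmonic series (substantial energy out to f₄) is the RAM signature;
a SAM stimulus concentrates its response at f₀. The young ear's DPOAE
threshold sits near the 25 dB SPL baseline because it has little OHC
loss.

## The analysis workflow

The numbered scripts under `analysis/` run the study end-to-end
(seed as optional first argument), writing tidy CSVs under `results/`:

| script | writes |
|---|---|
| `01_simulate_cohort.R` | cohort metadata, ground-truth synapses/OHC |
| `02_extract_metrics.R` | EFR/ABR/DPOAE metrics, the analysis table |
| `03_correlations.R` | Pearson + Fisher-CI screen (Bonferroni-corrected) |
| `04_cross_validation.R` | CV RMSE per model, ΔRMSE vs the ABR₈₀ family |
| `05_model_selection.R` | AICc tables, all mice and excluding acute noise |

On the default cohort (seed 1) the workflow prints, among other things:

```
validation (no/broad synaptopathy): best model ram_1000|none, RMSE 1.88 (SEM 0.04)
acute test set (focal synaptopathy): best model abr_80|none, RMSE 3.94
intercept-only baseline: validation 3.39, test 4.70 synapses/IHC
```

i.e. the RAM EFR at 1 kHz modulation is the best single predictor where
synapse loss is broad, every model does far worse on focal loss, and the
ABR wave-1 amplitude degrades least there — with prediction errors of
roughly 2 vs 4 synapses per IHC against an intercept-only baseline of
3.4. `run_pipeline()` performs the same stages in one call.

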