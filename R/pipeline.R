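#' EFR stimulus grid of the study design
#'
#' SAM and RAM tones at 110 and 1000 Hz modulation for each carrier.
#'
#' @param carriers carrier frequencies (Hz).
#' @return list of [stimulus_spec()]s.
#' @export
efr_stimulus_grid <- function(carriers = c(16000, 32000)) {
  grid <- expand.grid(kind = c("sam", "ram"), fm = c(110, 1000),
                      carrier = carriers, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i) {
    efr_stimulus(grid$kind[i], grid$carrier[i], grid$fm[i])
  })
}

#' Extract all EFR measures for a cohort
#'
#' Simulates the trial-level EFR for every ear x stimulus, runs the
#' balanced bootstrap, and computes the requested magnitude measures.
#' Ears flagged as missing the 1 kHz modulated EFRs at the 32 kHz carrier
#' are skipped for those conditions (the study's missingness pattern).
#'
#' @param cohort a [generate_cohort()] result.
#' @param methods EFR measures to compute (see [efr_methods()]).
#' @param stimuli list of EFR stimulus specs.
#' @param seed base seed; per-set seeds are derived deterministically.
#' @return tidy tibble: ear_id, carrier_hz, fm_hz, measure, method, value.
#' @export
extract_efr_table <- function(cohort, methods = "f0",
                              stimuli = efr_stimulus_grid(
                                cohort$config$frequencies),
                              seed = cohort$seed) {
  out <- list()
  z <- 0L
  for (si in seq_along(stimuli)) {
    spec <- stimuli[[si]]
    for (ei in seq_len(nrow(cohort$ears))) {
      ear <- cohort$ears$ear_id[ei]
      if (spec$fm_hz == 1000 && spec$carrier_hz == 32000 &&
          cohort$ears$missing_1khz_32k[ei]) next
      set_seed <- (seed * 977L + si * 131L + ei) %% 2147483647L
      tset <- simulate_efr_trials(cohort, ear, spec, seed = set_seed)
      z <- z + 1L
      out[[z]] <- efr_measures(tset, methods = methods,
                               n_draws = cohort$config$efr_n_draws,
                               seed = set_seed + 1L)
    }
  }
  dplyr::bind_rows(out)
}

#' Extract ABR wave-1 summaries for a cohort
#'
#' Synthetic mode supplies wave-1 amplitudes directly from the growth
#' simulator (bypassing waveform peak picking, which shares the same
#' summary type).
#'
#' @param cohort a [generate_cohort()] result.
#' @param seed base seed.
#' @return tibble per ear x frequency (see [abr_summary()]).
#' @export
extract_abr_table <- function(cohort, seed = cohort$seed) {
  freqs <- cohort$config$frequencies
  rows <- list()
  z <- 0L
  for (ei in seq_len(nrow(cohort$ears))) {
    for (f in freqs) {
      g <- simulate_abr_growth(cohort, cohort$ears$ear_id[ei], f,
                               seed = (seed * 977L + 50000L +
                                         ei * length(freqs) + match(f, freqs)))
      z <- z + 1L
      rows[[z]] <- abr_summary(g)
    }
  }
  dplyr::bind_rows(rows)
}

#' Extract DPOAE summaries for a cohort
#'
#' @param cohort a [generate_cohort()] result.
#' @param seed base seed.
#' @return tibble per ear x f2 (see [dpoae_summary()]).
#' @export
extract_dpoae_table <- function(cohort, seed = cohort$seed) {
  freqs <- cohort$config$frequencies
  rows <- list()
  z <- 0L
  for (ei in seq_len(nrow(cohort$ears))) {
    for (f in freqs) {
      io <- simulate_dpoae_io(cohort, cohort$ears$ear_id[ei], f,
                              seed = (seed * 977L + 90000L +
                                        ei * length(freqs) + match(f, freqs)))
      z <- z + 1L
      rows[[z]] <- dpoae_summary(io)
    }
  }
  dplyr::bind_rows(rows)
}

#' The study's single-measure model grid
#'
#' Six evoked options (none, ABR_80, SAM_110, SAM_1000, RAM_110, RAM_1000)
#' crossed with four DPOAE adjustments (none, threshold, DPOAE_40,
#' DPOAE_55).
#'
#' @param efr_method EFR magnitude method variant.
#' @param extended also include ABR_60/ABR_70 and the three slope models.
#' @return list of [model_spec()]s.
#' @export
default_model_grid <- function(efr_method = "f0", extended = FALSE) {
  evoked_sets <- list(character(), "abr_80", "sam_110", "sam_1000",
                      "ram_110", "ram_1000")
  if (extended) {
    evoked_sets <- c(evoked_sets,
                     list("abr_70", "abr_60", "slope_2", "slope_4",
                          "slope_all", c("abr_60", "ram_1000"),
                          c("abr_80", "ram_1000"),
                          c("abr_80", "slope_all")))
  }
  grid <- list()
  for (ev in evoked_sets) {
    for (adj in c("none", "threshold", "dpoae_40", "dpoae_55")) {
      grid[[length(grid) + 1L]] <-
        model_spec(ev, adjust = adj, efr_method = efr_method)
    }
  }
  grid
}

#' Run the full analysis pipeline
#'
#' simulate -> extract -> correlate -> cross-validate -> AICc-compare,
#' writing tidy CSV artifacts and a JSON manifest into `out_dir`. With
#' `resume = TRUE`, stages whose output files already exist are skipped
#' (the cheap deterministic cohort stage is always regenerated in memory).
#'
#' @param config a [cohort_config()].
#' @param seed integer seed; every stochastic stage derives its seed from
#'   it.
#' @param out_dir output directory (created if needed); `NULL` keeps
#'   everything in memory.
#' @param grid model grid; default [default_model_grid()].
#' @param cv a [cv_config()]; its seed is overridden by `seed`.
#' @param resume skip stages whose output CSV already exists.
#' @param quiet suppress progress messages.
#' @return (invisibly) list: cohort, analysis_table, correlations,
#'   cv_results (list of `cv_result`), cv_summary (tibble), aicc_all,
#'   aicc_excl, manifest.
#' @export
run_pipeline <- function(config = cohort_config(), seed = 1,
                         out_dir = NULL, grid = default_model_grid(),
                         cv = cv_config(seed = seed + 300000L),
                         resume = FALSE, quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  emit <- function(df, name) {
    if (!is.null(out_dir)) {
      utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
    }
  }
  stage_file <- function(name) {
    if (is.null(out_dir)) NULL else file.path(out_dir, name)
  }
  have <- function(name) {
    resume && !is.null(out_dir) && file.exists(file.path(out_dir, name))
  }
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)

  say("stage 1/6: cohort")
  cohort <- generate_cohort(config, seed = seed)
  emit(cohort$ears, "cohort_ears.csv")
  emit(cohort$truth, "cohort_truth.csv")

  say("stage 2/6: EFR measures")
  efr_tbl <- if (have("efr_measures.csv")) {
    tibble::as_tibble(utils::read.csv(stage_file("efr_measures.csv")))
  } else {
    x <- extract_efr_table(cohort, methods = "f0")
    emit(x, "efr_measures.csv")
    x
  }

  say("stage 3/6: ABR and DPOAE summaries")
  abr_tbl <- if (have("abr_summaries.csv")) {
    tibble::as_tibble(utils::read.csv(stage_file("abr_summaries.csv")))
  } else {
    x <- extract_abr_table(cohort)
    emit(x, "abr_summaries.csv")
    x
  }
  dpoae_tbl <- if (have("dpoae_summaries.csv")) {
    tibble::as_tibble(utils::read.csv(stage_file("dpoae_summaries.csv")))
  } else {
    x <- extract_dpoae_table(cohort)
    emit(x, "dpoae_summaries.csv")
    x
  }

  table <- build_analysis_table(cohort, efr_tbl, abr_tbl, dpoae_tbl)
  emit(table, "analysis_table.csv")

  say("stage 4/6: correlation screen")
  pairs <- expand.grid(
    measure = c("abr_80", "sam_110_f0", "sam_1000_f0", "ram_110_f0",
                "ram_1000_f0"),
    target = c("synapses_per_ihc", "dpoae_threshold", "dpoae_40",
               "dpoae_55"),
    stringsAsFactors = FALSE
  )
  correlations <- correlation_screen(table, pairs, by = "frequency_hz")
  emit(correlations, "correlations.csv")

  say("stage 5/6: cross-validated prediction error (",
      length(grid), " models)")
  cv_results <- lapply(grid, function(spec) {
    repeated_grouped_cv(spec, table, cv)
  })
  cv_summary <- dplyr::bind_rows(lapply(cv_results, function(r) {
    tibble::tibble(model_id = r$spec$model_id, adjust = r$spec$adjust,
                   mean_val = r$mean_val, sem_val = r$sem_val,
                   mean_test = r$mean_test, sem_test = r$sem_test,
                   n_rows = r$n_rows, n_ears = r$n_ears)
  }))
  emit(cv_summary, "cv_summary.csv")

  say("stage 6/6: AICc comparison")
  aicc_all <- compare_models_aicc(grid, table, scope = "all_mice")
  aicc_excl <- compare_models_aicc(grid, table, scope = "excluding_acute")
  emit(aicc_all, "aicc_all_mice.csv")
  emit(aicc_excl, "aicc_excluding_acute.csv")

  manifest <- list(
    package = "synapredict",
    seed = seed,
    n_ears = nrow(cohort$ears),
    n_models = length(grid),
    config = config[setdiff(names(config),
                            c("group_loss", "ohc_loss_db",
                              "harmonic_weights"))],
    artifacts = c("cohort_ears.csv", "cohort_truth.csv",
                  "efr_measures.csv", "abr_summaries.csv",
                  "dpoae_summaries.csv", "analysis_table.csv",
                  "correlations.csv", "cv_summary.csv",
                  "aicc_all_mice.csv", "aicc_excluding_acute.csv")
  )
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(list(cohort = cohort, analysis_table = table,
                 correlations = correlations, cv_results = cv_results,
                 cv_summary = cv_summary, aicc_all = aicc_all,
                 aicc_excl = aicc_excl, manifest = manifest))
}
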