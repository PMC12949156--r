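#' Assemble the long-format analysis table
#'
#' Joins ground truth (synapses/IHC), wide EFR measures, ABR summaries, and
#' DPOAE summaries on (ear_id, frequency_hz), restricted to the 16 and
#' 32 kHz regions, one row per ear x frequency. Missing cells are
#' preserved as `NA`; complete-case handling happens per model fit.
#'
#' @param cohort a [generate_cohort()] result (supplies group/sex and the
#'   ground truth).
#' @param efr_table tidy EFR measures: (ear_id, carrier_hz, measure,
#'   method, value); spread to columns named `<measure>_<method>` (e.g.
#'   `ram_1000_f0`).
#' @param abr_table per ear x frequency ABR summaries
#'   (see [abr_summary()]).
#' @param dpoae_table per ear x frequency DPOAE summaries
#'   (see [dpoae_summary()]).
#' @param frequencies analysis frequencies (Hz).
#' @return tibble: ear_id, group, sex, frequency_hz, synapses_per_ihc, one
#'   column per measure variant, dpoae_threshold, dpoae_40, dpoae_55.
#' @export
build_analysis_table <- function(cohort, efr_table, abr_table, dpoae_table,
                                 frequencies = c(16000, 32000)) {
  base <- dplyr::inner_join(cohort$ears[, c("ear_id", "group", "sex")],
                            cohort$truth[, c("ear_id", "frequency_hz",
                                             "synapses_per_ihc")],
                            by = "ear_id")
  base <- base[base$frequency_hz %in% frequencies, , drop = FALSE]

  efr_long <- tibble::tibble(
    ear_id = efr_table$ear_id,
    frequency_hz = efr_table$carrier_hz,
    column = paste(efr_table$measure, efr_table$method, sep = "_"),
    value = efr_table$value
  )
  if (anyDuplicated(efr_long[, c("ear_id", "frequency_hz", "column")])) {
    stop("duplicate (ear_id, frequency_hz, measure, method) keys in the ",
         "EFR table", call. = FALSE)
  }
  efr_wide <- tidyr::pivot_wider(efr_long, names_from = "column",
                                 values_from = "value")
  for (nm in list(efr_wide, abr_table, dpoae_table)) {
    if (anyDuplicated(nm[, c("ear_id", "frequency_hz")])) {
      stop("duplicate (ear_id, frequency_hz) keys in a measurement table",
           call. = FALSE)
    }
  }
  out <- dplyr::left_join(base, efr_wide, by = c("ear_id", "frequency_hz"))
  out <- dplyr::left_join(out, abr_table, by = c("ear_id", "frequency_hz"))
  out <- dplyr::left_join(out, dpoae_table, by = c("ear_id", "frequency_hz"))
  if (anyDuplicated(out[, c("ear_id", "frequency_hz")])) {
    stop("duplicate (ear_id, frequency_hz) rows after join", call. = FALSE)
  }
  tibble::as_tibble(out)
}

#' Specify a synapse-prediction model
#'
#' A model is a set of evoked-potential predictors, an optional DPOAE
#' adjustment covariate, and an optional sex term, in the linear form
#' `synapses ~ evoked measures + dpoae + sex` pooled over frequencies
#' (no frequency term). The empty evoked set with no adjustment is the
#' intercept-only baseline; the empty set with an adjustment is a
#' DPOAE-only model.
#'
#' @param evoked character vector from `abr_80`, `abr_70`, `abr_60`,
#'   `slope_2`, `slope_4`, `slope_all`, `sam_110`, `sam_1000`, `ram_110`,
#'   `ram_1000` (EFR names are resolved to `<name>_<efr_method>` columns).
#' @param adjust `"none"`, `"threshold"`, `"dpoae_40"`, or `"dpoae_55"`.
#' @param efr_method EFR magnitude method variant for the EFR predictors.
#' @param include_sex add a female-indicator term.
#' @return a `model_spec` list with a stable `model_id`.
#' @export
model_spec <- function(evoked = character(),
                       adjust = c("none", "threshold", "dpoae_40",
                                  "dpoae_55"),
                       efr_method = "f0",
                       include_sex = FALSE) {
  adjust <- match.arg(adjust)
  known <- c("abr_80", "abr_70", "abr_60", "slope_2", "slope_4",
             "slope_all", "sam_110", "sam_1000", "ram_110", "ram_1000")
  bad <- setdiff(evoked, known)
  if (length(bad)) {
    stop("unknown evoked measures: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  id <- paste0(
    if (length(evoked)) paste(evoked, collapse = "+") else "intercept",
    if (length(intersect(evoked, efr_measure_names())) &&
        efr_method != "f0") paste0(",", efr_method),
    "|", adjust, if (include_sex) "|sex"
  )
  structure(list(evoked = evoked, adjust = adjust, efr_method = efr_method,
                 include_sex = include_sex, model_id = id),
            class = "model_spec")
}

#' Model spec over arbitrary predictor columns
#'
#' Like [model_spec()] but taking table column names verbatim, for ad hoc
#' tables that do not use the study's measure naming.
#'
#' @param columns predictor column names (may be empty).
#' @param adjust,include_sex as in [model_spec()].
#' @return a `model_spec`.
#' @export
model_spec_raw <- function(columns = character(),
                           adjust = c("none", "threshold", "dpoae_40",
                                      "dpoae_55"),
                           include_sex = FALSE) {
  adjust <- match.arg(adjust)
  id <- paste0(if (length(columns)) paste(columns, collapse = "+") else
    "intercept", "|", adjust, if (include_sex) "|sex")
  structure(list(evoked = columns, adjust = adjust, efr_method = "raw",
                 include_sex = include_sex, model_id = id,
                 raw_columns = columns),
            class = "model_spec")
}

efr_measure_names <- function() {
  c("sam_110", "sam_1000", "ram_110", "ram_1000")
}

adjust_column <- function(adjust) {
  switch(adjust, none = NULL, threshold = "dpoae_threshold",
         dpoae_40 = "dpoae_40", dpoae_55 = "dpoae_55")
}

#' Predictor columns required by a model spec
#' @param spec a [model_spec()].
#' @return character vector of column names (may be empty).
#' @export
model_columns <- function(spec) {
  if (!is.null(spec$raw_columns)) {
    return(c(spec$raw_columns, adjust_column(spec$adjust),
             if (spec$include_sex) "sex_female"))
  }
  ev <- vapply(spec$evoked, function(e) {
    if (e %in% efr_measure_names()) paste(e, spec$efr_method, sep = "_")
    else e
  }, character(1), USE.NAMES = FALSE)
  c(ev, adjust_column(spec$adjust), if (spec$include_sex) "sex_female")
}

model_frame <- function(spec, table, outcome = "synapses_per_ihc") {
  if (spec$include_sex && !"sex_female" %in% names(table)) {
    table$sex_female <- as.numeric(table$sex == "F")
  }
  cols <- model_columns(spec)
  missing_cols <- setdiff(cols, names(table))
  if (length(missing_cols)) {
    stop("table lacks required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- table[, c(outcome, cols), drop = FALSE]
  keep <- stats::complete.cases(df)
  list(data = df[keep, , drop = FALSE], keep = keep, cols = cols,
       outcome = outcome, table = table)
}

#' Fit a synapse-prediction model by ordinary least squares
#'
#' Complete-case OLS on the analysis table, frequencies pooled with no
#' frequency term. The log-likelihood is the Gaussian maximum-likelihood
#' value computed from the residual sum of squares; the parameter count
#' `k` includes the intercept, every slope, and the residual variance.
#'
#' @param spec a [model_spec()].
#' @param table an analysis table (see [build_analysis_table()]).
#' @return a `fit_result`: `spec`, `fit` (the `lm`), `coefficients`, `n`,
#'   `k`, `loglik`, `sigma_ml`, `rows_used` (logical over `table`).
#' @export
fit_model <- function(spec, table) {
  mf <- model_frame(spec, table)
  dat <- mf$data
  k_coef <- 1 + length(mf$cols)
  if (nrow(dat) < k_coef + 2) {
    stop("too few complete rows (", nrow(dat), ") for model ",
         spec$model_id, call. = FALSE)
  }
  form <- if (length(mf$cols)) {
    stats::reformulate(sprintf("`%s`", mf$cols), response = mf$outcome)
  } else {
    stats::as.formula(paste(mf$outcome, "~ 1"))
  }
  fit <- stats::lm(form, data = dat)
  if (anyNA(stats::coef(fit))) {
    stop("rank-deficient fit; collinear columns: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "), call. = FALSE)
  }
  n <- nrow(dat)
  rss <- sum(stats::residuals(fit)^2)
  sigma2 <- rss / n
  loglik <- -n / 2 * (log(2 * pi * sigma2) + 1)
  structure(list(spec = spec, fit = fit,
                 coefficients = stats::coef(fit), n = n,
                 k = k_coef + 1, loglik = loglik,
                 sigma_ml = sqrt(sigma2), rows_used = mf$keep),
            class = "fit_result")
}

#' Root-mean-squared prediction error
#' @param y observed values.
#' @param yhat predictions (same length).
#' @return `sqrt(mean((y - yhat)^2))`.
#' @export
rmse <- function(y, yhat) {
  if (length(y) == 0 || length(y) != length(yhat)) {
    stop("y and yhat must be nonempty and of equal length", call. = FALSE)
  }
  sqrt(mean((y - yhat)^2))
}

#' Cross-validation configuration
#'
#' @param k_folds folds per repeat (default 10).
#' @param repeats repeats with reshuffled ears (default 10).
#' @param test_group group held out entirely as an independent test set
#'   (default the acute noise exposed group); `NULL` for none.
#' @param seed integer seed for fold shuffling.
#' @return a `cv_config` list.
#' @export
cv_config <- function(k_folds = 10, repeats = 10,
                      test_group = "acute_noise", seed = 1) {
  stopifnot(k_folds >= 2, repeats >= 1)
  structure(list(k_folds = k_folds, repeats = repeats,
                 test_group = test_group, seed = seed),
            class = "cv_config")
}

#' Repeated ear-grouped k-fold cross-validation
#'
#' The test group's rows are excluded from fold assignment and used only as
#' an independent test set. All rows from one ear share a fold (grouped
#' CV), fold sizes differ by at most one ear, and each repeat reshuffles
#' the ears. Per (repeat, fold) the model is trained on the other folds'
#' rows and RMSE is computed on the held-out fold (validation) and on the
#' full test set; means and standard errors pool all repeats x folds.
#'
#' @param spec a [model_spec()].
#' @param table an analysis table; rows incomplete for the model's columns
#'   are dropped first (complete-case per model).
#' @param cfg a [cv_config()].
#' @return a `cv_result`: `spec`, `per_fold` tibble (repeat, fold,
#'   n_train, n_val, rmse_val, rmse_test), `mean_val`, `sem_val`,
#'   `mean_test`, `sem_test`, `n_rows`, `n_ears`.
#' @export
repeated_grouped_cv <- function(spec, table, cfg = cv_config()) {
  mf <- model_frame(spec, table)
  used <- mf$table[mf$keep, , drop = FALSE]
  used$.y <- used$synapses_per_ihc
  is_test <- if (is.null(cfg$test_group)) rep(FALSE, nrow(used)) else
    used$group == cfg$test_group
  test <- used[is_test, , drop = FALSE]
  pool <- used[!is_test, , drop = FALSE]
  ears <- unique(pool$ear_id)
  if (length(ears) < cfg$k_folds) {
    stop("fewer ears (", length(ears), ") than folds", call. = FALSE)
  }

  rows <- withr::with_seed(cfg$seed, {
    out <- vector("list", cfg$repeats * cfg$k_folds)
    z <- 0L
    for (rep_i in seq_len(cfg$repeats)) {
      shuffled <- sample(ears)
      fold_of <- rep(seq_len(cfg$k_folds), length.out = length(shuffled))
      for (fold_i in seq_len(cfg$k_folds)) {
        val_ears <- shuffled[fold_of == fold_i]
        val <- pool[pool$ear_id %in% val_ears, , drop = FALSE]
        train <- pool[!pool$ear_id %in% val_ears, , drop = FALSE]
        fit <- fit_on_frame(spec, train, mf$cols)
        z <- z + 1L
        out[[z]] <- tibble::tibble(
          repeat_i = rep_i, fold = fold_i,
          val_ears = list(sort(val_ears)),
          n_train = nrow(train), n_val = nrow(val),
          rmse_val = rmse(val$.y, predict_frame(fit, val, mf$cols)),
          rmse_test = if (nrow(test)) {
            rmse(test$.y, predict_frame(fit, test, mf$cols))
          } else NA_real_
        )
      }
    }
    dplyr::bind_rows(out)
  })
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  structure(list(spec = spec, per_fold = rows,
                 mean_val = mean(rows$rmse_val), sem_val = sem(rows$rmse_val),
                 mean_test = mean(rows$rmse_test),
                 sem_test = sem(rows$rmse_test),
                 n_rows = nrow(used), n_ears = length(ears)),
            class = "cv_result")
}

# lean OLS used inside the CV loop
fit_on_frame <- function(spec, train, cols) {
  X <- cbind(`(Intercept)` = 1,
             as.matrix(train[, cols, drop = FALSE]))
  qr_fit <- qr(X)
  if (qr_fit$rank < ncol(X)) {
    stop("rank-deficient training fold for model ", spec$model_id,
         call. = FALSE)
  }
  qr.coef(qr_fit, train$.y)
}

predict_frame <- function(beta, newdata, cols) {
  X <- cbind(1, as.matrix(newdata[, cols, drop = FALSE]))
  drop(X %*% beta)
}

#' Change in CV prediction error relative to a reference model family
#'
#' Each model is paired with the reference model carrying the same DPOAE
#' adjustment (threshold with threshold, and so on). When the two models
#' were cross-validated with the same seed the per-(repeat, fold) RMSE
#' values are paired and the SEM is that of the paired differences.
#'
#' @param results list of `cv_result` objects (the model grid).
#' @param reference_evoked evoked set identifying the reference family
#'   (e.g. `"abr_80"`); a reference must exist for every adjustment used.
#' @param which compare validation (`"val"`) or test (`"test"`) RMSE.
#' @return tibble: model_id, adjust, delta_rmse (model - reference),
#'   delta_sem, paired.
#' @export
delta_rmse_vs_reference <- function(results, reference_evoked,
                                    which = c("val", "test")) {
  which <- match.arg(which)
  col <- paste0("rmse_", which)
  key <- function(r) paste(sort(r$spec$evoked), collapse = "+")
  refs <- results[vapply(results, key, "") ==
                    paste(sort(reference_evoked), collapse = "+")]
  ref_by_adjust <- stats::setNames(refs,
                                   vapply(refs, function(r) r$spec$adjust,
                                          ""))
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  rows <- lapply(results, function(r) {
    ref <- ref_by_adjust[[r$spec$adjust]]
    if (is.null(ref)) {
      stop("no reference result for adjustment ", r$spec$adjust,
           call. = FALSE)
    }
    a <- r$per_fold[[col]]
    b <- ref$per_fold[[col]]
    paired <- length(a) == length(b)
    d <- if (paired) a - b else NULL
    tibble::tibble(
      model_id = r$spec$model_id, adjust = r$spec$adjust,
      delta_rmse = mean(a) - mean(b),
      delta_sem = if (paired) sem(d) else sqrt(sem(a)^2 + sem(b)^2),
      paired = paired
    )
  })
  dplyr::bind_rows(rows)
}
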