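#' Complete-case filter over a model grid's columns
#'
#' Keeps only the (ear, frequency) rows complete in every column any model
#' in the grid uses, so all models are compared on an identical
#' observation set.
#'
#' @param table an analysis table.
#' @param required_columns columns that must be non-missing (typically the
#'   union over the grid plus the outcome).
#' @return the filtered table, with attributes `n_dropped` and `n_ears`.
#' @export
complete_case_filter <- function(table, required_columns) {
  missing_cols <- setdiff(required_columns, names(table))
  if (length(missing_cols)) {
    stop("table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  keep <- stats::complete.cases(table[, required_columns, drop = FALSE])
  out <- table[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    stop("complete-case filter removed every row", call. = FALSE)
  }
  attr(out, "n_dropped") <- sum(!keep)
  attr(out, "n_ears") <- length(unique(out$ear_id))
  out
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = AIC + 2 k (k + 1) / (n - k - 1)` with `AIC = 2 k - 2 loglik`
#' from the Gaussian OLS likelihood; `k` counts the intercept, the slopes,
#' and the residual variance.
#'
#' @param fit a `fit_result` (see [fit_model()]).
#' @return the AICc value.
#' @export
compute_aicc <- function(fit) {
  n <- fit$n
  k <- fit$k
  if (n - k - 1 <= 0) {
    stop("AICc undefined: n <= k + 1 (n = ", n, ", k = ", k, ")",
         call. = FALSE)
  }
  2 * k - 2 * fit$loglik + 2 * k * (k + 1) / (n - k - 1)
}

aicc_tier <- function(delta) {
  cut(delta, c(-Inf, 2, 10, Inf),
      labels = c("comparable", "ambiguous", "inferior"))
}

#' AICc comparison of a model grid on a common observation set
#'
#' Applies the complete-case filter for the union of the grid's columns
#' (optionally after excluding the acute noise exposed group), fits every
#' model on the identical filtered rows, and reports AICc, the difference
#' to the best model (delta AICc, 0 for the best), and the evidence tier:
#' comparable (<= 2), ambiguous (2-10), inferior (> 10).
#'
#' @param grid list of [model_spec()]s.
#' @param table an analysis table.
#' @param scope `"all_mice"` or `"excluding_acute"`.
#' @param test_group group excluded under `"excluding_acute"`.
#' @return tibble: model_id, adjust, n_obs, n_ears, k, aicc, delta_aicc,
#'   tier.
#' @export
compare_models_aicc <- function(grid, table,
                                scope = c("all_mice", "excluding_acute"),
                                test_group = "acute_noise") {
  scope <- match.arg(scope)
  if (scope == "excluding_acute") {
    table <- table[table$group != test_group, , drop = FALSE]
  }
  if (any(vapply(grid, function(s) s$include_sex, logical(1))) &&
      !"sex_female" %in% names(table)) {
    table$sex_female <- as.numeric(table$sex == "F")
  }
  required <- unique(c("synapses_per_ihc",
                       unlist(lapply(grid, model_columns))))
  filtered <- complete_case_filter(table, required)

  rows <- lapply(grid, function(spec) {
    fit <- tryCatch(fit_model(spec, filtered), error = function(e) {
      stop("AICc comparison aborted; model ", spec$model_id,
           " failed to fit: ", conditionMessage(e), call. = FALSE)
    })
    tibble::tibble(model_id = spec$model_id, adjust = spec$adjust,
                   n_obs = fit$n, n_ears = attr(filtered, "n_ears"),
                   k = fit$k, aicc = compute_aicc(fit))
  })
  out <- dplyr::bind_rows(rows)
  out$delta_aicc <- out$aicc - min(out$aicc)
  out$tier <- aicc_tier(out$delta_aicc)
  out[order(out$delta_aicc), ]
}
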