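#' Bonferroni-corrected confidence level
#'
#' `(1 - (1 - c/100) / n) * 100`, where `c` is the desired confidence level
#' in percent and `n` the number of comparisons.
#'
#' @param c_pct nominal confidence level in percent, in (0, 100).
#' @param n_comparisons number of comparisons, >= 1.
#' @return corrected confidence level in percent.
#' @export
bonferroni_conf_level <- function(c_pct, n_comparisons) {
  if (c_pct <= 0 || c_pct >= 100) {
    stop("confidence level must lie in (0, 100)", call. = FALSE)
  }
  if (n_comparisons < 1) stop("need n_comparisons >= 1", call. = FALSE)
  (1 - (1 - c_pct / 100) / n_comparisons) * 100
}

#' Pearson correlation with a Fisher-transform confidence interval
#'
#' Two-sided interval `tanh(atanh(r) +/- z / sqrt(n - 3))` with `z` the
#' standard-normal quantile at the (possibly Bonferroni-corrected)
#' confidence level. The `significant` flag records whether the interval
#' excludes 0.
#'
#' @param x,y numeric vectors (pairwise complete, n >= 4).
#' @param conf_level_pct confidence level in percent.
#' @return tibble: r, ci_low, ci_high, conf_level_pct, n, significant,
#'   degenerate (TRUE when |r| = 1 and the interval collapses).
#' @export
pearson_with_ci <- function(x, y, conf_level_pct = 95) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete observations", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance in x or y", call. = FALSE)
  }
  r <- stats::cor(x, y)
  degenerate <- abs(r) >= 1 - 1e-12
  if (degenerate) {
    lo <- hi <- r
  } else {
    z <- stats::qnorm(1 - (1 - conf_level_pct / 100) / 2)
    lo <- tanh(atanh(r) - z / sqrt(n - 3))
    hi <- tanh(atanh(r) + z / sqrt(n - 3))
  }
  tibble::tibble(r = r, ci_low = lo, ci_high = hi,
                 conf_level_pct = conf_level_pct, n = n,
                 significant = lo > 0 | hi < 0, degenerate = degenerate)
}

#' Correlation screen over measure/target pairs
#'
#' Computes every requested Pearson correlation at the Bonferroni-corrected
#' confidence level for the number of pairs screened, optionally excluding
#' one experimental group first (the way correlations are re-computed
#' without the acute noise exposed ears). Pairs with fewer than 4 complete
#' observations are reported as missing rather than failing the screen.
#'
#' @param table a data frame with the named columns (e.g. an analysis
#'   table; see [build_analysis_table()]).
#' @param pairs data frame with columns `measure` and `target` naming the
#'   columns to correlate; one row per comparison.
#' @param conf_level_pct nominal (uncorrected) confidence level.
#' @param exclude_group optional group label whose rows are dropped first
#'   (requires a `group` column).
#' @param by optional column name to split the screen by (e.g.
#'   `"frequency_hz"`); each stratum still uses the corrected level for
#'   the total number of comparisons.
#' @return tibble: measure, target (, by column), r, ci_low, ci_high,
#'   conf_level_pct, n, significant.
#' @export
correlation_screen <- function(table, pairs, conf_level_pct = 95,
                               exclude_group = NULL, by = NULL) {
  missing_cols <- setdiff(unique(c(pairs$measure, pairs$target, by)),
                          names(table))
  if (length(missing_cols)) {
    stop("columns not in table: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(exclude_group)) {
    table <- table[table$group != exclude_group, , drop = FALSE]
  }
  strata <- if (is.null(by)) list(all = table) else
    split(table, table[[by]])
  n_comp <- nrow(pairs) * length(strata)
  level <- bonferroni_conf_level(conf_level_pct, n_comp)

  out <- lapply(names(strata), function(s) {
    tab <- strata[[s]]
    rows <- lapply(seq_len(nrow(pairs)), function(i) {
      x <- tab[[pairs$measure[i]]]
      y <- tab[[pairs$target[i]]]
      res <- if (sum(is.finite(x) & is.finite(y)) < 4) {
        tibble::tibble(r = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                       conf_level_pct = level, n = sum(is.finite(x + y)),
                       significant = NA, degenerate = NA)
      } else {
        pearson_with_ci(x, y, level)
      }
      dplyr::bind_cols(
        tibble::tibble(measure = pairs$measure[i], target = pairs$target[i],
                       stratum = s),
        res
      )
    })
    dplyr::bind_rows(rows)
  })
  dplyr::bind_rows(out)
}
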