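#' DPOAE threshold from an input-output function
#'
#' The f2 level at which the emission level crosses 0 dB SPL: the lowest
#' upward crossing, linearly interpolated in dB-dB coordinates (or read out
#' at the first grid level above 0 with `method = "step"`). `NA` ("not
#' reached") if the emission never reaches 0 dB SPL.
#'
#' @param io a `dpoae_io` (see [simulate_dpoae_io()]) or any list with
#'   `l2_levels` (dB SPL, increasing) and `dp_level_db_spl`.
#' @param method `"interpolate"` (default) or `"step"`.
#' @return threshold (dB SPL) or `NA`.
#' @export
dpoae_threshold <- function(io, method = c("interpolate", "step")) {
  method <- match.arg(method)
  l2 <- io$l2_levels
  dp <- io$dp_level_db_spl
  if (length(l2) < 2) stop("need at least two I/O points", call. = FALSE)
  if (all(dp < 0)) return(NA_real_)
  if (dp[1] >= 0) return(l2[1])
  i <- which(dp[-1] >= 0 & dp[-length(dp)] < 0)[1] + 1L
  if (is.na(i)) return(NA_real_)
  if (method == "step") return(l2[i])
  l2[i - 1] + (0 - dp[i - 1]) * (l2[i] - l2[i - 1]) / (dp[i] - dp[i - 1])
}

#' Emission level at a given L2
#'
#' @param io a `dpoae_io`.
#' @param l2 probe level (dB SPL); must be one of the measured levels.
#' @return DPOAE level (dB SPL).
#' @export
dpoae_level_at <- function(io, l2) {
  i <- match(l2, io$l2_levels)
  if (is.na(i)) stop("L2 = ", l2, " dB SPL was not measured", call. = FALSE)
  io$dp_level_db_spl[i]
}

#' Summary covariates of one DPOAE input-output function
#'
#' @param io a `dpoae_io`.
#' @return tibble: ear_id, frequency_hz, dpoae_threshold (dB SPL or NA),
#'   dpoae_40, dpoae_55 (emission levels at L2 = 40 / 55 dB SPL).
#' @export
dpoae_summary <- function(io) {
  tibble::tibble(
    ear_id = io$ear_id %||% NA_character_,
    frequency_hz = io$f2_hz %||% NA_real_,
    dpoae_threshold = dpoae_threshold(io),
    dpoae_40 = dpoae_level_at(io, 40),
    dpoae_55 = dpoae_level_at(io, 55)
  )
}
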