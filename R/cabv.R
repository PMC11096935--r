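#' Cerebral arterial blood volume change over one cardiac cycle
#'
#' Computes the CaBV pulse from a CBFV pulse under the constant flow
#' forward model: venous outflow is approximated by the slow (6-s
#' windowed) mean of arterial inflow, and the insonated artery's
#' cross-section is assumed constant, so the cumulative sum of the
#' CBFV deviation from its windowed mean, times the sample interval,
#' tracks the arterial volume change in cm (velocity integrated over
#' time; the unknown cross-sectional area is divided out).
#'
#' `values[n]` is the sum of the first `n` deviation terms; the first
#' element already reflects the first deviation and is not re-zeroed
#' (min-max normalization downstream makes this immaterial to the
#' difference index).
#'
#' @param cbfv_pulse A `pulse` from [segment_pulses()] (CBFV channel).
#' @param mean_series A [time_series()] holding the windowed CBFV mean
#'   at the same sampling rate, covering the pulse's index span. Pass
#'   the `cbfv_mean` element of [preprocess_recording()]. By default
#'   the mean is evaluated per sample across the pulse; set
#'   `freeze_at_onset = TRUE` to hold it at the onset value instead.
#' @param freeze_at_onset Logical; see above.
#' @return A `cabv_pulse`: list with `values` (cm), `fs`, `onset_index`
#'   and `dt` (s).
#' @export
compute_cabv <- function(cbfv_pulse, mean_series, freeze_at_onset = FALSE) {
  stopifnot(inherits(cbfv_pulse, "pulse"),
            inherits(mean_series, "time_series"))
  if (abs(cbfv_pulse$fs - mean_series$fs) > 1e-9)
    stop("sampling rate mismatch between pulse and mean series")
  n <- length(cbfv_pulse$samples)
  i0 <- cbfv_pulse$onset_index
  idx <- i0:(i0 + n - 1L)
  if (i0 < 1L || max(idx) > length(mean_series$samples))
    stop("mean series does not cover the pulse's span")
  m <- mean_series$samples[idx]
  if (freeze_at_onset) m <- rep(m[1L], n)
  # assumption monitor: the model treats venous outflow as steady
  # within a cycle; flag pulses where the windowed mean moves a lot
  rel_var <- diff(range(m)) / max(abs(mean(m)), .Machine$double.eps)
  if (rel_var > 0.05)
    warning(sprintf(
      "windowed CBFV mean varies %.1f%% within a pulse; constant-outflow assumption is strained",
      100 * rel_var))
  dt <- 1 / cbfv_pulse$fs
  structure(
    list(values = cumsum(cbfv_pulse$samples - m) * dt,
         fs = cbfv_pulse$fs, onset_index = i0, dt = dt),
    class = "cabv_pulse"
  )
}

#' @export
print.cabv_pulse <- function(x, ...) {
  cat(sprintf("<cabv_pulse> %d samples @ %g Hz, onset %d, range %.4g..%.4g cm\n",
              length(x$values), x$fs, x$onset_index, min(x$values),
              max(x$values)))
  invisible(x)
}

#' Compute CaBV pulses for a list of ICP/CBFV pulse pairs
#'
#' Applies [compute_cabv()] to the CBFV member of every pair. Pairs
#' whose CBFV pulse cannot be converted (e.g. the mean series does not
#' cover its span) are skipped with a message rather than aborting the
#' batch; output order follows input order.
#'
#' @param pairs List of `pulse_pair` objects (QC-filtered).
#' @param mean_series Windowed CBFV mean [time_series()].
#' @param freeze_at_onset Passed to [compute_cabv()].
#' @return List of `list(icp_pulse, cabv_pulse, onset_lag)` elements.
#' @export
cabv_for_pairs <- function(pairs, mean_series, freeze_at_onset = FALSE) {
  out <- list()
  for (p in pairs) {
    cb <- tryCatch(
      suppressWarnings(compute_cabv(p$cbfv_pulse, mean_series,
                                    freeze_at_onset = freeze_at_onset)),
      error = function(e) {
        message(sprintf("skipping pair at onset %d: %s",
                        p$cbfv_pulse$onset_index, conditionMessage(e)))
        NULL
      })
    if (!is.null(cb))
      out[[length(out) + 1L]] <- list(icp_pulse = p$icp_pulse,
                                      cabv_pulse = cb,
                                      onset_lag = p$onset_lag)
  }
  out
}
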