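#' Min-max normalize a pulse to the unit interval
#'
#' Rescales a pulse (or CaBV pulse) so its minimum is exactly 0 and its
#' maximum exactly 1. Amplitude information is deliberately discarded:
#' the difference index compares shapes, not magnitudes.
#'
#' @param pulse A `pulse` or `cabv_pulse`.
#' @return A `normalized_pulse`: list with `values` in `[0, 1]`, `fs`,
#'   `onset_index`, `channel`.
#' @export
normalize_pulse <- function(pulse) {
  x <- if (inherits(pulse, "cabv_pulse")) pulse$values else pulse$samples
  if (length(x) == 0L) stop("empty pulse")
  rng <- range(x)
  if (diff(rng) <= 0)
    stop("degenerate (flat) pulse cannot be normalized")
  structure(
    list(values = (x - rng[1]) / (rng[2] - rng[1]),
         fs = pulse$fs, onset_index = pulse$onset_index,
         channel = if (inherits(pulse, "cabv_pulse")) "cabv" else pulse$channel),
    class = "normalized_pulse"
  )
}

#' Synchronize two normalized pulses at their onsets
#'
#' Both pulses are anchored so index 1 is the onset (the minimum at the
#' start of the ascending slope). Pulses arriving from
#' [segment_pulses()] already satisfy this; no resampling or rotation
#' is performed. A pulse whose global minimum falls beyond the first
#' quarter of the cycle is passed through with a warning so the
#' upstream segmentation can be audited; an early-phase minimum is
#' expected (a CaBV pulse normally dips to its minimum a few samples
#' after the onset, while arterial inflow still runs below its slow
#' mean). Lengths may differ.
#'
#' @param icp_norm,cabv_norm `normalized_pulse` objects.
#' @return List with elements `icp` and `cabv`, onset-aligned.
#' @export
synchronize <- function(icp_norm, cabv_norm) {
  for (p in list(icp_norm, cabv_norm)) {
    if (!inherits(p, "normalized_pulse")) stop("inputs must be normalized pulses")
    if (length(p$values) == 0L) stop("empty pulse")
    if (which.min(p$values) > length(p$values) / 4)
      warning(sprintf(
        "%s pulse minimum at sample %d of %d, far from its onset; not re-anchored",
        p$channel, which.min(p$values), length(p$values)))
  }
  list(icp = icp_norm, cabv = cabv_norm)
}

#' Difference index between an ICP and a CaBV pulse
#'
#' The DI is the sum of absolute sample-wise differences between the
#' normalized, onset-synchronized ICP and CaBV waveforms, taken from
#' the onset to the end of the CaBV pulse: the discrete area between
#' the two unit-amplitude contours. Lower DI means more similar
#' shapes. When the ICP pulse is shorter than the CaBV pulse its last
#' sample is held (`tail = "hold"`, default) or the comparison stops at
#' the shorter pulse (`tail = "truncate"`).
#'
#' @param icp_norm,cabv_norm `normalized_pulse` objects (onset-aligned).
#' @param tail Either `"hold"` or `"truncate"`; see Description.
#' @return List of class `di_record`: `di`, `n_compared`, plus slots
#'   `wave_id`, `period_label`, `onset_time` filled by [score_pairs()].
#' @export
difference_index <- function(icp_norm, cabv_norm,
                             tail = c("hold", "truncate")) {
  tail <- match.arg(tail)
  stopifnot(inherits(icp_norm, "normalized_pulse"),
            inherits(cabv_norm, "normalized_pulse"))
  icp <- icp_norm$values
  cabv <- cabv_norm$values
  if (length(icp) == 0L || length(cabv) == 0L) stop("empty pulse")
  m <- length(cabv)
  if (tail == "truncate") m <- min(m, length(icp))
  icp_ext <- if (length(icp) >= m) icp[seq_len(m)]
             else c(icp, rep(icp[length(icp)], m - length(icp)))
  structure(
    list(di = sum(abs(icp_ext - cabv[seq_len(m)])), n_compared = m,
         wave_id = NA_integer_, period_label = NA_character_,
         onset_time = (icp_norm$onset_index - 1) / icp_norm$fs),
    class = "di_record"
  )
}

#' Score labeled ICP/CaBV pairs with the difference index
#'
#' Normalizes, synchronizes and scores every pair that carries a period
#' label; unlabeled pairs (outside the baseline and plateau analysis
#' periods) are skipped. Pairs whose pulses are degenerate (flat) are
#' skipped with a message (QC normally removes these earlier).
#'
#' @param labeled_pairs List of elements
#'   `list(icp_pulse, cabv_pulse, period_label, ...)` as produced by
#'   [label_pulses()] after [cabv_for_pairs()].
#' @param wave_id Integer identifier of the source wave/recording.
#' @param tail Passed to [difference_index()].
#' @return Data frame with one row per scored pair: `wave_id`,
#'   `period_label`, `onset_time`, `di`, `n_compared`.
#' @export
score_pairs <- function(labeled_pairs, wave_id = 1L,
                        tail = c("hold", "truncate")) {
  tail <- match.arg(tail)
  rows <- list()
  n_anchor_warn <- 0L
  for (p in labeled_pairs) {
    if (is.na(p$period_label)) next
    rec <- tryCatch({
      icp_n <- normalize_pulse(p$icp_pulse)
      cabv_n <- normalize_pulse(p$cabv_pulse)
      syn <- withCallingHandlers(
        synchronize(icp_n, cabv_n),
        warning = function(w) {
          n_anchor_warn <<- n_anchor_warn + 1L
          invokeRestart("muffleWarning")
        })
      difference_index(syn$icp, syn$cabv, tail = tail)
    }, error = function(e) {
      message(sprintf("skipping pair at onset %d: %s",
                      p$icp_pulse$onset_index, conditionMessage(e)))
      NULL
    })
    if (is.null(rec)) next
    rows[[length(rows) + 1L]] <- data.frame(
      wave_id = wave_id, period_label = p$period_label,
      onset_time = rec$onset_time, di = rec$di,
      n_compared = rec$n_compared)
  }
  if (n_anchor_warn > 0L)
    message(sprintf(
      "%d pulse(s) had their minimum away from the onset (trend slope within the beat); kept onset-anchored",
      n_anchor_warn))
  if (length(rows) == 0L)
    return(data.frame(wave_id = integer(0), period_label = character(0),
                      onset_time = numeric(0), di = numeric(0),
                      n_compared = integer(0)))
  do.call(rbind, rows)
}
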