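#' Detect pulse onsets by multiscale local-minima analysis
#'
#' Deterministic multiscale minima detector in the spirit of automatic
#' multiscale peak detection, run on trough polarity. Within each
#' analysis window, for every scale `k = 1..K` (`K` spanning
#' `max_scale_s` seconds) a sample `i` is marked when
#' `x[i] < x[i - k]` and `x[i] < x[i + k]`. The scale with the greatest
#' number of marks, `gamma`, reflects the dominant beat half-period; a
#' sample is an onset candidate when it is marked at every scale
#' `1..gamma`. Windows overlap by 50\%; candidates from overlapping
#' windows are merged when within one sample of each other, and
#' candidates closer than a physiological refractory separation are
#' reduced to the lowest-valued sample. No randomness is involved.
#'
#' @param ts A filtered, upsampled [time_series()] (pulsatile channel).
#' @param window_s Analysis window length, s; should be at least twice
#'   the longest expected beat.
#' @param max_scale_s Largest analysis scale, s; about one expected
#'   beat length.
#' @param min_separation_s Refractory separation between onsets, s. The
#'   default tolerates heart rates up to 150 bpm; candidates closer
#'   than this (inter-peak notch dips next to a true trough) collapse
#'   onto the deeper sample.
#' @return Integer vector of strictly increasing onset sample indices.
#' @export
detect_onsets <- function(ts, window_s = 10, max_scale_s = 1.0,
                          min_separation_s = 0.4) {
  stopifnot(inherits(ts, "time_series"))
  x <- ts$samples
  n <- length(x)
  fs <- ts$fs
  L <- as.integer(round(window_s * fs))
  if (n < L) stop("series shorter than one analysis window")
  K <- max(as.integer(round(max_scale_s * fs)), 2L)
  K <- min(K, (L - 1L) %/% 2L)
  step <- max(L %/% 2L, 1L)
  starts <- seq(1L, max(n - L + 1L, 1L), by = step)
  if (starts[length(starts)] != n - L + 1L) starts <- c(starts, n - L + 1L)

  all_onsets <- integer(0)
  for (s0 in starts) {
    xs <- x[s0:(s0 + L - 1L)]
    counts <- integer(K)
    for (k in seq_len(K)) {
      idx <- (k + 1L):(L - k)
      counts[k] <- sum(xs[idx] < xs[idx - k] & xs[idx] < xs[idx + k])
    }
    gam <- which.max(counts)  # first maximum on ties
    if (counts[gam] == 0L) next
    # candidates survive marking at every scale 1..gamma; start from
    # scale-1 strict minima and filter upward (cheap: the set shrinks)
    cand <- which(xs[2:(L - 1L)] < xs[1:(L - 2L)] &
                    xs[2:(L - 1L)] < xs[3:L]) + 1L
    for (k in seq_len(gam)[-1]) {
      if (length(cand) == 0L) break
      cand <- cand[cand > k & cand <= L - k]
      cand <- cand[xs[cand] < xs[cand - k] & xs[cand] < xs[cand + k]]
    }
    all_onsets <- c(all_onsets, s0 - 1L + cand)
  }
  if (length(all_onsets) == 0L) return(integer(0))
  all_onsets <- sort(unique(all_onsets))

  # merge duplicates from overlapping windows (within 1 sample), then
  # enforce the refractory separation keeping the deepest trough
  merged <- merge_close(all_onsets, x, tol = 1L)
  merge_close(merged, x, tol = as.integer(round(min_separation_s * fs)))
}

# Collapse clusters of indices closer than `tol` samples to the index
# with the smallest signal value.
merge_close <- function(idx, x, tol) {
  if (length(idx) <= 1L) return(idx)
  out <- integer(0)
  cur <- idx[1]
  for (i in idx[-1]) {
    if (i - cur <= tol) {
      if (x[i] < x[cur]) cur <- i
    } else {
      out <- c(out, cur)
      cur <- i
    }
  }
  c(out, cur)
}

#' Segment a channel into single-cycle pulses
#'
#' Pulse `i` spans `[onset_i, onset_{i+1})`; the final onset starts no
#' pulse. Each pulse keeps its provenance index into the source series.
#'
#' @param ts A [time_series()].
#' @param onsets Integer vector of onset sample indices (sorted).
#' @param channel Channel name stored on each pulse.
#' @return List of `pulse` objects (`samples`, `fs`, `onset_index`,
#'   `duration`, `channel`); empty when fewer than 2 onsets.
#' @export
segment_pulses <- function(ts, onsets, channel = ts$label) {
  stopifnot(inherits(ts, "time_series"))
  if (length(onsets) < 2L) return(list())
  out <- vector("list", length(onsets) - 1L)
  for (i in seq_len(length(onsets) - 1L)) {
    i0 <- onsets[i]
    i1 <- onsets[i + 1L] - 1L
    out[[i]] <- structure(
      list(samples = ts$samples[i0:i1], fs = ts$fs, onset_index = i0,
           duration = (i1 - i0 + 1L) / ts$fs, channel = channel),
      class = "pulse"
    )
  }
  out
}

#' @export
print.pulse <- function(x, ...) {
  cat(sprintf("<pulse> %s: %d samples @ %g Hz, onset %d (%.2f s)\n",
              x$channel, length(x$samples), x$fs, x$onset_index,
              (x$onset_index - 1) / x$fs))
  invisible(x)
}

#' Pulse quality-control configuration
#'
#' Automated surrogate for visual pulse review: explicit rules with
#' machine-readable reason codes. A pulse is rejected when its duration
#' falls outside physiological beat bounds, any sample leaves the
#' channel's plausible range, any sample is non-finite, its
#' peak-to-trough amplitude is below a floor, or it carries more strict
#' local extrema than a clean beat can.
#'
#' @param min_duration,max_duration Beat duration bounds, s.
#' @param value_range Named list of per-channel plausible sample ranges.
#'   CBFV's lower bound is above zero: velocity dropping to zero in the
#'   insonated artery is a signal-loss artifact, not physiology.
#' @param min_pulse_amplitude Named list of per-channel peak-to-trough
#'   amplitude floors.
#' @param max_local_extrema Maximum count of prominent local extrema.
#' @param extrema_prominence Minimum swing, as a fraction of the
#'   pulse's peak-to-trough amplitude, for a direction reversal to
#'   count as an extremum; sub-threshold noise wiggles are ignored.
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(min_duration = 0.3, max_duration = 2.0,
                      value_range = list(icp = c(-10, 120),
                                         cbfv = c(1, 250),
                                         abp = c(20, 250)),
                      min_pulse_amplitude = list(icp = 1, cbfv = 5,
                                                 abp = 10),
                      max_local_extrema = 8L,
                      extrema_prominence = 0.05) {
  if (min_duration >= max_duration)
    stop("`min_duration` must be below `max_duration`")
  for (rg in value_range)
    if (rg[1] >= rg[2]) stop("value ranges must satisfy min < max")
  structure(list(min_duration = min_duration, max_duration = max_duration,
                 value_range = value_range,
                 min_pulse_amplitude = min_pulse_amplitude,
                 max_local_extrema = as.integer(max_local_extrema),
                 extrema_prominence = extrema_prominence),
            class = "qc_config")
}

# Direction reversals whose swing is at least `prom` (absolute units);
# with prom = 0 this equals the count of strict local extrema.
count_local_extrema <- function(x, prom = 0) {
  n <- length(x)
  if (n < 3L) return(0L)
  if (prom <= 0) {
    mid <- x[2:(n - 1L)]
    return(sum(mid > x[1:(n - 2L)] & mid > x[3:n]) +
             sum(mid < x[1:(n - 2L)] & mid < x[3:n]))
  }
  count <- 0L
  dir <- 0L
  hi <- x[1L]; lo <- x[1L]
  for (v in x[-1L]) {
    if (v > hi) hi <- v
    if (v < lo) lo <- v
    if (dir >= 0L && hi - v >= prom) {       # downturn after a high
      if (dir != 0L) count <- count + 1L
      dir <- -1L; lo <- v
    } else if (dir <= 0L && v - lo >= prom) {  # upturn after a low
      if (dir != 0L) count <- count + 1L
      dir <- 1L; hi <- v
    }
  }
  count
}

#' Quality-check a single pulse
#'
#' Applies the [qc_config()] rules in a fixed order and reports the
#' first violated rule. Rejection is a result, not an error.
#'
#' @param pulse A `pulse` from [segment_pulses()].
#' @param qc A [qc_config()].
#' @return List with `accept` (logical) and `reason` (`NA` when
#'   accepted; otherwise one of `"duration"`, `"nonfinite"`, `"range"`,
#'   `"amplitude"`, `"extrema"`).
#' @export
qc_pulse <- function(pulse, qc = qc_config()) {
  stopifnot(inherits(pulse, "pulse"))
  x <- pulse$samples
  if (pulse$duration < qc$min_duration || pulse$duration > qc$max_duration)
    return(list(accept = FALSE, reason = "duration"))
  if (any(!is.finite(x)))
    return(list(accept = FALSE, reason = "nonfinite"))
  rg <- qc$value_range[[pulse$channel]]
  if (!is.null(rg) && (any(x < rg[1]) || any(x > rg[2])))
    return(list(accept = FALSE, reason = "range"))
  amp_min <- qc$min_pulse_amplitude[[pulse$channel]]
  if (!is.null(amp_min) && diff(range(x)) < amp_min)
    return(list(accept = FALSE, reason = "amplitude"))
  prom <- qc$extrema_prominence * diff(range(x))
  if (count_local_extrema(x, prom) > qc$max_local_extrema)
    return(list(accept = FALSE, reason = "extrema"))
  list(accept = TRUE, reason = NA_character_)
}

#' Quality-check a list of pulses
#'
#' @param pulses List of `pulse` objects.
#' @param qc A [qc_config()].
#' @return Data frame with one row per pulse: `onset_index`,
#'   `duration`, `accept`, `reason`.
#' @export
qc_pulses <- function(pulses, qc = qc_config()) {
  res <- lapply(pulses, qc_pulse, qc = qc)
  data.frame(
    onset_index = vapply(pulses, function(p) p$onset_index, numeric(1)),
    duration = vapply(pulses, function(p) p$duration, numeric(1)),
    accept = vapply(res, function(r) r$accept, logical(1)),
    reason = vapply(res, function(r) r$reason, character(1))
  )
}

#' Pair ICP and CBFV pulses per cardiac cycle
#'
#' Greedy nearest-onset matching: candidate pairs within
#' `tolerance_s` of each other are accepted in order of increasing
#' onset lag, each pulse used at most once. The procedure is symmetric
#' in its two arguments. QC filtering is expected to have happened
#' upstream (pass only accepted pulses).
#'
#' @param icp_pulses,cbfv_pulses Onset-sorted lists of `pulse` objects.
#' @param tolerance_s Maximum |onset lag| for a pair, s.
#' @return List of `pulse_pair` objects (`icp_pulse`, `cbfv_pulse`,
#'   `onset_lag` in seconds, ICP minus CBFV).
#' @export
pair_pulses <- function(icp_pulses, cbfv_pulses, tolerance_s = 0.25) {
  if (length(icp_pulses) == 0L || length(cbfv_pulses) == 0L) return(list())
  t_icp <- vapply(icp_pulses, function(p) (p$onset_index - 1) / p$fs,
                  numeric(1))
  t_cbfv <- vapply(cbfv_pulses, function(p) (p$onset_index - 1) / p$fs,
                   numeric(1))
  cand <- list()
  for (i in seq_along(t_icp)) {
    js <- which(abs(t_cbfv - t_icp[i]) <= tolerance_s)
    for (j in js)
      cand[[length(cand) + 1L]] <- c(i, j, abs(t_cbfv[j] - t_icp[i]))
  }
  if (length(cand) == 0L) return(list())
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand[, 3], cand[, 1], cand[, 2]), , drop = FALSE]
  used_i <- logical(length(t_icp))
  used_j <- logical(length(t_cbfv))
  pairs <- list()
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    if (used_i[i] || used_j[j]) next
    used_i[i] <- TRUE; used_j[j] <- TRUE
    pairs[[length(pairs) + 1L]] <- structure(
      list(icp_pulse = icp_pulses[[i]], cbfv_pulse = cbfv_pulses[[j]],
           onset_lag = t_icp[i] - t_cbfv[j]),
      class = "pulse_pair"
    )
  }
  ord <- order(vapply(pairs, function(p) p$icp_pulse$onset_index,
                      numeric(1)))
  pairs[ord]
}
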