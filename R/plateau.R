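#' Slow trend signals of a recording
#'
#' Moving means of each channel over a trend window, plus cerebral
#' perfusion pressure (CPP = mean ABP - mean ICP), always recomputed
#' from the smoothed channels.
#'
#' @param rec A [recording()].
#' @param trend_window Moving-mean window, s (default 10).
#' @return A list of class `trend_series` with [time_series()] elements
#'   `mean_icp`, `mean_abp`, `mean_cbfv`, `cpp`.
#' @export
compute_trends <- function(rec, trend_window = 10) {
  stopifnot(inherits(rec, "recording"))
  if (rec_duration(rec) < trend_window)
    stop("recording shorter than the trend window")
  mi <- moving_mean(rec$icp, trend_window)
  ma <- moving_mean(rec$abp, trend_window)
  mc <- moving_mean(rec$cbfv, trend_window)
  cpp <- time_series(ma$samples - mi$samples, mi$fs, "mmHg", "cpp")
  structure(list(mean_icp = mi, mean_abp = ma, mean_cbfv = mc, cpp = cpp),
            class = "trend_series")
}

# Maximal index runs where `cond` holds, merging runs separated by
# gaps of at most `gap` samples. Returns a 2-column matrix [start, end].
runs_where <- function(cond, gap = 0L) {
  r <- rle(cond)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  if (length(keep) == 0L) return(matrix(integer(0), ncol = 2))
  m <- cbind(starts[keep], ends[keep])
  if (gap > 0L && nrow(m) > 1L) {
    merged <- list(m[1, ])
    for (i in 2:nrow(m)) {
      last <- merged[[length(merged)]]
      if (m[i, 1] - last[2] - 1L <= gap) {
        merged[[length(merged)]] <- c(last[1], m[i, 2])
      } else merged[[length(merged) + 1L]] <- m[i, ]
    }
    m <- do.call(rbind, merged)
  }
  m
}

#' Detect ICP plateau waves on trend signals
#'
#' A candidate wave is a maximal interval where mean ICP exceeds a
#' pre-wave reference level by at least `rise_mmhg`; short sub-threshold
#' dips (transient artifacts) of up to `gap_s` seconds are tolerated
#' inside a candidate. A candidate is accepted when (a) its peak mean
#' ICP exceeds `peak_mmhg`, (b) CPP within it falls at least
#' `cpp_drop_mmhg` below the pre-wave CPP reference, and (c) the
#' above-reference condition persists at least `min_duration_s`.
#'
#' The pre-wave reference is the median of mean ICP over the
#' `ref_window_s` seconds immediately preceding the candidate's rise
#' onset, where the rise onset is the last upward crossing of
#' (reference + 5 mmHg) before the peak; the reference is iterated once
#' so it settles on the pre-rise segment. The median resists transient
#' dips and spikes.
#'
#' @param trends A `trend_series` from [compute_trends()].
#' @param peak_mmhg Absolute mean-ICP threshold the peak must exceed
#'   (mmHg).
#' @param rise_mmhg Minimum rise of mean ICP above the pre-wave
#'   reference (mmHg).
#' @param cpp_drop_mmhg Minimum CPP drop below the pre-wave CPP
#'   reference (mmHg).
#' @param min_duration_s Minimum duration of the sustained rise (s).
#' @param ref_window_s Length of the pre-wave reference window (s).
#' @param gap_s Sub-threshold gap tolerance inside a wave (s).
#' @return List of `plateau_wave` objects: `wave_interval` (s),
#'   `peak_icp`, `baseline_icp` (reference level), `cpp_ref`, with
#'   `baseline_interval` and `plateau_interval` left for
#'   [select_periods()]. Empty list when nothing qualifies.
#' @export
detect_plateau_waves <- function(trends, peak_mmhg = 40, rise_mmhg = 15,
                                 cpp_drop_mmhg = 10, min_duration_s = 180,
                                 ref_window_s = 240, gap_s = 10) {
  stopifnot(inherits(trends, "trend_series"))
  icp <- trends$mean_icp$samples
  cpp <- trends$cpp$samples
  fs <- trends$mean_icp$fs
  n <- length(icp)
  gap <- as.integer(round(gap_s * fs))

  seeds <- runs_where(icp > peak_mmhg, gap = gap)
  if (nrow(seeds) == 0L) return(list())

  waves <- list()
  for (s in seq_len(nrow(seeds))) {
    peak_idx <- seeds[s, 1] - 1L + which.max(icp[seeds[s, 1]:seeds[s, 2]])
    # reference level, iterated once: seed window before the exceedance,
    # then re-anchored before the rise onset
    ref <- ref_level(icp, seeds[s, 1], ref_window_s, fs)
    for (it in 1:2) {
      rise_idx <- rise_onset(icp, peak_idx, ref + 5)
      ref <- ref_level(icp, rise_idx, ref_window_s, fs)
    }
    cpp_ref <- ref_level(cpp, rise_idx, ref_window_s, fs)

    above <- runs_where(icp >= ref + rise_mmhg, gap = gap)
    hit <- which(above[, 1] <= peak_idx & above[, 2] >= peak_idx)
    if (length(hit) == 0L) next
    w0 <- above[hit[1], 1]; w1 <- above[hit[1], 2]
    dur <- (w1 - w0 + 1L) / fs
    if (dur < min_duration_s) next
    if (icp[peak_idx] <= peak_mmhg) next
    if (min(cpp[w0:w1]) > cpp_ref - cpp_drop_mmhg) next
    waves[[length(waves) + 1L]] <- structure(
      list(wave_interval = c((w0 - 1) / fs, (w1 - 1) / fs),
           baseline_interval = c(NA_real_, NA_real_),
           plateau_interval = c(NA_real_, NA_real_),
           peak_icp = icp[peak_idx], baseline_icp = ref,
           cpp_ref = cpp_ref, fs = fs),
      class = "plateau_wave"
    )
  }
  if (length(waves) <= 1L) return(waves)
  # de-duplicate seeds that resolved to the same wave; keep time order
  ivs <- t(vapply(waves, function(w) w$wave_interval, numeric(2)))
  keep <- !duplicated(round(ivs[, 1], 3))
  waves <- waves[keep]
  waves[order(vapply(waves, function(w) w$wave_interval[1], numeric(1)))]
}

# Median over the `win_s` seconds ending just before index `idx`
# (truncated at the series start).
ref_level <- function(x, idx, win_s, fs) {
  lo <- max(1L, idx - as.integer(round(win_s * fs)))
  hi <- max(1L, idx - 1L)
  stats::median(x[lo:hi])
}

# Last upward crossing of `level` before `peak_idx`.
rise_onset <- function(x, peak_idx, level) {
  below <- which(x[seq_len(peak_idx)] < level)
  if (length(below) == 0L) return(1L)
  min(below[length(below)] + 1L, peak_idx)
}

#' @export
print.plateau_wave <- function(x, ...) {
  cat(sprintf("<plateau_wave> %.0f-%.0f s, peak ICP %.1f mmHg (baseline %.1f)\n",
              x$wave_interval[1], x$wave_interval[2], x$peak_icp,
              x$baseline_icp))
  if (!is.na(x$plateau_interval[1]))
    cat(sprintf("  baseline %.0f-%.0f s, plateau %.0f-%.0f s\n",
                x$baseline_interval[1], x$baseline_interval[2],
                x$plateau_interval[1], x$plateau_interval[2]))
  invisible(x)
}

#' Select baseline and plateau analysis periods for a detected wave
#'
#' The baseline period is the `baseline_length` seconds immediately
#' preceding the wave start (shortened with a warning when the
#' recording starts later; the wave is rejected when less than
#' `baseline_floor` seconds remain). The plateau period is the maximal
#' contiguous interval within the wave where mean ICP is at least 90\%
#' of the wave's maximum mean ICP, with the same artifact gap
#' tolerance used during detection.
#'
#' @param wave A `plateau_wave` from [detect_plateau_waves()].
#' @param trends The `trend_series` the wave was detected on.
#' @param baseline_length Nominal baseline period length, s.
#' @param baseline_floor Minimum acceptable baseline length, s.
#' @param plateau_fraction Fraction of the wave's ICP maximum defining
#'   the plateau (default 0.9).
#' @param gap_s Sub-threshold gap tolerance, s.
#' @return The wave with `baseline_interval` and `plateau_interval`
#'   filled, or `NULL` when the wave is excluded for want of pre-wave
#'   signal.
#' @export
select_periods <- function(wave, trends, baseline_length = 240,
                           baseline_floor = 60, plateau_fraction = 0.9,
                           gap_s = 10) {
  stopifnot(inherits(wave, "plateau_wave"), inherits(trends, "trend_series"))
  fs <- trends$mean_icp$fs
  icp <- trends$mean_icp$samples
  t0 <- wave$wave_interval[1]
  bl_start <- t0 - baseline_length
  if (bl_start < 0) {
    if (t0 < baseline_floor) {
      warning(sprintf(
        "wave at %.0f s excluded: only %.0f s of pre-wave signal (< %.0f s floor)",
        t0, t0, baseline_floor))
      return(NULL)
    }
    warning(sprintf("baseline shortened to %.0f s (recording starts late)", t0))
    bl_start <- 0
  }
  wave$baseline_interval <- c(bl_start, t0)

  i0 <- as.integer(round(wave$wave_interval[1] * fs)) + 1L
  i1 <- min(as.integer(round(wave$wave_interval[2] * fs)) + 1L, length(icp))
  seg <- icp[i0:i1]
  thr <- plateau_fraction * max(seg)
  runs <- runs_where(seg >= thr, gap = as.integer(round(gap_s * fs)))
  best <- runs[which.max(runs[, 2] - runs[, 1]), , drop = FALSE]
  wave$plateau_interval <- c((i0 + best[1, 1] - 2) / fs,
                             (i0 + best[1, 2] - 2) / fs)
  wave
}

#' Label pulse pairs by analysis period
#'
#' Attaches `period_label` (`"baseline"`, `"plateau"` or `NA`) to each
#' pair according to where its ICP onset time falls relative to the
#' wave's selected periods. Pulses during the rise or fall phases stay
#' unlabeled and are excluded from scoring.
#'
#' @param pairs List of pairs (with `icp_pulse` elements).
#' @param wave A `plateau_wave` with periods selected.
#' @return The pairs, each with a `period_label` element added.
#' @export
label_pulses <- function(pairs, wave) {
  stopifnot(inherits(wave, "plateau_wave"))
  if (is.na(wave$baseline_interval[1]) || is.na(wave$plateau_interval[1]))
    stop("wave periods not selected; call select_periods() first")
  lapply(pairs, function(p) {
    t_on <- (p$icp_pulse$onset_index - 1) / p$icp_pulse$fs
    p$period_label <-
      if (t_on >= wave$baseline_interval[1] && t_on < wave$baseline_interval[2])
        "baseline"
      else if (t_on >= wave$plateau_interval[1] && t_on <= wave$plateau_interval[2])
        "plateau"
      else NA_character_
    p
  })
}
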