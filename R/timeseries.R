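#' Uniformly sampled time series
#'
#' Lightweight container for a single channel of a neuromonitoring
#' recording: a numeric sample vector with a sampling frequency, a unit
#' string and a label. Time is implicit (sample `i` sits at
#' `(i - 1) / fs` seconds).
#'
#' @param samples Numeric vector of samples (channel units).
#' @param fs Sampling frequency in Hz (> 0).
#' @param unit Unit string, e.g. `"mmHg"` or `"cm/s"`.
#' @param label Channel label, e.g. `"icp"`.
#'
#' @return An object of class `time_series`.
#' @export
time_series <- function(samples, fs, unit = "", label = "") {
  if (!is.numeric(samples)) stop("`samples` must be numeric")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number")
  structure(
    list(samples = as.numeric(samples), fs = as.numeric(fs),
         unit = unit, label = label),
    class = "time_series"
  )
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf("<time_series> %s [%s], %d samples @ %g Hz (%.1f s)\n",
              x$label, x$unit, length(x$samples), x$fs,
              length(x$samples) / x$fs))
  invisible(x)
}

#' @export
length.time_series <- function(x) length(x$samples)

#' Time stamps of a time series
#'
#' @param ts A [time_series()].
#' @return Numeric vector of sample times in seconds, starting at 0.
#' @export
ts_times <- function(ts) {
  stopifnot(inherits(ts, "time_series"))
  (seq_along(ts$samples) - 1) / ts$fs
}

#' Three-channel neuromonitoring recording
#'
#' Bundles synchronized ICP, ABP and CBFV channels sharing one sampling
#' rate and sample count.
#'
#' @param icp,abp,cbfv [time_series()] objects for intracranial pressure
#'   (mmHg), arterial blood pressure (mmHg) and cerebral blood flow
#'   velocity (cm/s).
#' @param start_time Recording start time offset in seconds (default 0).
#'
#' @return An object of class `recording`.
#' @export
recording <- function(icp, abp, cbfv, start_time = 0) {
  chans <- list(icp = icp, abp = abp, cbfv = cbfv)
  for (nm in names(chans)) {
    if (!inherits(chans[[nm]], "time_series"))
      stop(sprintf("channel `%s` must be a time_series", nm))
  }
  fs <- vapply(chans, function(ch) ch$fs, numeric(1))
  if (length(unique(fs)) != 1L)
    stop("all channels must share the same sampling frequency")
  n <- vapply(chans, function(ch) length(ch$samples), numeric(1))
  if (length(unique(n)) != 1L)
    stop("all channels must share the same sample count")
  structure(
    list(icp = icp, abp = abp, cbfv = cbfv, start_time = start_time),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d samples @ %g Hz (%.1f s)\n",
              length(x$icp$samples), x$icp$fs,
              length(x$icp$samples) / x$icp$fs))
  for (nm in c("icp", "abp", "cbfv")) {
    ch <- x[[nm]]
    cat(sprintf("  %-5s [%s]  range %.1f..%.1f\n", nm, ch$unit,
                min(ch$samples), max(ch$samples)))
  }
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec A [recording()].
#' @return Duration in seconds.
#' @export
rec_duration <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  length(rec$icp$samples) / rec$icp$fs
}
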