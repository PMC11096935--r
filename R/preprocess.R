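#' Preprocessing configuration
#'
#' Defaults follow the pipeline's signal-conditioning chain: linear
#' upsampling to 200 Hz, zero-phase low-pass filtering at 12 Hz, a 6-s
#' moving mean for the venous-outflow proxy and a 10-s moving mean for
#' slow trend signals.
#'
#' @param target_fs Target sampling rate for upsampling, Hz.
#' @param lowpass_cutoff Low-pass cutoff frequency, Hz.
#' @param mean_window Moving-mean window for the CBFV mean (venous
#'   outflow proxy), seconds.
#' @param trend_window Moving-mean window for slow trend signals,
#'   seconds.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(target_fs = 200, lowpass_cutoff = 12,
                              mean_window = 6, trend_window = 10) {
  stopifnot(target_fs > 0, lowpass_cutoff > 0, mean_window > 0,
            trend_window > 0)
  if (lowpass_cutoff >= target_fs / 2)
    stop("`lowpass_cutoff` must be below the target Nyquist frequency")
  structure(list(target_fs = target_fs, lowpass_cutoff = lowpass_cutoff,
                 mean_window = mean_window, trend_window = trend_window),
            class = "preprocess_config")
}

#' Upsample a time series by linear interpolation
#'
#' Raises the sampling rate of a channel by linear interpolation between
#' the original sample instants. For an integer rate ratio the original
#' samples are reproduced exactly and the output has
#' `(N - 1) * ratio + 1` samples.
#'
#' @param ts A [time_series()].
#' @param target_fs Target sampling frequency, Hz; must be >= `ts$fs`.
#' @return A [time_series()] at `target_fs`.
#' @export
upsample_linear <- function(ts, target_fs) {
  stopifnot(inherits(ts, "time_series"))
  if (target_fs < ts$fs)
    stop("`target_fs` below source rate: upsampling only, no implicit decimation")
  if (target_fs == ts$fs) return(ts)
  n <- length(ts$samples)
  if (n < 2L) stop("need at least 2 samples to interpolate")
  t_end <- (n - 1) / ts$fs
  ratio <- target_fs / ts$fs
  if (abs(ratio - round(ratio)) < 1e-9) {
    m <- (n - 1L) * as.integer(round(ratio)) + 1L
  } else {
    m <- floor(t_end * target_fs) + 1L
  }
  t_new <- (seq_len(m) - 1) / target_fs
  y <- stats::approx(x = (seq_len(n) - 1) / ts$fs, y = ts$samples,
                     xout = t_new, method = "linear", rule = 2)$y
  time_series(y, target_fs, unit = ts$unit, label = ts$label)
}

# Odd (antisymmetric) reflection padding used to suppress IIR edge
# transients; linear in x, so filtering stays a linear operator.
reflect_pad <- function(x, p) {
  n <- length(x)
  p <- min(p, n - 1L)
  left <- 2 * x[1L] - x[(p + 1L):2L]
  right <- 2 * x[n] - x[(n - 1L):(n - p)]
  list(x = c(left, x, right), p = p)
}

#' Zero-phase low-pass filter
#'
#' Applies a Butterworth low-pass filter forward and backward
#' (zero-phase, so pulse-onset timing is not skewed). The design cutoff
#' is widened so that the -3 dB point of the combined forward-backward
#' response lands at `cutoff`. Edge transients are suppressed by odd
#' reflection padding long enough for the filter state to settle.
#'
#' @param ts A [time_series()].
#' @param cutoff Cutoff frequency in Hz (must be below Nyquist).
#' @param order Butterworth order of a single pass (default 4).
#' @return A filtered [time_series()] of identical length and rate.
#' @export
lowpass <- function(ts, cutoff, order = 4) {
  stopifnot(inherits(ts, "time_series"))
  if (cutoff <= 0 || cutoff >= ts$fs / 2)
    stop("`cutoff` must lie in (0, fs/2)")
  # |H|^2 of one pass = 1/(1 + (f/fc)^(2n)); after two passes the -3 dB
  # point solves (f/fc)^(2n) = sqrt(2) - 1.
  fc <- cutoff / (sqrt(2) - 1)^(1 / (2 * order))
  fc <- min(fc, 0.99 * ts$fs / 2)
  bf <- signal::butter(order, 2 * fc / ts$fs, type = "low")
  pad <- max(3L * (length(bf$b) + length(bf$a)),
             as.integer(round(9 * ts$fs / cutoff)))
  pp <- reflect_pad(ts$samples, pad)
  y <- signal::filtfilt(bf, pp$x)
  y <- y[(pp$p + 1L):(pp$p + length(ts$samples))]
  time_series(y, ts$fs, unit = ts$unit, label = ts$label)
}

#' Centered moving mean with truncated edges
#'
#' Each output sample is the arithmetic mean of the input over a window
#' centered on that sample. Windows are truncated (not padded) at the
#' series edges, so no data is invented. The window is rounded to an odd
#' sample count so centering is exact.
#'
#' @param ts A [time_series()].
#' @param window Window length in seconds (>= 2 samples, <= series).
#' @return A [time_series()] of identical length and rate.
#' @export
moving_mean <- function(ts, window) {
  stopifnot(inherits(ts, "time_series"))
  n <- length(ts$samples)
  w <- as.integer(round(window * ts$fs))
  if (w < 2L) stop("`window` must span at least 2 samples")
  if (w > n) stop("`window` longer than the series")
  h <- w %/% 2L
  x <- ts$samples
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  y <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  time_series(y, ts$fs, unit = ts$unit, label = ts$label)
}

#' Upsample and low-pass filter the pulsatile channels of a recording
#'
#' Convenience wrapper running the conditioning chain used before pulse
#' onset detection on the ICP and CBFV channels (ABP is only used for
#' slow trends and is left at the acquisition rate).
#'
#' @param rec A [recording()].
#' @param config A [preprocess_config()].
#' @return List with elements `icp`, `cbfv` (filtered 200-Hz
#'   [time_series()]) and `cbfv_mean` (moving mean of the filtered CBFV
#'   over `mean_window` seconds).
#' @export
preprocess_recording <- function(rec, config = preprocess_config()) {
  stopifnot(inherits(rec, "recording"))
  icp <- lowpass(upsample_linear(rec$icp, config$target_fs),
                 config$lowpass_cutoff)
  cbfv <- lowpass(upsample_linear(rec$cbfv, config$target_fs),
                  config$lowpass_cutoff)
  cbfv_mean <- moving_mean(cbfv, config$mean_window)
  list(icp = icp, cbfv = cbfv, cbfv_mean = cbfv_mean)
}
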