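#' Parametric cardiac pulse morphology
#'
#' Describes one cardiac cycle of a pulsatile channel as a sum of
#' raised-cosine peak components (for ICP the percussion, tidal and
#' dicrotic peaks P1/P2/P3) on top of a diastolic baseline shelf. A
#' scalar `roundness` morphs the shape from a saw-tooth with three
#' distinct maxima (`roundness = 0`, P1 dominant) to a pathologically
#' rounded single hump (`roundness = 1`): the three narrow peaks fade
#' with `(1 - roundness)^2` while a broad hump of width `merged_width`
#' centered on the tidal latency grows with `roundness * merged_amp`.
#'
#' All times are fractions of the cycle length; amplitudes are relative
#' (the rendered pulse is rescaled to unit peak before use).
#'
#' @param p1_amp,p2_amp,p3_amp Relative peak amplitudes (>= 0).
#' @param p1_time,p2_time,p3_time Peak latencies as strictly increasing
#'   fractions of the cycle in (0, 1).
#' @param peak_width Component width as a fraction of the cycle.
#' @param roundness Scalar in `[0, 1]`; see Description.
#' @param base_amp Amplitude of the diastolic baseline shelf, relative
#'   to the largest blended peak component. The shelf keeps late
#'   diastole well above the onset trough, so the onset stays the
#'   unique cycle minimum even under slowly falling mean trends.
#' @param base_sharpness Steepness exponent of the basin walls around
#'   the onset trough (the baseline term is
#'   `base_amp * (1 - cos(pi * phase)^(2 * base_sharpness))`); larger
#'   values give a narrower trough with steeper systolic foot and
#'   end-diastolic descent.
#' @param merged_amp,merged_width Amplitude and width of the rounded
#'   single-hump component reached at `roundness = 1`.
#' @return A list of class `pulse_morphology`.
#' @export
pulse_morphology <- function(p1_amp = 1.0, p2_amp = 0.8, p3_amp = 0.6,
                             p1_time = 0.12, p2_time = 0.45,
                             p3_time = 0.70, peak_width = 0.20,
                             roundness = 0, base_amp = 0.4,
                             base_sharpness = 160, merged_amp = 1.0,
                             merged_width = 0.9) {
  amps <- c(p1_amp, p2_amp, p3_amp)
  times <- c(p1_time, p2_time, p3_time)
  if (any(amps < 0)) stop("peak amplitudes must be >= 0")
  if (any(times <= 0) || any(times >= 1))
    stop("peak latencies must lie strictly inside (0, 1)")
  if (any(diff(times) <= 0))
    stop("peak latencies must be strictly increasing")
  if (roundness < 0 || roundness > 1)
    stop("`roundness` must lie in [0, 1]")
  if (peak_width <= 0 || merged_width <= 0)
    stop("peak widths must be positive")
  structure(
    list(p1_amp = p1_amp, p2_amp = p2_amp, p3_amp = p3_amp,
         p1_time = p1_time, p2_time = p2_time, p3_time = p3_time,
         peak_width = peak_width, roundness = roundness,
         base_amp = base_amp, base_sharpness = base_sharpness,
         merged_amp = merged_amp, merged_width = merged_width),
    class = "pulse_morphology"
  )
}

#' Default CBFV pulse morphology
#'
#' Transcranial-Doppler-like velocity pulse: a sharp early systolic peak
#' followed by a smaller dicrotic component on a decaying diastolic
#' tail. The shape is fixed; during simulated plateau waves only the
#' CBFV mean level is modulated.
#'
#' @return A [pulse_morphology()].
#' @export
cbfv_morphology <- function() {
  pulse_morphology(p1_amp = 1.0, p2_amp = 0.35, p3_amp = 0,
                   p1_time = 0.13, p2_time = 0.42, p3_time = 0.70,
                   peak_width = 0.24, roundness = 0, base_amp = 0.3)
}

#' Default ABP pulse morphology
#'
#' Radial-artery-like pressure pulse: systolic peak plus dicrotic wave.
#'
#' @return A [pulse_morphology()].
#' @export
abp_morphology <- function() {
  pulse_morphology(p1_amp = 1.0, p2_amp = 0.45, p3_amp = 0,
                   p1_time = 0.16, p2_time = 0.44, p3_time = 0.70,
                   peak_width = 0.26, roundness = 0, base_amp = 0.25)
}

# Raised cosine bump centered at `center` with full width `width`,
# evaluated on phase vector ph in [0, 1).
raised_cosine <- function(ph, center, width) {
  d <- ph - center
  out <- numeric(length(ph))
  inside <- abs(d) <= width / 2
  out[inside] <- 0.5 * (1 + cos(2 * pi * d[inside] / width))
  out
}

#' Render one cardiac cycle of a pulse waveform
#'
#' Deterministically renders one cycle of `cycle_length` seconds at
#' sampling rate `fs`. The returned vector covers `[0, cycle_length)`
#' (the next cycle would start at the next sample), its first sample is
#' the cycle minimum (value 0) and its maximum is 1 unless all blended
#' component amplitudes are zero, in which case the pulse is identically
#' zero.
#'
#' @param morphology A [pulse_morphology()].
#' @param cycle_length Cycle length in seconds, within `[0.3, 2]`.
#' @param fs Sampling rate in Hz; must exceed 24 Hz so the pulse
#'   harmonics shaped by the 12-Hz analysis band are representable.
#' @return Numeric vector of `round(cycle_length * fs)` samples.
#' @export
render_pulse <- function(morphology, cycle_length, fs) {
  stopifnot(inherits(morphology, "pulse_morphology"))
  if (cycle_length < 0.3 || cycle_length > 2.0)
    stop("`cycle_length` must lie in [0.3, 2] s")
  if (fs <= 24) stop("`fs` must exceed 24 Hz")
  m <- morphology
  n <- as.integer(round(cycle_length * fs))
  ph <- (seq_len(n) - 1) / n
  r <- m$roundness
  # the three narrow peaks fade quadratically with roundness while a
  # broad hump centered on the tidal latency grows linearly; neither
  # family moves or widens, so peaks submerge into the hump smoothly
  # and no component support crosses the onset
  amps <- c((1 - r)^2 * c(m$p1_amp, m$p2_amp, m$p3_amp),
            r * m$merged_amp)
  widths <- c(m$peak_width, m$peak_width, m$peak_width, m$merged_width)
  centers <- c(m$p1_time, m$p2_time, m$p3_time, m$p2_time)
  a_ref <- max(amps)
  if (a_ref == 0) return(numeric(n))
  u <- numeric(n)
  for (j in 1:4) {
    if (amps[j] > 0) u <- u + amps[j] * raised_cosine(ph, centers[j], widths[j])
  }
  # diastolic baseline: a flat shelf with steep symmetric walls into
  # the onset trough; the flat mid-cycle part cannot create inter-peak
  # maxima, the symmetric walls keep the (low-pass filtered) trough
  # centered on the onset, and the last sample stays high enough that
  # the onset remains the beat minimum under falling mean trends
  u <- u + a_ref * m$base_amp * (1 - cos(pi * ph)^(2 * m$base_sharpness))
  u / max(u)
}

#' Synthetic plateau-wave episode plan
#'
#' Parameters of one simulated three-channel recording containing (at
#' most) one ICP plateau wave. Defaults emulate a typical monitored
#' episode in a TBI cohort: mean ICP ramping from about 19.4 mmHg to
#' about 42.7 mmHg and back, mean CBFV dropping from about 44.2 to
#' about 32.9 cm/s during the wave, mean ABP held near 94 mmHg, heart
#' rate near 75 bpm, and the ICP pulse morphology rounding (P2
#' dominance) as mean ICP rises. The ICP pulse amplitude grows with mean
#' ICP (amplitude-pressure coupling).
#'
#' @param total_duration Recording length, s.
#' @param baseline_icp_mean,plateau_icp_mean Mean ICP before/at the
#'   plateau, mmHg (`plateau > baseline` when `wave = TRUE`).
#' @param baseline_cbfv_mean,plateau_cbfv_mean Mean CBFV before/at the
#'   plateau, cm/s.
#' @param abp_mean Mean ABP, mmHg (held constant).
#' @param wave_start Start of the ICP rise, s.
#' @param wave_rise_duration,wave_plateau_duration,wave_fall_duration
#'   Durations of the rise, sustained plateau and fall phases, s.
#' @param heart_rate_mean Mean heart rate, bpm.
#' @param heart_rate_cv Coefficient of variation of beat lengths.
#' @param noise_sd Named numeric vector of additive Gaussian noise SDs
#'   per channel (icp mmHg, abp mmHg, cbfv cm/s).
#' @param artifact_rate Artifact events per minute (spikes, flatlines,
#'   dropouts to zero, injected into one random channel each).
#' @param baseline_roundness,plateau_roundness ICP pulse roundness at
#'   baseline and at the plateau (the roundness ramps with the trend).
#' @param icp_pulse_amp Baseline ICP pulse peak-to-peak amplitude, mmHg.
#' @param icp_amp_slope Increase of ICP pulse amplitude per mmHg of mean
#'   ICP rise (dimensionless).
#' @param cbfv_pulse_amp CBFV pulse peak-to-peak amplitude, cm/s.
#' @param abp_pulse_amp ABP pulse peak-to-peak amplitude, mmHg.
#' @param wave If `FALSE`, generate a flat (no-wave) recording; the wave
#'   parameters are ignored.
#' @param seed Integer seed; the recording is fully reproducible from
#'   it.
#' @return A list of class `episode_plan`.
#' @export
episode_plan <- function(total_duration = 660,
                         baseline_icp_mean = 19.4,
                         plateau_icp_mean = 42.7,
                         baseline_cbfv_mean = 44.2,
                         plateau_cbfv_mean = 32.9,
                         abp_mean = 94,
                         wave_start = 270,
                         wave_rise_duration = 30,
                         wave_plateau_duration = 240,
                         wave_fall_duration = 90,
                         heart_rate_mean = 75,
                         heart_rate_cv = 0.05,
                         noise_sd = c(icp = 0.2, abp = 0.8, cbfv = 1.0),
                         artifact_rate = 0.2,
                         baseline_roundness = 0.15,
                         plateau_roundness = 0.85,
                         icp_pulse_amp = 4,
                         icp_amp_slope = 0.15,
                         cbfv_pulse_amp = 25,
                         abp_pulse_amp = 40,
                         wave = TRUE,
                         seed = 1L) {
  stopifnot(total_duration > 0, heart_rate_mean > 0, heart_rate_cv >= 0,
            artifact_rate >= 0, icp_pulse_amp > 0, cbfv_pulse_amp > 0)
  if (!all(c("icp", "abp", "cbfv") %in% names(noise_sd)))
    stop("`noise_sd` must name icp, abp and cbfv")
  if (any(noise_sd < 0)) stop("noise SDs must be >= 0")
  if (isTRUE(wave)) {
    if (plateau_icp_mean <= baseline_icp_mean)
      stop("`plateau_icp_mean` must exceed `baseline_icp_mean`")
    if (wave_rise_duration <= 0 || wave_plateau_duration <= 0 ||
        wave_fall_duration <= 0)
      stop("wave phase durations must be positive")
    wave_end <- wave_start + wave_rise_duration + wave_plateau_duration +
      wave_fall_duration
    if (wave_start < 0 || wave_end > total_duration)
      stop("the wave interval must be contained in the recording")
  }
  if (baseline_roundness < 0 || baseline_roundness > 1 ||
      plateau_roundness < 0 || plateau_roundness > 1)
    stop("roundness values must lie in [0, 1]")
  structure(
    list(total_duration = total_duration,
         baseline_icp_mean = baseline_icp_mean,
         plateau_icp_mean = plateau_icp_mean,
         baseline_cbfv_mean = baseline_cbfv_mean,
         plateau_cbfv_mean = plateau_cbfv_mean,
         abp_mean = abp_mean,
         wave_start = wave_start,
         wave_rise_duration = wave_rise_duration,
         wave_plateau_duration = wave_plateau_duration,
         wave_fall_duration = wave_fall_duration,
         heart_rate_mean = heart_rate_mean,
         heart_rate_cv = heart_rate_cv,
         noise_sd = noise_sd,
         artifact_rate = artifact_rate,
         baseline_roundness = baseline_roundness,
         plateau_roundness = plateau_roundness,
         icp_pulse_amp = icp_pulse_amp,
         icp_amp_slope = icp_amp_slope,
         cbfv_pulse_amp = cbfv_pulse_amp,
         abp_pulse_amp = abp_pulse_amp,
         wave = isTRUE(wave),
         seed = as.integer(seed)),
    class = "episode_plan"
  )
}

# Trapezoidal wave activation in [0, 1] evaluated at times t (seconds).
wave_ramp <- function(t, plan) {
  if (!plan$wave) return(numeric(length(t)))
  t0 <- plan$wave_start
  t1 <- t0 + plan$wave_rise_duration
  t2 <- t1 + plan$wave_plateau_duration
  t3 <- t2 + plan$wave_fall_duration
  out <- numeric(length(t))
  r <- t >= t0 & t < t1
  out[r] <- (t[r] - t0) / (t1 - t0)
  out[t >= t1 & t <= t2] <- 1
  f <- t > t2 & t <= t3
  out[f] <- (t3 - t[f]) / (t3 - t2)
  out
}

#' Generate a synthetic three-channel neuromonitoring recording
#'
#' Produces a 50-Hz ICP/ABP/CBFV [recording()] following an
#' [episode_plan()], together with its ground truth. Beat lengths are
#' drawn around `60 / heart_rate_mean` with the configured coefficient
#' of variation; all channels share the cardiac beat schedule. Mean ICP
#' ramps baseline -> plateau -> baseline over the wave interval while
#' the ICP pulse roundness and amplitude ramp in step; mean CBFV drops
#' during the wave; mean ABP is constant, so cerebral perfusion pressure
#' falls by the full ICP rise. Gaussian noise is added per channel and
#' artifacts (spikes, flatlines, dropouts to zero) are injected at the
#' configured rate with their locations recorded in the ground truth.
#'
#' The ground truth annotates: per-channel onset sample indices;
#' `wave_interval`, the span where the noise-free mean ICP trend exceeds
#' baseline by at least 15 mmHg (the rise margin a plateau-wave detector
#' keys on); `plateau_interval`, the programmed sustained phase;
#' `ramp_interval`, the full programmed wave including rise and fall;
#' per-beat roundness; and artifact intervals.
#'
#' @param plan An [episode_plan()].
#' @return List with elements `recording` ([recording()]) and
#'   `ground_truth` (class `ground_truth`).
#' @export
generate_recording <- function(plan) {
  stopifnot(inherits(plan, "episode_plan"))
  fs <- 50
  n_total <- as.integer(round(plan$total_duration * fs))
  withr::with_seed(plan$seed, {
    # --- cardiac beat schedule (shared by all channels) -------------
    mean_beat <- 60 / plan$heart_rate_mean
    onsets <- integer(0)
    pos <- 1L
    while (pos <= n_total) {
      len <- stats::rnorm(1, mean_beat, plan$heart_rate_cv * mean_beat)
      len <- min(max(len, 0.45), 1.8)
      nb <- max(as.integer(round(len * fs)), 15L)
      onsets <- c(onsets, pos)
      pos <- pos + nb
    }
    n_beats <- length(onsets)
    beat_len <- diff(c(onsets, pos))   # samples per beat

    # --- slow trends -------------------------------------------------
    t_all <- (seq_len(n_total) - 1) / fs
    ramp <- wave_ramp(t_all, plan)
    icp_trend <- plan$baseline_icp_mean +
      (plan$plateau_icp_mean - plan$baseline_icp_mean) * ramp
    cbfv_trend <- plan$baseline_cbfv_mean +
      (plan$plateau_cbfv_mean - plan$baseline_cbfv_mean) * ramp
    abp_trend <- rep(plan$abp_mean, n_total)

    # --- beat-by-beat waveforms -------------------------------------
    icp <- numeric(n_total); cbfv <- numeric(n_total); abp <- numeric(n_total)
    morph_cbfv <- cbfv_morphology()
    morph_abp <- abp_morphology()
    u_cache <- list()  # fixed-morphology pulses keyed by beat length
    roundness_per_beat <- numeric(n_beats)
    for (k in seq_len(n_beats)) {
      i0 <- onsets[k]
      nb <- min(beat_len[k], n_total - i0 + 1L)
      idx <- i0:(i0 + nb - 1L)
      cyc <- beat_len[k] / fs
      t_mid <- (i0 - 1 + beat_len[k] / 2) / fs
      r_k <- plan$baseline_roundness +
        (plan$plateau_roundness - plan$baseline_roundness) *
        wave_ramp(t_mid, plan)
      roundness_per_beat[k] <- r_k
      m_icp <- pulse_morphology(roundness = r_k)
      u_icp <- render_pulse(m_icp, cyc, fs)[seq_len(nb)]
      key <- as.character(beat_len[k])
      if (is.null(u_cache[[key]])) {
        u_cache[[key]] <- list(
          cbfv = render_pulse(morph_cbfv, cyc, fs),
          abp = render_pulse(morph_abp, cyc, fs)
        )
      }
      u_cbfv <- u_cache[[key]]$cbfv[seq_len(nb)]
      u_abp <- u_cache[[key]]$abp[seq_len(nb)]
      amp_icp <- plan$icp_pulse_amp + plan$icp_amp_slope *
        (plan$baseline_icp_mean +
           (plan$plateau_icp_mean - plan$baseline_icp_mean) *
           wave_ramp(t_mid, plan) - plan$baseline_icp_mean)
      icp[idx] <- icp_trend[idx] + amp_icp * (u_icp - mean(u_icp))
      cbfv[idx] <- cbfv_trend[idx] +
        plan$cbfv_pulse_amp * (u_cbfv - mean(u_cbfv))
      abp[idx] <- abp_trend[idx] +
        plan$abp_pulse_amp * (u_abp - mean(u_abp))
    }

    # --- noise -------------------------------------------------------
    if (plan$noise_sd[["icp"]] > 0)
      icp <- icp + stats::rnorm(n_total, 0, plan$noise_sd[["icp"]])
    if (plan$noise_sd[["abp"]] > 0)
      abp <- abp + stats::rnorm(n_total, 0, plan$noise_sd[["abp"]])
    if (plan$noise_sd[["cbfv"]] > 0)
      cbfv <- cbfv + stats::rnorm(n_total, 0, plan$noise_sd[["cbfv"]])

    # --- artifacts ---------------------------------------------------
    art <- data.frame(channel = character(0), kind = character(0),
                      start_s = numeric(0), end_s = numeric(0))
    if (plan$artifact_rate > 0) {
      n_art <- stats::rpois(1, plan$artifact_rate * plan$total_duration / 60)
      for (a in seq_len(n_art)) {
        kind <- sample(c("spike", "flatline", "dropout"), 1)
        chan <- sample(c("icp", "abp", "cbfv"), 1)
        dur <- switch(kind,
                      spike = 0.06,
                      flatline = stats::runif(1, 1, 3),
                      dropout = stats::runif(1, 0.5, 2))
        t0 <- stats::runif(1, 0, plan$total_duration - dur)
        i0 <- as.integer(floor(t0 * fs)) + 1L
        i1 <- min(as.integer(ceiling((t0 + dur) * fs)), n_total)
        seg <- i0:i1
        x <- switch(chan, icp = icp, abp = abp, cbfv = cbfv)
        x[seg] <- switch(kind,
                         spike = x[seg] + sample(c(-1, 1), 1) *
                           stats::runif(1, 25, 45),
                         flatline = x[i0],
                         dropout = 0)
        if (chan == "icp") icp <- x else if (chan == "abp") abp <- x else cbfv <- x
        art <- rbind(art, data.frame(channel = chan, kind = kind,
                                     start_s = t0, end_s = t0 + dur))
      }
    }
  })

  rec <- recording(
    icp = time_series(icp, fs, "mmHg", "icp"),
    abp = time_series(abp, fs, "mmHg", "abp"),
    cbfv = time_series(cbfv, fs, "cm/s", "cbfv")
  )

  delta <- plan$plateau_icp_mean - plan$baseline_icp_mean
  if (plan$wave && delta > 15) {
    frac <- 15 / delta
    t1 <- plan$wave_start + plan$wave_rise_duration * frac
    t2 <- plan$wave_start + plan$wave_rise_duration +
      plan$wave_plateau_duration + plan$wave_fall_duration * (1 - frac)
    wave_interval <- c(t1, t2)
  } else {
    wave_interval <- c(NA_real_, NA_real_)
  }
  gt <- structure(
    list(
      true_onsets = list(icp = onsets, abp = onsets, cbfv = onsets),
      fs = fs,
      wave_interval = wave_interval,
      plateau_interval = if (plan$wave)
        c(plan$wave_start + plan$wave_rise_duration,
          plan$wave_start + plan$wave_rise_duration +
            plan$wave_plateau_duration)
      else c(NA_real_, NA_real_),
      ramp_interval = if (plan$wave)
        c(plan$wave_start,
          plan$wave_start + plan$wave_rise_duration +
            plan$wave_plateau_duration + plan$wave_fall_duration)
      else c(NA_real_, NA_real_),
      roundness = roundness_per_beat,
      artifact_intervals = art
    ),
    class = "ground_truth"
  )
  list(recording = rec, ground_truth = gt)
}

#' Derive a child seed from a parent seed
#'
#' Deterministic integer mixing used to fan a single pipeline seed out
#' to per-recording (or per-stage) seeds. All arithmetic stays below
#' 2^53 so the result is exact in double precision, and the output is a
#' valid 32-bit seed.
#'
#' @param seed Parent integer seed.
#' @param i Child index (>= 0).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, i) {
  s <- as.numeric(seed) %% 94906265
  as.integer((s * 22695477 + as.numeric(i)) %% 2147483647)
}

#' Generate a cohort of synthetic plateau-wave recordings
#'
#' Draws `n_waves` recordings from jittered copies of a plan template.
#' Level parameters (mean ICP, CBFV, ABP, heart rate, pulse amplitudes)
#' receive about +/-10\% multiplicative log-normal jitter (sdlog 0.1;
#' heart rate sdlog 0.05). To keep every simulated wave a bona fide
#' plateau wave, the jittered plateau ICP is floored at
#' `baseline + 16` mmHg and at 41 mmHg; plateau CBFV is capped below the
#' jittered baseline CBFV. Each recording gets its own child seed via
#' [derive_seed()].
#'
#' @param n_waves Number of recordings (>= 1).
#' @param plan_template An [episode_plan()] providing the central
#'   parameter values.
#' @param seed Cohort-level integer seed.
#' @return List of `n_waves` elements, each a
#'   `list(recording, ground_truth, plan)`.
#' @export
generate_cohort <- function(n_waves, plan_template = episode_plan(),
                            seed = 1L) {
  stopifnot(n_waves >= 1, inherits(plan_template, "episode_plan"))
  out <- vector("list", n_waves)
  for (i in seq_len(n_waves)) {
    jseed <- derive_seed(seed, i)
    jit <- withr::with_seed(jseed, {
      list(lvl = stats::rlnorm(6, 0, 0.1), hr = stats::rlnorm(1, 0, 0.05))
    })
    p <- plan_template
    p$baseline_icp_mean <- p$baseline_icp_mean * jit$lvl[1]
    if (p$wave) {
      p$plateau_icp_mean <- max(p$plateau_icp_mean * jit$lvl[2],
                                p$baseline_icp_mean + 16, 41)
    }
    p$baseline_cbfv_mean <- p$baseline_cbfv_mean * jit$lvl[3]
    p$plateau_cbfv_mean <- min(p$plateau_cbfv_mean * jit$lvl[4],
                               0.95 * p$baseline_cbfv_mean)
    p$abp_mean <- p$abp_mean * jit$lvl[5]
    p$icp_pulse_amp <- p$icp_pulse_amp * jit$lvl[6]
    p$heart_rate_mean <- p$heart_rate_mean * jit$hr
    p$seed <- derive_seed(jseed, 1000L)
    r <- generate_recording(p)
    out[[i]] <- list(recording = r$recording, ground_truth = r$ground_truth,
                     plan = p)
  }
  out
}

#' Write / read an episode plan as YAML
#'
#' @param plan An [episode_plan()].
#' @param path File path.
#' @return `read_plan` returns an [episode_plan()];
#'   `write_plan` returns `path` invisibly.
#' @export
write_plan <- function(plan, path) {
  stopifnot(inherits(plan, "episode_plan"))
  vals <- unclass(plan)
  vals$noise_sd <- as.list(vals$noise_sd)  # keep channel names in YAML
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' @rdname write_plan
#' @export
read_plan <- function(path) {
  if (!file.exists(path)) stop("plan file not found: ", path)
  vals <- yaml::read_yaml(path)
  ns <- unlist(vals$noise_sd)
  vals$noise_sd <- NULL
  do.call(episode_plan, c(vals, list(noise_sd = ns)))
}

#' Write ground truth annotations as a sidecar CSV
#'
#' Long-format table with one row per annotation: onset indices, wave /
#' plateau / ramp intervals, per-beat roundness and artifact intervals.
#'
#' @param gt A `ground_truth` object from [generate_recording()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(gt, path) {
  stopifnot(inherits(gt, "ground_truth"))
  rows <- list()
  for (ch in names(gt$true_onsets)) {
    on <- gt$true_onsets[[ch]]
    rows[[length(rows) + 1L]] <- data.frame(
      kind = "onset", channel = ch, index = on,
      start_s = (on - 1) / gt$fs, end_s = NA_real_, value = NA_real_)
  }
  for (nm in c("wave_interval", "plateau_interval", "ramp_interval")) {
    rows[[length(rows) + 1L]] <- data.frame(
      kind = nm, channel = NA_character_, index = NA_integer_,
      start_s = gt[[nm]][1], end_s = gt[[nm]][2], value = NA_real_)
  }
  rows[[length(rows) + 1L]] <- data.frame(
    kind = "roundness", channel = "icp",
    index = seq_along(gt$roundness),
    start_s = NA_real_, end_s = NA_real_, value = gt$roundness)
  if (nrow(gt$artifact_intervals) > 0) {
    a <- gt$artifact_intervals
    rows[[length(rows) + 1L]] <- data.frame(
      kind = paste0("artifact_", a$kind), channel = a$channel,
      index = NA_integer_, start_s = a$start_s, end_s = a$end_s,
      value = NA_real_)
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
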