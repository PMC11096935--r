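# Shared fixtures, built once per test run and cached.

.fx_cache <- new.env(parent = emptyenv())

fx <- function(key, builder) {
  if (is.null(.fx_cache[[key]])) .fx_cache[[key]] <- builder()
  .fx_cache[[key]]
}

# Short plateau-wave plan used where the full default length is not
# needed: 120 s baseline, 30 s rise, 200 s plateau, 60 s fall.
short_plan <- function(seed = 1L, ...) {
  episode_plan(total_duration = 440, wave_start = 150,
               wave_rise_duration = 30, wave_plateau_duration = 200,
               wave_fall_duration = 60, seed = seed, ...)
}

# Flat (no-wave) recording used for onset-detection tests.
flat_plan <- function(seed = 1L, duration = 300, ...) {
  episode_plan(total_duration = duration, wave = FALSE, seed = seed, ...)
}

fx_short_noisefree <- function() fx("short_nf", function() {
  generate_recording(short_plan(
    seed = 11L, noise_sd = c(icp = 0, abp = 0, cbfv = 0),
    artifact_rate = 0))
})

fx_short_default <- function() fx("short_def", function() {
  generate_recording(short_plan(seed = 12L))
})

fx_short_analysis <- function() fx("short_analysis", function() {
  suppressMessages(analyze_recording(fx_short_default()$recording,
                                     baseline_length = 120))
})

# Jaccard overlap of two closed intervals.
interval_jaccard <- function(a, b) {
  lo <- max(a[1], b[1]); hi <- min(a[2], b[2])
  ov <- max(0, hi - lo)
  ov / ((a[2] - a[1]) + (b[2] - b[1]) - ov)
}

# Match detected onsets (200 Hz) against ground-truth 50-Hz onsets,
# excluding an edge margin where the detector has no context.
onset_recovery <- function(detected, truth50, n200, tol = 2L,
                           edge = 250L) {
  truth <- (truth50 - 1L) * 4L + 1L
  tin <- truth[truth > edge & truth < n200 - edge]
  din <- detected[detected > edge & detected < n200 - edge]
  errs <- vapply(tin, function(o) min(abs(din - o)), numeric(1))
  fp <- sum(vapply(din, function(o) min(abs(tin - o)), numeric(1)) > tol)
  list(sens = mean(errs <= tol), max_err = max(errs), n_true = length(tin),
       n_det = length(din), fp = fp)
}

# Independent strict-local-maxima counter (test-side oracle).
oracle_count_maxima <- function(x) {
  n <- length(x)
  sum(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] > x[3:n])
}

# Make a pulse object directly from samples (for unit tests).
make_pulse <- function(samples, fs = 200, onset_index = 1L,
                       channel = "icp") {
  structure(list(samples = samples, fs = fs, onset_index = onset_index,
                 duration = length(samples) / fs, channel = channel),
            class = "pulse")
}

make_norm <- function(values, fs = 200, onset_index = 1L,
                      channel = "icp") {
  structure(list(values = values, fs = fs, onset_index = onset_index,
                 channel = channel),
            class = "normalized_pulse")
}

# Brute-force two-sided exact Wilcoxon signed-rank p by enumerating all
# sign assignments (no ties assumed).
oracle_wilcoxon <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- min(sum(r[d > 0]), sum(r[d < 0]))
  total <- n * (n + 1) / 2
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_plus <- as.vector(signs %*% r)
  w_all <- pmin(w_plus, total - w_plus)
  list(w = w_obs, p = mean(w_all <= w_obs))
}
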