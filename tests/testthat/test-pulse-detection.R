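test_that("onset detection finds sinusoid minima at the analytic spacing", {
  t <- (0:11999) / 200
  on <- detect_onsets(time_series(sin(2 * pi * 1.25 * t), 200))
  sp <- diff(on)
  expect_equal(stats::median(sp), 160)
  expect_true(all(abs(sp - 160) <= 1))
  # minima of sin at phase 3/2 pi: t = 0.6 + k * 0.8 -> samples 121 + k*160
  expect_true(all((on - 121) %% 160 <= 1 | (on - 121) %% 160 >= 159))
})

test_that("onset detection handles degenerate input", {
  expect_length(detect_onsets(time_series(rep(5, 4000), 200)), 0)
  expect_error(detect_onsets(time_series(rnorm(100), 200)), "window")
})

test_that("noise-free synthetic onsets are recovered exactly", {
  rg <- fx_short_noisefree()
  pre <- preprocess_recording(rg$recording)
  for (ch in c("icp", "cbfv")) {
    det <- detect_onsets(pre[[ch]])
    st <- onset_recovery(det, rg$ground_truth$true_onsets[[ch]],
                         length(pre[[ch]]$samples))
    expect_equal(st$sens, 1.0)
    expect_equal(st$fp, 0)
  }
})

test_that("pulse segmentation spans onset to next onset", {
  ts <- time_series(sin(2 * pi * (0:999) / 100) + 2, 200, label = "icp")
  onsets <- c(76L, 176L, 276L, 376L, 476L)
  pulses <- segment_pulses(ts, onsets)
  expect_length(pulses, 4)
  expect_equal(sum(lengths(lapply(pulses, `[[`, "samples"))), 476 - 76)
  for (p in pulses)
    expect_identical(p$samples[1], ts$samples[p$onset_index])
  expect_length(segment_pulses(ts, c(10L)), 0)
})

test_that("quality control fires the right rule with the right reason", {
  clean <- render_pulse(pulse_morphology(roundness = 0.2), 0.8, 200)
  p_clean <- make_pulse(20 + 4 * clean, channel = "icp")
  expect_true(qc_pulse(p_clean)$accept)

  short <- make_pulse((20 + 4 * clean)[1:20], channel = "icp")
  expect_equal(qc_pulse(short)$reason, "duration")

  dropped <- 40 + 25 * render_pulse(cbfv_morphology(), 0.8, 200)
  dropped[60:80] <- 0
  expect_equal(qc_pulse(make_pulse(dropped, channel = "cbfv"))$reason,
               "range")

  nf <- 20 + 4 * clean; nf[10] <- NaN
  expect_equal(qc_pulse(make_pulse(nf, channel = "icp"))$reason,
               "nonfinite")

  flatish <- make_pulse(rep(20, 160) + 0.01 * clean, channel = "icp")
  expect_equal(qc_pulse(flatish)$reason, "amplitude")

  wiggly <- 20 + 4 * clean + 2 * sin(2 * pi * (0:159) / 10)
  expect_equal(qc_pulse(make_pulse(wiggly, channel = "icp"))$reason,
               "extrema")
})

test_that("tightening any QC bound never accepts more pulses", {
  rg <- fx_short_default()
  pre <- preprocess_recording(rg$recording)
  pulses <- segment_pulses(pre$icp, detect_onsets(pre$icp),
                           channel = "icp")[1:80]
  base <- sum(qc_pulses(pulses, qc_config())$accept)
  tighter <- list(
    qc_config(min_duration = 0.6),
    qc_config(max_duration = 0.7),
    qc_config(value_range = list(icp = c(15, 30), cbfv = c(1, 250),
                                 abp = c(20, 250))),
    qc_config(min_pulse_amplitude = list(icp = 5, cbfv = 5, abp = 10)),
    qc_config(max_local_extrema = 2L)
  )
  for (qc in tighter)
    expect_lte(sum(qc_pulses(pulses, qc)$accept), base)
})

test_that("pulse pairing is tolerance-bounded, injective and symmetric", {
  mk <- function(onsets, channel) {
    lapply(onsets, function(o) make_pulse(sin(1:100), onset_index = o,
                                          channel = channel))
  }
  icp <- mk(c(1L, 201L, 401L, 601L), "icp")
  cbfv <- mk(c(3L, 199L, 404L, 598L), "cbfv")
  pairs <- pair_pulses(icp, cbfv, tolerance_s = 0.25)
  expect_length(pairs, 4)
  expect_true(all(abs(vapply(pairs, `[[`, numeric(1), "onset_lag")) <=
                    0.25))

  # one member missing drops exactly that cycle
  pairs3 <- pair_pulses(icp, cbfv[-2], tolerance_s = 0.25)
  expect_length(pairs3, 3)
  expect_false(201L %in% vapply(pairs3, function(p) p$icp_pulse$onset_index,
                                integer(1)))

  # offset beyond tolerance pairs nothing
  far <- mk(c(101L, 301L, 501L), "cbfv")  # 0.5 s away
  expect_length(pair_pulses(icp[1:3], far, tolerance_s = 0.25), 0)

  # symmetry: swapping roles matches the same onset pairs
  fwd <- pair_pulses(icp, cbfv, tolerance_s = 0.25)
  rev <- pair_pulses(cbfv, icp, tolerance_s = 0.25)
  fwd_ids <- lapply(fwd, function(p) c(p$icp_pulse$onset_index,
                                       p$cbfv_pulse$onset_index))
  rev_ids <- lapply(rev, function(p) c(p$cbfv_pulse$onset_index,
                                       p$icp_pulse$onset_index))
  expect_setequal(vapply(fwd_ids, paste, collapse = "-", ""),
                  vapply(rev_ids, paste, collapse = "-", ""))
})
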