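test_that("rendered pulse peak structure follows the morphing contract", {
  # saw-tooth: three distinct maxima, percussion peak dominant
  m0 <- pulse_morphology(p1_amp = 1.0, p2_amp = 0.8, p3_amp = 0.6,
                         roundness = 0)
  u0 <- render_pulse(m0, 0.86, 200)
  expect_equal(oracle_count_maxima(u0), 3)
  expect_equal((which.max(u0) - 1) / length(u0), m0$p1_time,
               tolerance = 0.02)
  expect_equal(which.min(u0), 1L)
  expect_equal(u0[1], 0)
  expect_equal(max(u0), 1)

  # fully rounded: exactly one maximum
  u1 <- render_pulse(pulse_morphology(roundness = 1), 0.86, 200)
  expect_equal(oracle_count_maxima(u1), 1)

  # maxima counts monotone non-increasing 3 -> 1 along the roundness grid
  cnt <- vapply(seq(0, 1, by = 0.05), function(r) {
    oracle_count_maxima(render_pulse(pulse_morphology(roundness = r),
                                     0.86, 200))
  }, numeric(1))
  expect_true(all(diff(cnt) <= 0))
  expect_equal(cnt[1], 3)
  expect_equal(cnt[length(cnt)], 1)

  # zero component amplitudes give a flat zero pulse
  uz <- render_pulse(pulse_morphology(p1_amp = 0, p2_amp = 0, p3_amp = 0,
                                      merged_amp = 0), 0.86, 200)
  expect_true(all(uz == 0))

  # determinism
  expect_identical(render_pulse(m0, 0.86, 200), render_pulse(m0, 0.86, 200))
})

test_that("pulse rendering and morphology constructors validate input", {
  expect_error(render_pulse(pulse_morphology(), 0.2, 200), "cycle_length")
  expect_error(render_pulse(pulse_morphology(), 2.5, 200), "cycle_length")
  expect_error(render_pulse(pulse_morphology(), 0.86, 20), "fs")
  expect_error(pulse_morphology(p1_time = 0.5, p2_time = 0.4), "increasing")
  expect_error(pulse_morphology(p1_amp = -1), ">= 0")
  expect_error(pulse_morphology(roundness = 1.5), "roundness")
})

test_that("generated recordings hit the programmed ICP levels", {
  rg <- generate_recording(episode_plan(seed = 1))
  rec <- rg$recording
  gt <- rg$ground_truth
  fs <- rec$icp$fs
  # baseline window precedes the wave start (270 s) by design
  bl <- rec$icp$samples[(30 * fs):(270 * fs)]
  pl_idx <- (gt$plateau_interval[1] * fs):(gt$plateau_interval[2] * fs)
  expect_equal(mean(bl), 19.4, tolerance = 1.5 / 19.4)
  expect_equal(mean(rec$icp$samples[pl_idx]), 42.7, tolerance = 1.5 / 42.7)
  # CBFV drops, ABP level
  expect_equal(mean(rec$cbfv$samples[(30 * fs):(270 * fs)]), 44.2,
               tolerance = 0.1)
  expect_equal(mean(rec$cbfv$samples[pl_idx]), 32.9, tolerance = 0.1)
  expect_equal(mean(rec$abp$samples), 94, tolerance = 0.05)
})

test_that("noise-free beat minima sit exactly on the annotated onsets", {
  rg <- fx_short_noisefree()
  for (ch in c("icp", "cbfv", "abp")) {
    x <- rg$recording[[ch]]$samples
    on <- rg$ground_truth$true_onsets[[ch]]
    mins <- vapply(seq_len(length(on) - 1), function(k) {
      which.min(x[on[k]:(on[k + 1] - 1)]) + on[k] - 1L
    }, integer(1))
    expect_identical(mins, on[-length(on)])
  }
})

test_that("recording generation is deterministic and validates plans", {
  p <- episode_plan(seed = 42)
  a <- generate_recording(p)
  b <- generate_recording(p)
  expect_identical(a$recording$icp$samples, b$recording$icp$samples)
  expect_identical(a$ground_truth, b$ground_truth)

  expect_error(episode_plan(total_duration = 100, wave_start = 50),
               "contained")
  expect_error(episode_plan(plateau_icp_mean = 10), "exceed")
  expect_error(episode_plan(wave_rise_duration = -1), "positive")
})

test_that("generated trends satisfy the plateau-wave criteria", {
  # the 6-s mean ICP of a default recording must exceed 40 mmHg at the
  # peak, rise >= 15 mmHg over baseline, drop CPP >= 10 mmHg and stay
  # up >= 3 min -- the criteria the detector applies downstream
  rg <- fx("default_rec", function() generate_recording(episode_plan(seed = 3)))
  m6 <- moving_mean(rg$recording$icp, 6)$samples
  cpp6 <- moving_mean(rg$recording$abp, 6)$samples - m6
  fs <- rg$recording$icp$fs
  bl <- stats::median(m6[(30 * fs):(270 * fs)])
  expect_gt(max(m6), 40)
  expect_gte(max(m6) - bl, 15)
  expect_gte(stats::median(cpp6[(30 * fs):(270 * fs)]) - min(cpp6), 10)
  above <- m6 >= bl + 15
  expect_gte(max(rle(above)$lengths[rle(above)$values]) / fs, 180)
})

test_that("cohorts are seeded, jittered and contain one wave each", {
  co <- generate_cohort(4, episode_plan(), seed = 7)
  expect_length(co, 4)
  for (el in co) {
    expect_false(any(is.na(el$ground_truth$wave_interval)))
    expect_gte(el$plan$plateau_icp_mean, 41)
    expect_gte(el$plan$plateau_icp_mean - el$plan$baseline_icp_mean, 16)
  }
  # jitter actually varies levels between recordings
  bls <- vapply(co, function(el) el$plan$baseline_icp_mean, numeric(1))
  expect_gt(stats::sd(bls), 0)
  co2 <- generate_cohort(4, episode_plan(), seed = 7)
  expect_identical(co[[2]]$recording$icp$samples,
                   co2[[2]]$recording$icp$samples)
  expect_length(generate_cohort(1, episode_plan(), seed = 1), 1)
})

test_that("plans and ground truth round-trip through their file formats", {
  p <- episode_plan(seed = 5, heart_rate_mean = 68)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_plan(p, path)
  p2 <- read_plan(path)
  expect_equal(unclass(p), unclass(p2))

  gt <- fx_short_default()$ground_truth
  gpath <- withr::local_tempfile(fileext = ".csv")
  write_ground_truth(gt, gpath)
  tab <- utils::read.csv(gpath)
  expect_equal(sum(tab$kind == "onset" & tab$channel == "icp"),
               length(gt$true_onsets$icp))
  expect_equal(tab$start_s[tab$kind == "wave_interval"],
               gt$wave_interval[1])
})
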