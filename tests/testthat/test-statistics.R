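test_that("period summaries use interpolated order statistics", {
  s <- summarize_period(c(1, 2, 3, 4, 5), "baseline", "DI")
  expect_equal(c(s$q1, s$median, s$q3), c(2, 3, 4))
  expect_equal(s$n, 5)

  one <- summarize_period(7, "plateau", "ICP")
  expect_equal(c(one$q1, one$median, one$q3), c(7, 7, 7))

  # sort-based brute-force oracle for the interpolation convention
  set.seed(9)
  for (rep in 1:20) {
    x <- rnorm(sample(3:40, 1))
    s <- summarize_period(x)
    xs <- sort(x); n <- length(xs)
    br <- vapply(c(0.25, 0.5, 0.75), function(p) {
      h <- (n - 1) * p + 1
      lo <- floor(h); hi <- ceiling(h)
      xs[lo] + (h - lo) * (xs[hi] - xs[lo])
    }, numeric(1))
    expect_equal(c(s$q1, s$median, s$q3), br, tolerance = 1e-12)
  }
  expect_error(summarize_period(numeric(0)), "no values")
  expect_error(summarize_period(c(1, NA)), "finite")
})

test_that("the signed-rank test matches enumeration on small samples", {
  # five positive differences, no ties
  t5 <- wilcoxon_signed_rank(c(2, 3, 4, 5, 6), c(1, 1, 1, 1, 1))
  expect_equal(t5$statistic, 0)
  expect_equal(t5$p_value, 0.0625)
  expect_equal(t5$method, "exact")

  expect_error(wilcoxon_signed_rank(1:5, 1:5), "non-zero")
  expect_error(wilcoxon_signed_rank(1:4, 2:5 + 0.5), "non-zero|length|5")

  set.seed(10)
  for (rep in 1:10) {
    n <- sample(6:11, 1)
    x <- rnorm(n); y <- rnorm(n)
    got <- wilcoxon_signed_rank(x, y)
    want <- oracle_wilcoxon(x - y)
    expect_equal(got$statistic, want$w)
    expect_equal(got$p_value, want$p, tolerance = 1e-12)
  }
})

test_that("ties fall back to the corrected normal approximation", {
  x <- c(3, 3, 5, 5, 7, 8, 9, 10, 12, 1)
  y <- c(1, 1, 3, 3, 5, 5, 6, 6, 6, 4)
  got <- wilcoxon_signed_rank(x, y)
  expect_equal(got$method, "normal-approximation")
  ref <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                             correct = TRUE))
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("the test is invariant to common location shifts", {
  set.seed(11)
  x <- rnorm(12); y <- rnorm(12)
  a <- wilcoxon_signed_rank(x, y)
  b <- wilcoxon_signed_rank(x + 100, y + 100)
  expect_equal(a$statistic, b$statistic)
  expect_equal(a$p_value, b$p_value)
})

test_that("W stays within its combinatorial bounds", {
  set.seed(12)
  for (rep in 1:20) {
    n <- sample(5:30, 1)
    t <- wilcoxon_signed_rank(rnorm(n), rnorm(n))
    expect_gte(t$statistic, 0)
    expect_lte(t$statistic, t$n_pairs * (t$n_pairs + 1) / 2)
    expect_gte(t$p_value, 0)
    expect_lte(t$p_value, 1)
  }
})

test_that("period comparison pairs waves and excludes incomplete ones", {
  set.seed(13)
  mk_records <- function(wave_id, shift) {
    data.frame(
      wave_id = wave_id,
      period_label = rep(c("baseline", "plateau"), each = 20),
      onset_time = seq_len(40),
      di = c(rnorm(20, 26, 2), rnorm(20, 26 - shift, 2)),
      n_compared = 160L)
  }
  recs <- do.call(rbind, lapply(1:10, mk_records, shift = 6))
  cmp <- compare_periods(recs)
  expect_equal(nrow(cmp$per_wave), 10)
  expect_lte(cmp$test$n_pairs, 10)
  expect_true(cmp$significant)
  expect_lt(cmp$summaries$plateau$median, cmp$summaries$baseline$median)

  # a wave missing one period is excluded with a warning
  lop <- mk_records(11L, 6)
  lop <- lop[lop$period_label == "baseline", ]
  expect_warning(cmp2 <- compare_periods(rbind(recs, lop)), "missing")
  expect_equal(nrow(cmp2$per_wave), 10)

  # pooled mode runs on pulse-level values
  cmp3 <- compare_periods(recs, pairing = "pooled")
  expect_equal(cmp3$pairing, "pooled")
  expect_gt(cmp3$test$n_pairs, 10)
})

test_that("report rendering is deterministic and complete", {
  set.seed(14)
  wave_table <- data.frame(wave_id = 1:6, peak_icp = 41:46,
                           di_baseline = c(40, 44, 39, 42, 43, 41),
                           di_plateau = c(31, 36, 30, 33, 35, 32))
  recs <- data.frame(
    wave_id = rep(1:6, each = 12),
    period_label = rep(rep(c("baseline", "plateau"), each = 6), 6),
    onset_time = 1:72,
    di = rep(rbind(wave_table$di_baseline, wave_table$di_plateau),
             each = 6) + rnorm(72, 0, 0.01),
    n_compared = 160L)
  cmp <- compare_periods(recs)
  p1 <- withr::local_tempfile(fileext = ".txt")
  p2 <- withr::local_tempfile(fileext = ".txt")
  cfg <- list(seed = 1, n_recordings = 3)
  build_report(wave_table, cmp, cfg, p1)
  build_report(wave_table, cmp, cfg, p2)
  expect_identical(readLines(p1), readLines(p2))
  txt <- readLines(p1)
  expect_equal(sum(grepl("^\\s*[0-9]+\t", txt)), 6)  # one row per wave
  expect_true(any(grepl("seed: 1", txt)))
  expect_true(any(grepl("Wilcoxon", txt)))
})
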