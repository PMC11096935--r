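#' Full analysis of one recording
#'
#' Runs the complete per-recording chain: slow trends and plateau-wave
#' detection on the acquisition-rate signals; upsampling, low-pass
#' filtering and windowed CBFV mean; pulse onset detection on ICP and
#' CBFV; beat segmentation and quality control; per-cycle pairing;
#' CaBV computation; period labeling; and per-pulse difference-index
#' scoring.
#'
#' @param rec A [recording()].
#' @param wave_id Identifier attached to the DI records.
#' @param preprocess A [preprocess_config()].
#' @param qc A [qc_config()].
#' @param pairing_tolerance_s Onset tolerance for ICP/CBFV pairing, s.
#' @param tail DI tail handling, see [difference_index()].
#' @param baseline_length Baseline period length, s.
#' @return List: `di_records` (data frame), `wave` (a `plateau_wave`
#'   or `NULL`), `qc_log` (per-channel QC data frames), `n_onsets`
#'   (per-channel onset counts). When no wave is detected the DI
#'   records are empty.
#' @export
analyze_recording <- function(rec, wave_id = 1L,
                              preprocess = preprocess_config(),
                              qc = qc_config(),
                              pairing_tolerance_s = 0.25,
                              tail = c("hold", "truncate"),
                              baseline_length = 240) {
  tail <- match.arg(tail)
  stopifnot(inherits(rec, "recording"))

  trends <- compute_trends(rec, preprocess$trend_window)
  waves <- detect_plateau_waves(trends, ref_window_s = baseline_length)
  empty <- data.frame(wave_id = integer(0), period_label = character(0),
                      onset_time = numeric(0), di = numeric(0),
                      n_compared = integer(0))
  if (length(waves) == 0L)
    return(list(di_records = empty, wave = NULL, qc_log = NULL,
                n_onsets = NULL, trends = trends))
  wave <- select_periods(waves[[1L]], trends,
                         baseline_length = baseline_length)
  if (is.null(wave))
    return(list(di_records = empty, wave = NULL, qc_log = NULL,
                n_onsets = NULL, trends = trends))

  pre <- preprocess_recording(rec, preprocess)
  on_icp <- detect_onsets(pre$icp)
  on_cbfv <- detect_onsets(pre$cbfv)
  p_icp <- segment_pulses(pre$icp, on_icp, channel = "icp")
  p_cbfv <- segment_pulses(pre$cbfv, on_cbfv, channel = "cbfv")
  qc_icp <- qc_pulses(p_icp, qc)
  qc_cbfv <- qc_pulses(p_cbfv, qc)
  pairs <- pair_pulses(p_icp[qc_icp$accept], p_cbfv[qc_cbfv$accept],
                       tolerance_s = pairing_tolerance_s)
  with_cabv <- cabv_for_pairs(pairs, pre$cbfv_mean)
  labeled <- label_pulses(with_cabv, wave)
  di <- score_pairs(labeled, wave_id = wave_id, tail = tail)
  list(di_records = di, wave = wave,
       qc_log = list(icp = qc_icp, cbfv = qc_cbfv),
       n_onsets = c(icp = length(on_icp), cbfv = length(on_cbfv)),
       trends = trends)
}

# Mean of a trend series over a time interval [a, b] seconds.
interval_mean <- function(ts, interval) {
  i0 <- max(1L, as.integer(round(interval[1] * ts$fs)) + 1L)
  i1 <- min(length(ts$samples), as.integer(round(interval[2] * ts$fs)) + 1L)
  mean(ts$samples[i0:i1])
}

#' Run the cohort analysis end to end
#'
#' Simulates (or accepts) a cohort of plateau-wave recordings, analyzes
#' each with [analyze_recording()], assembles the per-wave table of
#' physiological levels and DI medians, compares baseline against
#' plateau and optionally writes a report plus result files. Every
#' stochastic step derives its seed from `seed`, so a rerun with the
#' same inputs is identical.
#'
#' @param n_waves Number of simulated recordings (ignored when
#'   `recordings` is supplied).
#' @param plan_template An [episode_plan()] for the simulation.
#' @param recordings Optional list of [recording()] objects to analyze
#'   instead of simulating.
#' @param seed Integer master seed for the simulation.
#' @param pairing Inference unit for [compare_periods()].
#' @param output_dir Optional directory; when given, writes
#'   `report.txt`, `di_records.csv`, `di_records.json` and `waves.csv`.
#' @param ... Passed on to [analyze_recording()].
#' @return List of class `cohort_analysis`: `di_records`, `wave_table`,
#'   `comparison`, `summaries` (per-signal period summaries),
#'   `n_recordings`, `n_waves_detected`.
#' @export
run_analysis <- function(n_waves = 15, plan_template = episode_plan(),
                         recordings = NULL, seed = 1L,
                         pairing = c("per_wave", "pooled"),
                         output_dir = NULL, ...) {
  pairing <- match.arg(pairing)
  if (is.null(recordings)) {
    cohort <- generate_cohort(n_waves, plan_template, seed = seed)
    recordings <- lapply(cohort, `[[`, "recording")
  }
  di_all <- list()
  wave_rows <- list()
  for (i in seq_along(recordings)) {
    res <- analyze_recording(recordings[[i]], wave_id = i, ...)
    if (is.null(res$wave)) {
      message(sprintf("recording %d: no plateau wave detected", i))
      next
    }
    di_all[[length(di_all) + 1L]] <- res$di_records
    tr <- res$trends
    w <- res$wave
    wave_rows[[length(wave_rows) + 1L]] <- data.frame(
      wave_id = i,
      wave_start = w$wave_interval[1], wave_end = w$wave_interval[2],
      baseline_start = w$baseline_interval[1],
      baseline_end = w$baseline_interval[2],
      plateau_start = w$plateau_interval[1],
      plateau_end = w$plateau_interval[2],
      peak_icp = w$peak_icp,
      icp_baseline = interval_mean(tr$mean_icp, w$baseline_interval),
      icp_plateau = interval_mean(tr$mean_icp, w$plateau_interval),
      cbfv_baseline = interval_mean(tr$mean_cbfv, w$baseline_interval),
      cbfv_plateau = interval_mean(tr$mean_cbfv, w$plateau_interval),
      abp_baseline = interval_mean(tr$mean_abp, w$baseline_interval),
      abp_plateau = interval_mean(tr$mean_abp, w$plateau_interval))
  }
  if (length(di_all) == 0L) stop("no waves detected in any recording")
  di_records <- do.call(rbind, di_all)
  wave_table <- do.call(rbind, wave_rows)
  comparison <- compare_periods(di_records, pairing = pairing)
  per_wave <- comparison$per_wave
  wave_table <- merge(wave_table, per_wave, by = "wave_id", all.x = TRUE)

  summaries <- list()
  for (v in c("icp", "cbfv", "abp")) {
    for (per in c("baseline", "plateau")) {
      summaries[[paste(v, per, sep = "_")]] <-
        summarize_period(wave_table[[paste(v, per, sep = "_")]], per,
                         toupper(v))
    }
    summaries[[paste0(v, "_test")]] <- tryCatch(
      wilcoxon_signed_rank(wave_table[[paste0(v, "_baseline")]],
                           wave_table[[paste0(v, "_plateau")]]),
      error = function(e) NULL)
  }

  out <- structure(
    list(di_records = di_records, wave_table = wave_table,
         comparison = comparison, summaries = summaries,
         n_recordings = length(recordings),
         n_waves_detected = nrow(wave_table)),
    class = "cohort_analysis"
  )
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_results(di_records, comparison,
                  file.path(output_dir, "di_records"))
    utils::write.csv(wave_table, file.path(output_dir, "waves.csv"),
                     row.names = FALSE)
    build_report(wave_table, comparison,
                 config = list(n_recordings = length(recordings),
                               seed = seed, pairing = pairing),
                 path = file.path(output_dir, "report.txt"))
  }
  out
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat(sprintf("<cohort_analysis> %d/%d recordings with a detected wave, %d pulse pairs\n",
              x$n_waves_detected, x$n_recordings, nrow(x$di_records)))
  print(x$comparison)
  invisible(x)
}
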