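#' Read a multichannel recording from disk
#'
#' Two on-disk formats are supported. `"csv"` is the canonical
#' plain-text format: a column-name header line, a metadata comment
#' line `# fs=<Hz> units=<icp>,<abp>,<cbfv>`, then comma-separated
#' data ('.' decimal, UTF-8). An optional `time` column is validated
#' for uniformity (within 1\% of the sample interval) and discarded —
#' time is implicit. `"feather"` is the Arrow IPC container for long
#' recordings (one column per channel, `fs` and units in the schema
#' metadata); it requires the `arrow` package.
#'
#' @param path File path.
#' @param format_name `"csv"` or `"feather"`.
#' @return A [recording()].
#' @export
read_recording <- function(path, format_name = c("csv", "feather")) {
  format_name <- match.arg(format_name)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format_name == "csv") read_recording_csv(path) else read_recording_feather(path)
}

read_recording_csv <- function(path) {
  hdr <- readLines(path, n = 2L)
  cols <- strsplit(hdr[1], ",", fixed = TRUE)[[1]]
  meta <- hdr[2]
  if (!grepl("^#\\s*fs=", meta))
    stop("malformed metadata line (expected '# fs=... units=...'): ", meta)
  fs <- as.numeric(sub("^#\\s*fs=([0-9.eE+-]+).*$", "\\1", meta))
  units <- strsplit(sub("^.*units=([^ ]+).*$", "\\1", meta), ",")[[1]]
  dat <- utils::read.csv(path, skip = 2L, header = FALSE,
                         col.names = cols, colClasses = "numeric")
  for (ch in c("icp", "abp", "cbfv"))
    if (!ch %in% cols) stop("missing channel column: ", ch)
  if ("time" %in% cols) {
    dt <- diff(dat$time)
    if (any(abs(dt - 1 / fs) > 0.01 / fs))
      stop("time column is not uniform at the declared sampling rate")
    dat$time <- NULL
    units <- units[cols != "time"]
    cols <- cols[cols != "time"]
  }
  names(units) <- cols
  recording(
    icp = time_series(dat$icp, fs, units[["icp"]], "icp"),
    abp = time_series(dat$abp, fs, units[["abp"]], "abp"),
    cbfv = time_series(dat$cbfv, fs, units[["cbfv"]], "cbfv")
  )
}

read_recording_feather <- function(path) {
  if (!requireNamespace("arrow", quietly = TRUE))
    stop("the 'feather' container format requires the arrow package")
  tb <- arrow::read_feather(path, as_data_frame = FALSE)
  md <- tb$metadata
  fs <- as.numeric(md$fs)
  if (!length(fs) || !is.finite(fs)) stop("container lacks fs metadata")
  dat <- as.data.frame(tb)
  for (ch in c("icp", "abp", "cbfv"))
    if (!ch %in% names(dat)) stop("missing channel dataset: ", ch)
  recording(
    icp = time_series(dat$icp, fs, md$unit_icp %||% "mmHg", "icp"),
    abp = time_series(dat$abp, fs, md$unit_abp %||% "mmHg", "abp"),
    cbfv = time_series(dat$cbfv, fs, md$unit_cbfv %||% "cm/s", "cbfv")
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a multichannel recording to disk
#'
#' Inverse of [read_recording()]; see there for the formats. Refuses
#' to overwrite an existing file unless `overwrite = TRUE`.
#'
#' @param rec A [recording()].
#' @param path Output file path.
#' @param format_name `"csv"` or `"feather"`.
#' @param overwrite Logical.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format_name = c("csv", "feather"),
                            overwrite = FALSE) {
  format_name <- match.arg(format_name)
  stopifnot(inherits(rec, "recording"))
  if (length(rec$icp$samples) == 0L) stop("refusing to write an empty recording")
  if (file.exists(path) && !overwrite)
    stop("file exists (use overwrite = TRUE): ", path)
  if (format_name == "csv") {
    con <- file(path, open = "wt")
    on.exit(close(con))
    writeLines(c("icp,abp,cbfv",
                 sprintf("# fs=%.10g units=%s,%s,%s", rec$icp$fs,
                         rec$icp$unit, rec$abp$unit, rec$cbfv$unit)), con)
    utils::write.table(
      data.frame(icp = rec$icp$samples, abp = rec$abp$samples,
                 cbfv = rec$cbfv$samples),
      con, sep = ",", col.names = FALSE, row.names = FALSE)
  } else {
    if (!requireNamespace("arrow", quietly = TRUE))
      stop("the 'feather' container format requires the arrow package")
    tb <- arrow::arrow_table(
      data.frame(icp = rec$icp$samples, abp = rec$abp$samples,
                 cbfv = rec$cbfv$samples))
    tb$metadata <- list(fs = as.character(rec$icp$fs),
                        unit_icp = rec$icp$unit, unit_abp = rec$abp$unit,
                        unit_cbfv = rec$cbfv$unit)
    arrow::write_feather(tb, path)
  }
  invisible(path)
}

#' Write per-pulse DI records and the period comparison to disk
#'
#' Writes `<path>.csv` with one row per scored pulse pair (wave id,
#' period label, onset time, DI, samples compared) and `<path>.json`
#' with the period summaries and test result.
#'
#' @param di_records Data frame from [score_pairs()].
#' @param comparison A `period_comparison` from [compare_periods()].
#' @param path Output path stem (extensions are appended).
#' @return Character vector of the two file paths, invisibly.
#' @export
write_results <- function(di_records, comparison, path) {
  stopifnot(is.data.frame(di_records))
  if (nrow(di_records) == 0L) stop("no DI records to write")
  csv_path <- paste0(path, ".csv")
  json_path <- paste0(path, ".json")
  utils::write.csv(di_records, csv_path, row.names = FALSE)
  summ <- list(
    baseline = unclass(comparison$summaries$baseline),
    plateau = unclass(comparison$summaries$plateau),
    test = if (is.null(comparison$test)) NULL
           else unclass(comparison$test),
    pairing = comparison$pairing,
    alpha = comparison$alpha,
    significant = comparison$significant
  )
  jsonlite::write_json(summ, json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(csv_path, json_path))
}
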