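#' Median and quartile summary of a set of values
#'
#' Quartiles use linear interpolation between order statistics
#' (\code{\link[stats]{quantile}} type 7).
#'
#' @param values Numeric vector (finite, non-empty).
#' @param label Period label carried on the summary.
#' @param variable Name of the summarized variable.
#' @return A list of class `period_summary`: `median`, `q1`, `q3`,
#'   `n`, `period_label`, `variable`.
#' @export
summarize_period <- function(values, label = NA_character_,
                             variable = NA_character_) {
  if (length(values) == 0L) stop("no values to summarize")
  if (any(!is.finite(values))) stop("values must be finite")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  structure(list(median = q[2], q1 = q[1], q3 = q[3],
                 n = length(values), period_label = label,
                 variable = variable),
            class = "period_summary")
}

#' @export
print.period_summary <- function(x, ...) {
  cat(sprintf("%s [%s]: median %.3g (Q1-Q3 %.3g-%.3g), n = %d\n",
              x$variable, x$period_label, x$median, x$q1, x$q3, x$n))
  invisible(x)
}

#' Paired Wilcoxon signed-rank test
#'
#' Differences are `x - y`; zero differences are dropped (Wilcoxon's
#' original rule), absolute differences are ranked with average ranks
#' on ties, and the statistic `W` is the smaller of the positive- and
#' negative-rank sums. The two-sided p-value is exact — from the
#' signed-rank distribution, obtained by convolution across ranks —
#' whenever there are no ties and at most `exact_max` pairs remain;
#' otherwise a normal approximation with tie and continuity correction
#' is used.
#'
#' @param x,y Paired numeric vectors of equal length.
#' @param exact_max Largest n for which the exact null distribution is
#'   used (default 25).
#' @return A list of class `paired_test`: `statistic` (W), `p_value`,
#'   `n_pairs` (after zero removal), `method`.
#' @export
wilcoxon_signed_rank <- function(x, y, exact_max = 25) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n < 5L)
    stop("fewer than 5 non-zero differences; the signed-rank test is uninformative here")
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  w_neg <- sum(r[d < 0])
  w <- min(w_pos, w_neg)
  ties <- any(duplicated(abs(d)))
  if (!ties && n <= exact_max) {
    # exact two-sided p: by symmetry P(W+ >= M - w) = P(W+ <= w)
    p <- min(1, 2 * stats::psignrank(w, n))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- w_pos - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)   # continuity correction
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal-approximation"
  }
  structure(list(statistic = w, p_value = p, n_pairs = n, method = method),
            class = "paired_test")
}

#' @export
print.paired_test <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank: W = %g, n = %d, p = %.4g (%s)\n",
              x$statistic, x$n_pairs, x$p_value, x$method))
  invisible(x)
}

#' Compare baseline and plateau periods
#'
#' Summarizes the difference index per period and runs the paired
#' Wilcoxon signed-rank test. The default inference unit is the wave
#' (`pairing = "per_wave"`): each wave contributes its median DI per
#' period, and waves missing either period are excluded with a
#' warning. `pairing = "pooled"` pairs pulse-level values ranked by
#' onset order within period and is provided for exploration only —
#' pooled pulses from one wave are not independent (pseudo-replicated).
#'
#' @param di_records Data frame from [score_pairs()] (possibly several
#'   waves row-bound together).
#' @param pairing `"per_wave"` or `"pooled"`.
#' @param alpha Significance level (reported, not enforced).
#' @return List of class `period_comparison`: `summaries` (list of
#'   [summarize_period()] results for both periods), `per_wave` (data
#'   frame of per-wave medians), `test` (a `paired_test`), `pairing`,
#'   `alpha`, `significant`.
#' @export
compare_periods <- function(di_records, pairing = c("per_wave", "pooled"),
                            alpha = 0.05) {
  pairing <- match.arg(pairing)
  stopifnot(is.data.frame(di_records))
  if (nrow(di_records) == 0L) stop("no DI records")
  bl <- di_records[di_records$period_label == "baseline", ]
  pl <- di_records[di_records$period_label == "plateau", ]

  per_wave <- do.call(rbind, lapply(split(di_records, di_records$wave_id),
    function(dd) data.frame(
      wave_id = dd$wave_id[1],
      di_baseline = stats::median(dd$di[dd$period_label == "baseline"]),
      di_plateau = stats::median(dd$di[dd$period_label == "plateau"]),
      n_baseline = sum(dd$period_label == "baseline"),
      n_plateau = sum(dd$period_label == "plateau"))))
  rownames(per_wave) <- NULL
  incomplete <- !is.finite(per_wave$di_baseline) |
    !is.finite(per_wave$di_plateau) |
    per_wave$n_baseline == 0 | per_wave$n_plateau == 0
  if (any(incomplete)) {
    warning(sprintf("excluding %d wave(s) missing one period",
                    sum(incomplete)))
    per_wave <- per_wave[!incomplete, ]
  }

  test <- if (pairing == "per_wave") {
    tryCatch(
      wilcoxon_signed_rank(per_wave$di_baseline, per_wave$di_plateau),
      error = function(e) {
        warning("paired test skipped: ", conditionMessage(e))
        NULL
      })
  } else {
    nb <- min(nrow(bl), nrow(pl))
    bl_o <- bl[order(bl$wave_id, bl$onset_time), ]
    pl_o <- pl[order(pl$wave_id, pl$onset_time), ]
    wilcoxon_signed_rank(bl_o$di[seq_len(nb)], pl_o$di[seq_len(nb)])
  }
  structure(
    list(summaries = list(
           baseline = summarize_period(bl$di, "baseline", "DI"),
           plateau = summarize_period(pl$di, "plateau", "DI")),
         per_wave = per_wave, test = test, pairing = pairing,
         alpha = alpha,
         significant = if (is.null(test)) NA else test$p_value < alpha),
    class = "period_comparison"
  )
}

#' @export
print.period_comparison <- function(x, ...) {
  print(x$summaries$baseline)
  print(x$summaries$plateau)
  if (is.null(x$test)) cat("paired test skipped (too few waves)\n")
  else print(x$test)
  cat(sprintf("pairing: %s; significant at %.2g: %s\n", x$pairing,
              x$alpha, x$significant))
  invisible(x)
}

#' Render a plain-text analysis report
#'
#' Writes a deterministic, human-readable run report: configuration
#' echo, one row per wave (periods, mean physiological levels, DI
#' medians), period summaries and the paired test result.
#'
#' @param wave_table Data frame with one row per wave (as produced by
#'   [run_analysis()]).
#' @param comparison A `period_comparison`.
#' @param config List echoed into the report header.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
build_report <- function(wave_table, comparison, config, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("# ICP vs CaBV pulse-shape similarity report")
  w("")
  w("## Configuration")
  cfg <- unlist(config)
  for (nm in names(cfg)) w("- %s: %s", nm, cfg[[nm]])
  w("")
  w("## Waves")
  utils::write.table(format(wave_table, digits = 4), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  w("")
  w("## Difference index")
  for (s in comparison$summaries)
    w("- %s: median %.3f (Q1-Q3 %.3f-%.3f), n = %d", s$period_label,
      s$median, s$q1, s$q3, s$n)
  t <- comparison$test
  if (is.null(t)) {
    w("- paired test skipped (too few waves)")
  } else {
    w("- Wilcoxon signed-rank (%s): W = %g, n = %d, p = %.4g (%s)",
      comparison$pairing, t$statistic, t$n_pairs, t$p_value, t$method)
    w("- significant at alpha %.2g: %s", comparison$alpha,
      comparison$significant)
  }
  invisible(path)
}
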