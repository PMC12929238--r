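#' Compare effect-onset latencies between two groups
#'
#' One-shot analysis of a real or synthetic dataset: estimates the onset
#' latency of each group under the requested measures, forms the latency
#' difference (shifted minus baseline), runs the by-participant bootstrap
#' with all requested confidence-interval constructions, and runs the
#' participant-level permutation test.
#'
#' @param data a [gaze_table()], a binarized [bin_series()] result, or a
#'   [proportion_table()].
#' @param binning_cfg a [binning_config()]; used (and required) when `data`
#'   is a gaze table. With a `proportion_table`, the per-bin test switches to
#'   the relative-proportion t-test automatically.
#' @param latency_cfg a [latency_config()].
#' @param resampling_cfg a [resampling_config()].
#' @param measures latency measures to report (default: all four).
#' @param groups length-2 character vector `c(baseline, shifted)`; defaults
#'   to sorted group labels.
#' @param run_stratified additionally run the stratified bootstrap.
#' @return an object of class `latency_comparison`: list with `results` (the
#'   per-measure record data.frame of [run_simulation()] shape), `groups`,
#'   and the configs used.
#' @export
compare_onsets <- function(data, binning_cfg = binning_config(),
                           latency_cfg = latency_config(),
                           resampling_cfg = resampling_config(),
                           measures = latency_measures(), groups = NULL,
                           run_stratified = FALSE) {
  if (inherits(data, "gaze_table")) {
    data <- bin_series(data, binning_cfg)
  }
  if (inherits(data, "proportion_table")) {
    latency_cfg$bin_test <- "relative_proportion_ttest"
    u <- resolve_units(data)
    bcfg <- counts_bin_cfg(u$counts)
  } else {
    u <- resolve_units(data)
    bcfg <- counts_bin_cfg(u$counts) %||% binning_cfg
  }
  if (is.null(groups)) groups <- sort(unique(u$counts$group))
  if (!is.null(resampling_cfg$seed)) set.seed(resampling_cfg$seed)
  rcfg <- resampling_cfg
  rcfg$seed <- NULL
  res <- analyze_counts(u$counts, u$type, rcfg, latency_cfg, bcfg, measures,
                        groups, run_stratified = run_stratified)
  structure(list(results = res, groups = groups,
                 latency_cfg = latency_cfg, resampling_cfg = rcfg,
                 binning_cfg = bcfg),
            class = "latency_comparison")
}

#' @export
print.latency_comparison <- function(x, ...) {
  r <- x$results[x$results$scheme == "by_participant", , drop = FALSE]
  cat(sprintf("<latency_comparison> %s vs %s (shifted - baseline)\n",
              x$groups[2L], x$groups[1L]))
  ci_methods <- sub("^lower_", "", grep("^lower_", names(r), value = TRUE))
  for (i in seq_len(nrow(r))) {
    cat(sprintf("  %-22s onset %s: %g ms | %s: %g ms | diff %g ms%s | perm p = %.4g\n",
                r$measure[i], x$groups[1L], r$onset_baseline[i],
                x$groups[2L], r$onset_shifted[i], r$diff[i],
                if (r$censored[i]) " (censored)" else "", r$perm_p[i]))
    for (mtd in ci_methods) {
      cat(sprintf("      %-10s CI [%.1f, %.1f]\n", mtd,
                  r[[paste0("lower_", mtd)]][i], r[[paste0("upper_", mtd)]][i]))
    }
  }
  invisible(x)
}

#' Export comparison results as a tidy data.frame
#'
#' @param x a `latency_comparison`.
#' @param ... unused.
#' @return the underlying record data.frame.
#' @export
as.data.frame.latency_comparison <- function(x, ...) {
  as.data.frame(x$results)
}
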