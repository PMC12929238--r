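#' Latency measure configuration
#'
#' Chooses the onset-latency measure and its parameters. Four measures are
#' supported:
#' \describe{
#'   \item{`consecutive`}{first of `k_consecutive` consecutive bins with a
#'     significant positive effect.}
#'   \item{`consecutive_threshold`}{as above, and every bin of the run must
#'     additionally exceed the effect-size threshold.}
#'   \item{`holm`}{first bin significant after Holm-Bonferroni correction
#'     with a positive effect.}
#'   \item{`holm_threshold`}{as above, and that bin must exceed the
#'     effect-size threshold.}
#' }
#' The effect-size threshold is 0.2 log-odds (about 55% target probability)
#' for the pooled logistic per-bin test, and a 0.03 raw proportion difference
#' (competitor minus unrelated) for the relative-proportion t-test.
#'
#' @param measure one of `"consecutive"`, `"consecutive_threshold"`,
#'   `"holm"`, `"holm_threshold"`.
#' @param k_consecutive run length `k` for the consecutive-bins measures
#'   (default 5).
#' @param alpha per-bin significance level (default 0.05).
#' @param logodds_threshold effect-size threshold on the log-odds scale
#'   (default 0.2).
#' @param prop_diff_threshold effect-size threshold on the raw proportion
#'   difference scale (default 0.03).
#' @param bin_test `"pooled_logistic"` (trial-level binary data) or
#'   `"relative_proportion_ttest"` (participant-level proportion data).
#' @return an object of class `latency_config`.
#' @export
latency_config <- function(measure = "consecutive_threshold",
                           k_consecutive = 5L, alpha = 0.05,
                           logodds_threshold = 0.2,
                           prop_diff_threshold = 0.03,
                           bin_test = "pooled_logistic") {
  measure <- match.arg(measure, c("consecutive", "consecutive_threshold",
                                  "holm", "holm_threshold"))
  bin_test <- match.arg(bin_test,
                        c("pooled_logistic", "relative_proportion_ttest"))
  stopifnot(alpha > 0, alpha < 1, k_consecutive >= 1,
            logodds_threshold >= 0, prop_diff_threshold >= 0)
  structure(list(measure = measure, k_consecutive = as.integer(k_consecutive),
                 alpha = alpha, logodds_threshold = logodds_threshold,
                 prop_diff_threshold = prop_diff_threshold,
                 bin_test = bin_test),
            class = "latency_config")
}

#' All four latency measures
#' @return character vector of the four measure names.
#' @export
latency_measures <- function() {
  c("consecutive", "consecutive_threshold", "holm", "holm_threshold")
}

#' Pooled logistic per-bin test
#'
#' Intercept-only logistic regression of the pooled trial-level binary target
#' indicators of one group in one bin. With `s` successes out of `n`, the
#' maximum-likelihood intercept is `b = log(phat / (1 - phat))` with Wald
#' standard error `1 / sqrt(n * phat * (1 - phat))`; a two-sided Wald test
#' against 0 (chance looking) gives the p-value. Under complete separation
#' (`s = 0` or `s = n`), where the Wald statistic collapses, an exact
#' two-sided binomial test against 0.5 is used instead, with the estimate
#' reported as +/-Inf and the threshold criterion passed only when `s = n`.
#'
#' @param values binary vector (one group x bin), or alternatively pass
#'   `s` and `n` directly.
#' @param alpha significance level.
#' @param logodds_threshold effect-size threshold on the log-odds scale.
#' @param s,n optional success/total counts replacing `values`.
#' @return a one-row `data.frame`: `estimate` (log-odds), `se`, `n_obs`,
#'   `p_value`, `positive`, `significant_positive`, `exceeds_threshold`.
#' @export
pooled_logistic_bin_test <- function(values = NULL, alpha = 0.05,
                                     logodds_threshold = 0.2,
                                     s = NULL, n = NULL) {
  if (is.null(s)) {
    if (!all(values %in% c(0, 1))) {
      stop("pooled_logistic_bin_test: values must be binary", call. = FALSE)
    }
    s <- sum(values)
    n <- length(values)
  }
  r <- logistic_bin_tests(s, n, alpha, logodds_threshold)
  data.frame(estimate = r$estimate, se = r$se, n_obs = n, p_value = r$p_value,
             positive = r$positive, significant_positive = r$significant,
             exceeds_threshold = r$exceeds)
}

# vectorized over bins: s, n integer vectors
logistic_bin_tests <- function(s, n, alpha, logodds_threshold) {
  m <- length(s)
  est <- rep(NA_real_, m); se <- rep(NA_real_, m)
  p <- rep(1, m)
  sep <- n > 0 & (s == 0L | s == n)
  ok <- n > 0 & !sep
  ph <- s[ok] / n[ok]
  est[ok] <- log(ph / (1 - ph))
  se[ok] <- 1 / sqrt(n[ok] * ph * (1 - ph))
  p[ok] <- 2 * stats::pnorm(-abs(est[ok] / se[ok]))
  # separation: exact binomial two-sided tail vs 0.5 is 2 * 0.5^n
  est[sep] <- ifelse(s[sep] == n[sep], Inf, -Inf)
  p[sep] <- pmin(1, 2 * 0.5^n[sep])
  positive <- !is.na(est) & est > 0
  list(
    estimate = est, se = se, p_value = p, positive = positive,
    significant = p < alpha & positive,
    exceeds = ifelse(sep, s == n,
                     ifelse(is.na(est), FALSE, est > logodds_threshold))
  )
}

#' Relative-proportion per-bin t-test
#'
#' One-sample t-test of participant-level relative competitor proportions
#' (competitor / (competitor + unrelated)) against 0.5 in one bin, for
#' pre-averaged proportion data without trial-level records. Participants for
#' whom the relative proportion is undefined in the bin (both proportions 0)
#' are excluded. The effect-size threshold is on the raw difference scale:
#' the mean of competitor minus unrelated proportions must exceed
#' `prop_diff_threshold`.
#'
#' @param rel participant-level relative proportions for the bin (NA =
#'   undefined, excluded).
#' @param diff participant-level raw differences `p_competitor - p_unrelated`
#'   for the same bin.
#' @param alpha significance level.
#' @param prop_diff_threshold threshold on the mean raw difference.
#' @return a one-row `data.frame` as in [pooled_logistic_bin_test()], with
#'   `estimate` the mean relative proportion.
#' @export
relative_proportion_bin_test <- function(rel, diff = NULL, alpha = 0.05,
                                         prop_diff_threshold = 0.03) {
  if (is.null(diff)) diff <- rep(NA_real_, length(rel))
  r <- ttest_bin_tests(matrix(rel, ncol = 1), matrix(diff, ncol = 1),
                       alpha, prop_diff_threshold)
  data.frame(estimate = r$estimate, se = r$se, n_obs = r$n_obs,
             p_value = r$p_value, positive = r$positive,
             significant_positive = r$significant,
             exceeds_threshold = r$exceeds)
}

# vectorized over bins: rel, dif are participant x bin matrices
ttest_bin_tests <- function(rel, dif, alpha, prop_diff_threshold) {
  nn <- colSums(!is.na(rel))
  mu <- colMeans(rel, na.rm = TRUE)
  sd <- apply(rel, 2L, stats::sd, na.rm = TRUE)
  mu[nn == 0] <- NA_real_
  se <- sd / sqrt(nn)
  tstat <- (mu - 0.5) / se
  p <- rep(1, length(nn))
  ok <- nn >= 2 & !is.na(sd) & sd > 0
  p[ok] <- 2 * stats::pt(-abs(tstat[ok]), df = nn[ok] - 1)
  # zero variance: degenerate, never significant
  positive <- !is.na(mu) & mu > 0.5
  mdif <- colMeans(dif, na.rm = TRUE)
  list(
    estimate = mu, se = se, n_obs = nn, p_value = p, positive = positive,
    significant = ok & p < alpha & positive,
    exceeds = !is.na(mdif) & mdif > prop_diff_threshold
  )
}

#' Holm-Bonferroni step-down rejections
#'
#' Family-wise error control over the `m` bins of the ROI: sort p-values
#' ascending and reject while `p_(i) <= alpha / (m - i + 1)`. Implemented via
#' the monotone adjusted p-values of `stats::p.adjust(method = "holm")`
#' (rejection iff adjusted p <= alpha, which is equivalent to the step-down
#' rule); ties are handled stably in bin order.
#'
#' @param p_values vector of raw p-values, one per bin.
#' @param alpha family-wise error level.
#' @return logical rejection flags, same length/order as `p_values`.
#' @export
holm_correct <- function(p_values, alpha = 0.05) {
  stopifnot(length(p_values) >= 1, all(p_values >= 0 & p_values <= 1))
  stats::p.adjust(p_values, method = "holm") <= alpha
}

#' Estimate onset latency from per-bin test results
#'
#' Scans the ordered per-bin results for the first bin satisfying the
#' configured measure and returns its start time as the onset latency. When
#' no bin qualifies the estimate is censored at the ROI end (`roi_end_ms`),
#' which keeps resampling distributions at full length; the censoring flag is
#' carried through all downstream summaries.
#'
#' @param bins a `data.frame` of per-bin results covering bins
#'   `0..m-1` in order, with columns `p_value`, `positive`,
#'   `significant_positive`, `exceeds_threshold` (missing bins count as not
#'   significant with p = 1).
#' @param cfg a [latency_config()].
#' @param bin_cfg a [binning_config()] giving ROI geometry, or a list with
#'   `roi_start_ms`, `bin_width_ms`, `n_bins`, `roi_end_ms`.
#' @param group optional group label carried into the result.
#' @return an object of class `latency_estimate`: list with `group`,
#'   `measure`, `latency_ms`, `censored`, `source_bin_index`.
#' @export
estimate_latency <- function(bins, cfg, bin_cfg, group = NA_character_) {
  m <- bin_cfg$n_bins
  p <- rep(1, m); sig <- rep(FALSE, m); exc <- rep(FALSE, m)
  pos <- rep(FALSE, m)
  idx <- bins$bin_index + 1L
  p[idx] <- bins$p_value
  sig[idx] <- bins$significant_positive
  exc[idx] <- bins$exceeds_threshold
  pos[idx] <- bins$positive
  bin <- scan_onset_bin(p, sig, exc, pos, cfg)
  new_latency_estimate(bin, cfg$measure, bin_cfg, group)
}

# onset bin (0-based) or NA from vectorized per-bin flags
scan_onset_bin <- function(p, sig, exc, pos, cfg) {
  m <- length(p)
  if (cfg$measure %in% c("consecutive", "consecutive_threshold")) {
    flags <- sig
    if (cfg$measure == "consecutive_threshold") flags <- flags & exc
    k <- cfg$k_consecutive
    if (m < k) return(NA_integer_)
    if (k == 1L) {
      w <- which(flags)
      return(if (length(w)) w[1L] - 1L else NA_integer_)
    }
    run <- cumsum(as.numeric(flags))
    wsum <- run[k:m] - c(0, run)[1:(m - k + 1L)]
    w <- which(wsum == k)
    if (length(w)) w[1L] - 1L else NA_integer_
  } else {
    rej <- holm_correct(p, cfg$alpha) & pos
    if (cfg$measure == "holm_threshold") rej <- rej & exc
    w <- which(rej)
    if (length(w)) w[1L] - 1L else NA_integer_
  }
}

new_latency_estimate <- function(bin, measure, bin_cfg, group) {
  censored <- is.na(bin)
  structure(list(
    group = group, measure = measure,
    latency_ms = if (censored) bin_cfg$roi_end_ms else
      bin_cfg$roi_start_ms + bin * bin_cfg$bin_width_ms,
    censored = censored,
    source_bin_index = if (censored) NA_integer_ else as.integer(bin)
  ), class = "latency_estimate")
}

#' @export
print.latency_estimate <- function(x, ...) {
  cat(sprintf("<latency_estimate> group %s | %s | %s ms%s\n",
              x$group, x$measure, format(x$latency_ms),
              if (x$censored) " (censored at ROI end)" else ""))
  invisible(x)
}

#' Latency difference between groups
#'
#' Difference in onset latency, shifted minus baseline. Censored latencies
#' enter at the ROI end; the result carries a flag when either operand was
#' censored.
#'
#' @param shifted,baseline [estimate_latency()] results under the same
#'   measure.
#' @return numeric difference in ms with attribute `censored` (logical).
#' @export
latency_difference <- function(shifted, baseline) {
  if (!identical(shifted$measure, baseline$measure)) {
    stop("latency_difference: measures differ", call. = FALSE)
  }
  structure(shifted$latency_ms - baseline$latency_ms,
            censored = shifted$censored || baseline$censored)
}

# ---- fast group-level pipeline --------------------------------------------

# Pooled per-bin tests for one group from count matrices; rows selects
# participant rows (with multiplicity under bootstrap, implementing clone
# reweighting by construction).
group_bin_tests_counts <- function(counts, rows, cfg) {
  s <- colSums(counts$s[rows, , drop = FALSE])
  n <- colSums(counts$n[rows, , drop = FALSE])
  logistic_bin_tests(s, n, cfg$alpha, cfg$logodds_threshold)
}

group_bin_tests_props <- function(props, rows, cfg) {
  ttest_bin_tests(props$rel[rows, , drop = FALSE],
                  props$dif[rows, , drop = FALSE],
                  cfg$alpha, cfg$prop_diff_threshold)
}

# onset bins (0-based, NA = censored) for several measures at once,
# sharing the per-bin tests
onset_bins_multi <- function(tests, cfg, measures) {
  vapply(measures, function(ms) {
    cfg$measure <- ms
    scan_onset_bin(tests$p_value, tests$significant, tests$exceeds,
                   tests$positive, cfg)
  }, integer(1))
}

# latency differences (shifted - baseline) for several measures; censored
# onsets mapped to roi_end. Returns list(diff = named numeric, censored =
# named logical).
latency_diffs_multi <- function(tests_shift, tests_base, cfg, bin_cfg,
                                measures) {
  b1 <- onset_bins_multi(tests_shift, cfg, measures)
  b0 <- onset_bins_multi(tests_base, cfg, measures)
  to_ms <- function(b) ifelse(is.na(b), bin_cfg$roi_end_ms,
                              bin_cfg$roi_start_ms + b * bin_cfg$bin_width_ms)
  list(diff = to_ms(b1) - to_ms(b0), censored = is.na(b1) | is.na(b0),
       onset_shifted = to_ms(b1), onset_baseline = to_ms(b0))
}
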