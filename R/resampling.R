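#' Resampling configuration
#'
#' Parameters of the bootstrap and permutation procedures: the number of
#' bootstrap resamples `B` (2000 by default) and permutations `P` (1000 by
#' default), the confidence level, the interval constructions to compute, the
#' bootstrap scheme, and whether resampling is stratified by condition
#' (preserving per-condition participant counts, as in condition-balanced
#' word-recognition designs).
#'
#' @param n_bootstrap number of bootstrap resamples `B` (default 2000).
#' @param n_permutation number of permutations `P` (default 1000).
#' @param ci_level confidence level (default 0.95).
#' @param ci_methods subset of `"percentile"`, `"normal"`, `"empirical"`,
#'   `"bc"`, `"bca"`.
#' @param bootstrap_scheme `"by_participant"` (resample whole participants
#'   within groups) or `"stratified"` (resample trial values within
#'   group x participant x bin strata).
#' @param stratify_by_condition resample within condition strata.
#' @param seed optional integer seed.
#' @return an object of class `resampling_config`.
#' @export
resampling_config <- function(n_bootstrap = 2000L, n_permutation = 1000L,
                              ci_level = 0.95,
                              ci_methods = c("percentile", "normal",
                                             "empirical", "bc", "bca"),
                              bootstrap_scheme = "by_participant",
                              stratify_by_condition = FALSE, seed = NULL) {
  stopifnot(n_bootstrap >= 1, n_permutation >= 1,
            ci_level > 0, ci_level < 1)
  ci_methods <- match.arg(ci_methods,
                          c("percentile", "normal", "empirical", "bc", "bca"),
                          several.ok = TRUE)
  bootstrap_scheme <- match.arg(bootstrap_scheme,
                                c("by_participant", "stratified"))
  structure(list(n_bootstrap = as.integer(n_bootstrap),
                 n_permutation = as.integer(n_permutation),
                 ci_level = ci_level, ci_methods = ci_methods,
                 bootstrap_scheme = bootstrap_scheme,
                 stratify_by_condition = stratify_by_condition, seed = seed),
            class = "resampling_config")
}

new_resample_distribution <- function(values, kind, censored_fraction,
                                      observed = NULL, measures = NULL) {
  structure(list(values = values, kind = kind,
                 censored_fraction = censored_fraction,
                 observed = observed, measures = measures),
            class = "resample_distribution")
}

#' @export
print.resample_distribution <- function(x, ...) {
  cat(sprintf("<resample_distribution> %s | %d draws | measures: %s\n",
              x$kind, nrow(x$values), paste(colnames(x$values), collapse = ", ")))
  cat("censored fraction:",
      paste(sprintf("%s=%.3f", names(x$censored_fraction),
                    x$censored_fraction), collapse = ", "), "\n")
  invisible(x)
}

#' Extract resampled values for one measure
#' @param dist a `resample_distribution`.
#' @param measure measure name; defaults to the first column.
#' @return numeric vector of length B (or P).
#' @export
resample_values <- function(dist, measure = NULL) {
  if (is.null(measure)) measure <- colnames(dist$values)[1L]
  dist$values[, measure]
}

# resample participant row indices for one group, with replacement,
# within condition strata when requested
draw_group_rows <- function(rows, condition, stratify) {
  if (!stratify) return(rows[sample.int(length(rows), replace = TRUE)])
  unlist(lapply(split(rows, condition[rows]), function(r) {
    r[sample.int(length(r), replace = TRUE)]
  }), use.names = FALSE)
}

resolve_units <- function(data, n_bins = NULL) {
  if (inherits(data, "binned_series")) {
    list(counts = participant_bin_counts(data, n_bins), type = "counts")
  } else if (inherits(data, "proportion_table")) {
    list(counts = participant_bin_props(data, n_bins), type = "props")
  } else if (is.list(data) && !is.null(data$s)) {
    list(counts = data, type = "counts")
  } else if (is.list(data) && !is.null(data$rel)) {
    list(counts = data, type = "props")
  } else stop("unsupported data type for resampling", call. = FALSE)
}

tests_fun_for <- function(type) {
  if (type == "counts") group_bin_tests_counts else group_bin_tests_props
}

#' By-participant bootstrap of the latency difference
#'
#' Draws, `B` times, `n` participants per group with replacement (all of a
#' drawn participant's trials are carried along, so within-participant and
#' within-trial dependencies are preserved), re-estimates the onset latency
#' of each group and their difference on every resample, and returns the
#' bootstrap distribution. Participants drawn more than once enter the pooled
#' per-bin counts with their multiplicity, which is the correct clone
#' weighting. With `cfg$stratify_by_condition`, draws are made within each
#' condition stratum, preserving per-condition counts.
#'
#' @param data a binarized `binned_series`, a `proportion_table`, or the
#'   count structure from [participant_bin_counts()].
#' @param cfg a [resampling_config()].
#' @param latency_cfg a [latency_config()].
#' @param bin_cfg a [binning_config()] (taken from `data` when attached).
#' @param measures measures to evaluate per resample (default: the one in
#'   `latency_cfg`).
#' @param groups length-2 character vector `c(baseline, shifted)`; defaults
#'   to the sorted group labels.
#' @return a `resample_distribution` with a `B x length(measures)` value
#'   matrix of latency differences (shifted minus baseline, ms).
#' @export
bootstrap_by_participant <- function(data, cfg, latency_cfg,
                                     bin_cfg = NULL, measures = NULL,
                                     groups = NULL) {
  u <- resolve_units(data)
  counts <- u$counts
  if (is.null(bin_cfg)) bin_cfg <- counts_bin_cfg(counts)
  if (is.null(measures)) measures <- latency_cfg$measure
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  gs <- resolve_groups(counts, groups)
  tests_fun <- tests_fun_for(u$type)
  B <- cfg$n_bootstrap
  vals <- matrix(NA_real_, B, length(measures),
                 dimnames = list(NULL, measures))
  cens <- matrix(FALSE, B, length(measures))
  for (b in seq_len(B)) {
    r0 <- draw_group_rows(gs$base_rows, counts$condition,
                          cfg$stratify_by_condition)
    r1 <- draw_group_rows(gs$shift_rows, counts$condition,
                          cfg$stratify_by_condition)
    d <- latency_diffs_multi(tests_fun(counts, r1, latency_cfg),
                             tests_fun(counts, r0, latency_cfg),
                             latency_cfg, bin_cfg, measures)
    vals[b, ] <- d$diff
    cens[b, ] <- d$censored
  }
  new_resample_distribution(vals, "bootstrap", stats::setNames(colMeans(cens), measures),
                            measures = measures)
}

#' Stratified bootstrap of the latency difference
#'
#' Keeps every participant in every resample and instead resamples, within
#' each (group, participant, bin) stratum of `m` trial-level binary values,
#' `m` values with replacement, independently across strata. This breaks the
#' within-trial autocorrelation of the gaze time series and does not
#' re-weight participants, which is why its false-positive behaviour differs
#' from the by-participant scheme under inter-participant timing variability.
#' Because all downstream statistics depend on the data only through stratum
#' success counts, the stratum draw is performed as the distributionally
#' exact Binomial(m, s/m) draw on the count.
#'
#' @inheritParams bootstrap_by_participant
#' @return a `resample_distribution` as in [bootstrap_by_participant()].
#' @export
bootstrap_stratified <- function(data, cfg, latency_cfg, bin_cfg = NULL,
                                 measures = NULL, groups = NULL) {
  u <- resolve_units(data)
  if (u$type != "counts") {
    stop("bootstrap_stratified: requires trial-level binary data", call. = FALSE)
  }
  counts <- u$counts
  if (is.null(bin_cfg)) bin_cfg <- counts_bin_cfg(counts)
  if (is.null(measures)) measures <- latency_cfg$measure
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  gs <- resolve_groups(counts, groups)
  B <- cfg$n_bootstrap
  vals <- matrix(NA_real_, B, length(measures),
                 dimnames = list(NULL, measures))
  cens <- matrix(FALSE, B, length(measures))
  n <- counts$n
  prob <- ifelse(n > 0, counts$s / pmax(n, 1L), 0)
  cs <- counts
  for (b in seq_len(B)) {
    cs$s <- matrix(stats::rbinom(length(n), as.vector(n), as.vector(prob)),
                   nrow = nrow(n))
    d <- latency_diffs_multi(
      group_bin_tests_counts(cs, gs$shift_rows, latency_cfg),
      group_bin_tests_counts(cs, gs$base_rows, latency_cfg),
      latency_cfg, bin_cfg, measures)
    vals[b, ] <- d$diff
    cens[b, ] <- d$censored
  }
  new_resample_distribution(vals, "bootstrap", stats::setNames(colMeans(cens), measures),
                            measures = measures)
}

#' Participant-level permutation test of the latency difference
#'
#' Re-assigns whole participants to the two groups at random `P` times
#' (within condition strata when `cfg$stratify_by_condition`), recomputes the
#' latency difference on each permuted dataset to build the null
#' distribution, and reports the two-sided p-value as the plain proportion of
#' null values with absolute value at least as large as the observed
#' difference.
#'
#' @inheritParams bootstrap_by_participant
#' @return a `resample_distribution` of kind `"permutation_null"`, with
#'   `observed` (named numeric, per measure) and `p_value` components.
#' @export
permutation_test <- function(data, cfg, latency_cfg, bin_cfg = NULL,
                             measures = NULL, groups = NULL) {
  u <- resolve_units(data)
  counts <- u$counts
  if (is.null(bin_cfg)) bin_cfg <- counts_bin_cfg(counts)
  if (is.null(measures)) measures <- latency_cfg$measure
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  gs <- resolve_groups(counts, groups)
  tests_fun <- tests_fun_for(u$type)
  stat <- function(r1, r0) {
    latency_diffs_multi(tests_fun(counts, r1, latency_cfg),
                        tests_fun(counts, r0, latency_cfg),
                        latency_cfg, bin_cfg, measures)
  }
  obs <- stat(gs$shift_rows, gs$base_rows)
  all_rows <- c(gs$base_rows, gs$shift_rows)
  n_base <- length(gs$base_rows)
  P <- cfg$n_permutation
  vals <- matrix(NA_real_, P, length(measures),
                 dimnames = list(NULL, measures))
  cens <- matrix(FALSE, P, length(measures))
  strata <- if (cfg$stratify_by_condition) {
    split(all_rows, counts$condition[all_rows])
  } else list(all_rows)
  n_base_per <- if (cfg$stratify_by_condition) {
    vapply(split(gs$base_rows, counts$condition[gs$base_rows]), length,
           integer(1))[names(strata)]
  } else n_base
  for (p in seq_len(P)) {
    base_p <- integer(0); shift_p <- integer(0)
    for (k in seq_along(strata)) {
      rows_k <- strata[[k]]
      pick <- sample.int(length(rows_k), n_base_per[[k]])
      base_p <- c(base_p, rows_k[pick])
      shift_p <- c(shift_p, rows_k[-pick])
    }
    d <- stat(shift_p, base_p)
    vals[p, ] <- d$diff
    cens[p, ] <- d$censored
  }
  pval <- vapply(measures, function(ms) {
    mean(abs(vals[, ms]) >= abs(obs$diff[[ms]]))
  }, numeric(1))
  out <- new_resample_distribution(vals, "permutation_null", stats::setNames(colMeans(cens), measures),
                                   observed = obs$diff, measures = measures)
  out$p_value <- pval
  out$observed_censored <- obs$censored
  out
}

resolve_groups <- function(counts, groups) {
  glab <- counts$group
  if (is.null(groups)) groups <- sort(unique(glab))
  if (length(groups) != 2L) {
    stop("resampling: exactly two groups required", call. = FALSE)
  }
  base_rows <- which(glab == groups[1L])
  shift_rows <- which(glab == groups[2L])
  if (!length(base_rows) || !length(shift_rows)) {
    stop("resampling: a group has no participants", call. = FALSE)
  }
  list(base_rows = base_rows, shift_rows = shift_rows, groups = groups)
}

counts_bin_cfg <- function(counts) {
  if (!is.null(counts$config)) return(counts$config)
  # proportion-table path: geometry from bin starts
  starts <- counts$bin_start_ms
  width <- if (length(starts) > 1) starts[2L] - starts[1L] else 1
  list(roi_start_ms = starts[1L], bin_width_ms = width,
       n_bins = length(starts), roi_end_ms = starts[length(starts)] + width)
}

#' Bootstrap confidence interval
#'
#' Computes one of five interval constructions from a bootstrap distribution
#' of the latency difference:
#' \describe{
#'   \item{percentile}{empirical `alpha/2` and `1 - alpha/2` quantiles.}
#'   \item{normal}{`observed - bias +/- z * sd(boot)` with
#'     `bias = mean(boot) - observed`.}
#'   \item{empirical}{(basic / backwards percentile)
#'     `[2 * observed - q(1 - alpha/2), 2 * observed - q(alpha/2)]`.}
#'   \item{bc}{bias-corrected: `z0 = qnorm(#\{boot < observed\} / B)`,
#'     bounds at the `pnorm(2 * z0 +/- z)` quantiles.}
#'   \item{bca}{accelerated bias-corrected: additionally uses the jackknife
#'     acceleration `a = sum((mean(j) - j)^3) / (6 * sum((mean(j) - j)^2)^1.5)`
#'     over leave-one-participant-out statistics `j`.}
#' }
#' Quantiles use linear interpolation of order statistics (`type = 7`). A
#' constant bootstrap distribution yields the zero-width interval at that
#' value for every method. When all bootstrap values fall on one side of the
#' observed value, `z0` is clamped to `+/- qnorm(1 / (B + 1))` and the result
#' flagged in the diagnostics.
#'
#' @param dist a `resample_distribution` or numeric vector of bootstrap
#'   values.
#' @param observed observed statistic (ms).
#' @param method one of `"percentile"`, `"normal"`, `"empirical"`, `"bc"`,
#'   `"bca"`.
#' @param level confidence level (default 0.95).
#' @param jackknife_values leave-one-participant-out statistics, required for
#'   `"bca"`.
#' @param measure measure column when `dist` is a `resample_distribution`.
#' @return an object of class `interval_result`: list with `method`,
#'   `lower_ms`, `upper_ms`, and `diagnostics` (z0, a, boot_mean, boot_sd,
#'   z0_clamped).
#' @export
bootstrap_ci <- function(dist, observed, method = "percentile", level = 0.95,
                         jackknife_values = NULL, measure = NULL) {
  boot <- if (inherits(dist, "resample_distribution")) {
    resample_values(dist, measure)
  } else as.numeric(dist)
  method <- match.arg(method,
                      c("percentile", "normal", "empirical", "bc", "bca"))
  if (!length(boot)) stop("bootstrap_ci: empty distribution", call. = FALSE)
  alpha <- 1 - level
  bm <- mean(boot)
  bs <- if (length(boot) > 1) stats::sd(boot) else 0
  z0 <- NA_real_; a <- NA_real_; clamped <- FALSE
  if (bs == 0) {
    return(new_interval(method, boot[1L], boot[1L], z0, a, bm, 0, clamped))
  }
  q <- function(g) as.numeric(stats::quantile(boot, g, type = 7, names = FALSE))
  zc <- stats::qnorm(1 - alpha / 2)
  if (method == "percentile") {
    lo <- q(alpha / 2); hi <- q(1 - alpha / 2)
  } else if (method == "normal") {
    bias <- bm - observed
    lo <- observed - bias - zc * bs
    hi <- observed - bias + zc * bs
  } else if (method == "empirical") {
    lo <- 2 * observed - q(1 - alpha / 2)
    hi <- 2 * observed - q(alpha / 2)
  } else {
    B <- length(boot)
    frac <- sum(boot < observed) / B
    if (frac <= 0 || frac >= 1) {
      # qnorm(1 / (B + 1)) is negative: frac = 0 clamps low, frac = 1 high
      z0 <- if (frac <= 0) stats::qnorm(1 / (B + 1)) else
        -stats::qnorm(1 / (B + 1))
      clamped <- TRUE
    } else z0 <- stats::qnorm(frac)
    if (method == "bca") {
      if (is.null(jackknife_values)) {
        stop("bootstrap_ci: bca requires jackknife_values", call. = FALSE)
      }
      jm <- mean(jackknife_values)
      d <- jm - jackknife_values
      denom <- sum(d^2)^1.5
      a <- if (denom == 0) 0 else sum(d^3) / (6 * denom)
    } else a <- 0
    adj <- function(z) {
      zz <- z0 + (z0 + z) / (1 - a * (z0 + z))
      stats::pnorm(zz)
    }
    lo <- q(adj(-zc)); hi <- q(adj(zc))
  }
  new_interval(method, lo, hi, z0, a, bm, bs, clamped)
}

new_interval <- function(method, lo, hi, z0, a, bm, bs, clamped) {
  structure(list(method = method, lower_ms = min(lo, hi),
                 upper_ms = max(lo, hi),
                 diagnostics = list(z0 = z0, a = a, boot_mean = bm,
                                    boot_sd = bs, z0_clamped = clamped)),
            class = "interval_result")
}

#' @export
print.interval_result <- function(x, ...) {
  cat(sprintf("<interval_result> %s: [%.1f, %.1f] ms\n",
              x$method, x$lower_ms, x$upper_ms))
  invisible(x)
}

#' Leave-one-participant-out jackknife of the latency difference
#'
#' Recomputes the latency difference with each participant left out in turn
#' (from their own group, the other group untouched). The participant is the
#' resampling unit, so the jackknife for the BCa acceleration is taken over
#' participants, not observations.
#'
#' @inheritParams bootstrap_by_participant
#' @return numeric vector, one statistic per left-out participant, for the
#'   requested `measures` (matrix with one column per measure).
#' @export
jackknife_latency_diff <- function(data, latency_cfg, bin_cfg = NULL,
                                   measures = NULL, groups = NULL) {
  u <- resolve_units(data)
  counts <- u$counts
  if (is.null(bin_cfg)) bin_cfg <- counts_bin_cfg(counts)
  if (is.null(measures)) measures <- latency_cfg$measure
  gs <- resolve_groups(counts, groups)
  tests_fun <- tests_fun_for(u$type)
  all_rows <- c(gs$base_rows, gs$shift_rows)
  out <- matrix(NA_real_, length(all_rows), length(measures),
                dimnames = list(counts$participants[all_rows], measures))
  for (i in seq_along(all_rows)) {
    drop <- all_rows[i]
    r0 <- setdiff(gs$base_rows, drop)
    r1 <- setdiff(gs$shift_rows, drop)
    d <- latency_diffs_multi(tests_fun(counts, r1, latency_cfg),
                             tests_fun(counts, r0, latency_cfg),
                             latency_cfg, bin_cfg, measures)
    out[i, ] <- d$diff
  }
  out
}

#' Wilson score interval for a binomial proportion
#'
#' Used for power and Type I error estimates over `n_sims` simulations.
#'
#' @param successes number of successes (vectorized).
#' @param trials number of trials (>= 1).
#' @param level confidence level (default 0.95).
#' @return a data.frame with columns `estimate`, `lower`, `upper`.
#' @export
wilson_interval <- function(successes, trials, level = 0.95) {
  if (any(trials < 1)) stop("wilson_interval: trials must be >= 1", call. = FALSE)
  stopifnot(all(successes >= 0), all(successes <= trials))
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- successes / trials
  denom <- 1 + z^2 / trials
  center <- (p + z^2 / (2 * trials)) / denom
  half <- z * sqrt(p * (1 - p) / trials + z^2 / (4 * trials^2)) / denom
  data.frame(estimate = p, lower = pmax(0, center - half),
             upper = pmin(1, center + half))
}
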