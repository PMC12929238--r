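#' Binning configuration
#'
#' Defines the analysis region of interest (ROI) and how raw gaze samples are
#' reduced to per-trial bin values. The ROI starts at cue onset plus a saccade
#' execution offset (200 ms by default) and is divided into `m` fixed-width
#' bins. Samples on excluded AOIs (whitespace by default) are removed before
#' the per-bin target proportion is computed; proportions are then optionally
#' binarized (>= 0.5 becomes 1).
#'
#' @param roi_start_ms ROI start, ms relative to cue onset. Defaults to
#'   `saccade_offset_ms`.
#' @param roi_end_ms ROI end; `roi_end_ms - roi_start_ms` must be an integer
#'   multiple of `bin_width_ms`.
#' @param bin_width_ms bin width in ms (> 0); 50 ms by default.
#' @param saccade_offset_ms offset added to both ROI boundaries to account
#'   for saccade execution time (default 200 ms).
#' @param target_aoi label counted as the effect of interest.
#' @param exclude_aois labels removed before proportions are computed.
#' @param binarize replace proportions >= 0.5 with 1 and < 0.5 with 0.
#' @return an object of class `binning_config`.
#' @export
binning_config <- function(roi_start_ms = NULL, roi_end_ms = NULL,
                           bin_width_ms = 50, saccade_offset_ms = 200,
                           target_aoi = "target",
                           exclude_aois = "whitespace", binarize = TRUE) {
  if (bin_width_ms <= 0) {
    stop("binning_config: bin_width_ms must be > 0", call. = FALSE)
  }
  if (is.null(roi_start_ms)) roi_start_ms <- saccade_offset_ms
  if (is.null(roi_end_ms)) roi_end_ms <- roi_start_ms + 40 * bin_width_ms
  span <- roi_end_ms - roi_start_ms
  m <- span / bin_width_ms
  if (abs(m - round(m)) > 1e-8) {
    stop("binning_config: ROI span must be an integer multiple of bin width",
         call. = FALSE)
  }
  structure(list(
    roi_start_ms = roi_start_ms, roi_end_ms = roi_end_ms,
    bin_width_ms = bin_width_ms, saccade_offset_ms = saccade_offset_ms,
    target_aoi = target_aoi, exclude_aois = exclude_aois,
    binarize = binarize, n_bins = as.integer(round(m))
  ), class = "binning_config")
}

#' @export
print.binning_config <- function(x, ...) {
  cat(sprintf(
    "<binning_config> ROI [%g, %g) ms | %d bins x %g ms | target '%s' | %s\n",
    x$roi_start_ms, x$roi_end_ms, x$n_bins, x$bin_width_ms, x$target_aoi,
    if (x$binarize) "binarized" else "proportions"))
  invisible(x)
}

#' Bin a gaze table into per-trial target indicators
#'
#' Restricts samples to the ROI, drops excluded AOIs, assigns each remaining
#' sample to the half-open bin `[start, start + width)` containing it, and
#' computes per participant-by-trial-by-bin the proportion of retained samples
#' on the target AOI. With `cfg$binarize` the proportion is replaced by a 0/1
#' indicator (>= 0.5 -> 1). Bins in which a trial retains no samples emit no
#' record (common with low-rate webcam sampling).
#'
#' @param g a [gaze_table()].
#' @param cfg a [binning_config()].
#' @return a `data.frame` of class `binned_series` with columns `participant`,
#'   `group`, `condition`, `trial`, `bin_index`, `bin_start_ms`, `value`, and
#'   attributes `config` (the `binning_config`).
#' @export
bin_series <- function(g, cfg) {
  stopifnot(inherits(cfg, "binning_config"))
  keep <- !(g$aoi %in% cfg$exclude_aois) &
    g$time_ms >= cfg$roi_start_ms & g$time_ms < cfg$roi_end_ms
  gs <- g[keep, , drop = FALSE]
  if (nrow(gs) == 0L) {
    out <- data.frame(participant = character(), group = character(),
                      condition = character(), trial = character(),
                      bin_index = integer(), bin_start_ms = numeric(),
                      value = numeric(), stringsAsFactors = FALSE)
    class(out) <- c("binned_series", "data.frame")
    attr(out, "config") <- cfg
    return(out)
  }
  bin <- floor((gs$time_ms - cfg$roi_start_ms) / cfg$bin_width_ms)
  key <- paste(gs$participant, gs$trial, bin, sep = "\r")
  is_target <- as.numeric(gs$aoi == cfg$target_aoi)
  agg <- rowsum(cbind(target = is_target, n = 1), key, reorder = FALSE)
  first <- !duplicated(key)
  value <- agg[, "target"] / agg[, "n"]
  if (cfg$binarize) value <- as.numeric(value >= 0.5)
  out <- data.frame(
    participant = gs$participant[first],
    group = gs$group[first],
    condition = gs$condition[first],
    trial = gs$trial[first],
    bin_index = as.integer(bin[first]),
    bin_start_ms = cfg$roi_start_ms + bin[first] * cfg$bin_width_ms,
    value = as.numeric(value),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$participant, out$trial, out$bin_index), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("binned_series", "data.frame")
  attr(out, "config") <- cfg
  out
}

#' Binarize bin values
#'
#' @param x numeric vector of proportions.
#' @return 0/1 vector; values >= 0.5 map to 1. Idempotent.
#' @export
binarize <- function(x) as.numeric(x >= 0.5)

# ---- internal fast representation -----------------------------------------
# Participant-by-bin success/trial count matrices. All pooled per-bin tests,
# and hence all latency statistics, depend on the data only through these
# counts, which makes bootstrap and permutation statistics cheap: resampling
# participants is row selection, pooling is colSums.

#' Participant-by-bin count matrices
#'
#' Collapses a binarized [bin_series()] result to, per participant and bin,
#' the number of trials looking at target (`s`) and the number of trials with
#' any retained data (`n`). This is the sufficient statistic for the pooled
#' per-bin logistic test, and the unit structure on which by-participant and
#' stratified resampling operate.
#'
#' @param binned a `binned_series` with binary values.
#' @param n_bins number of bins `m`; taken from the attached config when
#'   absent.
#' @return list with elements `s`, `n` (participant x bin integer matrices),
#'   `participants`, `group`, `condition` (aligned with matrix rows), and the
#'   `binning_config`.
#' @export
participant_bin_counts <- function(binned, n_bins = NULL) {
  cfg <- attr(binned, "config")
  if (is.null(n_bins)) n_bins <- cfg$n_bins
  if (!all(binned$value %in% c(0, 1))) {
    stop("participant_bin_counts: values must be binary (use binarize)",
         call. = FALSE)
  }
  ids <- unique(binned$participant)
  pi <- match(binned$participant, ids)
  s <- matrix(0L, nrow = length(ids), ncol = n_bins,
              dimnames = list(ids, NULL))
  n <- s
  idx <- cbind(pi, binned$bin_index + 1L)
  # accumulate trial counts per participant x bin
  flat <- (idx[, 2L] - 1L) * length(ids) + idx[, 1L]
  s[] <- tabulate(flat[binned$value == 1], nbins = length(s))
  n[] <- tabulate(flat, nbins = length(n))
  first <- !duplicated(binned$participant)
  list(
    s = s, n = n, participants = ids,
    group = stats::setNames(binned$group[first], binned$participant[first])[ids],
    condition = stats::setNames(binned$condition[first],
                                binned$participant[first])[ids],
    config = cfg
  )
}

# Direct gaze-table -> count-matrix path used by the simulation engine:
# equivalent to participant_bin_counts(bin_series(g, cfg)) for binarized
# configs, but works on integer keys throughout.
gaze_to_counts <- function(g, cfg) {
  stopifnot(isTRUE(cfg$binarize))
  keep <- !(g$aoi %in% cfg$exclude_aois) &
    g$time_ms >= cfg$roi_start_ms & g$time_ms < cfg$roi_end_ms
  ids <- unique(g$participant)
  m <- cfg$n_bins
  first <- !duplicated(g$participant)
  grp <- stats::setNames(g$group[first], g$participant[first])[ids]
  cnd <- stats::setNames(g$condition[first], g$participant[first])[ids]
  P <- length(ids)
  s <- matrix(0L, P, m, dimnames = list(ids, NULL))
  n <- s
  if (any(keep)) {
    pi <- match(g$participant[keep], ids)
    utr <- unique(g$trial)
    tri <- match(g$trial[keep], utr)
    bin <- as.integer(floor((g$time_ms[keep] - cfg$roi_start_ms) /
                              cfg$bin_width_ms))
    tb <- ((pi - 1L) * length(utr) + (tri - 1L)) * m + bin + 1L
    nt <- tabulate(tb, nbins = P * length(utr) * m)
    st <- tabulate(tb[g$aoi[keep] == cfg$target_aoi],
                   nbins = P * length(utr) * m)
    filled <- which(nt > 0L)
    val <- as.integer(st[filled] / nt[filled] >= 0.5)
    cell0 <- filled - 1L
    bin_f <- cell0 %% m
    pi_f <- cell0 %/% (m * length(utr))
    # column-major flat index of (participant, bin) in the P x m matrices
    pb <- bin_f * P + pi_f + 1L
    n[] <- tabulate(pb, nbins = P * m)
    s[] <- tabulate(pb[val == 1L], nbins = P * m)
  }
  list(s = s, n = n, participants = ids, group = grp, condition = cnd,
       config = cfg)
}

# Counts representation for proportion tables: matrices of the per-bin
# relative competitor proportion and raw competitor-minus-unrelated
# difference, rows = participants. Undefined relative proportions
# (competitor and unrelated both 0) are NA and excluded bin-wise downstream.
participant_bin_props <- function(ptab, n_bins = NULL) {
  if (is.null(n_bins)) n_bins <- max(ptab$bin_index) + 1L
  ids <- unique(ptab$participant)
  rel <- matrix(NA_real_, nrow = length(ids), ncol = n_bins,
                dimnames = list(ids, NULL))
  dif <- rel
  i <- cbind(match(ptab$participant, ids), ptab$bin_index + 1L)
  denom <- ptab$p_competitor + ptab$p_unrelated
  rel[i] <- ifelse(denom > 0, ptab$p_competitor / denom, NA_real_)
  dif[i] <- ptab$p_competitor - ptab$p_unrelated
  first <- !duplicated(ptab$participant)
  starts <- sort(unique(ptab$bin_start_ms))
  list(
    rel = rel, dif = dif, participants = ids,
    group = stats::setNames(ptab$group[first], ptab$participant[first])[ids],
    condition = stats::setNames(ptab$condition[first],
                                ptab$participant[first])[ids],
    bin_start_ms = if (length(starts) >= n_bins) starts[seq_len(n_bins)] else
      seq(from = min(starts), by = if (length(starts) > 1) min(diff(starts)) else 1,
          length.out = n_bins)
  )
}
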