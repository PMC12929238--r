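#' Construct a gaze table
#'
#' A gaze table is the long-format record of gaze samples used throughout the
#' package: one row per gaze sample, with the participant it belongs to, the
#' group and (optional) condition of that participant, the trial, the sample
#' time in milliseconds relative to cue onset, and the area-of-interest (AOI)
#' label the gaze fell on.
#'
#' @param participant character/factor vector of participant labels.
#' @param group group label per sample (e.g. `"baseline"` / `"shifted"`).
#'   Every participant must belong to exactly one group.
#' @param condition optional stratum label per sample (e.g. a preview
#'   condition); defaults to a single condition `"all"`.
#' @param trial trial label per sample; trials are nested in participants.
#' @param time_ms finite numeric sample time in ms relative to cue onset.
#' @param aoi AOI label per sample (e.g. `"target"`, `"competitor"`,
#'   `"whitespace"`).
#' @param aoi_levels declared AOI vocabulary. Labels outside it trigger a
#'   warning naming the unknown labels.
#'
#' @return A `data.frame` of class `gaze_table` with columns
#'   `participant`, `group`, `condition`, `trial`, `time_ms`, `aoi`.
#' @export
gaze_table <- function(participant, group, condition = NULL, trial, time_ms,
                       aoi, aoi_levels = NULL) {
  n <- length(time_ms)
  if (is.null(condition)) condition <- rep("all", n)
  g <- data.frame(
    participant = as.character(participant),
    group       = as.character(group),
    condition   = as.character(condition),
    trial       = as.character(trial),
    time_ms     = as.numeric(time_ms),
    aoi         = as.character(aoi),
    stringsAsFactors = FALSE
  )
  validate_gaze_table(g, aoi_levels = aoi_levels)
  class(g) <- c("gaze_table", "data.frame")
  g
}

validate_gaze_table <- function(g, aoi_levels = NULL) {
  if (!all(is.finite(g$time_ms))) {
    stop("gaze table: all time_ms values must be finite", call. = FALSE)
  }
  # each (participant, trial) pair must sit in exactly one group and condition
  key <- paste(g$participant, g$trial, sep = "\r")
  for (col in c("group", "condition")) {
    n_per <- tapply(g[[col]], key, function(x) length(unique(x)))
    if (any(n_per > 1L)) {
      bad <- names(n_per)[which(n_per > 1L)[1L]]
      stop(sprintf("gaze table: participant/trial '%s' maps to multiple %ss",
                   gsub("\r", "/", bad), col), call. = FALSE)
    }
  }
  if (!is.null(aoi_levels)) {
    unknown <- setdiff(unique(g$aoi), aoi_levels)
    if (length(unknown)) {
      warning("gaze table: unknown AOI labels: ",
              paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  invisible(g)
}

#' @export
print.gaze_table <- function(x, ...) {
  cat(sprintf(
    "<gaze_table> %d samples | %d participants | groups: %s | %d trials/participant (median)\n",
    nrow(x), length(unique(x$participant)),
    paste(unique(x$group), collapse = ", "),
    stats::median(tapply(x$trial, x$participant,
                         function(t) length(unique(t))))))
  NextMethod()
}

#' Read a gaze table from delimited text
#'
#' Reads a CSV/TSV file with a header row into a validated [gaze_table()].
#' Columns may be renamed through `column_map`; rows keep file order.
#'
#' @param path path to a delimited text file with header.
#' @param column_map named character vector mapping the six canonical field
#'   names (`participant`, `group`, `condition`, `trial`, `time_ms`, `aoi`)
#'   to column names in the file. Fields absent from the map are looked up
#'   under their canonical names. `condition` is optional in the file.
#' @param sep field separator; `","` by default, use `"\t"` for TSV.
#' @param aoi_levels optional declared AOI vocabulary (see [gaze_table()]).
#' @return a `gaze_table`.
#' @export
read_gaze_table <- function(path, column_map = NULL, sep = ",",
                            aoi_levels = NULL) {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE)
  fields <- c("participant", "group", "condition", "trial", "time_ms", "aoi")
  cm <- stats::setNames(fields, fields)
  if (!is.null(column_map)) cm[names(column_map)] <- unname(column_map)
  required <- setdiff(fields, "condition")
  missing <- required[!cm[required] %in% names(raw)]
  if (length(missing)) {
    stop("read_gaze_table: missing column(s): ",
         paste(sprintf("'%s' (mapped to '%s')", missing, cm[missing]),
               collapse = ", "), call. = FALSE)
  }
  tm <- suppressWarnings(as.numeric(raw[[cm["time_ms"]]]))
  if (anyNA(tm)) {
    stop(sprintf("read_gaze_table: non-numeric time_ms at data row %d",
                 which(is.na(tm))[1L]), call. = FALSE)
  }
  cond <- if (cm["condition"] %in% names(raw)) raw[[cm["condition"]]] else NULL
  gaze_table(
    participant = raw[[cm["participant"]]],
    group       = raw[[cm["group"]]],
    condition   = cond,
    trial       = raw[[cm["trial"]]],
    time_ms     = tm,
    aoi         = raw[[cm["aoi"]]],
    aoi_levels  = aoi_levels
  )
}

#' Write a gaze table to CSV
#'
#' @param g a [gaze_table()].
#' @param path output file path.
#' @export
write_gaze_table <- function(g, path) {
  utils::write.csv(as.data.frame(g), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Shift all sample times of one group
#'
#' Adds a fixed interval to every sample time of the given group, which is how
#' a known true latency difference is injected into simulated datasets: the
#' shifted group's whole time course moves right on the time axis by
#' `delta_ms` while the other group is untouched.
#'
#' @param g a [gaze_table()].
#' @param group the group whose times to shift.
#' @param delta_ms shift in ms (may be negative).
#' @return the shifted `gaze_table`.
#' @export
shift_group_time <- function(g, group, delta_ms) {
  if (!group %in% g$group) {
    stop(sprintf("shift_group_time: no group '%s' in gaze table", group),
         call. = FALSE)
  }
  sel <- g$group == group
  g$time_ms[sel] <- g$time_ms[sel] + delta_ms
  g
}

#' Add per-participant timing noise
#'
#' Draws one offset per participant from Normal(0, `sd_ms`) and adds it to all
#' of that participant's sample times. This inflates between-participant
#' variability in effect timing while leaving the true group-level latency
#' difference unchanged; it is the stress applied when probing false-positive
#' rates under increased inter-participant variation.
#'
#' @param g a [gaze_table()].
#' @param sd_ms standard deviation of the per-participant offset, ms (>= 0).
#' @param seed optional integer seed for reproducibility.
#' @return a `gaze_table` with shifted times; the per-participant offsets are
#'   attached as attribute `"offsets"` (named numeric vector).
#' @export
add_participant_noise <- function(g, sd_ms, seed = NULL) {
  if (sd_ms < 0) stop("add_participant_noise: sd_ms must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  ids <- unique(g$participant)
  eps <- stats::rnorm(length(ids), mean = 0, sd = sd_ms)
  names(eps) <- ids
  g$time_ms <- g$time_ms + eps[g$participant]
  attr(g, "offsets") <- eps
  g
}

#' Construct a participant-by-bin proportion table
#'
#' Pre-averaged looking proportions per participant and time bin, the input
#' shape of word-recognition datasets shared without trial-level records:
#' proportions of looks to the target, the cohort competitor, and the
#' unrelated pictures, averaged over trials within participant and bin.
#'
#' @param participant,condition,bin_index,bin_start_ms,p_target,p_competitor,p_unrelated
#'   column vectors; proportions must lie in \[0, 1\], one row per
#'   participant-by-bin.
#' @param group optional group label per row (needed for two-group
#'   comparisons); defaults to `"all"`.
#' @return a `data.frame` of class `proportion_table`.
#' @export
proportion_table <- function(participant, condition = NULL, bin_index,
                             bin_start_ms, p_target, p_competitor,
                             p_unrelated, group = NULL) {
  n <- length(participant)
  if (is.null(condition)) condition <- rep("all", n)
  if (is.null(group)) group <- rep("all", n)
  p <- data.frame(
    participant = as.character(participant),
    group = as.character(group),
    condition = as.character(condition),
    bin_index = as.integer(bin_index),
    bin_start_ms = as.numeric(bin_start_ms),
    p_target = as.numeric(p_target),
    p_competitor = as.numeric(p_competitor),
    p_unrelated = as.numeric(p_unrelated),
    stringsAsFactors = FALSE
  )
  props <- c(p$p_target, p$p_competitor, p$p_unrelated)
  if (any(props < 0 | props > 1, na.rm = TRUE)) {
    stop("proportion_table: proportions must lie in [0, 1]", call. = FALSE)
  }
  key <- paste(p$participant, p$bin_index)
  if (anyDuplicated(key)) {
    stop("proportion_table: duplicate participant x bin rows", call. = FALSE)
  }
  class(p) <- c("proportion_table", "data.frame")
  p
}

#' Read a proportion table from CSV
#'
#' @param path CSV file with header columns `participant`, `condition`
#'   (optional), `group` (optional), `bin_index` or `bin_start_ms`,
#'   `p_target`, `p_competitor`, `p_unrelated`.
#' @param bin_width_ms bin width used to derive `bin_index` from
#'   `bin_start_ms` (or vice versa) when only one is present.
#' @return a `proportion_table`.
#' @export
read_proportion_table <- function(path, bin_width_ms = NULL) {
  raw <- utils::read.csv(path, check.names = FALSE)
  need <- c("participant", "p_target", "p_competitor", "p_unrelated")
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    stop("read_proportion_table: missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  has_idx <- "bin_index" %in% names(raw)
  has_start <- "bin_start_ms" %in% names(raw)
  if (!has_idx && !has_start) {
    stop("read_proportion_table: need bin_index or bin_start_ms", call. = FALSE)
  }
  if (!has_idx) {
    starts <- sort(unique(raw$bin_start_ms))
    width <- if (!is.null(bin_width_ms)) bin_width_ms else min(diff(starts))
    raw$bin_index <- as.integer(round((raw$bin_start_ms - starts[1L]) / width))
  }
  if (!has_start) {
    width <- if (!is.null(bin_width_ms)) bin_width_ms else 1
    raw$bin_start_ms <- raw$bin_index * width
  }
  proportion_table(
    participant = raw$participant,
    condition = if ("condition" %in% names(raw)) raw$condition else NULL,
    group = if ("group" %in% names(raw)) raw$group else NULL,
    bin_index = raw$bin_index,
    bin_start_ms = raw$bin_start_ms,
    p_target = raw$p_target,
    p_competitor = raw$p_competitor,
    p_unrelated = raw$p_unrelated
  )
}
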