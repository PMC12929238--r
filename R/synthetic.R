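#' Synthetic gaze-data specification
#'
#' Defines a generative model for two-group visual-world gaze time courses
#' with a known ground-truth onset, so that every estimation and resampling
#' procedure in the package can be exercised without external data. Each
#' participant `i` has a true preference onset
#' `tau_i = tau_base_ms + delta_group_ms (shifted group) + Normal(0, sigma_subj_ms)`;
#' each trial jitters it further by `Normal(0, sigma_trial_ms)`. Within a
#' trial the gaze is a two-state persistent chain: at each sample the
#' previous AOI state is kept with probability `rho`, otherwise redrawn from
#' the marginal target probability, which is `p_pre` before the trial's
#' onset, ramps linearly to `p_max` over `ramp_ms`, and in
#' `competitor_transient` mode decays back to `p_pre` after
#' `effect_duration_ms`. Samples are replaced by whitespace looks with
#' probability `p_whitespace`. Sampling is either at a fixed rate (infrared
#' regime, e.g. 120 Hz) or with right-skewed lognormal inter-sample gaps at a
#' given mean rate (webcam regime, roughly 1-50 Hz with variable gaps).
#'
#' @param n_participants participants per group.
#' @param n_trials trials per participant.
#' @param tau_base_ms true population onset, ms after cue onset.
#' @param delta_group_ms true onset shift of the `"shifted"` group.
#' @param sigma_subj_ms between-participant onset SD.
#' @param sigma_trial_ms within-participant trial onset jitter SD.
#' @param p_pre pre-onset target probability (chance looking, default 0.5).
#' @param p_max post-ramp target probability plateau.
#' @param ramp_ms linear ramp duration.
#' @param rho gaze-state persistence in \[0, 1): probability of repeating the
#'   previous sample's AOI state.
#' @param p_whitespace probability a sample is an off-AOI (whitespace) look.
#' @param sampling list: `list(fixed_hz = 120)` or
#'   `list(webcam = list(mean_hz = 15, jitter = 0.6))` (jitter is the
#'   lognormal sdlog of the inter-sample gaps).
#' @param trial_length_ms trial duration.
#' @param effect_mode `"target_preference"` (lasting preference) or
#'   `"competitor_transient"` (small transient competitor preference that
#'   decays after `effect_duration_ms`).
#' @param effect_duration_ms plateau duration in `competitor_transient` mode.
#' @param n_conditions number of condition strata participants are spread
#'   over evenly (for condition-balanced designs; default 1).
#' @param seed optional integer seed.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_participants = 24L, n_trials = 24L,
                           tau_base_ms = 800, delta_group_ms = 0,
                           sigma_subj_ms = 60, sigma_trial_ms = 30,
                           p_pre = 0.5, p_max = 0.95, ramp_ms = 200,
                           rho = 0.9, p_whitespace = 0.05,
                           sampling = list(fixed_hz = 120),
                           trial_length_ms = 2400,
                           effect_mode = "target_preference",
                           effect_duration_ms = 400,
                           n_conditions = 1L, seed = NULL) {
  effect_mode <- match.arg(effect_mode,
                           c("target_preference", "competitor_transient"))
  probs <- c(p_pre, p_max, p_whitespace)
  stopifnot(all(probs >= 0 & probs <= 1), rho >= 0, rho < 1,
            sigma_subj_ms >= 0, sigma_trial_ms >= 0, ramp_ms >= 0,
            trial_length_ms > 0, n_participants >= 1, n_trials >= 1)
  if (!is.null(sampling$fixed_hz) && sampling$fixed_hz <= 0) {
    stop("synthetic_spec: fixed_hz must be > 0", call. = FALSE)
  }
  if (tau_base_ms + ramp_ms > trial_length_ms) {
    stop("synthetic_spec: onset ramp extends beyond trial length", call. = FALSE)
  }
  structure(list(
    n_participants = as.integer(n_participants),
    n_trials = as.integer(n_trials), tau_base_ms = tau_base_ms,
    delta_group_ms = delta_group_ms, sigma_subj_ms = sigma_subj_ms,
    sigma_trial_ms = sigma_trial_ms, p_pre = p_pre, p_max = p_max,
    ramp_ms = ramp_ms, rho = rho, p_whitespace = p_whitespace,
    sampling = sampling, trial_length_ms = trial_length_ms,
    effect_mode = effect_mode, effect_duration_ms = effect_duration_ms,
    n_conditions = as.integer(n_conditions), seed = seed
  ), class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  rate <- if (!is.null(x$sampling$fixed_hz)) {
    sprintf("fixed %g Hz", x$sampling$fixed_hz)
  } else sprintf("webcam ~%g Hz", x$sampling$webcam$mean_hz)
  cat(sprintf(
    "<synthetic_spec> %d/group x %d trials | onset %g ms (+%g shifted, subj SD %g) | %s | %s\n",
    x$n_participants, x$n_trials, x$tau_base_ms, x$delta_group_ms,
    x$sigma_subj_ms, rate, x$effect_mode))
  invisible(x)
}

# marginal target (or competitor-relative) probability at time t given onset
marginal_prob <- function(t, tau, spec) {
  ramp <- max(spec$ramp_ms, 1e-9)
  # zero ramp is a step that is already at p_max at the onset sample itself
  up <- if (spec$ramp_ms <= 0) as.numeric(t >= tau) else
    pmin(pmax((t - tau) / ramp, 0), 1)
  p <- spec$p_pre + (spec$p_max - spec$p_pre) * up
  if (spec$effect_mode == "competitor_transient") {
    t_off <- tau + spec$ramp_ms + spec$effect_duration_ms
    down <- pmin(pmax((t - t_off) / ramp, 0), 1)
    p <- p - (spec$p_max - spec$p_pre) * down * (p > spec$p_pre)
    p <- pmax(p, spec$p_pre)
  }
  p
}

# sample times for n_trials trials; returns list(time, trial_index)
sample_times <- function(spec, n_trials) {
  if (!is.null(spec$sampling$fixed_hz)) {
    step <- 1000 / spec$sampling$fixed_hz
    tt <- seq(0, spec$trial_length_ms - 1e-9, by = step)
    list(time = rep(tt, n_trials),
         trial = rep(seq_len(n_trials), each = length(tt)))
  } else {
    wc <- spec$sampling$webcam
    mean_gap <- 1000 / wc$mean_hz
    sdlog <- if (!is.null(wc$jitter)) wc$jitter else 0.6
    meanlog <- log(mean_gap) - sdlog^2 / 2
    time <- vector("list", n_trials)
    for (tr in seq_len(n_trials)) {
      k <- max(4L, ceiling(spec$trial_length_ms / mean_gap * 3))
      gaps <- stats::rlnorm(k, meanlog, sdlog)
      tt <- cumsum(c(stats::runif(1, 0, mean_gap), gaps))
      while (tt[length(tt)] < spec$trial_length_ms) {
        tt <- c(tt, tt[length(tt)] + cumsum(stats::rlnorm(k, meanlog, sdlog)))
      }
      time[[tr]] <- tt[tt < spec$trial_length_ms]
    }
    lens <- lengths(time)
    list(time = unlist(time, use.names = FALSE),
         trial = rep(seq_len(n_trials), lens))
  }
}

#' Generate a synthetic two-group gaze table
#'
#' Simulates gaze samples for a `"baseline"` and a `"shifted"` group under a
#' [synthetic_spec()] and returns the gaze table together with the
#' ground-truth per-participant onsets.
#'
#' @param spec a [synthetic_spec()].
#' @param groups group labels, default `c("baseline", "shifted")`; the second
#'   group gets the `delta_group_ms` onset shift.
#' @param seed optional integer seed (overrides `spec$seed`).
#' @return list with `gaze` (a [gaze_table()]) and `truth` (data.frame:
#'   `participant`, `group`, `condition`, `true_onset_ms`).
#' @export
generate_gaze <- function(spec, groups = c("baseline", "shifted"),
                          seed = NULL) {
  if (is.null(seed)) seed <- spec$seed
  if (!is.null(seed)) set.seed(seed)
  n_per <- spec$n_participants
  total <- 2L * n_per
  ids <- sprintf("p%03d", seq_len(total))
  grp <- rep(groups, each = n_per)
  cond <- rep_len(sprintf("c%d", seq_len(spec$n_conditions)), total)
  tau_i <- spec$tau_base_ms +
    ifelse(grp == groups[2L], spec$delta_group_ms, 0) +
    stats::rnorm(total, 0, spec$sigma_subj_ms)
  trial_lab <- sprintf("t%02d", seq_len(spec$n_trials))
  # per-participant sample times; fixed-rate grids are shared, webcam gaps
  # are drawn fresh per trial
  st_list <- if (!is.null(spec$sampling$fixed_hz)) {
    st <- sample_times(spec, spec$n_trials)
    rep(list(st), total)
  } else {
    lapply(seq_len(total), function(i) sample_times(spec, spec$n_trials))
  }
  lens <- vapply(st_list, function(st) length(st$time), integer(1))
  time <- unlist(lapply(st_list, `[[`, "time"), use.names = FALSE)
  trial_idx <- unlist(lapply(st_list, `[[`, "trial"), use.names = FALSE)
  pidx <- rep(seq_len(total), lens)
  tau_t <- tau_i[pidx] +
    stats::rnorm(total * spec$n_trials, 0, spec$sigma_trial_ms)[
      (pidx - 1L) * spec$n_trials + trial_idx]
  pmarg <- marginal_prob(time, tau_t, spec)
  ns <- length(time)
  trial_start <- c(TRUE, trial_idx[-1L] != trial_idx[-ns] |
                     pidx[-1L] != pidx[-ns])
  redraw <- trial_start | stats::runif(ns) >= spec$rho
  candidate <- stats::runif(ns) < pmarg
  # state = candidate value at the most recent redraw position
  state <- candidate[cummax(seq_len(ns) * redraw)]
  aoi <- ifelse(state, "target", "competitor")
  if (spec$p_whitespace > 0) {
    aoi[stats::runif(ns) < spec$p_whitespace] <- "whitespace"
  }
  # constructed columns satisfy the gaze-table invariants by design, so the
  # validating constructor is bypassed
  g <- data.frame(participant = ids[pidx], group = grp[pidx],
                  condition = cond[pidx], trial = trial_lab[trial_idx],
                  time_ms = time, aoi = aoi, stringsAsFactors = FALSE)
  class(g) <- c("gaze_table", "data.frame")
  truth <- data.frame(participant = ids, group = grp, condition = cond,
                      true_onset_ms = tau_i, stringsAsFactors = FALSE)
  list(gaze = g, truth = truth)
}

#' Generate a synthetic participant-by-bin proportion table
#'
#' Simulates pre-averaged looking proportions in the shape of shared
#' word-recognition datasets: per participant and time bin, the proportions
#' of looks to target, cohort competitor, and unrelated pictures. The target
#' proportion is held at a constant baseline; among non-target looks the
#' competitor's relative share follows the transient effect profile of the
#' spec (0.5 before onset, ramping up, then decaying back). Proportions are
#' averages of simulated per-sample categorical draws, so they carry
#' realistic sampling noise that shrinks with `n_trials`.
#'
#' @param spec a [synthetic_spec()] with `effect_mode = "competitor_transient"`.
#' @param bin_width_ms bin width of the emitted table (default 40).
#' @param p_target_base constant target-look proportion (default 0.25).
#' @param groups group labels as in [generate_gaze()].
#' @param seed optional integer seed.
#' @return list with `proportions` (a [proportion_table()]) and `truth`.
#' @export
generate_proportion_table <- function(spec, bin_width_ms = 40,
                                      p_target_base = 0.25,
                                      groups = c("baseline", "shifted"),
                                      seed = NULL) {
  if (spec$effect_mode != "competitor_transient") {
    stop("generate_proportion_table: requires competitor_transient mode",
         call. = FALSE)
  }
  if (is.null(seed)) seed <- spec$seed
  if (!is.null(seed)) set.seed(seed)
  n_per <- spec$n_participants
  total <- 2L * n_per
  ids <- sprintf("p%03d", seq_len(total))
  grp <- rep(groups, each = n_per)
  cond <- rep_len(sprintf("c%d", seq_len(spec$n_conditions)), total)
  tau_i <- spec$tau_base_ms +
    ifelse(grp == groups[2L], spec$delta_group_ms, 0) +
    stats::rnorm(total, 0, spec$sigma_subj_ms)
  m <- floor(spec$trial_length_ms / bin_width_ms)
  starts <- (seq_len(m) - 1L) * bin_width_ms
  hz <- if (!is.null(spec$sampling$fixed_hz)) spec$sampling$fixed_hz else
    spec$sampling$webcam$mean_hz
  k_bin <- max(1L, round(bin_width_ms / 1000 * hz)) * spec$n_trials
  rows <- vector("list", total)
  for (i in seq_len(total)) {
    mid <- starts + bin_width_ms / 2
    q <- marginal_prob(mid, tau_i[i], spec)  # competitor share of non-target
    n_t <- stats::rbinom(m, k_bin, p_target_base)
    n_rest <- k_bin - n_t
    n_c <- stats::rbinom(m, n_rest, q)
    rows[[i]] <- data.frame(
      participant = ids[i], group = grp[i], condition = cond[i],
      bin_index = seq_len(m) - 1L, bin_start_ms = starts,
      p_target = n_t / k_bin, p_competitor = n_c / k_bin,
      p_unrelated = (n_rest - n_c) / k_bin, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  ptab <- proportion_table(tab$participant, tab$condition, tab$bin_index,
                           tab$bin_start_ms, tab$p_target, tab$p_competitor,
                           tab$p_unrelated, group = tab$group)
  truth <- data.frame(participant = ids, group = grp, condition = cond,
                      true_onset_ms = tau_i, stringsAsFactors = FALSE)
  list(proportions = ptab, truth = truth)
}

#' Write synthetic data with its ground-truth sidecar
#'
#' @param x result of [generate_gaze()] or [generate_proportion_table()].
#' @param path output CSV path for the data; the ground truth is written
#'   next to it as `<path>_truth.csv`.
#' @export
write_synthetic <- function(x, path) {
  if (!is.null(x$gaze)) {
    write_gaze_table(x$gaze, path)
  } else {
    utils::write.csv(as.data.frame(x$proportions), path, row.names = FALSE,
                     quote = FALSE)
  }
  truth_path <- sub("(\\.[^.]+)?$", "_truth.csv", path)
  utils::write.csv(x$truth, truth_path, row.names = FALSE, quote = FALSE)
  invisible(c(path, truth_path))
}
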