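# Shared fixtures, built in code.

# Fully deterministic two-group gaze data: pre-onset all competitor
# (p_pre = 0), post-onset all target, no jitter, no whitespace. Latency
# estimates on such data are exact, which makes shift-equivariance and
# engine identities testable to equality.
deterministic_spec <- function(n_participants = 6L, n_trials = 4L,
                               delta_group_ms = 0, tau_base_ms = 800) {
  synthetic_spec(
    n_participants = n_participants, n_trials = n_trials,
    tau_base_ms = tau_base_ms, delta_group_ms = delta_group_ms,
    sigma_subj_ms = 0, sigma_trial_ms = 0, p_pre = 0, p_max = 1,
    ramp_ms = 0, rho = 0, p_whitespace = 0,
    sampling = list(fixed_hz = 120), trial_length_ms = 2400)
}

# Small stochastic spec for resampling structure tests.
small_spec <- function(n_participants = 8L, n_trials = 8L, ...) {
  synthetic_spec(n_participants = n_participants, n_trials = n_trials, ...)
}

# Hand-built gaze table: values chosen so per-bin contents are explicit.
toy_gaze <- function() {
  gaze_table(
    participant = rep("p1", 6),
    group = rep("baseline", 6),
    trial = rep("t1", 6),
    time_ms = c(210, 220, 230, 260, 270, 280),
    aoi = c("target", "competitor", "target",
            "competitor", "whitespace", "competitor"))
}

toy_binning <- function() {
  binning_config(roi_start_ms = 200, roi_end_ms = 300, bin_width_ms = 50,
                 saccade_offset_ms = 200)
}

# brute-force Holm step-down: sorted p, reject while p_(i) <= alpha/(m-i+1)
holm_oracle <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  rej <- logical(m)
  for (i in seq_len(m)) {
    if (p[ord[i]] <= alpha / (m - i + 1)) rej[ord[i]] <- TRUE else break
  }
  rej
}

# exhaustive onset scan oracle: first index whose k-window is all TRUE
first_run_oracle <- function(flags, k) {
  m <- length(flags)
  for (i in seq_len(m - k + 1)) {
    if (all(flags[i:(i + k - 1)])) return(i - 1L)
  }
  NA_integer_
}
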