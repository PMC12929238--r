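test_that("pooled logistic bin test matches the Wald closed forms", {
  r <- pooled_logistic_bin_test(s = 50, n = 100)
  expect_equal(r$estimate, 0)
  expect_equal(r$p_value, 1)
  expect_false(r$significant_positive)

  r <- pooled_logistic_bin_test(s = 60, n = 100)
  expect_equal(r$estimate, log(0.6 / 0.4), tolerance = 1e-10)
  expect_equal(r$se, 1 / sqrt(100 * 0.6 * 0.4), tolerance = 1e-10)
  expect_equal(r$p_value, 2 * pnorm(-abs(r$estimate / r$se)), tolerance = 1e-12)
  expect_lt(r$p_value, 0.05)
  expect_true(r$significant_positive)
  expect_true(r$exceeds_threshold)  # 0.405 > 0.2

  # vector input instead of counts
  rv <- pooled_logistic_bin_test(c(rep(1, 60), rep(0, 40)))
  expect_equal(rv$estimate, r$estimate)
  expect_error(pooled_logistic_bin_test(c(0.2, 1)), "binary")
})

test_that("pooled logistic agrees with an ML logistic fit on random inputs", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(5:200, 1)
    s <- sample(seq_len(n - 1), 1)  # non-separated
    r <- pooled_logistic_bin_test(s = s, n = n)
    fit <- suppressWarnings(
      glm(c(rep(1, s), rep(0, n - s)) ~ 1, family = binomial,
          control = glm.control(epsilon = 1e-12)))
    expect_equal(r$estimate, unname(coef(fit)), tolerance = 1e-6)
    expect_equal(r$se, sqrt(vcov(fit)[1, 1]), tolerance = 1e-6)
  }
})

test_that("separation falls back to the exact binomial test", {
  r <- pooled_logistic_bin_test(s = 20, n = 20)
  expect_equal(r$p_value, 2 * 0.5^20, tolerance = 1e-12)
  expect_equal(r$p_value,
               binom.test(20, 20, 0.5)$p.value, tolerance = 1e-12)
  expect_true(r$significant_positive)
  expect_true(r$exceeds_threshold)
  expect_equal(r$estimate, Inf)

  r0 <- pooled_logistic_bin_test(s = 0, n = 20)
  expect_equal(r0$estimate, -Inf)
  expect_false(r0$significant_positive)
  expect_false(r0$exceeds_threshold)

  # n = 1 separated bins are never significant at 0.05 (p = 1)
  r1 <- pooled_logistic_bin_test(s = 1, n = 1)
  expect_equal(r1$p_value, 1)
})

test_that("empty bins give a non-significant no-data result", {
  r <- pooled_logistic_bin_test(s = 0, n = 0)
  expect_equal(r$p_value, 1)
  expect_false(r$significant_positive)
  expect_false(r$exceeds_threshold)
})

test_that("relative-proportion t-test matches t-distribution arithmetic", {
  r <- relative_proportion_bin_test(c(0.4, 0.5, 0.6))
  expect_equal(r$estimate, 0.5)
  expect_equal(r$p_value, 1)

  r <- relative_proportion_bin_test(c(0.6, 0.7, 0.8),
                                    diff = c(0.1, 0.2, 0.2))
  tt <- t.test(c(0.6, 0.7, 0.8), mu = 0.5)
  expect_equal(r$p_value, tt$p.value, tolerance = 1e-12)
  expect_false(r$significant_positive)  # p ~ 0.074 > 0.05
  expect_true(r$exceeds_threshold)      # mean diff 1/6 > 0.03

  # undefined relative proportions (0/0) are excluded bin-wise
  r <- relative_proportion_bin_test(c(0.6, NA, 0.8))
  expect_equal(r$n_obs, 2)

  # zero variance is degenerate, never significant
  r <- relative_proportion_bin_test(c(0.7, 0.7, 0.7))
  expect_equal(r$p_value, 1)
  expect_false(r$significant_positive)
})

test_that("Holm rejections equal the brute-force step-down on random vectors", {
  expect_equal(holm_correct(0.04, 0.05), TRUE)
  expect_equal(holm_correct(c(0.001, 0.04), 0.05), c(TRUE, TRUE))
  p <- c(0.2, 0.009, 0.012, 0.001, 0.3)
  expect_equal(holm_correct(p, 0.05), p %in% c(0.001, 0.009, 0.012))

  set.seed(7)
  for (i in 1:50) {
    m <- sample(1:12, 1)
    p <- round(runif(m)^2, 3)
    expect_identical(holm_correct(p, 0.05), holm_oracle(p, 0.05))
  }
})

test_that("onset scan matches the exhaustive window oracle", {
  bin_cfg <- list(roi_start_ms = 200, roi_end_ms = 700, bin_width_ms = 50,
                  n_bins = 10L)
  flags <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE)
  bins <- data.frame(bin_index = 0:9, p_value = ifelse(flags, 1e-6, 0.5),
                     positive = flags, significant_positive = flags,
                     exceeds_threshold = flags)
  est <- estimate_latency(bins, latency_config("consecutive"), bin_cfg)
  expect_equal(est$source_bin_index, 3L)
  expect_equal(est$latency_ms, 350)

  # joint significance + threshold criterion delays onset
  bins2 <- bins
  bins2$significant_positive <- TRUE
  bins2$positive <- TRUE
  bins2$p_value <- 1e-6
  bins2$exceeds_threshold <- c(FALSE, FALSE, rep(TRUE, 8))
  est2 <- estimate_latency(bins2, latency_config("consecutive_threshold"),
                           bin_cfg)
  expect_equal(est2$source_bin_index, 2L)
  expect_equal(estimate_latency(bins2, latency_config("consecutive"),
                                bin_cfg)$source_bin_index, 0L)

  # property: scan equals oracle over random flag vectors and k
  set.seed(21)
  for (i in 1:40) {
    m <- sample(5:12, 1)
    fl <- runif(m) < 0.5
    k <- sample(1:4, 1)
    cfg <- latency_config("consecutive", k_consecutive = k)
    b <- data.frame(bin_index = seq_len(m) - 1L,
                    p_value = ifelse(fl, 1e-5, 0.6), positive = fl,
                    significant_positive = fl, exceeds_threshold = fl)
    bc <- list(roi_start_ms = 0, roi_end_ms = m * 50, bin_width_ms = 50,
               n_bins = m)
    est <- estimate_latency(b, cfg, bc)
    oracle <- first_run_oracle(fl, k)
    if (is.na(oracle)) {
      expect_true(est$censored)
      expect_equal(est$latency_ms, bc$roi_end_ms)
    } else {
      expect_equal(est$source_bin_index, oracle)
    }
  }
})

test_that("k = 1 consecutive measure reduces to the first significant bin", {
  set.seed(3)
  fl <- runif(12) < 0.4
  fl[12] <- TRUE
  b <- data.frame(bin_index = 0:11, p_value = ifelse(fl, 1e-5, 0.6),
                  positive = fl, significant_positive = fl,
                  exceeds_threshold = fl)
  bc <- list(roi_start_ms = 0, roi_end_ms = 600, bin_width_ms = 50,
             n_bins = 12L)
  est <- estimate_latency(b, latency_config("consecutive", k_consecutive = 1),
                          bc)
  expect_equal(est$source_bin_index, which(fl)[1] - 1L)
})

test_that("threshold variants never yield an earlier latency", {
  set.seed(9)
  for (i in 1:20) {
    m <- 12L
    sig <- runif(m) < 0.6
    exc <- sig & runif(m) < 0.7
    b <- data.frame(bin_index = 0:(m - 1),
                    p_value = ifelse(sig, 1e-5, 0.6), positive = sig,
                    significant_positive = sig, exceeds_threshold = exc)
    bc <- list(roi_start_ms = 0, roi_end_ms = m * 50, bin_width_ms = 50,
               n_bins = m)
    for (pair in list(c("consecutive", "consecutive_threshold"),
                      c("holm", "holm_threshold"))) {
      plain <- estimate_latency(b, latency_config(pair[1]), bc)
      thr <- estimate_latency(b, latency_config(pair[2]), bc)
      expect_gte(thr$latency_ms, plain$latency_ms)
    }
  }
})

test_that("Holm measures pick the first corrected positive rejection", {
  p <- c(0.5, 1e-6, 1e-6, 0.3, 1e-6)
  pos <- c(TRUE, FALSE, TRUE, TRUE, TRUE)  # bin 1 significant but negative
  exc <- c(FALSE, FALSE, FALSE, FALSE, TRUE)
  b <- data.frame(bin_index = 0:4, p_value = p, positive = pos,
                  significant_positive = pos & p < 0.05,
                  exceeds_threshold = exc)
  bc <- list(roi_start_ms = 0, roi_end_ms = 250, bin_width_ms = 50,
             n_bins = 5L)
  expect_equal(estimate_latency(b, latency_config("holm"),
                                bc)$source_bin_index, 2L)
  expect_equal(estimate_latency(b, latency_config("holm_threshold"),
                                bc)$source_bin_index, 4L)
})

test_that("latency differences subtract and propagate censoring", {
  bc <- list(roi_start_ms = 200, roi_end_ms = 2200, bin_width_ms = 50,
             n_bins = 40L)
  mk <- function(bin) vwplat:::new_latency_estimate(bin, "consecutive", bc, "g")
  expect_equal(as.numeric(latency_difference(mk(3L), mk(3L))), 0)
  d <- latency_difference(mk(7L), mk(3L))
  expect_equal(as.numeric(d), 200)
  expect_false(attr(d, "censored"))
  # baseline censored at roi_end 2200, shifted at 400 -> -1800, flagged
  d2 <- latency_difference(mk(4L), mk(NA_integer_))
  expect_equal(as.numeric(d2), 400 - 2200)
  expect_true(attr(d2, "censored"))
  e1 <- mk(1L); e1$measure <- "holm"
  expect_error(latency_difference(e1, mk(1L)), "measures differ")
})

test_that("latency is shift-equivariant on deterministic data", {
  spec <- deterministic_spec(n_participants = 4, n_trials = 3)
  g <- generate_gaze(spec, seed = 1)$gaze
  cfg <- binning_config()
  lat <- function(gz, measure) {
    cnt <- participant_bin_counts(bin_series(gz, cfg))
    gs <- vwplat:::resolve_groups(cnt, NULL)
    tests <- vwplat:::group_bin_tests_counts(cnt, gs$shift_rows,
                                             latency_config(measure))
    b <- vwplat:::scan_onset_bin(tests$p_value, tests$significant,
                                 tests$exceeds, tests$positive,
                                 latency_config(measure))
    cfg$roi_start_ms + b * cfg$bin_width_ms
  }
  for (ms in latency_measures()) {
    base <- lat(g, ms)
    for (j in c(2L, 6L)) {
      shifted <- lat(shift_group_time(g, "shifted", j * cfg$bin_width_ms), ms)
      expect_equal(shifted, base + j * cfg$bin_width_ms)
    }
  }
})
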