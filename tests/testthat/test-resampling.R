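make_counts <- function(spec, seed = 1) {
  g <- generate_gaze(spec, seed = seed)$gaze
  participant_bin_counts(bin_series(g, binning_config()))
}

test_that("by-participant bootstrap uses whole participants per group", {
  spec <- small_spec(n_participants = 5, n_trials = 6)
  cnt <- make_counts(spec, seed = 4)
  lcfg <- latency_config()
  rcfg <- resampling_config(n_bootstrap = 40, n_permutation = 10, seed = 8)

  # instrument: capture draws through the internal drawer
  draws <- list()
  set.seed(8)
  for (b in 1:10) {
    r <- vwplat:::draw_group_rows(1:5, rep("all", 10), FALSE)
    expect_length(r, 5)            # exactly n participant slots
    expect_true(all(r %in% 1:5))   # from that group only
    draws[[b]] <- r
  }
  expect_gt(length(unique(vapply(draws, paste, "", collapse = ","))), 1)

  dist <- bootstrap_by_participant(cnt, rcfg, lcfg)
  expect_s3_class(dist, "resample_distribution")
  expect_equal(nrow(dist$values), 40)
  expect_true(all(is.finite(dist$values)))
})

test_that("degenerate single-participant groups give a constant bootstrap", {
  spec <- small_spec(n_participants = 1, n_trials = 6)
  cnt <- make_counts(spec, seed = 5)
  dist <- bootstrap_by_participant(
    cnt, resampling_config(n_bootstrap = 25, seed = 1), latency_config())
  expect_equal(length(unique(resample_values(dist))), 1)
})

test_that("bootstrap omits a fixed participant at the (1 - 1/n)^n rate", {
  n <- 10
  B <- 2000
  set.seed(123)
  omitted <- mean(replicate(B, !(1 %in% sample.int(n, replace = TRUE))))
  p <- (1 - 1 / n)^n
  se <- sqrt(p * (1 - p) / B)
  expect_lt(abs(omitted - p), 3 * se)
})

test_that("stratified bootstrap keeps all participants and stratum sizes", {
  spec <- small_spec(n_participants = 4, n_trials = 6)
  cnt <- make_counts(spec, seed = 6)
  rcfg <- resampling_config(n_bootstrap = 20, seed = 2)
  dist <- bootstrap_stratified(cnt, rcfg, latency_config())
  expect_equal(nrow(dist$values), 20)

  # stratum success counts are Binomial(n, s/n): bounded by the stratum size,
  # and strata with all-0 or all-n trials are invariant
  set.seed(2)
  prob <- ifelse(cnt$n > 0, cnt$s / pmax(cnt$n, 1), 0)
  for (i in 1:10) {
    s_star <- matrix(rbinom(length(cnt$n), as.vector(cnt$n), as.vector(prob)),
                     nrow = nrow(cnt$n))
    expect_true(all(s_star <= cnt$n))
    fixed <- cnt$s == 0 | cnt$s == cnt$n
    expect_equal(s_star[fixed], cnt$s[fixed])
  }
})

test_that("one trial per participant makes stratified resamples identical", {
  spec <- small_spec(n_participants = 4, n_trials = 1)
  cnt <- make_counts(spec, seed = 9)
  dist <- bootstrap_stratified(
    cnt, resampling_config(n_bootstrap = 15, seed = 3), latency_config())
  expect_equal(length(unique(resample_values(dist))), 1)
})

test_that("stratified draws break across-bin trial identity for m >= 2", {
  # two trials, one with all-target and one with no-target in two bins:
  # counts s = 1 of n = 2 per bin; independent Binomial(2, 1/2) draws per
  # bin recreate the original (1, 1) pattern with probability < 1
  set.seed(11)
  draws <- replicate(200, rbinom(2, 2, 0.5))
  expect_lt(mean(draws[1, ] == 1 & draws[2, ] == 1), 1)
  expect_gt(var(as.numeric(draws)), 0)
})

test_that("permutation p-value is the plain proportion of the stated rule", {
  # observed 150 vs null {-100, 0, 50, 150, 200}: two values have
  # |null| >= 150 -> p = 2/5
  null <- c(-100, 0, 50, 150, 200)
  expect_equal(mean(abs(null) >= abs(150)), 0.4)

  spec <- small_spec(n_participants = 6, n_trials = 6)
  cnt <- make_counts(spec, seed = 10)
  rcfg <- resampling_config(n_bootstrap = 5, n_permutation = 25, seed = 12)
  pt <- permutation_test(cnt, rcfg, latency_config())
  expect_equal(pt$kind, "permutation_null")
  expect_equal(nrow(pt$values), 25)
  # p lies on the {0, 1/P, ..., 1} lattice
  expect_true(pt$p_value * 25 == round(pt$p_value * 25))
  # forced-zero rule: observed larger than all null values
  p0 <- mean(abs(resample_values(pt)) >= abs(max(abs(pt$values)) + 1))
  expect_equal(p0, 0)
})

test_that("permutation reassigns whole participants, groups stay size n", {
  set.seed(5)
  all_rows <- 1:12
  for (i in 1:10) {
    pick <- sample.int(12, 6)
    expect_length(setdiff(all_rows, all_rows[pick]), 6)
  }
  # null distribution on exchangeable groups is symmetric around 0
  spec <- small_spec(n_participants = 8, n_trials = 6, sigma_subj_ms = 100)
  cnt <- make_counts(spec, seed = 3)
  rcfg <- resampling_config(n_bootstrap = 5, n_permutation = 200, seed = 17)
  pt <- permutation_test(cnt, rcfg, latency_config())
  vals <- resample_values(pt)
  nz <- vals[vals != 0]
  expect_gt(length(nz), 20)
  expect_lt(abs(mean(sign(nz))), 3 / sqrt(length(nz)))
})

test_that("bootstrap CI methods satisfy their closed forms and identities", {
  # constant distribution: zero-width interval for every method
  const <- rep(42, 100)
  for (mtd in c("percentile", "normal", "empirical", "bc", "bca")) {
    ci <- bootstrap_ci(const, observed = 42, method = mtd,
                       jackknife_values = rep(42, 10))
    expect_equal(c(ci$lower_ms, ci$upper_ms), c(42, 42))
  }

  # normal interval closed form: observed 10, boot mean 12, sd ~2
  set.seed(1)
  boot_n <- rnorm(1e5, 12, 2)
  ci <- bootstrap_ci(boot_n, observed = 10, method = "normal")
  expect_equal(ci$lower_ms, 10 - (mean(boot_n) - 10) - qnorm(.975) * sd(boot_n),
               tolerance = 1e-10)
  expect_equal(c(ci$lower_ms, ci$upper_ms), c(4.08, 11.92), tolerance = 0.01)

  # exactly symmetric bootstrap values about the observed value:
  # percentile = empirical, BC = percentile (z0 = 0), BCa = BC (a = 0)
  sym <- c(-(50:1), 50:1) + 7
  cp <- bootstrap_ci(sym, 7, "percentile")
  ce <- bootstrap_ci(sym, 7, "empirical")
  cb <- bootstrap_ci(sym, 7, "bc")
  ca <- bootstrap_ci(sym, 7, "bca", jackknife_values = sym)
  expect_equal(c(cp$lower_ms, cp$upper_ms), c(ce$lower_ms, ce$upper_ms))
  expect_equal(cb$diagnostics$z0, 0)
  expect_equal(c(cb$lower_ms, cb$upper_ms), c(cp$lower_ms, cp$upper_ms))
  expect_equal(ca$diagnostics$a, 0)
  expect_equal(c(ca$lower_ms, ca$upper_ms), c(cb$lower_ms, cb$upper_ms))

  # percentile at level 1 is the full range
  ci1 <- bootstrap_ci(boot_n[1:100], 12, "percentile", level = 1 - 1e-12)
  expect_equal(c(ci1$lower_ms, ci1$upper_ms),
               range(boot_n[1:100]), tolerance = 1e-6)

  # one-sided degenerate counts clamp z0 and flag it
  cc <- bootstrap_ci(1:100, observed = 0, method = "bc")
  expect_true(cc$diagnostics$z0_clamped)
})

test_that("CI constructions agree with boot::boot.ci on continuous data", {
  skip_if_not_installed("boot")
  set.seed(99)
  x <- rnorm(40, 5, 2)
  t0 <- mean(x)
  bo <- boot::boot(x, function(d, i) mean(d[i]), R = 4000)
  jack <- vapply(seq_along(x), function(i) mean(x[-i]), 0)
  L <- mean(jack) - jack
  bci <- boot::boot.ci(bo, type = c("norm", "perc", "basic", "bca"), L = L)
  tol <- 0.05  # quantile-convention differences vanish as O(1/B)
  ci <- bootstrap_ci(bo$t[, 1], t0, "normal")
  expect_equal(c(ci$lower_ms, ci$upper_ms), bci$normal[2:3], tolerance = tol)
  ci <- bootstrap_ci(bo$t[, 1], t0, "percentile")
  expect_equal(c(ci$lower_ms, ci$upper_ms), bci$percent[4:5], tolerance = tol)
  ci <- bootstrap_ci(bo$t[, 1], t0, "empirical")
  expect_equal(c(ci$lower_ms, ci$upper_ms), bci$basic[4:5], tolerance = tol)
  ci <- bootstrap_ci(bo$t[, 1], t0, "bca", jackknife_values = jack)
  expect_equal(c(ci$lower_ms, ci$upper_ms), bci$bca[4:5], tolerance = tol)
})

test_that("Wilson intervals reproduce printed and algebraic values", {
  w <- wilson_interval(805, 1000)
  expect_equal(round(c(w$lower, w$upper), 2), c(0.78, 0.83))
  w <- wilson_interval(817, 1000)
  expect_equal(round(c(w$lower, w$upper), 2), c(0.79, 0.84))
  w <- wilson_interval(799, 1000)
  expect_equal(round(100 * c(w$lower, w$upper), 1), c(77.3, 82.3))

  # 0 successes: score lower bound is exactly 0
  expect_equal(wilson_interval(0, 25)$lower, 0)
  expect_equal(wilson_interval(25, 25)$upper, 1)
  expect_error(wilson_interval(1, 0), ">= 1")

  # agrees with the score interval of prop.test (no continuity correction)
  for (x in c(3, 12, 50)) {
    w <- wilson_interval(x, 60)
    pt <- prop.test(x, 60, correct = FALSE)
    expect_equal(c(w$lower, w$upper), as.numeric(pt$conf.int),
                 tolerance = 1e-9)
  }
})

test_that("resampling is reproducible under a fixed seed", {
  spec <- small_spec(n_participants = 5, n_trials = 5)
  cnt <- make_counts(spec, seed = 30)
  rcfg <- resampling_config(n_bootstrap = 15, n_permutation = 15, seed = 77)
  d1 <- bootstrap_by_participant(cnt, rcfg, latency_config())
  d2 <- bootstrap_by_participant(cnt, rcfg, latency_config())
  expect_identical(d1$values, d2$values)
  p1 <- permutation_test(cnt, rcfg, latency_config())
  p2 <- permutation_test(cnt, rcfg, latency_config())
  expect_identical(p1$p_value, p2$p_value)
})
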