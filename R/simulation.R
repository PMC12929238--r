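#' Build a Monte Carlo simulation plan
#'
#' Enumerates the full grid of simulation cells (group size x effect size x
#' per-participant noise SD), derives deterministic child seeds for each
#' cell, and reports the planned accounting: total simulations, total
#' resampled datasets (`n_sims * (B + P)`, plus another `B` per simulation
#' when the stratified bootstrap is also run), and total per-bin model fits
#' (`resamples * m bins * 2 groups`).
#'
#' @param group_sizes vector of per-group sample sizes `n`.
#' @param effect_sizes vector of true latency shifts in ms (0 gives Type I
#'   error cells).
#' @param noise_sds vector of per-participant timing noise SDs in ms
#'   (default 0 = none).
#' @param n_sims simulations per cell (default 1000).
#' @param resampling_cfg a [resampling_config()] (supplies B and P).
#' @param latency_cfg a [latency_config()].
#' @param binning_cfg a [binning_config()] (supplies the bin count `m`).
#' @param run_stratified also run the stratified bootstrap in every
#'   simulation (adds `B` resamples per simulation to the accounting).
#' @param sample_with_replacement sample the `2n` participants per
#'   simulation with replacement from the seed pool (needed when the pool is
#'   smaller than `2n`).
#' @param condition_balanced draw an equal number of participants per
#'   condition into each group, and stratify all resampling by condition.
#' @param master_seed integer master seed; per-simulation child seeds are
#'   derived from it deterministically so cells can run in any order.
#' @return an object of class `simulation_plan` with elements `cells`
#'   (data.frame: `cell`, `n`, `delta_ms`, `noise_sd_ms`), the configs, and
#'   `totals` (list: `n_simulations`, `n_resamples`, `n_bin_fits`).
#' @export
build_plan <- function(group_sizes, effect_sizes, noise_sds = 0,
                       n_sims = 1000L,
                       resampling_cfg = resampling_config(),
                       latency_cfg = latency_config(),
                       binning_cfg = binning_config(),
                       run_stratified = FALSE,
                       sample_with_replacement = FALSE,
                       condition_balanced = FALSE,
                       master_seed = 1L) {
  if (!length(group_sizes) || !length(effect_sizes) || !length(noise_sds)) {
    stop("build_plan: empty grid", call. = FALSE)
  }
  cells <- expand.grid(n = group_sizes, delta_ms = effect_sizes,
                       noise_sd_ms = noise_sds, KEEP.OUT.ATTRS = FALSE)
  cells <- cells[order(cells$n, cells$delta_ms, cells$noise_sd_ms), ,
                 drop = FALSE]
  rownames(cells) <- NULL
  cells$cell <- seq_len(nrow(cells))
  cells <- cells[, c("cell", "n", "delta_ms", "noise_sd_ms")]
  B <- resampling_cfg$n_bootstrap
  P <- resampling_cfg$n_permutation
  per_sim <- B + P + if (run_stratified) B else 0L
  n_sim_total <- nrow(cells) * n_sims
  totals <- list(
    n_simulations = n_sim_total,
    n_resamples = n_sim_total * per_sim,
    n_bin_fits = n_sim_total * per_sim * binning_cfg$n_bins * 2
  )
  structure(list(cells = cells, n_sims = as.integer(n_sims),
                 resampling_cfg = resampling_cfg, latency_cfg = latency_cfg,
                 binning_cfg = binning_cfg, run_stratified = run_stratified,
                 sample_with_replacement = sample_with_replacement,
                 condition_balanced = condition_balanced,
                 master_seed = as.integer(master_seed), totals = totals),
            class = "simulation_plan")
}

#' @export
print.simulation_plan <- function(x, ...) {
  cat(sprintf(
    "<simulation_plan> %d cells x %d sims = %s simulations\n",
    nrow(x$cells), x$n_sims, format(x$totals$n_simulations, big.mark = ",")))
  cat(sprintf("  resampled datasets: %s | bin-level fits: %s\n",
              format(x$totals$n_resamples, big.mark = ","),
              format(x$totals$n_bin_fits, big.mark = ",", scientific = FALSE)))
  invisible(x)
}

# deterministic child seed below 2^31 for (master, cell, sim)
child_seed <- function(master, cell, sim) {
  as.integer((as.double(master) * 48271 + cell * 100003 + sim * 7919) %%
               2147483629)
}

# sample 2n participants from a pool and split into baseline/shifted
draw_groups <- function(pool_ids, pool_cond, n, with_replacement,
                        condition_balanced) {
  if (condition_balanced) {
    conds <- split(pool_ids, pool_cond)
    k <- length(conds)
    if (n %% k != 0) {
      stop(sprintf("condition-balanced draw: group size %d not divisible by %d conditions",
                   n, k), call. = FALSE)
    }
    per <- 2L * n / k
    picked <- lapply(conds, function(ids) {
      if (!with_replacement && length(ids) < per) {
        stop("insufficient participants in a condition stratum", call. = FALSE)
      }
      sample(ids, per, replace = with_replacement)
    })
    # split each condition's draw evenly between groups
    base <- unlist(lapply(picked, function(x) x[seq_len(per / 2)]),
                   use.names = FALSE)
    shift <- unlist(lapply(picked, function(x) x[(per / 2 + 1):per]),
                    use.names = FALSE)
  } else {
    if (!with_replacement && length(pool_ids) < 2L * n) {
      stop(sprintf("insufficient pool: need %d participants, have %d",
                   2L * n, length(pool_ids)), call. = FALSE)
    }
    picked <- sample(pool_ids, 2L * n, replace = with_replacement)
    base <- picked[seq_len(n)]
    shift <- picked[(n + 1L):(2L * n)]
  }
  list(baseline = base, shifted = shift)
}

#' Run one simulation
#'
#' Executes one iteration of the Monte Carlo protocol for one cell: draw
#' `2n` participants (from a seed gaze-table pool, or freshly generated from
#' a [synthetic_spec()]), split them into Baseline and Shifted groups, shift
#' the Shifted group's sample times by the cell's effect size, optionally add
#' per-participant timing noise, bin, estimate all requested latency
#' measures, and run the bootstrap (by-participant, plus stratified when the
#' plan requests it) and the permutation test.
#'
#' @param seed_data a [gaze_table()] pool to subsample, or a
#'   [synthetic_spec()] from which a fresh `2n`-participant null dataset is
#'   generated for the simulation.
#' @param cell one row of `plan$cells` (or a list with `n`, `delta_ms`,
#'   `noise_sd_ms`).
#' @param plan a [build_plan()] result.
#' @param sim_index index of this simulation within the cell (seeds the RNG
#'   together with the plan's master seed).
#' @param measures latency measures to evaluate (default: all four).
#' @return a `data.frame` with one row per measure x bootstrap scheme:
#'   observed latencies and difference, censoring flags, permutation p, and
#'   lower/upper bounds for every CI method.
#' @export
run_simulation <- function(seed_data, cell, plan, sim_index = 1L,
                           measures = latency_measures()) {
  rcfg <- plan$resampling_cfg
  lcfg <- plan$latency_cfg
  bcfg <- plan$binning_cfg
  set.seed(child_seed(plan$master_seed, cell$cell %||% 0L, sim_index))
  n <- cell$n
  if (inherits(seed_data, "synthetic_spec")) {
    spec <- seed_data
    spec$n_participants <- n
    spec$seed <- NULL
    g <- generate_gaze(spec, seed = NULL)$gaze
    # regenerated data already has baseline/shifted labels; randomize the
    # group split so the generator's delta (usually 0) and the cell's shift
    # compose correctly
    ids <- unique(g$participant)
    cond <- tapply(g$condition, g$participant, function(x) x[1L])[ids]
    grp <- draw_groups(ids, cond, n, FALSE, plan$condition_balanced)
    relab <- stats::setNames(rep("baseline", length(ids)), ids)
    relab[grp$shifted] <- "shifted"
    g$group <- unname(relab[g$participant])
  } else {
    ids <- unique(seed_data$participant)
    first <- !duplicated(seed_data$participant)
    cond <- stats::setNames(seed_data$condition[first],
                            seed_data$participant[first])[ids]
    grp <- draw_groups(ids, cond, n, plan$sample_with_replacement,
                       plan$condition_balanced)
    picked <- c(grp$baseline, grp$shifted)
    # clone relabeling keeps duplicated draws distinct participants
    new_id <- sprintf("%s#%d", picked, seq_along(picked))
    row_idx <- split(seq_len(nrow(seed_data)), seed_data$participant)
    rows <- row_idx[picked]
    g <- seed_data[unlist(rows, use.names = FALSE), , drop = FALSE]
    g$participant <- rep(new_id, lengths(rows))
    g$group <- rep(rep(c("baseline", "shifted"), each = n), lengths(rows))
    class(g) <- c("gaze_table", "data.frame")
  }
  if (cell$delta_ms != 0) g <- shift_group_time(g, "shifted", cell$delta_ms)
  if (cell$noise_sd_ms > 0) g <- add_participant_noise(g, cell$noise_sd_ms)
  counts <- gaze_to_counts(g, bcfg)
  rcfg$seed <- NULL
  rcfg$stratify_by_condition <- plan$condition_balanced
  analyze_counts(counts, "counts", rcfg, lcfg, bcfg, measures,
                 groups = c("baseline", "shifted"),
                 run_stratified = plan$run_stratified,
                 cell = cell, sim_index = sim_index)
}

# shared core of run_simulation and compare_onsets: observed estimates +
# bootstrap CIs (+ optional stratified bootstrap) + permutation p
analyze_counts <- function(counts, type, rcfg, lcfg, bcfg, measures, groups,
                           run_stratified = FALSE, cell = NULL,
                           sim_index = NA_integer_) {
  tests_fun <- tests_fun_for(type)
  gs <- resolve_groups(counts, groups)
  obs <- latency_diffs_multi(tests_fun(counts, gs$shift_rows, lcfg),
                             tests_fun(counts, gs$base_rows, lcfg),
                             lcfg, bcfg, measures)
  perm <- permutation_test(counts, rcfg, lcfg, bcfg, measures, groups)
  jack <- if ("bca" %in% rcfg$ci_methods) {
    jackknife_latency_diff(counts, lcfg, bcfg, measures, groups)
  } else NULL
  schemes <- c("by_participant", if (run_stratified) "stratified")
  out <- list()
  for (scheme in schemes) {
    dist <- if (scheme == "by_participant") {
      bootstrap_by_participant(counts, rcfg, lcfg, bcfg, measures, groups)
    } else {
      bootstrap_stratified(counts, rcfg, lcfg, bcfg, measures, groups)
    }
    for (ms in measures) {
      row <- data.frame(
        cell = if (!is.null(cell)) cell$cell %||% NA_integer_ else NA_integer_,
        n = if (!is.null(cell)) cell$n else length(gs$base_rows),
        delta_ms = if (!is.null(cell)) cell$delta_ms else NA_real_,
        noise_sd_ms = if (!is.null(cell)) cell$noise_sd_ms else NA_real_,
        sim = sim_index, measure = ms, scheme = scheme,
        onset_baseline = obs$onset_baseline[[ms]],
        onset_shifted = obs$onset_shifted[[ms]],
        diff = obs$diff[[ms]], censored = obs$censored[[ms]],
        perm_p = perm$p_value[[ms]],
        boot_censored_fraction = dist$censored_fraction[[ms]],
        stringsAsFactors = FALSE)
      for (mtd in rcfg$ci_methods) {
        ci <- bootstrap_ci(dist, obs$diff[[ms]], mtd, rcfg$ci_level,
                           jackknife_values = if (mtd == "bca") jack[, ms],
                           measure = ms)
        row[[paste0("lower_", mtd)]] <- ci$lower_ms
        row[[paste0("upper_", mtd)]] <- ci$upper_ms
      }
      out[[length(out) + 1L]] <- row
    }
  }
  do.call(rbind, out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a full simulation plan
#'
#' Loops all cells and simulations of a plan and row-binds the per-simulation
#' records. Cells are independent given the master seed, so results do not
#' depend on execution order.
#'
#' @param plan a [build_plan()] result.
#' @param seed_data pool gaze table or [synthetic_spec()] (see
#'   [run_simulation()]).
#' @param measures latency measures to evaluate.
#' @param progress print per-cell progress to stderr.
#' @return data.frame of simulation records (class `simulation_records`).
#' @export
run_plan <- function(plan, seed_data, measures = latency_measures(),
                     progress = FALSE) {
  recs <- vector("list", nrow(plan$cells) * plan$n_sims)
  k <- 0L
  for (ci in seq_len(nrow(plan$cells))) {
    cell <- plan$cells[ci, ]
    if (progress) {
      message(sprintf("cell %d/%d: n=%d delta=%g noise=%g",
                      ci, nrow(plan$cells), cell$n, cell$delta_ms,
                      cell$noise_sd_ms))
    }
    for (s in seq_len(plan$n_sims)) {
      k <- k + 1L
      recs[[k]] <- run_simulation(seed_data, cell, plan, s, measures)
    }
  }
  out <- do.call(rbind, recs)
  class(out) <- c("simulation_records", "data.frame")
  out
}

#' Aggregate simulation records of one cell
#'
#' Summarizes the records of one simulation cell into power or Type I error
#' (with Wilson confidence intervals), per-CI-method coverage of the true
#' effect size, and latency-distribution summaries. For cells with
#' `true_delta > 0`, the bootstrap "power" counts simulations whose CI lower
#' bound is strictly above 0 and the permutation power counts simulations
#' with a positive observed difference and p below `alpha`; for null cells
#' (`true_delta = 0`), Type I error counts CIs strictly excluding 0 and
#' permutation rejections at `alpha`. Coverage counts CIs containing
#' `true_delta`.
#'
#' @param records simulation records (one cell) from [run_plan()] or
#'   [run_simulation()].
#' @param alpha significance level for the permutation test (default 0.05).
#' @param true_delta the cell's true latency difference in ms.
#' @param level Wilson interval level (default 0.95).
#' @return a `data.frame` (class `cell_summary`): one row per
#'   measure x scheme x test with columns `test`, `estimate` (power or Type I),
#'   `wilson_lower`, `wilson_upper`, `coverage`, `n_sims`,
#'   `censored_fraction`, `mean_diff`, `sd_diff`.
#' @export
aggregate_cell <- function(records, alpha = 0.05, true_delta = 0,
                           level = 0.95) {
  if (!nrow(records)) stop("aggregate_cell: no records", call. = FALSE)
  ci_methods <- sub("^lower_", "",
                    grep("^lower_", names(records), value = TRUE))
  is_power <- true_delta > 0
  out <- list()
  for (ms in unique(records$measure)) {
    for (sch in unique(records$scheme)) {
      r <- records[records$measure == ms & records$scheme == sch, ,
                   drop = FALSE]
      nsim <- nrow(r)
      add <- function(test, hits, coverage = NA_real_) {
        w <- wilson_interval(hits, nsim, level)
        out[[length(out) + 1L]] <<- data.frame(
          measure = ms, scheme = sch, test = test,
          estimate = w$estimate, wilson_lower = w$lower,
          wilson_upper = w$upper, coverage = coverage, n_sims = nsim,
          censored_fraction = mean(r$censored),
          mean_diff = mean(r$diff), sd_diff = stats::sd(r$diff),
          stringsAsFactors = FALSE)
      }
      # permutation test only once (scheme-independent): report under
      # by_participant rows
      if (sch == "by_participant") {
        hits <- if (is_power) sum(r$diff > 0 & r$perm_p < alpha) else
          sum(r$perm_p < alpha)
        add("permutation", hits)
      }
      for (mtd in ci_methods) {
        lo <- r[[paste0("lower_", mtd)]]
        hi <- r[[paste0("upper_", mtd)]]
        hits <- if (is_power) sum(lo > 0) else sum(lo > 0 | hi < 0)
        add(paste0("ci_", mtd), hits,
            coverage = mean(lo <= true_delta & true_delta <= hi))
      }
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("cell_summary", "data.frame")
  res
}

#' Pooled power and coverage from null-cell bootstrap intervals
#'
#' The shape of the bootstrap distribution of a latency difference does not
#' depend on the injected shift: shifting one group by `delta` translates the
#' whole distribution, and hence the CI bounds, by `delta`. Null-cell
#' (`delta = 0`) intervals can therefore be translated by each effect size of
#' interest and re-scored, pooling many simulations into more precise power
#' and coverage estimates per CI method.
#'
#' @param records simulation records from a `delta_ms = 0` cell.
#' @param effect_sizes effect sizes (ms) to translate to.
#' @param level Wilson interval level.
#' @return data.frame: per measure x scheme x CI method x effect size, the
#'   translated power/Type-I estimate with Wilson bounds and coverage; plus
#'   pooled rows (`delta_ms = NA`) averaging over the effect sizes.
#' @export
pooled_shift_estimates <- function(records, effect_sizes, level = 0.95) {
  stopifnot(all(records$delta_ms == 0 | is.na(records$delta_ms)))
  ci_methods <- sub("^lower_", "",
                    grep("^lower_", names(records), value = TRUE))
  out <- list()
  for (ms in unique(records$measure)) {
    for (sch in unique(records$scheme)) {
      r <- records[records$measure == ms & records$scheme == sch, ,
                   drop = FALSE]
      nsim <- nrow(r)
      for (mtd in ci_methods) {
        lo0 <- r[[paste0("lower_", mtd)]]
        hi0 <- r[[paste0("upper_", mtd)]]
        per_delta <- lapply(effect_sizes, function(d) {
          lo <- lo0 + d; hi <- hi0 + d
          hits <- if (d > 0) sum(lo > 0) else sum(lo > 0 | hi < 0)
          w <- wilson_interval(hits, nsim, level)
          data.frame(measure = ms, scheme = sch, test = paste0("ci_", mtd),
                     delta_ms = d, estimate = w$estimate,
                     wilson_lower = w$lower, wilson_upper = w$upper,
                     coverage = mean(lo <= d & d <= hi), n_sims = nsim,
                     stringsAsFactors = FALSE)
        })
        per_delta <- do.call(rbind, per_delta)
        pooled <- data.frame(
          measure = ms, scheme = sch, test = paste0("ci_", mtd),
          delta_ms = NA_real_, estimate = mean(per_delta$estimate),
          wilson_lower = NA_real_, wilson_upper = NA_real_,
          coverage = mean(per_delta$coverage),
          n_sims = nsim * length(effect_sizes), stringsAsFactors = FALSE)
        out[[length(out) + 1L]] <- rbind(per_delta, pooled)
      }
    }
  }
  do.call(rbind, out)
}
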