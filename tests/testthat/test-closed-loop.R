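# Schedule sampling, the loop itself, and the evaluation scaffolding.

test_that("schedule sampling draws k amplitudes per type without replacement", {
  for (k in 1:4) {
    stimuli <- sample_schedule_stimuli(default_grid, k, seed = k)
    expect_length(stimuli, 5L * k)
    df <- data.frame(
      t = vapply(stimuli, function(p) p$type_index, integer(1)),
      a = vapply(stimuli, function(p) p$cathodic_amplitude_uA, integer(1)))
    expect_equal(unname(table(df$t)), rep(k, 5), ignore_attr = TRUE)
    expect_false(any(duplicated(df)))
  }
  expect_error(sample_schedule_stimuli(default_grid, 7, seed = 1),
               "exceeds")
})

test_that("schedule sampling is seeded and deliverable", {
  s1 <- sample_schedule_stimuli(default_grid, 2, seed = 5)
  s2 <- sample_schedule_stimuli(default_grid, 2, seed = 5)
  expect_identical(s1, s2)
  grid_keys <- vapply(default_grid$pulses, function(p)
    paste(p$type_index, p$cathodic_amplitude_uA), character(1))
  for (p in s1) {
    expect_true(paste(p$type_index, p$cathodic_amplitude_uA) %in% grid_keys)
  }
})

test_that("best_attainable_class follows the desirability order", {
  reg <- fixture_region
  cls <- vapply(default_grid$pulses, function(p)
    latent_class(reg, p$cathodic_amplitude_uA, p$type_index), integer(1))
  best <- best_attainable_class(reg, default_grid)
  expect_true(best %in% cls)
  if (1L %in% cls) expect_equal(best, 1L)
  # order property on synthetic label sets
  expect_equal(focalstim:::best_class(c(0L, 2L, 4L)), 2L)
  expect_equal(focalstim:::best_class(c(0L, 0L)), 0L)
  expect_equal(focalstim:::best_class(c(4L, 3L)), 3L)
  expect_equal(focalstim:::best_class(c(3L, 1L, 2L)), 1L)
})

test_that("run_region logs the full schedule and stops on the target class", {
  log <- run_region(fixture_region,
                    seeds = list(sampling = 1, training = 2, rendering = 3))
  expect_equal(log$schedule, c(5L, 10L, 15L, 20L, 46L))
  expect_lte(length(log$iterations), 5L)
  for (i in seq_along(log$iterations)) {
    expect_equal(log$iterations[[i]]$n_trials, log$schedule[i])
  }
  if (!is.na(log$stop_iteration)) {
    last <- log$iterations[[log$stop_iteration]]
    expect_equal(last$delivered$class, log$target_class)
    expect_equal(log$achieved_class, log$target_class)
  }
  # delivered stimuli are deliverable-set members
  for (it in log$iterations) {
    if (!is.null(it$delivered)) {
      expect_true(it$delivered$cathodic_amplitude_uA %%
                    it$delivered$duration_ratio == 0)
    }
  }
})

test_that("cumulative mode pools trials from earlier iterations", {
  seeds <- list(sampling = 31, training = 32, rendering = 33)
  log <- run_region(fixture_region, seeds = seeds, target_class = -1L,
                    cumulative = TRUE)
  # with an unreachable target the loop runs the full schedule; by the
  # second iteration the cumulative training pool exceeds the fresh
  # sample, so the surrogate sees more points than n_trials
  n_pts <- vapply(log$iterations, function(it)
    if (is.null(it$surrogate)) NA_integer_ else
      as.integer(it$surrogate$n_points), integer(1))
  n_fresh <- vapply(log$iterations, function(it) it$n_trials, integer(1))
  later <- which(!is.na(n_pts))
  later <- later[later >= 2]
  expect_true(any(n_pts[later] > n_fresh[later]))
})

test_that("an all-subthreshold region yields class 0 and no surrogate", {
  hyper <- region_hyper(threshold_range = c(150, 160))
  reg <- sample_region(4, hyper = hyper)
  log <- run_region(reg, seeds = list(sampling = 1, training = 2,
                                      rendering = 3))
  expect_equal(log$achieved_class, 0L)
  expect_true(is.na(log$stop_iteration))
  for (it in log$iterations) expect_null(it$surrogate)
})

test_that("run logs are bit-identical JSON for identical seed triples", {
  seeds <- list(sampling = 21, training = 22, rendering = 23)
  j1 <- write_run_log(run_region(fixture_region, seeds = seeds))
  j2 <- write_run_log(run_region(fixture_region, seeds = seeds))
  expect_identical(as.character(j1), as.character(j2))
  j3 <- write_run_log(run_region(fixture_region,
                                 seeds = list(sampling = 24, training = 22,
                                              rendering = 23)))
  expect_false(identical(as.character(j1), as.character(j3)))
})

test_that("random-control closed form matches a direct Monte Carlo check", {
  # oracle: for m best-class points among 46, P(hit in k draws) =
  # 1 - choose(46 - m, k) / choose(46, k)
  set.seed(8)
  for (m in c(1, 3, 8)) {
    for (k in c(5, 15)) {
      cf <- control_success_prob(m, k, 46)
      mc <- mean(replicate(8000, any(sample(46, k) <= m)))
      expect_lt(abs(mc - cf), 0.02)
    }
  }
  expect_equal(control_success_prob(0, 5), 0)
  expect_equal(control_success_prob(3, 46), 1)
  expect_equal(control_success_prob(2, 45), 1)
})

test_that("on a designed ensemble every run reaches the best class by
           schedule end", {
  # designed conditions: class 1 or 2 attainable everywhere, roundest
  # type restricted to ratios with fine amplitude rounding, noiseless
  # imaging — the loop must always converge within the schedule
  hyper <- region_hyper(t_opt_choices = 3:4)
  grid <- build_grid()
  for (r in 1:12) {
    reg <- sample_region(derive_seed(7, 1, r), hyper = hyper)
    cls <- vapply(grid$pulses, function(p)
      latent_class(reg, p$cathodic_amplitude_uA, p$type_index), integer(1))
    best <- focalstim:::best_class(cls)
    expect_true(best %in% c(1L, 2L))
    log <- run_region(reg, grid = grid,
                      seeds = list(sampling = derive_seed(7, 2, r),
                                   training = derive_seed(7, 3, r),
                                   rendering = derive_seed(7, 4, r)),
                      noiseless = TRUE)
    lat <- vapply(log$iterations, function(it)
      if (is.null(it$delivered)) NA_integer_ else it$delivered$latent_class,
      integer(1))
    achieved <- any(!is.na(lat) & focalstim:::class_rank(lat) <=
                      focalstim:::class_rank(best))
    expect_true(achieved, label = sprintf("region %d converged", r))
  }
})

test_that("evaluation curves are monotone and bounded", {
  ev <- evaluate_ensemble(n_regions = 3, n_repeats = 2, seed = 3)
  expect_equal(ev$trial_counts, c(5L, 10L, 15L, 20L))
  for (curve in list(ev$method_curve, ev$control_curve,
                     ev$control_closed_form)) {
    expect_true(all(curve >= 0 & curve <= 1))
    expect_true(all(diff(curve) >= -1e-12))   # cumulative definition
  }
  expect_length(ev$runs, 6L)
})
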