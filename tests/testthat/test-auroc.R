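test_that("bin_counts follows the half-open bin convention", {
  task <- small_task()
  ev <- trial_schedule(task, "conditioning")
  ev <- ev[ev$cue_id == "B", ][1, , drop = FALSE]
  key <- trial_key(ev$session_id, ev$trial)

  # no spikes -> all-zero counts
  cnt <- bin_counts(numeric(0), character(0), ev, c(0, 1), 0.1)
  expect_true(all(cnt == 0))
  expect_equal(dim(cnt), c(1, 10))

  # a spike exactly on a bin boundary falls in the later bin
  st <- ev$cue_on + 0.1
  cnt <- bin_counts(st, key, ev, c(0, 1), 0.1)
  expect_equal(unname(cnt[1, ]), c(0, 1, 0, 0, 0, 0, 0, 0, 0, 0))

  # 10 spikes placed at the left edges of 100-ms bins -> one per bin
  st <- ev$cue_on + seq(0, 0.9, by = 0.1)
  cnt <- bin_counts(st, rep(key, 10), ev, c(0, 1), 0.1)
  expect_equal(unname(cnt[1, ]), rep(1, 10))

  # window outside the recorded trial span is rejected
  expect_error(bin_counts(st, rep(key, 10), ev, c(-5, 1), 0.1),
               "outside the recorded trial span")
})

test_that("auroc_bin reproduces the analytic cases", {
  # identical multisets lie on the diagonal: exactly 0.5
  expect_identical(auroc_bin(c(0, 1, 1, 2, 3), c(0, 1, 1, 2, 3)), 0.5)
  expect_identical(auroc_bin(c(2, 2, 2), c(2, 2, 2)), 0.5)
  # perfect separation
  expect_equal(auroc_bin(c(5, 5, 5), c(0, 0, 0)), 1.0)
  expect_equal(auroc_bin(c(0, 0, 0), c(5, 5, 5)), 0.0)
  # a worked small instance, against the independent brute-force oracle
  expect_equal(auroc_bin(c(2, 3), c(0, 1, 1, 2)),
               oracle_auroc(c(2, 3), c(0, 1, 1, 2)), tolerance = 1e-12)
  # empty inputs are rejected
  expect_error(auroc_bin(numeric(0), c(1, 2)), "non-empty")
})

test_that("auroc_bin matches the brute-force oracle on random instances", {
  set.seed(42)
  for (i in 1:300) {
    test <- rpois(sample(1:8, 1), sample(0:4, 1))
    base <- rpois(sample(1:12, 1), sample(0:4, 1))
    expect_equal(auroc_bin(test, base), oracle_auroc(test, base),
                 tolerance = 1e-12)
  }
})

test_that("auroc_bin satisfies its order and scale invariances", {
  set.seed(7)
  for (i in 1:50) {
    test <- rpois(6, 2)
    base <- rpois(10, 2)
    a <- auroc_bin(test, base)
    expect_gte(a, 0)
    expect_lte(a, 1)
    # monotone: adding a constant to every test count never decreases it
    expect_gte(auroc_bin(test + 2, base) + 1e-12, a)
    # scale invariance: min-max normalization absorbs positive scaling
    expect_equal(auroc_bin(3 * test, 3 * base), a, tolerance = 1e-12)
  }
})

test_that("null neurons give auROC values near 0.5 across bins", {
  task <- task_spec(cond_trials_per_cue = 12)
  flat <- archetype_params("phasic", baseline_rate = 5, phasic_gain = 0,
                           noise_sd = 0)
  pop <- population_spec(n_phasic = 50, n_sustained_excited = 0,
                         n_sustained_inhibited = 0, seed = 50,
                         phasic = flat,
                         coding_sd = c(b_minus_d = 0, a_minus_c = 0),
                         coding_mean = c(b_minus_d = 0, a_minus_c = 0))
  ds <- simulate_population(pop, task, phases = "conditioning")
  mat <- auroc_matrix(ds$spikes, ds$events, "B", window = c(0, 2))
  expect_true(all(mat$values >= 0 & mat$values <= 1))
  inside <- mean(abs(mat$values - 0.5) <= 0.1)
  expect_gte(inside, 0.95)
})

test_that("excitation during the cue raises cue-bin auROC above pre-cue", {
  task <- small_task()
  params <- archetype_params("sustained_excited", baseline_rate = 8,
                             sustained_gain = 8, noise_sd = 0)
  pop <- population_spec(n_phasic = 0, n_sustained_excited = 5,
                         n_sustained_inhibited = 0, seed = 8,
                         sustained_excited = params)
  ds <- simulate_population(pop, task, phases = "conditioning")
  mat <- auroc_matrix(ds$spikes, ds$events, "B", window = c(-1, 2))
  pre <- mat$bin_centers < 0
  expect_gt(mean(mat$values[, !pre]), mean(mat$values[, pre]))
  # single-trial degenerate case: one bin equal to all baseline bins
  expect_identical(auroc_bin(2, rep(2, 10)), 0.5)
})

test_that("auroc_matrix rejects a cue with no trials", {
  task <- small_task()
  ev <- trial_schedule(task, "conditioning")
  sp <- data.frame(neuron_id = 1, session_id = ev$session_id[1],
                   trial = ev$trial[1], spike_time = 3)
  expect_error(auroc_matrix(sp, ev[ev$cue_id == "B", ], "A"),
               "no trials for cue A")
})

test_that("analysis_config enforces bin/window compatibility", {
  expect_error(analysis_config(bin_width = 0.3), "divide")
  expect_error(analysis_config(threshold_step = 0), "threshold_step")
  cfg <- analysis_config()
  expect_equal(cfg$bin_width, 0.1)
  expect_equal(cfg$threshold_step, 0.01)
  expect_equal(cfg$sustained_window, c(1, 10))
})
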