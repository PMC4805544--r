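probe_data <- function(seed, n = 12, rho = 0.6, ...) {
  task <- task_spec()
  pop <- population_spec(n_phasic = n, n_sustained_excited = 0,
                         n_sustained_inhibited = 0, seed = seed, rho = rho,
                         ...)
  ds <- simulate_population(pop, task, phases = "probe")
  ds$task <- task
  ds
}

test_that("cue contrasts are antisymmetric and match textbook statistics", {
  ds <- probe_data(31)
  bd <- phasic_contrast(ds$spikes, ds$events, "B", "D")
  db <- phasic_contrast(ds$spikes, ds$events, "D", "B")
  expect_equal(bd$per_neuron$difference, -db$per_neuron$difference)
  expect_equal(bd$t, -db$t)
  expect_equal(bd$df, length(unique(ds$spikes$neuron_id)) - 1)

  ref <- oracle_paired_t(bd$per_neuron$response_pos,
                         bd$per_neuron$response_neg)
  expect_equal(bd$t, ref$t, tolerance = 1e-10)
  expect_equal(bd$p, ref$p, tolerance = 1e-10)

  ac <- phasic_contrast(ds$spikes, ds$events, "A", "C")
  cc <- inferred_vs_cached_correlation(bd$per_neuron$difference,
                                       ac$per_neuron$difference)
  ref <- oracle_pearson(bd$per_neuron$difference, ac$per_neuron$difference)
  expect_equal(cc$r, ref$r, tolerance = 1e-10)
  expect_equal(cc$p, ref$p, tolerance = 1e-10)
  expect_equal(cc$df, cc$n - 2)
})

test_that("probe contrasts recover the generator's coding structure", {
  ds <- probe_data(32, n = 40)
  bd <- phasic_contrast(ds$spikes, ds$events, "B", "D")
  ac <- phasic_contrast(ds$spikes, ds$events, "A", "C")
  # estimated contrasts track the per-neuron ground truth
  expect_gt(cor(bd$per_neuron$difference, ds$truth$b_minus_d), 0.7)
  expect_gt(cor(ac$per_neuron$difference, ds$truth$a_minus_c), 0.7)
  expect_gt(bd$mean_difference, 0)
  expect_gt(ac$mean_difference, 0)
  # duplicated contrast correlates perfectly with itself
  cc <- inferred_vs_cached_correlation(bd$per_neuron$difference,
                                       bd$per_neuron$difference)
  expect_equal(cc$r, 1)
  # degenerate inputs are rejected
  expect_error(inferred_vs_cached_correlation(rep(1, 5), rnorm(5)),
               "zero variance")
})

test_that("auroc-unit contrasts agree in sign with rate-unit contrasts", {
  ds <- probe_data(33, n = 15)
  r <- phasic_contrast(ds$spikes, ds$events, "B", "D", units = "rate")
  a <- phasic_contrast(ds$spikes, ds$events, "B", "D", units = "auroc")
  expect_equal(sign(a$mean_difference), sign(r$mean_difference))
  expect_true(all(abs(a$per_neuron$response_pos) <= 0.5 + 1e-12))
})

test_that("sustained contrast isolates the late-cue inferred-value signal", {
  ds <- probe_data(34, n = 40)
  ac <- sustained_contrast(ds$spikes, ds$events, "A", "C")
  expect_gt(ac$mean_difference, 0)
  expect_equal(ac$window, c(1, 10))
  # removing the sustained transfer component centres the contrast on zero
  ds0 <- probe_data(35, n = 40,
                    phasic = archetype_params("phasic",
                                              sustained_transfer = 0))
  ac0 <- sustained_contrast(ds0$spikes, ds0$events, "A", "C")
  expect_lt(abs(ac0$mean_difference), 3 * stats::sd(ac0$per_neuron$difference) /
              sqrt(nrow(ac0$per_neuron)))
})

test_that("onset-reward difference tracks the learning trajectory", {
  task <- task_spec()
  pop <- population_spec(n_phasic = 25, n_sustained_excited = 0,
                         n_sustained_inhibited = 0, seed = 36)
  ds <- simulate_population(pop, task, phases = "conditioning")
  first <- ds$events$session_id == 3
  last <- ds$events$session_id == 8
  m1 <- auroc_matrix(ds$spikes[ds$spikes$session_id == 3, ],
                     ds$events[first, ], "B", window = c(0, 1.5))
  m6 <- auroc_matrix(ds$spikes[ds$spikes$session_id == 8, ],
                     ds$events[last, ], "B", window = c(0, 1.5))
  d1 <- onset_reward_difference(m1)
  d6 <- onset_reward_difference(m6)
  # reward-dominated early, onset-dominated late
  expect_lt(mean(d1), 0)
  expect_gt(mean(d6), 0)

  mig <- migration_analysis(ds$spikes, ds$events, task)
  expect_gt(mig$correlation$r, 0)
  expect_lt(mig$correlation$p, 0.05)
  expect_equal(mig$correlation$df, mig$correlation$n - 2)
  # flat neurons give a near-zero difference
  flat <- population_spec(n_phasic = 10, n_sustained_excited = 0,
                          n_sustained_inhibited = 0, seed = 37,
                          phasic = archetype_params("phasic", phasic_gain = 0,
                                                    noise_sd = 0))
  dsf <- simulate_population(flat, task, phases = "conditioning")
  mf <- auroc_matrix(dsf$spikes[dsf$spikes$session_id == 3, ],
                     dsf$events[dsf$events$session_id == 3, ], "B",
                     window = c(0, 1.5))
  expect_lt(abs(mean(onset_reward_difference(mf))), 0.05)
})

test_that("migration correlation rejects degenerate inputs", {
  expect_error(migration_correlation(rep(0.2, 10), rep(1:5, 2)),
               "zero variance")
  expect_error(migration_correlation(c(1, 2), c(1, 2)), "at least 3")
})

test_that("behavioral ANOVAs detect conditioning and flag degenerate data", {
  task <- task_spec()
  bh <- simulate_behavior(task, behavior_params(n_rats = 14), seed = 38)
  cond <- behavior_stats(bh, "conditioning")
  cue_row <- cond$anova[cond$anova$term == "cue_id", ]
  expect_lt(cue_row$p, 0.05)
  expect_gt(cue_row$F, 1)
  probe <- behavior_stats(bh, "probe")
  expect_lt(probe$anova$p[probe$anova$term == "cue_id"], 0.05)

  # all-zero occupancy is flagged, not tested
  bh0 <- simulate_behavior(task, behavior_params(n_rats = 2, base = 0,
                                                 asymptote = 0, transfer = 0,
                                                 c_level = 0), seed = 39)
  z <- behavior_stats(bh0, "conditioning")
  expect_true(z$degenerate)

  # preconditioning cue effect behaves like a null test
  pre <- behavior_stats(bh, "preconditioning")
  expect_equal(nrow(pre$anova), 1)
})
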