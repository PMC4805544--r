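# build an auroc_matrix object directly, for tests that need exact traces
fake_auroc_matrix <- function(values, window = c(0, 10), bin_width = 0.1) {
  nb <- ncol(values)
  structure(list(values = values, neuron_ids = seq_len(nrow(values)),
                 bin_centers = window[1] + (seq_len(nb) - 0.5) * bin_width,
                 cue_id = "B", window = window,
                 config = analysis_config()),
            class = "auroc_matrix")
}

test_that("response_pca recovers structure and fixes signs", {
  # identical rows: zero centered variance, all scores equal
  m <- matrix(rep(c(0.5, 0.7, 0.6, 0.5), each = 6), nrow = 6)
  p <- response_pca(m, 2)
  expect_true(all(abs(p$scores) < 1e-12))
  expect_false(any(is.na(p$explained)))

  # rank-1 matrix plus tiny noise: first component carries >99% variance
  set.seed(11)
  u <- rnorm(30); v <- rnorm(40)
  m <- outer(u, v) + matrix(rnorm(1200, sd = 1e-3), 30)
  p <- response_pca(m, 3)
  expect_gt(p$explained[1], 0.99)
  # deterministic sign: largest-magnitude loading positive per component
  for (j in 1:3) {
    expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
  }

  # scores + loadings reproduce the best rank-3 approximation (Eckart-Young)
  set.seed(12)
  m <- matrix(rnorm(25 * 18), 25)
  p <- response_pca(m, 3)
  recon <- p$scores %*% t(p$loadings) +
    matrix(p$center, 25, 18, byrow = TRUE)
  sv <- svd(scale(m, scale = FALSE))
  best3 <- sv$u[, 1:3] %*% diag(sv$d[1:3]) %*% t(sv$v[, 1:3]) +
    matrix(colMeans(m), 25, 18, byrow = TRUE)
  expect_equal(recon, best3, tolerance = 1e-8)
  err3 <- sum((m - recon)^2)
  best2 <- sv$u[, 1:2] %*% diag(sv$d[1:2]) %*% t(sv$v[, 1:2]) +
    matrix(colMeans(m), 25, 18, byrow = TRUE)
  expect_lte(err3, sum((m - best2)^2))

  expect_error(response_pca(matrix(0, 2, 5), 3), "n_components")
})

test_that("cluster_neurons separates well-separated clouds and handles k = n", {
  set.seed(13)
  x <- rbind(matrix(rnorm(20, 0, 0.1), ncol = 2),
             matrix(rnorm(20, 10, 0.1), ncol = 2),
             matrix(rnorm(20, -10, 0.1), ncol = 2))
  truth <- rep(1:3, each = 10)
  cl <- cluster_neurons(x, 3)
  expect_true(same_partition(cl, truth))

  expect_equal(cluster_neurons(x[1:4, ], 4), 1:4)
  expect_error(cluster_neurons(x[1:2, ], 3), "fewer neurons")
})

test_that("clustering matches the naive complete-linkage oracle", {
  set.seed(14)
  for (i in 1:12) {
    n <- sample(5:30, 1)
    d <- sample(2:3, 1)
    x <- matrix(rnorm(n * d, sd = 2), n) +
      matrix(rnorm(3, sd = 6)[sample(1:3, n, TRUE)], n, d)
    for (k in c(2, 3)) {
      expect_true(same_partition(cluster_neurons(x, k),
                                 oracle_complete_linkage(x, k)))
    }
  }
})

test_that("archetype labelling assigns the three response types", {
  set.seed(15)
  nb <- 100
  centers <- seq(0.05, 9.95, by = 0.1)
  phasic_tr <- 0.5 + 0.4 * exp(-centers / 0.3) +
    0.35 * (exp(-pmax(centers - 1, 0) / 0.3) * (centers >= 1))
  exc_tr <- rep(0.75, nb)
  inh_tr <- rep(0.3, nb)
  mk <- function(tr, n) {
    t(replicate(n, pmin(1, pmax(0, tr + rnorm(nb, sd = 0.02)))))
  }
  vals <- rbind(mk(phasic_tr, 8), mk(exc_tr, 8), mk(inh_tr, 8))
  mat <- fake_auroc_matrix(vals)
  clusters <- rep(1:3, each = 8)
  lab <- label_archetypes(clusters, mat)
  expect_equal(lab$archetype[1], "phasic")
  expect_equal(lab$archetype[9], "sustained_excited")
  expect_equal(lab$archetype[17], "sustained_inhibited")

  # inverting the excited cluster's trace about 0.5 flips it to inhibited
  vals2 <- vals
  vals2[9:16, ] <- 1 - vals2[9:16, ]
  lab2 <- label_archetypes(clusters, fake_auroc_matrix(vals2))
  expect_equal(lab2$archetype[9], "sustained_inhibited")
  expect_equal(lab2$archetype[17], "sustained_excited")
  expect_equal(lab2$archetype[1], "phasic")

  # an all-flat population forced into 3 clusters is ambiguous
  flat <- fake_auroc_matrix(matrix(0.5, 9, nb))
  expect_error(label_archetypes(rep(1:3, each = 3), flat), "ambiguous")
})

test_that("classification recovers generator archetypes and is order-invariant", {
  task <- small_task(n_cond_sessions = 3, cond_trials_per_cue = 6)
  pop <- population_spec(n_phasic = 15, n_sustained_excited = 15,
                         n_sustained_inhibited = 15, seed = 16)
  ds <- simulate_population(pop, task, phases = "conditioning")
  mat <- auroc_matrix(ds$spikes, ds$events, "B")
  lab <- classify_neurons(mat)
  acc <- mean(lab$archetype == ds$truth$archetype)
  expect_gte(acc, 0.9)

  # permuting neuron order leaves every neuron's label unchanged
  perm <- sample(nrow(mat$values))
  mat_p <- mat
  mat_p$values <- mat$values[perm, ]
  mat_p$neuron_ids <- mat$neuron_ids[perm]
  lab_p <- classify_neurons(mat_p)
  m <- match(lab$neuron_id, lab_p$neuron_id)
  expect_equal(lab_p$archetype[m], lab$archetype)
})

test_that("waveform criteria implement the width and deflection rules", {
  feats <- data.frame(neuron_id = 1:4,
                      negative_half_width = c(500, 300, 500, 470),
                      max_positive_deflection = c(0.4, 0.9, -0.05, 0),
                      min_negative_deflection = c(-1, -1, -0.8, -1))
  wide <- classify_waveform(feats)
  expect_equal(wide, c(TRUE, FALSE, FALSE, FALSE))

  # zero negative deflection leaves the ratio undefined
  feats$min_negative_deflection[2] <- 0
  expect_error(classify_waveform(feats), "zero negative deflection")

  # a stricter ratio threshold is configurable
  feats2 <- data.frame(negative_half_width = 500,
                       max_positive_deflection = 0.3,
                       min_negative_deflection = -1)
  expect_true(classify_waveform(feats2, waveform_criteria(450, 0.2)))
  expect_false(classify_waveform(feats2, waveform_criteria(450, 0.5)))
})
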