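# Independent reference implementations used to cross-check the package.
# These deliberately share no code with the implementation paths.

# Brute-force threshold-sweep auROC: explicit loop over the grid, descending
# trapezoid accumulation from the (1,1) endpoint down to (0,0).
oracle_auroc <- function(test, base, step = 0.01) {
  pooled <- c(test, base)
  mn <- min(pooled); mx <- max(pooled)
  if (mx == mn) return(0.5)
  tn <- (test - mn) / (mx - mn)
  bn <- (base - mn) / (mx - mn)
  xs <- 1; ys <- 1
  for (u in seq(0, 1, by = step)) {
    xs <- c(xs, sum(bn > u) / length(bn))
    ys <- c(ys, sum(tn > u) / length(tn))
  }
  xs <- c(xs, 0); ys <- c(ys, 0)
  area <- 0
  for (i in seq_len(length(xs) - 1)) {
    area <- area + (xs[i] - xs[i + 1]) * (ys[i] + ys[i + 1]) / 2
  }
  area
}

# Naive O(n^3) agglomerative complete-linkage clustering, cutting at k
# clusters; merge ties broken by lowest pair indices.
oracle_complete_linkage <- function(x, k) {
  x <- as.matrix(x)
  n <- nrow(x)
  D <- as.matrix(stats::dist(x))
  clusters <- as.list(seq_len(n))
  while (length(clusters) > k) {
    m <- length(clusters)
    best_d <- Inf; bi <- 0; bj <- 0
    for (i in seq_len(m - 1)) {
      for (j in seq(i + 1, m)) {
        d <- max(D[clusters[[i]], clusters[[j]]])
        if (d < best_d) { best_d <- d; bi <- i; bj <- j }
      }
    }
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  lab <- integer(n)
  for (i in seq_along(clusters)) lab[clusters[[i]]] <- i
  lab
}

# Two labelings describe the same partition iff their cross-table has
# exactly one non-zero cell in every row and column.
same_partition <- function(a, b) {
  tab <- table(a, b)
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}

# Textbook paired t test.
oracle_paired_t <- function(x, y) {
  d <- x - y
  n <- length(d)
  t <- mean(d) / (stats::sd(d) / sqrt(n))
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1))
}

# Textbook Pearson correlation with t-based two-sided p.
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, df = n - 2, p = 2 * stats::pt(-abs(t), n - 2))
}

# Direct linear solve of V = T (R + gamma V).
oracle_policy_values <- function(Tm, R, gamma) {
  V <- solve(diag(nrow(Tm)) - gamma * Tm, Tm %*% R)
  stats::setNames(as.vector(V), rownames(Tm))
}

# Small task used throughout the tests: same within-trial structure,
# fewer trials and sessions.
small_task <- function(...) {
  defaults <- list(n_precond_sessions = 1, precond_trials_per_pair = 2,
                   n_cond_sessions = 2, cond_trials_per_cue = 3,
                   probe_reminders = 1, probe_trials_per_cue = 2)
  do.call(task_spec, utils::modifyList(defaults, list(...)))
}
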