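#' Onset-versus-reward auROC difference
#'
#' For each neuron, the mean auROC over the first `onset_window` (default
#' 500 ms) after cue-B onset minus the mean auROC over the same-length
#' window after the first reward delivery within B. Early in learning the
#' reward-aligned response dominates (negative differences); as the
#' transient migrates to cue onset the difference turns positive.
#'
#' @param mat An `auroc_matrix` for cue B whose window covers both the
#'   onset window and `reward_time + onset_window`.
#' @param reward_time Time of the first reward delivery, s after cue onset.
#' @param config An [analysis_config()].
#' @return Named numeric vector of differences (auROC units), one per
#'   neuron.
#' @export
onset_reward_difference <- function(mat, reward_time = 1,
                                    config = analysis_config()) {
  stopifnot(inherits(mat, "auroc_matrix"))
  if (is.null(reward_time) || !is.finite(reward_time)) {
    stop("onset_reward_difference: missing reward time")
  }
  w <- config$onset_window
  onset <- mat$bin_centers >= 0 & mat$bin_centers < w
  reward <- mat$bin_centers >= reward_time & mat$bin_centers < reward_time + w
  if (!any(onset) || sum(reward) != sum(onset)) {
    stop("onset_reward_difference: matrix window must cover [0, ", w,
         ") and [", reward_time, ", ", reward_time + w, ")")
  }
  out <- rowMeans(mat$values[, onset, drop = FALSE]) -
    rowMeans(mat$values[, reward, drop = FALSE])
  names(out) <- mat$neuron_ids
  out
}

#' Correlation of the onset-reward difference with training session
#'
#' Pearson correlation, across neuron-session observations, between the
#' conditioning-session index and the onset-versus-reward auROC difference.
#' A positive correlation is the peak-migration signature: the response
#' moves from reward to cue onset over training.
#'
#' @param differences Numeric vector of onset-reward differences.
#' @param sessions Parallel vector of session indices.
#' @return A list of class `migration_cor` with `r`, `n`, `df` (n - 2) and
#'   two-sided `p`.
#' @export
migration_correlation <- function(differences, sessions) {
  stopifnot(length(differences) == length(sessions))
  if (length(differences) < 3) {
    stop("migration_correlation: need at least 3 neuron-session points")
  }
  if (stats::sd(differences) == 0 || stats::sd(sessions) == 0) {
    stop("migration_correlation: zero variance in differences or sessions")
  }
  ct <- stats::cor.test(sessions, differences, method = "pearson")
  out <- list(r = unname(ct$estimate), n = length(differences),
              df = unname(ct$parameter), p = ct$p.value)
  class(out) <- "migration_cor"
  out
}

# Baseline-subtracted mean firing rate (Hz) of each neuron to each cue of a
# pair in a post-onset window. The baseline rate is estimated per neuron
# from the pre-cue baseline window pooled over all trials in `events`
# (shared between the two cues, so it cancels exactly in the paired
# contrast).
cue_pair_rates <- function(spikes, events, cue_pos, cue_neg,
                           window, config = analysis_config(),
                           neurons = NULL) {
  if (is.null(neurons)) neurons <- sort(unique(spikes$neuron_id))
  skey <- trial_key(spikes$session_id, spikes$trial)
  width <- diff(window)
  bwidth <- diff(config$baseline_window)
  by_neuron <- split(seq_len(nrow(spikes)), spikes$neuron_id)
  one_cue <- function(sel, cue) {
    ev <- events[events$cue_id == cue, , drop = FALSE]
    if (nrow(ev) == 0) stop("cue_pair_rates: no trials for cue ", cue)
    cnt <- bin_counts(spikes$spike_time[sel], skey[sel], ev, window,
                      bin_width = width)
    mean(cnt) / width
  }
  # baseline pooled across all trials in `events` regardless of cue, so the
  # same estimate is subtracted from both cues and cancels in the contrast
  ekey <- trial_key(events$session_id, events$trial)
  base_rate <- function(sel) {
    st <- spikes$spike_time[sel]
    sk <- skey[sel]
    n_in <- vapply(seq_len(nrow(events)), function(i) {
      lo <- events$cue_on[i] + config$baseline_window[1]
      hi <- events$cue_on[i] + config$baseline_window[2]
      sum(sk == ekey[i] & st >= lo & st < hi)
    }, numeric(1))
    mean(n_in) / bwidth
  }
  res <- t(vapply(neurons, function(n) {
    sel <- by_neuron[[as.character(n)]]
    if (is.null(sel)) sel <- integer(0)
    b <- base_rate(sel)
    c(pos = one_cue(sel, cue_pos) - b, neg = one_cue(sel, cue_neg) - b)
  }, numeric(2)))
  data.frame(neuron_id = neurons, response_pos = res[, "pos"],
             response_neg = res[, "neg"],
             difference = res[, "pos"] - res[, "neg"])
}

#' Phasic between-cue contrast (first second of the cue)
#'
#' Per-neuron baseline-subtracted mean firing rate over the first
#' `cue_response_window` (default 1 s) of `cue_pos` minus that of
#' `cue_neg`, with a paired two-sided t test (df = n - 1). `B - D` indexes
#' cached value, `A - C` inferred value.
#'
#' @param spikes Spike table restricted to the session of interest
#'   (normally the probe session).
#' @param events Matching [trial_schedule()] rows for that session.
#' @param cue_pos,cue_neg The cue pair.
#' @param config An [analysis_config()].
#' @param neurons Optional neuron ids (e.g. the phasic-classified subset).
#' @param units `"rate"` (default, baseline-subtracted Hz) or `"auroc"`
#'   (mean auROC in the window, baseline-referenced by construction).
#' @return A list of class `cue_contrast` with the per-neuron table
#'   (`per_neuron`), `mean_difference`, `t`, `df`, `p`, `window`, `units`.
#' @export
phasic_contrast <- function(spikes, events, cue_pos, cue_neg,
                            config = analysis_config(), neurons = NULL,
                            units = c("rate", "auroc")) {
  cue_contrast(spikes, events, cue_pos, cue_neg,
               window = c(0, config$cue_response_window), config = config,
               neurons = neurons, units = match.arg(units))
}

#' Sustained between-cue contrast (final portion of the cue)
#'
#' As [phasic_contrast()], but over `config$sustained_window` (default the
#' final 9 s of a 10-s cue).
#'
#' @inheritParams phasic_contrast
#' @return A `cue_contrast` list.
#' @export
sustained_contrast <- function(spikes, events, cue_pos, cue_neg,
                               config = analysis_config(), neurons = NULL,
                               units = c("rate", "auroc")) {
  cue_contrast(spikes, events, cue_pos, cue_neg,
               window = config$sustained_window, config = config,
               neurons = neurons, units = match.arg(units))
}

cue_contrast <- function(spikes, events, cue_pos, cue_neg, window,
                         config = analysis_config(), neurons = NULL,
                         units = "rate") {
  if (units == "rate") {
    per <- cue_pair_rates(spikes, events, cue_pos, cue_neg, window, config,
                          neurons)
  } else {
    mp <- auroc_matrix(spikes, events, cue_pos, config, window, neurons)
    mn <- auroc_matrix(spikes, events, cue_neg, config, window, neurons)
    per <- data.frame(neuron_id = mp$neuron_ids,
                      response_pos = rowMeans(mp$values) - 0.5,
                      response_neg = rowMeans(mn$values) - 0.5)
    per$difference <- per$response_pos - per$response_neg
  }
  if (nrow(per) < 2) {
    stop("cue_contrast: need at least 2 neurons for a paired test")
  }
  tt <- stats::t.test(per$response_pos, per$response_neg, paired = TRUE)
  out <- list(per_neuron = per, cue_pos = cue_pos, cue_neg = cue_neg,
              mean_difference = mean(per$difference),
              t = unname(tt$statistic), df = unname(tt$parameter),
              p = tt$p.value, window = window, units = units)
  class(out) <- "cue_contrast"
  out
}

#' @export
print.cue_contrast <- function(x, ...) {
  cat(sprintf("%s - %s contrast over [%g, %g) s (%s units): mean %.3f, t(%d) = %.2f, p = %.3g\n",
              x$cue_pos, x$cue_neg, x$window[1], x$window[2], x$units,
              x$mean_difference, x$df, x$t, x$p))
  invisible(x)
}

#' Correlation between cached- and inferred-value coding
#'
#' Pearson correlation across neurons between the per-neuron cached-value
#' contrast (B - D) and inferred-value contrast (A - C), with df = n - 2.
#' A strong positive correlation indicates that the same neurons carry both
#' signals, i.e. a common error-coding framework.
#'
#' @param b_minus_d,a_minus_c Per-neuron contrasts (same neurons, same
#'   order), e.g. the `difference` columns of two [phasic_contrast()]
#'   results.
#' @return A list of class `coding_cor` with `r`, `df`, `n`, `p`.
#' @export
inferred_vs_cached_correlation <- function(b_minus_d, a_minus_c) {
  stopifnot(length(b_minus_d) == length(a_minus_c))
  if (length(b_minus_d) < 3) {
    stop("inferred_vs_cached_correlation: need at least 3 neurons")
  }
  if (stats::sd(b_minus_d) == 0 || stats::sd(a_minus_c) == 0) {
    stop("inferred_vs_cached_correlation: zero variance in a contrast")
  }
  ct <- stats::cor.test(b_minus_d, a_minus_c, method = "pearson")
  out <- list(r = unname(ct$estimate), df = unname(ct$parameter),
              n = length(b_minus_d), p = ct$p.value)
  class(out) <- "coding_cor"
  out
}

#' Food-cup occupancy statistics per phase
#'
#' Means and factorial ANOVAs of the percentage of cue time spent in the
#' food cup, following the design of each phase: preconditioning tests for
#' any difference among the four cues (one-way); conditioning tests
#' cue (B vs D) x session; the probe tests cue (A vs C) x trial. Cells are
#' rat x session (or trial) x cue means.
#'
#' @param behavior A `behavior_table` (see [simulate_behavior()]).
#' @param phase One of `"preconditioning"`, `"conditioning"`, `"probe"`.
#' @return A list of class `behavior_stats` with `means` (per-cue cell
#'   means) and `anova` (term, df, F, p), plus `degenerate = TRUE` when the
#'   response has no variance (all-zero occupancy).
#' @export
behavior_stats <- function(behavior, phase = c("conditioning",
                                               "preconditioning", "probe")) {
  phase <- match.arg(phase)
  bh <- behavior[behavior$phase == phase, , drop = FALSE]
  if (nrow(bh) == 0) stop("behavior_stats: no rows for phase ", phase)
  if (phase == "probe") bh <- bh[bh$cue_id %in% c("A", "C"), , drop = FALSE]
  if (phase == "conditioning") {
    bh <- bh[bh$cue_id %in% c("B", "D"), , drop = FALSE]
  }
  if (length(unique(bh$cue_id)) < 2) {
    stop("behavior_stats: need at least 2 cues")
  }
  unit <- if (phase == "conditioning") "session_id" else
    if (phase == "probe") "trial" else NULL
  if (phase == "probe") {
    # pair off interleaved A/C presentations by within-cue order
    bh$trial <- stats::ave(bh$trial, bh$rat_id, bh$cue_id,
                           FUN = function(x) rank(x, ties.method = "first"))
  }
  agg_by <- c("rat_id", "cue_id", unit)
  cells <- stats::aggregate(bh["occupancy"], by = bh[agg_by], FUN = mean)
  counts <- stats::aggregate(bh["occupancy"], by = bh[agg_by], FUN = length)
  if (length(unique(counts$occupancy)) > 1 ||
      nrow(cells) < length(unique(bh$cue_id)) * length(unique(bh$rat_id))) {
    full <- expand.grid(lapply(bh[agg_by], unique))
    have <- do.call(paste, cells[agg_by])
    missing_cells <- full[!do.call(paste, full) %in% have, , drop = FALSE]
    if (nrow(missing_cells)) {
      stop("behavior_stats: empty design cells: ",
           paste(utils::capture.output(print(utils::head(missing_cells))),
                 collapse = "\n"))
    }
  }
  means <- stats::aggregate(cells["occupancy"],
                            by = cells[c("cue_id", unit)], FUN = mean)
  degenerate <- stats::sd(cells$occupancy) == 0
  if (degenerate) {
    anova_tab <- data.frame(term = "cue_id", df = NA_integer_,
                            F = NA_real_, p = NA_real_)
  } else {
    cells$cue_id <- factor(cells$cue_id)
    if (!is.null(unit)) {
      cells$unit <- factor(cells[[unit]])
      fit <- stats::aov(occupancy ~ cue_id * unit, data = cells)
    } else {
      fit <- stats::aov(occupancy ~ cue_id, data = cells)
    }
    s <- summary(fit)[[1]]
    terms <- trimws(rownames(s))
    keep <- terms != "Residuals"
    if (!is.null(unit)) terms <- sub("unit", unit, terms, fixed = TRUE)
    anova_tab <- data.frame(term = terms[keep],
                            df = s$Df[keep],
                            df_resid = s$Df[!keep],
                            F = s$`F value`[keep],
                            p = s$`Pr(>F)`[keep])
  }
  out <- list(phase = phase, means = means, anova = anova_tab,
              degenerate = degenerate)
  class(out) <- "behavior_stats"
  out
}

#' @export
print.behavior_stats <- function(x, ...) {
  cat("Food-cup occupancy,", x$phase, "phase\n")
  if (x$degenerate) {
    cat("  degenerate: occupancy has zero variance; tests not computed\n")
  } else {
    for (i in seq_len(nrow(x$anova))) {
      cat(sprintf("  %s: F(%d, %d) = %.2f, p = %.3g\n", x$anova$term[i],
                  x$anova$df[i], x$anova$df_resid[i], x$anova$F[i],
                  x$anova$p[i]))
    }
  }
  invisible(x)
}
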