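#' Analysis configuration
#'
#' Bin widths, analysis windows and threshold grid for the auROC firing-rate
#' normalization and the downstream statistics. All windows are in seconds
#' relative to cue onset and are half-open; the defaults are 100-ms bins, a
#' 0-to-1 discrimination-threshold sweep in 0.01 steps, a 1-s pre-cue
#' baseline, a 500-ms onset window (for onset-vs-reward comparisons), a 1-s
#' cue-response window (for between-cue contrasts), the final 9 s of a 10-s
#' cue as the sustained window, and alpha 0.05.
#'
#' @param bin_width Spike-count bin width, s. Must divide every window.
#' @param threshold_step Discrimination-threshold step on the normalized
#'   count scale, in (0, 1].
#' @param baseline_window Length-2 window relative to cue onset used as the
#'   baseline count distribution.
#' @param onset_window Length of the post-event window (s) for
#'   onset-vs-reward comparisons.
#' @param cue_response_window Length of the initial cue window (s) for
#'   between-cue contrasts.
#' @param sustained_window Length-2 window (s after cue onset) for sustained
#'   contrasts.
#' @param alpha Nominal test level.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(bin_width = 0.1,
                            threshold_step = 0.01,
                            baseline_window = c(-1, 0),
                            onset_window = 0.5,
                            cue_response_window = 1,
                            sustained_window = c(1, 10),
                            alpha = 0.05) {
  stopifnot(bin_width > 0, threshold_step > 0, threshold_step <= 1,
            length(baseline_window) == 2,
            baseline_window[1] < baseline_window[2],
            onset_window > 0, cue_response_window > 0,
            length(sustained_window) == 2,
            sustained_window[1] < sustained_window[2],
            alpha > 0, alpha < 1)
  divides <- function(x) abs(x / bin_width - round(x / bin_width)) < 1e-9
  if (!all(divides(c(diff(baseline_window), onset_window,
                     cue_response_window, diff(sustained_window))))) {
    stop("analysis_config: bin_width must divide all analysis windows")
  }
  out <- list(bin_width = bin_width, threshold_step = threshold_step,
              baseline_window = baseline_window, onset_window = onset_window,
              cue_response_window = cue_response_window,
              sustained_window = sustained_window, alpha = alpha)
  class(out) <- "analysis_config"
  out
}

#' Per-trial, per-bin spike counts around cue onset
#'
#' Counts one neuron's spikes in half-open bins (a spike exactly on a
#' boundary falls in the later bin) of a window aligned to cue onset, for
#' every trial in `events`.
#'
#' @param spike_times Numeric vector of this neuron's spike times (s from
#'   trial start), parallel to `spike_keys`.
#' @param spike_keys Character vector `"<session_id>.<trial>"` identifying
#'   each spike's trial (see [trial_key()]).
#' @param events Rows of a [trial_schedule()] table, one per cue
#'   presentation, all sharing a cue id.
#' @param window Length-2 window in seconds relative to cue onset.
#' @param bin_width Bin width in seconds.
#' @return An integer matrix with one row per row of `events` and one column
#'   per bin; column names give bin centers relative to cue onset.
#' @export
bin_counts <- function(spike_times, spike_keys, events, window, bin_width) {
  stopifnot(length(window) == 2, window[1] < window[2], bin_width > 0)
  if (length(unique(events$cue_id)) > 1) {
    stop("bin_counts: events must all share one cue_id")
  }
  nb <- round(diff(window) / bin_width)
  if (abs(nb * bin_width - diff(window)) > 1e-9) {
    stop("bin_counts: bin_width must divide the window")
  }
  lo <- events$cue_on + window[1]
  hi <- events$cue_on + window[2]
  if (any(lo < 0) || any(hi > events$trial_duration + 1e-9)) {
    stop("bin_counts: window extends outside the recorded trial span")
  }
  counts <- matrix(0L, nrow(events), nb)
  ekey <- trial_key(events$session_id, events$trial)
  for (i in seq_len(nrow(events))) {
    st <- spike_times[spike_keys == ekey[i]]
    rel <- st - events$cue_on[i]
    rel <- rel[rel >= window[1] & rel < window[2]]
    if (length(rel)) {
      # the 1e-9 snap keeps exact bin-boundary spikes in the later bin even
      # after floating-point alignment arithmetic
      idx <- floor((rel - window[1]) / bin_width + 1e-9) + 1L
      idx[idx > nb] <- nb  # guard against FP edge at the upper boundary
      counts[i, ] <- tabulate(idx, nbins = nb)
    }
  }
  colnames(counts) <- format(window[1] + (seq_len(nb) - 0.5) * bin_width)
  counts
}

#' Composite key identifying a trial within a dataset
#' @param session_id,trial Vectors of session ids and trial indices.
#' @return Character vector of keys.
#' @export
trial_key <- function(session_id, trial) paste(session_id, trial, sep = ".")

#' Baseline-referenced ROC normalization of one bin
#'
#' Compares a distribution of test spike counts against a distribution of
#' baseline counts: all counts are pooled and jointly min-max normalized to
#' `[0, 1]`; a discrimination threshold is then swept from 0 to 1 in
#' `threshold_step` steps, recording at each threshold the fraction of test
#' bins strictly above it (hit rate) and the fraction of baseline bins
#' strictly above it (false-alarm rate); the area under the resulting ROC
#' curve, with endpoints (0,0) and (1,1) appended, is returned by
#' trapezoidal integration. 0.5 means no difference from baseline, values
#' above 0.5 excitation, below 0.5 inhibition. Identical test and baseline
#' multisets (including the all-equal degenerate case) return exactly 0.5.
#'
#' @param test_counts,baseline_counts Non-empty numeric vectors of spike
#'   counts.
#' @param threshold_step Threshold grid step in (0, 1].
#' @return A value in `[0, 1]`.
#' @export
auroc_bin <- function(test_counts, baseline_counts, threshold_step = 0.01) {
  if (length(test_counts) == 0 || length(baseline_counts) == 0) {
    stop("auroc_bin: test and baseline counts must be non-empty")
  }
  rng <- range(c(test_counts, baseline_counts))
  if (rng[1] == rng[2]) return(0.5)
  if (length(test_counts) == length(baseline_counts) &&
      all(sort(test_counts) == sort(baseline_counts))) {
    return(0.5)  # identical multisets: the ROC is the diagonal
  }
  tn <- (test_counts - rng[1]) / (rng[2] - rng[1])
  bn <- (baseline_counts - rng[1]) / (rng[2] - rng[1])
  th <- seq(0, 1, by = threshold_step)
  hit <- vapply(th, function(u) mean(tn > u), numeric(1))
  fa <- vapply(th, function(u) mean(bn > u), numeric(1))
  x <- c(0, rev(fa), 1)
  y <- c(0, rev(hit), 1)
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}

#' Neuron-by-time matrix of baseline-referenced auROC values
#'
#' For each neuron and each post-onset bin, compares the distribution of
#' test counts (that bin's latency, pooled across all trials of the cue)
#' against the pooled baseline distribution (every baseline-window bin of
#' every trial of that cue), using [auroc_bin()].
#'
#' @param spikes Spike table (neuron_id, session_id, trial, spike_time).
#' @param events [trial_schedule()] rows; only rows with `cue_id` are used.
#' @param cue_id Cue whose trials are analysed.
#' @param config An [analysis_config()].
#' @param window Length-2 post-onset analysis window (s relative to cue
#'   onset).
#' @param neurons Optional vector of neuron ids (defaults to all in
#'   `spikes`).
#' @return An object of class `auroc_matrix`: a list with `values` (neurons
#'   x bins, all in `[0,1]`), `neuron_ids` and `bin_centers` (s relative to
#'   cue onset).
#' @export
auroc_matrix <- function(spikes, events, cue_id, config = analysis_config(),
                         window = c(0, 10), neurons = NULL) {
  ev <- events[events$cue_id == cue_id, , drop = FALSE]
  if (nrow(ev) == 0) stop("auroc_matrix: no trials for cue ", cue_id)
  if (is.null(neurons)) neurons <- sort(unique(spikes$neuron_id))
  if (length(neurons) == 0) stop("auroc_matrix: no neurons to analyse")
  bw <- config$bin_width
  nb <- round(diff(window) / bw)
  vals <- matrix(NA_real_, length(neurons), nb)
  skey_all <- trial_key(spikes$session_id, spikes$trial)
  by_neuron <- split(seq_len(nrow(spikes)), spikes$neuron_id)
  for (j in seq_along(neurons)) {
    sel <- by_neuron[[as.character(neurons[j])]]
    if (is.null(sel)) sel <- integer(0)
    test <- bin_counts(spikes$spike_time[sel], skey_all[sel], ev, window, bw)
    base <- bin_counts(spikes$spike_time[sel], skey_all[sel], ev,
                       config$baseline_window, bw)
    base_pool <- as.vector(base)
    for (b in seq_len(nb)) {
      vals[j, b] <- auroc_bin(test[, b], base_pool, config$threshold_step)
    }
  }
  centers <- window[1] + (seq_len(nb) - 0.5) * bw
  out <- list(values = vals, neuron_ids = neurons, bin_centers = centers,
              cue_id = cue_id, window = window, config = config)
  class(out) <- "auroc_matrix"
  out
}

#' @export
print.auroc_matrix <- function(x, ...) {
  cat(sprintf("auROC matrix: %d neurons x %d bins (cue %s, window [%g, %g) s)\n",
              nrow(x$values), ncol(x$values), x$cue_id,
              x$window[1], x$window[2]))
  invisible(x)
}

#' Export an auROC matrix as a neuron-by-bin CSV
#' @param x An `auroc_matrix`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_auroc_matrix <- function(x, file) {
  df <- data.frame(neuron_id = x$neuron_ids, x$values)
  names(df)[-1] <- paste0("t", format(x$bin_centers, trim = TRUE))
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
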