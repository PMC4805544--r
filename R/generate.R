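#' Firing-rate archetype parameters
#'
#' Parameters for one of the three VTA response archetypes the clustering
#' analysis is designed to recover: `phasic` (transient excitation at cue
#' onset and reward, the putative dopaminergic pattern), `sustained_excited`
#' (tonic excitation across the cue, putative GABAergic) and
#' `sustained_inhibited` (tonic suppression across the cue).
#'
#' The phasic archetype carries a per-session learning trajectory: the
#' reward-aligned transient weight is maximal in the first conditioning
#' session and declines linearly, while the cue-onset weight rises linearly
#' to its maximum in the final session, emulating the migration of the peak
#' response from reward to cue onset. In the probe session phasic neurons
#' additionally express per-neuron coding strengths: the cached-value
#' contrast (B minus D) and the inferred-value contrast (A minus C), both in
#' Hz over the first second of the cue, plus a sustained inferred-value
#' component over the remainder of cue A.
#'
#' @param archetype One of `"phasic"`, `"sustained_excited"`,
#'   `"sustained_inhibited"`.
#' @param baseline_rate Baseline firing rate, Hz.
#' @param phasic_gain Peak amplitude of phasic transients, Hz.
#' @param onset_latency Latency of transients after their trigger, s.
#' @param decay_tau Exponential decay constant of transients, s.
#' @param sustained_gain Amplitude of tonic modulation during cues, Hz
#'   (applied negatively for the inhibited archetype).
#' @param trajectory Length-2 vector `c(w_min, w_max)` bounding the linear
#'   per-session transient weights.
#' @param novelty_weight Fraction of `phasic_gain` expressed as an onset
#'   transient to any cue before learning (preconditioning).
#' @param generalization Fraction of `phasic_gain` expressed to the
#'   unrewarded control cue D during conditioning.
#' @param probe_onset_weight Fraction of `phasic_gain` shared by all four
#'   cue-onset transients in the probe session.
#' @param sustained_transfer Fraction of the per-neuron inferred-value coding
#'   strength expressed as sustained firing over the final portion of cue A
#'   (set to 0 to ablate the sustained inferred-value signal).
#' @param b_sustained_boost Extra tonic drive to cue B (relative to
#'   `sustained_gain`) for the sustained-excited archetype once B predicts
#'   reward.
#' @param noise_sd Standard deviation of the per-trial log-normal gain
#'   applied to all modulation components (trial-to-trial variability).
#' @return An object of class `archetype_params`.
#' @export
archetype_params <- function(archetype = c("phasic", "sustained_excited",
                                           "sustained_inhibited"),
                             baseline_rate = NULL,
                             phasic_gain = 15,
                             onset_latency = 0.05,
                             decay_tau = 0.2,
                             sustained_gain = 8,
                             trajectory = c(0.25, 1),
                             novelty_weight = 0.3,
                             generalization = 0.15,
                             probe_onset_weight = 0.5,
                             sustained_transfer = 0.3,
                             b_sustained_boost = 0.4,
                             noise_sd = 0.25) {
  archetype <- match.arg(archetype)
  if (is.null(baseline_rate)) {
    baseline_rate <- switch(archetype, phasic = 6,
                            sustained_excited = 15, sustained_inhibited = 10)
  }
  stopifnot(baseline_rate >= 0, phasic_gain >= 0, decay_tau > 0,
            sustained_gain >= 0, length(trajectory) == 2,
            trajectory[1] <= trajectory[2], noise_sd >= 0,
            onset_latency >= 0)
  out <- list(archetype = archetype, baseline_rate = baseline_rate,
              phasic_gain = phasic_gain, onset_latency = onset_latency,
              decay_tau = decay_tau, sustained_gain = sustained_gain,
              trajectory = trajectory, novelty_weight = novelty_weight,
              generalization = generalization,
              probe_onset_weight = probe_onset_weight,
              sustained_transfer = sustained_transfer,
              b_sustained_boost = b_sustained_boost,
              noise_sd = noise_sd)
  class(out) <- "archetype_params"
  out
}

# Linear learning trajectory over conditioning sessions: the cue-onset weight
# rises from w_min to w_max while the reward weight falls from w_max to w_min.
trajectory_weights <- function(params, session_within, n_sessions) {
  frac <- if (n_sessions > 1) (session_within - 1) / (n_sessions - 1) else 1
  w <- params$trajectory
  c(onset = w[1] + (w[2] - w[1]) * frac,
    reward = w[2] - (w[2] - w[1]) * frac)
}

# Modulation components for one cue presentation, times relative to cue
# onset. Returns a data.frame(kind, t0, t1, amp, tau): kind "exp" is an
# amp * exp(-(t - t0)/tau) transient for t >= t0; kind "box" is a constant
# amp on [t0, t1).
response_components <- function(params, cue_id, phase, session_within, task,
                                coding = c(b_minus_d = 0, a_minus_c = 0)) {
  if (!cue_id %in% c("A", "B", "C", "D")) {
    stop("unknown_cue: cue_id must be one of A, B, C, D, got ", cue_id)
  }
  if (!phase %in% task_phases) stop("unknown phase: ", phase)
  cd <- task$cue_duration
  lat <- params$onset_latency
  comp <- function(kind, t0, t1, amp, tau = NA_real_) {
    data.frame(kind = kind, t0 = t0, t1 = t1, amp = amp, tau = tau)
  }
  out <- list()
  if (params$archetype == "phasic") {
    g <- params$phasic_gain
    tau <- params$decay_tau
    if (phase == "preconditioning") {
      out <- list(comp("exp", lat, cd, g * params$novelty_weight, tau))
    } else if (phase == "conditioning") {
      w <- trajectory_weights(params, session_within, task$n_cond_sessions)
      if (cue_id == "B") {
        out <- c(list(comp("exp", lat, cd, g * w[["onset"]], tau)),
                 lapply(task$reward_offsets, function(r) {
                   comp("exp", r + lat, cd, g * w[["reward"]], tau)
                 }))
      } else if (cue_id == "D") {
        out <- list(comp("exp", lat, cd, g * params$generalization, tau))
      }
    } else { # probe
      w <- trajectory_weights(params, task$n_cond_sessions,
                              task$n_cond_sessions)
      out <- list(comp("exp", lat, cd, g * params$probe_onset_weight, tau))
      if (cue_id == "B") {
        out <- c(out,
                 list(comp("box", 0, 1, coding[["b_minus_d"]])),
                 lapply(task$reward_offsets, function(r) {
                   comp("exp", r + lat, cd, g * w[["reward"]], tau)
                 }))
      } else if (cue_id == "A") {
        out <- c(out,
                 list(comp("box", 0, 1, coding[["a_minus_c"]]),
                      comp("box", 1, cd,
                           params$sustained_transfer * coding[["a_minus_c"]])))
      }
    }
  } else if (params$archetype == "sustained_excited") {
    amp <- params$sustained_gain
    boost <- if (cue_id == "B" && phase != "preconditioning") {
      1 + params$b_sustained_boost
    } else 1
    out <- list(comp("box", 0, cd, amp * boost))
  } else if (params$archetype == "sustained_inhibited") {
    out <- list(comp("box", 0, cd, -params$sustained_gain))
  } else {
    stop("unknown_archetype: ", params$archetype)
  }
  do.call(rbind, out)
}

# Evaluate summed modulation components (no baseline, no rectification) at
# vector of times t (same frame as the components).
eval_components <- function(comps, t) {
  m <- numeric(length(t))
  if (is.null(comps) || nrow(comps) == 0) return(m)
  for (i in seq_len(nrow(comps))) {
    k <- comps$kind[i]
    if (k == "exp") {
      on <- t >= comps$t0[i]
      m[on] <- m[on] + comps$amp[i] * exp(-(t[on] - comps$t0[i]) / comps$tau[i])
    } else {
      on <- t >= comps$t0[i] & t < comps$t1[i]
      m[on] <- m[on] + comps$amp[i]
    }
  }
  m
}

#' Firing-rate template for one cue presentation
#'
#' Builds the trial-time rate function (Hz) of a neuron with the given
#' archetype parameters for a single presentation of `cue_id` in the given
#' session, with the cue onset placed `task$pre_cue` seconds into the trial
#' window. Rates are rectified at zero after summing baseline and modulation
#' components.
#'
#' @param params An [archetype_params()].
#' @param cue_id One of `"A"`, `"B"`, `"C"`, `"D"`.
#' @param session_id Global session id (see [trial_schedule()]).
#' @param task A [task_spec()].
#' @param coding Named vector with `b_minus_d` and `a_minus_c` coding
#'   strengths (Hz) used in the probe session.
#' @return A vectorized function of trial time (s) returning the rate in Hz,
#'   with the component table attached as attribute `"components"` (times
#'   relative to cue onset).
#' @export
rate_template <- function(params, cue_id, session_id, task,
                          coding = c(b_minus_d = 0, a_minus_c = 0)) {
  stopifnot(inherits(params, "archetype_params"), inherits(task, "task_spec"))
  phase <- session_phase(task, session_id)
  sw <- session_within_phase(task, phase, session_id)
  comps <- response_components(params, cue_id, phase, sw, task, coding)
  onset <- task$pre_cue
  fn <- function(t) {
    pmax(0, params$baseline_rate + eval_components(comps, t - onset))
  }
  attr(fn, "components") <- comps
  attr(fn, "cue_onset") <- onset
  fn
}

session_phase <- function(task, session_id) {
  for (ph in task_phases) if (session_id %in% session_ids(task, ph)) return(ph)
  stop("session_id ", session_id, " outside the task's sessions")
}

#' Synthetic population specification
#'
#' @param n_phasic,n_sustained_excited,n_sustained_inhibited Neuron counts
#'   per archetype.
#' @param seed Integer seed; identical specs and seeds give identical output.
#' @param rho Correlation between the per-neuron cached-value (B-D) and
#'   inferred-value (A-C) coding strengths.
#' @param coding_mean,coding_sd Means and SDs (Hz) of the bivariate normal
#'   coding strengths, named `b_minus_d` and `a_minus_c`.
#' @param wide_fraction Fraction of phasic neurons given wide (>450 us)
#'   action-potential waveforms with a positive deflection.
#' @param phasic,sustained_excited,sustained_inhibited [archetype_params()]
#'   for each archetype.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n_phasic = 100,
                            n_sustained_excited = 100,
                            n_sustained_inhibited = 100,
                            seed = 1,
                            rho = 0.6,
                            coding_mean = c(b_minus_d = 5, a_minus_c = 4),
                            coding_sd = c(b_minus_d = 6, a_minus_c = 5),
                            wide_fraction = 0.08,
                            phasic = archetype_params("phasic"),
                            sustained_excited = archetype_params("sustained_excited"),
                            sustained_inhibited = archetype_params("sustained_inhibited")) {
  stopifnot(n_phasic >= 0, n_sustained_excited >= 0, n_sustained_inhibited >= 0,
            n_phasic + n_sustained_excited + n_sustained_inhibited > 0,
            rho >= -1, rho <= 1, all(coding_sd >= 0),
            wide_fraction >= 0, wide_fraction <= 1)
  out <- list(n_phasic = as.integer(n_phasic),
              n_sustained_excited = as.integer(n_sustained_excited),
              n_sustained_inhibited = as.integer(n_sustained_inhibited),
              seed = as.integer(seed), rho = rho,
              coding_mean = coding_mean, coding_sd = coding_sd,
              wide_fraction = wide_fraction,
              phasic = phasic, sustained_excited = sustained_excited,
              sustained_inhibited = sustained_inhibited)
  class(out) <- "population_spec"
  out
}

# Correlated coding strengths via a 2x2 Cholesky factor.
draw_coding <- function(n, rho, mean, sd) {
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  b <- mean[["b_minus_d"]] + sd[["b_minus_d"]] * z1
  a <- mean[["a_minus_c"]] + sd[["a_minus_c"]] *
    (rho * z1 + sqrt(1 - rho^2) * z2)
  data.frame(b_minus_d = b, a_minus_c = a)
}

#' Simulate a synthetic VTA population
#'
#' Draws spike trains for every neuron and trial from the archetype rate
#' templates with an exact inhomogeneous-Poisson thinning sampler, together
#' with ground-truth labels and mean-waveform features. Reproducible: the
#' same specification and seed give identical output.
#'
#' @param pop A [population_spec()].
#' @param task A [task_spec()].
#' @param phases Phases to simulate (defaults to all three).
#' @return A list of class `vta_dataset` with elements `spikes`
#'   (neuron_id, session_id, phase, trial, spike_time), `events` (the
#'   [trial_schedule()]), `waveforms` (neuron_id, negative_half_width,
#'   max_positive_deflection, min_negative_deflection), and `truth`
#'   (neuron_id, archetype, b_minus_d, a_minus_c, wide_waveform).
#' @export
simulate_population <- function(pop, task = task_spec(),
                                phases = task_phases) {
  stopifnot(inherits(pop, "population_spec"), inherits(task, "task_spec"))
  phases <- match.arg(phases, task_phases, several.ok = TRUE)
  set.seed(pop$seed)
  events <- trial_schedule(task, phases)

  n_total <- pop$n_phasic + pop$n_sustained_excited + pop$n_sustained_inhibited
  archetypes <- rep(c("phasic", "sustained_excited", "sustained_inhibited"),
                    c(pop$n_phasic, pop$n_sustained_excited,
                      pop$n_sustained_inhibited))
  coding <- draw_coding(n_total, pop$rho, pop$coding_mean, pop$coding_sd)
  wide <- rep(FALSE, n_total)
  if (pop$n_phasic > 0) {
    wide[seq_len(pop$n_phasic)] <-
      stats::runif(pop$n_phasic) < pop$wide_fraction
  }
  truth <- data.frame(neuron_id = seq_len(n_total), archetype = archetypes,
                      b_minus_d = coding$b_minus_d,
                      a_minus_c = coding$a_minus_c,
                      wide_waveform = wide, stringsAsFactors = FALSE)
  waveforms <- draw_waveforms(truth)

  # group trials with identical cue structure within each session, so the
  # thinning sampler can vectorize across the trials of a group
  spikes <- vector("list", 0)
  for (sid in unique(events$session_id)) {
    sev <- events[events$session_id == sid, ]
    phase <- sev$phase[1]
    sw <- session_within_phase(task, phase, sid)
    tkey <- vapply(split(sev$cue_id, sev$trial), paste, "", collapse = "+")
    for (tt in unique(tkey)) {
      trials <- as.integer(names(tkey)[tkey == tt])
      # component layout of this trial type (from its first trial)
      proto <- sev[sev$trial == trials[1], , drop = FALSE]
      dur <- proto$trial_duration[1]
      for (n in seq_len(n_total)) {
        params <- pop[[archetypes[n]]]
        cod <- c(b_minus_d = coding$b_minus_d[n],
                 a_minus_c = coding$a_minus_c[n])
        comps <- do.call(rbind, lapply(seq_len(nrow(proto)), function(i) {
          cc <- response_components(params, proto$cue_id[i], phase, sw, task,
                                    cod)
          if (!is.null(cc) && nrow(cc)) {
            cc$t0 <- cc$t0 + proto$cue_on[i]
            cc$t1 <- cc$t1 + proto$cue_on[i]
          }
          cc
        }))
        sp <- sample_inhomogeneous(params$baseline_rate, comps,
                                   n_trials = length(trials), duration = dur,
                                   noise_sd = params$noise_sd)
        if (nrow(sp)) {
          spikes[[length(spikes) + 1L]] <- data.frame(
            neuron_id = n, session_id = sid, phase = phase,
            trial = trials[sp$trial], spike_time = sp$spike_time,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  spikes <- if (length(spikes)) do.call(rbind, spikes) else
    data.frame(neuron_id = integer(0), session_id = integer(0),
               phase = character(0), trial = integer(0),
               spike_time = numeric(0))
  spikes <- spikes[order(spikes$neuron_id, spikes$session_id, spikes$trial,
                         spikes$spike_time), ]
  rownames(spikes) <- NULL
  out <- list(spikes = spikes, events = events, waveforms = waveforms,
              truth = truth, task = task)
  class(out) <- "vta_dataset"
  out
}

#' Sample repeated trials of one cue presentation for one neuron
#'
#' Draws spike trains from the [rate_template()] of a single cue
#' presentation (cue onset at `task$pre_cue` seconds into the trial window)
#' with the exact inhomogeneous-Poisson thinning sampler. Useful for
#' calibration checks and small simulations outside the full task schedule.
#'
#' @inheritParams rate_template
#' @param n_trials Number of independent trials to draw.
#' @param seed Optional seed set before sampling.
#' @return A data.frame with columns `trial` and `spike_time` (s from trial
#'   start); the trial window length is attached as attribute `"duration"`.
#' @export
sample_spike_trains <- function(params, cue_id, session_id, task, n_trials,
                                coding = c(b_minus_d = 0, a_minus_c = 0),
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  phase <- session_phase(task, session_id)
  sw <- session_within_phase(task, phase, session_id)
  comps <- response_components(params, cue_id, phase, sw, task, coding)
  if (!is.null(comps) && nrow(comps)) {
    comps$t0 <- comps$t0 + task$pre_cue
    comps$t1 <- comps$t1 + task$pre_cue
  }
  dur <- task$pre_cue + task$cue_duration + task$post_cue
  out <- sample_inhomogeneous(params$baseline_rate, comps, n_trials, dur,
                              params$noise_sd)
  attr(out, "duration") <- dur
  out
}

# Exact thinning sampler for a piecewise rate shared by n_trials trials, with
# a per-trial log-normal gain on the modulation. The proposal bound is the
# baseline plus the sum of positive component amplitudes times the largest
# trial gain; rates are rectified at zero before acceptance.
sample_inhomogeneous <- function(baseline, comps, n_trials, duration,
                                 noise_sd = 0) {
  gains <- if (noise_sd > 0) {
    pmin(4, pmax(0.25, exp(stats::rnorm(n_trials, 0, noise_sd))))
  } else rep(1, n_trials)
  pos <- if (!is.null(comps) && nrow(comps)) sum(pmax(0, comps$amp)) else 0
  rmax <- baseline + pos * max(gains)
  if (rmax <= 0) {
    stop("non-positive rate bound: baseline and gains are all zero-negative")
  }
  m <- stats::rpois(1, rmax * duration * n_trials)
  if (m == 0) {
    return(data.frame(trial = integer(0), spike_time = numeric(0)))
  }
  t <- stats::runif(m, 0, duration)
  tr <- sample.int(n_trials, m, replace = TRUE)
  rate <- pmax(0, baseline + gains[tr] * eval_components(comps, t))
  keep <- stats::runif(m) < rate / rmax
  out <- data.frame(trial = tr[keep], spike_time = t[keep])
  out[order(out$trial, out$spike_time), , drop = FALSE]
}

# Waveform features consistent with the classifier's wide-waveform criterion:
# wide neurons exceed the 450 us half-width threshold and have a positive
# maximal deflection; narrow neurons fail at least the width criterion.
draw_waveforms <- function(truth) {
  n <- nrow(truth)
  hw <- ifelse(truth$wide_waveform,
               pmax(470, stats::rnorm(n, 550, 40)),
               pmin(430, pmax(120, stats::rnorm(n, 300, 50))))
  max_pos <- ifelse(truth$wide_waveform,
                    stats::runif(n, 0.2, 0.8),
                    stats::runif(n, -0.2, 0.6))
  min_neg <- -stats::runif(n, 0.5, 1.5)
  data.frame(neuron_id = truth$neuron_id,
             negative_half_width = hw,
             max_positive_deflection = max_pos,
             min_negative_deflection = min_neg)
}

#' Behavioral simulation parameters
#'
#' @param n_rats Number of simulated rats.
#' @param base Food-cup occupancy probability for neutral cues.
#' @param asymptote Occupancy probability for cue B at the end of
#'   conditioning.
#' @param transfer Occupancy probability for cue A in the probe test
#'   (the preconditioning transfer effect); set equal to `c_level` for a
#'   null generator.
#' @param c_level Occupancy probability for control cue C at probe.
#' @param precision Beta-distribution precision of per-trial occupancy
#'   (larger = less trial-to-trial variability).
#' @return An object of class `behavior_params`.
#' @export
behavior_params <- function(n_rats = 14, base = 0.05, asymptote = 0.70,
                            transfer = 0.40, c_level = 0.08,
                            precision = 30) {
  probs <- c(base = base, asymptote = asymptote, transfer = transfer,
             c_level = c_level)
  if (any(probs < 0 | probs > 1)) {
    stop("behavior_params: occupancy probabilities must lie in [0, 1]")
  }
  stopifnot(n_rats >= 1, precision > 0)
  out <- list(n_rats = as.integer(n_rats), base = base,
              asymptote = asymptote, transfer = transfer,
              c_level = c_level, precision = precision)
  class(out) <- "behavior_params"
  out
}

#' Simulate food-cup occupancy for the three task phases
#'
#' Per-trial percentage of cue time spent with the head in the food cup,
#' drawn from Beta distributions whose means encode the expected learning
#' pattern: all cues at a common low rate in preconditioning; occupancy to B
#' growing linearly across conditioning sessions while D stays at base; at
#' probe, B near asymptote, D low, and A above C by the transfer effect.
#'
#' @param task A [task_spec()].
#' @param params A [behavior_params()].
#' @param seed Integer seed.
#' @return A `behavior_table` data.frame with columns `rat_id`, `session_id`,
#'   `phase`, `trial`, `cue_id`, `occupancy` (percent of cue time, 0-100).
#' @export
simulate_behavior <- function(task = task_spec(), params = behavior_params(),
                              seed = 1) {
  stopifnot(inherits(task, "task_spec"), inherits(params, "behavior_params"))
  set.seed(seed)
  events <- trial_schedule(task)
  S <- task$n_cond_sessions
  mu_for <- function(phase, cue, sid) {
    if (phase == "preconditioning") return(params$base)
    if (phase == "conditioning") {
      if (cue == "B") {
        sw <- session_within_phase(task, "conditioning", sid)
        return(params$base + (params$asymptote - params$base) * sw / S)
      }
      return(params$base)
    }
    switch(cue, B = params$asymptote, D = params$base,
           A = params$transfer, C = params$c_level)
  }
  rows <- vector("list", params$n_rats)
  for (r in seq_len(params$n_rats)) {
    mu <- mapply(mu_for, events$phase, events$cue_id, events$session_id)
    occ <- vapply(mu, function(m) {
      if (m <= 0) return(0)
      if (m >= 1) return(100)
      100 * stats::rbeta(1, m * params$precision, (1 - m) * params$precision)
    }, numeric(1))
    rows[[r]] <- data.frame(rat_id = r, session_id = events$session_id,
                            phase = events$phase, trial = events$trial,
                            cue_id = events$cue_id, occupancy = occ,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("behavior_table", "data.frame")
  out
}
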