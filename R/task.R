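#' Sensory-preconditioning task specification
#'
#' Describes the three-phase task: (1) preconditioning, in which two pairs of
#' auditory cues are presented back-to-back (A then B, C then D) with no
#' reward; (2) conditioning, in which cue B is paired with reward delivered at
#' fixed offsets within the cue and cue D is presented unrewarded; (3) a probe
#' test with a few rewarded B / unrewarded D reminder trials followed by
#' unrewarded presentations of A and C.
#'
#' Times are seconds. Each trial is represented as a window that starts
#' `pre_cue` seconds before the first cue onset and ends `post_cue` seconds
#' after the last cue offset; spike times are measured from the start of this
#' window. The inter-trial interval separates windows and carries no data; it
#' can be compressed with `iti_scale` without touching any within-trial
#' timing.
#'
#' @param cue_duration Cue length in seconds.
#' @param reward_offsets Reward delivery times, seconds after onset of cue B.
#' @param n_precond_sessions,precond_trials_per_pair Preconditioning phase:
#'   number of sessions and number of A->B (and C->D) pair trials per session.
#' @param n_cond_sessions,cond_trials_per_cue Conditioning phase: number of
#'   sessions and number of B (and D) trials per session, run in 3-trial
#'   blocks.
#' @param probe_reminders Number of rewarded-B (and D) reminder trials at the
#'   start of the probe session.
#' @param probe_trials_per_cue Number of unrewarded A (and C) probe trials.
#' @param iti_range Inter-trial interval range in seconds.
#' @param iti_scale Multiplier applied to `iti_range` (for compressed test
#'   runs; within-trial timing is unaffected).
#' @param pre_cue,post_cue Seconds of recorded window before the first cue
#'   onset and after the last cue offset of each trial.
#' @return An object of class `task_spec`.
#' @examples
#' task <- task_spec()
#' ev <- trial_schedule(task)
#' head(ev)
#' @export
task_spec <- function(cue_duration = 10,
                      reward_offsets = c(1, 4, 7),
                      n_precond_sessions = 2,
                      precond_trials_per_pair = 6,
                      n_cond_sessions = 6,
                      cond_trials_per_cue = 6,
                      probe_reminders = 3,
                      probe_trials_per_cue = 6,
                      iti_range = c(180, 360),
                      iti_scale = 1,
                      pre_cue = 2,
                      post_cue = 2) {
  stopifnot(cue_duration > 0,
            all(reward_offsets > 0), all(reward_offsets < cue_duration),
            n_precond_sessions >= 1, precond_trials_per_pair >= 1,
            n_cond_sessions >= 1, cond_trials_per_cue >= 1,
            probe_reminders >= 0, probe_trials_per_cue >= 1,
            length(iti_range) == 2, iti_range[1] <= iti_range[2],
            iti_scale > 0, pre_cue > 0, post_cue >= 0)
  spec <- list(cue_duration = cue_duration,
               reward_offsets = sort(reward_offsets),
               n_precond_sessions = n_precond_sessions,
               precond_trials_per_pair = precond_trials_per_pair,
               n_cond_sessions = n_cond_sessions,
               cond_trials_per_cue = cond_trials_per_cue,
               probe_reminders = probe_reminders,
               probe_trials_per_cue = probe_trials_per_cue,
               iti_range = iti_range * iti_scale,
               pre_cue = pre_cue,
               post_cue = post_cue)
  class(spec) <- "task_spec"
  spec
}

#' @export
print.task_spec <- function(x, ...) {
  cat("Sensory-preconditioning task\n")
  cat(sprintf("  cue duration: %g s; rewards in B at %s s after onset\n",
              x$cue_duration, paste(x$reward_offsets, collapse = ", ")))
  cat(sprintf("  preconditioning: %d sessions x %d A->B + %d C->D pair trials\n",
              x$n_precond_sessions, x$precond_trials_per_pair,
              x$precond_trials_per_pair))
  cat(sprintf("  conditioning: %d sessions x %d B(reward) + %d D trials\n",
              x$n_cond_sessions, x$cond_trials_per_cue, x$cond_trials_per_cue))
  cat(sprintf("  probe: %d B + %d D reminders, then %d A + %d C unrewarded\n",
              x$probe_reminders, x$probe_reminders,
              x$probe_trials_per_cue, x$probe_trials_per_cue))
  invisible(x)
}

#' Phase labels used throughout the package
#' @keywords internal
task_phases <- c("preconditioning", "conditioning", "probe")

# Session ids are global and consecutive across phases:
# 1..n_precond, then conditioning, then the single probe session.
session_ids <- function(task, phase) {
  switch(phase,
    preconditioning = seq_len(task$n_precond_sessions),
    conditioning = task$n_precond_sessions + seq_len(task$n_cond_sessions),
    probe = task$n_precond_sessions + task$n_cond_sessions + 1L,
    stop("unknown phase: ", phase))
}

# Session index within its phase (1-based), used by learning trajectories.
session_within_phase <- function(task, phase, session_id) {
  match(session_id, session_ids(task, phase))
}

#' Build the trial/event table for one or all phases
#'
#' Returns one row per cue presentation. Preconditioning pair trials
#' contribute two rows (the leading and trailing cue share a `trial` index).
#' All times are seconds from the start of the trial window; rewards are
#' stored as a semicolon-free list column `reward_times`.
#'
#' @param task A [task_spec()].
#' @param phases Character vector of phases to include.
#' @return A data.frame of class `trial_events` with columns `session_id`,
#'   `phase`, `trial`, `cue_id`, `cue_on`, `cue_off`, `reward_times`
#'   (list column of numeric vectors) and `trial_duration`.
#' @export
trial_schedule <- function(task, phases = task_phases) {
  stopifnot(inherits(task, "task_spec"))
  phases <- match.arg(phases, task_phases, several.ok = TRUE)
  rows <- list()
  add <- function(session, phase, trial, cue, on, rewards, dur) {
    rows[[length(rows) + 1L]] <<- data.frame(
      session_id = session, phase = phase, trial = trial, cue_id = cue,
      cue_on = on, cue_off = on + task$cue_duration,
      trial_duration = dur, stringsAsFactors = FALSE)
    rewards_list[[length(rows)]] <<- rewards
  }
  rewards_list <- list()
  cd <- task$cue_duration
  pre <- task$pre_cue

  if ("preconditioning" %in% phases) {
    dur <- pre + 2 * cd + task$post_cue
    for (s in session_ids(task, "preconditioning")) {
      # blocked design; block order alternates across days
      first_ab <- (session_within_phase(task, "preconditioning", s) %% 2L) == 1L
      pairs <- if (first_ab) c("AB", "CD") else c("CD", "AB")
      trial <- 0L
      for (p in pairs) {
        lead <- substr(p, 1, 1); trail <- substr(p, 2, 2)
        for (k in seq_len(task$precond_trials_per_pair)) {
          trial <- trial + 1L
          add(s, "preconditioning", trial, lead, pre, numeric(0), dur)
          add(s, "preconditioning", trial, trail, pre + cd, numeric(0), dur)
        }
      }
    }
  }

  if ("conditioning" %in% phases) {
    dur <- pre + cd + task$post_cue
    n <- task$cond_trials_per_cue
    for (s in session_ids(task, "conditioning")) {
      # 3-trial blocks, starting block counterbalanced across sessions
      b_first <- (session_within_phase(task, "conditioning", s) %% 2L) == 1L
      blocks <- block_order(n, b_first)
      for (trial in seq_along(blocks)) {
        cue <- blocks[trial]
        rew <- if (cue == "B") pre + task$reward_offsets else numeric(0)
        add(s, "conditioning", trial, cue, pre, rew, dur)
      }
    }
  }

  if ("probe" %in% phases) {
    dur <- pre + cd + task$post_cue
    s <- session_ids(task, "probe")
    trial <- 0L
    # interleaved B/D reminders (B rewarded), then interleaved A/C unrewarded
    for (k in seq_len(task$probe_reminders)) {
      for (cue in c("B", "D")) {
        trial <- trial + 1L
        rew <- if (cue == "B") pre + task$reward_offsets else numeric(0)
        add(s, "probe", trial, cue, pre, rew, dur)
      }
    }
    for (k in seq_len(task$probe_trials_per_cue)) {
      for (cue in c("A", "C")) {
        trial <- trial + 1L
        add(s, "probe", trial, cue, pre, numeric(0), dur)
      }
    }
  }

  ev <- do.call(rbind, rows)
  ev$reward_times <- rewards_list
  rownames(ev) <- NULL
  class(ev) <- c("trial_events", "data.frame")
  validate_trial_events(ev, task)
  ev
}

# alternating 3-trial blocks of B and D covering n trials of each cue
block_order <- function(n, b_first) {
  out <- character(0)
  left <- c(B = n, D = n)
  cue <- if (b_first) "B" else "D"
  while (sum(left) > 0) {
    take <- min(3L, left[[cue]])
    out <- c(out, rep(cue, take))
    left[[cue]] <- left[[cue]] - take
    other <- if (cue == "B") "D" else "B"
    if (left[[other]] > 0) cue <- other
  }
  out
}

#' Validate a trial-event table against the task contract
#'
#' Checks cue durations, reward placement (rewards only during cue B), and the
#' structural guarantee that cue A is never contemporaneous with, or
#' contiguous to, a reward in conditioning or probe phases.
#'
#' @param events A `trial_events` data.frame.
#' @param task The [task_spec()] the events should conform to.
#' @return `events`, invisibly; stops with a descriptive error otherwise.
#' @export
validate_trial_events <- function(events, task) {
  req <- c("session_id", "phase", "trial", "cue_id", "cue_on", "cue_off",
           "reward_times")
  miss <- setdiff(req, names(events))
  if (length(miss)) {
    stop("trial_events: missing column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(events) == 0) return(invisible(events))
  if (!all(events$cue_id %in% c("A", "B", "C", "D"))) {
    stop("trial_events: cue_id outside {A,B,C,D}")
  }
  if (!all(events$phase %in% task_phases)) {
    stop("trial_events: unknown phase label")
  }
  durs <- events$cue_off - events$cue_on
  if (any(abs(durs - task$cue_duration) > 1e-9)) {
    stop("trial_events: cue_off - cue_on must equal the task cue duration")
  }
  has_rew <- lengths(events$reward_times) > 0
  if (any(has_rew & events$cue_id != "B")) {
    stop("trial_events: rewards on a cue other than B")
  }
  if (any(has_rew & events$phase == "preconditioning")) {
    stop("trial_events: rewards during preconditioning")
  }
  # rewards must fall inside the B cue window
  for (i in which(has_rew)) {
    rt <- events$reward_times[[i]]
    if (any(rt < events$cue_on[i] | rt >= events$cue_off[i])) {
      stop("trial_events: reward outside its cue window (row ", i, ")")
    }
  }
  # cue A never contemporaneous or contiguous with reward in phases 2-3:
  # no rewarded row may share a trial with an A row outside preconditioning
  post <- events$phase != "preconditioning"
  a_keys <- unique(paste(events$session_id, events$trial)[post & events$cue_id == "A"])
  r_keys <- unique(paste(events$session_id, events$trial)[post & has_rew])
  if (length(intersect(a_keys, r_keys))) {
    stop("trial_events: cue A shares a trial with reward outside preconditioning")
  }
  # A precedes B only in preconditioning
  if (any(post & events$cue_id == "A")) {
    for (key in a_keys) {
      sub <- events[paste(events$session_id, events$trial) == key, ]
      if (any(sub$cue_id == "B")) {
        stop("trial_events: A and B share a trial outside preconditioning")
      }
    }
  }
  invisible(events)
}
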