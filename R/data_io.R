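#' Read and write trial-aligned electrophysiology bundles
#'
#' A dataset bundle is four plain CSV files in one directory:
#' `spikes.csv` (neuron_id, session_id, phase, trial, spike_time),
#' `events.csv` (session_id, phase, trial, cue_id, cue_on, cue_off,
#' reward_times, trial_duration), `waveforms.csv` (neuron_id,
#' negative_half_width, max_positive_deflection, min_negative_deflection)
#' and `behavior.csv` (rat_id, session_id, phase, trial, cue_id, occupancy).
#' Reward times within a trial are serialized as a `;`-separated field and
#' held in memory as a list column. All times are seconds from trial start,
#' 0-based; trial windows are half-open `[0, duration)`.
#'
#' @param path Directory containing (or to contain) the four CSV files.
#' @param bundle A list with elements `spikes`, `events`, `waveforms`,
#'   `behavior` (any may be `NULL` except `events`).
#' @return `read_dataset()` returns a validated bundle (class
#'   `vta_dataset`); `write_dataset()` returns `path` invisibly.
#' @name dataset_io
NULL

dataset_files <- c(spikes = "spikes.csv", events = "events.csv",
                   waveforms = "waveforms.csv", behavior = "behavior.csv")

#' @rdname dataset_io
#' @export
write_dataset <- function(bundle, path) {
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("write_dataset: cannot create directory ", path)
  }
  ev <- as.data.frame(bundle$events)
  ev$reward_times <- vapply(bundle$events$reward_times, function(r) {
    paste(format(r, trim = TRUE, scientific = FALSE), collapse = ";")
  }, character(1))
  tables <- list(
    spikes = bundle$spikes[, c("neuron_id", "session_id", "phase", "trial",
                               "spike_time")],
    events = ev[, c("session_id", "phase", "trial", "cue_id", "cue_on",
                    "cue_off", "reward_times", "trial_duration")],
    waveforms = bundle$waveforms[, c("neuron_id", "negative_half_width",
                                     "max_positive_deflection",
                                     "min_negative_deflection")],
    behavior = bundle$behavior)
  for (nm in names(dataset_files)) {
    tab <- tables[[nm]]
    if (is.null(tab)) {
      tab <- empty_table(nm)
    }
    utils::write.csv(tab, file.path(path, dataset_files[[nm]]),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

empty_table <- function(which) {
  switch(which,
    spikes = data.frame(neuron_id = integer(0), session_id = integer(0),
                        phase = character(0), trial = integer(0),
                        spike_time = numeric(0)),
    events = data.frame(session_id = integer(0), phase = character(0),
                        trial = integer(0), cue_id = character(0),
                        cue_on = numeric(0), cue_off = numeric(0),
                        reward_times = character(0),
                        trial_duration = numeric(0)),
    waveforms = data.frame(neuron_id = integer(0),
                           negative_half_width = numeric(0),
                           max_positive_deflection = numeric(0),
                           min_negative_deflection = numeric(0)),
    behavior = data.frame(rat_id = integer(0), session_id = integer(0),
                          phase = character(0), trial = integer(0),
                          cue_id = character(0), occupancy = numeric(0)))
}

#' @rdname dataset_io
#' @export
read_dataset <- function(path) {
  tabs <- lapply(names(dataset_files), function(nm) {
    f <- file.path(path, dataset_files[[nm]])
    if (!file.exists(f)) stop("read_dataset: missing file ", f)
    got <- utils::read.csv(f, stringsAsFactors = FALSE,
                           colClasses = NA)
    want <- names(empty_table(nm))
    miss <- setdiff(want, names(got))
    if (length(miss)) {
      stop("read_dataset: ", dataset_files[[nm]], " missing column(s): ",
           paste(miss, collapse = ", "))
    }
    got[, want, drop = FALSE]
  })
  names(tabs) <- names(dataset_files)
  ev <- tabs$events
  ev$reward_times <- lapply(as.character(ev$reward_times), function(s) {
    if (is.na(s) || !nzchar(s)) numeric(0) else
      as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
  })
  class(ev) <- c("trial_events", "data.frame")
  bh <- tabs$behavior
  class(bh) <- c("behavior_table", "data.frame")
  bundle <- list(spikes = tabs$spikes, events = ev,
                 waveforms = tabs$waveforms, behavior = bh)
  class(bundle) <- "vta_dataset"
  validate_dataset(bundle)
  bundle
}

#' Validate a dataset bundle
#'
#' Checks the type invariants (non-negative spike times inside the trial
#' window, half-widths positive, occupancy within 0-100, rewards only on cue
#' B outside preconditioning) and the cross-references (every spike's and
#' behavior row's trial exists in the events table). Errors name the table
#' and offending row.
#'
#' @param bundle A dataset bundle as returned by [read_dataset()] or
#'   [simulate_population()].
#' @return The bundle, invisibly.
#' @export
validate_dataset <- function(bundle) {
  ev <- bundle$events
  sp <- bundle$spikes
  if (nrow(sp)) {
    bad <- which(sp$spike_time < 0)
    if (length(bad)) {
      stop("spikes.csv row ", bad[1], ": negative spike_time ",
           sp$spike_time[bad[1]])
    }
    ekey <- unique(paste(ev$session_id, ev$trial))
    skey <- paste(sp$session_id, sp$trial)
    bad <- which(!skey %in% ekey)
    if (length(bad)) {
      stop("spikes.csv row ", bad[1], ": trial (session ",
           sp$session_id[bad[1]], ", trial ", sp$trial[bad[1]],
           ") not present in events.csv")
    }
    if ("trial_duration" %in% names(ev)) {
      durs <- ev$trial_duration[match(skey, paste(ev$session_id, ev$trial))]
      bad <- which(sp$spike_time >= durs)
      if (length(bad)) {
        stop("spikes.csv row ", bad[1], ": spike_time ",
             sp$spike_time[bad[1]], " outside trial window [0, ",
             durs[bad[1]], ")")
      }
    }
  }
  if (nrow(ev)) {
    durs <- ev$cue_off - ev$cue_on
    if (diff(range(durs)) > 1e-9) {
      stop("events.csv: inconsistent cue durations")
    }
    has_rew <- lengths(ev$reward_times) > 0
    bad <- which(has_rew & (ev$cue_id != "B" | ev$phase == "preconditioning"))
    if (length(bad)) {
      stop("events.csv row ", bad[1],
           ": rewards allowed only on cue B outside preconditioning")
    }
  }
  wf <- bundle$waveforms
  if (!is.null(wf) && nrow(wf)) {
    bad <- which(!(wf$negative_half_width > 0))
    if (length(bad)) {
      stop("waveforms.csv row ", bad[1], ": negative_half_width must be > 0")
    }
  }
  bh <- bundle$behavior
  if (!is.null(bh) && nrow(bh)) {
    bad <- which(bh$occupancy < 0 | bh$occupancy > 100)
    if (length(bad)) {
      stop("behavior.csv row ", bad[1], ": occupancy outside [0, 100]")
    }
  }
  invisible(bundle)
}
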