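#' Run configuration for the end-to-end pipeline
#'
#' Bundles every stage's configuration with a single seed. All analysis
#' defaults mirror the standard parameters: 100-ms bins, 0.01 threshold
#' steps, 3 principal components, 3 clusters, 450-us waveform criterion,
#' 0.5-s / 1-s / final-9-s analysis windows, alpha 0.05.
#'
#' @param seed Integer seed recorded in every output.
#' @param task A [task_spec()].
#' @param population A [population_spec()] (its own seed is overridden by
#'   `seed`).
#' @param analysis An [analysis_config()].
#' @param behavior A [behavior_params()].
#' @param agent_alpha,agent_gamma Agent learning-rate and discount.
#' @param phases Phases to simulate and analyse.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1,
                       task = task_spec(),
                       population = population_spec(),
                       analysis = analysis_config(),
                       behavior = behavior_params(),
                       agent_alpha = 0.1,
                       agent_gamma = 0.98,
                       phases = task_phases) {
  stopifnot(inherits(task, "task_spec"),
            inherits(population, "population_spec"),
            inherits(analysis, "analysis_config"),
            inherits(behavior, "behavior_params"))
  n_total <- population$n_phasic + population$n_sustained_excited +
    population$n_sustained_inhibited
  if (n_total <= 0) stop("run_config: population has zero neurons")
  population$seed <- as.integer(seed)
  out <- list(seed = as.integer(seed), task = task, population = population,
              analysis = analysis, behavior = behavior,
              agent_alpha = agent_alpha, agent_gamma = agent_gamma,
              phases = match.arg(phases, task_phases, several.ok = TRUE))
  class(out) <- "run_config"
  out
}

#' Peak-migration analysis across conditioning sessions
#'
#' Computes, for every neuron and conditioning session, the
#' onset-versus-reward auROC difference for cue B, and correlates it with
#' the session index across all neuron-session observations.
#'
#' @param spikes,events Spike and event tables covering the conditioning
#'   sessions.
#' @param task A [task_spec()].
#' @param config An [analysis_config()].
#' @param neurons Optional neuron subset (e.g. phasic-classified ids).
#' @return A list of class `migration_analysis` with the per-observation
#'   table (`per_observation`: neuron_id, session, difference) and the
#'   [migration_correlation()] result (`correlation`).
#' @export
migration_analysis <- function(spikes, events, task,
                               config = analysis_config(), neurons = NULL) {
  sids <- session_ids(task, "conditioning")
  first_reward <- task$reward_offsets[1]
  window <- c(0, first_reward + config$onset_window)
  obs <- list()
  for (sid in sids) {
    ev <- events[events$session_id == sid & events$cue_id == "B", ,
                 drop = FALSE]
    if (nrow(ev) == 0) next
    sp <- spikes[spikes$session_id == sid, , drop = FALSE]
    mat <- auroc_matrix(sp, ev, "B", config, window, neurons)
    d <- onset_reward_difference(mat, first_reward, config)
    obs[[length(obs) + 1L]] <- data.frame(
      neuron_id = mat$neuron_ids,
      session = session_within_phase(task, "conditioning", sid),
      difference = unname(d))
  }
  per <- do.call(rbind, obs)
  out <- list(per_observation = per,
              correlation = migration_correlation(per$difference,
                                                  per$session))
  class(out) <- "migration_analysis"
  out
}

#' Run the full pipeline: generate, normalize, classify, analyse, simulate
#'
#' Stages: (1) simulate the population and behavior; (2) write the dataset
#' bundle; (3) compute the cue-B auROC matrix over conditioning and
#' classify neurons into the three archetypes (plus the waveform flag);
#' (4) compute the error-signal statistics (peak migration, probe
#' phasic and sustained contrasts, cached-vs-inferred correlation) on the
#' phasic-classified subset and the behavioral ANOVAs; (5) run the
#' model-free/model-based agent comparison. Everything is written under
#' `out_dir` (`data/`, `auroc_matrix.csv`, `labels.csv`, `stats.json`,
#' `manifest.json`); `stats.json` is byte-stable given the config and seed,
#' while the manifest carries the timestamp.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return A list of class `pipeline_report` with elements `dataset`,
#'   `labels`, `auroc`, `stats` and `paths`, invisibly writable via the
#'   files above.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  task <- config$task
  ds <- stage("generate", simulate_population(config$population, task,
                                              config$phases))
  ds$behavior <- stage("generate_behavior",
                       simulate_behavior(task, config$behavior,
                                         seed = config$seed + 1L))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stage("write", write_dataset(ds, file.path(out_dir, "data")))

  cond_ids <- session_ids(task, "conditioning")
  cond_ev <- ds$events[ds$events$session_id %in% cond_ids, , drop = FALSE]
  cond_sp <- ds$spikes[ds$spikes$session_id %in% cond_ids, , drop = FALSE]
  mat <- stage("auroc", auroc_matrix(cond_sp, cond_ev, "B", config$analysis,
                                     window = c(0, task$cue_duration)))
  labels <- stage("classify", classify_neurons(mat, config$analysis,
                                               waveforms = ds$waveforms))
  write_auroc_matrix(mat, file.path(out_dir, "auroc_matrix.csv"))
  utils::write.csv(labels, file.path(out_dir, "labels.csv"),
                   row.names = FALSE, quote = FALSE)

  phasic_ids <- labels$neuron_id[labels$archetype == "phasic"]
  stats <- list(seed = config$seed)
  stats$classification <- list(
    n_neurons = nrow(labels),
    n_phasic = length(phasic_ids),
    n_sustained_excited = sum(labels$archetype == "sustained_excited"),
    n_sustained_inhibited = sum(labels$archetype == "sustained_inhibited"),
    n_wide_waveform = sum(labels$wide_waveform))
  if (length(phasic_ids) >= 3) {
    mig <- stage("analyze_migration",
                 migration_analysis(cond_sp, cond_ev, task, config$analysis,
                                    neurons = phasic_ids))
    stats$migration <- mig$correlation[c("r", "n", "df", "p")]
  }
  if ("probe" %in% config$phases && length(phasic_ids) >= 2) {
    pid <- session_ids(task, "probe")
    pev <- ds$events[ds$events$session_id == pid, , drop = FALSE]
    psp <- ds$spikes[ds$spikes$session_id == pid, , drop = FALSE]
    ct <- function(f, pos, neg) {
      stage("analyze_contrasts",
            f(psp, pev, pos, neg, config$analysis, neurons = phasic_ids))
    }
    bd <- ct(phasic_contrast, "B", "D")
    ac <- ct(phasic_contrast, "A", "C")
    cor_bd_ac <- stage("analyze_correlation",
                       inferred_vs_cached_correlation(
                         bd$per_neuron$difference, ac$per_neuron$difference))
    stats$probe <- list(
      cached_b_minus_d = bd[c("mean_difference", "t", "df", "p")],
      inferred_a_minus_c = ac[c("mean_difference", "t", "df", "p")],
      cached_vs_inferred = cor_bd_ac[c("r", "df", "n", "p")],
      sustained_a_minus_c = ct(sustained_contrast, "A",
                               "C")[c("mean_difference", "t", "df", "p")],
      sustained_b_minus_d = ct(sustained_contrast, "B",
                               "D")[c("mean_difference", "t", "df", "p")])
  }
  stats$behavior <- lapply(stats::setNames(config$phases, config$phases),
                           function(ph) {
    bs <- stage("analyze_behavior", behavior_stats(ds$behavior, ph))
    if (bs$degenerate) list(degenerate = TRUE) else
      list(anova = bs$anova)
  })
  agents <- stage("agents", compare_agents(task, config$agent_alpha,
                                           config$agent_gamma))
  stats$agents <- list(onsets = agents$onsets, contrasts = agents$contrasts)

  stats_path <- file.path(out_dir, "stats.json")
  jsonlite::write_json(stats, stats_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  manifest <- list(package = "vtarpe",
                   version = as.character(utils::packageVersion("vtarpe")),
                   r_version = paste(R.version$major, R.version$minor,
                                     sep = "."),
                   seed = config$seed,
                   config_hash = config_digest(config),
                   started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
                   finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  out <- list(dataset = ds, labels = labels, auroc = mat, stats = stats,
              paths = list(out_dir = out_dir, stats = stats_path))
  class(out) <- "pipeline_report"
  invisible(out)
}

# 32-bit polynomial rolling hash of the deparsed configuration (manifest
# provenance only, not cryptographic)
config_digest <- function(config) {
  bytes <- utf8ToInt(paste(deparse(config), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
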