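config_schema <- list(
  env = c("transit_duration", "reward_delay_min", "reward_delay_max",
          "step_cost", "success_reward", "max_steps", "cue_duration",
          "post_reward_duration"),
  network = c("Nx", "Nz", "gamma", "tau", "scale", "w_density"),
  train = c("policy_lr", "clip_epsilon", "entropy_coef", "rollout_horizon",
            "ppo_epochs", "minibatch_size", "n_episodes", "discount",
            "gae_lambda", "value_coef", "grad_clip", "normalize_adv",
            "eval_window", "seed", "hidden_size"))

#' Load and validate a run configuration
#'
#' Configurations are YAML files with optional sections `env`, `network`
#' and `train`; missing keys take the package defaults, unknown keys are
#' rejected by name. The shipped `"table1"` preset carries the reference
#' simulation settings (16 neuron and 16 astrocyte units, discretization
#' 0.01, learning rate 0.001, clip 0.2, entropy coefficient 0.05, horizon
#' 64, 16 epochs, minibatch 64, 10,000 episodes, reward delay 2-8, maximum
#' trial length 20).
#'
#' @param path Path to a YAML config file (ignored when `preset` given).
#' @param preset Name of a shipped preset (currently `"table1"`).
#' @return List with `env` (a [task_config()]), `network` (argument list
#'   for [asnen_params()]), and `train` (a [train_config()]).
#' @export
load_config <- function(path = NULL, preset = NULL) {
  if (!is.null(preset)) {
    path <- system.file("config", paste0(preset, ".yaml"), package = "asnen")
    if (path == "") stop(sprintf("unknown preset '%s'", preset))
  }
  raw <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
    raw <- yaml::read_yaml(path)
    if (is.null(raw)) {
      warning("empty config file; using all defaults")
      raw <- list()
    }
  }
  bad_sections <- setdiff(names(raw), names(config_schema))
  if (length(bad_sections) > 0L)
    stop(sprintf("unknown config section(s): %s",
                 paste(bad_sections, collapse = ", ")))
  for (sec in names(config_schema)) {
    bad <- setdiff(names(raw[[sec]]), config_schema[[sec]])
    if (length(bad) > 0L)
      stop(sprintf("unknown key(s) in section '%s': %s", sec,
                   paste(bad, collapse = ", ")))
  }
  list(env = do.call(task_config, raw$env %||% list()),
       network = raw$network %||% list(),
       train = do.call(train_config, raw$train %||% list()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a run manifest
#'
#' Records everything needed to reproduce a run bit-identically: the
#' command, the full configuration snapshot, the seed, the package
#' version, a timestamp, and MD5 digests of every artifact written.
#'
#' @param out_dir Run output directory.
#' @param command Command name.
#' @param config Configuration list (as from [load_config()]).
#' @param seed Integer seed.
#' @param files Paths of artifacts to digest.
#' @param extra Optional named list of extra fields (e.g. architecture).
#' @return Path of the written `manifest.json` (invisibly).
#' @export
write_manifest <- function(out_dir, command, config, seed, files,
                           extra = list()) {
  digests <- as.list(tools::md5sum(files))
  names(digests) <- basename(names(digests))
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  man <- c(list(command = command, seed = as.integer(seed),
                config = strip(config),
                package_version = as.character(utils::packageVersion("asnen")),
                timestamp = format(Sys.time(), tz = "UTC",
                                   "%Y-%m-%dT%H:%M:%SZ"),
                digests = digests),
           extra)
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_manifest
#' @param manifest_path Path to a `manifest.json`.
#' @return `read_manifest` returns the parsed manifest list.
#' @export
read_manifest <- function(manifest_path) {
  jsonlite::read_json(manifest_path, simplifyVector = TRUE)
}

rebuild_config <- function(cfg) {
  # config round-tripped through JSON: restore classed objects
  list(env = do.call(task_config, cfg$env[setdiff(names(cfg$env), "")]),
       network = as.list(cfg$network),
       train = do.call(train_config, cfg$train[config_schema$train
                                               [config_schema$train %in%
                                                  names(cfg$train)]]))
}

#' Run a packaged experiment command
#'
#' Single entry point tying the modules together; each command writes its
#' artifacts plus a manifest into `out_dir` (created if missing) and
#' returns the artifact paths.
#'
#' Commands: `"train"` (one training run; metrics CSV + checkpoint),
#' `"rollout"` (record internal states of a checkpointed agent; tidy CSV),
#' `"analyze"` (trained-vs-untrained event-locked comparison + per-unit
#' profiles of a checkpoint), `"classify"` (photometry pipeline on trace +
#' event CSVs), `"synth"` (generate synthetic photometry CSVs), and
#' `"compare"` (train across seeds and architectures; per-run metrics +
#' summary table).
#'
#' @param command One of train, rollout, analyze, classify, synth,
#'   compare.
#' @param config Configuration from [load_config()] (defaults applied when
#'   NULL).
#' @param out_dir Output directory.
#' @param seed Integer seed (overrides the config seed).
#' @param arch Architecture for train/rollout/analyze.
#' @param model Checkpoint path (rollout/analyze); defaults to an untrained
#'   agent when NULL.
#' @param traces,events CSV paths for classify.
#' @param synth Optional [synth_spec()] for synth.
#' @param seeds,archs Vectors for compare.
#' @param n_episodes Optional override of the configured episode budget.
#' @return Invisible list of written artifact paths (plus command-specific
#'   results).
#' @export
run_experiment <- function(command = c("train", "rollout", "analyze",
                                       "classify", "synth", "compare"),
                           config = NULL, out_dir = "asnen_run", seed = 1L,
                           arch = "asnen", model = NULL, traces = NULL,
                           events = NULL, synth = NULL,
                           seeds = 1:3, archs = c("asnen", "vrnn", "lstm"),
                           n_episodes = NULL) {
  command <- match.arg(command)
  if (is.null(config)) config <- load_config()
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  config$train$seed <- as.integer(seed)
  if (!is.null(n_episodes)) config$train$n_episodes <- as.integer(n_episodes)
  files <- character(0)
  result <- NULL

  if (command == "train") {
    run <- train_agent(config$env, config$train, arch)
    mpath <- file.path(out_dir, sprintf("metrics_%s_seed%d.csv", arch, seed))
    utils::write.csv(run$metrics, mpath, row.names = FALSE)
    cpath <- file.path(out_dir, sprintf("network_%s_seed%d.json", arch, seed))
    save_network(run$agent$params, cpath)
    files <- c(mpath, cpath)
    result <- run
  } else if (command == "synth") {
    if (is.null(synth)) synth <- synth_spec(seed = seed)
    synth$seed <- as.integer(seed)
    ts <- generate_traces(synth)
    tp <- file.path(out_dir, "traces.csv")
    ep <- file.path(out_dir, "events.csv")
    write_traces(ts, tp, ep)
    files <- c(tp, ep)
    result <- ts
  } else if (command == "classify") {
    if (is.null(traces) || is.null(events))
      stop("classify requires traces and events CSV paths")
    ts <- read_traces(traces, events)
    out <- photometry_pipeline(ts)
    cp <- file.path(out_dir, "classification.csv")
    utils::write.csv(data.frame(rel_time = out$rel_time,
                                mean_trace = out$mean_trace,
                                class = out$class),
                     cp, row.names = FALSE)
    files <- cp
    result <- out
  } else if (command %in% c("rollout", "analyze")) {
    set.seed(seed)
    agent <- agent_init(arch, hidden_size = config$train$hidden_size)
    if (!is.null(model)) agent$params <- load_network(model)
    rec <- record_rollouts(agent, config$env, n_success_trials = 10L,
                           max_attempts = 300L)
    rp <- file.path(out_dir, "recording_steps.csv")
    utils::write.csv(cbind(rec$steps, as.data.frame(rec$z)), rp,
                     row.names = FALSE)
    files <- rp
    result <- rec
    if (command == "analyze") {
      set.seed(seed)
      untrained <- agent_init(arch, hidden_size = config$train$hidden_size)
      rec0 <- record_rollouts(untrained, config$env, n_success_trials = 10L,
                              max_attempts = 300L)
      cmp <- pre_post_compare(rec0, rec)
      up <- unit_profiles(rec)
      ap <- file.path(out_dir, "analysis.csv")
      utils::write.csv(data.frame(unit = seq_along(up$classes),
                                  class = as.character(up$classes)),
                       ap, row.names = FALSE)
      files <- c(files, ap)
      result <- list(recording = rec, compare = cmp, profiles = up)
    }
  } else if (command == "compare") {
    summary_rows <- list()
    for (a in archs) for (s in seeds) {
      cfg_s <- config
      cfg_s$train$seed <- as.integer(s)
      run <- train_agent(cfg_s$env, cfg_s$train, a)
      mp <- file.path(out_dir, sprintf("metrics_%s_seed%d.csv", a, s))
      utils::write.csv(run$metrics, mp, row.names = FALSE)
      files <- c(files, mp)
      summary_rows[[length(summary_rows) + 1L]] <- data.frame(
        arch = a, seed = s,
        params = parameter_count(run$agent),
        final_success = utils::tail(run$metrics$moving_success, 1L),
        final_return = utils::tail(run$metrics$moving_return, 1L),
        auc_success = metric_auc(run$metrics$moving_success),
        auc_return = metric_auc(run$metrics$moving_return))
    }
    sm <- do.call(rbind, summary_rows)
    sp <- file.path(out_dir, "summary.csv")
    utils::write.csv(sm, sp, row.names = FALSE)
    files <- c(files, sp)
    result <- sm
  }

  man <- write_manifest(out_dir, command, config, seed, files,
                        extra = list(arch = arch))
  invisible(list(files = files, manifest = man, result = result))
}

#' Re-run a command from its manifest
#'
#' Reproduces a previous run from the recorded command, configuration and
#' seed; with identical package versions the artifact digests match the
#' manifest bit for bit.
#'
#' @param manifest_path Path to a `manifest.json`.
#' @param out_dir Output directory for the re-run.
#' @return As [run_experiment()].
#' @export
rerun_from_manifest <- function(manifest_path, out_dir) {
  man <- read_manifest(manifest_path)
  cfg <- rebuild_config(man$config)
  run_experiment(man$command, cfg, out_dir, seed = man$seed,
                 arch = man$arch %||% "asnen")
}
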