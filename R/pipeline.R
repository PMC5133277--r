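#' Default pipeline configuration
#'
#' Nested list mirroring the experiment: design block (scenes, lists,
#' participants, trials per participant), geometry block, simulator
#' parameter block, filter block (RT cutoff, x-flip jitter, start radius,
#' GCA bins) and model block (measures to fit, df policy, whether to run
#' the growth-curve analysis). Defaults reproduce the full study design:
#' 225 scenes x 4 cells, 4 Latin lists, 64 participants x 100 trials.
#'
#' @param ... named overrides merged into the defaults (nested lists are
#'   merged recursively).
#' @return list of class `run_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    design = list(n_scenes = 225L, n_lists = 4L, n_participants = 64L,
                  per_participant = 100L),
    geometry = list(width_px = 1024, height_px = 768,
                    button_inset_frac = 0.15, start_radius_px = 50,
                    button_radius_px = 40, sample_rate_hz = 60),
    params = unclass(sim_params())[c(
      "beta_conflict", "beta_accuracy", "beta_rt_s", "participant_sd",
      "scene_sd", "conflict_participant_sd", "conflict_scene_sd",
      "rt_participant_sd_s", "motor_noise_px", "base_speed_px_per_step",
      "latency_base_s", "latency_jitter_s", "conflict_w_frac",
      "max_duration_s")],
    filter = list(k_sd = 4, jitter_px = 3, start_radius_px = 50,
                  n_bins = 101L),
    models = list(measures = c("accuracy", "rt_s", "initial_degree",
                               "latency_s", "xflips", "auc"),
                  df_policy = "satterthwaite", gca = FALSE)
  )
  overrides <- list(...)
  if (length(overrides)) cfg <- modifyList(cfg, overrides)
  class(cfg) <- "run_config"
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks every block against its module constructor; errors on invalid
#' values.
#'
#' @param config a `run_config` (or plain list).
#' @return the config, invisibly.
#' @export
validate_config <- function(config) {
  stopifnot(is.numeric(config$seed), length(config$seed) == 1)
  d <- config$design
  stopifnot(d$n_scenes >= 1, d$n_lists >= 1, d$n_participants >= 1,
            d$per_participant >= 1)
  do.call(screen_geometry, config$geometry)
  do.call(sim_params, config$params)
  stopifnot(config$filter$k_sd > 0, config$filter$jitter_px >= 0,
            config$filter$n_bins >= 2)
  stopifnot(config$models$df_policy %in% c("satterthwaite", "normal"))
  invisible(config)
}

#' Read / write a configuration as YAML
#'
#' @param path file path.
#' @param config a `run_config`.
#' @return `read_config` returns a validated `run_config`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  basis_names <- c("intercept", "plausibility", "congruency", "order",
                   "plaus_cong", "plaus_order", "cong_order",
                   "plaus_cong_order")
  for (b in c("beta_conflict", "beta_accuracy", "beta_rt_s")) {
    if (!is.null(cfg$params[[b]])) {
      v <- unlist(cfg$params[[b]])
      if (is.null(names(v)) && length(v) == 8) names(v) <- basis_names
      cfg$params[[b]] <- v
    }
  }
  cfg <- modifyList(unclass(default_config()), cfg)
  class(cfg) <- "run_config"
  validate_config(cfg)
  cfg
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' Write / read the trial and cursor-sample tables as CSV
#'
#' `trials.csv` holds one row per trial (no trajectory); `samples.csv`
#' holds one row per cursor sample (`participant_id`, `trial_index`,
#' `t_ms`, `x_px`, `y_px`). UTF-8, header row, "." decimal separator.
#'
#' @param trials a `trial_table`.
#' @param dir output directory (created if missing).
#' @param geometry the geometry used when re-assembling trajectories.
#' @return `write_trials_csv` returns the two file paths;
#'   `read_trials_csv` returns a `trial_table` with re-assembled
#'   trajectories.
#' @export
write_trials_csv <- function(trials, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  flat <- trials[, setdiff(names(trials), c("trajectory", "canonical")),
                 drop = FALSE]
  trials_path <- file.path(dir, "trials.csv")
  write.csv(flat, trials_path, row.names = FALSE)
  samples <- do.call(rbind, lapply(seq_len(nrow(trials)), function(i) {
    s <- trials$trajectory[[i]]$samples
    data.frame(participant_id = trials$participant_id[i],
               trial_index = trials$trial_index[i],
               t_ms = s$t_ms, x_px = s$x_px, y_px = s$y_px)
  }))
  samples_path <- file.path(dir, "samples.csv")
  write.csv(samples, samples_path, row.names = FALSE)
  c(trials = trials_path, samples = samples_path)
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(dir, geometry = screen_geometry()) {
  trials <- read.csv(file.path(dir, "trials.csv"),
                     stringsAsFactors = FALSE)
  samples <- read.csv(file.path(dir, "samples.csv"))
  key <- paste(samples$participant_id, samples$trial_index)
  split_samples <- split(samples, factor(key, levels = unique(key)))
  idx <- match(paste(trials$participant_id, trials$trial_index),
               names(split_samples))
  answer <- answer_for(trials$congruency)
  trials$trajectory <- lapply(seq_len(nrow(trials)), function(i) {
    s <- split_samples[[idx[i]]]
    traj <- list(
      samples = data.frame(t_ms = s$t_ms, x_px = s$x_px, y_px = s$y_px),
      geometry = geometry,
      chosen_side = side_of(trials$response[i], trials$counterbalance[i]),
      correct_side = side_of(answer[i], trials$counterbalance[i])
    )
    class(traj) <- "mt_trajectory"
    traj
  })
  class(trials) <- c("trial_table", "data.frame")
  trials
}

hash_file <- function(path) unname(tools::md5sum(path))

#' Run the full pipeline: simulate, preprocess, measure, fit, report
#'
#' Executes every stage from a single configuration and seed, writes all
#' stage outputs under `out_dir` (trial/sample CSVs, filter report JSON,
#' measure and cell-summary CSVs, fit CSV, markdown tables, model-spec
#' sidecar) and returns a manifest with the config hash and per-file
#' hashes. Deterministic stages reproduce identical hashes for identical
#' config + seed.
#'
#' @param config a [default_config()]-style configuration.
#' @param out_dir output directory.
#' @return the manifest (list of class `run_manifest`), invisibly writable
#'   via its `manifest.json` copy in `out_dir`.
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "design"
  manifest <- list(files = list(), stages = character(0))
  result <- tryCatch({
    geometry <- do.call(screen_geometry, config$geometry)
    params <- do.call(sim_params, config$params)

    bank <- build_item_bank(config$design$n_scenes)
    lists <- build_latin_lists(bank, config$design$n_lists)
    sched <- build_schedules(lists, config$design$n_participants,
                             config$design$per_participant,
                             seed = config$seed)
    manifest$stages <- c(manifest$stages, "design")

    stage <- "simulate"
    trials <- simulate_experiment(sched, params, geometry,
                                  seed = config$seed)
    paths <- write_trials_csv(trials, out_dir)
    manifest$stages <- c(manifest$stages, "simulate")

    stage <- "preprocess"
    prep <- preprocess_trials(trials, k_sd = config$filter$k_sd)
    report_path <- file.path(out_dir, "filter_report.json")
    jsonlite::write_json(unclass(prep$report), report_path,
                         auto_unbox = TRUE, digits = NA)
    message(sprintf(
      "preprocess: %d trials in, %d RT outliers (%.1f%%) removed, %d errors excluded, %d retained",
      prep$report$n_input, prep$report$n_removed_rt,
      100 * prep$report$n_removed_rt / prep$report$n_input,
      prep$report$n_removed_error_trials, prep$report$n_retained))
    manifest$stages <- c(manifest$stages, "preprocess")

    stage <- "measure"
    measures <- measure_trials(prep$trials,
                               start_radius_px = config$filter$start_radius_px,
                               jitter_px = config$filter$jitter_px)
    measures_path <- file.path(out_dir, "measures.csv")
    write.csv(measures, measures_path, row.names = FALSE)
    summary <- summarize_cells(measures, accuracy_data = prep$accuracy_trials)
    summary_path <- file.path(out_dir, "cell_summary.csv")
    write.csv(summary, summary_path, row.names = FALSE)
    writeLines(table1_markdown(summary), file.path(out_dir, "table1.md"))
    manifest$stages <- c(manifest$stages, "measure")

    stage <- "fit"
    fits <- list()
    coded <- code_contrasts(measures)
    acc_data <- prep$accuracy_trials
    acc_data$accuracy <- acc_data$correct
    acc_data <- code_contrasts(acc_data)
    for (m in config$models$measures) {
      fits[[m]] <- if (m == "accuracy") {
        fit_accuracy_glmm(acc_data)
      } else if (m == "xflips") {
        fit_lmm_maximal(coded, m, family = "poisson",
                        df_policy = config$models$df_policy)
      } else {
        fit_lmm_maximal(coded, m, df_policy = config$models$df_policy)
      }
    }
    if (isTRUE(config$models$gca)) {
      profiles <- gca_profiles(prep$trials, n_bins = config$filter$n_bins)
      fits[["gca"]] <- fit_gca(profiles,
                               df_policy = config$models$df_policy)
    }
    if (length(fits)) {
      write.csv(fits_table(fits), file.path(out_dir, "fits.csv"),
                row.names = FALSE)
      writeLines(table2_markdown(fits), file.path(out_dir, "table2.md"))
      spec <- lapply(fits, function(f) list(
        formula = f$formula, family = f$family, df_policy = f$df_policy,
        singular = f$singular, converged = f$converged,
        reduction_path = f$reduction_path, n_obs = f$n_obs))
      jsonlite::write_json(spec, file.path(out_dir, "model_spec.json"),
                           auto_unbox = TRUE)
    }
    manifest$stages <- c(manifest$stages, "fit")
    list(trials = trials, prep = prep, measures = measures,
         summary = summary, fits = fits)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })

  config_path <- file.path(out_dir, "config.yaml")
  write_config(config, config_path)
  out_files <- setdiff(list.files(out_dir, full.names = TRUE),
                       file.path(out_dir, "manifest.json"))
  manifest$config_hash <- hash_file(config_path)
  manifest$files <- as.list(setNames(
    vapply(out_files, hash_file, ""), basename(out_files)))
  manifest$filter_report <- unclass(result$prep$report)
  manifest$versions <- list(package = as.character(packageVersion("mtverify")),
                            r = paste(R.version$major, R.version$minor,
                                      sep = "."))
  manifest$timestamp <- format(Sys.time(), tz = "UTC")
  class(manifest) <- "run_manifest"
  json <- manifest
  class(json) <- NULL
  jsonlite::write_json(json, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(structure(c(manifest, list(result = result)),
                      class = "run_manifest"))
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("pipeline run:", paste(x$stages, collapse = " -> "), "\n")
  cat("config hash:", x$config_hash, "\n")
  cat(length(x$files), "output files\n")
  invisible(x)
}
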