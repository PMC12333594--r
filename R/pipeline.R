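#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis with defaults that
#' reproduce the reference settings: 1-49 Hz band, 100 Hz analysis rate,
#' \[-500, 0) ms baseline, Cz reference, 1000 balanced resamples with a 95%
#' pointwise CI, full post-stimulus regression window, and the 800-2000 ms /
#' 0-50 Hz / 0.5 Hz spectral-centroid grid. The simulation block is scaled
#' by `sim` (a [sim_params()] object).
#'
#' @param sim A [sim_params()] object describing the cohort to simulate.
#' @param band Analysis band in Hz.
#' @param target_fs Analysis sampling rate in Hz.
#' @param baseline Baseline window in ms.
#' @param n_resamples Balanced partitions for every null.
#' @param ci_level Pointwise CI level.
#' @param regression_window Phase-slope window in ms.
#' @param centroid_window Spectral-centroid window in ms.
#' @param centroid_f_range,centroid_bin_hz Centroid PSD grid.
#' @param pair Target electrode pair for phase/centroid stages.
#' @param seed Master seed; every stage derives its streams from it.
#' @return A list of class `run_config`.
#' @export
pipeline_config <- function(sim = sim_params(),
                            band = c(1, 49), target_fs = 100,
                            baseline = c(-500, 0),
                            n_resamples = 1000, ci_level = 0.95,
                            regression_window = c(0, 3000),
                            centroid_window = c(800, 2000),
                            centroid_f_range = c(0, 50),
                            centroid_bin_hz = 0.5,
                            pair = c("CP1", "CP2"),
                            seed = 1L) {
  structure(
    list(sim = sim, band = band, target_fs = target_fs, baseline = baseline,
         n_resamples = n_resamples, ci_level = ci_level,
         regression_window = regression_window,
         centroid_window = centroid_window,
         centroid_f_range = centroid_f_range,
         centroid_bin_hz = centroid_bin_hz, pair = pair, seed = seed),
    class = "run_config"
  )
}

#' Run the end-to-end analysis
#'
#' Simulates (or loads) a cohort, preprocesses it, and runs the requested
#' stages, writing each stage's CSV/JSON outputs plus a machine-readable run
#' manifest (config hash, seed, package version, files written) to
#' `out_dir`. Stages: `behavior`, `erp`, `hemi`, `phase`, `slopes`,
#' `centroid`, or `all`.
#'
#' @param config A [pipeline_config()] object.
#' @param out_dir Output directory (created if needed).
#' @param stages Character vector of stage names, or `"all"`.
#' @param epochs_list Optional pre-built list of [eeg_epochs] (skips
#'   simulation; assumed already preprocessed).
#' @return Invisibly, a list with the stage results and the manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = "results",
                         stages = "all", epochs_list = NULL) {
  all_stages <- c("behavior", "erp", "hemi", "phase", "slopes", "centroid")
  if (identical(stages, "all")) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  put_csv <- function(x, name) {
    path <- file.path(out_dir, name)
    readr::write_csv(x, path)
    files <<- c(files, path)
  }
  put_json <- function(x, name) {
    path <- file.path(out_dir, name)
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <<- c(files, path)
  }
  results <- list()

  needs_eeg <- length(setdiff(stages, "behavior")) > 0
  if (needs_eeg && is.null(epochs_list)) {
    cohort <- simulate_cohort(config$sim)
    epochs_list <- purrr::map(cohort, function(s) {
      preprocess(s$epochs, config$band[1L], config$band[2L], config$target_fs,
                 config$baseline)
    })
  }

  if ("behavior" %in% stages) {
    resp <- simulate_responses(n_pairs = config$sim$n_subjects,
                               n_sessions = config$sim$n_sessions,
                               trials_per_session = config$sim$trials_per_session,
                               seed = config$seed)
    results$behavior <- list(
      accuracy = accuracy_vs_chance(resp),
      sessions = session_accuracy_anova(resp),
      lying = lying_proportion_regression(resp)
    )
    put_csv(resp, "responses.csv")
    put_json(lapply(results$behavior, as.list), "behavior_stats.json")
  }
  if ("erp" %in% stages) {
    results$erp <- condition_erps(epochs_list)
    put_csv(results$erp$windows, "erp_windows.csv")
    put_csv(results$erp$grand, "erp_grand.csv")
  }
  if ("hemi" %in% stages) {
    chans <- epochs_list[[1L]]$channels
    pairs <- dplyr::filter(pair_table(), .data$left %in% chans,
                           .data$right %in% chans)
    if (!nrow(pairs)) stop("no homologous pairs present in the montage",
                           call. = FALSE)
    results$hemi <- list(
      waveforms = pair_difference(epochs_list, pairs),
      components = component_stats(epochs_list, pairs)
    )
    put_csv(results$hemi$waveforms, "pair_waveforms.csv")
    put_csv(results$hemi$components, "component_stats.csv")
  }
  ps_list <- NULL
  if (any(c("phase", "slopes") %in% stages)) {
    ps_list <- purrr::map(epochs_list, pair_phase_shift, pair = config$pair)
  }
  if ("phase" %in% stages) {
    prof <- cohort_conditioning_shift(ps_list)
    env <- null_envelope(ps_list, config$n_resamples, config$seed,
                         config$ci_level)
    exc <- exceedance(prof, env)
    results$phase <- list(profile = prof, envelope = env, exceedance = exc)
    put_csv(exc$flags, "conditioning_shift.csv")
    put_json(exc$intervals, "significant_intervals.json")
  }
  if ("slopes" %in% stages) {
    tbl <- slope_table(ps_list, config$n_resamples, config$seed,
                       config$regression_window)
    results$slopes <- list(table = tbl, anova = compare_slopes(tbl))
    put_csv(tbl, "slopes.csv")
    put_json(as.list(results$slopes$anova), "slopes_anova.json")
  }
  if ("centroid" %in% stages) {
    tbl <- cohort_centroids(epochs_list, window = config$centroid_window,
                            electrodes = config$pair,
                            n_resamples = min(config$n_resamples, 200),
                            f_range = config$centroid_f_range,
                            bin_hz = config$centroid_bin_hz,
                            seed = config$seed)
    tests <- interaction_tests(tbl)
    results$centroid <- list(table = tbl, tests = tests)
    put_csv(tbl, "centroids.csv")
    put_json(list(anova = tidy.centroid_tests(tests),
                  crossover = tests$crossover,
                  control_crossover = tests$control_crossover),
             "centroid_tests.json")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("hemiphase")),
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    stages = stages,
    files = basename(files),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  put_json(manifest, "manifest.json")
  invisible(c(results, list(manifest = manifest)))
}
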