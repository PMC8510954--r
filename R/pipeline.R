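# End-to-end orchestration: simulate -> extract -> (robustness inside the
# evaluation loop) -> search -> evaluate -> report, as one reproducible run
# with a config, structured outputs and a manifest.

#' Build a run configuration
#'
#' @param cohort a [cohort_config()]
#' @param designs named list of [experiment_design()]s to run
#' @param n_candidates,ensemble_k,metric,n_internal workflow-search budget
#' @param n_iterations,train_frac outer split plan
#' @param seed master seed; stage seeds are derived from it
#' @param output_dir where the report bundle is written
#' @return object of class `run_config`
#' @export
run_config <- function(cohort = cohort_config(),
                       designs = list(multi_observer = experiment_design("multi")),
                       n_candidates = 1000L, ensemble_k = 10L,
                       metric = "f1_weighted", n_internal = 5L,
                       n_iterations = 10L, train_frac = 0.8,
                       seed = 1L, output_dir = "hgp_run") {
  stopifnot(length(designs) > 0,
            all(vapply(designs, inherits, logical(1), "experiment_design")))
  structure(list(cohort = cohort, designs = designs,
                 n_candidates = as.integer(n_candidates),
                 ensemble_k = as.integer(ensemble_k), metric = metric,
                 n_internal = as.integer(n_internal),
                 n_iterations = as.integer(n_iterations),
                 train_frac = train_frac, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "run_config")
}

#' Run the full pipeline
#'
#' Writes per-stage outputs under `config$output_dir`: cohort metadata and
#' Dice table, the feature table with its manifest, per-design metric
#' summaries and ROC bands, and a run manifest listing every file with the
#' seeds and config used.
#'
#' @param config [run_config()]
#' @param write_volumes also export NIfTI volumes/masks (off by default;
#'   they dominate disk usage)
#' @param verbose progress messages
#' @return list with `cohort`, `features`, `results`, `files`
#' @export
run_pipeline <- function(config, write_volumes = FALSE, verbose = TRUE) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(...)
  files <- character(0)
  out <- function(name) file.path(config$output_dir, name)

  say("stage 1/4: simulate cohort")
  cohort <- generate_cohort(config$cohort)
  utils::write.csv(cohort$metadata, out("cohort_metadata.csv"),
                   row.names = FALSE)
  files <- c(files, out("cohort_metadata.csv"))
  if (write_volumes)
    files <- c(files, write_cohort(cohort, out("nifti")))
  dsc <- pairwise_dice_table(cohort_masks_by_lesion(cohort))
  write_dsc_table(dsc, out("dice_table.csv"))
  files <- c(files, out("dice_table.csv"))

  say("stage 2/4: extract features")
  rois <- unique(vapply(config$designs, `[[`, character(1), "roi"))
  features <- extract_cohort_features(cohort, rois = rois)
  write_feature_table(features, out("features.csv"))
  files <- c(files, out("features.csv"), out("features_manifest.json"))

  say("stage 3/4: reliability diagnostics")
  lesion_ft <- features[features$roi == rois[1], , drop = FALSE]
  icc_rec <- icc_table(lesion_ft)
  utils::write.csv(icc_rec, out("icc_table.csv"), row.names = FALSE)
  files <- c(files, out("icc_table.csv"))

  say("stage 4/4: evaluate designs")
  splits <- make_splits(cohort$metadata, config$n_iterations,
                        config$train_frac, seed = config$seed + 1L)
  results <- list()
  for (nm in names(config$designs)) {
    say("  design: ", nm)
    res <- run_experiment(features, config$designs[[nm]], splits,
                          n_candidates = config$n_candidates,
                          k = config$ensemble_k, metric = config$metric,
                          n_internal = config$n_internal,
                          seed = config$seed + 1000L, verbose = verbose)
    results[[nm]] <- res
    f <- out(paste0("metrics_", nm, ".csv"))
    utils::write.csv(cbind(design = nm, res$summary), f, row.names = FALSE)
    files <- c(files, f)
    if (length(res$roc) > 1L) {
      rb <- roc_band(res$roc)
      f <- out(paste0("roc_band_", nm, ".csv"))
      utils::write.csv(data.frame(fpr = rb$fpr, tpr_mean = rb$tpr_mean,
                                  lo = pmax(rb$tpr_mean - rb$w, 0),
                                  hi = pmin(rb$tpr_mean + rb$w, 1)),
                       f, row.names = FALSE)
      files <- c(files, f)
    }
  }
  combined <- do.call(rbind, lapply(names(results), function(nm)
    cbind(design = nm, results[[nm]]$summary)))
  utils::write.csv(combined, out("metrics_all.csv"), row.names = FALSE)
  files <- c(files, out("metrics_all.csv"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("hgpradiomics")),
    seed = config$seed,
    config = .config_digestible(config),
    files = basename(files),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, out("run_manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files <- c(files, out("run_manifest.json"))
  invisible(list(cohort = cohort, features = features, results = results,
                 files = files))
}

.config_digestible <- function(config) {
  cf <- unclass(config)
  cf$cohort <- unclass(cf$cohort)
  cf$designs <- lapply(cf$designs, unclass)
  cf
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `extract`, `evaluate`, `all` (default).
#' Used by `inst/cli/hgpradiomics-cli`.
#'
#' @param args character vector of CLI arguments
#' @return exit code (0 on success)
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  get_opt <- function(flag, default) {
    i <- which(args == flag)
    if (length(i) == 1L && i < length(args)) args[i + 1L] else default
  }
  cmd <- if (length(args) && !startsWith(args[1], "--")) args[1] else "all"
  seed <- as.integer(get_opt("--seed", "1"))
  outdir <- get_opt("--out", "hgp_run")
  n_pat <- as.integer(get_opt("--n-patients", "32"))
  n_cand <- as.integer(get_opt("--n-candidates", "1000"))
  ens_k <- as.integer(get_opt("--ensemble-k", "10"))
  n_iter <- as.integer(get_opt("--n-iterations", "10"))
  eff <- as.numeric(get_opt("--texture-effect", "1"))
  metric <- get_opt("--metric", "f1_weighted")
  cc <- cohort_config(n_patients = n_pat, texture_effect = eff, seed = seed,
                      volume_dim = c(48L, 48L, 16L))
  rc <- run_config(cohort = cc, n_candidates = n_cand, ensemble_k = ens_k,
                   metric = metric, n_iterations = n_iter, seed = seed,
                   output_dir = outdir)
  if (cmd == "simulate") {
    cohort <- generate_cohort(cc)
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(cohort$metadata,
                     file.path(outdir, "cohort_metadata.csv"),
                     row.names = FALSE)
    write_cohort(cohort, file.path(outdir, "nifti"))
  } else if (cmd == "extract") {
    cohort <- generate_cohort(cc)
    features <- extract_cohort_features(cohort)
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_feature_table(features, file.path(outdir, "features.csv"))
  } else if (cmd %in% c("evaluate", "all")) {
    run_pipeline(rc)
  } else {
    message("unknown subcommand: ", cmd)
    return(invisible(2L))
  }
  invisible(0L)
}
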