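#' Default end-to-end run configuration
#'
#' Returns the configuration list consumed by [runPipeline()]: a simulated
#' five-platform study at the default cohort and platform design, default
#' filters, screening at alpha 0.05 with peak-height QC 3000, a 61/21-style
#' stratified split (train fraction 61/82), nested CV for both model
#' families, feature stepping on the validation set and a permutation null.
#'
#' @param outdir output directory.
#' @param seed run seed.
#' @param n_resamples outer resamples for nested CV and the permutation null.
#' @return nested configuration list.
#' @export
defaultRunConfig <- function(outdir = "metamark_run", seed = 1L,
                             n_resamples = 100L) {
  list(
    input = "simulate",
    outdir = outdir,
    seed = as.integer(seed),
    cohort = list(n_case = 52L, n_control = 30L),
    effects = list(n = 30L, cv = 0.3),
    filter = list(min_median_abundance = 1000, min_presence_fraction = 0.5),
    screen = list(alpha = 0.05, min_peak_height = 3000),
    split = list(train_fraction = 61 / 82),
    annotation = list(tolerance_ppm = 20, db_path = system.file(
      "extdata", "metabolite_db.tsv", package = "metamark")),
    model = list(families = c("svm", "plsda"),
                 n_resamples = as.integer(n_resamples),
                 outer_fraction = 0.8, rfe_step = 20L, inner_folds = 10L),
    permutation = list(enabled = TRUE,
                       n_resamples = as.integer(n_resamples)))
}

#' Read a run configuration from a YAML file
#'
#' Missing fields are filled from [defaultRunConfig()].
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
readRunConfig <- function(path) {
  user <- yaml::read_yaml(path)
  mergeConfig(defaultRunConfig(), user)
}

mergeConfig <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- mergeConfig(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

validateRunConfig <- function(config) {
  has_files <- !is.null(config$input_files)
  simulate <- identical(config$input, "simulate")
  if (has_files && simulate)
    stop("config must choose exactly one input mode: ",
         "remove 'input_files' or set input != 'simulate'")
  if (!has_files && !simulate)
    stop("config must either set input: simulate or provide input_files")
  if (has_files) {
    missing <- config$input_files[!file.exists(unlist(config$input_files))]
    if (length(missing))
      stop("input file(s) not found: ", paste(unlist(missing),
                                              collapse = ", "))
  }
  invisible(config)
}

stageLog <- function(manifest, stage, ..., verbose) {
  info <- list(...)
  if (verbose)
    message(sprintf("[%s] %s", stage,
                    paste(names(info), unlist(info), sep = "=",
                          collapse = " ")))
  manifest$stages[[stage]] <- info
  manifest
}

#' Run the full discovery pipeline
#'
#' Executes simulate (or load) -> preprocess (filter, internal-standard
#' normalization, platform merge) -> stratified train/validation split ->
#' univariate screen on the training samples -> annotation -> nested-CV
#' ranking per model family -> feature-stepping validation -> permutation
#' null. Every stage writes its output as a tab-delimited table under
#' `outdir` and logs its input/output shapes; the returned manifest (also
#' written as `manifest.json`) records counts, seeds and output checksums,
#' which is sufficient to re-run any stage bit-identically.
#'
#' @param config configuration list (see [defaultRunConfig()]) or a YAML
#'   path.
#' @param outdir,seed optional overrides of the config values.
#' @param verbose print per-stage log lines.
#' @return the manifest list, invisibly; side effect: tables under `outdir`.
#' @export
runPipeline <- function(config = defaultRunConfig(), outdir = NULL,
                        seed = NULL, verbose = TRUE) {
  if (is.character(config)) config <- readRunConfig(config)
  if (!is.null(outdir)) config$outdir <- outdir
  if (!is.null(seed)) config$seed <- as.integer(seed)
  validateRunConfig(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, config = config, stages = list(),
                   files = character(0))
  t0 <- Sys.time()

  ## --- simulate or load ----------------------------------------------------
  if (identical(config$input, "simulate")) {
    cohort <- sampleCohort(do.call(cohortSpec, config$cohort),
                           seed = config$seed)
    effects <- defaultEffects(n = config$effects$n, cv = config$effects$cv)
    sets <- generateFeatureMatrix(cohort, defaultPlatformSpecs(), effects,
                                  generatorConfig(seed = config$seed))
    writeFeatureTables(sets, file.path(config$outdir, "simulated"))
    truth <- attr(sets, "ground_truth")
  } else {
    cohort <- read.delim(config$input_files$samples,
                         stringsAsFactors = FALSE)
    sets <- lapply(config$input_files$features, readFeatureTable,
                   sampleData = cohort)
    truth <- NULL
  }
  manifest <- stageLog(manifest, "input",
                       n_samples = nrow(cohort), n_platforms = length(sets),
                       n_features = sum(vapply(sets, nrow, 0L)),
                       verbose = verbose)

  ## --- preprocess ----------------------------------------------------------
  fcfg <- do.call(filterConfig, mergeConfig(
    list(min_median_abundance = 1000, mass_defect_intercept = 0.3,
         mass_defect_slope = 0.001, min_presence_fraction = 0.5),
    config$filter))
  filtered <- lapply(sets, filterFeatures, config = fcfg)
  report <- do.call(rbind, lapply(filtered, `[[`, "report"))
  merged <- mergePlatforms(lapply(filtered, `[[`, "matrix"))
  merged <- normalizeInternalStandards(merged)
  report_path <- file.path(config$outdir, "filter_report.tsv")
  write.table(report, report_path, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  writeFeatureTable(merged, file.path(config$outdir, "merged_normalized.tsv"))
  manifest <- stageLog(manifest, "preprocess",
                       n_in = sum(report$features_in),
                       n_surviving = sum(report$surviving),
                       verbose = verbose)

  ## --- split ---------------------------------------------------------------
  split <- stratifiedSplit(sampleData(merged),
                           train_fraction = config$split$train_fraction,
                           seed = config$seed)
  write.table(split, file.path(config$outdir, "split.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  tr_ids <- split$sample_id[split$partition == "train"]
  va_ids <- split$sample_id[split$partition == "validation"]
  train <- merged[, colnames(merged) %in% tr_ids]
  valid <- merged[, colnames(merged) %in% va_ids]
  manifest <- stageLog(manifest, "split", n_train = ncol(train),
                       n_validation = ncol(valid), verbose = verbose)

  ## --- univariate screen (training samples only) ---------------------------
  screen <- screenFeatures(train, alpha = config$screen$alpha,
                           min_peak_height = config$screen$min_peak_height)
  writeScreenTable(screen, file.path(config$outdir, "univariate_screen.tsv"))
  cnt <- attr(screen, "counts")
  train_model <- modelingSet(train, screen)
  valid_model <- valid[rownames(train_model), ]
  manifest <- stageLog(manifest, "screen",
                       n_tested = cnt[["n_tested"]],
                       n_significant = cnt[["n_significant"]],
                       n_qc_removed = cnt[["n_qc_removed"]],
                       n_modeled = cnt[["n_passed"]], verbose = verbose)

  ## --- annotation ----------------------------------------------------------
  if (!is.null(config$annotation$db_path) &&
      nzchar(config$annotation$db_path) &&
      file.exists(config$annotation$db_path)) {
    db <- readMetaboliteDB(config$annotation$db_path)
    fd <- featureData(train_model)
    fd$presence_fraction <- rowMeans(areas(train_model) > 0)
    hits <- annotateFeatures(fd, db,
                             tolerance_ppm = config$annotation$tolerance_ppm)
    write.table(hits, file.path(config$outdir, "annotations.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE,
                fileEncoding = "UTF-8")
    manifest <- stageLog(manifest, "annotate", n_hits = nrow(hits),
                         verbose = verbose)
  }

  ## --- nested CV, stepping, permutation per family -------------------------
  results <- list()
  for (fam in config$model$families) {
    spec <- modelSpec(fam, rfe_step = config$model$rfe_step,
                      inner_folds = config$model$inner_folds)
    cv <- nestedCvRank(train_model, spec = spec,
                       n_resamples = config$model$n_resamples,
                       outer_fraction = config$model$outer_fraction,
                       seed = config$seed)
    write.table(cv$resamples,
                file.path(config$outdir, paste0("resamples_", fam, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(cv$vip_index,
                file.path(config$outdir, paste0("vip_index_", fam, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    stepping <- featureSteppingEval(train_model, valid_X = valid_model,
                                    vip_index = cv, spec = spec,
                                    seed = config$seed)
    write.table(stepping,
                file.path(config$outdir, paste0("stepping_", fam, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    results[[fam]] <- list(cv = cv, stepping = stepping)
    manifest <- stageLog(manifest, paste0("model_", fam),
                         mean_test_auc = round(cv$summary["mean", "auc"], 4),
                         mean_test_accuracy =
                           round(cv$summary["mean", "accuracy"], 4),
                         best_stepping_auc = round(max(stepping$auc), 4),
                         verbose = verbose)
    if (isTRUE(config$permutation$enabled)) {
      null <- permutationNull(train_model, spec = spec,
                              n_resamples = config$permutation$n_resamples,
                              outer_fraction = config$model$outer_fraction,
                              seed = config$seed + 1L)
      write.table(null$resamples,
                  file.path(config$outdir,
                            paste0("permutation_null_", fam, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      results[[fam]]$null <- null
      manifest <- stageLog(manifest, paste0("permutation_", fam),
                           null_mean_auc = round(null$mean_auc, 4),
                           null_lo = round(null$interval[[1]], 4),
                           null_hi = round(null$interval[[2]], 4),
                           verbose = verbose)
    }
  }

  manifest$elapsed_seconds <- as.numeric(difftime(Sys.time(), t0, "secs"))
  files <- list.files(config$outdir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(config$outdir, "manifest.json"))
  manifest$files <- as.list(tools::md5sum(files))
  if (!is.null(truth)) manifest$n_planted <- nrow(truth)
  jsonlite::write_json(manifest[c("seed", "stages", "elapsed_seconds",
                                  "files")],
                       file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  manifest$results <- results
  invisible(manifest)
}
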