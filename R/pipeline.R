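#' @include AllClasses.R synthetic.R preprocess.R augment.R train.R
NULL

#' Demo run configuration
#'
#' A desk-scale end-to-end configuration: 16 synthetic 64x64 images (12
#' train / 4 test), preprocessing on, augmentation to 24 training images, a
#' tiny depth-3 / 8-channel network and 10 epochs of 20 steps. Finishes in
#' a few minutes on one CPU. All stage seeds derive from `seed`.
#'
#' @param outRoot results root directory.
#' @param runId unique run identifier (one directory per run).
#' @param seed master seed.
#' @return nested run-configuration list accepted by [runPipeline()].
#' @export
demoRunConfig <- function(outRoot, runId = "demo", seed = 1L) {
  seed <- as.integer(seed) %% 2000000000L
  list(
    run_id = runId,
    out_root = outRoot,
    seed = seed,
    n_train = 12L,
    n_test = 4L,
    simulate = list(imageSize = c(64L, 64L), nTrees = 2L, branchDepth = 3L,
                    rootWidthPx = 2, widthDecay = 0.7, branchAngleDeg = 30,
                    vesselContrast = 0.35, illuminationGradient = 0.2,
                    noiseSigma = 0.03, seed = seed),
    preprocess = list(enabled = TRUE),
    augment = list(targetCount = 24L, seed = seed + 1L),
    model = list(depth = 3L, baseChannels = 8L, fusionChannels = 16L),
    train = list(epochs = 10L, stepsPerEpoch = 20L, batchSize = 2L,
                 learningRate = 1e-3, loss = "bce", threshold = 0.5,
                 seed = seed + 3L))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full pipeline
#'
#' Executes simulate -> preprocess -> augment -> train -> evaluate from one
#' nested configuration (see [demoRunConfig()] for the schema; each block
#' feeds the corresponding config constructor). Results — data, processed
#' and augmented manifests, checkpoint, metrics JSON/CSV, and a provenance
#' snapshot of the full configuration — are written under
#' `out_root/run_id`. An existing run directory is refused, never
#' overwritten; on a stage failure, outputs of completed stages are
#' retained.
#'
#' The metrics report depends only on the configuration and seed, so two
#' runs with the same configuration (under different `run_id`s) produce
#' identical `metrics.json` files on a single-threaded CPU.
#'
#' @param config nested run-configuration list.
#' @param verbose print stage progress.
#' @return the run directory path, invisibly; its `metrics.json` holds the
#'   aggregate and per-image results.
#' @export
runPipeline <- function(config, verbose = FALSE) {
  run_dir <- file.path(config$out_root, config$run_id)
  if (dir.exists(run_dir))
    stop("run directory already exists (refusing to overwrite): ", run_dir)
  dir.create(run_dir, recursive = TRUE)
  say <- function(...) if (verbose) message(...)

  seed <- as.integer(config$seed %||% 1L)
  sim_cfg <- .stage("config", do.call(vesselSimConfig, config$simulate))
  pre_list <- config$preprocess %||% list()
  pre_enabled <- !identical(pre_list$enabled, FALSE)
  pre_list$enabled <- NULL
  pre_cfg <- .stage("config", do.call(preprocessConfig, c(pre_list, list(enabled = pre_enabled))))
  mdl_cfg <- .stage("config", do.call(modelConfig, config$model %||% list()))
  trn_cfg <- .stage("config", do.call(trainConfig, config$train %||% list()))

  n_train <- as.integer(config$n_train)
  n_test <- as.integer(config$n_test)

  say("simulate: ", n_train, " train + ", n_test, " test images")
  data_man <- .stage("simulate", generateDataset(
    sim_cfg, n_train + n_test, file.path(run_dir, "data"),
    split = rep(c("train", "test"), c(n_train, n_test))))

  say("preprocess (enabled = ", pre_enabled, ")")
  pre_man <- .stage("preprocess",
    preprocessDataset(data_man, pre_cfg, file.path(run_dir, "preprocessed")))

  train_entries <- pre_man@entries[pre_man@entries$split == "train", ]
  test_entries <- pre_man@entries[pre_man@entries$split == "test", ]
  train_man <- new("DatasetManifest", entries = train_entries, root = pre_man@root)
  test_man <- new("DatasetManifest", entries = test_entries, root = pre_man@root)

  aug_list <- config$augment %||% list()
  if (is.null(aug_list$seed)) aug_list$seed <- seed + 1L
  aug_cfg <- .stage("config", do.call(augmentConfig, aug_list))
  say("augment: ", nrow(train_entries), " -> ", aug_cfg@targetCount, " images")
  aug_man <- .stage("augment",
    augmentDataset(train_man, aug_cfg, file.path(run_dir, "augmented")))

  say("train: ", trn_cfg@epochs, " epochs x ", trn_cfg@stepsPerEpoch, " steps")
  model <- .stage("train", buildModel(mdl_cfg, seed = seed + 2L))
  fit <- .stage("train", trainModel(model, aug_man, trn_cfg, verbose = verbose))
  .stage("train", saveCheckpoint(fit$model, file.path(run_dir, "checkpoint.rds")))
  utils::write.csv(fit$history, file.path(run_dir, "history.csv"),
                   row.names = FALSE)

  say("evaluate on ", nrow(test_entries), " test images")
  ev <- .stage("evaluate",
    evaluateModel(fit$model, test_man, threshold = trn_cfg@threshold))
  rep <- ev$report
  metrics <- list(
    aggregate = list(mode = "micro", accuracy = rep@accuracy,
                     precision = rep@precision, recall = rep@recall,
                     f1 = rep@f1, iou = rep@iou),
    per_image = ev$table)
  jsonlite::write_json(metrics, file.path(run_dir, "metrics.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  utils::write.csv(ev$table, file.path(run_dir, "metrics.csv"),
                   row.names = FALSE)

  prov <- list(run_id = config$run_id, seed = seed, config = config,
               package_version = as.character(utils::packageVersion("vesselseg")),
               final_train_loss = fit$history$loss[nrow(fit$history)])
  jsonlite::write_json(prov, file.path(run_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say(sprintf("done: test F1 %.3f, IoU %.3f", rep@f1, rep@iou))
  invisible(run_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
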