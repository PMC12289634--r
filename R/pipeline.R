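#' End-to-end pipeline
#'
#' Orchestrates generate -> split -> (augment) -> train -> evaluate (with
#' post-processing) and the augmentation ablation experiment. Every run is
#' a pure function of its configuration and seeds.
#'
#' @name pipeline
NULL

#' Experiment configuration
#'
#' @param n_samples synthetic dataset size.
#' @param image_size (height, width) of generated scenes.
#' @param obstruction_mix obstruction strata cycled over samples.
#' @param data_seed,split_seed seeds for generation and splitting.
#' @param augment logical: double the training set by augmentation?
#' @param augment_cfg an [augment_config()].
#' @param augment_seed seed for the augmentation copies.
#' @param fractions a [split_fractions()].
#' @param model_cfg a [model_config()].
#' @param train_cfg a [train_config()] (holds weight-init and batch seeds).
#' @param post_cfg a [post_config()].
#' @param test_shift NULL, or a list of [sample_scene_params()] overrides
#'   (e.g. `angle_range`, `illum_range`) used to generate a
#'   distribution-shifted test set in place of the in-distribution one.
#' @param out_dir optional directory to persist artifacts (checkpoint,
#'   metrics CSV, run manifest JSON).
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(n_samples = 200L, image_size = c(64L, 64L),
                              obstruction_mix = c(0, 0.5, 0.9),
                              data_seed = 1L, split_seed = 2L,
                              augment = TRUE,
                              augment_cfg = augment_config(),
                              augment_seed = 3L,
                              fractions = split_fractions(),
                              model_cfg = micro_model_config(),
                              train_cfg = train_config(learning_rate = 1e-3,
                                                       max_epochs = 30L),
                              post_cfg = post_config(),
                              test_shift = NULL,
                              out_dir = NULL) {
  structure(list(n_samples = as.integer(n_samples),
                 image_size = as.integer(image_size),
                 obstruction_mix = obstruction_mix,
                 data_seed = as.integer(data_seed),
                 split_seed = as.integer(split_seed),
                 augment = isTRUE(augment), augment_cfg = augment_cfg,
                 augment_seed = as.integer(augment_seed),
                 fractions = fractions, model_cfg = model_cfg,
                 train_cfg = train_cfg, post_cfg = post_cfg,
                 test_shift = test_shift, out_dir = out_dir),
            class = "experiment_config")
}

#' Run one end-to-end experiment
#'
#' Generates a synthetic dataset, splits it, optionally doubles the
#' training set by augmentation, trains the model, and evaluates on the
#' held-out test set with post-processing applied to predictions.
#'
#' @param config an [experiment_config()].
#' @param verbose print progress?
#' @return list with `model`, `log` (training curve), `metrics`
#'   (test-set [evaluate_model()] report), `timing`
#'   ([time_inference()] on a test image), `split`, and `test_ids`.
#' @export
run_experiment <- function(config = experiment_config(), verbose = FALSE) {
  samples <- generate_dataset(config$n_samples, config$data_seed,
                              config$obstruction_mix, config$image_size)
  split <- split_dataset(seq_len(config$n_samples), config$fractions,
                         config$split_seed)
  train_samples <- samples[split$train]
  if (config$augment) {
    cfg <- config$augment_cfg
    if (is.null(cfg$output_size)) cfg$output_size <- config$image_size
    train_samples <- augment_dataset(train_samples, cfg, config$augment_seed)
  }
  val_samples <- samples[split$val]
  pool <- c(train_samples, val_samples)
  idx <- list(train = seq_along(train_samples),
              val = length(train_samples) + seq_along(val_samples))

  model0 <- init_model(config$model_cfg, config$train_cfg$seed)
  fitres <- fit(model0, idx, pool, config$train_cfg, verbose = verbose)

  test_samples <- if (is.null(config$test_shift)) samples[split$test] else {
    do.call(generate_dataset,
            c(list(n = length(split$test),
                   seed = derive_seed(config$data_seed, 5417L),
                   obstruction_mix = config$obstruction_mix,
                   image_size = config$image_size),
              config$test_shift))
  }
  metrics <- evaluate_model(fitres$model, test_samples, postprocess_on = TRUE,
                            config = config$post_cfg)
  timing <- time_inference(fitres$model, list(test_samples[[1]]$image),
                           n_warmup = 1, n_timed = 3)
  res <- list(model = fitres$model, log = fitres$log, metrics = metrics,
              timing = timing, split = split, test_ids = split$test)
  if (!is.null(config$out_dir)) persist_run(res, config)
  res
}

persist_run <- function(res, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  save_checkpoint(res$model, file.path(config$out_dir, "checkpoint.rds"))
  write.csv(res$log, file.path(config$out_dir, "loss_log.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(res$metrics),
            file.path(config$out_dir, "metrics.csv"), row.names = FALSE)
  manifest <- list(
    n_samples = config$n_samples, image_size = config$image_size,
    obstruction_mix = config$obstruction_mix,
    seeds = list(data = config$data_seed, split = config$split_seed,
                 augment = config$augment_seed, train = config$train_cfg$seed),
    augment = config$augment,
    best_epoch = attr(res$log, "best_epoch"),
    stopped_epoch = attr(res$log, "stopped_epoch"),
    test_ids = res$test_ids,
    timing_ms = res$timing$duration_ms)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA),
             file.path(config$out_dir, "run_manifest.json"))
  invisible(NULL)
}

#' Augmentation ablation
#'
#' Runs the experiment twice with identical data, split and seeds,
#' differing only in the augmentation flag, and reports paired per-class
#' metrics with the relative improvement `(with - without) / without`.
#'
#' @param config an [experiment_config()]; its `augment` flag is ignored.
#' @param verbose print progress?
#' @return list with `with_aug`, `without_aug` (run results) and
#'   `improvement`, a data frame of relative metric changes per class.
#' @export
ablation_augmentation <- function(config = experiment_config(),
                                  verbose = FALSE) {
  cfg_on <- config; cfg_on$augment <- TRUE
  cfg_off <- config; cfg_off$augment <- FALSE
  if (!is.null(config$out_dir)) {
    cfg_on$out_dir <- file.path(config$out_dir, "with_aug")
    cfg_off$out_dir <- file.path(config$out_dir, "without_aug")
  }
  on <- run_experiment(cfg_on, verbose = verbose)
  off <- run_experiment(cfg_off, verbose = verbose)
  stopifnot(identical(on$test_ids, off$test_ids))
  mw <- as.data.frame(on$metrics); mo <- as.data.frame(off$metrics)
  metric_cols <- setdiff(names(mw), "class")
  imp <- mw
  imp[metric_cols] <- (mw[metric_cols] - mo[metric_cols]) / mo[metric_cols]
  list(with_aug = on, without_aug = off, improvement = imp)
}
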