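# End-to-end pipeline: phantoms (or a user manifest) -> median filter
# -> U-Net segmentation -> ROI extraction -> SqueezeNet features (with
# optional AOA hyperparameter tuning) -> DBN classification -> per-class
# evaluation reports on the train and test splits.  Every stochastic
# stage is seeded from the global seed via derive_seed(), so a run is
# reproducible end to end.

pipeline_defaults <- function() {
  list(
    seed = 1L,
    out_dir = NULL,  # filled with a tempdir at validation
    dataset = list(source = "synthetic", manifest = NULL,
                   n_per_class = 30L, size = 32L, noise_rate = 0.05),
    preprocessing = list(mf_window = 3L),
    split = list(ratio = "60:40", stratify = TRUE),
    unet = list(depth = 2L, base = 8L, epochs = 40L, lr = 5e-3,
                batch = 8L, threshold = 0.5, pos_weight = 3),
    roi = list(mode = "mask"),
    squeezenet = list(stem = 8L, fire_n = c(4L, 4L, 4L, 4L, 8L, 8L, 8L, 8L),
                      head_width = 32L,
                      augment = TRUE,
                      min_train_accuracy = 0.85,
                      default_hyper = list(lr = 3e-3, batch = 8L, epochs = 8L,
                                           weight_decay = 1e-5)),
    aoa = list(enabled = TRUE, N = 5L, tmax = 5L, C1 = 2, C2 = 6, C3 = 2,
               p_threshold = 0.5, val_fraction = 0.2, max_epochs = 8L),
    dbn = list(hidden = c(24L, 12L), pretrain_epochs = 10L, cd_lr = 0.02,
               finetune_epochs = 300L, finetune_lr = 0.3, batch = 16L)
  )
}

merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults))
      stop("unknown config key '", full, "'", call. = FALSE)
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]])) &&
        key != "default_hyper") {
      if (!is.list(user[[key]]))
        stop("config key '", full, "' must be a mapping", call. = FALSE)
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Validate (and default-fill) a pipeline configuration
#'
#' @param config a YAML file path or a nested list; unknown keys are
#'   rejected with the offending key named.
#' @return A fully defaulted, range-checked `run_config` list.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("no such config file: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  cfg <- merge_config(pipeline_defaults(), config)
  if (is.null(cfg$out_dir)) cfg$out_dir <- tempfile("mammocad_run_")
  w <- cfg$preprocessing$mf_window
  if (w %% 2L == 0L || w < 3L)
    stop("preprocessing.mf_window must be an odd integer >= 3", call. = FALSE)
  if (cfg$aoa$N < 2L) stop("aoa.N must be >= 2", call. = FALSE)
  if (cfg$aoa$tmax < 1L) stop("aoa.tmax must be >= 1", call. = FALSE)
  if (!cfg$dataset$source %in% c("synthetic", "manifest"))
    stop("dataset.source must be 'synthetic' or 'manifest'", call. = FALSE)
  if (cfg$dataset$source == "manifest") {
    if (is.null(cfg$dataset$manifest) || !file.exists(cfg$dataset$manifest))
      stop("dataset.manifest must name an existing CSV when source = 'manifest'",
           call. = FALSE)
  } else {
    if (cfg$dataset$n_per_class < 1L)
      stop("dataset.n_per_class must be >= 1", call. = FALSE)
    if (cfg$dataset$size %% 2L^cfg$unet$depth != 0L)
      stop("dataset.size must be divisible by 2^unet.depth", call. = FALSE)
    if (cfg$dataset$size %% 8L != 0L)
      stop("dataset.size must be divisible by 8 for the feature extractor",
           call. = FALSE)
  }
  if (!cfg$roi$mode %in% c("mask", "crop"))
    stop("roi.mode must be 'mask' or 'crop'", call. = FALSE)
  class(cfg) <- "run_config"
  cfg
}

#' Run the full classification pipeline
#'
#' Executes, in order: dataset generation (or manifest loading),
#' median-filter preprocessing, train/test splitting, U-Net training and
#' segmentation, ROI extraction, optional AOA hyperparameter tuning,
#' SqueezeNet training and feature extraction, DBN pretraining +
#' finetuning, and evaluation on both splits.  A stage failure aborts
#' with the stage name after persisting the partial record to
#' `out_dir/partial_record.rds`.
#'
#' @param config a `run_config`, nested list, or YAML path (passed to
#'   [validate_config()]).
#' @return A `run_record`: config, per-stage timings, AOA history and
#'   best hyperparameters, train/test `eval_report`s, and artifact
#'   paths.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  record <- list(config = cfg, timings = list())
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      saveRDS(record, file.path(cfg$out_dir, "partial_record.rds"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    record$timings[[name]] <<- proc.time()[["elapsed"]] - t0
    out
  }

  manifest <- stage("dataset", {
    if (cfg$dataset$source == "synthetic") {
      generate_dataset(cfg$dataset$n_per_class, cfg$dataset$size,
                       cfg$dataset$noise_rate,
                       seed = derive_seed(cfg$seed, "dataset"),
                       out_dir = file.path(cfg$out_dir, "data"))
    } else read_manifest(cfg$dataset$manifest)
  })

  sp <- stage("split", split_dataset(manifest, cfg$split$ratio,
                                     seed = derive_seed(cfg$seed, "split"),
                                     stratify = cfg$split$stratify))
  phan_tr <- stage("load", load_phantoms(sp$train))
  phan_te <- load_phantoms(sp$test)

  filt <- function(ps) lapply(ps, function(p) {
    p$image <- median_filter(normalize_intensity(p$image), cfg$preprocessing$mf_window)
    p
  })
  phan_tr <- stage("preprocess", filt(phan_tr))
  phan_te <- filt(phan_te)

  size <- nrow(phan_tr[[1]]$image)
  unet <- stage("segmentation", {
    m <- build_unet(cfg$unet$depth, cfg$unet$base, in_size = size,
                    seed = derive_seed(cfg$seed, "unet-init"))
    train_segmenter(m, phan_tr, epochs = cfg$unet$epochs, lr = cfg$unet$lr,
                    batch = cfg$unet$batch,
                    seed = derive_seed(cfg$seed, "unet-train"),
                    pos_weight = cfg$unet$pos_weight)
  })

  rois <- function(ps) lapply(ps, function(p) {
    mask <- segment(unet, p$image, threshold = cfg$unet$threshold)
    apply_mask(p$image, mask, mode = cfg$roi$mode)
  })
  roi_tr <- stage("roi", rois(phan_tr))
  roi_te <- rois(phan_te)
  lab_tr <- vapply(phan_tr, `[[`, character(1), "label")
  lab_te <- vapply(phan_te, `[[`, character(1), "label")
  saveRDS(list(images = roi_tr, labels = lab_tr),
          file.path(cfg$out_dir, "train_rois.rds"))

  sq_spec <- squeezenet_spec(fire_n = cfg$squeezenet$fire_n,
                             stem = cfg$squeezenet$stem,
                             head_width = cfg$squeezenet$head_width,
                             in_size = size)
  hyper <- cfg$squeezenet$default_hyper
  if (isTRUE(cfg$aoa$enabled)) {
    tuned <- stage("tuning", tune_squeezenet(
      roi_tr, lab_tr, spec = sq_spec,
      space = default_search_space(cfg$aoa$max_epochs),
      config = aoa_config(N = cfg$aoa$N, tmax = cfg$aoa$tmax, C1 = cfg$aoa$C1,
                          C2 = cfg$aoa$C2, C3 = cfg$aoa$C3,
                          p_threshold = cfg$aoa$p_threshold, mode = "maximize",
                          seed = derive_seed(cfg$seed, "aoa")),
      val_fraction = cfg$aoa$val_fraction,
      seed = derive_seed(cfg$seed, "tune"),
      default_hyper = cfg$squeezenet$default_hyper))
    record$aoa_history <- tuned$result$history
    record$best_hyper <- tuned$best_hyper
    record$tuned_val_precision <- tuned$val_precision
    record$default_val_precision <- tuned$default_precision
    hyper <- tuned$best_hyper
  }

  sqnet <- stage("features", {
    # under-convergence guard: the phantom classes are separable, so a
    # final model that cannot fit its own training set has fallen into a
    # poor optimization basin (partial or total output collapse);
    # retrain with the learning rate halved, up to 3 times
    h <- hyper
    for (attempt in 1:4) {
      m <- build_squeezenet(sq_spec, n_classes = length(unique(lab_tr)),
                            seed = derive_seed(cfg$seed, "squeezenet-init"))
      m <- train_squeezenet(m, roi_tr, lab_tr, hyper = h,
                            seed = derive_seed(cfg$seed, "squeezenet-train"),
                            augment = cfg$squeezenet$augment)
      acc <- mean(predict(m, roi_tr) == lab_tr)
      if (acc >= cfg$squeezenet$min_train_accuracy || attempt == 4L) break
      h$lr <- h$lr / 2
      record$collapse_retries <- (record$collapse_retries %||% 0L) + 1L
    }
    m
  })
  feat_tr <- extract_features(sqnet, roi_tr)
  feat_te <- extract_features(sqnet, roi_te)
  # min-max normalize features to [0, 1] on training statistics, so the
  # DBN's sigmoid visible units see a well-scaled input
  fmin <- apply(feat_tr, 2L, min)
  frng <- pmax(apply(feat_tr, 2L, max) - fmin, 1e-8)
  scale01 <- function(f) clamp(sweep(sweep(f, 2L, fmin), 2L, frng, "/"), 0, 1)
  feat_tr <- scale01(feat_tr); feat_te <- scale01(feat_te)
  utils::write.csv(data.frame(label = lab_tr, feat_tr),
                   file.path(cfg$out_dir, "features_train.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(label = lab_te, feat_te),
                   file.path(cfg$out_dir, "features_test.csv"),
                   row.names = FALSE)

  dbn <- stage("classification", {
    m <- build_dbn(ncol(feat_tr), hidden = cfg$dbn$hidden,
                   n_classes = length(unique(lab_tr)), lr = cfg$dbn$cd_lr,
                   seed = derive_seed(cfg$seed, "dbn-init"))
    m <- pretrain_stack(m, feat_tr, epochs = cfg$dbn$pretrain_epochs,
                        batch = cfg$dbn$batch,
                        seed = derive_seed(cfg$seed, "dbn-pretrain"))
    m <- finetune(m, feat_tr, lab_tr, epochs = cfg$dbn$finetune_epochs,
                  lr = cfg$dbn$finetune_lr, batch = cfg$dbn$batch,
                  seed = derive_seed(cfg$seed, "dbn-finetune"))
    # convergence guard mirroring the feature stage: mean-squared-error
    # finetuning on sigmoid stacks can plateau long before it converges,
    # so extend training (deterministically) while the model has not yet
    # fit its separable training set
    for (ext in 1:3) {
      if (mean(predict(m, feat_tr) == lab_tr) >=
          cfg$squeezenet$min_train_accuracy) break
      m <- finetune(m, feat_tr, lab_tr, epochs = cfg$dbn$finetune_epochs,
                    lr = cfg$dbn$finetune_lr, batch = cfg$dbn$batch,
                    seed = derive_seed(cfg$seed, paste0("dbn-finetune-ext", ext)))
      record$dbn_extensions <- (record$dbn_extensions %||% 0L) + 1L
    }
    m
  })

  ev <- stage("evaluation", {
    classes <- sort(unique(c(lab_tr, lab_te)))
    pred_tr <- predict(dbn, feat_tr)
    pred_te <- predict(dbn, feat_te)
    cm_tr <- confusion(lab_tr, pred_tr, classes)
    cm_te <- confusion(lab_te, pred_te, classes)
    rep_tr <- per_class_metrics(cm_tr)
    rep_te <- per_class_metrics(cm_te)
    write_report(rep_tr, file.path(cfg$out_dir, "report_train.csv"))
    write_report(rep_te, file.path(cfg$out_dir, "report_test.csv"))
    list(confusion_train = cm_tr, confusion_test = cm_te,
         report_train = rep_tr, report_test = rep_te,
         accuracy_train = mean(pred_tr == lab_tr),
         accuracy_test = mean(pred_te == lab_te))
  })
  record <- c(record, ev)
  record$models <- list(unet = unet, squeezenet = sqnet, dbn = dbn)
  record$artifacts <- list(
    out_dir = cfg$out_dir,
    report_train = file.path(cfg$out_dir, "report_train.csv"),
    report_test = file.path(cfg$out_dir, "report_test.csv"))
  class(record) <- "run_record"
  record
}

#' @export
print.run_record <- function(x, ...) {
  cat("Pipeline run (seed", x$config$seed, ")\n")
  cat(sprintf("  accuracy: train %.3f, test %.3f\n",
              x$accuracy_train, x$accuracy_test))
  if (!is.null(x$best_hyper))
    cat("  tuned hyperparameters:",
        paste(names(x$best_hyper), signif(unlist(x$best_hyper), 4),
              sep = " = ", collapse = ", "), "\n")
  cat("  stage timings (s):",
      paste(names(x$timings), sprintf("%.1f", unlist(x$timings)),
            sep = " ", collapse = ", "), "\n")
  cat("\nTest split report:\n")
  print(x$report_test)
  invisible(x)
}
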