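# Hyperparameter tuning of the SqueezeNet trainer with the Archimedes
# optimizer.  The fitness of a candidate hyperparameter vector is the
# macro-averaged precision on a stratified validation split carved from
# the training set: train a fresh model under the candidate settings,
# predict the validation images, score.

#' Default hyperparameter search space for the SqueezeNet trainer
#'
#' Learning rate and weight decay on a log scale, batch size and epoch
#' count as integers — the conventional trainer knobs.
#'
#' @param max_epochs upper bound on the epochs dimension.
#' @return A [search_space()].
#' @export
default_search_space <- function(max_epochs = 6L) {
  search_space(list(
    list(name = "lr", lower = 3e-4, upper = 5e-3, scale = "log", type = "real"),
    list(name = "batch", lower = 4, upper = 16, scale = "linear", type = "integer"),
    list(name = "epochs", lower = 2, upper = max_epochs, scale = "linear",
         type = "integer"),
    list(name = "weight_decay", lower = 1e-6, upper = 1e-3, scale = "log",
         type = "real")))
}

#' Tune SqueezeNet training hyperparameters with AOA
#'
#' @param images list of (ROI) images.
#' @param labels labels, one per image.
#' @param spec a [squeezenet_spec()].
#' @param space a [search_space()]; defaults to [default_search_space()].
#' @param config an [aoa_config()] (mode is forced to `"maximize"`).
#' @param val_fraction fraction of the data held out (stratified) as the
#'   validation split scored by the fitness.
#' @param seed integer seed controlling the split and the per-candidate
#'   training runs.
#' @param default_hyper the default trainer settings; the search is
#'   warm-started from them (they seed one object of the initial
#'   population) and their validation precision is reported for
#'   ablation comparisons.
#' @return List with `result` (the `aoa_result`), `best_hyper` (decoded
#'   list), `val_precision` (best validation macro-precision found), and
#'   `default_precision` — the validation precision of a model trained
#'   with `default_hyper`.
#' @export
tune_squeezenet <- function(images, labels, spec = squeezenet_spec(),
                            space = default_search_space(),
                            config = aoa_config(N = 5L, tmax = 5L),
                            val_fraction = 0.2, seed = 1L,
                            default_hyper = list(lr = 3e-3, batch = 8L,
                                                 epochs = 6L,
                                                 weight_decay = 1e-5)) {
  labels <- as.character(labels)
  df <- data.frame(idx = seq_along(images), label = labels,
                   stringsAsFactors = FALSE)
  sp <- split_dataset(df, ratio = 1 - val_fraction,
                      seed = derive_seed(seed, "tune-split"))
  tr <- sp$train$idx; va <- sp$test$idx
  eval_hyper <- function(h) {
    model <- build_squeezenet(spec, n_classes = length(unique(labels)),
                              seed = derive_seed(seed, "tune-model"))
    model <- train_squeezenet(model, images[tr], labels[tr], hyper = h,
                              seed = derive_seed(seed, "tune-train"))
    precision_fitness(labels[va], predict(model, images[va]))
  }
  config$mode <- "maximize"
  result <- aoa_optimize(eval_hyper, space, config,
                         x0 = encode_position(default_hyper, space))
  list(result = result, best_hyper = result$best,
       default_precision = eval_hyper(default_hyper),
       val_precision = result$best_fitness)
}
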