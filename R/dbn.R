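# Deep belief network classifier.
#
# A stack of restricted Boltzmann machines is pretrained greedily with
# one-step contrastive divergence (CD-1): hidden states are Bernoulli
# samples of P(H1|V1), the visible reconstruction is a sample of
# P(V2|H1), and the weight update is the difference of the data and
# reconstruction outer products scaled by the learning rate.  Layer k's
# training input is layer k-1's hidden probabilities (mean field; samples
# are used only inside CD-1).  The unrolled stack plus a linear output
# layer is then finetuned by backpropagation against the mean squared
# error between the network output and one-hot targets.  Inference is
# sampling-free and deterministic.

#' Create one RBM layer
#'
#' @param n_vis,n_hid visible and hidden unit counts.
#' @param lr contrastive-divergence learning rate.
#' @param seed integer seed for the small-normal weight initialization.
#' @return An `rbm_layer`: list with weight matrix `W` (visible x
#'   hidden), visible bias `a`, hidden bias `b`, and `lr`.
#' @export
rbm_layer <- function(n_vis, n_hid, lr = 0.1, seed = 1L) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  structure(list(W = matrix(stats::rnorm(n_vis * n_hid, sd = 0.1), n_vis, n_hid),
                 a = numeric(n_vis), b = numeric(n_hid), lr = lr),
            class = "rbm_layer")
}

as_row_matrix <- function(v, d, what) {
  if (is.null(dim(v))) v <- matrix(v, nrow = 1L)
  if (ncol(v) != d)
    stop(what, " has ", ncol(v), " columns but the layer expects ", d,
         call. = FALSE)
  v
}

#' Hidden-unit activation probabilities
#'
#' `sigma(W' v + b)` per hidden unit: the probability that each hidden
#' neuron turns on given the visible vector.
#'
#' @param layer an `rbm_layer`.
#' @param v visible vector, or a matrix with one sample per row.
#' @return Probability vector/matrix with values in (0, 1).
#' @export
hidden_prob <- function(layer, v) {
  v <- as_row_matrix(v, nrow(layer$W), "visible input")
  p <- sigmoid(v %*% layer$W + rep(layer$b, each = nrow(v)))
  if (nrow(p) == 1L) as.numeric(p) else p
}

#' Visible-unit activation probabilities
#'
#' `sigma(W h + a)` per visible unit.
#'
#' @param layer an `rbm_layer`.
#' @param h hidden vector, or a matrix with one sample per row.
#' @return Probability vector/matrix with values in (0, 1).
#' @export
visible_prob <- function(layer, h) {
  h <- as_row_matrix(h, ncol(layer$W), "hidden input")
  p <- sigmoid(h %*% t(layer$W) + rep(layer$a, each = nrow(h)))
  if (nrow(p) == 1L) as.numeric(p) else p
}

#' One contrastive-divergence (CD-1) update
#'
#' Samples `H1 ~ P(H1|V1)` and `V2 ~ P(V2|H1)`, takes `H2` as the
#' probabilities `P(H2|V2)`, and applies the batch-averaged updates
#' `W <- W + lr (H1'V1 - H2'V2)`, `a <- a + lr <V1 - V2>`,
#' `b <- b + lr <H1 - H2>`.  Draws come from the current RNG stream, so
#' a fixed seed gives identical updates.
#'
#' @param layer an `rbm_layer`.
#' @param v1 visible batch: matrix with one sample per row (values in
#'   `[0, 1]`).
#' @return List with the updated `layer` and the mean squared `V1 - V2`
#'   reconstruction `error`.
#' @export
cd1_step <- function(layer, v1) {
  v1 <- as_row_matrix(v1, nrow(layer$W), "visible batch")
  m <- nrow(v1)
  if (m == 0L) stop("empty batch", call. = FALSE)
  h1p <- sigmoid(v1 %*% layer$W + rep(layer$b, each = m))
  h1 <- (matrix(stats::runif(length(h1p)), m) < h1p) + 0
  v2p <- sigmoid(h1 %*% t(layer$W) + rep(layer$a, each = m))
  v2 <- (matrix(stats::runif(length(v2p)), m) < v2p) + 0
  h2 <- sigmoid(v2 %*% layer$W + rep(layer$b, each = m))
  layer$W <- layer$W + layer$lr * (crossprod(v1, h1) - crossprod(v2, h2)) / m
  layer$a <- layer$a + layer$lr * colMeans(v1 - v2)
  layer$b <- layer$b + layer$lr * colMeans(h1 - h2)
  list(layer = layer, error = mean((v1 - v2)^2))
}

#' Build a DBN classifier
#'
#' @param n_vis input feature dimension.
#' @param hidden hidden layer widths of the RBM stack.
#' @param n_classes number of classes (>= 2).
#' @param lr contrastive-divergence learning rate for every layer.
#' @param seed integer seed.
#' @return An object of class `dbn`.
#' @export
build_dbn <- function(n_vis, hidden = c(64L, 32L), n_classes = 3L,
                      lr = 0.1, seed = 1L) {
  if (n_classes < 2L) stop("n_classes must be >= 2", call. = FALSE)
  dims <- c(n_vis, hidden)
  stack <- lapply(seq_along(hidden), function(k)
    rbm_layer(dims[k], dims[k + 1L], lr = lr, seed = derive_seed(seed, paste0("rbm", k))))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(derive_seed(seed, "dbn-out"))
  out <- list(W = matrix(stats::rnorm(hidden[length(hidden)] * n_classes, sd = 0.1),
                         hidden[length(hidden)], n_classes),
              b = numeric(n_classes))
  structure(list(rbm_stack = stack, output_layer = out,
                 n_classes = as.integer(n_classes), classes = NULL,
                 trace = list()),
            class = "dbn")
}

#' @export
print.dbn <- function(x, ...) {
  dims <- c(nrow(x$rbm_stack[[1]]$W),
            vapply(x$rbm_stack, function(l) ncol(l$W), integer(1)))
  cat(sprintf("DBN: %s -> %d classes%s\n",
              paste(dims, collapse = " -> "), x$n_classes,
              if (length(x$trace)) " (trained)" else ""))
  invisible(x)
}

#' Greedy layer-wise RBM pretraining
#'
#' Trains each RBM in turn with CD-1; the training input of layer k is
#' the hidden probabilities of the trained layer k-1.
#'
#' @param model a `dbn`.
#' @param data matrix of training samples (rows) with values in
#'   `[0, 1]`, columns matching the first visible layer.
#' @param epochs pretraining epochs per layer.
#' @param batch mini-batch size.
#' @param seed integer seed.
#' @return The model, with `trace$pretrain` holding a per-layer matrix
#'   of per-epoch mean reconstruction errors.
#' @export
pretrain_stack <- function(model, data, epochs = 20L, batch = 16L, seed = 1L) {
  stopifnot(inherits(model, "dbn"))
  data <- as_row_matrix(data, nrow(model$rbm_stack[[1]]$W), "training data")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  x <- data
  traces <- list()
  for (k in seq_along(model$rbm_stack)) {
    layer <- model$rbm_stack[[k]]
    errs <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(nrow(x))
      tot <- 0; nb <- 0L
      for (b0 in seq(1L, nrow(x), by = batch)) {
        take <- ord[b0:min(b0 + batch - 1L, nrow(x))]
        stp <- cd1_step(layer, x[take, , drop = FALSE])
        layer <- stp$layer
        tot <- tot + stp$error; nb <- nb + 1L
      }
      errs[ep] <- tot / max(nb, 1L)
    }
    model$rbm_stack[[k]] <- layer
    traces[[k]] <- errs
    x <- hidden_prob(layer, x)  # mean-field input for the next layer
    if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  }
  model$trace$pretrain <- traces
  model
}

dbn_forward <- function(model, features) {
  acts <- list(features)
  x <- features
  for (layer in model$rbm_stack) {
    x <- sigmoid(x %*% layer$W + rep(layer$b, each = nrow(x)))
    acts[[length(acts) + 1L]] <- x
  }
  out <- x %*% model$output_layer$W + rep(model$output_layer$b, each = nrow(x))
  list(out = out, acts = acts)
}

#' Mean squared error against one-hot targets
#'
#' `E = (1/m) * sum_i ||Y'_i - Y_i||^2`, the finetuning objective.
#'
#' @param y_hat m x K matrix of network outputs.
#' @param y m x K matrix of one-hot targets.
#' @return A scalar.
#' @export
dbn_mse <- function(y_hat, y) {
  if (!all(dim(y_hat) == dim(y))) stop("output/target shapes differ", call. = FALSE)
  sum((y_hat - y)^2) / nrow(y)
}

#' Backpropagation finetuning of the unrolled DBN
#'
#' Gradient descent on the mean squared error between the linear output
#' layer and one-hot targets, backpropagated through the sigmoid stack.
#'
#' @param model a (typically pretrained) `dbn`.
#' @param features m x D feature matrix.
#' @param labels length-m label vector.
#' @param epochs finetuning epochs.
#' @param lr gradient-descent learning rate.
#' @param batch mini-batch size.
#' @param seed integer seed.
#' @return The model, with `trace$finetune` holding the per-epoch E.
#' @export
finetune <- function(model, features, labels, epochs = 50L, lr = 0.1,
                     batch = 16L, seed = 1L) {
  stopifnot(inherits(model, "dbn"))
  features <- as_row_matrix(features, nrow(model$rbm_stack[[1]]$W), "features")
  labels <- as.character(labels)
  classes <- model$classes %||% sort(unique(labels))
  if (length(classes) > model$n_classes)
    stop("more label classes than the model's ", model$n_classes, call. = FALSE)
  yi <- match(labels, classes)
  if (anyNA(yi)) stop("label outside the model's class set", call. = FALSE)
  model$classes <- classes
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  m <- nrow(features)
  Y <- matrix(0, m, model$n_classes)
  Y[cbind(seq_len(m), yi)] <- 1
  errs <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(m)
    for (b0 in seq(1L, m, by = batch)) {
      take <- ord[b0:min(b0 + batch - 1L, m)]
      xb <- features[take, , drop = FALSE]
      yb <- Y[take, , drop = FALSE]
      fw <- dbn_forward(model, xb)
      dout <- 2 * (fw$out - yb) / nrow(xb)
      top <- fw$acts[[length(fw$acts)]]
      dW_out <- crossprod(top, dout)
      db_out <- colSums(dout)
      d <- dout %*% t(model$output_layer$W)
      for (k in rev(seq_along(model$rbm_stack))) {
        h <- fw$acts[[k + 1L]]
        d <- d * h * (1 - h)  # through the sigmoid
        W_old <- model$rbm_stack[[k]]$W
        model$rbm_stack[[k]]$W <- W_old - lr * crossprod(fw$acts[[k]], d)
        model$rbm_stack[[k]]$b <- model$rbm_stack[[k]]$b - lr * colSums(d)
        d <- d %*% t(W_old)
      }
      model$output_layer$W <- model$output_layer$W - lr * dW_out
      model$output_layer$b <- model$output_layer$b - lr * db_out
    }
    errs[ep] <- dbn_mse(dbn_forward(model, features)$out, Y)
  }
  model$trace$finetune <- errs
  model
}

#' Predict with the DBN
#'
#' Deterministic forward pass on hidden probabilities (no sampling);
#' class = argmax of the output scores, ties broken by the lowest class
#' index.
#'
#' @param object a trained `dbn`.
#' @param features feature matrix (or single vector).
#' @param type `"class"` for labels, `"score"` for the raw score matrix.
#' @param ... unused.
#' @return Character labels, or an m x K score matrix.
#' @export
predict.dbn <- function(object, features, type = c("class", "score"), ...) {
  type <- match.arg(type)
  features <- as_row_matrix(features, nrow(object$rbm_stack[[1]]$W), "features")
  scores <- dbn_forward(object, features)$out
  if (type == "score") {
    colnames(scores) <- object$classes
    return(scores)
  }
  if (is.null(object$classes)) stop("model has no class labels; finetune first",
                                    call. = FALSE)
  object$classes[max.col(scores, ties.method = "first")]
}
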