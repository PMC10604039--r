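# SqueezeNet classifier / feature extractor.
#
# One stem convolution plus eight fire modules.  A fire module squeezes
# the incoming channels through n 1x1 filters (ReLU), then expands in
# parallel through 4n 1x1 filters and 4n 3x3 filters (ReLU each) whose
# outputs are concatenated, so every fire module emits exactly 8n
# channels regardless of its input width.  Stride-2 max-pooling follows
# the stem and the second and fourth fire modules, so a 64 px input
# reaches an 8x8 map (32 px reaches 4x4) before the head.  The head is a
# 1x1 convolution to `head_width` channels followed by global average
# pooling — the pooled vector is the feature representation handed to
# the downstream classifier — and a dense softmax layer on top for
# training.

#' Describe a SqueezeNet architecture
#'
#' @param fire_n squeeze-filter counts for the eight fire modules
#'   (length-8 integer vector; each module expands to 4n + 4n channels).
#' @param stem filters in the stem 3x3 convolution.
#' @param head_width channels of the 1x1 head convolution; this is the
#'   feature dimension after global average pooling.  Desk-scale default
#'   32; the full-scale profile uses 1000.
#' @param in_size input image side; must be divisible by 8 (three
#'   stride-2 pools).
#' @return A `squeezenet_spec` list.
#' @export
squeezenet_spec <- function(fire_n = c(4L, 4L, 4L, 4L, 8L, 8L, 8L, 8L),
                            stem = 8L, head_width = 32L, in_size = 32L) {
  fire_n <- as.integer(fire_n)
  if (length(fire_n) != 8L)
    stop("a SqueezeNet spec needs exactly 8 fire modules, got ",
         length(fire_n), call. = FALSE)
  if (any(fire_n < 1L)) stop("fire squeeze widths must be >= 1", call. = FALSE)
  if (as.integer(in_size) %% 8L != 0L)
    stop("in_size must be divisible by 8 (three stride-2 pools)", call. = FALSE)
  structure(list(fire_n = fire_n, stem = as.integer(stem),
                 head_width = as.integer(head_width),
                 in_size = as.integer(in_size)),
            class = "squeezenet_spec")
}

#' Output channel count of one fire module
#'
#' A fire module with squeeze width `n` always emits `4n + 4n = 8n`
#' channels (the two expand branches concatenated), independent of its
#' input channel count.
#'
#' @param n squeeze-filter count.
#' @return `8 * n`.
#' @export
fire_out_channels <- function(n) 8L * as.integer(n)

#' Build a SqueezeNet classifier
#'
#' @param spec a [squeezenet_spec()].
#' @param n_classes number of output classes (>= 2).
#' @param seed integer seed; identical seeds give identical initial
#'   weights.
#' @return An object of class `squeezenet`.
#' @export
build_squeezenet <- function(spec = squeezenet_spec(), n_classes = 3L, seed = 1L) {
  stopifnot(inherits(spec, "squeezenet_spec"))
  n_classes <- as.integer(n_classes)
  if (n_classes < 2L) stop("n_classes must be >= 2", call. = FALSE)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  pars <- list(stem = make_conv(1L, spec$stem, 3L))
  cin <- spec$stem
  for (i in 1:8) {
    n <- spec$fire_n[i]
    pars[[paste0("f", i, "s")]] <- make_conv(cin, n, 1L)
    pars[[paste0("f", i, "e1")]] <- make_conv(n, 4L * n, 1L)
    pars[[paste0("f", i, "e3")]] <- make_conv(n, 4L * n, 3L)
    cin <- 8L * n
  }
  pars$headconv <- make_conv(cin, spec$head_width, 1L)
  pars$fc <- make_dense(spec$head_width, n_classes)
  structure(list(spec = spec, n_classes = n_classes, pars = pars,
                 history = list()),
            class = "squeezenet")
}

#' @export
print.squeezenet <- function(x, ...) {
  np <- sum(vapply(x$pars, function(p) length(p$W) + length(p$b), numeric(1)))
  cat(sprintf(
    "SqueezeNet: stem %d + 8 fire modules (n = %s), head %d -> %d classes, %d parameters\n",
    x$spec$stem, paste(x$spec$fire_n, collapse = ","),
    x$spec$head_width, x$n_classes, np))
  invisible(x)
}

squeezenet_forward <- function(model, x, N, upto = c("probs", "features")) {
  upto <- match.arg(upto)
  p <- model$pars
  s <- model$spec$in_size
  sh <- c(s, s, 1L, N)
  caches <- list()
  cf <- conv_fwd(p$stem, x, sh); rf <- relu_fwd(cf$out)
  caches$stem <- list(conv = cf$cache, relu = rf$cache)
  x <- rf$out; sh[3] <- p$stem$Cout
  pf <- maxpool_fwd(x, sh)
  caches$pool0 <- pf$cache
  x <- pf$out; sh <- pf$sh
  for (i in 1:8) {
    fc <- list()
    cf <- conv_fwd(p[[paste0("f", i, "s")]], x, sh); rf <- relu_fwd(cf$out)
    fc$squeeze <- list(conv = cf$cache, relu = rf$cache)
    xs <- rf$out
    shs <- sh; shs[3] <- p[[paste0("f", i, "s")]]$Cout
    cf1 <- conv_fwd(p[[paste0("f", i, "e1")]], xs, shs); rf1 <- relu_fwd(cf1$out)
    fc$e1 <- list(conv = cf1$cache, relu = rf1$cache)
    cf3 <- conv_fwd(p[[paste0("f", i, "e3")]], xs, shs); rf3 <- relu_fwd(cf3$out)
    fc$e3 <- list(conv = cf3$cache, relu = rf3$cache)
    x <- cbind(rf1$out, rf3$out)
    sh[3] <- ncol(x)
    caches[[paste0("fire", i)]] <- fc
    if (i %in% c(2L, 4L)) {
      pf <- maxpool_fwd(x, sh)
      caches[[paste0("pool", i)]] <- pf$cache
      x <- pf$out; sh <- pf$sh
    }
  }
  cf <- conv_fwd(p$headconv, x, sh); rf <- relu_fwd(cf$out)
  caches$headconv <- list(conv = cf$cache, relu = rf$cache)
  x <- rf$out; sh[3] <- p$headconv$Cout
  gf <- gap_fwd(x, sh)
  caches$gap <- gf$cache
  feats <- gf$out
  if (upto == "features") return(list(features = feats))
  df <- dense_fwd(p$fc, feats)
  caches$fc <- df$cache
  list(probs = softmax_rows(df$out), logits = df$out, features = feats,
       caches = caches)
}

squeezenet_backward <- function(model, dlogits, caches) {
  p <- model$pars
  grads <- list()
  bk <- dense_bwd(p$fc, dlogits, caches$fc)
  grads$fc <- list(W = bk$dW, b = bk$db)
  d <- gap_bwd(bk$dx, caches$gap)
  d <- relu_bwd(d, caches$headconv$relu)
  bk <- conv_bwd(p$headconv, d, caches$headconv$conv)
  grads$headconv <- list(W = bk$dW, b = bk$db)
  d <- bk$dx
  for (i in 8:1) {
    if (i %in% c(2L, 4L)) d <- maxpool_bwd(d, caches[[paste0("pool", i)]])
    fc <- caches[[paste0("fire", i)]]
    c1 <- p[[paste0("f", i, "e1")]]$Cout
    d1 <- relu_bwd(d[, seq_len(c1), drop = FALSE], fc$e1$relu)
    d3 <- relu_bwd(d[, -seq_len(c1), drop = FALSE], fc$e3$relu)
    bk1 <- conv_bwd(p[[paste0("f", i, "e1")]], d1, fc$e1$conv)
    grads[[paste0("f", i, "e1")]] <- list(W = bk1$dW, b = bk1$db)
    bk3 <- conv_bwd(p[[paste0("f", i, "e3")]], d3, fc$e3$conv)
    grads[[paste0("f", i, "e3")]] <- list(W = bk3$dW, b = bk3$db)
    ds <- relu_bwd(bk1$dx + bk3$dx, fc$squeeze$relu)
    bks <- conv_bwd(p[[paste0("f", i, "s")]], ds, fc$squeeze$conv)
    grads[[paste0("f", i, "s")]] <- list(W = bks$dW, b = bks$db)
    d <- bks$dx
  }
  d <- maxpool_bwd(d, caches$pool0)
  d <- relu_bwd(d, caches$stem$relu)
  bk <- conv_bwd(p$stem, d, caches$stem$conv)
  grads$stem <- list(W = bk$dW, b = bk$db)
  grads
}

#' Train the SqueezeNet classifier
#'
#' Cross-entropy loss minimized with Adam under the supplied
#' hyperparameters (typically decoded from an optimizer position).
#' Records the mean training loss per epoch and, when validation data
#' are given, the validation macro-precision per epoch.
#'
#' @param model a `squeezenet`.
#' @param images list of input matrices (side = spec `in_size`).
#' @param labels character/factor labels, one per image, >= 2 classes.
#' @param hyper list with `lr`, `batch`, `epochs`, `weight_decay`.
#' @param seed integer seed for shuffling.
#' @param val_images,val_labels optional held-out data for the
#'   per-epoch precision trace.
#' @param augment expand the training set with the 8 dihedral
#'   transforms (flips/rotations) of each image; useful because lesion
#'   orientation is arbitrary.  Default FALSE.
#' @return The trained model; `history` gains `loss` and (if validation
#'   data were supplied) `val_precision` vectors.
#' @export
train_squeezenet <- function(model, images, labels,
                             hyper = list(lr = 3e-3, batch = 8L, epochs = 6L,
                                          weight_decay = 1e-5),
                             seed = 1L, val_images = NULL, val_labels = NULL,
                             augment = FALSE) {
  stopifnot(inherits(model, "squeezenet"))
  if (length(images) == 0L) stop("empty training set", call. = FALSE)
  labels <- as.character(labels)
  if (isTRUE(augment)) {
    a <- augment_dihedral(images, labels)
    images <- a$images
    labels <- a$labels
  }
  classes <- model$classes %||% sort(unique(labels))
  if (length(classes) < 2L) stop("need >= 2 classes to train", call. = FALSE)
  model$classes <- classes
  epochs <- as.integer(hyper$epochs %||% 5L)
  if (epochs == 0L) {
    model$history <- list(loss = numeric(0), val_precision = numeric(0))
    return(model)
  }
  batchsz <- as.integer(hyper$batch %||% 8L)
  lr <- hyper$lr %||% 3e-3
  wd <- hyper$weight_decay %||% 0
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  yi <- match(labels, classes)
  if (anyNA(yi)) stop("label outside the model's class set", call. = FALSE)
  n <- length(images)
  st <- adam_init()
  loss_tr <- numeric(epochs)
  valp_tr <- if (is.null(val_images)) NULL else numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    tot <- 0
    for (b0 in seq(1L, n, by = batchsz)) {
      take <- ord[b0:min(b0 + batchsz - 1L, n)]
      nb <- length(take)
      x <- stack_images(images[take])
      fw <- squeezenet_forward(model, x, nb)
      pr <- fw$probs
      sel <- cbind(seq_len(nb), yi[take])
      tot <- tot - sum(log(pmax(pr[sel], 1e-12)))
      dz <- pr
      dz[sel] <- dz[sel] - 1
      grads <- squeezenet_backward(model, dz / nb, fw$caches)
      upd <- adam_step(model$pars, grads, st, lr, weight_decay = wd)
      model$pars <- upd$pars; st <- upd$st
    }
    loss_tr[ep] <- tot / n
    if (!is.null(val_images)) {
      pred <- predict(model, val_images)
      valp_tr[ep] <- precision_fitness(as.character(val_labels), pred)
    }
  }
  model$history <- list(loss = loss_tr, val_precision = valp_tr)
  model
}

#' Predict class labels with a SqueezeNet
#'
#' @param object a trained `squeezenet`.
#' @param images list of input matrices.
#' @param type `"class"` for labels, `"prob"` for the probability matrix.
#' @param ... unused.
#' @return Character vector of labels, or an N x K probability matrix.
#' @export
predict.squeezenet <- function(object, images, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (is.matrix(images)) images <- list(images)
  fw <- squeezenet_forward(object, stack_images(images), length(images))
  if (type == "prob") {
    colnames(fw$probs) <- object$classes
    return(fw$probs)
  }
  object$classes[max.col(fw$probs, ties.method = "first")]
}

# the 8 symmetries of the square: identity, flips, rotations
augment_dihedral <- function(images, labels) {
  tfs <- list(identity,
              function(x) x[nrow(x):1, , drop = FALSE],
              function(x) x[, ncol(x):1, drop = FALSE],
              function(x) t(x),
              function(x) t(x)[nrow(x):1, , drop = FALSE],
              function(x) t(x)[, ncol(x):1, drop = FALSE],
              function(x) x[nrow(x):1, ncol(x):1, drop = FALSE],
              function(x) t(x[nrow(x):1, ncol(x):1, drop = FALSE]))
  list(images = unlist(lapply(images, function(m) lapply(tfs, function(tf) tf(m))),
                       recursive = FALSE),
       labels = rep(labels, each = length(tfs)))
}

#' Extract the feature vector of an image
#'
#' The post-average-pool, pre-softmax activations: the `head_width`-long
#' vector obtained after the 1x1 head convolution and global average
#' pooling.  A pure, deterministic function of the weights and the
#' image.
#'
#' @param model a `squeezenet` (trained or freshly built).
#' @param img a single image matrix, or a list of them.
#' @return A numeric vector (single image) or an N x `head_width` matrix.
#' @export
extract_features <- function(model, img) {
  stopifnot(inherits(model, "squeezenet"))
  imgs <- if (is.matrix(img)) list(img) else img
  bad <- vapply(imgs, function(m)
    nrow(m) != model$spec$in_size || ncol(m) != model$spec$in_size, logical(1))
  if (any(bad))
    stop("input size does not match the model's ", model$spec$in_size,
         "x", model$spec$in_size, " input", call. = FALSE)
  fw <- squeezenet_forward(model, stack_images(imgs), length(imgs),
                           upto = "features")
  if (is.matrix(img)) as.numeric(fw$features) else fw$features
}
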