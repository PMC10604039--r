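# U-Net mass segmentation.
#
# Contracting path: per level two padded 3x3 convolutions + ReLU, then
# 2x2 max-pool (stride 2).  Expanding path: nearest-neighbour x2
# upsampling followed by a 2x2 convolution, concatenation with the
# matching encoder feature map (skip connection), then two 3x3
# convolutions + ReLU.  A final 1x1 convolution maps the feature vector
# at each pixel to a foreground logit, so the output mask has exactly
# the input shape.  Convolutions are "same"-padded: the decoder restores
# the input resolution level by level, and no cropping is needed.

#' Build a U-Net segmentation model
#'
#' @param depth number of down/up-sampling levels (>= 1).
#' @param base number of filters at the first level; doubled per level.
#' @param in_size input image side in pixels; must be divisible by
#'   `2^depth`.
#' @param seed integer seed for the (He-normal) weight initialization;
#'   the same seed gives identical initial parameters.
#' @return An object of class `unet`.
#' @export
build_unet <- function(depth = 2L, base = 8L, in_size = 32L, seed = 1L) {
  depth <- as.integer(depth); base <- as.integer(base); in_size <- as.integer(in_size)
  if (depth < 1L) stop("depth must be >= 1", call. = FALSE)
  if (base < 1L) stop("base channels must be >= 1", call. = FALSE)
  if (in_size %% 2L^depth != 0L)
    stop("input size ", in_size, " is not divisible by 2^depth = ", 2L^depth,
         call. = FALSE)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  ch <- base * 2L^(seq_len(depth) - 1L)
  pars <- list()
  cin <- 1L
  for (l in seq_len(depth)) {
    pars[[paste0("enc", l, "a")]] <- make_conv(cin, ch[l], 3L)
    pars[[paste0("enc", l, "b")]] <- make_conv(ch[l], ch[l], 3L)
    cin <- ch[l]
  }
  cb <- base * 2L^depth
  pars$bota <- make_conv(cin, cb, 3L)
  pars$botb <- make_conv(cb, cb, 3L)
  cup <- cb
  for (l in rev(seq_len(depth))) {
    pars[[paste0("up", l)]] <- make_conv(cup, ch[l], 2L)
    pars[[paste0("dec", l, "a")]] <- make_conv(2L * ch[l], ch[l], 3L)
    pars[[paste0("dec", l, "b")]] <- make_conv(ch[l], ch[l], 3L)
    cup <- ch[l]
  }
  pars$head <- make_conv(ch[1], 1L, 1L)
  structure(list(depth = depth, base = base, in_size = in_size,
                 pars = pars, history = numeric(0)),
            class = "unet")
}

#' @export
print.unet <- function(x, ...) {
  np <- sum(vapply(x$pars, function(p) length(p$W) + length(p$b), numeric(1)))
  cat(sprintf("U-Net: depth %d, base %d channels, %dx%d input, %d parameters\n",
              x$depth, x$base, x$in_size, x$in_size, np))
  if (length(x$history))
    cat(sprintf("  trained %d epochs, final loss %.4f\n",
                length(x$history), x$history[length(x$history)]))
  invisible(x)
}

# forward pass over a batch; returns logits plus all caches for backprop
unet_forward <- function(model, x, N) {
  s <- model$in_size
  p <- model$pars
  caches <- list()
  sh <- c(s, s, 1L, N)
  skips <- list()
  for (l in seq_len(model$depth)) {
    for (sub in c("a", "b")) {
      nm <- paste0("enc", l, sub)
      cf <- conv_fwd(p[[nm]], x, sh)
      rf <- relu_fwd(cf$out)
      caches[[nm]] <- list(conv = cf$cache, relu = rf$cache)
      x <- rf$out
      sh[3] <- p[[nm]]$Cout
    }
    skips[[l]] <- list(x = x, sh = sh)
    pf <- maxpool_fwd(x, sh)
    caches[[paste0("pool", l)]] <- pf$cache
    x <- pf$out; sh <- pf$sh
  }
  for (nm in c("bota", "botb")) {
    cf <- conv_fwd(p[[nm]], x, sh)
    rf <- relu_fwd(cf$out)
    caches[[nm]] <- list(conv = cf$cache, relu = rf$cache)
    x <- rf$out; sh[3] <- p[[nm]]$Cout
  }
  for (l in rev(seq_len(model$depth))) {
    uf <- upsample_fwd(x, sh)
    caches[[paste0("ups", l)]] <- uf$cache
    x <- uf$out; sh <- uf$sh
    nm <- paste0("up", l)
    cf <- conv_fwd(p[[nm]], x, sh)
    rf <- relu_fwd(cf$out)
    caches[[nm]] <- list(conv = cf$cache, relu = rf$cache)
    x <- rf$out; sh[3] <- p[[nm]]$Cout
    skip <- skips[[l]]
    caches[[paste0("cat", l)]] <- c(skip_ch = skip$sh[3])
    x <- cbind(skip$x, x)
    sh[3] <- sh[3] + skip$sh[3]
    for (sub in c("a", "b")) {
      nm <- paste0("dec", l, sub)
      cf <- conv_fwd(p[[nm]], x, sh)
      rf <- relu_fwd(cf$out)
      caches[[nm]] <- list(conv = cf$cache, relu = rf$cache)
      x <- rf$out; sh[3] <- p[[nm]]$Cout
    }
  }
  cf <- conv_fwd(p$head, x, sh)
  caches$head <- list(conv = cf$cache)
  list(logits = cf$out, caches = caches)
}

# backprop of d(loss)/d(logits); returns gradients for every layer
unet_backward <- function(model, dlogits, caches) {
  p <- model$pars
  grads <- list()
  dskips <- list()
  bk <- conv_bwd(p$head, dlogits, caches$head$conv)
  grads$head <- list(W = bk$dW, b = bk$db)
  d <- bk$dx
  for (l in seq_len(model$depth)) {
    for (sub in c("b", "a")) {
      nm <- paste0("dec", l, sub)
      d <- relu_bwd(d, caches[[nm]]$relu)
      bk <- conv_bwd(p[[nm]], d, caches[[nm]]$conv)
      grads[[nm]] <- list(W = bk$dW, b = bk$db)
      d <- bk$dx
    }
    kc <- caches[[paste0("cat", l)]][["skip_ch"]]
    dskips[[l]] <- d[, seq_len(kc), drop = FALSE]  # skip-connection branch
    d <- d[, -seq_len(kc), drop = FALSE]
    nm <- paste0("up", l)
    d <- relu_bwd(d, caches[[nm]]$relu)
    bk <- conv_bwd(p[[nm]], d, caches[[nm]]$conv)
    grads[[nm]] <- list(W = bk$dW, b = bk$db)
    d <- upsample_bwd(bk$dx, caches[[paste0("ups", l)]])
  }
  for (nm in c("botb", "bota")) {
    d <- relu_bwd(d, caches[[nm]]$relu)
    bk <- conv_bwd(p[[nm]], d, caches[[nm]]$conv)
    grads[[nm]] <- list(W = bk$dW, b = bk$db)
    d <- bk$dx
  }
  for (l in rev(seq_len(model$depth))) {
    d <- maxpool_bwd(d, caches[[paste0("pool", l)]])
    d <- d + dskips[[l]]
    for (sub in c("b", "a")) {
      nm <- paste0("enc", l, sub)
      d <- relu_bwd(d, caches[[nm]]$relu)
      bk <- conv_bwd(p[[nm]], d, caches[[nm]]$conv)
      grads[[nm]] <- list(W = bk$dW, b = bk$db)
      d <- bk$dx
    }
  }
  grads
}

#' Train the U-Net on phantoms with ground-truth masks
#'
#' Pixel-wise binary cross-entropy on the foreground logits, minimized
#' with Adam over shuffled mini-batches.  Mass pixels are a small
#' minority of each image, so the foreground term is up-weighted by
#' `pos_weight`; this favours recall and keeps thin spiculation arms in
#' the predicted masks, which downstream feature extraction depends on.
#' The per-epoch mean training loss is appended to the model's
#' `history`.
#'
#' @param model a `unet` from [build_unet()].
#' @param phantoms list of `phantom` objects (images already
#'   preprocessed as desired); at least 2.
#' @param epochs training epochs; 0 returns the model unchanged.
#' @param lr Adam learning rate.
#' @param batch mini-batch size.
#' @param seed integer seed controlling shuffling.
#' @param pos_weight multiplier on the foreground loss term (1 =
#'   unweighted cross-entropy).
#' @return The trained `unet`, with `history` holding one mean loss per
#'   epoch.
#' @export
train_segmenter <- function(model, phantoms, epochs = 30L, lr = 5e-3,
                            batch = 8L, seed = 1L, pos_weight = 3) {
  stopifnot(inherits(model, "unet"))
  if (length(phantoms) < 2L)
    stop("need at least 2 phantoms with masks to train", call. = FALSE)
  if (epochs == 0L) return(model)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  n <- length(phantoms)
  st <- adam_init()
  trace <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; ep_px <- 0
    for (b0 in seq(1L, n, by = batch)) {
      take <- ord[b0:min(b0 + batch - 1L, n)]
      nb <- length(take)
      x <- stack_images(lapply(phantoms[take], `[[`, "image"))
      y <- stack_images(lapply(phantoms[take], function(p) p$mask + 0))
      fw <- unet_forward(model, x, nb)
      z <- fw$logits
      # weighted BCE with logits: w*y*softplus(-z) + (1-y)*(z + softplus(-z));
      # gradient -w*y*(1-sigmoid(z)) + (1-y)*sigmoid(z)
      sp <- log1p(exp(-abs(z))) + pmax(-z, 0)
      loss <- sum(pos_weight * y * sp + (1 - y) * (z + sp))
      ep_loss <- ep_loss + loss; ep_px <- ep_px + length(z)
      sg <- sigmoid(z)
      dz <- (-pos_weight * y * (1 - sg) + (1 - y) * sg) / length(z)
      grads <- unet_backward(model, dz, fw$caches)
      upd <- adam_step(model$pars, grads, st, lr)
      model$pars <- upd$pars; st <- upd$st
    }
    trace[ep] <- ep_loss / ep_px
  }
  model$history <- c(model$history, trace)
  model
}

#' Segment an image into a binary mass mask
#'
#' @param model a trained `unet`.
#' @param img numeric matrix matching the model's input size.
#' @param threshold foreground probability cutoff (default 0.5).
#' @return A 0/1 integer matrix of the image's shape.
#' @export
segment <- function(model, img, threshold = 0.5) {
  stopifnot(inherits(model, "unet"))
  stop_if_not_image(img)
  if (nrow(img) != model$in_size || ncol(img) != model$in_size)
    stop("image is ", nrow(img), "x", ncol(img), " but the model expects ",
         model$in_size, "x", model$in_size, call. = FALSE)
  fw <- unet_forward(model, matrix(as.vector(img), ncol = 1L), 1L)
  prob <- sigmoid(fw$logits)
  matrix(as.integer(prob >= threshold), nrow(img), ncol(img))
}

#' Combine an image with its predicted mask for the classifier
#'
#' `mode = "mask"` zeroes the background (`img * mask`); `mode = "crop"`
#' cuts the mask's bounding box and bilinearly resizes it to
#' `out_size`.  An empty mask passes the full image through unchanged —
#' the path taken by normal (mass-free) images.
#'
#' @param img numeric image matrix.
#' @param mask 0/1 matrix of the same shape.
#' @param mode `"mask"` or `"crop"`.
#' @param out_size output side for `"crop"` (defaults to the input size).
#' @return A numeric image matrix.
#' @export
apply_mask <- function(img, mask, mode = c("mask", "crop"), out_size = nrow(img)) {
  mode <- match.arg(mode)
  stop_if_not_image(img)
  if (!all(dim(img) == dim(mask)))
    stop("image and mask shapes differ", call. = FALSE)
  if (sum(mask) == 0) return(img)
  if (mode == "mask") return(img * mask)
  rr <- range(which(rowSums(mask) > 0))
  cc <- range(which(colSums(mask) > 0))
  resize_bilinear(img[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE], out_size, out_size)
}

resize_bilinear <- function(img, h, w) {
  sh <- nrow(img); sw <- ncol(img)
  at_r <- if (sh == 1L) rep(1, h) else seq(1, sh, length.out = h)
  at_c <- if (sw == 1L) rep(1, w) else seq(1, sw, length.out = w)
  i0 <- pmin(floor(at_r), max(sh - 1L, 1L)); fi <- at_r - i0
  j0 <- pmin(floor(at_c), max(sw - 1L, 1L)); fj <- at_c - j0
  i1 <- pmin(i0 + 1L, sh); j1 <- pmin(j0 + 1L, sw)
  a <- img[i0, j0, drop = FALSE] * ((1 - fi) %o% (1 - fj)) +
       img[i1, j0, drop = FALSE] * (fi %o% (1 - fj)) +
       img[i0, j1, drop = FALSE] * ((1 - fi) %o% fj) +
       img[i1, j1, drop = FALSE] * (fi %o% fj)
  a
}

#' Dice overlap coefficient between two binary masks
#'
#' `2|A∩B| / (|A| + |B|)`; two empty masks score 1 (perfect agreement on
#' absence).
#'
#' @param a,b 0/1 matrices of equal shape.
#' @return A number in `[0, 1]`.
#' @export
dice <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("mask shapes differ", call. = FALSE)
  sa <- sum(a != 0); sb <- sum(b != 0)
  if (sa + sb == 0) return(1)
  2 * sum(a != 0 & b != 0) / (sa + sb)
}
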