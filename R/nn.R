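# Minimal dense/convolutional network engine in vectorized base R.
#
# Activations for a batch of N feature maps of height H, width W and C
# channels are stored as a numeric matrix with N*H*W rows and C columns;
# row (n-1)*H*W + p holds pixel p (column-major within the plane) of
# image n.  Convolutions are computed by gathering each receptive field
# into a patch matrix (im2col) and multiplying by a (k*k*Cin) x Cout
# weight matrix; the gather index tables depend only on the geometry and
# are cached.  This keeps every layer a handful of large matrix
# operations, which is fast enough for the desk-scale nets used here
# (32-64 px inputs, tens of channels).

.nn_cache <- new.env(parent = emptyenv())

nn_cached <- function(key, builder) {
  v <- get0(key, envir = .nn_cache)
  if (is.null(v)) {
    v <- builder()
    assign(key, v, envir = .nn_cache)
  }
  v
}

# HW x k^2 table of source plane indices per output pixel (NA = zero pad);
# pad `pt` on top/left, so odd k gives "same" symmetric padding and k=2
# pads one row/col at bottom/right.
conv_idx <- function(H, W, k, pt) {
  nn_cached(sprintf("ci:%d:%d:%d:%d", H, W, k, pt), function() {
    r <- rep(seq_len(H), times = W)
    c <- rep(seq_len(W), each = H)
    A <- matrix(NA_integer_, H * W, k * k)
    j <- 0L
    for (dx in 0:(k - 1L)) for (dy in 0:(k - 1L)) {
      j <- j + 1L
      sr <- r - pt + dy; sc <- c - pt + dx
      ok <- sr >= 1L & sr <= H & sc >= 1L & sc <= W
      A[ok, j] <- (sc[ok] - 1L) * H + sr[ok]
    }
    A
  })
}

batch_idx <- function(A, plane, N) {
  # replicate a per-plane index table across a batch of planes of size
  # `plane` (A may have fewer rows than `plane`, e.g. pooling tables)
  A[rep(seq_len(nrow(A)), times = N), , drop = FALSE] +
    rep((seq_len(N) - 1L) * plane, each = nrow(A))
}

conv_batch_idx <- function(H, W, k, pt, N) {
  nn_cached(sprintf("cb:%d:%d:%d:%d:%d", H, W, k, pt, N), function() {
    batch_idx(conv_idx(H, W, k, pt), H * W, N)
  })
}

# -- layers -------------------------------------------------------------
# Each layer is a named list of parameter matrices; forward returns
# list(out, cache); backward returns list(grads, dx).

make_conv <- function(Cin, Cout, k) {
  # He-normal initialization, drawn from the current RNG stream
  W <- matrix(stats::rnorm(k * k * Cin * Cout, sd = sqrt(2 / (k * k * Cin))),
              k * k * Cin, Cout)
  # small positive bias keeps narrow ReLU stacks from dying at init
  list(W = W, b = rep(0.01, Cout), k = as.integer(k),
       pt = (as.integer(k) - 1L) %/% 2L, Cin = Cin, Cout = Cout)
}

conv_fwd <- function(lay, x, sh) {
  H <- sh[1]; W <- sh[2]; Cin <- sh[3]; N <- sh[4]
  stopifnot(Cin == lay$Cin)
  k2 <- lay$k^2
  Ab <- conv_batch_idx(H, W, lay$k, lay$pt, N)
  X <- matrix(0, N * H * W, k2 * Cin)
  iv <- as.vector(Ab)
  nas <- is.na(iv)
  for (c in seq_len(Cin)) {
    v <- x[iv, c]
    if (any(nas)) v[nas] <- 0
    X[, (c - 1L) * k2 + seq_len(k2)] <- v
  }
  Y <- X %*% lay$W
  Y <- Y + rep(lay$b, each = nrow(Y))
  list(out = Y, cache = list(X = X, Ab = Ab, sh = sh))
}

conv_bwd <- function(lay, dY, cache) {
  sh <- cache$sh
  k2 <- lay$k^2
  dW <- crossprod(cache$X, dY)
  db <- colSums(dY)
  dXp <- dY %*% t(lay$W)
  dx <- matrix(0, nrow(dY), lay$Cin)
  for (c in seq_len(lay$Cin)) {
    for (j in seq_len(k2)) {
      idx <- cache$Ab[, j]
      ok <- !is.na(idx)
      col <- dXp[, (c - 1L) * k2 + j]
      dx[idx[ok], c] <- dx[idx[ok], c] + col[ok]
    }
  }
  list(dW = dW, db = db, dx = dx)
}

relu_fwd <- function(x) {
  out <- x * (x > 0)
  list(out = out, cache = x > 0)
}
relu_bwd <- function(dY, cache) dY * cache

pool_idx <- function(H, W) {
  nn_cached(sprintf("pi:%d:%d", H, W), function() {
    Ho <- H %/% 2L; Wo <- W %/% 2L
    ro <- rep(seq_len(Ho), times = Wo)
    co <- rep(seq_len(Wo), each = Ho)
    A <- matrix(0L, Ho * Wo, 4L)
    j <- 0L
    for (dc in 0:1) for (dr in 0:1) {
      j <- j + 1L
      A[, j] <- (2L * co - 2L + dc) * H + (2L * ro - 1L + dr)
    }
    A
  })
}

maxpool_fwd <- function(x, sh) {
  H <- sh[1]; W <- sh[2]; C <- sh[3]; N <- sh[4]
  stopifnot(H %% 2L == 0L, W %% 2L == 0L)
  Ab <- nn_cached(sprintf("pb:%d:%d:%d", H, W, N), function() {
    batch_idx(pool_idx(H, W), H * W, N)
  })
  no <- nrow(Ab)
  out <- matrix(0, no, C)
  src <- matrix(0L, no, C)
  iv <- as.vector(Ab)
  for (c in seq_len(C)) {
    M <- matrix(x[iv, c], no, 4L)
    mi <- max.col(M, ties.method = "first")
    pick <- cbind(seq_len(no), mi)
    out[, c] <- M[pick]
    src[, c] <- Ab[pick]
  }
  list(out = out, cache = list(src = src, n_in = nrow(x)),
       sh = c(H %/% 2L, W %/% 2L, C, N))
}

maxpool_bwd <- function(dY, cache) {
  dx <- matrix(0, cache$n_in, ncol(dY))
  for (c in seq_len(ncol(dY))) dx[cache$src[, c], c] <- dY[, c]
  dx
}

up_idx <- function(H, W) {
  # out pixel (r, c) of the 2H x 2W map sources in pixel (ceil(r/2), ceil(c/2))
  nn_cached(sprintf("ui:%d:%d", H, W), function() {
    Ho <- 2L * H; Wo <- 2L * W
    r <- rep(seq_len(Ho), times = Wo)
    c <- rep(seq_len(Wo), each = Ho)
    ((c + 1L) %/% 2L - 1L) * H + (r + 1L) %/% 2L
  })
}

upsample_fwd <- function(x, sh) {
  H <- sh[1]; W <- sh[2]; C <- sh[3]; N <- sh[4]
  idx <- nn_cached(sprintf("ub:%d:%d:%d", H, W, N), function() {
    u <- up_idx(H, W)
    as.vector(matrix(u, length(u), N) +
              rep((seq_len(N) - 1L) * H * W, each = length(u)))
  })
  list(out = x[idx, , drop = FALSE], cache = list(sh = sh),
       sh = c(2L * H, 2L * W, C, N))
}

upsample_bwd <- function(dY, cache) {
  sh <- cache$sh
  H <- sh[1]; W <- sh[2]; N <- sh[4]
  # children of input pixel (r, c) are the 2x2 block at (2r-1, 2c-1)
  A <- nn_cached(sprintf("uc:%d:%d:%d", H, W, N), function() {
    batch_idx(pool_idx(2L * H, 2L * W), 4L * H * W, N)
  })
  dY[A[, 1], , drop = FALSE] + dY[A[, 2], , drop = FALSE] +
    dY[A[, 3], , drop = FALSE] + dY[A[, 4], , drop = FALSE]
}

gap_fwd <- function(x, sh) {
  # global average pool: one value per channel per image
  HW <- sh[1] * sh[2]; N <- sh[4]
  g <- rep(seq_len(N), each = HW)
  list(out = rowsum(x, g) / HW, cache = list(g = g, HW = HW))
}
gap_bwd <- function(dY, cache) dY[cache$g, , drop = FALSE] / cache$HW

make_dense <- function(din, dout) {
  list(W = matrix(stats::rnorm(din * dout, sd = sqrt(2 / din)), din, dout),
       b = numeric(dout))
}
dense_fwd <- function(lay, x) {
  list(out = x %*% lay$W + rep(lay$b, each = nrow(x)), cache = x)
}
dense_bwd <- function(lay, dY, cache) {
  list(dW = crossprod(cache, dY), db = colSums(dY), dx = dY %*% t(lay$W))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# stack a list of H x W matrices into the (N*H*W) x 1 activation layout
stack_images <- function(imgs) {
  matrix(unlist(imgs, use.names = FALSE), ncol = 1L)
}

# -- Adam ---------------------------------------------------------------
# `pars` is a flat named list whose elements are lists holding numeric
# parameter arrays named W/b; grads mirrors that structure.

adam_init <- function() list(t = 0L, m = list(), v = list())

adam_step <- function(pars, grads, st, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  b1t <- 1 - beta1^st$t
  b2t <- 1 - beta2^st$t
  for (nm in names(grads)) {
    for (p in names(grads[[nm]])) {
      key <- paste0(nm, ".", p)
      g <- grads[[nm]][[p]]
      if (weight_decay > 0 && p == "W") g <- g + weight_decay * pars[[nm]][[p]]
      m <- st$m[[key]] %||% (g * 0)
      v <- st$v[[key]] %||% (g * 0)
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      st$m[[key]] <- m
      st$v[[key]] <- v
      pars[[nm]][[p]] <- pars[[nm]][[p]] - lr * (m / b1t) / (sqrt(v / b2t) + eps)
    }
  }
  list(pars = pars, st = st)
}
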