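# Synthetic mammogram phantoms.
#
# Each phantom is a small grayscale image on a smooth parenchyma-like
# background: `normal` carries no mass, `benign` a compact isotropic
# Gaussian blob, `malignant` the same blob with 4-8 radial spiculation
# arms (irregular margins being the geometric hallmark of malignancy).
# Images are corrupted with salt-and-pepper impulses at a configurable
# rate, and every phantom carries a ground-truth mask thresholded at
# half-maximum of the noise-free mass field, so segmentation and
# classification stages can be trained and scored without external data.

PHANTOM_CLASSES <- c("normal", "benign", "malignant")

#' Generate one synthetic phantom
#'
#' @param label one of `"normal"`, `"benign"`, `"malignant"`.
#' @param size image side in pixels (square), at least 16.
#' @param noise_rate fraction of pixels replaced by salt-and-pepper
#'   impulses (exact 0 or 1 values), in `[0, 0.5)`.
#' @param seed integer seed; the same arguments and seed always produce
#'   pixel-identical output.
#' @return An object of class `phantom`: a list with `image` (numeric
#'   matrix in `[0, 1]`), `mask` (0/1 integer matrix, all zero for
#'   normals), `label`, and `seed`.
#' @examples
#' p <- generate_phantom("malignant", size = 64, noise_rate = 0.05, seed = 7)
#' range(p$image); sum(p$mask)
#' @export
generate_phantom <- function(label, size = 32L, noise_rate = 0.05, seed = 1L) {
  label <- as.character(label)
  if (length(label) != 1L || !label %in% PHANTOM_CLASSES)
    stop("unknown label '", label, "'; expected one of: ",
         paste(PHANTOM_CLASSES, collapse = ", "), call. = FALSE)
  size <- as.integer(size)
  if (size < 16L) stop("size must be >= 16 pixels", call. = FALSE)
  if (noise_rate < 0 || noise_rate >= 0.5)
    stop("noise_rate must lie in [0, 0.5)", call. = FALSE)

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  bg <- phantom_background(size)
  if (label == "normal") {
    blob <- matrix(0, size, size)
    mask <- matrix(0L, size, size)
  } else {
    blob <- phantom_mass(size, spiculated = label == "malignant")
    mask <- matrix(as.integer(blob >= 0.5 * max(blob)), size, size)
  }
  img <- clamp(bg + blob, 0.02, 0.98)  # keep clean pixels strictly inside (0,1)

  n_imp <- round(noise_rate * size * size)
  if (n_imp > 0L) {
    at <- sample.int(size * size, n_imp)
    img[at] <- as.numeric(stats::runif(n_imp) < 0.5)
  }
  structure(list(image = img, mask = mask, label = label, seed = seed,
                 n_impulses = n_imp),
            class = "phantom")
}

# smooth low-frequency background in [0.15, 0.45], emulating parenchymal
# texture: coarse uniform grid, bilinearly upsampled
phantom_background <- function(size) {
  nc <- max(4L, size %/% 8L) + 1L
  g <- matrix(stats::runif(nc * nc), nc, nc)
  at <- seq(1, nc, length.out = size)
  i0 <- pmin(floor(at), nc - 1L); fi <- at - i0
  row_interp <- g[i0, , drop = FALSE] * (1 - fi) + g[i0 + 1L, , drop = FALSE] * fi
  up <- row_interp[, i0, drop = FALSE] * rep(1 - fi, each = size) +
        row_interp[, i0 + 1L, drop = FALSE] * rep(fi, each = size)
  0.15 + 0.3 * up
}

# noise-free mass field: Gaussian blob, optionally with radial arms whose
# intensity decays along their length so the half-maximum mask keeps the
# proximal part of each arm (-> irregular, spiculated outline)
phantom_mass <- function(size, spiculated) {
  cx <- stats::runif(1, 0.38, 0.62) * size
  cy <- stats::runif(1, 0.38, 0.62) * size
  sigma <- size / 8 * stats::runif(1, 0.9, 1.1)
  amp <- stats::runif(1, 0.45, 0.55)
  xs <- matrix(rep(seq_len(size), each = size), size)   # column coord
  ys <- matrix(rep(seq_len(size), times = size), size)  # row coord
  dx <- xs - cx; dy <- ys - cy
  blob <- amp * exp(-(dx^2 + dy^2) / (2 * sigma^2))
  if (!spiculated) return(blob)
  n_arm <- sample(4:8, 1L)
  theta <- stats::runif(1, 0, 2 * pi) + seq(0, 2 * pi, length.out = n_arm + 1L)[-1] +
    stats::runif(n_arm, -0.25, 0.25)
  # arm width sits above the resolution limit of a 3x3 median filter, so
  # spiculation survives the pipeline's own denoising step
  wid <- max(1.5, sigma / 3)
  for (k in seq_len(n_arm)) {
    len <- stats::runif(1, 2.2, 3.5) * sigma
    along <- dx * cos(theta[k]) + dy * sin(theta[k])
    perp  <- -dx * sin(theta[k]) + dy * cos(theta[k])
    fall <- pmax(0, 0.9 - 0.55 * along / len)        # 0.9 at base -> 0.35 at tip
    fall[along < 0 | along > len] <- 0
    blob <- pmax(blob, amp * fall * exp(-perp^2 / (2 * wid^2)))
  }
  blob
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("phantom: %s, %dx%d, %d mask px, %d impulses (seed %d)\n",
              x$label, nrow(x$image), ncol(x$image), sum(x$mask),
              x$n_impulses, x$seed))
  invisible(x)
}

#' Generate a phantom dataset on disk
#'
#' Writes `n_per_class` phantoms per class as 8-bit grayscale PNGs, mask
#' PNGs for the lesion classes, and a CSV manifest with columns
#' `path,mask_path,label` (mask_path empty for normals).  Deterministic:
#' the same arguments and seed give byte-identical files.
#'
#' @param n_per_class phantoms per class (>= 1).
#' @param size,noise_rate,seed forwarded to [generate_phantom()]; each
#'   phantom gets its own seed derived from `seed`.
#' @param out_dir output directory, created if needed.
#' @return A `dataset_manifest`: data.frame with columns `path`,
#'   `mask_path`, `label`, plus a `class_counts` attribute.
#' @export
generate_dataset <- function(n_per_class, size = 32L, noise_rate = 0.05,
                             seed = 1L, out_dir) {
  if (n_per_class < 1L) stop("n_per_class must be >= 1", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create out_dir: ", out_dir, call. = FALSE)
  rows <- list(); i <- 0L
  for (label in PHANTOM_CLASSES) {
    for (k in seq_len(n_per_class)) {
      i <- i + 1L
      p <- generate_phantom(label, size, noise_rate,
                            seed = derive_seed(seed, sprintf("phantom-%s-%d", label, k)))
      img_path <- file.path(out_dir, sprintf("img_%04d_%s.png", i, label))
      write_image(p$image, img_path)
      mask_path <- ""
      if (label != "normal") {
        mask_path <- file.path(out_dir, sprintf("mask_%04d.png", i))
        write_image(p$mask + 0, mask_path)
      }
      rows[[i]] <- data.frame(path = img_path, mask_path = mask_path,
                              label = label, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  as_manifest(manifest)
}

as_manifest <- function(df) {
  stopifnot(all(c("path", "mask_path", "label") %in% names(df)))
  if (anyDuplicated(df$path)) stop("duplicate image paths in manifest", call. = FALSE)
  attr(df, "class_counts") <- table(factor(df$label, levels = PHANTOM_CLASSES))
  class(df) <- c("dataset_manifest", "data.frame")
  df
}

#' Read a dataset manifest CSV
#'
#' @param path CSV with header `path,mask_path,label`; relative image
#'   paths are resolved against the manifest's directory.
#' @return A `dataset_manifest` data.frame.
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$mask_path[is.na(df$mask_path)] <- ""
  rel <- !file.exists(df$path) & file.exists(file.path(dirname(path), df$path))
  df$path[rel] <- file.path(dirname(path), df$path[rel])
  relm <- nzchar(df$mask_path) & !file.exists(df$mask_path) &
    file.exists(file.path(dirname(path), df$mask_path))
  df$mask_path[relm] <- file.path(dirname(path), df$mask_path[relm])
  as_manifest(df)
}

#' Load manifest records into phantom objects
#'
#' Normals (empty `mask_path`) get an all-zero mask.
#'
#' @param manifest a `dataset_manifest`.
#' @return List of `phantom` objects.
#' @export
load_phantoms <- function(manifest) {
  lapply(seq_len(nrow(manifest)), function(i) {
    img <- read_image(manifest$path[i])
    mask <- if (nzchar(manifest$mask_path[i])) {
      m <- read_image(manifest$mask_path[i])
      matrix(as.integer(m > 0.5), nrow(m), ncol(m))
    } else matrix(0L, nrow(img), ncol(img))
    structure(list(image = img, mask = mask, label = manifest$label[i],
                   seed = NA_integer_, n_impulses = NA_integer_),
              class = "phantom")
  })
}
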