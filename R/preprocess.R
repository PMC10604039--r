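# Pre-processing: intensity normalization and median-filter denoising.
# The median filter is the pipeline's impulse-noise removal step: every
# pixel is replaced by the median of its window x window neighbourhood,
# which deletes isolated salt-and-pepper impulses while keeping step
# edges in place.

#' Rescale image intensities to the unit interval
#'
#' 8-bit input (max value > 1) is divided by 255; input already in
#' `[0, 1]` is returned unchanged, so the map is idempotent.
#'
#' @param img numeric matrix of intensities.
#' @return Numeric matrix with values in `[0, 1]`.
#' @export
normalize_intensity <- function(img) {
  stop_if_not_image(img)
  if (max(img) > 1) img <- img / 255
  clamp(img, 0, 1)
}

#' Median filter with edge replication
#'
#' Replaces each pixel with the median of the `window` x `window`
#' neighbourhood centred on it.  Borders are handled by replicating the
#' edge rows/columns, so the output has the same shape as the input and
#' every output value is drawn from the multiset of input values in its
#' neighbourhood.
#'
#' @param img numeric matrix in `[0, 1]`.
#' @param window odd integer window side, `>= 3`; edge replication
#'   makes any window size well-defined, including on single-row
#'   images.
#' @return The filtered image, same shape as `img`.
#' @examples
#' m <- matrix(0.2, 5, 5); m[3, 3] <- 1
#' median_filter(m, 3)  # the isolated impulse disappears
#' @export
median_filter <- function(img, window = 3L) {
  stop_if_not_image(img)
  window <- as.integer(window)
  if (length(window) != 1L || is.na(window) || window < 3L || window %% 2L == 0L)
    stop("window must be an odd integer >= 3", call. = FALSE)
  h <- nrow(img); w <- ncol(img)
  r <- window %/% 2L
  # replicate-pad, then gather each neighbourhood as one row of `patch`
  ri <- clamp(seq_len(h + 2L * r) - r, 1L, h)
  ci <- clamp(seq_len(w + 2L * r) - r, 1L, w)
  pad <- img[ri, ci, drop = FALSE]
  hp <- h + 2L * r
  base <- as.vector(outer(seq_len(h) + r, (seq_len(w) + r - 1L) * hp, `+`))
  off <- as.vector(outer(-r:r, (-r:r) * hp, `+`))
  patch <- matrix(pad[rep(base, times = length(off)) +
                      rep(off, each = length(base))],
                  nrow = length(base))
  out <- apply(patch, 1L, stats::median)
  matrix(out, nrow = h, ncol = w)
}
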