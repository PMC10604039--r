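# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child seed from a global seed and a stage name
#'
#' Every stochastic stage of the pipeline draws its own seed
#' deterministically from the global run seed and a stage label, so stages
#' can be re-run in isolation and still reproduce the full run.
#'
#' @param seed integer global seed.
#' @param stage character stage label.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  # small multiplicative hash of the stage label, folded into 31 bits
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 2147483647
  as.integer((as.numeric(seed) + h) %% 2147483647)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stop_if_not_image <- function(img) {
  if (!is.matrix(img) || !is.numeric(img) || length(img) == 0L)
    stop("expected a non-empty numeric matrix image", call. = FALSE)
  if (any(!is.finite(img)))
    stop("image contains non-finite values", call. = FALSE)
  invisible(img)
}

# round-half-up to `digits`, the convention used for reported percentages
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}
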