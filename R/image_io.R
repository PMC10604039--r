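# Grayscale image I/O: 8-bit PNG via the png package, plus plain/raw PGM
# (the native format of classic mammography archives).  All images are
# handled in memory as numeric matrices with values in [0, 1], indexed
# [row, column].

#' Read a grayscale image
#'
#' Supports 8-bit grayscale PNG and PGM (both plain `P2` and binary `P5`).
#' Multichannel PNGs are reduced to grayscale by averaging the colour
#' channels.
#'
#' @param path file path ending in `.png` or `.pgm` (case-insensitive).
#' @return A numeric matrix with values in `[0, 1]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("no such image file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = {
      x <- png::readPNG(path)
      if (length(dim(x)) == 3L) x <- apply(x[, , 1:min(3L, dim(x)[3]), drop = FALSE], c(1, 2), mean)
      x
    },
    pgm = read_pgm(path),
    stop("unsupported image extension '", ext, "' (use png or pgm)", call. = FALSE)
  )
  stop_if_not_image(img)
  clamp(img, 0, 1)
}

#' Write a grayscale image
#'
#' Values are clamped to `[0, 1]` and quantized to 8 bits.
#'
#' @param img numeric matrix in `[0, 1]`.
#' @param path destination ending in `.png` or `.pgm`.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  stop_if_not_image(img)
  img <- clamp(img, 0, 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img, target = path),
    pgm = write_pgm(img, path),
    stop("unsupported image extension '", ext, "' (use png or pgm)", call. = FALSE)
  )
  invisible(path)
}

# -- PGM ----------------------------------------------------------------

read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 2L))
  if (!magic %in% c("P2", "P5"))
    stop("not a PGM file (magic '", magic, "'): ", path, call. = FALSE)
  # header tokens: width height maxval, with '#' comments allowed
  tok <- character(0)
  buf <- character(0)
  in_comment <- FALSE
  while (length(tok) < 3L) {
    ch <- rawToChar(readBin(con, "raw", 1L))
    if (length(ch) == 0L || ch == "") stop("truncated PGM header: ", path, call. = FALSE)
    if (ch == "#") in_comment <- TRUE
    if (ch == "\n") in_comment <- FALSE
    if (in_comment) next
    if (grepl("[[:space:]]", ch)) {
      if (length(buf)) { tok <- c(tok, paste(buf, collapse = "")); buf <- character(0) }
    } else buf <- c(buf, ch)
  }
  w <- as.integer(tok[1]); h <- as.integer(tok[2]); maxval <- as.integer(tok[3])
  if (anyNA(c(w, h, maxval)) || w < 1L || h < 1L || maxval < 1L)
    stop("malformed PGM header: ", path, call. = FALSE)
  vals <- if (magic == "P5") {
    as.integer(readBin(con, "raw", w * h))
  } else {
    scan(con, what = integer(), n = w * h, quiet = TRUE)
  }
  if (length(vals) != w * h) stop("truncated PGM data: ", path, call. = FALSE)
  matrix(vals / maxval, nrow = h, ncol = w, byrow = TRUE)
}

write_pgm <- function(img, path) {
  v <- round(t(img) * 255)  # row-major order
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P2\n%d %d\n255\n", ncol(img), nrow(img)), con, eos = NULL)
  writeChar(paste(as.integer(v), collapse = "\n"), con, eos = NULL)
  writeChar("\n", con, eos = NULL)
  invisible(path)
}
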