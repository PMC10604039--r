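# Evaluation: stratified train/test splitting, confusion matrices, and
# per-class one-vs-rest metrics reported the way CAD studies tabulate
# them — accuracy, sensitivity, specificity and F-measure per class as
# percentages, plus an unweighted Average row.

#' Split a dataset into train and test partitions
#'
#' The ratio is given training-share first ("70:30" = 70% training,
#' 30% testing).  With stratification (the default) each class is split
#' at the same ratio, so 1000 records with 300/350/350 per class at
#' 70:30 give exactly 700 training and 300 testing records.
#'
#' @param manifest a `dataset_manifest` (or any data.frame with a
#'   `label` column).
#' @param ratio `"60:40"`, `"70:30"`, or any `"a:b"` with positive
#'   parts; alternatively a single numeric training fraction.
#' @param seed integer seed.
#' @param stratify split each class separately (default TRUE).
#' @return List with `train` and `test` manifests: a disjoint,
#'   exhaustive partition of the input rows.
#' @export
split_dataset <- function(manifest, ratio = "70:30", seed = 1L, stratify = TRUE) {
  if (is.character(ratio)) {
    parts <- as.numeric(strsplit(ratio, ":", fixed = TRUE)[[1]])
    if (length(parts) != 2L || anyNA(parts) || any(parts <= 0))
      stop("ratio must be 'a:b' with positive parts", call. = FALSE)
    frac <- parts[1] / sum(parts)
  } else {
    frac <- as.numeric(ratio)
    if (is.na(frac) || frac <= 0 || frac >= 1)
      stop("numeric ratio must be a training fraction in (0, 1)", call. = FALSE)
  }
  labels <- manifest$label
  n <- length(labels)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  if (stratify) {
    idx_tr <- integer(0)
    for (k in unique(labels)) {
      at <- which(labels == k)
      if (length(at) < 2L)
        stop("class '", k, "' has fewer than 2 samples; cannot stratify",
             call. = FALSE)
      idx_tr <- c(idx_tr, at[sample.int(length(at))][seq_len(round(frac * length(at)))])
    }
  } else {
    idx_tr <- sample.int(n)[seq_len(round(frac * n))]
  }
  idx_tr <- sort(idx_tr)
  list(train = keep_manifest_class(manifest[idx_tr, , drop = FALSE]),
       test = keep_manifest_class(manifest[-idx_tr, , drop = FALSE]))
}

keep_manifest_class <- function(df) {
  rownames(df) <- NULL
  if (all(c("path", "mask_path", "label") %in% names(df))) as_manifest(df) else df
}

#' Confusion matrix
#'
#' @param y_true,y_pred equal-length label vectors.
#' @param class_order label ordering for rows/columns; defaults to the
#'   sorted union of observed labels.  Labels outside it are an error.
#' @return A `confusion_matrix`: K x K integer matrix, rows = true
#'   class, columns = predicted class.
#' @export
confusion <- function(y_true, y_pred, class_order = NULL) {
  if (length(y_true) != length(y_pred))
    stop("label vectors differ in length", call. = FALSE)
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (is.null(class_order)) class_order <- sort(unique(c(y_true, y_pred)))
  bad <- setdiff(unique(c(y_true, y_pred)), class_order)
  if (length(bad))
    stop("labels outside class_order: ", paste(bad, collapse = ", "),
         call. = FALSE)
  cm <- table(factor(y_true, levels = class_order),
              factor(y_pred, levels = class_order))
  cm <- matrix(as.integer(cm), length(class_order),
               dimnames = list(true = class_order, predicted = class_order))
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

#' Per-class one-vs-rest metrics report
#'
#' For each class k, treating k as positive and the rest as negative:
#' accuracy `(TP+TN)/total`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, and F-measure `2*prec*sens/(prec+sens)` with per-class
#' precision `TP/(TP+FP)`.  Metrics are reported as percentages rounded
#' half-up to 2 decimals, with an unweighted Average row; the raw
#' fractions are kept in the `"raw"` attribute.  A zero denominator
#' yields 0 with a warning.
#'
#' @param cm a `confusion_matrix`.
#' @return An `eval_report` data.frame with columns `Class`, `Accuracy`,
#'   `Sensitivity`, `Specificity`, `FMeasure`.
#' @export
per_class_metrics <- function(cm) {
  if (sum(cm) == 0) stop("empty confusion matrix", call. = FALSE)
  classes <- rownames(cm)
  total <- sum(cm)
  safe_div <- function(num, den, what, k) {
    if (den == 0) {
      warning("zero denominator for ", what, " of class '", k, "'; reporting 0",
              call. = FALSE)
      return(0)
    }
    num / den
  }
  raw <- t(vapply(seq_along(classes), function(i) {
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp
    tn <- total - tp - fn - fp
    k <- classes[i]
    prec <- safe_div(tp, tp + fp, "precision", k)
    sens <- safe_div(tp, tp + fn, "sensitivity", k)
    c(accuracy = (tp + tn) / total,
      sensitivity = sens,
      specificity = safe_div(tn, tn + fp, "specificity", k),
      f_measure = if (prec + sens == 0) {
        warning("zero denominator for F-measure of class '", k,
                "'; reporting 0", call. = FALSE)
        0
      } else 2 * prec * sens / (prec + sens))
  }, numeric(4)))
  rownames(raw) <- classes
  raw <- rbind(raw, Average = colMeans(raw))
  report <- data.frame(Class = rownames(raw),
                       Accuracy = round_half_up(100 * raw[, "accuracy"]),
                       Sensitivity = round_half_up(100 * raw[, "sensitivity"]),
                       Specificity = round_half_up(100 * raw[, "specificity"]),
                       FMeasure = round_half_up(100 * raw[, "f_measure"]),
                       row.names = NULL, stringsAsFactors = FALSE)
  attr(report, "raw") <- raw
  class(report) <- c("eval_report", "data.frame")
  report
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Per-class metrics (%, one-vs-rest):\n")
  print.data.frame(x, row.names = FALSE, digits = 5)
  invisible(x)
}

#' Write an evaluation report to CSV or JSON
#'
#' @param report an `eval_report`.
#' @param path destination ending in `.csv` or `.json`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  ext <- tolower(tools::file_ext(path))
  df <- as.data.frame(report)
  switch(ext,
    csv = utils::write.csv(df, path, row.names = FALSE, quote = FALSE),
    json = jsonlite::write_json(df, path, digits = NA),
    stop("unsupported report extension '", ext, "'", call. = FALSE))
  invisible(path)
}

#' Read an evaluation report written by [write_report()]
#'
#' @param path `.csv` or `.json` file.
#' @return An `eval_report` data.frame (percent values only; the raw
#'   fractions are not serialized).
#' @export
read_report <- function(path) {
  ext <- tolower(tools::file_ext(path))
  df <- switch(ext,
    csv = utils::read.csv(path, stringsAsFactors = FALSE),
    json = as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE)),
    stop("unsupported report extension '", ext, "'", call. = FALSE))
  class(df) <- c("eval_report", "data.frame")
  df
}
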