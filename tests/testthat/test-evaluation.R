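fake_manifest <- function(counts) {
  labs <- rep(names(counts), times = counts)
  data.frame(path = sprintf("img%04d.png", seq_along(labs)),
             mask_path = "", label = labs, stringsAsFactors = FALSE)
}

test_that("70:30 stratified split of 300/350/350 gives exactly 700/300", {
  mf <- fake_manifest(c(normal = 300, benign = 350, malignant = 350))
  sp <- split_dataset(mf, "70:30", seed = 1)
  expect_equal(nrow(sp$train), 700)
  expect_equal(nrow(sp$test), 300)
  expect_equal(unname(table(sp$train$label)[c("normal", "benign", "malignant")]),
               unname(c(210L, 245L, 245L)), ignore_attr = TRUE)
  # partition: disjoint and exhaustive
  expect_length(intersect(sp$train$path, sp$test$path), 0)
  expect_setequal(c(sp$train$path, sp$test$path), mf$path)
})

test_that("60:40 split of 30 balanced records keeps class balance", {
  mf <- fake_manifest(c(normal = 10, benign = 10, malignant = 10))
  sp <- split_dataset(mf, "60:40", seed = 2)
  expect_equal(unname(table(sp$train$label)), rep(6L, 3), ignore_attr = TRUE)
  expect_equal(unname(table(sp$test$label)), rep(4L, 3), ignore_attr = TRUE)
})

test_that("splits are deterministic and validate their inputs", {
  mf <- fake_manifest(c(normal = 10, benign = 10, malignant = 10))
  a <- split_dataset(mf, "70:30", seed = 7)
  b <- split_dataset(mf, "70:30", seed = 7)
  expect_identical(a$train$path, b$train$path)
  expect_error(split_dataset(mf, "0:30"), "positive")
  expect_error(split_dataset(fake_manifest(c(normal = 1, benign = 5)), "60:40"),
               "fewer than 2")
})

test_that("confusion matrices tally correctly and reject unknown labels", {
  yt <- c("a", "a", "a", "b", "b", "b", "c", "c", "c")
  yp <- c("a", "a", "b", "b", "b", "c", "c", "a", "c")
  cm <- confusion(yt, yp, c("a", "b", "c"))
  expect_equal(unname(cm["a", ]), c(2L, 1L, 0L), ignore_attr = TRUE)
  expect_equal(unname(cm["b", ]), c(0L, 2L, 1L), ignore_attr = TRUE)
  expect_equal(unname(cm["c", ]), c(1L, 0L, 2L), ignore_attr = TRUE)
  expect_equal(sum(cm), 9)
  perfect <- confusion(yt, yt)
  expect_true(all(perfect[upper.tri(perfect) | lower.tri(perfect)] == 0))
  expect_error(confusion(yt, yp, c("a", "b")), "outside")
})

test_that("per-class metrics match hand-computed values on a 2-class matrix", {
  cm <- confusion(rep(c("x", "y"), c(10, 10)),
                  c(rep("x", 8), "y", "y", "x", rep("y", 9)),
                  c("x", "y"))
  expect_equal(unname(cm[1, ]), c(8L, 2L), ignore_attr = TRUE)
  rep_ <- per_class_metrics(cm)
  x <- rep_[rep_$Class == "x", ]
  expect_equal(x$Sensitivity, 80.00)
  expect_equal(x$Specificity, 90.00)
  expect_equal(x$Accuracy, 85.00)
  prec <- 8 / 9
  expect_equal(x$FMeasure, round(100 * 2 * prec * 0.8 / (prec + 0.8), 2))
  # binary one-vs-rest duality
  y <- rep_[rep_$Class == "y", ]
  expect_equal(x$Sensitivity, per_class_metrics(cm)[2, "Specificity"])
  expect_equal(y$Sensitivity, x$Specificity)
})

test_that("perfect predictions give 100.00 everywhere", {
  cm <- confusion(c("a", "b", "c"), c("a", "b", "c"))
  rep_ <- per_class_metrics(cm)
  expect_true(all(as.matrix(rep_[, -1]) == 100))
})

test_that("metrics agree with a brute-force implementation on random matrices", {
  set.seed(99)
  for (r in 1:100) {
    K <- sample(2:4, 1)
    cm <- matrix(rpois(K * K, 5), K, K,
                 dimnames = list(letters[1:K], letters[1:K]))
    if (sum(cm) == 0) cm[1, 1] <- 1
    class(cm) <- c("confusion_matrix", class(cm))
    got <- suppressWarnings(attr(per_class_metrics(cm), "raw"))
    want <- brute_metrics(cm)
    expect_equal(unname(got[1:K, ]), unname(want), tolerance = 1e-12)
    # Average row is the unweighted mean of the class rows
    expect_equal(unname(got["Average", ]), unname(colMeans(want)))
  }
})

test_that("zero denominators report 0 with a warning", {
  cm <- matrix(c(5L, 3L, 0L, 0L), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  class(cm) <- c("confusion_matrix", class(cm))
  w <- capture_warnings(rep_ <- per_class_metrics(cm))
  expect_gte(length(w), 1)
  expect_match(w, "zero denominator", all = TRUE)
  expect_equal(rep_[rep_$Class == "b", "Sensitivity"], 0)
})

test_that("reports round-trip through CSV and JSON", {
  cm <- confusion(rep(c("a", "b", "c"), times = c(5, 6, 7)),
                  c(rep("a", 4), "b", rep("b", 5), "c", rep("c", 6), "a"))
  rep_ <- per_class_metrics(cm)
  for (ext in c(".csv", ".json")) {
    path <- tempfile(fileext = ext)
    write_report(rep_, path)
    back <- read_report(path)
    expect_equal(back$Class, rep_$Class)
    for (col in c("Accuracy", "Sensitivity", "Specificity", "FMeasure"))
      expect_equal(back[[col]], rep_[[col]])
  }
})
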