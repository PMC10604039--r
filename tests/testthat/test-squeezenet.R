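test_that("architecture invariants are enforced at build time", {
  expect_error(squeezenet_spec(fire_n = rep(2L, 7)), "exactly 8")
  expect_error(squeezenet_spec(fire_n = c(rep(2L, 7), 0L)), ">= 1")
  expect_error(squeezenet_spec(in_size = 20), "divisible by 8")
  expect_error(build_squeezenet(squeezenet_spec(), n_classes = 1), "n_classes")
  expect_equal(fire_out_channels(4), 32L)  # 4n + 4n expand channels
  m <- build_squeezenet(squeezenet_spec(fire_n = c(4L, rep(2L, 7))), 3, seed = 1)
  expect_equal(m$pars$f1e1$Cout, 16L)
  expect_equal(m$pars$f1e3$Cout, 16L)
  expect_equal(m$pars$f2s$Cin, 32L)  # next squeeze sees the 8n concat
})

test_that("builds are seed-deterministic and probabilities normalize", {
  spec <- squeezenet_spec(fire_n = rep(2L, 8), stem = 4L, head_width = 8L,
                          in_size = 16L)
  a <- build_squeezenet(spec, 3, seed = 9)
  b <- build_squeezenet(spec, 3, seed = 9)
  expect_identical(a$pars, b$pars)
  a$classes <- c("x", "y", "z")
  img <- matrix(runif(256), 16, 16)
  pr <- predict(a, img, type = "prob")
  expect_equal(sum(pr), 1, tolerance = 1e-6)
  expect_true(all(pr >= 0))
})

test_that("spatial resolution halves at each stated pooling stage", {
  # stem pool + pools after fire 2 and fire 4: 64 px -> 8x8 before the head
  spec <- squeezenet_spec(fire_n = rep(2L, 8), stem = 4L, head_width = 8L,
                          in_size = 64L)
  m <- build_squeezenet(spec, 2, seed = 1)
  fw <- mammoCAD:::squeezenet_forward(m, matrix(runif(64 * 64), ncol = 1), 1L)
  expect_equal(fw$caches$gap$HW, 8L * 8L)
})

test_that("feature extraction is a pure deterministic function with fixed dim", {
  spec <- squeezenet_spec(fire_n = rep(4L, 8), stem = 8L, head_width = 8L,
                          in_size = 16L)
  m <- build_squeezenet(spec, 3, seed = 2)
  i1 <- generate_phantom("benign", 16, 0, seed = 1)$image
  i2 <- generate_phantom("normal", 16, 0, seed = 2)$image
  f1 <- extract_features(m, i1)
  expect_length(f1, 8L)  # the head's input width
  expect_identical(f1, extract_features(m, i1))
  expect_false(identical(f1, extract_features(m, i2)))
  fm <- extract_features(m, list(i1, i2))
  expect_equal(dim(fm), c(2L, 8L))
  expect_equal(fm[1, ], f1)
  expect_error(extract_features(m, matrix(0, 8, 8)), "input size")
})

test_that("training descends, records traces, and epochs = 0 returns untrained", {
  phans <- make_phantom_set(4, size = 16, seed0 = 700)
  imgs <- lapply(phans, `[[`, "image")
  labs <- vapply(phans, `[[`, character(1), "label")
  spec <- squeezenet_spec(fire_n = rep(2L, 8), stem = 4L, head_width = 8L,
                          in_size = 16L)
  m0 <- build_squeezenet(spec, 3, seed = 1)
  mz <- train_squeezenet(m0, imgs, labs, hyper = list(epochs = 0))
  expect_identical(mz$pars, m0$pars)
  expect_length(mz$history$loss, 0)
  drops <- vapply(1:3, function(s) {
    m <- build_squeezenet(spec, 3, seed = s)
    m <- train_squeezenet(m, imgs, labs,
                          hyper = list(lr = 2e-3, batch = 6, epochs = 4,
                                       weight_decay = 0), seed = s)
    m$history$loss[1] - m$history$loss[4]
  }, numeric(1))
  expect_gte(median(drops), 0)
  # validation precision trace
  m <- build_squeezenet(spec, 3, seed = 1)
  m <- train_squeezenet(m, imgs, labs, hyper = list(lr = 2e-3, epochs = 2),
                        seed = 1, val_images = imgs, val_labels = labs)
  expect_length(m$history$val_precision, 2L)
  expect_true(all(is.finite(m$history$val_precision)))
  expect_error(train_squeezenet(m0, list(), character(0)), "empty")
})

test_that("dihedral augmentation produces 8 label-preserving variants", {
  img <- matrix(runif(64), 8, 8)
  a <- mammoCAD:::augment_dihedral(list(img), "benign")
  expect_length(a$images, 8L)
  expect_equal(unique(a$labels), "benign")
  expect_equal(a$images[[1]], img)
  # all variants are distinct views of the same multiset of pixels
  for (v in a$images) expect_equal(sort(as.vector(v)), sort(as.vector(img)))
  expect_equal(length(unique(lapply(a$images, as.vector))), 8L)
})
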