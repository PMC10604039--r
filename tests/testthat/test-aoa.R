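sphere5 <- function() {
  search_space(lapply(1:5, function(i)
    list(name = paste0("x", i), lower = -5, upper = 5)))
}

test_that("configuration and search-space invariants are enforced", {
  expect_error(aoa_config(N = 1), "N must be >= 2")
  expect_error(aoa_config(tmax = 0), "tmax")
  expect_error(aoa_config(norm_range = c(0.9, 0.1)), "norm_range")
  expect_error(search_space(list(list(name = "a", lower = 2, upper = 1))),
               "lower < upper")
  expect_error(search_space(list(list(name = "a", lower = -1, upper = 1,
                                      scale = "log"))), "positive")
})

test_that("transfer function and density factor match their closed forms", {
  expect_equal(transfer_function(100, 100), 1.0)
  expect_equal(transfer_function(0, 100), exp(-1))
  expect_equal(density_factor(100, 100), 0.0)
  expect_equal(density_factor(50, 100), exp(-0.5) - 0.5)
  # monotone increase of TF; d larger early than at the end
  tf <- transfer_function(1:200, 200)
  expect_true(all(diff(tf) > 0))
  expect_gt(density_factor(1, 200), density_factor(200, 200))
  expect_error(transfer_function(5, 0), "tmax")
})

test_that("population initialization honours bounds, ranges and determinism", {
  cfg <- aoa_config(N = 20, tmax = 10, seed = 1)
  f <- function(x) sum(x^2)
  set.seed(5)
  st <- init_population(cfg, rep(-5, 5), rep(5, 5), f)
  expect_equal(dim(st$x), c(20, 5))
  expect_true(all(st$x >= -5 & st$x <= 5))
  expect_true(all(st$den > 0 & st$den < 1))
  expect_true(all(st$vol > 0 & st$vol < 1))
  expect_true(all(st$acc >= -5 & st$acc <= 5))
  expect_equal(st$best$fitness, min(st$fitness))
  # zero-range bounds pin every position
  set.seed(5)
  st2 <- init_population(cfg, rep(2, 3), rep(2, 3), f)
  expect_true(all(st2$x == 2))
  # determinism
  set.seed(9); a <- init_population(cfg, rep(-1, 2), rep(1, 2), f)
  set.seed(9); b <- init_population(cfg, rep(-1, 2), rep(1, 2), f)
  expect_identical(a, b)
  expect_error(init_population(cfg, c(1, 0), c(0, 1), f), "lower")
})

test_that("density/volume updates contract toward the best object", {
  cfg <- aoa_config(N = 4, tmax = 10)
  set.seed(2)
  st <- init_population(cfg, rep(0, 3), rep(1, 3), function(x) sum(x))
  # rand forced to 1: everything lands exactly on the best values
  r1 <- matrix(1, 4, 3)
  st1 <- update_density_volume(st, rand_den = r1, rand_vol = r1)
  expect_equal(st1$den, matrix(rep(st$best$den, each = 4), 4, 3))
  # already at best: no movement regardless of rand
  st$den <- matrix(rep(st$best$den, each = 4), 4, 3)
  st2 <- update_density_volume(st, rand_den = matrix(runif(12), 4, 3),
                               rand_vol = matrix(runif(12), 4, 3))
  expect_equal(st2$den, st$den)
  # general contraction, elementwise
  set.seed(3)
  st3 <- init_population(cfg, rep(0, 3), rep(1, 3), function(x) sum(x))
  st4 <- update_density_volume(st3)
  bd <- matrix(rep(st3$best$den, each = 4), 4, 3)
  expect_true(all(abs(st4$den - bd) <= abs(st3$den - bd) + 1e-12))
})

test_that("acceleration update matches hand-evaluated equations and normalizes", {
  cfg <- aoa_config(N = 2, tmax = 10)
  set.seed(4)
  st <- init_population(cfg, -5, 5, function(x) x^2)
  st$den <- matrix(c(0.2, 0.6), 2, 1)
  st$vol <- matrix(c(0.5, 0.25), 2, 1)
  st$acc <- matrix(c(1.5, -2), 2, 1)
  st$best <- list(x = 0.5, den = 0.7, vol = 0.9, acc = 1.2, fitness = 0.25)
  # exploration branch (TF <= 0.5), materials chosen as the other object
  st_e <- update_acceleration(st, TF = 0.4, mr = c(2L, 1L))
  expect_equal(st_e$acc[1, 1], (0.6 + 0.25 * (-2)) / (0.2 * 0.5))
  expect_equal(st_e$acc[2, 1], (0.2 + 0.5 * 1.5) / (0.6 * 0.25))
  expect_true(all(st_e$acc_norm >= 0.1 - 1e-12 & st_e$acc_norm <= 0.9 + 1e-12))
  # exploitation branch (TF > 0.5) pulls from the best object
  st_x <- update_acceleration(st, TF = 0.8)
  expect_equal(st_x$acc[1, 1], (0.7 + 0.9 * 1.2) / (0.2 * 0.5))
  expect_equal(st_x$acc[2, 1], (0.7 + 0.9 * 1.2) / (0.6 * 0.25))
  # degenerate normalization: identical accelerations map to the midpoint
  st$den <- matrix(0.5, 2, 1); st$vol <- matrix(0.5, 2, 1)
  st_d <- update_acceleration(st, TF = 0.8)
  expect_equal(unname(st_d$acc_norm), matrix(0.5, 2, 1))
})

test_that("position updates follow both branches and respect bounds", {
  cfg <- aoa_config(N = 2, tmax = 10, C1 = 2, C2 = 6, C3 = 2)
  set.seed(6)
  st <- init_population(cfg, -5, 5, function(x) x^2)
  st$acc_norm <- matrix(c(0.3, 0.7), 2, 1)
  st$best <- list(x = 1.0, den = 0.5, vol = 0.5, acc = 1, fitness = 1)
  st$x <- matrix(c(-2, 3), 2, 1)
  # exploration with partner = self leaves positions unchanged
  st_e <- update_position(st, TF = 0.4, d = 0.6,
                          rand = matrix(0.5, 2, 1), xr = c(1L, 2L))
  expect_equal(st_e$x, st$x)
  # exploitation, hand-computed: x_best + F*C2*r*accn*d*(C3*TF*x_best - x)
  st_x <- update_position(st, TF = 0.8, d = 0.2,
                          rand = matrix(0.5, 2, 1), P = c(0.3, 0.9))
  expect_equal(st_x$x[1, 1], 1 + 1 * 6 * 0.5 * 0.3 * 0.2 * (2 * 0.8 * 1 - (-2)))
  expect_equal(st_x$x[2, 1], 1 - 1 * 6 * 0.5 * 0.7 * 0.2 * (2 * 0.8 * 1 - 3))
  # clamping
  st$acc_norm <- matrix(0.9, 2, 1)
  st_c <- update_position(st, TF = 0.8, d = 1,
                          rand = matrix(1, 2, 1), P = c(0, 0))
  expect_true(all(st_c$x >= -5 & st_c$x <= 5))
})

test_that("zero random draws make densities, volumes and positions fixed points", {
  cfg <- aoa_config(N = 3, tmax = 10)
  set.seed(8)
  st <- init_population(cfg, rep(-2, 2), rep(2, 2), function(x) sum(x^2))
  z <- matrix(0, 3, 2)
  st2 <- update_density_volume(st, rand_den = z, rand_vol = z)
  expect_equal(st2$den, st$den)
  expect_equal(st2$vol, st$vol)
  st2 <- update_acceleration(st2, TF = 0.4, mr = c(1L, 2L, 3L))
  st3 <- update_position(st2, TF = 0.4, d = 0.5, rand = z, xr = c(2L, 3L, 1L))
  expect_equal(st3$x, st2$x)
})

test_that("decoding applies scales, rounding, and inverts encoding on grids", {
  sp <- search_space(list(
    list(name = "lr", lower = 1e-4, upper = 1e-1, scale = "log"),
    list(name = "batch", lower = 8, upper = 64, type = "integer")))
  mid <- (log10(1e-4) + log10(1e-1)) / 2
  d <- decode_position(c(mid, 8.4), sp)
  expect_equal(d$lr, 10^(-2.5))
  expect_equal(d$batch, 8)
  for (v in list(list(lr = 1e-3, batch = 16), list(lr = 1e-2, batch = 64))) {
    expect_equal(decode_position(encode_position(v, sp), sp), v)
  }
})

test_that("optimizer history is elitist-monotone and tmax=1 returns the initial best", {
  sp <- sphere5()
  r <- aoa_optimize(function(h) sum(unlist(h)^2), sp,
                    aoa_config(N = 10, tmax = 30, mode = "minimize", seed = 3))
  expect_true(all(diff(r$history$best_fitness) <= 0))
  r1 <- aoa_optimize(function(h) sum(unlist(h)^2), sp,
                     aoa_config(N = 10, tmax = 1, mode = "minimize", seed = 3))
  expect_equal(r1$history$best_fitness[1], min(r1$history$best_fitness[1],
                                               r1$best_fitness))
  # failing fitness propagates with the offending position attached
  expect_error(
    aoa_optimize(function(h) stop("boom"), sp, aoa_config(N = 3, tmax = 1)),
    "position")
})

test_that("maximization mode tracks the largest fitness", {
  sp <- search_space(list(list(name = "x", lower = -1, upper = 1)))
  r <- aoa_optimize(function(h) -(h$x - 0.5)^2, sp,
                    aoa_config(N = 10, tmax = 40, mode = "maximize", seed = 2))
  expect_true(all(diff(r$history$best_fitness) >= 0))
  expect_gt(r$best_fitness, -0.01)
})

test_that("warm-start positions seed the initial population", {
  sp <- sphere5()
  r <- aoa_optimize(function(h) sum(unlist(h)^2), sp,
                    aoa_config(N = 5, tmax = 1, mode = "minimize", seed = 4),
                    x0 = rep(0, 5))
  expect_lte(r$best_fitness, 1e-12)  # the optimum was handed in; elitism keeps it
})

test_that("macro precision handles perfect, degenerate and hand-counted cases", {
  expect_equal(precision_fitness(c("a", "b", "c"), c("a", "b", "c")), 1.0)
  # binary: TP=9 FP=1 for "pos"; 9 correct negatives, 1 missed positive
  y_true <- c(rep("pos", 10), rep("neg", 10))
  y_pred <- c(rep("pos", 9), "neg", "pos", rep("neg", 9))
  # pos: TP 9, FP 1 -> 0.9 ; neg: TP 9, FP 1 -> 0.9
  expect_equal(precision_fitness(y_true, y_pred), 0.9)
  # all predictions one class in a 3-class problem
  y_true <- rep(c("a", "b", "c"), times = c(2, 3, 5))
  y_pred <- rep("c", 10)
  expect_equal(precision_fitness(y_true, y_pred), (5 / 10) / 3)
  expect_error(precision_fitness(character(0), character(0)), "empty")
})
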