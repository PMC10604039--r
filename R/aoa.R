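# Archimedes Optimization Algorithm (AOA).
#
# A population metaheuristic inspired by buoyancy: each candidate
# solution is an "object" carrying a position, a density, a volume and
# an acceleration.  Densities and volumes drift toward the best object;
# accelerations are refreshed either from a randomly chosen object
# (exploration, collisions) or from the best object (exploitation, calm
# fluid), the switch being governed by a transfer function TF =
# exp((t - tmax)/tmax) that grows toward 1: exploration while TF <= 0.5,
# exploitation after.  A density-decrease factor d = TF - t/tmax shrinks
# the step size over time.  The implementation is elitist: the best
# position/fitness ever seen is never lost.
#
# Search dimensions may be linear or log-scaled and real- or
# integer-valued; the optimizer works in the (possibly log-transformed)
# coordinates and `decode_position()` maps a position back to
# hyperparameter values.

#' AOA configuration
#'
#' @param N population size (>= 2).
#' @param tmax iteration budget (>= 1).
#' @param C1,C2,C3 user constants scaling the exploration step, the
#'   exploitation step, and the transfer function inside the
#'   exploitation target `T = C3 * TF`.
#' @param p_threshold cutoff on the uniform draw deciding the direction
#'   flag F (+1 if P <= p_threshold, else -1).
#' @param norm_range two-element range `[l, u]` for acceleration
#'   normalization.
#' @param mode `"minimize"` or `"maximize"`.
#' @param seed integer seed.
#' @return An `aoa_config` list.
#' @export
aoa_config <- function(N = 20L, tmax = 100L, C1 = 2, C2 = 6, C3 = 2,
                       p_threshold = 0.5, norm_range = c(0.1, 0.9),
                       mode = c("minimize", "maximize"), seed = 1L) {
  mode <- match.arg(mode)
  N <- as.integer(N); tmax <- as.integer(tmax)
  if (N < 2L) stop("population size N must be >= 2", call. = FALSE)
  if (tmax < 1L) stop("tmax must be >= 1", call. = FALSE)
  l <- norm_range[1]; u <- norm_range[2]
  if (!(0 < l && l < u && u < 1))
    stop("norm_range must satisfy 0 < l < u < 1", call. = FALSE)
  structure(list(N = N, tmax = tmax, C1 = C1, C2 = C2, C3 = C3,
                 p_threshold = p_threshold, norm_range = c(l, u),
                 mode = mode, seed = as.integer(seed)),
            class = "aoa_config")
}

#' Bounded, typed search space
#'
#' @param dims list of dimension descriptors, each a list/vector with
#'   `name`, `lower`, `upper`, optional `scale` (`"linear"` or `"log"`)
#'   and `type` (`"real"` or `"integer"`).
#' @return A `search_space` data.frame.
#' @export
search_space <- function(dims) {
  df <- do.call(rbind, lapply(dims, function(d) {
    data.frame(name = d$name, lower = as.numeric(d$lower),
               upper = as.numeric(d$upper),
               scale = d$scale %||% "linear", type = d$type %||% "real",
               stringsAsFactors = FALSE)
  }))
  if (any(df$lower >= df$upper))
    stop("each dimension needs lower < upper", call. = FALSE)
  if (!all(df$scale %in% c("linear", "log")) ||
      !all(df$type %in% c("real", "integer")))
    stop("scale must be linear/log and type real/integer", call. = FALSE)
  if (any(df$scale == "log" & df$lower <= 0))
    stop("log-scaled dimensions need positive bounds", call. = FALSE)
  class(df) <- c("search_space", "data.frame")
  df
}

# optimizer-coordinate bounds: log dims are searched in log10 space
space_bounds <- function(space) {
  lo <- ifelse(space$scale == "log", log10(space$lower), space$lower)
  hi <- ifelse(space$scale == "log", log10(space$upper), space$upper)
  list(lower = lo, upper = hi)
}

#' Decode an optimizer position into hyperparameter values
#'
#' Log-scaled dimensions are exponentiated back, integer dimensions
#' rounded to the nearest integer (then clamped into bounds).  On grid
#' values this inverts [encode_position()].
#'
#' @param x numeric position in optimizer coordinates.
#' @param space a [search_space()].
#' @return Named list of decoded values.
#' @export
decode_position <- function(x, space) {
  out <- as.list(rep(NA_real_, nrow(space)))
  names(out) <- space$name
  for (i in seq_len(nrow(space))) {
    v <- if (space$scale[i] == "log") 10^x[i] else x[i]
    if (space$type[i] == "integer")
      v <- clamp(round(v), ceiling(space$lower[i]), floor(space$upper[i]))
    out[[i]] <- v
  }
  out
}

#' Encode hyperparameter values into optimizer coordinates
#'
#' @param values named list/vector of hyperparameter values.
#' @param space a [search_space()].
#' @return Numeric position vector.
#' @export
encode_position <- function(values, space) {
  v <- unlist(values[space$name])
  ifelse(space$scale == "log", log10(v), v)
}

#' Initialize the AOA population
#'
#' Positions uniform within the per-dimension bounds, densities and
#' volumes uniform in (0, 1), accelerations uniform within the bounds;
#' all fitnesses evaluated and the best object recorded.
#'
#' @param config an [aoa_config()].
#' @param lower,upper numeric bound vectors (equal length, the problem
#'   dimension).
#' @param fitness_fn function(position vector) -> scalar fitness.
#' @param x0 optional list of warm-start positions replacing the first
#'   objects' uniform draws (clamped to the bounds).
#' @return An `aoa_state` list with elements `x`, `den`, `vol`, `acc`
#'   (N x D matrices), `fitness`, `best`, `t`.
#' @export
init_population <- function(config, lower, upper, fitness_fn, x0 = NULL) {
  D <- length(lower)
  if (length(upper) != D) stop("bound length mismatch", call. = FALSE)
  if (any(lower > upper)) stop("need lower <= upper on every dimension", call. = FALSE)
  N <- config$N
  ru <- function() matrix(stats::runif(N * D), N, D)
  span <- matrix(rep(upper - lower, each = N), N, D)
  lo <- matrix(rep(lower, each = N), N, D)
  x <- lo + ru() * span
  if (!is.null(x0)) {
    if (is.numeric(x0)) x0 <- list(x0)
    for (i in seq_len(min(length(x0), N)))
      x[i, ] <- clamp(x0[[i]], lower, upper)
  }
  den <- ru()
  vol <- ru()
  acc <- lo + ru() * span
  fitness <- apply(x, 1L, fitness_fn)
  bi <- best_index(fitness, config$mode)
  state <- list(x = x, den = den, vol = vol, acc = acc, fitness = fitness,
                best = list(x = x[bi, ], den = den[bi, ], vol = vol[bi, ],
                            acc = acc[bi, ], fitness = fitness[bi]),
                t = 0L, lower = lower, upper = upper, config = config)
  class(state) <- "aoa_state"
  state
}

best_index <- function(fitness, mode) {
  if (mode == "maximize") which.max(fitness) else which.min(fitness)
}

is_better <- function(a, b, mode) {
  if (mode == "maximize") a > b else a < b
}

#' Exploration-to-exploitation transfer function
#'
#' `TF(t) = exp((t - tmax) / tmax)`, strictly increasing in `t` and
#' equal to 1 at `t = tmax`.
#'
#' @param t iteration (0 <= t <= tmax).
#' @param tmax iteration budget (>= 1).
#' @return A scalar in (0, 1].
#' @export
transfer_function <- function(t, tmax) {
  if (tmax < 1) stop("tmax must be >= 1", call. = FALSE)
  if (any(t < 0) || any(t > tmax)) stop("need 0 <= t <= tmax", call. = FALSE)
  exp((t - tmax) / tmax)
}

#' Density-decrease factor
#'
#' `d(t) = exp((t - tmax)/tmax) - t/tmax`; shrinks the position-update
#' step as iterations progress (0 at `t = tmax`).
#'
#' @inheritParams transfer_function
#' @return A scalar.
#' @export
density_factor <- function(t, tmax) {
  if (tmax < 1) stop("tmax must be >= 1", call. = FALSE)
  exp((t - tmax) / tmax) - t / tmax
}

#' Drift densities and volumes toward the best object
#'
#' `den_i <- den_i + r * (den_best - den_i)` (and likewise for volume),
#' with a fresh uniform draw per object per dimension.
#'
#' @param state an `aoa_state`.
#' @param rand_den,rand_vol optional N x D matrices of draws in `[0,1]`
#'   (supplied by oracle tests; fresh uniforms when `NULL`).
#' @return The updated state.
#' @export
update_density_volume <- function(state, rand_den = NULL, rand_vol = NULL) {
  N <- nrow(state$x); D <- ncol(state$x)
  if (is.null(rand_den)) rand_den <- matrix(stats::runif(N * D), N, D)
  if (is.null(rand_vol)) rand_vol <- matrix(stats::runif(N * D), N, D)
  bden <- matrix(rep(state$best$den, each = N), N, D)
  bvol <- matrix(rep(state$best$vol, each = N), N, D)
  state$den <- state$den + rand_den * (bden - state$den)
  state$vol <- state$vol + rand_vol * (bvol - state$vol)
  state
}

#' Update and normalize accelerations
#'
#' Exploration (`TF <= 0.5`): each object collides with a random
#' "material" `mr` and takes acceleration
#' `(den_mr + vol_mr * acc_mr) / (den_i * vol_i)`.  Exploitation
#' (`TF > 0.5`): the best object replaces `mr`.  Accelerations are then
#' normalized per dimension to `u * (acc - min)/(max - min) + l`; when a
#' dimension is degenerate (max = min) every object gets the midpoint
#' `(l + u)/2`.  Denominators are floored at 1e-12.
#'
#' @param state an `aoa_state` whose densities/volumes were updated this
#'   iteration.
#' @param TF transfer-function value for this iteration.
#' @param mr optional integer vector of material indices (oracle tests).
#' @return The updated state (`acc` raw, `acc_norm` normalized).
#' @export
update_acceleration <- function(state, TF, mr = NULL) {
  N <- nrow(state$x); D <- ncol(state$x)
  if (TF <= 0.5) {
    if (is.null(mr)) mr <- sample.int(N, N, replace = TRUE)
    num <- state$den[mr, , drop = FALSE] +
      state$vol[mr, , drop = FALSE] * state$acc[mr, , drop = FALSE]
  } else {
    num <- matrix(rep(state$best$den + state$best$vol * state$best$acc,
                      each = N), N, D)
  }
  denom <- pmax(state$den * state$vol, 1e-12)
  state$acc <- num / denom
  l <- state$config$norm_range[1]; u <- state$config$norm_range[2]
  mn <- apply(state$acc, 2L, min)
  mx <- apply(state$acc, 2L, max)
  acc_norm <- matrix(0, N, D)
  for (j in seq_len(D)) {
    acc_norm[, j] <- if (mx[j] > mn[j])
      (u - l) * (state$acc[, j] - mn[j]) / (mx[j] - mn[j]) + l
    else (l + u) / 2
  }
  state$acc_norm <- acc_norm
  state
}

#' Update positions (exploration or exploitation step)
#'
#' Exploration (`TF <= 0.5`):
#' `x_i <- x_i + C1 * r * accn_i * d * (x_rand - x_i)`.
#' Exploitation: `x_i <- x_best + F * C2 * r * accn_i * d *
#' (C3 * TF * x_best - x_i)` with direction flag `F = +1` if the uniform
#' draw `P <= p_threshold`, else `-1`.  Positions are clamped to the
#' bounds afterwards.
#'
#' @param state an `aoa_state` with normalized accelerations.
#' @param TF transfer-function value.
#' @param d density-decrease factor value.
#' @param rand optional N x D draw matrix; `P` optional length-N draws;
#'   `xr` optional indices of the random partner objects (oracle tests).
#' @return The updated state.
#' @export
update_position <- function(state, TF, d, rand = NULL, P = NULL, xr = NULL) {
  N <- nrow(state$x); D <- ncol(state$x)
  cfg <- state$config
  if (is.null(rand)) rand <- matrix(stats::runif(N * D), N, D)
  if (TF <= 0.5) {
    if (is.null(xr)) xr <- sample.int(N, N, replace = TRUE)
    state$x <- state$x + cfg$C1 * rand * state$acc_norm * d *
      (state$x[xr, , drop = FALSE] - state$x)
  } else {
    if (is.null(P)) P <- stats::runif(N)
    Fflag <- ifelse(P <= cfg$p_threshold, 1, -1)
    Tt <- cfg$C3 * TF
    xb <- matrix(rep(state$best$x, each = N), N, D)
    state$x <- xb + Fflag * cfg$C2 * rand * state$acc_norm * d *
      (Tt * xb - state$x)
  }
  lo <- matrix(rep(state$lower, each = N), N, D)
  hi <- matrix(rep(state$upper, each = N), N, D)
  state$x <- pmin(pmax(state$x, lo), hi)
  state
}

#' Run the Archimedes optimizer
#'
#' @param fitness_fn function taking a decoded hyperparameter list (see
#'   [decode_position()]) and returning a scalar fitness.
#' @param space a [search_space()].
#' @param config an [aoa_config()].
#' @param x0 optional warm-start position(s), in optimizer coordinates
#'   (see [encode_position()]), seeded into the initial population.
#' @return An `aoa_result`: list with `best` (decoded values),
#'   `best_fitness`, `best_position`, `history` (data.frame of
#'   per-iteration best fitness), and `config`.
#' @export
aoa_optimize <- function(fitness_fn, space, config = aoa_config(), x0 = NULL) {
  stopifnot(inherits(space, "search_space"))
  b <- space_bounds(space)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)
  eval_fn <- function(x) {
    v <- tryCatch(fitness_fn(decode_position(x, space)), error = function(e)
      stop("fitness function failed at position [",
           paste(signif(x, 4), collapse = ", "), "]: ", conditionMessage(e),
           call. = FALSE))
    as.numeric(v)
  }
  state <- init_population(config, b$lower, b$upper, eval_fn, x0 = x0)
  history <- data.frame(iteration = 0L, best_fitness = state$best$fitness)
  for (t in seq_len(config$tmax)) {
    state$t <- t
    TF <- transfer_function(t, config$tmax)
    d <- density_factor(t, config$tmax)
    state <- update_density_volume(state)
    state <- update_acceleration(state, TF)
    state <- update_position(state, TF, d)
    state$fitness <- apply(state$x, 1L, eval_fn)
    bi <- best_index(state$fitness, config$mode)
    if (is_better(state$fitness[bi], state$best$fitness, config$mode)) {
      state$best <- list(x = state$x[bi, ], den = state$den[bi, ],
                         vol = state$vol[bi, ], acc = state$acc[bi, ],
                         fitness = state$fitness[bi])
    }
    history <- rbind(history,
                     data.frame(iteration = t, best_fitness = state$best$fitness))
  }
  structure(list(best = decode_position(state$best$x, space),
                 best_fitness = state$best$fitness,
                 best_position = state$best$x,
                 history = history, config = config, space = space),
            class = "aoa_result")
}

#' @export
print.aoa_result <- function(x, ...) {
  cat(sprintf("AOA result: best fitness %.6g after %d iterations (N = %d)\n",
              x$best_fitness, x$config$tmax, x$config$N))
  cat("  best: ", paste(names(x$best), signif(unlist(x$best), 5),
                        sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Macro-averaged precision fitness
#'
#' Per-class one-vs-rest precision `TP / (TP + FP)`, averaged without
#' weighting over the classes present in the true or predicted labels;
#' a class never predicted (TP + FP = 0) contributes 0.
#'
#' @param y_true,y_pred equal-length label vectors.
#' @return A number in `[0, 1]`.
#' @export
precision_fitness <- function(y_true, y_pred) {
  if (length(y_true) == 0L) stop("empty label vectors", call. = FALSE)
  if (length(y_true) != length(y_pred))
    stop("label vectors differ in length", call. = FALSE)
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  classes <- sort(unique(c(y_true, y_pred)))
  prec <- vapply(classes, function(k) {
    tp <- sum(y_pred == k & y_true == k)
    fp <- sum(y_pred == k & y_true != k)
    if (tp + fp == 0) 0 else tp / (tp + fp)
  }, numeric(1))
  mean(prec)
}
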