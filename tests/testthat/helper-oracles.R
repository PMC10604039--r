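# Independent brute-force oracles used across the suite.  These are
# deliberately written in the most literal way possible (explicit loops,
# no shared code with the package internals).

# median filter: explicit loops with edge replication
brute_median_filter <- function(img, window) {
  r <- window %/% 2
  H <- nrow(img); W <- ncol(img)
  out <- matrix(0, H, W)
  for (i in 1:H) for (j in 1:W) {
    vals <- c()
    for (di in -r:r) for (dj in -r:r) {
      ii <- min(max(i + di, 1), H)
      jj <- min(max(j + dj, 1), W)
      vals <- c(vals, img[ii, jj])
    }
    out[i, j] <- sort(vals)[(length(vals) + 1) %/% 2]
  }
  out
}

# one-vs-rest metrics from the four cells, explicit per class
brute_metrics <- function(cm) {
  K <- nrow(cm); total <- sum(cm)
  out <- matrix(0, K, 4)
  for (k in 1:K) {
    tp <- cm[k, k]
    fn <- sum(cm[k, ]) - tp
    fp <- sum(cm[, k]) - tp
    tn <- total - tp - fn - fp
    acc <- (tp + tn) / total
    sens <- if (tp + fn > 0) tp / (tp + fn) else 0
    spec <- if (tn + fp > 0) tn / (tn + fp) else 0
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    f <- if (prec + sens > 0) 2 * prec * sens / (prec + sens) else 0
    out[k, ] <- c(acc, sens, spec, f)
  }
  colnames(out) <- c("accuracy", "sensitivity", "specificity", "f_measure")
  out
}

# mask compactness: perimeter^2 / (4 pi area), perimeter counted as
# exposed 4-neighbour edges
mask_compactness <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  per <- 0
  for (i in 1:H) for (j in 1:W) if (mask[i, j] == 1) {
    if (i == 1 || mask[i - 1, j] == 0) per <- per + 1
    if (i == H || mask[i + 1, j] == 0) per <- per + 1
    if (j == 1 || mask[i, j - 1] == 0) per <- per + 1
    if (j == W || mask[i, j + 1] == 0) per <- per + 1
  }
  per^2 / (4 * pi * sum(mask))
}

# number of 8-connected foreground components (flood fill)
mask_components <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  seen <- matrix(FALSE, H, W)
  comps <- 0
  for (i in 1:H) for (j in 1:W) {
    if (mask[i, j] == 1 && !seen[i, j]) {
      comps <- comps + 1
      queue <- list(c(i, j)); seen[i, j] <- TRUE
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (di in -1:1) for (dj in -1:1) {
          a <- p[1] + di; b <- p[2] + dj
          if (a >= 1 && a <= H && b >= 1 && b <= W &&
              mask[a, b] == 1 && !seen[a, b]) {
            seen[a, b] <- TRUE
            queue[[length(queue) + 1]] <- c(a, b)
          }
        }
      }
    }
  }
  comps
}

# hand-executed single Archimedes iteration on a 2-object, 1-D toy.
# Pure scalar arithmetic following the update equations step by step;
# all random draws are passed in explicitly.
aoa_reference_iteration <- function(x, den, vol, acc, best, t, tmax,
                                    C1, C2, C3, lower, upper,
                                    r_den, r_vol, mr, r_pos, P, xr,
                                    l = 0.1, u = 0.9, p_threshold = 0.5) {
  TF <- exp((t - tmax) / tmax)
  d <- exp((t - tmax) / tmax) - t / tmax
  den2 <- c(den[1] + r_den[1] * (best$den - den[1]),
            den[2] + r_den[2] * (best$den - den[2]))
  vol2 <- c(vol[1] + r_vol[1] * (best$vol - vol[1]),
            vol[2] + r_vol[2] * (best$vol - vol[2]))
  acc2 <- numeric(2)
  for (i in 1:2) {
    if (TF <= 0.5) {
      num <- den2[mr[i]] + vol2[mr[i]] * acc[mr[i]]
    } else {
      num <- best$den + best$vol * best$acc
    }
    acc2[i] <- num / max(den2[i] * vol2[i], 1e-12)
  }
  mn <- min(acc2); mx <- max(acc2)
  accn <- if (mx > mn) (u - l) * (acc2 - mn) / (mx - mn) + l else rep((l + u) / 2, 2)
  x2 <- numeric(2)
  for (i in 1:2) {
    if (TF <= 0.5) {
      x2[i] <- x[i] + C1 * r_pos[i] * accn[i] * d * (x[xr[i]] - x[i])
    } else {
      Fflag <- if (P[i] <= p_threshold) 1 else -1
      Tt <- C3 * TF
      x2[i] <- best$x + Fflag * C2 * r_pos[i] * accn[i] * d * (Tt * best$x - x[i])
    }
    x2[i] <- min(max(x2[i], lower), upper)
  }
  list(x = x2, den = den2, vol = vol2, acc = acc2, acc_norm = accn,
       TF = TF, d = d)
}

# small helper: deterministic set of preprocessed phantoms
make_phantom_set <- function(n_per_class, size = 32, noise = 0.05, seed0 = 100,
                             filter = TRUE) {
  out <- list()
  i <- 0
  for (lab in c("normal", "benign", "malignant")) {
    for (k in seq_len(n_per_class)) {
      i <- i + 1
      p <- generate_phantom(lab, size, noise, seed = seed0 + i)
      if (filter) p$image <- median_filter(p$image, 3)
      out[[i]] <- p
    }
  }
  out
}

# the canonical 8-pattern bars-and-stripes set on a 2x2 grid (4 visible
# units): all-dark/all-light counted under both orientations
bars_and_stripes <- function() {
  rbind(c(0, 0, 0, 0), c(1, 1, 1, 1),   # rows: dark, light
        c(1, 1, 0, 0), c(0, 0, 1, 1),   # horizontal bars
        c(0, 0, 0, 0), c(1, 1, 1, 1),   # columns: dark, light
        c(1, 0, 1, 0), c(0, 1, 0, 1))   # vertical stripes
}
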