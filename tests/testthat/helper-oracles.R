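# Independent oracles and fixture generators used across the suite.
# The fold oracle deliberately works on explicit coordinate sets with
# string keys, a different representation from the package's matrix
# arithmetic, so the two routes share no code.

# Brute-force fold mismatch: mirror the 0-based foreground coordinate list
# about each candidate line (floor, round, ceil and floor + 0.5 of the
# centroid coordinate) and count the symmetric difference; the mismatch
# area is half that count, minimized over candidates.
oracle_fold <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  rr <- idx[, 1] - 1
  cc <- idx[, 2] - 1
  keys <- paste(rr, cc)
  one_axis <- function(coord_vals, other_vals, centroid) {
    cands <- unique(c(floor(centroid), round(centroid), ceiling(centroid),
                      floor(centroid) + 0.5))
    best <- Inf
    for (L in cands) {
      refl <- round(2 * L) - coord_vals
      rkeys <- if (identical(coord_vals, rr)) paste(refl, other_vals)
               else paste(other_vals, refl)
      sym_diff <- length(setdiff(keys, rkeys)) + length(setdiff(rkeys, keys))
      best <- min(best, sym_diff / 2)
    }
    best
  }
  list(delta_major = one_axis(rr, cc, mean(rr)),
       delta_minor = one_axis(cc, rr, mean(cc)),
       area = length(keys))
}

# Random sparse-ish binary mask with at least one foreground pixel.
random_mask <- function(m, n, p = 0.35) {
  repeat {
    mat <- matrix(as.integer(stats::runif(m * n) < p), m, n)
    if (sum(mat) > 0) return(mat)
  }
}

# Mask mirror-symmetric about both center lines: a random monotone
# staircase quadrant (rows contiguous from the center column, widths
# non-increasing away from the center) reflected into all four corners,
# which keeps the symmetrized mask a single connected component. `odd`
# controls whether the symmetry lines fall on a pixel (odd extent) or
# between pixels (even extent).
doubly_symmetric_mask <- function(k = 5, odd = TRUE, p = 0.5) {
  w <- sort(sample.int(k, k, replace = TRUE), decreasing = TRUE)
  q <- matrix(0L, k, k)                    # row 1 = center row
  for (i in seq_len(k)) q[i, seq_len(w[i])] <- 1L
  if (odd) {
    m <- matrix(0L, 2 * k - 1, 2 * k - 1)
    m[k:(2 * k - 1), k:(2 * k - 1)] <- q   # bottom-right, center pixel (k,k)
    m[k:(2 * k - 1), k:1] <- q             # bottom-left
    m[k:1, ] <- m[k:(2 * k - 1), ]         # top half
  } else {
    br <- q
    m <- rbind(cbind(br[k:1, k:1], br[k:1, ]), cbind(br[, k:1], br))
  }
  m
}

# Mask equal to its transpose (H and V profiles coincide).
transpose_symmetric_mask <- function(k = 8, p = 0.4) {
  q <- random_mask(k, k, p)
  as.integer(q | t(q)) |> matrix(k, k)
}

# Random synthetic shape spec spanning the generator's parameter space.
random_shape_spec <- function(seed) {
  set.seed(seed)
  n_h <- sample(0:3, 1)
  harmonics <- lapply(seq_len(n_h), function(i) {
    c(sample(2:6, 1), stats::runif(1, 0, 0.35), stats::runif(1, 0, 2 * pi))
  })
  shape_spec(canvas = c(64, 64),
             radii = c(stats::runif(1, 10, 16), stats::runif(1, 7, 11)),
             rotation = stats::runif(1, 0, pi),
             harmonics = harmonics,
             noise_sd = stats::runif(1, 0, 0.5),
             seed = seed)
}

# Tiny labeled feature table for classifier plumbing tests.
toy_feature_table <- function(n_per_class = 30, seed = 1) {
  set.seed(seed)
  labs <- rep(c("nevus", "melanoma", "dysplastic"), each = n_per_class)
  centers <- list(nevus = c(0.05, 0.02), melanoma = c(0.8, 0.35),
                  dysplastic = c(0.3, 0.12))
  a1 <- unlist(lapply(labs, function(l) centers[[l]][1] + stats::rnorm(1, 0, 0.02)))
  a2 <- unlist(lapply(labs, function(l) centers[[l]][2] + stats::rnorm(1, 0, 0.01)))
  data.frame(sample_id = sprintf("s%03d", seq_along(labs)),
             A1 = a1, A2 = a2,
             A3 = 0.25, A4 = stats::runif(length(labs), 0.4, 1),
             label = factor(labs, levels = c("nevus", "melanoma", "dysplastic")),
             dataset = "synthetic", stringsAsFactors = FALSE)
}
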