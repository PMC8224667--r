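test_that("fold_overlap is zero for mirror-symmetric shapes", {
  rect <- matrix(1L, 3, 5)
  f <- fold_overlap(rect)
  expect_equal(f$delta_major, 0)
  expect_equal(f$delta_minor, 0)

  plus <- matrix(0L, 5, 5); plus[3, ] <- 1L; plus[, 3] <- 1L
  fp <- fold_overlap(plus)
  expect_equal(fp$delta_major + fp$delta_minor, 0)

  expect_error(fold_overlap(matrix(0L, 4, 4)), "foreground")
})

test_that("fold_overlap matches the coordinate-reflection oracle", {
  # the L-pentomino, with orientation forced to zero
  m <- matrix(0L, 6, 6)
  for (p in list(c(1, 1), c(2, 1), c(3, 1), c(3, 2), c(3, 3)))
    m[p[1] + 1, p[2] + 1] <- 1L
  frame <- shape_frame(m)
  frame$orientation <- 0
  got <- fold_overlap(m, frame)
  want <- oracle_fold(m)
  expect_equal(got$delta_major, want$delta_major)
  expect_equal(got$delta_minor, want$delta_minor)
  expect_equal(asymmetry_A1(got), (want$delta_major + want$delta_minor) / 5)

  set.seed(202)
  for (i in 1:50) {
    m <- random_mask(sample(3:16, 1), sample(3:16, 1), p = stats::runif(1, 0.2, 0.7))
    got <- fold_overlap(m)
    want <- oracle_fold(m)
    expect_identical(as.numeric(got$delta_major), as.numeric(want$delta_major))
    expect_identical(as.numeric(got$delta_minor), as.numeric(want$delta_minor))
  }
})

test_that("A1 and A2 follow their defining arithmetic", {
  mk <- function(dmin, dmaj, al)
    structure(list(delta_minor = dmin, delta_major = dmaj, area = al),
              class = "fold_result")
  expect_equal(asymmetry_A1(mk(0, 0, 15)), 0)
  expect_equal(asymmetry_A2(mk(0, 0, 15)), 0)
  expect_equal(asymmetry_A1(mk(3, 2, 10)), 0.5)
  expect_equal(asymmetry_A2(mk(3, 2, 10)), 0.2)
  expect_error(asymmetry_A1(mk(0, 0, 0)), "empty")
  expect_error(asymmetry_A2(mk(0, 0, 0)), "empty")
  # min never exceeds half the sum
  set.seed(8)
  for (i in 1:25) {
    al <- sample(5:50, 1)
    f <- mk(sample(0:al, 1), sample(0:al, 1), al)
    expect_lte(asymmetry_A2(f), asymmetry_A1(f) / 2)
  }
})

test_that("quadrant decomposition partitions the lesion and flags empties", {
  plus <- matrix(0L, 5, 5); plus[3, ] <- 1L; plus[, 3] <- 1L
  q <- quadrant_decompose(plus)
  expect_equal(sum(q$delta_area), mask_area(plus))
  # binary input: centroid == center of mass, every ratio term is 1,
  # so A3 is the mean of the quadrant area fractions
  expect_equal(asymmetry_A3(q), 0.25)
  expect_equal(q$d_centroid[!q$empty], q$d_mass[!q$empty])

  # L-pentomino: quadrant areas and centroid distances by direct arithmetic
  m <- matrix(0L, 6, 6)
  pts <- list(c(1, 1), c(2, 1), c(3, 1), c(3, 2), c(3, 3))
  for (p in pts) m[p[1] + 1, p[2] + 1] <- 1L
  fr <- shape_frame(m)           # centroid (2.4, 1.6)
  qd <- quadrant_decompose(m, fr)
  # Q1 top-right (r<2.4, c>=1.6): none; Q2 top-left: (1,1),(2,1)
  # Q3 bottom-left (r>=2.4, c<1.6): (3,1); Q4: (3,2),(3,3)
  expect_equal(qd$delta_area, c(0, 2, 1, 2))
  expect_true(qd$empty[1])
  expect_equal(qd$d_centroid[2], sqrt((1.5 - 2.4)^2 + (1 - 1.6)^2))
  expect_equal(qd$d_centroid[3], sqrt((3 - 2.4)^2 + (1 - 1.6)^2))
  expect_equal(qd$d_centroid[4], sqrt((3 - 2.4)^2 + (2.5 - 1.6)^2))

  # all mass in one quadrant
  corner <- matrix(0L, 6, 6); corner[1:2, 5:6] <- 1L
  fr2 <- list(centroid = c(3.5, 2.5), center_of_mass = c(3.5, 2.5))
  qc <- quadrant_decompose(corner, structure(fr2, class = "shape_frame"))
  expect_equal(sum(qc$empty), 3)
  expect_equal(qc$delta_area[1], 4)

  # the three lambda readings disagree on asymmetric shapes
  q_ratio <- quadrant_decompose(m, fr, lambda_formula = "ratio-product")
  q_area <- quadrant_decompose(m, fr, lambda_formula = "area-ratio-only")
  q_diff <- quadrant_decompose(m, fr, lambda_formula = "difference-product")
  expect_equal(q_ratio$lambda, q_area$lambda)  # binary input: ratios all 1
  expect_false(isTRUE(all.equal(q_ratio$lambda, q_diff$lambda)))
})

test_that("A3 averages the per-quadrant terms", {
  mkq <- function(lam) structure(list(lambda = lam), class = "quadrant_decomposition")
  expect_equal(asymmetry_A3(mkq(c(1, 1, 1, 1))), 1)
  expect_equal(asymmetry_A3(mkq(c(0.2, 0.3, 0.25, 0.25))), 0.25)
})

test_that("projection histograms count rows and columns of the bounding box", {
  rect <- matrix(0L, 6, 8); rect[2:4, 3:7] <- 1L
  p <- projection_histograms(rect)
  expect_equal(p$H, rep(3, 5))
  expect_equal(p$V, rep(5, 3))

  plus <- matrix(0L, 5, 5); plus[3, ] <- 1L; plus[, 3] <- 1L
  pp <- projection_histograms(plus)
  expect_equal(pp$H, c(1, 1, 5, 1, 1))
  expect_equal(pp$V, c(1, 1, 5, 1, 1))

  m <- matrix(0L, 6, 6)
  for (q in list(c(1, 1), c(2, 1), c(3, 1), c(3, 2), c(3, 3)))
    m[q[1] + 1, q[2] + 1] <- 1L
  pl <- projection_histograms(m)
  expect_equal(pl$H, c(3, 1, 1))
  expect_equal(pl$V, c(1, 1, 3))

  # mass conservation on random masks
  set.seed(31)
  for (i in 1:20) {
    rm <- random_mask(sample(3:12, 1), sample(3:12, 1))
    pr <- projection_histograms(rm)
    expect_equal(sum(pr$H), sum(rm))
    expect_equal(sum(pr$V), sum(rm))
  }
})

test_that("A4 is the Pearson correlation of the resampled profiles", {
  # transpose-symmetric: identical profiles
  set.seed(12)
  for (i in 1:10) {
    m <- transpose_symmetric_mask(sample(5:12, 1))
    expect_equal(asymmetry_A4(projection_histograms(m)), 1)
  }
  # both profiles constant: defined as 1
  expect_equal(asymmetry_A4(projection_histograms(matrix(1L, 3, 5))), 1)
  # one constant profile: defined as 0
  p0 <- structure(list(H = c(2, 2, 2), V = c(1, 3, 2)),
                  class = "projection_histograms")
  expect_equal(asymmetry_A4(p0, n_bins = 3), 0)
  # n_bins equal to the profile length leaves the values untouched
  p1 <- structure(list(H = c(3, 1, 1), V = c(1, 1, 3)),
                  class = "projection_histograms")
  expect_equal(asymmetry_A4(p1, n_bins = 3), -0.5)
  expect_error(asymmetry_A4(p1, n_bins = 1), "n_bins")
})

test_that("extract_features runs the full pipeline with the stated bounds", {
  sq <- matrix(0L, 7, 7); sq[3:5, 3:5] <- 1L
  f <- extract_features(sq)
  expect_equal(unname(f[c("A1", "A2")]), c(0, 0))
  expect_equal(unname(f["A4"]), 1)

  # seeded three-lobe blob is measurably asymmetric
  blob <- rasterize_shape(shape_spec(radii = c(16, 11),
                                     harmonics = list(c(3, 0.4, 1.1),
                                                      c(4, 0.2, 2.3)),
                                     seed = 11))
  fb <- extract_features(blob)
  expect_gt(fb["A1"], 0.05)
  expect_gt(fb["A2"], 0)

  expect_error(extract_features(matrix(0L, 5, 5)), "foreground")
})

test_that("doubly mirror-symmetric shapes have zero fold asymmetry", {
  set.seed(77)
  for (i in 1:15) {
    m <- doubly_symmetric_mask(sample(3:7, 1), odd = i %% 2 == 0)
    f <- extract_features(m)
    expect_equal(unname(f["A1"]), 0)
    expect_equal(unname(f["A2"]), 0)
  }
})

test_that("median fold asymmetry grows with the lobe amplitude", {
  amps <- c(0, 0.1, 0.2, 0.3)
  med <- sapply(amps, function(a) {
    vals <- sapply(1:50, function(sd) {
      f <- extract_features(rasterize_shape(lobe_family(a, seed = sd)))
      f[c("A1", "A2")]
    })
    apply(vals, 1, stats::median)
  })
  expect_true(all(diff(med["A1", ]) >= 0))
  expect_true(all(diff(med["A2", ]) >= 0))
})

test_that("A1 is robust to re-rasterization at a rotated orientation", {
  for (sd in c(2, 4)) {
    base <- shape_spec(canvas = c(72, 72), radii = c(22, 12),
                       harmonics = list(c(3, 0.25, 0.9), c(5, 0.1, 2.0)),
                       rotation = 0, seed = sd)
    rot <- base; rot$rotation <- pi / 6
    m0 <- rasterize_shape(base); m30 <- rasterize_shape(rot)
    expect_gte(mask_area(m0), 500)
    a0 <- extract_features(m0)["A1"]
    a30 <- extract_features(m30)["A1"]
    expect_lte(abs(a0 - a30), 0.1)
  }
})
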