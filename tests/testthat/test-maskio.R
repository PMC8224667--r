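test_that("load_mask binarizes rasters at the requested threshold", {
  d <- withr::local_tempdir()
  # all-background image
  p0 <- file.path(d, "zero.png")
  png::writePNG(matrix(0, 5, 5), p0)
  expect_equal(sum(load_mask(p0)), 0)

  # 0/255 image: threshold 0 recovers the exact pattern
  pat <- matrix(as.integer(stats::runif(25) < 0.5), 5, 5)
  p1 <- file.path(d, "pat.png")
  png::writePNG(pat * 1, p1)
  expect_equal(unclass(load_mask(p1)), pat, ignore_attr = TRUE)

  # three-level image: threshold 128 keeps only the 255 pixels
  lv <- matrix(c(0, 128, 255)[sample.int(3, 25, replace = TRUE)], 5, 5)
  p2 <- file.path(d, "levels.png")
  png::writePNG(lv / 255, p2)
  m <- load_mask(p2, threshold = 128)
  expect_equal(unclass(m), matrix(as.integer(lv == 255), 5, 5),
               ignore_attr = TRUE)

  expect_error(load_mask(file.path(d, "absent.png")), "cannot read")
})

test_that("mask write/read round-trip is bit-exact", {
  d <- withr::local_tempdir()
  set.seed(42)
  for (i in 1:5) {
    m <- binary_mask(random_mask(sample(3:20, 1), sample(3:20, 1)))
    p <- file.path(d, sprintf("m%d.png", i))
    write_mask(m, p)
    expect_identical(unclass(load_mask(p)), unclass(m))
  }
})

test_that("largest_component keeps the biggest blob and honors connectivity", {
  # single blob is returned unchanged
  m <- matrix(0L, 6, 6); m[2:4, 2:4] <- 1L
  expect_equal(unclass(largest_component(m)), m, ignore_attr = TRUE)

  # 9-px blob beats 2-px blob
  m2 <- m; m2[6, 5:6] <- 1L
  expect_equal(unclass(largest_component(m2)), m, ignore_attr = TRUE)

  # diagonal touch: one component under 8-connectivity, two under 4
  md <- matrix(0L, 4, 4); md[1, 1] <- 1L; md[2, 2:3] <- 1L
  expect_equal(sum(largest_component(md, 8)), 3)
  expect_equal(sum(largest_component(md, 4)), 2)

  # tie: keep the blob containing the row-major-first foreground pixel
  mt <- matrix(0L, 5, 7)
  mt[4:5, 1:2] <- 1L            # blob A, first pixel (3,0) 0-based
  mt[1:2, 6:7] <- 1L            # blob B, first pixel (0,5): earlier row-major
  keep <- largest_component(mt)
  expect_equal(sum(keep), 4)
  expect_equal(unname(keep[1, 7]), 1L)
  expect_equal(unname(keep[4, 1]), 0L)

  expect_error(largest_component(matrix(0L, 3, 3)), "foreground")
})

test_that("largest_component output is a connected subset of the input", {
  set.seed(99)
  for (i in 1:20) {
    m <- random_mask(sample(5:14, 1), sample(5:14, 1), p = 0.4)
    lc <- largest_component(m)
    expect_true(all(lc <= m))          # subset of the input foreground
    # connectedness: relabelling the output finds exactly one component
    expect_equal(max(lesionasym:::label_components(lc, 8)), 1L)
  }
})

test_that("manifest and feature-table CSV round-trips validate their schema", {
  d <- withr::local_tempdir()
  man <- data.frame(
    sample_id = c("a", "b", "c"),
    mask_path = c("a.png", "b.png", "c.png"),
    image_path = c("", "", ""),
    label = c("nevus", "melanoma", "dysplastic"),
    dataset = c("B1", "B2", "synthetic"), stringsAsFactors = FALSE)
  mp <- file.path(d, "manifest.csv")
  utils::write.csv(man, mp, row.names = FALSE)
  rd <- read_manifest(mp)
  expect_equal(nrow(rd), 3)
  expect_s3_class(rd$label, "factor")
  expect_equal(as.character(rd$label), man$label)

  # empty manifest with a valid header is fine
  utils::write.csv(man[0, ], mp, row.names = FALSE)
  expect_equal(nrow(read_manifest(mp)), 0)

  # schema violations
  utils::write.csv(man[, -2], mp, row.names = FALSE)
  expect_error(read_manifest(mp), "mask_path")
  bad <- man; bad$label[2] <- "melanomma"
  utils::write.csv(bad, mp, row.names = FALSE)
  expect_error(read_manifest(mp), "melanomma.*row 2")
  dup <- man; dup$sample_id <- c("a", "a", "c")
  utils::write.csv(dup, mp, row.names = FALSE)
  expect_error(read_manifest(mp), "unique")

  ft <- data.frame(sample_id = c("a", "b"),
                   A1 = c(0.1, 0.25), A2 = c(0.05, 0.1),
                   A3 = c(0.25, 0.25), A4 = c(0.9, 0.4),
                   label = c("nevus", "melanoma"), dataset = "synthetic",
                   stringsAsFactors = FALSE)
  fp <- file.path(d, "features.csv")
  write_features(ft, fp)
  back <- read_features(fp)
  expect_equal(back$A1, ft$A1)
  expect_equal(as.character(back$label), ft$label)
  expect_error(write_features(ft[, -3], fp), "A2")
})
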