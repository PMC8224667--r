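#' Fold a lesion about its principal axes and measure the mismatch
#'
#' After alignment the major axis is horizontal and the minor axis
#' vertical. The mask is folded about each axis: the foreground pixel set
#' is reflected about a horizontal line (major fold) or a vertical line
#' (minor fold) through the centroid, and the mismatch is the area of the
#' non-overlapping parts, i.e. half the symmetric-difference (XOR) count
#' between the set and its reflection. "Maximum overlap" is realized by
#' trying the integer fold lines `floor`, `round` and `ceiling` of the
#' sub-pixel centroid coordinate and keeping the one with the smallest
#' mismatch. Pixels whose reflection falls outside the canvas count as
#' mismatches.
#'
#' @param aligned an axis-aligned [binary_mask] (see [align_to_axes()]).
#' @param frame its [shape_frame()]; recomputed when `NULL`.
#' @return a list of class `fold_result` with `delta_major`, `delta_minor`
#'   (mismatch areas in pixels), `area` (`AL`), and the chosen fold lines
#'   `line_major`,
#'   `line_minor` (0-based row/column).
#' @export
fold_overlap <- function(aligned, frame = NULL) {
  aligned <- as_binary_mask(aligned)
  stop_if_empty(aligned, "fold_overlap")
  if (is.null(frame)) frame <- shape_frame(aligned)
  maj <- best_fold(aligned, frame$centroid[1L], axis = "row")
  mino <- best_fold(aligned, frame$centroid[2L], axis = "col")
  structure(list(
    delta_major = maj$delta, delta_minor = mino$delta,
    area = sum(aligned),
    line_major = maj$line, line_minor = mino$line
  ), class = "fold_result")
}

# Reflect the foreground set about candidate fold lines and keep the line
# minimizing the mismatch. delta = AL - |S intersect reflect(S)|, which
# equals half the whole-plane XOR count. Candidates are the floor, round
# and ceiling of the sub-pixel centroid coordinate plus the half-integer
# midline between floor and ceiling: shapes of even extent are mirror
# symmetric about a half-integer line, which an integer line can never
# realize. All candidates have 2L integer, so reflections stay on-grid.
best_fold <- function(mask, coord, axis) {
  cands <- unique(c(floor(coord), round(coord), ceiling(coord),
                    floor(coord) + 0.5))
  best <- Inf; best_line <- cands[1L]
  M <- nrow(mask); N <- ncol(mask)
  area <- sum(mask)
  for (L in cands) {
    twoL <- as.integer(round(2 * L))
    if (axis == "row") {
      src <- 0:(M - 1L)
      refl <- twoL - src                 # reflected 0-based row of each row
      ok <- refl >= 0L & refl <= M - 1L
      overlap <- sum(mask[src[ok] + 1L, , drop = FALSE] *
                     mask[refl[ok] + 1L, , drop = FALSE])
    } else {
      src <- 0:(N - 1L)
      refl <- twoL - src
      ok <- refl >= 0L & refl <= N - 1L
      overlap <- sum(mask[, src[ok] + 1L, drop = FALSE] *
                     mask[, refl[ok] + 1L, drop = FALSE])
    }
    delta <- area - overlap
    if (delta < best) { best <- delta; best_line <- L }
  }
  list(delta = best, line = best_line)
}

#' Asymmetry index A1: total fold mismatch
#'
#' `A1 = dA_minor/AL + dA_major/AL`, the summed relative non-overlap of the
#' two principal-axis folds. 0 for a doubly mirror-symmetric lesion, up to
#' 2 for a shape with no fold overlap at all.
#'
#' @param fold a [fold_overlap()] result.
#' @return a scalar in `[0, 2]`.
#' @export
asymmetry_A1 <- function(fold) {
  if (fold$area <= 0) stop("A1 undefined for an empty lesion", call. = FALSE)
  (fold$delta_minor + fold$delta_major) / fold$area
}

#' Asymmetry index A2: minimum fold mismatch
#'
#' `A2 = min(dA_minor, dA_major)/AL`: the lesion's best mirror symmetry
#' over the two principal axes. Always `A2 <= A1/2`.
#'
#' @inheritParams asymmetry_A1
#' @return a scalar in `[0, 1]`.
#' @export
asymmetry_A2 <- function(fold) {
  if (fold$area <= 0) stop("A2 undefined for an empty lesion", call. = FALSE)
  min(fold$delta_minor, fold$delta_major) / fold$area
}

#' Quadrant decomposition of an aligned lesion
#'
#' The lesion is split into four quadrants about its centroid: Q1
#' top-right, Q2 top-left, Q3 bottom-left, Q4 bottom-right, with pixels on
#' the centroid row/column assigned to the non-negative (bottom/right)
#' side. Per quadrant `i` it records the foreground area `dA_i`, the
#' distance `dD_i` from the quadrant centroid to the whole-lesion centroid,
#' the analogous center-of-mass distance `mM_i`, and a per-quadrant
#' asymmetry term `lambda_i`.
#'
#' Three readings of the lambda composition are available:
#' \describe{
#'   \item{`"ratio-product"` (default)}{`lambda_i = (dA_i/AL) * (dD_i/mM_i)`,
#'     with the ratio defined as 1 when `mM_i` is below `eps` (in
#'     particular always on binary-only input, where `dD_i = mM_i`).}
#'   \item{`"area-ratio-only"`}{`lambda_i = dA_i/AL`.}
#'   \item{`"difference-product"`}{`lambda_i = (AL - dA_i) * (dD_i - mM_i)`.}
#' }
#' Empty quadrants get `dA_i = 0`, `dD_i = mM_i = 0`, ratio term 1, and are
#' flagged in `empty`.
#'
#' @param aligned an axis-aligned [binary_mask].
#' @param frame its [shape_frame()]; recomputed when `NULL`.
#' @param image optional grayscale matrix (same dims) weighting the centers
#'   of mass.
#' @param lambda_formula one of `"ratio-product"`, `"area-ratio-only"`,
#'   `"difference-product"`.
#' @param eps guard for near-zero `mM_i` (default `1e-9` pixels).
#' @return a list of class `quadrant_decomposition` with vectors
#'   `delta_area`, `d_centroid`, `d_mass`, `lambda` (length 4, Q1..Q4),
#'   logical `empty`, and the lesion `area`.
#' @export
quadrant_decompose <- function(aligned, frame = NULL, image = NULL,
                               lambda_formula = c("ratio-product",
                                                  "area-ratio-only",
                                                  "difference-product"),
                               eps = 1e-9) {
  aligned <- as_binary_mask(aligned)
  stop_if_empty(aligned, "quadrant_decompose")
  lambda_formula <- match.arg(lambda_formula)
  if (is.null(frame)) frame <- shape_frame(aligned, image)
  xy <- fg_coords(aligned)
  r <- xy[, 1L]; c <- xy[, 2L]
  cr <- frame$centroid[1L]; cc <- frame$centroid[2L]
  top <- r - cr < 0; right <- c - cc >= 0
  quad <- ifelse(top, ifelse(right, 1L, 2L), ifelse(right, 4L, 3L))
  w <- if (is.null(image)) rep(1, nrow(xy)) else image[which(aligned != 0L)]
  AL <- nrow(xy)
  dA <- dD <- mM <- numeric(4L)
  empty <- logical(4L)
  com <- frame$center_of_mass
  for (i in 1:4) {
    sel <- quad == i
    dA[i] <- sum(sel)
    if (!any(sel)) {
      empty[i] <- TRUE
      dD[i] <- 0; mM[i] <- 0
    } else {
      qc <- c(mean(r[sel]), mean(c[sel]))
      dD[i] <- sqrt(sum((qc - frame$centroid)^2))
      wq <- w[sel]
      if (sum(wq) <= 0) {
        qm <- qc
      } else {
        qm <- c(sum(wq * r[sel]) / sum(wq), sum(wq * c[sel]) / sum(wq))
      }
      mM[i] <- sqrt(sum((qm - com)^2))
    }
  }
  ratio <- ifelse(mM < eps, 1, dD / mM)
  lambda <- switch(lambda_formula,
    "ratio-product" = (dA / AL) * ratio,
    "area-ratio-only" = dA / AL,
    "difference-product" = (AL - dA) * (dD - mM)
  )
  structure(list(
    delta_area = dA, d_centroid = dD, d_mass = mM, lambda = lambda,
    empty = empty, area = AL, lambda_formula = lambda_formula
  ), class = "quadrant_decomposition")
}

#' Asymmetry index A3: mean quadrant asymmetry
#'
#' The average of the four per-quadrant asymmetry terms.
#'
#' @param quad a [quadrant_decompose()] result.
#' @return `mean(lambda)`.
#' @export
asymmetry_A3 <- function(quad) {
  mean(quad$lambda)
}

#' Projection histograms of a mask
#'
#' Crops the mask to its foreground bounding box and counts foreground
#' pixels per column (`H`, length = bounding-box width) and per row (`V`,
#' length = bounding-box height). Both profiles sum to the lesion area.
#'
#' @param mask a [binary_mask] with at least one foreground pixel.
#' @return a list of class `projection_histograms` with `H`, `V`, and their
#'   means `H_mean`, `V_mean`.
#' @export
projection_histograms <- function(mask) {
  mask <- as_binary_mask(mask)
  stop_if_empty(mask, "projection_histograms")
  rows <- range(which(rowSums(mask) > 0))
  cols <- range(which(colSums(mask) > 0))
  sub <- mask[rows[1L]:rows[2L], cols[1L]:cols[2L], drop = FALSE]
  H <- unname(colSums(sub))
  V <- unname(rowSums(sub))
  structure(list(H = H, V = V, H_mean = mean(H), V_mean = mean(V)),
            class = "projection_histograms")
}

#' Asymmetry index A4: projection-histogram correlation
#'
#' The column profile `H` and row profile `V` generally have different
#' lengths, so both are linearly resampled to a common length `n_bins`
#' before taking the Pearson correlation. A symmetric, blob-like lesion has
#' similar profiles (correlation near 1); the more asymmetric the shape,
#' the lower the correlation. If both resampled profiles are constant the
#' correlation is defined as 1; if exactly one is constant, as 0.
#'
#' @param proj a [projection_histograms()] result.
#' @param n_bins common resampling length (default 64, must be >= 2).
#' @return a scalar in `[-1, 1]`.
#' @export
asymmetry_A4 <- function(proj, n_bins = 64) {
  if (n_bins < 2) stop("`n_bins` must be at least 2", call. = FALSE)
  h <- resample_profile(proj$H, n_bins)
  v <- resample_profile(proj$V, n_bins)
  sh <- stats::sd(h); sv <- stats::sd(v)
  if (sh == 0 && sv == 0) return(1)
  if (sh == 0 || sv == 0) return(0)
  stats::cor(h, v)
}

# Linear interpolation onto n equally spaced sample points spanning the
# profile, rescaled so total mass is approximately preserved.
resample_profile <- function(p, n) {
  if (length(p) == 1L) return(rep(p, n) * (1 / n))
  out <- stats::approx(seq_along(p), p, xout = seq(1, length(p), length.out = n))$y
  out * (length(p) / n)
}

#' Extract the four asymmetry indices from a lesion mask
#'
#' Runs the full shape-asymmetry pipeline: keep the largest connected
#' component, estimate the principal-axis frame, rotate the lesion so its
#' axes align with the grid, then compute the fold indices `A1` and `A2`,
#' the quadrant index `A3`, and the projection-histogram correlation `A4`
#' (all on the aligned mask).
#'
#' @param mask a [binary_mask] with at least one foreground pixel.
#' @param image optional grayscale companion (same dims) used for
#'   intensity-weighted centers of mass in `A3`.
#' @param n_bins resampling length for `A4` (default 64).
#' @param lambda_formula quadrant lambda reading for `A3`; see
#'   [quadrant_decompose()].
#' @return a named numeric vector `c(A1, A2, A3, A4)`.
#' @examples
#' m <- rasterize_shape(shape_spec(harmonics = list(c(3, 0.3, 1))))
#' extract_features(m)
#' @export
extract_features <- function(mask, image = NULL, n_bins = 64,
                             lambda_formula = "ratio-product") {
  mask <- as_binary_mask(mask)
  stop_if_empty(mask, "extract_features")
  mask <- largest_component(mask)
  frame <- shape_frame(mask, image)
  aligned <- align_to_axes(mask, frame, image)
  aimg <- attr(aligned, "image")
  aframe <- shape_frame(aligned, aimg)
  fold <- fold_overlap(aligned, aframe)
  quad <- quadrant_decompose(aligned, aframe, aimg,
                             lambda_formula = lambda_formula)
  proj <- projection_histograms(aligned)
  c(A1 = asymmetry_A1(fold),
    A2 = asymmetry_A2(fold),
    A3 = asymmetry_A3(quad),
    A4 = asymmetry_A4(proj, n_bins))
}

#' Extract features for every lesion in a manifest
#'
#' @param manifest a manifest data frame from [read_manifest()], or a path
#'   to a manifest CSV.
#' @param masks optional named list of in-memory masks keyed by
#'   `sample_id`; when absent, masks are loaded from `mask_path`.
#' @inheritParams extract_features
#' @return a feature table data frame (`sample_id`, `A1`..`A4`, `label`,
#'   `dataset`) suitable for [write_features()] and [ffbpn()].
#' @export
extract_features_table <- function(manifest, masks = NULL, n_bins = 64,
                                   lambda_formula = "ratio-product") {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  feats <- matrix(NA_real_, nrow(manifest), 4L,
                  dimnames = list(NULL, c("A1", "A2", "A3", "A4")))
  for (i in seq_len(nrow(manifest))) {
    id <- manifest$sample_id[i]
    m <- if (!is.null(masks)) masks[[id]] else load_mask(manifest$mask_path[i])
    img <- if (!is.null(manifest$image_path[i]) && !is.na(manifest$image_path[i]) &&
               nzchar(manifest$image_path[i]))
      load_gray(manifest$image_path[i]) else NULL
    feats[i, ] <- extract_features(m, img, n_bins, lambda_formula)
  }
  data.frame(sample_id = manifest$sample_id, feats,
             label = manifest$label, dataset = manifest$dataset,
             stringsAsFactors = FALSE)
}
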