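#' Foreground area of a mask
#'
#' @param mask a [binary_mask] (or coercible matrix).
#' @return the number of foreground pixels (the lesion area `AL`).
#' @export
mask_area <- function(mask) {
  sum(as_binary_mask(mask))
}

#' Centroid, center of mass and principal-axis frame of a lesion
#'
#' Computes the geometric frame of the foreground pixel set: the area
#' centroid, the intensity-weighted center of mass (identical to the
#' centroid when no grayscale image is supplied), the orientation of the
#' major principal axis, and the axis lengths of the circumscribing
#' ellipse derived from the second central moments.
#'
#' The orientation is `theta = atan2(2*mu11, mu20 - mu02) / 2`, measured in
#' radians from the column (x) axis, in `(-pi/2, pi/2]`. For shapes whose
#' moment matrix is isotropic (`mu11 = 0` and `mu20 = mu02`: squares,
#' crosses, disks) every axis is principal and `theta` is defined as 0.
#'
#' @param mask a [binary_mask] with at least one foreground pixel.
#' @param image optional grayscale matrix of identical dimensions; when
#'   supplied, the center of mass weights foreground pixels by intensity.
#' @return an object of class `shape_frame`: a list with 0-based
#'   `centroid = c(r, c)`, `center_of_mass`, `orientation` (radians),
#'   `major_len`, `minor_len` (pixels), and `area`.
#' @export
shape_frame <- function(mask, image = NULL) {
  mask <- as_binary_mask(mask)
  stop_if_empty(mask, "shape_frame")
  if (!is.null(image)) {
    if (!all(dim(image) == dim(mask)))
      stop("image dimensions must match the mask", call. = FALSE)
    if (any(image < 0)) stop("image intensities must be non-negative", call. = FALSE)
  }
  xy <- fg_coords(mask)
  r <- xy[, 1L]; c <- xy[, 2L]
  centroid <- c(mean(r), mean(c))
  if (is.null(image)) {
    com <- centroid
  } else {
    w <- image[which(mask != 0L)]
    if (sum(w) <= 0) {
      com <- centroid
    } else {
      com <- c(sum(w * r) / sum(w), sum(w * c) / sum(w))
    }
  }
  # second central moments in (x = col, y = row) coordinates
  dx <- c - centroid[2L]; dy <- r - centroid[1L]
  mu20 <- sum(dx * dx); mu02 <- sum(dy * dy); mu11 <- sum(dx * dy)
  eps <- 1e-12
  if (abs(mu11) < eps && abs(mu20 - mu02) < eps) {
    theta <- 0
  } else {
    theta <- 0.5 * atan2(2 * mu11, mu20 - mu02)
  }
  n <- nrow(xy)
  # eigenvalues of the normalized second-moment matrix -> ellipse semi-axes
  common <- (mu20 + mu02) / n
  diff <- sqrt(((mu20 - mu02) / n)^2 + 4 * (mu11 / n)^2)
  l1 <- (common + diff) / 2
  l2 <- (common - diff) / 2
  structure(list(
    centroid = centroid,
    center_of_mass = com,
    orientation = theta,
    major_len = 4 * sqrt(max(l1, 0)),
    minor_len = 4 * sqrt(max(l2, 0)),
    area = n
  ), class = "shape_frame")
}

#' @export
print.shape_frame <- function(x, ...) {
  cat(sprintf(
    "<shape_frame: centroid (%.2f, %.2f), theta %.4f rad, axes %.1f x %.1f, area %d>\n",
    x$centroid[1L], x$centroid[2L], x$orientation,
    x$major_len, x$minor_len, x$area))
  invisible(x)
}

#' Rotate a mask so its principal axes align with the grid
#'
#' Rotates the mask by `-theta` about its sub-pixel centroid with
#' nearest-neighbor resampling (which preserves binarity), on an enlarged
#' square canvas of side `ceiling(sqrt(M^2 + N^2)) + 2` so no foreground
#' pixel is clipped. If the recomputed orientation of the result still
#' exceeds the angular tolerance, one corrective second pass is applied.
#'
#' @param mask a [binary_mask].
#' @param frame its [shape_frame()]; recomputed when `NULL`.
#' @param image optional grayscale companion rotated with the same
#'   transform (returned as attribute `"image"`).
#' @param tol angular tolerance in radians for "aligned" (default 0.05).
#' @return the rotated [binary_mask]; when `image` is given, the rotated
#'   image travels along as `attr(, "image")`.
#' @export
align_to_axes <- function(mask, frame = NULL, image = NULL, tol = 0.05) {
  mask <- as_binary_mask(mask)
  stop_if_empty(mask, "align_to_axes")
  if (is.null(frame)) frame <- shape_frame(mask, image)
  out <- rotate_mask(mask, frame$orientation, frame$centroid, image)
  f2 <- shape_frame(out$mask)
  if (abs(f2$orientation) > tol) {
    out <- rotate_mask(out$mask, f2$orientation, f2$centroid, out$image)
  }
  res <- out$mask
  if (!is.null(out$image)) attr(res, "image") <- out$image
  res
}

# Rotate by -theta about `centroid` (0-based r,c) onto an enlarged canvas.
rotate_mask <- function(mask, theta, centroid, image = NULL) {
  M <- nrow(mask); N <- ncol(mask)
  S <- as.integer(ceiling(sqrt(M^2 + N^2))) + 2L
  ctr <- (S - 1) / 2  # 0-based center of the output canvas
  # output pixel offsets (0-based)
  rr <- matrix(rep(0:(S - 1L), S), S, S) - ctr          # dy
  cc <- matrix(rep(0:(S - 1L), each = S), S, S) - ctr   # dx
  ct <- cos(theta); st <- sin(theta)
  # snap to exact values at multiples of pi/2 so quarter turns are rigid
  if (abs(ct) < 1e-9) ct <- 0
  if (abs(st) < 1e-9) st <- 0
  if (abs(abs(ct) - 1) < 1e-9) ct <- sign(ct)
  if (abs(abs(st) - 1) < 1e-9) st <- sign(st)
  # inverse map: source = centroid + R(theta) %*% dst_offset
  src_c <- centroid[2L] + ct * cc - st * rr
  src_r <- centroid[1L] + st * cc + ct * rr
  # round half up (not half to even): consistent rounding keeps
  # half-integer-offset grids rigid instead of duplicating rows
  si <- floor(src_r + 0.5) + 1  # back to 1-based matrix indices
  sj <- floor(src_c + 0.5) + 1
  ok <- si >= 1 & si <= M & sj >= 1 & sj <= N
  out <- matrix(0L, S, S)
  idx <- cbind(si[ok], sj[ok])
  out[ok] <- mask[idx]
  img_out <- NULL
  if (!is.null(image)) {
    img_out <- matrix(0, S, S)
    img_out[ok] <- image[idx]
  }
  list(mask = binary_mask(out), image = img_out)
}
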