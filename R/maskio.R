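#' Binary lesion masks
#'
#' A binary mask is an `M x N` integer matrix of 0/1 values: 1 marks lesion
#' (foreground) pixels, 0 background. Throughout the package pixel
#' coordinates are 0-based, `(r, c)` with row `r` in `[0, M)` increasing
#' downwards and column `c` in `[0, N)` increasing to the right, origin at
#' the top-left corner. Matrices are stored with R's usual 1-based indexing;
#' every user-facing coordinate (centroids, fold lines, ...) is 0-based.
#'
#' @param pixels a numeric or logical matrix; any non-zero entry becomes 1.
#' @return an integer 0/1 matrix of class `binary_mask`.
#' @examples
#' m <- binary_mask(matrix(c(0, 1, 1, 0), 2, 2))
#' mask_area(m)
#' @export
binary_mask <- function(pixels) {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix", call. = FALSE)
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("mask must have at least one row and one column", call. = FALSE)
  if (anyNA(pixels)) stop("mask contains missing values", call. = FALSE)
  m <- matrix(as.integer(pixels != 0), nrow(pixels), ncol(pixels))
  class(m) <- c("binary_mask", "matrix")
  m
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask %d x %d, %d foreground px>\n",
              nrow(x), ncol(x), sum(x)))
  invisible(x)
}

as_binary_mask <- function(x) {
  if (inherits(x, "binary_mask")) return(x)
  binary_mask(x)
}

stop_if_empty <- function(mask, what = "operation") {
  if (sum(mask) == 0L)
    stop(sprintf("%s requires a mask with at least one foreground pixel", what),
         call. = FALSE)
  invisible(mask)
}

# Foreground coordinates as an n x 2 matrix of 0-based (r, c).
fg_coords <- function(mask) {
  idx <- which(mask != 0L, arr.ind = TRUE)
  cbind(r = idx[, 1L] - 1L, c = idx[, 2L] - 1L)
}

#' Read a lesion mask from a PNG or TIFF file
#'
#' Decodes a raster image and binarizes it: any pixel with intensity
#' strictly greater than `threshold` becomes foreground. Intensities are on
#' the native integer scale of the file (0-255 for 8-bit images, 0-65535 for
#' 16-bit). Masks are assumed pre-segmented, so the default threshold 0
#' keeps every non-zero pixel. Multi-channel images use the first channel.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @param threshold intensity cut; pixels `> threshold` map to 1.
#' @return a [binary_mask].
#' @seealso [write_mask()], [load_gray()]
#' @export
load_mask <- function(path, threshold = 0) {
  binary_mask(read_raster(path) > threshold)
}

#' Read a grayscale image (native integer intensity scale)
#'
#' Companion intensities for intensity-weighted centers of mass. Dimensions
#' must match the paired mask when the two are used together.
#'
#' @inheritParams load_mask
#' @return a numeric matrix of non-negative intensities.
#' @export
load_gray <- function(path) {
  read_raster(path)
}

read_raster <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path, as.is = TRUE),
    stop("unsupported image format: .", ext, " (use PNG or TIFF)", call. = FALSE)
  )
  if (length(img) == 0L) stop("empty raster in ", path, call. = FALSE)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  if (!is.matrix(img)) img <- as.matrix(img)
  # readPNG scales to [0,1]; restore the 8-bit integer scale so thresholds
  # are expressed in native units for both formats.
  if (ext == "png") img <- round(img * 255)
  img
}

#' Write a binary mask as an 8-bit PNG
#'
#' Foreground pixels are written as 255, background as 0, so
#' `load_mask(path)` reproduces the mask bit-exactly.
#'
#' @param mask a [binary_mask] (or coercible matrix).
#' @param path output path, `.png`.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  mask <- as_binary_mask(mask)
  png::writePNG(matrix(as.double(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Keep the largest connected foreground component
#'
#' Lesion analysis assumes a single lesion per image; segmentation debris is
#' removed by retaining only the connected component with the most pixels.
#' Ties are broken in favour of the component containing the row-major first
#' foreground pixel.
#'
#' @param mask a [binary_mask].
#' @param connectivity 4 or 8 (default) neighbour connectivity.
#' @return a [binary_mask] of the same dimensions.
#' @export
largest_component <- function(mask, connectivity = 8) {
  mask <- as_binary_mask(mask)
  stop_if_empty(mask, "largest_component")
  if (!connectivity %in% c(4, 8))
    stop("`connectivity` must be 4 or 8", call. = FALSE)
  lab <- label_components(mask, connectivity)
  sizes <- tabulate(lab[lab > 0L])
  best_size <- max(sizes)
  # row-major scan (r fastest varying over columns): traverse by row then col
  cand <- which(sizes == best_size)
  if (length(cand) > 1L) {
    # first foreground pixel in row-major order belonging to a candidate
    ord <- order(row(mask)[mask == 1L], col(mask)[mask == 1L])
    labs_rm <- lab[mask == 1L][ord]
    keep <- labs_rm[labs_rm %in% cand][1L]
  } else {
    keep <- cand
  }
  binary_mask(lab == keep)
}

# Two-pass-free BFS labelling; masks are small so an R queue is fine.
label_components <- function(mask, connectivity) {
  M <- nrow(mask); N <- ncol(mask)
  lab <- matrix(0L, M, N)
  if (connectivity == 4) {
    dr <- c(-1L, 1L, 0L, 0L); dc <- c(0L, 0L, -1L, 1L)
  } else {
    dr <- c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L)
    dc <- c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L)
  }
  nextlab <- 0L
  todo <- which(mask == 1L)
  for (start in todo) {
    if (lab[start] != 0L) next
    nextlab <- nextlab + 1L
    queue <- start
    lab[start] <- nextlab
    while (length(queue)) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      pr <- ((p - 1L) %% M) + 1L
      pc <- ((p - 1L) %/% M) + 1L
      for (k in seq_along(dr)) {
        nr <- pr + dr[k]; nc <- pc + dc[k]
        if (nr >= 1L && nr <= M && nc >= 1L && nc <= N) {
          q <- (nc - 1L) * M + nr
          if (mask[q] == 1L && lab[q] == 0L) {
            lab[q] <- nextlab
            queue <- c(queue, q)
          }
        }
      }
    }
  }
  lab
}

lesion_classes <- c("nevus", "melanoma", "dysplastic")
dataset_ids <- c("B1", "B2", "B3", "B4", "synthetic")

#' Read a sample manifest CSV
#'
#' A manifest lists one lesion per row with columns `sample_id`,
#' `mask_path`, optional `image_path`, `label` (one of `nevus`, `melanoma`,
#' `dysplastic`) and `dataset` (one of `B1`-`B4` or `synthetic`).
#'
#' @param path CSV path (comma separated, header row, UTF-8).
#' @return a data frame with the manifest columns; `label` is a factor over
#'   the three lesion classes.
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "mask_path", "label", "dataset")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("manifest is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!"image_path" %in% names(df)) df$image_path <- NA_character_
  if (anyDuplicated(df$sample_id))
    stop("manifest sample_id values must be unique", call. = FALSE)
  validate_labels(df$label)
  bad <- which(!df$dataset %in% dataset_ids)
  if (length(bad))
    stop(sprintf("unknown dataset id '%s' in manifest row %d",
                 df$dataset[bad[1L]], bad[1L]), call. = FALSE)
  df$label <- factor(df$label, levels = lesion_classes)
  df[c("sample_id", "mask_path", "image_path", "label", "dataset")]
}

validate_labels <- function(labels) {
  bad <- which(!as.character(labels) %in% lesion_classes)
  if (length(bad))
    stop(sprintf("unknown class label '%s' in row %d (expected %s)",
                 as.character(labels)[bad[1L]], bad[1L],
                 paste(lesion_classes, collapse = "/")), call. = FALSE)
  invisible(labels)
}

#' Write / read a feature table CSV
#'
#' Feature tables hold one lesion per row with columns `sample_id`, `A1`,
#' `A2`, `A3`, `A4`, `label`, `dataset`. Writing then reading yields an
#' identical table.
#'
#' @param features a data frame with the feature-table columns.
#' @param path CSV path.
#' @return `write_features` returns `path` invisibly; `read_features`
#'   returns the table with `label` as a factor.
#' @export
write_features <- function(features, path) {
  required <- c("sample_id", "A1", "A2", "A3", "A4", "label", "dataset")
  missing <- setdiff(required, names(features))
  if (length(missing))
    stop("feature table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  validate_labels(features$label)
  utils::write.csv(features[required], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "A1", "A2", "A3", "A4", "label", "dataset")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("feature table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  validate_labels(df$label)
  df$label <- factor(df$label, levels = lesion_classes)
  df[required]
}
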