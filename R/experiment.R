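# Experiment harness: the benchmark-dataset catalog, stratified
# splitting, the architecture-sweep plan, its execution, and the SVM /
# k-NN comparator baselines.

#' Benchmark dataset catalog
#'
#' Bookkeeping for the four public image collections the classifier was
#' designed around: identifier, image count, per-class counts and image
#' type. Shipped as reference constants; the images themselves are
#' external and never required.
#'
#' @return a data frame with one row per dataset (`B1`-`B4`): `dataset`,
#'   `name`, `n_images`, `n_classes`, `nevus`, `melanoma`, `dysplastic`,
#'   `image_type`.
#' @export
dataset_catalog <- function() {
  cat <- data.frame(
    dataset = c("B1", "B2", "B3", "B4"),
    name = c("7-Point", "PH2", "MED-NODE", "PAD-UFES-20"),
    n_images = c(439L, 197L, 170L, 289L),
    n_classes = c(3L, 3L, 2L, 2L),
    nevus = c(68L, 80L, 100L, 241L),
    melanoma = c(297L, 40L, 70L, 48L),
    dysplastic = c(74L, 77L, 0L, 0L),
    image_type = c("dermoscopic", "dermoscopic", "non-dermoscopic",
                   "dermoscopic"),
    stringsAsFactors = FALSE
  )
  stopifnot(all(cat$nevus + cat$melanoma + cat$dysplastic == cat$n_images))
  cat
}

#' Stratified train/validation/test split
#'
#' Splits `n` samples into disjoint, exhaustive train/validation/test
#' index sets, stratified by class when labels are given (per-class
#' proportions within one sample of the global ratio, by largest-remainder
#' allocation). In fractions mode the sizes are `floor(f_train * n)`,
#' `floor(f_val * n)` and the remainder; explicit counts are also accepted
#' so historical bookkeeping (e.g. 765/165/165 of 1095) is representable.
#'
#' @param n total number of samples.
#' @param fractions three fractions summing to 1 (default
#'   `c(0.70, 0.15, 0.15)`); ignored when `counts` is given.
#' @param counts optional explicit integer sizes `c(train, val, test)`
#'   summing to `n`.
#' @param labels optional class labels (length `n`) for stratification.
#' @param seed seed for the shuffle.
#' @return a list of class `data_split` with integer index vectors
#'   `train`, `val`, `test` and the `seed`.
#' @export
split_dataset <- function(n, fractions = c(0.70, 0.15, 0.15), counts = NULL,
                          labels = NULL, seed = 1) {
  if (n < 1) stop("`n` must be positive", call. = FALSE)
  if (is.null(counts)) {
    if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-8)
      stop("`fractions` must be three numbers summing to 1", call. = FALSE)
    sizes <- c(floor(fractions[1L] * n), floor(fractions[2L] * n), 0L)
    sizes[3L] <- n - sizes[1L] - sizes[2L]
  } else {
    if (length(counts) != 3L || sum(counts) != n)
      stop("`counts` must be three sizes summing to n", call. = FALSE)
    sizes <- as.integer(counts)
  }
  if (is.null(labels)) labels <- rep("all", n)
  if (length(labels) != n)
    stop("`labels` must have length n", call. = FALSE)
  labels <- as.character(labels)
  classes <- unique(labels)

  # largest-remainder allocation of each split size across classes
  alloc <- matrix(0L, length(classes), 3L,
                  dimnames = list(classes, c("train", "val", "test")))
  n_class <- table(labels)[classes]
  remaining <- as.integer(n_class)
  for (s in 1:2) {
    quota <- sizes[s] * as.integer(n_class) / n
    base <- pmin(floor(quota), remaining)
    short <- sizes[s] - sum(base)
    pref <- order(quota - floor(quota), decreasing = TRUE)
    while (short > 0L) {
      filled <- FALSE
      for (ci in pref) {
        if (short == 0L) break
        if (remaining[ci] - base[ci] > 0L) {
          base[ci] <- base[ci] + 1L
          short <- short - 1L
          filled <- TRUE
        }
      }
      if (!filled) break
    }
    alloc[, s] <- as.integer(base)
    remaining <- remaining - as.integer(base)
  }
  alloc[, 3L] <- remaining

  # Repair pass: largest-remainder train/val allocation can leave the
  # remainder (test) column more than one sample off a class's
  # proportional share. Shift single units between classes, preserving
  # row (class) and column (part) totals, until every cell is within one
  # sample of its exact quota.
  Q <- outer(as.integer(n_class), sizes) / n
  for (rep_i in seq_len(50L)) {
    dev <- alloc - Q
    bad <- which(abs(dev) > 1 + 1e-9, arr.ind = TRUE)
    if (nrow(bad) == 0L) break
    i <- bad[1L, 1L]; s <- bad[1L, 2L]
    if (dev[i, s] > 0) {
      s2 <- which.min(dev[i, ])                       # part where class i is short
      cand <- which(dev[, s] < 0 & alloc[, s2] > 0)   # class to take i's slot
      if (!length(cand) || s2 == s) break
      j <- cand[which.min(dev[cand, s])]
      alloc[i, s] <- alloc[i, s] - 1L; alloc[i, s2] <- alloc[i, s2] + 1L
      alloc[j, s] <- alloc[j, s] + 1L; alloc[j, s2] <- alloc[j, s2] - 1L
    } else {
      s2 <- which.max(dev[i, ])
      cand <- which(dev[, s] > 0 & alloc[, s] > 0)
      if (!length(cand) || s2 == s) break
      j <- cand[which.max(dev[cand, s])]
      alloc[i, s] <- alloc[i, s] + 1L; alloc[i, s2] <- alloc[i, s2] - 1L
      alloc[j, s] <- alloc[j, s] - 1L; alloc[j, s2] <- alloc[j, s2] + 1L
    }
  }

  idx <- with_seed(seed, {
    out <- list(train = integer(), val = integer(), test = integer())
    for (ci in seq_along(classes)) {
      pool <- sample(which(labels == classes[ci]))
      k1 <- alloc[ci, 1L]; k2 <- alloc[ci, 2L]
      out$train <- c(out$train, pool[seq_len(k1)])
      out$val <- c(out$val, pool[k1 + seq_len(k2)])
      out$test <- c(out$test, pool[k1 + k2 + seq_len(alloc[ci, 3L])])
    }
    out
  })
  structure(list(train = sort(idx$train), val = sort(idx$val),
                 test = sort(idx$test), seed = seed),
            class = "data_split")
}

#' Enumerate an architecture-sweep plan
#'
#' Crosses every non-empty subset of the dataset identifiers with the
#' hidden-layer sizes (and optional feature subsets) in a deterministic
#' order: subsets by increasing size then lexicographically, sizes
#' ascending. Four datasets and sizes `{8, 12, 16, 20}` give the study's
#' 60 configurations.
#'
#' @param datasets character vector of dataset ids.
#' @param hidden_sizes integer vector of hidden-layer sizes.
#' @param feature_subsets optional list of character vectors of feature
#'   names; default a single subset of all four indices.
#' @return a data frame with one row per configuration: `config_id`,
#'   `datasets` (`+`-joined), `n_hidden`, `features` (`+`-joined).
#' @export
enumerate_plan <- function(datasets, hidden_sizes,
                           feature_subsets = list(c("A1", "A2", "A3", "A4"))) {
  if (length(datasets) < 1L || length(hidden_sizes) < 1L)
    stop("need at least one dataset and one hidden size", call. = FALSE)
  if (anyDuplicated(datasets))
    stop("dataset ids must be unique", call. = FALSE)
  D <- length(datasets)
  subsets <- list()
  for (size in seq_len(D)) {
    combos <- utils::combn(sort(datasets), size, simplify = FALSE)
    subsets <- c(subsets, combos)
  }
  rows <- list()
  for (ss in subsets) {
    for (h in sort(hidden_sizes)) {
      for (fs in feature_subsets) {
        rows[[length(rows) + 1L]] <- data.frame(
          datasets = paste(ss, collapse = "+"),
          n_hidden = as.integer(h),
          features = paste(fs, collapse = "+"),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  plan <- do.call(rbind, rows)
  plan <- cbind(config_id = seq_len(nrow(plan)), plan)
  plan
}

#' Run an architecture sweep
#'
#' Trains and evaluates one classifier per plan row: the feature table is
#' restricted to the row's dataset subset and feature columns, split
#' stratified by class, and a network with the row's hidden size is
#' trained. Subsets whose samples span only two classes get two-output
#' networks. Configurations with fewer than 10 training samples are
#' skipped with a warning. The minimum-test-MSE row is flagged as the best
#' architecture.
#'
#' @param features a feature table ([extract_features_table()] layout).
#' @param plan a plan from [enumerate_plan()].
#' @param fractions train/val/test fractions.
#' @param seed master seed; each configuration derives its own.
#' @param ... passed to [network_config()] (e.g. `max_iter`).
#' @return a data frame of class `sweep_result`: per configuration the
#'   plan columns plus `n_train`, `test_mse`, `test_accuracy`,
#'   `stop_reason`, `skipped`, and `best` (`TRUE` on the minimum-test-MSE
#'   row). Detailed per-class reports are in `attr(, "reports")`.
#' @export
run_sweep <- function(features, plan, fractions = c(0.70, 0.15, 0.15),
                      seed = 1, ...) {
  if (is.null(plan) || nrow(plan) == 0L)
    stop("`plan` must contain at least one configuration", call. = FALSE)
  res <- plan
  res$n_train <- NA_integer_
  res$test_mse <- NA_real_
  res$test_accuracy <- NA_real_
  res$stop_reason <- NA_character_
  res$skipped <- FALSE
  reports <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    ds <- strsplit(plan$datasets[i], "+", fixed = TRUE)[[1L]]
    fs <- strsplit(plan$features[i], "+", fixed = TRUE)[[1L]]
    sub <- features[features$dataset %in% ds, , drop = FALSE]
    sub$label <- droplevels(factor(sub$label))
    cfg_seed <- (seed * 1009L + i) %% .Machine$integer.max
    split <- if (nrow(sub)) {
      split_dataset(nrow(sub), fractions, labels = sub$label, seed = cfg_seed)
    } else {
      list(train = integer(), val = integer(), test = integer())
    }
    if (length(split$train) < 10L) {
      warning(sprintf("configuration %d (%s, %d hidden): fewer than 10 training samples, skipped",
                      plan$config_id[i], plan$datasets[i], plan$n_hidden[i]))
      res$skipped[i] <- TRUE
      next
    }
    fml <- stats::as.formula(paste("label ~", paste(fs, collapse = " + ")))
    fit <- ffbpn(fml, sub, hidden = plan$n_hidden[i], split = split,
                 seed = cfg_seed, ...)
    res$n_train[i] <- length(split$train)
    res$test_mse[i] <- fit$mse["test"]
    res$test_accuracy[i] <- mean(fit$test_pred == fit$test_true)
    res$stop_reason[i] <- fit$stop_reason
    reports[[i]] <- fit$test_report
  }
  res$best <- FALSE
  done <- which(!res$skipped & is.finite(res$test_mse))
  if (length(done)) res$best[done[which.min(res$test_mse[done])]] <- TRUE
  attr(res, "reports") <- reports
  class(res) <- c("sweep_result", "data.frame")
  res
}

#' Comparator classifiers on a shared split
#'
#' Fits the network alongside an RBF-kernel support vector machine and a
#' k-nearest-neighbour classifier (k = 5) on the same
#' train/validation/test split and reports the same metric suite for each,
#' so the three methods are directly comparable. The SVM and k-NN use
#' established library implementations; only the network is trained here.
#'
#' @param features a feature table; predictors are the four indices.
#' @param split a [split_dataset()] result (validation indices are unused
#'   by SVM/k-NN).
#' @param seed seed for the network initialization.
#' @param hidden hidden-layer size for the network (default 16).
#' @param methods which classifiers to run.
#' @param ... passed to [network_config()].
#' @return a named list (one entry per method) of
#'   [classification_report()] objects.
#' @export
comparators <- function(features, split, seed = 1, hidden = 16,
                        methods = c("ffbpn", "svm", "knn"), ...) {
  methods <- match.arg(methods, several.ok = TRUE)
  feats <- c("A1", "A2", "A3", "A4")
  x <- as.matrix(features[feats])
  y <- droplevels(factor(features$label))
  tr <- c(split$train)
  te <- c(split$test)
  if (length(tr) < 10L) stop("fewer than 10 training samples", call. = FALSE)
  # features constant on the training set (e.g. A3 on binary-only input)
  # carry no information and upset distance-based methods; drop them for
  # the comparator fits, mirroring the network's degenerate-feature flag
  keep <- apply(x[tr, , drop = FALSE], 2L, function(v) diff(range(v)) > 0)
  x <- x[, keep, drop = FALSE]
  out <- list()
  classes <- levels(y)
  if ("ffbpn" %in% methods) {
    fit <- ffbpn(label ~ A1 + A2 + A3 + A4,
                 data.frame(features[feats], label = y),
                 hidden = hidden, split = split, seed = seed, ...)
    out$ffbpn <- fit$test_report
  }
  if ("svm" %in% methods) {
    sv <- e1071::svm(x[tr, , drop = FALSE], y[tr], kernel = "radial")
    pred <- stats::predict(sv, x[te, , drop = FALSE])
    out$svm <- classification_report(y[te], pred, classes)
  }
  if ("knn" %in% methods) {
    pred <- with_seed(seed,
      class::knn(x[tr, , drop = FALSE], x[te, , drop = FALSE], y[tr], k = 5))
    out$knn <- classification_report(y[te], pred, classes)
  }
  out
}
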