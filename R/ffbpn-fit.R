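#' Fit a feedforward back-propagation lesion classifier
#'
#' Fits a single-hidden-layer feedforward network to asymmetry features by
#' Levenberg-Marquardt least squares on a one-hot coding of the class
#' labels, with an internal stratified train/validation/test split and
#' validation-based early stopping. This is the package's central model
#' interface; the underlying primitives ([init_network()], [train_lm()],
#' [predict_class()]) are exported for direct use.
#'
#' @param formula a model formula, e.g. `label ~ A1 + A2 + A3 + A4`; the
#'   response must be a factor (or coercible) giving the lesion class.
#' @param data a data frame containing the variables (typically a feature
#'   table from [extract_features_table()]).
#' @param hidden hidden-layer size (default 16, the size found to balance
#'   fit and generalization).
#' @param split train/validation/test fractions summing to 1 (default
#'   `c(0.70, 0.15, 0.15)`), or a [split_dataset()] result, or a list with
#'   integer index vectors `train`, `val`, `test`.
#' @param seed seed controlling both the split and the weight
#'   initialization.
#' @param ... further arguments passed to [network_config()]
#'   (`max_iter`, `mu0`, `mu_factor`, `max_val_fail`, ...).
#' @return an object of class `ffbpn`: a list with the trained network
#'   (`net`), `config`, `classes`, `split` (index sets), `history`,
#'   `stop_reason`, per-split `mse`, the held-out test predictions and
#'   their `test_report` (per-class metric suite), plus `call` and `terms`.
#' @examples
#' \donttest{
#' ds <- make_dataset(n_per_class = 30, seed = 1)
#' feats <- extract_features_table(ds$manifest, ds$masks)
#' fit <- ffbpn(label ~ A1 + A2 + A3 + A4, feats, hidden = 8, seed = 1,
#'              max_iter = 50)
#' print(fit)
#' predict(fit, feats[1:3, ])
#' }
#' @seealso [predict.ffbpn()], [classification_report()]
#' @export
ffbpn <- function(formula, data, hidden = 16, split = c(0.70, 0.15, 0.15),
                  seed = 1, ...) {
  cl <- match.call()
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  if (!is.factor(y)) y <- factor(y)
  y <- droplevels(y)
  x <- as.matrix(mf[, -1L, drop = FALSE])
  if (!is.numeric(x)) stop("all predictors must be numeric", call. = FALSE)
  classes <- levels(y)
  if (length(classes) < 2L)
    stop("need at least two classes to fit a classifier", call. = FALSE)

  idx <- resolve_split(split, n = nrow(x), labels = y, seed = seed)
  config <- network_config(n_in = ncol(x), n_hidden = hidden,
                           n_out = length(classes), seed = seed, ...)
  net <- init_network(config)
  t_all <- one_hot(y, classes)
  trained <- train_lm(net,
                      x[idx$train, , drop = FALSE], t_all[idx$train, , drop = FALSE],
                      x[idx$val, , drop = FALSE], t_all[idx$val, , drop = FALSE],
                      x[idx$test, , drop = FALSE], t_all[idx$test, , drop = FALSE],
                      config)
  net <- trained$net

  mse_by_split <- c(
    train = net_mse(net, x[idx$train, , drop = FALSE], t_all[idx$train, , drop = FALSE]),
    val = net_mse(net, x[idx$val, , drop = FALSE], t_all[idx$val, , drop = FALSE]),
    test = net_mse(net, x[idx$test, , drop = FALSE], t_all[idx$test, , drop = FALSE])
  )
  test_pred <- if (length(idx$test)) {
    factor(predict_class(net, x[idx$test, , drop = FALSE], classes),
           levels = classes)
  } else {
    factor(character(), levels = classes)
  }
  test_true <- y[idx$test]
  report <- if (length(idx$test))
    classification_report(test_true, test_pred, classes) else NULL

  structure(list(
    net = net, config = config, classes = classes, split = idx,
    history = trained$history, stop_reason = trained$stop_reason,
    mse = mse_by_split,
    test_pred = test_pred, test_true = test_true, test_report = report,
    x = x, y = y, terms = stats::terms(mf), call = cl
  ), class = "ffbpn")
}

resolve_split <- function(split, n, labels, seed) {
  if (is.list(split) && all(c("train", "val", "test") %in% names(split)))
    return(split[c("train", "val", "test")])
  if (is.numeric(split) && length(split) == 3L)
    return(split_dataset(n, fractions = split, labels = labels, seed = seed))
  stop("`split` must be three fractions or a list of train/val/test indices",
       call. = FALSE)
}

#' @export
print.ffbpn <- function(x, ...) {
  cat("Feedforward back-propagation lesion classifier\n")
  cat(sprintf("  architecture: %d-%d-%d (tanh hidden, linear output)\n",
              x$config$n_in, x$config$n_hidden, x$config$n_out))
  cat(sprintf("  classes: %s\n", paste(x$classes, collapse = ", ")))
  cat(sprintf("  split: %d train / %d val / %d test\n",
              length(x$split$train), length(x$split$val), length(x$split$test)))
  cat(sprintf("  LM iterations: %d (stop: %s)\n",
              nrow(x$history), x$stop_reason))
  cat(sprintf("  MSE: train %.4g, val %.4g, test %.4g\n",
              x$mse["train"], x$mse["val"], x$mse["test"]))
  if (length(x$test_pred))
    cat(sprintf("  test accuracy: %.3f\n",
                mean(x$test_pred == x$test_true)))
  invisible(x)
}

#' @export
summary.ffbpn <- function(object, ...) {
  structure(list(fit = object), class = "summary.ffbpn")
}

#' @export
print.summary.ffbpn <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$fit$test_report)) {
    cat("\nPer-class test metrics (one-vs-rest):\n")
    print(round(as.data.frame(x$fit$test_report$metrics), 4))
  }
  invisible(x)
}

#' @export
coef.ffbpn <- function(object, ...) {
  object$net[c("W1", "b1", "W2", "b2")]
}

#' Predict method for fitted lesion classifiers
#'
#' @param object a fitted [ffbpn()] model.
#' @param newdata a data frame with the model's predictor columns; when
#'   omitted, the training-time feature matrix is used.
#' @param type `"class"` (default) for predicted labels, `"raw"` for the
#'   network's numeric outputs (one column per class).
#' @param ... unused.
#' @return a factor of predicted labels, or the raw output matrix.
#' @export
predict.ffbpn <- function(object, newdata = NULL,
                          type = c("class", "raw"), ...) {
  type <- match.arg(type)
  x <- if (is.null(newdata)) {
    object$x
  } else {
    tt <- stats::delete.response(object$terms)
    as.matrix(stats::model.frame(tt, newdata))
  }
  if (type == "raw") return(ffbpn_forward(object$net, x))
  factor(predict_class(object$net, x, object$classes), levels = object$classes)
}

#' @export
fitted.ffbpn <- function(object, ...) {
  ffbpn_forward(object$net, object$x)
}

#' @export
residuals.ffbpn <- function(object, ...) {
  ffbpn_forward(object$net, object$x) - one_hot(object$y, object$classes)
}

#' Plot the training history of a fitted classifier
#'
#' Draws the per-iteration training, validation and test MSE on a log
#' scale, the standard diagnostic for over- or under-training.
#'
#' @param x a fitted [ffbpn()] model.
#' @param ... further arguments passed to [graphics::matplot()].
#' @export
plot.ffbpn <- function(x, ...) {
  h <- x$history
  if (!nrow(h)) {
    warning("no training iterations to plot")
    return(invisible(x))
  }
  graphics::matplot(h$iter, cbind(h$mse_train, h$mse_val, h$mse_test),
                    type = "l", lty = 1, lwd = 2,
                    col = c("black", "steelblue", "firebrick"),
                    log = "y", xlab = "LM iteration", ylab = "MSE", ...)
  graphics::legend("topright", c("train", "validation", "test"),
                   col = c("black", "steelblue", "firebrick"),
                   lty = 1, lwd = 2, bty = "n")
  invisible(x)
}

#' Serialize / restore a fitted network as JSON
#'
#' Stores the weights, input scaling, configuration, class labels and a
#' history summary in a plain-text JSON file.
#'
#' @param fit a fitted [ffbpn()] model or a bare `ffbpn_net`.
#' @param path output JSON path.
#' @return `write_ffbpn_json` returns `path` invisibly; `read_ffbpn_json`
#'   returns a list with `net` (an `ffbpn_net`) and `classes`.
#' @export
write_ffbpn_json <- function(fit, path) {
  net <- if (inherits(fit, "ffbpn")) fit$net else fit
  classes <- if (inherits(fit, "ffbpn")) fit$classes else
    paste0("class", seq_len(nrow(net$W2)))
  obj <- list(
    classes = classes,
    W1 = net$W1, b1 = net$b1, W2 = net$W2, b2 = net$b2,
    scaling = net$scaling,
    config = unclass(net$config),
    stop_reason = if (inherits(fit, "ffbpn")) fit$stop_reason else NULL,
    mse = if (inherits(fit, "ffbpn")) as.list(fit$mse) else NULL
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_ffbpn_json
#' @export
read_ffbpn_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  config <- do.call(network_config, obj$config[names(obj$config) %in%
    names(formals(network_config))])
  scaling <- obj$scaling
  if (!is.null(scaling)) scaling$degenerate <- as.logical(scaling$degenerate)
  net <- structure(list(
    W1 = matrix(obj$W1, config$n_hidden, config$n_in),
    b1 = as.numeric(obj$b1),
    W2 = matrix(obj$W2, config$n_out, config$n_hidden),
    b2 = as.numeric(obj$b2),
    scaling = scaling, config = config
  ), class = "ffbpn_net")
  list(net = net, classes = obj$classes)
}
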