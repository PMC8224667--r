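# Low-level feedforward network machinery: one hidden tanh layer, linear
# outputs, full-batch Levenberg-Marquardt least-squares training on the
# one-hot coding residuals.

#' Network training configuration
#'
#' @param n_in number of input features (4 asymmetry indices by default).
#' @param n_hidden hidden-layer size (the study sweeps 8, 12, 16, 20; any
#'   value >= 1 is allowed).
#' @param n_out number of output units (3 for the three-class problem, 2
#'   for two-class dataset subsets).
#' @param mu0 initial Levenberg-Marquardt damping (default 0.01, the
#'   conventional "learning rate" of the reference implementation).
#' @param mu_factor multiplicative damping update (> 1, default 10).
#' @param mu_max damping overflow bound; training stops above it.
#' @param max_iter maximum accepted LM iterations (default 1000).
#' @param max_val_fail consecutive validation-MSE increases tolerated
#'   before early stopping (default 6).
#' @param grad_tol stop when the gradient infinity-norm falls below this.
#' @param scale_inputs min-max scale inputs to `[-1, 1]` using
#'   training-set statistics (default `TRUE`).
#' @param seed RNG seed for weight initialization.
#' @return a list of class `network_config`.
#' @export
network_config <- function(n_in = 4, n_hidden = 16, n_out = 3,
                           mu0 = 0.01, mu_factor = 10, mu_max = 1e10,
                           max_iter = 1000, max_val_fail = 6,
                           grad_tol = 1e-7, scale_inputs = TRUE, seed = 1) {
  stopifnot(n_in >= 1, n_hidden >= 1, n_out >= 1, mu0 > 0, mu_factor > 1,
            max_iter >= 0)
  structure(list(n_in = as.integer(n_in), n_hidden = as.integer(n_hidden),
                 n_out = as.integer(n_out), mu0 = mu0, mu_factor = mu_factor,
                 mu_max = mu_max, max_iter = as.integer(max_iter),
                 max_val_fail = as.integer(max_val_fail), grad_tol = grad_tol,
                 scale_inputs = isTRUE(scale_inputs), seed = as.integer(seed)),
            class = "network_config")
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Initialize a network with seeded uniform random weights
#'
#' Weights and biases are drawn independently from `U[-0.5, 0.5]` using the
#' configuration seed; the same seed always yields the identical network.
#' Input scaling starts as the identity and is learned by [train_lm()].
#'
#' @param config a [network_config()].
#' @return a list of class `ffbpn_net` with weight matrices `W1`
#'   (`n_hidden x n_in`), `b1`, `W2` (`n_out x n_hidden`), `b2`, and
#'   `scaling` (per-feature `min`/`max`, `NULL` until learned).
#' @export
init_network <- function(config) {
  k <- config$n_hidden; ni <- config$n_in; no <- config$n_out
  w <- with_seed(config$seed,
                 stats::runif(k * ni + k + no * k + no, -0.5, 0.5))
  unflatten_weights(w, config)
}

flatten_weights <- function(net) {
  c(as.vector(net$W1), net$b1, as.vector(net$W2), net$b2)
}

unflatten_weights <- function(w, config, scaling = NULL) {
  k <- config$n_hidden; ni <- config$n_in; no <- config$n_out
  i <- 0L
  W1 <- matrix(w[i + seq_len(k * ni)], k, ni); i <- i + k * ni
  b1 <- w[i + seq_len(k)]; i <- i + k
  W2 <- matrix(w[i + seq_len(no * k)], no, k); i <- i + no * k
  b2 <- w[i + seq_len(no)]
  structure(list(W1 = W1, b1 = b1, W2 = W2, b2 = b2,
                 scaling = scaling, config = config),
            class = "ffbpn_net")
}

# Min-max scaling to [-1, 1] learned on the training inputs; constant
# features are flagged and mapped to 0.
learn_scaling <- function(x) {
  mins <- apply(x, 2L, min); maxs <- apply(x, 2L, max)
  list(min = mins, max = maxs, degenerate = maxs - mins <= 0)
}

apply_scaling <- function(x, scaling) {
  if (is.null(scaling)) return(x)
  span <- scaling$max - scaling$min
  span[scaling$degenerate] <- 1
  sweep(sweep(x, 2L, (scaling$min + scaling$max) / 2), 2L, span / 2, "/")
}

#' Forward pass of the network
#'
#' Computes `y = W2 tanh(W1 x_s + b1) + b2`, where `x_s` is the min-max
#' scaled input (identity until scaling has been learned).
#'
#' @param net an `ffbpn_net`.
#' @param x a feature vector of length `n_in`, or a matrix with `n_in`
#'   columns (one sample per row).
#' @return an output vector of length `n_out`, or an `n x n_out` matrix.
#' @export
ffbpn_forward <- function(net, x) {
  single <- is.null(dim(x))
  xm <- if (single) matrix(x, 1L) else as.matrix(x)
  if (ncol(xm) != ncol(net$W1))
    stop(sprintf("input has %d feature(s); network expects %d",
                 ncol(xm), ncol(net$W1)), call. = FALSE)
  xs <- apply_scaling(xm, net$scaling)
  H <- tanh(xs %*% t(net$W1) + rep(1, nrow(xs)) %o% net$b1)
  Y <- H %*% t(net$W2) + rep(1, nrow(xs)) %o% net$b2
  if (single) drop(Y) else Y
}

# Residuals e = y - t (n x n_out) and the analytic Jacobian de/dw
# (rows = sample-output pairs, outputs stacked; cols = flattened weights).
lm_residual_jacobian <- function(net, x, targets) {
  n <- nrow(x); k <- nrow(net$W1); ni <- ncol(net$W1); no <- nrow(net$W2)
  xs <- apply_scaling(x, net$scaling)
  H <- tanh(xs %*% t(net$W1) + rep(1, n) %o% net$b1)       # n x k
  Y <- H %*% t(net$W2) + rep(1, n) %o% net$b2              # n x no
  E <- Y - targets
  D <- 1 - H * H                                           # tanh'
  P <- k * ni + k + no * k + no
  J <- matrix(0, n * no, P)
  for (kk in seq_len(no)) {
    rows <- (kk - 1L) * n + seq_len(n)
    Dk <- D * rep(net$W2[kk, ], each = n)                  # n x k
    # dW1[j,i] block, column-major over (j, i)
    J[rows, seq_len(k * ni)] <-
      Dk[, rep(seq_len(k), ni)] * xs[, rep(seq_len(ni), each = k)]
    J[rows, k * ni + seq_len(k)] <- Dk
    # dW2[k',j]: nonzero only for k' == kk
    off <- k * ni + k
    J[rows, off + (seq_len(k) - 1L) * no + kk] <- H
    J[rows, off + no * k + kk] <- 1
  }
  list(e = as.vector(E), J = J, mse = mean(E * E))
}

net_mse <- function(net, x, targets) {
  if (is.null(x) || nrow(x) == 0L) return(NA_real_)
  E <- ffbpn_forward(net, x) - targets
  mean(E * E)
}

#' Train a network with Levenberg-Marquardt backpropagation
#'
#' Full-batch damped Gauss-Newton on the sum of squared output residuals:
#' each step solves `(J'J + mu I) dw = -J'e` over all flattened weights. A
#' step is accepted when the training MSE decreases, after which `mu` is
#' divided by `mu_factor`; otherwise `mu` is multiplied by `mu_factor` and
#' the step retried. Training stops at `max_iter` accepted iterations, when
#' `mu` exceeds `mu_max`, when the gradient infinity-norm falls below
#' `grad_tol`, or after `max_val_fail` consecutive validation-MSE
#' increases, in which case the weights with the best validation MSE are
#' returned.
#'
#' @param net an initial `ffbpn_net` from [init_network()].
#' @param x_train,t_train training inputs (`n x n_in`) and one-hot targets
#'   (`n x n_out`).
#' @param x_val,t_val optional validation set for early stopping.
#' @param x_test,t_test optional monitoring set (never influences
#'   training).
#' @param config a [network_config()]; defaults to `net$config`.
#' @return a list with the trained `net` and a `history` data frame
#'   (per accepted iteration: `mse_train`, `mse_val`, `mse_test`, `mu`)
#'   plus `stop_reason` in `max_iter`, `mu_overflow`, `grad_tol`,
#'   `val_fail`.
#' @export
train_lm <- function(net, x_train, t_train, x_val = NULL, t_val = NULL,
                     x_test = NULL, t_test = NULL, config = net$config) {
  x_train <- as.matrix(x_train); t_train <- as.matrix(t_train)
  if (nrow(x_train) == 0L) stop("training set is empty", call. = FALSE)
  if (nrow(x_train) != nrow(t_train))
    stop("inputs and targets disagree in length", call. = FALSE)
  if (!is.null(x_val)) { x_val <- as.matrix(x_val); t_val <- as.matrix(t_val) }
  if (!is.null(x_test)) { x_test <- as.matrix(x_test); t_test <- as.matrix(t_test) }
  if (config$scale_inputs && is.null(net$scaling))
    net$scaling <- learn_scaling(x_train)

  hist <- list()
  stop_reason <- "max_iter"
  if (config$max_iter == 0L) {
    return(list(net = net, history = empty_history(), stop_reason = "max_iter"))
  }
  w <- flatten_weights(net)
  rj <- lm_residual_jacobian(net, x_train, t_train)
  mse <- rj$mse
  mu <- config$mu0
  best_val <- Inf; best_w <- w; val_fail <- 0L
  have_val <- !is.null(x_val) && nrow(x_val) > 0L

  for (it in seq_len(config$max_iter)) {
    g <- crossprod(rj$J, rj$e)
    if (max(abs(g)) < config$grad_tol) { stop_reason <- "grad_tol"; break }
    JtJ <- crossprod(rj$J)
    accepted <- FALSE
    while (!accepted) {
      H <- JtJ + diag(mu, ncol(JtJ))
      dw <- tryCatch(solve(H, -g), error = function(e) NULL)
      if (!is.null(dw)) {
        trial_w <- w + as.vector(dw)
        trial_net <- unflatten_weights(trial_w, config, net$scaling)
        trial_mse <- net_mse(trial_net, x_train, t_train)
        if (is.finite(trial_mse) && trial_mse < mse) {
          w <- trial_w; net <- trial_net; mse <- trial_mse
          mu <- max(mu / config$mu_factor, 1e-20)
          accepted <- TRUE
          break
        }
      }
      mu <- mu * config$mu_factor
      if (mu > config$mu_max) break
    }
    if (!accepted) { stop_reason <- "mu_overflow"; break }

    mse_val <- if (have_val) net_mse(net, x_val, t_val) else NA_real_
    mse_test <- if (!is.null(x_test)) net_mse(net, x_test, t_test) else NA_real_
    hist[[length(hist) + 1L]] <- c(iter = it, mse_train = mse,
                                   mse_val = mse_val, mse_test = mse_test,
                                   mu = mu)
    if (have_val) {
      if (mse_val < best_val) {
        best_val <- mse_val; best_w <- w; val_fail <- 0L
      } else {
        val_fail <- val_fail + 1L
        if (val_fail >= config$max_val_fail) { stop_reason <- "val_fail"; break }
      }
    }
    rj <- lm_residual_jacobian(net, x_train, t_train)
    mse <- rj$mse
  }
  if (have_val) net <- unflatten_weights(best_w, config, net$scaling)
  history <- if (length(hist)) {
    as.data.frame(do.call(rbind, hist))
  } else {
    empty_history()
  }
  list(net = net, history = history, stop_reason = stop_reason)
}

empty_history <- function() {
  data.frame(iter = integer(), mse_train = numeric(), mse_val = numeric(),
             mse_test = numeric(), mu = numeric())
}

#' Predict the class of a feature vector
#'
#' The predicted class is the label of the maximal output unit; ties are
#' broken in favour of the lowest class index.
#'
#' @param net a trained `ffbpn_net`.
#' @param x a feature vector or matrix (one sample per row).
#' @param classes ordered class labels, one per output unit.
#' @return a character vector of predicted labels.
#' @export
predict_class <- function(net, x, classes) {
  if (length(classes) != nrow(net$W2))
    stop("`classes` must name one label per output unit", call. = FALSE)
  y <- ffbpn_forward(net, x)
  if (is.null(dim(y))) y <- matrix(y, 1L)
  classes[apply(y, 1L, which.max)]
}

#' Hidden-layer size heuristic
#'
#' Rule-of-thumb estimate of the hidden-neuron count from the number of
#' input nodes `n_in`, input samples `n_samples` and hidden layers
#' `n_layers`. The `"printed"` variant is
#' `ceiling((n_in + n_samples) / n_layers)`; the `"sqrt"` variant,
#' `ceiling(sqrt(n_in + n_samples) / n_layers)`, gives counts in the tens
#' for typical study sizes. The two variants differ by orders of magnitude;
#' both are provided because the literature reports sizes consistent only
#' with the latter.
#'
#' @param n_in,n_samples,n_layers positive integers.
#' @param variant `"printed"` or `"sqrt"`.
#' @return an integer hidden-layer size.
#' @export
suggest_hidden_neurons <- function(n_in, n_samples, n_layers = 1,
                                   variant = c("printed", "sqrt")) {
  variant <- match.arg(variant)
  if (n_in < 1 || n_samples < 1 || n_layers < 1)
    stop("all inputs must be positive", call. = FALSE)
  switch(variant,
    printed = as.integer(ceiling((n_in + n_samples) / n_layers)),
    sqrt = as.integer(ceiling(sqrt(n_in + n_samples) / n_layers))
  )
}

# One-hot coding of a factor over its levels.
one_hot <- function(y, classes = levels(y)) {
  y <- factor(y, levels = classes)
  m <- matrix(0, length(y), length(classes),
              dimnames = list(NULL, classes))
  m[cbind(seq_along(y), as.integer(y))] <- 1
  m
}
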