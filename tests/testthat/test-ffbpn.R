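test_that("network initialization is seed-deterministic with the right shapes", {
  cfg <- network_config(n_in = 4, n_hidden = 16, n_out = 3, seed = 5)
  n1 <- init_network(cfg)
  n2 <- init_network(cfg)
  expect_identical(n1$W1, n2$W1)
  expect_identical(n1$b2, n2$b2)
  expect_equal(dim(n1$W1), c(16, 4))
  expect_equal(dim(n1$W2), c(3, 16))
  expect_true(all(abs(lesionasym:::flatten_weights(n1)) <= 0.5))

  n3 <- init_network(network_config(n_in = 4, n_hidden = 16, n_out = 3, seed = 6))
  expect_false(identical(n1$W1, n3$W1))
})

test_that("the forward pass computes W2 tanh(W1 x + b1) + b2", {
  cfg <- network_config(n_in = 1, n_hidden = 1, n_out = 1,
                        scale_inputs = FALSE, seed = 1)
  net <- init_network(cfg)
  net$W1[] <- 1; net$b1[] <- 0; net$W2[] <- 1; net$b2[] <- 0
  expect_equal(ffbpn_forward(net, 0), 0)
  expect_equal(ffbpn_forward(net, 1), tanh(1))

  zero <- net; zero$W1[] <- 0; zero$W2[] <- 0
  expect_equal(ffbpn_forward(zero, 3.7), 0)

  expect_error(ffbpn_forward(net, c(1, 2)), "expects")
})

test_that("the LM Jacobian matches central finite differences", {
  cfg <- network_config(n_in = 3, n_hidden = 4, n_out = 2,
                        scale_inputs = FALSE, seed = 9)
  net <- init_network(cfg)
  set.seed(10)
  X <- matrix(stats::rnorm(15), 5, 3)
  Tg <- matrix(stats::rnorm(10), 5, 2)
  rj <- lesionasym:::lm_residual_jacobian(net, X, Tg)
  w0 <- lesionasym:::flatten_weights(net)
  h <- 1e-6
  num <- matrix(0, length(rj$e), length(w0))
  for (p in seq_along(w0)) {
    wp <- w0; wp[p] <- wp[p] + h
    wm <- w0; wm[p] <- wm[p] - h
    ep <- as.vector(ffbpn_forward(lesionasym:::unflatten_weights(wp, cfg), X) - Tg)
    em <- as.vector(ffbpn_forward(lesionasym:::unflatten_weights(wm, cfg), X) - Tg)
    num[, p] <- (ep - em) / (2 * h)
  }
  expect_lt(max(abs(num - rj$J)) / max(abs(num)), 1e-5)
})

test_that("LM training solves a realizable one-neuron regression", {
  x <- matrix(seq(-2, 2, length.out = 20), ncol = 1)
  y <- 0.5 * tanh(2 * x)
  cfg <- network_config(n_in = 1, n_hidden = 1, n_out = 1,
                        scale_inputs = FALSE, seed = 4, max_iter = 200)
  res <- train_lm(init_network(cfg), x, y, config = cfg)
  expect_lte(utils::tail(res$history$mse_train, 1), 1e-6)
  # training MSE strictly decreases on every accepted step
  expect_true(all(diff(res$history$mse_train) < 0))
})

test_that("training with max_iter = 0 returns the initial network untouched", {
  cfg <- network_config(n_in = 2, n_hidden = 2, n_out = 1,
                        scale_inputs = FALSE, seed = 2, max_iter = 0)
  net <- init_network(cfg)
  res <- train_lm(net, matrix(1:4, 2, 2), matrix(c(0, 1), 2, 1), config = cfg)
  expect_identical(res$net$W1, net$W1)
  expect_equal(nrow(res$history), 0)
  expect_error(train_lm(net, matrix(numeric(), 0, 2), matrix(numeric(), 0, 1),
                        config = cfg), "empty")
})

test_that("a student network recovers a noiseless teacher", {
  cfgT <- network_config(n_in = 2, n_hidden = 3, n_out = 1,
                         scale_inputs = FALSE, seed = 11, max_iter = 300)
  teacher <- init_network(cfgT)
  set.seed(13)
  X <- matrix(stats::runif(400, -1, 1), 200, 2)
  Y <- matrix(ffbpn_forward(teacher, X), ncol = 1)
  student_cfg <- network_config(n_in = 2, n_hidden = 3, n_out = 1,
                                scale_inputs = FALSE, seed = 22, max_iter = 300)
  res <- train_lm(init_network(student_cfg), X, Y, config = student_cfg)
  expect_lt(utils::tail(res$history$mse_train, 1), 1e-4)
})

test_that("training trajectories are seed-deterministic", {
  ft <- toy_feature_table(20, seed = 3)
  f1 <- ffbpn(label ~ A1 + A2 + A4, ft, hidden = 4, seed = 9, max_iter = 40)
  f2 <- ffbpn(label ~ A1 + A2 + A4, ft, hidden = 4, seed = 9, max_iter = 40)
  expect_identical(f1$history, f2$history)
  expect_identical(coef(f1), coef(f2))
})

test_that("predict_class takes the argmax with low-index tie-breaking", {
  cfg <- network_config(n_in = 3, n_hidden = 2, n_out = 3,
                        scale_inputs = FALSE, seed = 1)
  net <- init_network(cfg)
  # force constant outputs through the biases
  net$W1[] <- 0; net$W2[] <- 0
  classes <- c("nevus", "melanoma", "dysplastic")
  net$b2 <- c(0.9, 0.2, 0.1)
  expect_equal(predict_class(net, c(0, 0, 0), classes), "nevus")
  net$b2 <- c(0.5, 0.5, 0.1)
  expect_equal(predict_class(net, c(0, 0, 0), classes), "nevus")
  net$b2 <- c(0.1, 0.2, 0.9)
  expect_equal(predict_class(net, c(0, 0, 0), classes), "dysplastic")
  expect_error(predict_class(net, c(0, 0, 0), classes[1:2]), "label per output")
})

test_that("the hidden-size heuristic evaluates both variants", {
  expect_equal(suggest_hidden_neurons(4, 170, 1, "printed"), 174L)
  expect_equal(suggest_hidden_neurons(4, 765, 1, "printed"), 769L)
  expect_equal(suggest_hidden_neurons(4, 192, 1, "sqrt"), 14L)
  expect_error(suggest_hidden_neurons(0, 10, 1), "positive")
})

test_that("the ffbpn model object supports the standard methods", {
  ft <- toy_feature_table(25, seed = 5)
  fit <- ffbpn(label ~ A1 + A2 + A3 + A4, ft, hidden = 6, seed = 2,
               max_iter = 60)
  expect_s3_class(fit, "ffbpn")
  expect_equal(length(fit$split$train) + length(fit$split$val) +
                 length(fit$split$test), nrow(ft))

  out <- predict(fit, ft[1:4, ], type = "raw")
  expect_equal(dim(out), c(4, 3))
  cls <- predict(fit, ft[1:4, ])
  expect_s3_class(cls, "factor")
  expect_equal(levels(cls), fit$classes)

  expect_equal(dim(residuals(fit)), c(nrow(ft), 3))
  expect_equal(names(coef(fit)), c("W1", "b1", "W2", "b2"))
  expect_output(print(fit), "architecture: 4-6-3")
  expect_output(print(summary(fit)), "Per-class test metrics")

  # degenerate constant feature (A3) is flagged, not fatal
  expect_true(fit$net$scaling$degenerate[["A3"]])

  # separable toy table: near-perfect held-out accuracy
  expect_gte(mean(fit$test_pred == fit$test_true), 0.9)
})

test_that("JSON serialization round-trips a fitted network", {
  ft <- toy_feature_table(15, seed = 7)
  fit <- ffbpn(label ~ A1 + A2 + A4, ft, hidden = 3, seed = 3, max_iter = 30)
  path <- withr::local_tempfile(fileext = ".json")
  write_ffbpn_json(fit, path)
  back <- read_ffbpn_json(path)
  x <- as.matrix(ft[c("A1", "A2", "A4")])
  expect_equal(ffbpn_forward(back$net, x), ffbpn_forward(fit$net, x))
  expect_equal(back$classes, fit$classes)
})
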