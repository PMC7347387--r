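# STRF ridge fit, double-exponential nonlinearity, plasticity stage,
# combined loss, and the shared predict contract.

test_that("ridge STRF recovers a planted linear receptive field", {
  ds <- small_dataset("linear", seed = 3, noise_sd = 0)
  dw <- dataset_windows(ds)
  fit <- fit_strf(dw$train$x, dw$train$y, validation = dw$validation)
  w_true <- as.numeric(small_templates()[[1]])
  expect_gt(cor(as.numeric(fit$w), w_true), 0.95)
  # noiseless linear data: held-out prediction is essentially perfect
  p <- predict(fit, dw$test$x)
  expect_gt(cor(p, dw$test$y), 0.999)
})

test_that("ridge of a zero response is the zero STRF", {
  dw <- small_windows()
  fit <- fit_strf(dw$train$x, rep(0, nrow(dw$train$x)),
                  validation = list(x = dw$validation$x,
                                    y = rep(0, nrow(dw$validation$x))))
  expect_true(all(fit$w == 0))
  expect_equal(fit$bias, 0)
})

test_that("STRF prediction equals the explicit dot-product oracle", {
  dw <- small_windows()
  ds <- small_dataset()
  fit <- fit_strf(dw$train$x, dw$train$y, validation = dw$validation)
  x <- dw$test$x[1:7, , drop = FALSE]
  p <- predict(fit, x)
  oracle <- numeric(7)
  for (i in 1:7) {
    xm <- matrix(x[i, ], 12, 10)
    acc <- 0
    for (lag in 1:12) for (f in 1:10) acc <- acc + fit$w[lag, f] * xm[lag, f]
    oracle[i] <- acc + fit$bias
  }
  expect_equal(p, oracle, tolerance = 1e-10)
})

test_that("double exponential has the right limits and inflection value", {
  p <- c(a = 2.5, b = -1, c = 0.7, kappa = 0.3)
  expect_equal(double_exponential(1e6, p), p[["b"]] + p[["a"]])
  expect_equal(double_exponential(-1e6, p), p[["b"]])
  expect_equal(double_exponential(0.7, p),
               p[["b"]] + p[["a"]] * exp(-1))
  # monotone for a > 0, bounded between b and b + a
  x <- seq(-5, 5, by = 0.1)
  y <- double_exponential(x, p)
  expect_true(all(diff(y) >= 0))          # saturates flat in floating point
  expect_true(all(diff(y[x > -2 & x < 2]) > 0))
  expect_true(all(y >= p[["b"]] & y <= p[["b"]] + p[["a"]]))
})

test_that("plasticity gain follows the printed recursion", {
  # zero input keeps the output at zero for any parameters
  z <- stp_adaptation(matrix(0, 50, 4), u = c(0.1, 0.5, 0.9, 1),
                      tau = c(2, 5, 10, 80))
  expect_true(all(z == 0))
  # u = 0: pure geometric relaxation of the initial state
  y <- stp_adaptation(matrix(1, 30, 1), u = 0, tau = 5, d0 = 0.8)
  d <- attr(y, "gain")
  expect_equal(as.numeric(d), 0.8 * (1 - 1 / 5)^(1:30))
  # constant drive: gain converges to u*X*tau / (1 + u*X*tau),
  # verified by iterating the recursion to convergence (oracle)
  u <- 0.3; tau <- 8; X <- 1.7
  y2 <- stp_adaptation(matrix(X, 3000, 1), u = u, tau = tau)
  d_inf <- attr(y2, "gain")[3000]
  expect_equal(d_inf, u * X * tau / (1 + u * X * tau), tolerance = 1e-8)
  d_it <- 0
  for (t in 1:5000) d_it <- d_it + u * X * (1 - d_it) - d_it / tau
  expect_equal(d_inf, d_it, tolerance = 1e-8)
  expect_error(stp_adaptation(matrix(1, 5, 1), u = 0.5, tau = -1), "tau")
  expect_error(stp_adaptation(matrix(-1, 5, 1), u = 0.5, tau = 2),
               "nonnegative")
})

test_that("combined loss matches its definition and the compiled version", {
  with_seed(8, {
    y <- rnorm(200)
    yh <- rnorm(200)
  })
  expect_equal(combined_loss(y, y), -1)
  expect_equal(combined_loss(y, y + 3), 9 - 1)
  oracle <- mean((y - yh)^2) - cor(y, yh)
  expect_equal(combined_loss(y, yh), oracle)
  expect_equal(dstrf:::cpp_combined_loss(y, yh), oracle)
  # zero-variance prediction: correlation term defined as 0
  expect_equal(combined_loss(y, rep(2, 200)), mean((y - 2)^2))
})

test_that("network prediction is deterministic and bias-only on silence", {
  m <- small_trained_cnn()
  dw <- small_windows()
  x <- dw$test$x[1:20, , drop = FALSE]
  p1 <- predict(m, x)
  p2 <- predict(m, x)
  expect_identical(p1, p2)
  z <- matrix(0, 3, 120)
  expect_equal(predict(m, z), rep(m$weights$bias, 3))
  expect_error(predict(m, matrix(0, 2, 77)), "mismatch")
})

test_that("network response is positively homogeneous off the output bias", {
  m <- small_trained_cnn()
  dw <- small_windows()
  x <- dw$test$x[3, ]
  b <- m$weights$bias
  y1 <- predict(m, matrix(x, 1))
  for (s in c(0.999, 1.001)) {   # small scalings stay in the linear region
    ys <- predict(m, matrix(s * x, 1))
    expect_equal(ys - b, s * (y1 - b), tolerance = 1e-8)
  }
})

test_that("training obeys the early-stopping contract and is seeded", {
  ds <- small_dataset(seed = 21)
  dw <- dataset_windows(ds)
  cfg <- training_config(learning_rate = 1e-3, max_epochs = 12,
                         patience = 2, seed = 21)
  f1 <- train_cnn(dw$train$x, dw$train$y, validation = dw$validation,
                  config = cfg)
  expect_lte(f1$history$epochs_run - f1$history$best_epoch, 2)
  expect_equal(f1$history$best_val_loss,
               min(f1$history$val_loss))
  f2 <- train_cnn(dw$train$x, dw$train$y, validation = dw$validation,
                  config = cfg)
  expect_identical(f1$weights, f2$weights)   # same seed, same fit
  cfg2 <- cfg; cfg2$seed <- 22L
  f3 <- train_cnn(dw$train$x, dw$train$y, validation = dw$validation,
                  config = cfg2)
  expect_false(identical(f1$weights$conv1, f3$weights$conv1))
})

test_that("compiled weight gradients match finite differences", {
  with_seed(55, {
    m <- cnn_init(cnn_spec(input_lags = 12, n_bands = 10), seed = 55)
    x <- matrix(abs(rnorm(16 * 120)), 16)
    y <- rnorm(16)
  })
  lg <- dstrf:::cpp_cnn_loss_grads(m$weights, x, y, 12, 10)
  eps <- 1e-6
  worst <- 0
  for (nm in setdiff(names(lg$grads), "bias")) {
    w <- m$weights[[nm]]
    idx <- with_seed(56, cbind(sample(nrow(w), 4, replace = TRUE),
                               sample(ncol(w), 4, replace = TRUE)))
    for (r in 1:4) {
      wp <- m$weights; wm <- m$weights
      wp[[nm]][idx[r, 1], idx[r, 2]] <- wp[[nm]][idx[r, 1], idx[r, 2]] + eps
      wm[[nm]][idx[r, 1], idx[r, 2]] <- wm[[nm]][idx[r, 1], idx[r, 2]] - eps
      fd <- (dstrf:::cpp_cnn_loss_grads(wp, x, y, 12, 10)$loss -
             dstrf:::cpp_cnn_loss_grads(wm, x, y, 12, 10)$loss) / (2 * eps)
      worst <- max(worst, abs(lg$grads[[nm]][idx[r, 1], idx[r, 2]] - fd))
    }
  }
  expect_lt(worst, 1e-6)
})
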