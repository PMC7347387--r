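# Exact linearization machinery: locally connected expansion, MLP
# equivalence, the two DSTRF routes, jackknife statistics, significance
# masking and state switches.

test_that("locally connected expansion reproduces convolution exactly", {
  # identity 1x1 kernel
  k1 <- array(1, c(1, 1, 1, 1))
  w1 <- conv_to_locally_connected(k1, c(5, 4))
  expect_equal(as.matrix(w1), diag(20), ignore_attr = TRUE)
  # random 3x3 kernels vs a direct sliding-window convolution oracle
  with_seed(12, {
    k <- array(rnorm(3 * 3 * 2 * 3), c(3, 3, 2, 3))
    x <- array(rnorm(5 * 4 * 2), c(5, 4, 2))
  })
  w <- conv_to_locally_connected(k, c(5, 4))
  expect_true(all(Matrix::rowSums(w != 0) <= 18))
  got <- as.numeric(w %*% as.numeric(x))
  oracle <- array(0, c(5, 4, 3))
  for (l in 1:3) for (m in 1:5) for (n in 1:4) {
    acc <- 0
    for (dh in 1:3) for (dw in 1:3) for (c in 1:2) {
      mm <- m + dh - 2; nn <- n + dw - 2
      if (mm >= 1 && mm <= 5 && nn >= 1 && nn <= 4)
        acc <- acc + k[dh, dw, c, l] * x[mm, nn, c]
    }
    oracle[m, n, l] <- acc
  }
  expect_equal(got, as.numeric(oracle), tolerance = 1e-12)
  expect_error(conv_to_locally_connected(k, c(5, 4), stride = 2), "stride")
})

test_that("the equivalent MLP reproduces the network on arbitrary inputs", {
  m <- small_trained_cnn()
  mlp <- cnn_to_mlp(m)
  with_seed(4, x <- matrix(rnorm(100 * 120), 100))
  expect_lt(max(abs(mlp_forward(mlp, x) - predict(m, x))), 1e-10)
  z <- rep(0, 120)
  expect_equal(mlp_forward(mlp, z), m$weights$bias)
})

test_that("weight-product and gradient DSTRFs agree and satisfy the
           local-linearity identity", {
  m <- small_trained_cnn()
  mlp <- cnn_to_mlp(m)
  dw <- small_windows()
  with_seed(5, rows <- sample(nrow(dw$test$x), 12))
  for (r in rows) {
    x <- dw$test$x[r, ]
    d_g <- compute_dstrf(m, x, "gradient")
    d_w <- compute_dstrf(m, x, "weight_product", mlp = mlp)
    expect_lt(max(abs(d_g - d_w)), 1e-10)
    yhat <- predict(m, matrix(x, 1))
    expect_lt(abs(sum(d_g * matrix(x, 12, 10)) + m$weights$bias - yhat),
              1e-8)
  }
})

test_that("the DSTRF is constant within a linear region", {
  m <- small_trained_cnn()
  dw <- small_windows()
  x <- dw$test$x[7, ]
  d0 <- compute_dstrf(m, x, "gradient")
  # a perturbation small enough to flip no unit leaves it bitwise equal
  d1 <- compute_dstrf(m, x * (1 + 1e-10), "gradient")
  expect_identical(d0, d1)
})

test_that("a fully active hand-built network is globally linear", {
  # all-positive weights and nonnegative inputs: every unit stays active,
  # so the DSTRF equals the plain product of the weight matrices everywhere
  sp <- cnn_spec(input_lags = 6, n_bands = 5)
  with_seed(9, m <- cnn_init(sp, seed = 9))
  m$weights <- lapply(m$weights, function(w) if (is.matrix(w)) abs(w) else w)
  xs <- with_seed(2, matrix(abs(rnorm(3 * 30)), 3))
  ds <- lapply(1:3, function(i) compute_dstrf(m, xs[i, ], "gradient"))
  expect_equal(ds[[1]], ds[[2]], tolerance = 1e-12)
  expect_equal(ds[[2]], ds[[3]], tolerance = 1e-12)
})

test_that("a DSTRF series stacks per-window linearizations in order", {
  m <- small_trained_cnn()
  dw <- small_windows()
  x <- dw$test$x[1:30, , drop = FALSE]
  series <- compute_dstrf_series(m, x)
  expect_equal(dim(series), c(30, 120))
  for (r in c(1, 17, 30))
    expect_equal(matrix(series[r, ], 12, 10),
                 compute_dstrf(m, x[r, ], "gradient"))
})

test_that("jackknife mean and standard error follow the formula", {
  expect_equal(jackknife_mean_se(rep(3.2, 8)), list(mean = 3.2, se = 0))
  expect_equal(jackknife_mean_se(c(0, 2)), list(mean = 1, se = 1))
  with_seed(3, th <- rnorm(11))
  js <- jackknife_mean_se(th)
  n <- length(th)
  expect_equal(js$mean, mean(th))
  expect_equal(js$se, sqrt((n - 1) / n * sum((th - mean(th))^2)))
  expect_error(jackknife_mean_se(1), "at least 2")
})

test_that("sign-agreement masking keeps only near-unanimous coefficients", {
  with_seed(21, est <- array(rnorm(20 * 6 * 8), c(20, 6, 8)))
  est[, 2, 3] <- abs(est[, 2, 3])           # 20/20 positive -> kept
  est[, 4, 5] <- -abs(est[, 4, 5])          # 20/20 negative -> kept
  est[, 1, 1] <- abs(est[, 1, 1])
  est[1:2, 1, 1] <- -1                      # 18/20 positive -> zeroed
  msk <- significance_mask(est, min_agree = 19)
  expect_true(msk[2, 3]); expect_true(msk[4, 5]); expect_false(msk[1, 1])
  # brute-force sign-counting oracle over every coefficient
  oracle <- apply(est, c(2, 3), function(v)
    sum(v > 0) >= 19 || sum(v < 0) >= 19)
  expect_equal(unclass(msk), oracle, ignore_attr = TRUE)
  # masked mean: zeros where insignificant, ensemble mean elsewhere
  mean_series <- dstrf:::new_dstrf_series(attr(msk, "mean_series"), c(2, 4))
  masked <- apply_mask(mean_series, msk)
  expect_equal(masked[2, 3], mean(est[, 2, 3]))
  expect_equal(masked[1, 1], 0)
  # idempotence and sign preservation
  again <- apply_mask(masked, msk)
  expect_equal(unclass(again), unclass(masked))
  expect_true(all(sign(masked[msk]) == sign(mean_series[msk])))
  expect_error(significance_mask(est, min_agree = 25), "exceed")
})

test_that("leave-one-segment-out ensemble trains on disjoint folds", {
  ds <- small_dataset(seed = 31, duration_s = 30)
  cfg <- small_config(seed = 31, epochs = 2)
  ens <- train_jackknife_ensemble(ds$spectrogram, ds$response, ds$split,
                                  cfg, n = 2,
                                  spec = cnn_spec(input_lags = 12,
                                                  n_bands = 10))
  expect_length(ens$models, 2)
  ho <- do.call(rbind, ens$held_out)
  expect_true(ho[1, 2] <= ho[2, 1])     # disjoint contiguous halves
  # segment lengths differ by <= 1 frame
  lens <- ho[, 2] - ho[, 1] + 1
  expect_lte(abs(diff(lens)), 1)
  # different folds give different fits
  expect_false(identical(ens$models[[1]]$weights$conv1,
                         ens$models[[2]]$weights$conv1))
  expect_error(train_jackknife_ensemble(ds$spectrogram, ds$response,
                                        ds$split, cfg, n = 1), "at least 2")
})

test_that("state-switch counting matches the activation-pattern oracle", {
  m <- small_trained_cnn()
  mlp <- cnn_to_mlp(m)
  dw <- small_windows()
  x <- dw$test$x[1:15, , drop = FALSE]
  got <- count_state_switches(m, x)
  pats <- lapply(seq_len(15), function(i)
    unlist(mlp_forward(mlp, x[i, ], states = TRUE)$states))
  oracle <- mean(vapply(seq_len(14), function(i)
    sum(pats[[i]] != pats[[i + 1]]), numeric(1)))
  expect_equal(got, oracle)
  # identical consecutive windows switch nothing
  xx <- x[c(1, 1, 1), ]
  expect_equal(count_state_switches(m, xx), 0)
})
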