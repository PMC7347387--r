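# Nonlinearity metrics: complexity, gain change, temporal hold, alignment,
# shape change and subtype clustering.

mk_series <- function(mat_list) {
  dims <- dim(mat_list[[1]])
  vals <- t(vapply(mat_list, as.numeric, numeric(prod(dims))))
  dstrf:::new_dstrf_series(vals, dims)
}

base_pattern <- function(lag = 10, band = 5) {
  p <- matrix(0, 40, 32)
  p[lag + (-2:2), band + (-2:2)] <-
    outer(exp(-(-2:2)^2 / 2), exp(-(-2:2)^2 / 2))
  p
}

test_that("complexity counts the effective number of templates", {
  p <- base_pattern()
  expect_equal(complexity(mk_series(rep(list(p), 12))), 1)
  # k orthogonal equal-norm templates in equal counts -> k
  ps <- list(base_pattern(8, 4), base_pattern(20, 12), base_pattern(32, 24))
  series <- mk_series(rep(ps, each = 10))
  expect_equal(complexity(series), 3, tolerance = 1e-10)
  expect_error(complexity(mk_series(list(0 * p, 0 * p))), "all-zero")
})

test_that("complexity matches an independent eigendecomposition oracle", {
  with_seed(14, vals <- matrix(rnorm(25 * 60), 25))
  series <- dstrf:::new_dstrf_series(vals, c(10, 6))
  got <- complexity(series)
  ev <- eigen(crossprod(vals), symmetric = TRUE, only.values = TRUE)$values
  sv <- sqrt(pmax(ev, 0))
  expect_equal(got, sum(sv) / max(sv), tolerance = 1e-6)
})

test_that("gain change is the spread of per-slice magnitudes", {
  p <- base_pattern()
  expect_equal(gain_change(mk_series(rep(list(p), 7))), 0)
  pz <- p - mean(p)            # zero-mean slice: |W| = sd of coefficients
  s <- sd(as.numeric(pz))
  series <- mk_series(list(pz, 2 * pz))
  expect_equal(gain_change(series), s / sqrt(2))
  # formula oracle on random slices
  with_seed(15, vals <- matrix(rnorm(9 * 1280), 9))
  series2 <- dstrf:::new_dstrf_series(vals, c(40, 32))
  mags <- apply(vals, 1, function(v) sqrt(sum((v - mean(v))^2) / (1280 - 1)))
  expect_equal(gain_change(series2),
               sqrt(sum((mags - mean(mags))^2) / (9 - 1)))
})

drift_series <- function(n_events = 40, hold = 5, gap = 34) {
  p <- base_pattern(20, 10)
  slices <- list()
  for (e in seq_len(n_events)) {
    for (j in 0:hold) {
      s <- matrix(0, 40, 32)
      src <- dstrf:::shift_slices(matrix(as.numeric(p), 1), -j, c(40, 32))
      slices[[length(slices) + 1]] <- matrix(src, 40, 32)
    }
    for (g in seq_len(gap)) slices[[length(slices) + 1]] <- matrix(0, 40, 32)
  }
  mk_series(slices)
}

test_that("temporal hold recovers a planted drift duration", {
  series <- drift_series(n_events = 40, hold = 5)
  expect_equal(temporal_hold(series), 5)
  # direct evaluation of the shifted/unshifted correlations for n = 5:
  # within an event the realigned later slice matches exactly (beta = 1)
  x <- unclass(series)
  n <- 5
  lead <- x[seq_len(nrow(x) - n) + n, ]
  beta <- dstrf:::row_cor(x[seq_len(nrow(x) - n), ],
                          dstrf:::shift_slices(lead, n, c(40, 32)))
  ok <- is.finite(beta)
  expect_true(all(beta[ok] > 0.999))
  expect_gt(sum(ok), 30)
})

test_that("temporal hold is zero for static or independent slices", {
  p <- base_pattern()
  static <- mk_series(rep(list(p), 80))
  expect_equal(temporal_hold(static, max_shift = 20), 0)
  with_seed(16, vals <- matrix(rnorm(120 * 1280), 120))
  noise <- dstrf:::new_dstrf_series(vals, c(40, 32))
  expect_equal(temporal_hold(noise, max_shift = 20), 0)
})

test_that("alignment recovers planted shifts up to a global offset", {
  p <- base_pattern(20, 16)
  with_seed(18, true_shifts <- sample(-6:6, 30, replace = TRUE))
  slices <- lapply(true_shifts, function(s)
    matrix(dstrf:::shift_slices(matrix(as.numeric(p), 1), s, c(40, 32)),
           40, 32))
  series <- mk_series(slices)
  al <- align_dstrfs(series, max_shift = 10)
  expect_true(al$converged)
  rel <- al$shifts + true_shifts   # aligned slice = p shifted by s + n
  # recovery up to a constant offset; iterative alignment to a running
  # mean may leave isolated off-by-one slices (a local optimum)
  modal <- as.integer(names(which.max(table(rel))))
  expect_gte(mean(rel == modal), 0.9)
  expect_lt(complexity(al$aligned), 1.2)
  # already-aligned series: all shifts zero after one sweep
  al0 <- align_dstrfs(mk_series(rep(list(p), 10)), max_shift = 5)
  expect_true(all(al0$shifts == 0))
  expect_true(al0$converged)
  # mean slice-to-mean correlation never decreases across sweeps
  expect_true(all(diff(al$mean_cor_history) > -1e-8))
})

test_that("shape change discounts gain and drift but not templates", {
  p <- base_pattern(18, 8)
  with_seed(19, gains <- runif(25, 0.2, 3))
  gain_only <- mk_series(lapply(gains, function(g) g * p))
  expect_equal(shape_change(gain_only), 1, tolerance = 1e-8)
  # pure drift collapses to ~1 after alignment, below raw complexity
  drift <- mk_series(lapply(0:14, function(j)
    matrix(dstrf:::shift_slices(matrix(as.numeric(p), 1), j, c(40, 32)),
           40, 32)))
  expect_lt(shape_change(drift), 1.2)
  expect_gt(complexity(drift), 2)
  # two alternating orthogonal equal-norm templates stay rank 2
  q <- base_pattern(18, 24)
  two <- mk_series(rep(list(p, q), 12))
  expect_equal(shape_change(two), 2, tolerance = 0.2)
})

test_that("clustering finds planted subtypes and scale invariance", {
  p1 <- base_pattern(12, 6); p2 <- base_pattern(28, 26)
  with_seed(20, {
    slices <- lapply(1:60, function(i) {
      base <- if (i %% 2) p1 else p2
      base + matrix(rnorm(1280, sd = 0.02), 40, 32)
    })
  })
  series <- mk_series(slices)
  cl <- cluster_dstrfs(series, k_range = 1:4, seed = 2)
  expect_equal(cl$k, 2)
  lab <- cl$labels
  expect_equal(length(unique(lab[seq(1, 60, 2)])), 1)
  expect_equal(length(unique(lab[seq(2, 60, 2)])), 1)
  m1 <- cl$mean_dstrfs[[lab[1]]]
  expect_gt(cor(as.numeric(m1), as.numeric(p1)), 0.9)
  # a single template plus noise is one cluster
  with_seed(22, one <- lapply(1:40, function(i)
    p1 + matrix(rnorm(1280, sd = 0.02), 40, 32)))
  expect_equal(cluster_dstrfs(mk_series(one), k_range = 1:4, seed = 2)$k, 1)
  # labels are invariant to a global positive rescaling
  cl2 <- cluster_dstrfs(mk_series(lapply(slices, `*`, 7.3)),
                        k_range = 1:4, seed = 2)
  expect_true(all(cl2$labels == cl$labels) ||
                all(cl2$labels == 3 - cl$labels))
})

test_that("metric invariances under global rescaling", {
  with_seed(23, vals <- matrix(rnorm(20 * 1280), 20))
  s1 <- dstrf:::new_dstrf_series(vals, c(40, 32))
  s2 <- dstrf:::new_dstrf_series(5 * vals, c(40, 32))
  expect_equal(complexity(s1), complexity(s2))
  expect_equal(gain_change(s2), 5 * gain_change(s1))
  expect_equal(shape_change(s1, max_shift = 5), shape_change(s2, max_shift = 5))
})
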