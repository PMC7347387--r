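# Cochlear spectrogram, band reduction, windowing and splitting.

test_that("silence maps to an all-zero spectrogram of the right shape", {
  wav <- waveform(rep(0, 11025), 11025)
  sp <- auditory_spectrogram(wav)
  expect_equal(dim(sp), c(100, 128))
  expect_true(all(sp == 0))
  expect_equal(length(attr(sp, "center_freqs")), 128)
  expect_true(all(diff(attr(sp, "center_freqs")) > 0))
})

test_that("white noise at 11025 Hz gives 100 frames x 128 nonnegative bands", {
  wav <- waveform(dstrf:::with_seed(9, runif(11025, -1, 1)), 11025)
  sp <- auditory_spectrogram(wav)
  expect_equal(dim(sp), c(100, 128))
  expect_true(all(sp >= 0))
})

test_that("a pure tone concentrates energy near its band (bandpass oracle)", {
  skip_if_not_installed("signal")
  rate <- 11025
  cf <- attr(auditory_spectrogram(waveform(rep(0, 2206), rate)),
             "center_freqs")
  target <- 60                      # a mid-bank filter
  tone <- sin(2 * pi * cf[target] * seq_len(2 * rate) / rate)
  sp <- auditory_spectrogram(waveform(tone, rate))
  energy <- colSums(sp[20:180, ])  # avoid circular-filtering edges
  # the package's own answer: energy concentrated around the target band
  hit <- which.max(energy)
  expect_lte(abs(hit - target), 4)
  # independent oracle: per-band Butterworth bandpass energy of the raw tone
  oracle_energy <- vapply(seq(40, 80, by = 4), function(b) {
    bw <- cf[b] / 8
    ny <- rate / 2
    bf <- signal::butter(2, c(max(cf[b] - bw, 1), min(cf[b] + bw, ny - 1)) / ny,
                         type = "pass")
    mean(signal::filtfilt(bf, tone)^2)
  }, numeric(1))
  expect_equal(which.max(oracle_energy), which(seq(40, 80, by = 4) == target))
})

test_that("delaying audio by whole frames shifts the spectrogram", {
  rate <- 11000                      # integer samples per 10 ms frame
  with_seed(3, x <- runif(rate, -1, 1))
  k <- 5
  sp1 <- auditory_spectrogram(waveform(x, rate))
  sp2 <- auditory_spectrogram(waveform(c(rep(0, k * rate / 100), x), rate))
  mid <- 30:70
  expect_equal(unclass(sp2)[mid + k, ], unclass(sp1)[mid, ],
               tolerance = 0.05)
})

test_that("band reduction averages contiguous groups and keeps energy", {
  with_seed(7, vals <- matrix(abs(rnorm(50 * 128)), 50))
  sp <- dstrf:::new_spectrogram(vals, 100,
                                exp(seq(log(180), log(7000), length.out = 128)))
  red <- reduce_bands(sp, 32)
  expect_equal(dim(red), c(50, 32))
  # brute-force group-mean oracle over contiguous groups of 4
  oracle <- sapply(seq_len(32), function(g)
    rowMeans(vals[, (g - 1) * 4 + 1:4]))
  expect_equal(unclass(red), oracle, ignore_attr = TRUE)
  # constant input stays constant; impulse locality
  cst <- dstrf:::new_spectrogram(matrix(2.5, 10, 128), 100,
                                 attr(sp, "center_freqs"))
  expect_true(all(unclass(reduce_bands(cst, 32)) == 2.5))
  imp <- matrix(0, 10, 128); imp[, 1] <- 1
  impr <- reduce_bands(dstrf:::new_spectrogram(imp, 100,
                                               attr(sp, "center_freqs")), 32)
  expect_true(all(unclass(impr)[, -1] == 0))
  expect_true(all(unclass(impr)[, 1] > 0))
  expect_error(reduce_bands(sp, 200), "exceeds")
})

test_that("windowing covers the stimulus causally with full overlap", {
  with_seed(1, sp <- matrix(rnorm(100 * 6), 100))
  w <- make_windows(sp, window_frames = 40)
  expect_equal(nrow(w), 61)                      # 100 - 40 + 1
  expect_equal(attr(w, "first_valid_frame"), 39L)
  # consecutive windows share 39 frames exactly
  m1 <- matrix(w[1, ], 40, 6)
  m2 <- matrix(w[2, ], 40, 6)
  expect_identical(m1[-1, ], m2[-40, ])
  # window k reproduces frames k..k+39
  m5 <- matrix(w[5, ], 40, 6)
  expect_identical(m5, sp[5:44, ])
  # 40-frame input -> a single window equal to the input
  w1 <- make_windows(sp[1:40, ], 40)
  expect_equal(nrow(w1), 1)
  expect_identical(matrix(w1[1, ], 40, 6), sp[1:40, ])
  expect_error(make_windows(sp[1:10, ], 40), "exceeds")
})

test_that("band reduction commutes with windowing", {
  with_seed(2, vals <- matrix(abs(rnorm(80 * 16)), 80))
  sp <- dstrf:::new_spectrogram(vals, 100, exp(seq(log(200), log(4000),
                                                   length.out = 16)))
  red <- reduce_bands(sp, 4)
  w_red <- make_windows(red, 20)
  # reduce after windowing: group-average the lag-blocks of each window
  w_full <- make_windows(sp, 20)
  grp <- floor((seq_len(16) - 1) * 4 / 16) + 1
  manual <- sapply(seq_len(4), function(g) {
    cols <- which(grp == g)
    blocks <- lapply(cols, function(f) w_full[, (f - 1) * 20 + 1:20])
    Reduce(`+`, blocks) / length(cols)
  })
  expect_equal(unclass(w_red), matrix(manual, nrow(w_red)),
               ignore_attr = TRUE)
})

test_that("splits are disjoint, ordered and reproducible", {
  sp <- matrix(0, 1000, 4)
  resp <- rnorm(1000)
  s <- split_dataset(sp, resp, fractions = c(0.97, 0.03), test_range = NULL)
  expect_equal(length(s$train), 970)
  expect_equal(length(s$validation), 30)
  expect_length(intersect(s$train, s$validation), 0)
  s2 <- split_dataset(sp, resp, fractions = c(0.97, 0.03))
  expect_identical(s[c("train", "validation", "test")],
                   s2[c("train", "validation", "test")])
  expect_warning(split_dataset(sp, resp, fractions = c(1, 0)), "empty")
  expect_error(split_dataset(sp, resp, fractions = c(0.9, 0.03, 0.07),
                             test_range = 901:1000,
                             test_repeats = matrix(0, 2, 50)),
               "does not match")
})

test_that("valid-mode windowing drops straddling windows at split joins", {
  with_seed(4, sp <- matrix(rnorm(300 * 5), 300))
  resp <- rnorm(300)
  idx <- c(1:120, 181:300)           # two runs separated by a gap
  wf <- windows_for(sp, resp, idx, window_frames = 40)
  # each run loses its first 39 frames: (120-39) + (120-39) windows
  expect_equal(nrow(wf$x), 81 + 81)
  expect_equal(attr(wf$x, "segments"), c(81L, 81L))
  # alignment: window i predicts response at its final frame
  fi <- attr(wf$x, "frame_index")
  expect_equal(wf$y, resp[fi])
  expect_identical(matrix(wf$x[1, ], 40, 5), sp[1:40, ])
  expect_identical(matrix(wf$x[82, ], 40, 5), sp[181:220, ])
})

test_that("flattened windows reconstruct the original frame series", {
  with_seed(6, sp <- matrix(rnorm(70 * 8), 70))
  w <- make_windows(sp, 25)
  fr <- dstrf:::frames_from_windows(w)
  expect_length(fr, 1)
  expect_equal(fr[[1]], sp)
})
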