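# Causal stimulus windowing and dataset splitting.
#
# Lag convention: a window is a `window_frames x n_bands` patch whose last
# row (lag index `window_frames`) is the current stimulus frame; the window
# ending at frame t predicts the response at frame t.  Windows are stored
# vectorised as rows of an n x (window_frames * n_bands) matrix with the lag
# axis fastest (column j = lag + window_frames * (band - 1)).

#' Slide a causal time-frequency window over a spectrogram
#'
#' @param spec an `auditory_spectrogram` (or plain frames x bands matrix).
#' @param window_frames window length in frames (default 40, i.e. 400 ms at
#'   100 Hz).
#' @param stride hop between consecutive windows in frames (default 1, so
#'   consecutive windows overlap at `window_frames - 1` frames).
#' @return a `windowed_stimulus`: an n x (window_frames * n_bands) matrix
#'   with attributes `window_frames`, `n_bands`, `stride`,
#'   `first_valid_frame` (0-based index of the first predicted frame, equal
#'   to `window_frames - 1`), `frame_index` (1-based frame predicted by each
#'   window) and `segments` (run lengths of temporally contiguous windows).
#' @export
make_windows <- function(spec, window_frames = 40, stride = 1) {
  frames <- nrow(spec)
  n_bands <- ncol(spec)
  if (window_frames > frames)
    stop("window_frames exceeds the number of frames")
  stopifnot(stride >= 1)
  n <- (frames - window_frames) %/% stride + 1
  starts <- seq(0L, by = as.integer(stride), length.out = n)  # 0-based
  x <- matrix(0, n, window_frames * n_bands)
  sp <- unclass(spec)
  for (f in seq_len(n_bands)) {
    for (lag in seq_len(window_frames)) {
      x[, (f - 1L) * window_frames + lag] <- sp[starts + lag, f]
    }
  }
  new_windows(x, window_frames, n_bands, stride,
              frame_index = starts + window_frames,
              segments = if (stride == 1) n else rep(1L, n))
}

new_windows <- function(x, window_frames, n_bands, stride, frame_index,
                        segments) {
  structure(x,
            window_frames = as.integer(window_frames),
            n_bands = as.integer(n_bands),
            stride = as.integer(stride),
            first_valid_frame = as.integer(window_frames - 1L),
            frame_index = as.integer(frame_index),
            segments = as.integer(segments),
            class = c("windowed_stimulus", "matrix", "array"))
}

#' @export
print.windowed_stimulus <- function(x, ...) {
  cat(sprintf("<windowed stimulus: %d windows of %d lags x %d bands (stride %d)>\n",
              nrow(x), attr(x, "window_frames"), attr(x, "n_bands"),
              attr(x, "stride")))
  invisible(x)
}

window_dims <- function(windows) {
  c(attr(windows, "window_frames"), attr(windows, "n_bands"))
}

# reconstruct the stimulus frame series underlying stride-1 windows,
# per contiguous segment; returns a list of frames x bands matrices with
# `offset` = number of history frames preceding the first predicted frame
frames_from_windows <- function(windows) {
  wf <- attr(windows, "window_frames")
  nb <- attr(windows, "n_bands")
  stopifnot(attr(windows, "stride") == 1L)
  segs <- attr(windows, "segments")
  out <- vector("list", length(segs))
  row0 <- 0L
  lag_cols <- function(lag) (seq_len(nb) - 1L) * wf + lag
  for (s in seq_along(segs)) {
    len <- segs[s]
    first <- matrix(windows[row0 + 1L, ], wf, nb)  # lag-major reshape
    rest <- windows[row0 + seq_len(len), lag_cols(wf), drop = FALSE]
    out[[s]] <- rbind(first[-wf, , drop = FALSE], rest)
    row0 <- row0 + len
  }
  out
}

#' Partition stimulus frames into train / validation / test splits
#'
#' Splits are contiguous, non-overlapping frame ranges in the order
#' train, validation, test.  Windows are later formed within each range
#' separately (valid-mode windowing), so windows straddling a split
#' boundary never exist and the first `window_frames - 1` frames of each
#' range are not predicted.
#'
#' @param spec spectrogram (frames x bands) the split refers to.
#' @param response response series, one value per stimulus frame.
#' @param fractions named or unnamed fractions summing to 1; either
#'   `c(train, validation)` of the non-test frames (when `test_range` is
#'   given) or `c(train, validation, test)`.
#' @param test_range optional explicit 1-based contiguous frame indices for
#'   the test split.
#' @param test_repeats optional trials x frames matrix of repeated responses
#'   to the test range.
#' @param seed stored for provenance (the split itself is deterministic).
#' @return a `data_split` with integer index vectors `train`,
#'   `validation`, `test` and the `test_repeats` matrix.
#' @export
split_dataset <- function(spec, response, fractions = c(0.9, 0.03, 0.07),
                          test_range = NULL, test_repeats = NULL,
                          seed = NULL) {
  frames <- nrow(spec)
  if (length(response) != frames)
    stop("response length must equal the spectrogram frame count")
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  if (!is.null(test_range)) {
    test <- as.integer(test_range)
    if (length(fractions) == 3) fractions <- fractions[1:2] / sum(fractions[1:2])
    rest <- setdiff(seq_len(frames), test)
    n_tr <- round(fractions[1] * length(rest))
    train <- rest[seq_len(n_tr)]
    validation <- setdiff(rest, train)
  } else {
    if (length(fractions) == 2) fractions <- c(fractions, 0)
    n_tr <- round(fractions[1] * frames)
    n_va <- round(fractions[2] * frames)
    train <- seq_len(n_tr)
    validation <- seq_len(n_va) + n_tr
    test <- if (n_tr + n_va < frames) seq(n_tr + n_va + 1L, frames) else integer(0)
  }
  if (length(validation) == 0)
    warning("validation split is empty")
  if (!is.null(test_repeats)) {
    test_repeats <- as.matrix(test_repeats)
    if (ncol(test_repeats) != length(test))
      stop("test repeats length does not match the test range")
  }
  structure(list(train = as.integer(train),
                 validation = as.integer(validation),
                 test = as.integer(test),
                 test_repeats = test_repeats,
                 seed = seed),
            class = "data_split")
}

#' @export
print.data_split <- function(x, ...) {
  cat(sprintf("<data split: %d train / %d validation / %d test frames%s>\n",
              length(x$train), length(x$validation), length(x$test),
              if (is.null(x$test_repeats)) ""
              else sprintf(", %d test repeats", nrow(x$test_repeats))))
  invisible(x)
}

# Window one split subset: valid-mode windows within each contiguous run of
# the subset's frame indices, with the aligned response targets.
#' Extract aligned windows and response targets for one split subset
#'
#' @param spec spectrogram (frames x bands).
#' @param response response series (one value per frame).
#' @param idx integer frame indices of the subset (e.g. `split$train`).
#' @param window_frames,stride windowing parameters, see [make_windows()].
#' @return list with elements `x` (a `windowed_stimulus`) and `y` (response
#'   value aligned to each window's final frame).
#' @export
windows_for <- function(spec, response, idx, window_frames = 40, stride = 1) {
  idx <- as.integer(idx)
  runs <- split(idx, cumsum(c(1L, diff(idx) != 1L)))
  xs <- list(); ys <- list(); fi <- list(); segs <- integer(0)
  nb <- ncol(spec)
  for (r in runs) {
    if (length(r) < window_frames) next
    w <- make_windows(unclass(spec)[r, , drop = FALSE], window_frames, stride)
    xs[[length(xs) + 1L]] <- unclass(w)
    frames_global <- r[attr(w, "frame_index")]
    fi[[length(fi) + 1L]] <- frames_global
    ys[[length(ys) + 1L]] <- response[frames_global]
    segs <- c(segs, attr(w, "segments"))
  }
  if (!length(xs)) stop("no split segment is long enough for one window")
  x <- do.call(rbind, xs)
  x <- new_windows(x, window_frames, nb, stride,
                   frame_index = unlist(fi), segments = segs)
  list(x = x, y = unlist(ys))
}
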