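# Stimulus frontend: cochlear-style auditory spectrogram and band reduction.

#' Construct a waveform object
#'
#' @param samples numeric vector of audio samples (arbitrary units).
#' @param rate sampling rate in samples/second.
#' @return an object of class `waveform`.
#' @export
waveform <- function(samples, rate) {
  samples <- as.numeric(samples)
  if (!all(is.finite(samples))) stop("waveform contains non-finite samples")
  if (!(is.numeric(rate) && length(rate) == 1 && rate > 0))
    stop("rate must be a positive scalar")
  structure(list(samples = samples, rate = rate), class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform: %d samples @ %g Hz (%.2f s)>\n",
              length(x$samples), x$rate, length(x$samples) / x$rate))
  invisible(x)
}

new_spectrogram <- function(values, frame_rate, center_freqs) {
  structure(values,
            frame_rate = frame_rate,
            center_freqs = center_freqs,
            class = c("auditory_spectrogram", "matrix", "array"))
}

#' @export
print.auditory_spectrogram <- function(x, ...) {
  cf <- attr(x, "center_freqs")
  cat(sprintf(
    "<auditory spectrogram: %d frames x %d bands @ %g Hz, %.0f-%.0f Hz>\n",
    nrow(x), ncol(x), attr(x, "frame_rate"), min(cf), max(cf)))
  invisible(x)
}

#' Auditory spectrogram of an acoustic waveform
#'
#' Computes a simplified cochlear-model time-frequency representation:
#' a bank of constant-Q fourth-order gammatone-style filters log-spaced
#' between `f_lo` and `f_hi`, followed by a hair-cell stage
#' (half-wave rectification, one-pole low-pass, cube-root compression),
#' a lateral-inhibition stage (first-order difference across bands with
#' half-wave rectification), and short-term energy integration to the
#' output frame rate.
#'
#' Filtering is performed in the frequency domain (zero-phase magnitude
#' response), so the first/last few frames carry circular edge effects.
#'
#' @param wav a [waveform()].
#' @param n_bands number of cochlear filters (default 128).
#' @param frame_rate output frame rate in Hz (default 100).
#' @param f_lo,f_hi frequency range of the filterbank in Hz (the top must
#'   stay below half the sampling rate; 5.4 kHz spans speech at 11025 Hz).
#' @param q filter quality factor (center frequency / bandwidth).
#' @return an `auditory_spectrogram`: `ceiling(duration * frame_rate)` frames
#'   by `n_bands` nonnegative values, with `frame_rate` and ascending
#'   `center_freqs` attributes.
#' @export
auditory_spectrogram <- function(wav, n_bands = 128, frame_rate = 100,
                                 f_lo = 180, f_hi = 5400, q = 8) {
  stopifnot(inherits(wav, "waveform"))
  x <- wav$samples
  rate <- wav$rate
  if (length(x) < rate / frame_rate)
    stop("audio shorter than one output frame")
  if (rate < 2 * f_hi)
    stop("sampling rate must be at least twice the highest filter frequency")
  n <- length(x)
  n_frames <- ceiling(n / rate * frame_rate)
  cf <- exp(seq(log(f_lo), log(f_hi), length.out = n_bands))

  xf <- fft(x)
  freqs <- (seq_len(n) - 1) / n * rate
  freqs <- pmin(freqs, rate - freqs)  # |f| on the circular axis

  # one-pole low-pass state coefficient for the hair-cell stage (~ 1 kHz)
  lp_a <- exp(-2 * pi * 1000 / rate)

  comp <- matrix(0, n, n_bands)
  for (b in seq_len(n_bands)) {
    bw <- cf[b] / q
    h <- (1 + ((freqs - cf[b]) / bw)^2)^-2  # 4th-order rolloff
    s <- Re(fft(xf * h, inverse = TRUE)) / n
    s[s < 0] <- 0                           # half-wave rectification
    s <- stats::filter(s * (1 - lp_a), lp_a, method = "recursive")
    comp[, b] <- as.numeric(s)^(1 / 3)      # cube-root compression
  }

  # lateral inhibition: spectral first difference, rectified
  li <- comp
  li[, -1] <- comp[, -1] - comp[, -n_bands]
  li[li < 0] <- 0

  # frame integration (mean energy per frame)
  edges <- floor((0:n_frames) * rate / frame_rate)
  edges[n_frames + 1] <- n
  out <- matrix(0, n_frames, n_bands)
  for (k in seq_len(n_frames)) {
    i0 <- edges[k] + 1
    i1 <- max(edges[k + 1], i0)
    out[k, ] <- colMeans(li[i0:i1, , drop = FALSE])
  }
  new_spectrogram(out, frame_rate, cf)
}

#' Reduce the number of frequency bands of a spectrogram
#'
#' Averages contiguous groups of bands (the native 128-band representation
#' is typically reduced to 32 bands to limit model parameters).  Grouping is
#' near-equal-sized when the native count is not divisible by `n_out`; the
#' reported center frequencies are geometric means per group.
#'
#' @param spec an `auditory_spectrogram`.
#' @param n_out number of output bands (default 32).
#' @return an `auditory_spectrogram` with `n_out` bands and the same frames.
#' @export
reduce_bands <- function(spec, n_out = 32) {
  stopifnot(inherits(spec, "auditory_spectrogram"))
  native <- ncol(spec)
  if (n_out > native) stop("n_out exceeds the native band count")
  grp <- floor((seq_len(native) - 1) * n_out / native) + 1
  vals <- vapply(seq_len(n_out), function(g)
    rowMeans(spec[, grp == g, drop = FALSE]), numeric(nrow(spec)))
  cf <- attr(spec, "center_freqs")
  cfo <- vapply(seq_len(n_out), function(g) exp(mean(log(cf[grp == g]))),
                numeric(1))
  new_spectrogram(matrix(vals, nrow = nrow(spec)), attr(spec, "frame_rate"),
                  cfo)
}
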