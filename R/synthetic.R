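# Synthetic stimuli and ground-truth neurons with controllable
# nonlinearities.  Every pipeline stage is testable against these known
# generative models without any external data.

#' Generate a synthetic auditory-spectrogram stimulus
#'
#' The stimulus is a sum of seeded random moving ripples (drifting
#' sinusoidal spectrotemporal modulations with gaussian spectral envelopes
#' and smoothed random temporal gates) over a smoothed noise floor, scaled
#' to unit mean.  It is nonnegative and spectrotemporally correlated, a
#' stand-in for the modulation structure of a speech spectrogram without
#' phonetic content.
#'
#' @param duration_s stimulus duration in seconds (>= 5).
#' @param n_bands number of frequency bands (default 32).
#' @param frame_rate frames per second (default 100).
#' @param seed RNG seed; the output is a deterministic function of it.
#' @param n_ripples number of ripple components (default 12).
#' @return an `auditory_spectrogram` of `duration_s * frame_rate` frames.
#' @export
generate_stimulus <- function(duration_s, n_bands = 32, frame_rate = 100,
                              seed = 1, n_ripples = 12) {
  stopifnot(duration_s >= 5)
  frames <- round(duration_s * frame_rate)
  with_seed(seed, {
    tt <- seq_len(frames) / frame_rate
    fb <- seq_len(n_bands)
    vals <- matrix(0, frames, n_bands)
    for (k in seq_len(n_ripples)) {
      rate_hz <- runif(1, 0.5, 8)             # temporal modulation rate
      scale_cyc <- runif(1, 0, 0.25)          # spectral density, cyc/band
      phase <- runif(1, 0, 2 * pi)
      cb <- runif(1, 1, n_bands)              # spectral center
      bwidth <- runif(1, 2, 10)               # spectral spread (bands)
      amp <- runif(1, 0.3, 1)
      ripple <- 0.5 * (1 + cos(2 * pi * (rate_hz * tt) %o% rep(1, n_bands) +
                               2 * pi * scale_cyc * rep(1, frames) %o% fb +
                               phase))
      genv <- exp(-0.5 * ((fb - cb) / bwidth)^2)
      # smoothed random on/off gate so ripples come and go
      gate <- stats::filter(rexp_gate(frames), rep(1 / 50, 50), sides = 2)
      gate[is.na(gate)] <- 0
      vals <- vals + amp * as.numeric(gate) * ripple *
        rep(1, frames) %o% genv
    }
    floor_mat <- matrix(abs(rnorm(frames * n_bands, sd = 0.2)), frames)
    floor_mat <- t(apply(floor_mat, 1, smooth_ma, k = 3))
    floor_mat <- apply(floor_mat, 2, smooth_ma, k = 5)
    vals <- vals + floor_mat
    # slow loudness dynamics (pauses, emphatic passages): a log-normal
    # envelope with ~1.5 s correlation time, as natural speech shows
    env <- exp(0.5 * scale(smooth_ma(rnorm(frames), k = 150))[, 1])
    vals <- vals * env
    # flat long-run spectrum: seeds then differ in structure, not in a
    # shared average band profile
    vals <- sweep(vals, 2, colMeans(vals), "/")
    vals <- vals / mean(vals)
    cf <- exp(seq(log(180), log(7000), length.out = n_bands))
    new_spectrogram(vals, frame_rate, cf)
  })
}

rexp_gate <- function(n) as.numeric(runif(n) < 0.4)

smooth_ma <- function(x, k) {
  as.numeric(stats::filter(x, rep(1 / k, k), sides = 2, circular = TRUE))
}

#' Build a localized spectrotemporal receptive-field template
#'
#' A gabor-like lag x frequency pattern: gaussian frequency tuning times a
#' biphasic (excitatory peak followed by inhibitory trough) temporal kernel
#' at a given latency, normalised to unit Frobenius norm.
#'
#' @param n_lags,n_bands template dimensions (default 40 x 32).
#' @param center_band peak frequency band.
#' @param band_width gaussian spread across bands.
#' @param peak_lag latency of the excitatory peak, in frames back from the
#'   current frame (e.g. 8 = 80 ms before the predicted response frame).
#' @param phase `"onset"` for a biphasic kernel, `"sustained"` for a purely
#'   positive one.
#' @return an `n_lags x n_bands` matrix with unit Frobenius norm.
#' @export
rf_template <- function(n_lags = 40, n_bands = 32, center_band = 12,
                        band_width = 3, peak_lag = 8, phase = "onset") {
  lag_back <- (n_lags - 1):0   # frames before "now" for lag index 1..n_lags
  tmp <- exp(-0.5 * ((lag_back - peak_lag) / 2.5)^2)
  if (phase == "onset")
    tmp <- tmp - 0.6 * exp(-0.5 * ((lag_back - peak_lag - 6) / 3.5)^2)
  fw <- exp(-0.5 * ((seq_len(n_bands) - center_band) / band_width)^2)
  w <- tmp %o% fw
  w / sqrt(sum(w^2))
}

#' Specify a synthetic ground-truth neuron
#'
#' Generative response models with known, controllable nonlinearities, one
#' per nonlinearity class that the receptive-field metrics are designed to
#' detect:
#' \describe{
#'   \item{linear}{`y = <W, X_t>` — a fixed spectrotemporal template.}
#'   \item{static_nl}{`y = dexp(<W, X_t>)` — template drive through the
#'     double-exponential output nonlinearity.}
#'   \item{gain_adaptive}{`y = <W, X_t> * exp(-eta * (B_t - mean(B)))`
#'     with `B_t` the spectral balance (the fraction of exponentially
#'     weighted recent energy, time constant `tau_e` frames, carried by
#'     the upper half of the bands) — log-linear contrast gain control
#'     driven by a scale-free stimulus dimension the template itself does
#'     not read out.}
#'   \item{temporal_hold}{`y_t = max_{0<=j<=hold} m_(t-j)` with
#'     `m = <W, X>` — a sustained response to a transient feature whose
#'     effective latency shifts over the hold period.}
#'   \item{multi_template}{`y = <W1, X_t>` when a band-energy statistic of
#'     the current stimulus exceeds a threshold, else `<W2, X_t>` —
#'     stimulus-dependent template switching.}
#' }
#'
#' @param kind one of `"linear"`, `"static_nl"`, `"gain_adaptive"`,
#'   `"temporal_hold"`, `"multi_template"`.
#' @param templates list of one or two lag x band template matrices;
#'   defaults to built-in [rf_template()]s.
#' @param eta adaptation strength (gain_adaptive): the log-gain is
#'   `-eta * (B_t - mean(B))` with `B_t` the spectral balance; against
#'   the ~0.045 spread of the balance statistic the default 20 makes the
#'   gain vary severalfold, in the range of strong cortical gain
#'   control.
#' @param tau_e adaptation time constant in frames (default 15 = 150 ms,
#'   rapid cortical adaptation; the state is computed from the stimulus
#'   window itself so it is fully observable to a windowed model).
#' @param hold hold duration in frames, <= 30 (temporal_hold; default 30 =
#'   300 ms, the upper end of the range the hold metric probes: long
#'   sustained responses differ clearly from linear smoothing, while
#'   short holds are largely absorbed by a smeared linear readout).
#' @param theta switching threshold (multi_template); `NULL` = median of
#'   the switching statistic over the stimulus.
#' @param dexp_params named vector `a, b, c, kappa` for static_nl.
#' @param noise_sd trial-noise standard deviation in units of the response
#'   standard deviation (the clean response is z-scored).
#' @return a `synthetic_neuron` specification.
#' @export
synthetic_neuron <- function(kind = c("linear", "static_nl", "gain_adaptive",
                                      "temporal_hold", "multi_template"),
                             templates = NULL, eta = 20, tau_e = 15,
                             hold = 30, theta = NULL,
                             dexp_params = c(a = 2, b = 0, c = 0.5,
                                             kappa = 0.7),
                             noise_sd = 1) {
  kind <- match.arg(kind)
  if (is.null(templates)) {
    templates <- list(rf_template(center_band = 10, peak_lag = 6),
                      rf_template(center_band = 24, band_width = 2.5,
                                  peak_lag = 14, phase = "sustained"))
  }
  stopifnot(hold <= 30, noise_sd >= 0, tau_e > 0)
  structure(list(kind = kind, templates = templates, eta = eta,
                 tau_e = tau_e, hold = hold, theta = theta,
                 dexp_params = dexp_params, noise_sd = noise_sd),
            class = "synthetic_neuron")
}

#' Simulate the clean response of a synthetic neuron
#'
#' Deterministic and causal given the neuron specification and the windowed
#' stimulus; see [synthetic_neuron()] for the generative forms.  The
#' returned series is z-scored over its length.
#'
#' @param windows a stride-1 `windowed_stimulus`.
#' @param neuron a `synthetic_neuron`.
#' @param zscore whether to z-score the response (default TRUE).
#' @return numeric response series, one value per window.
#' @export
simulate_neuron <- function(windows, neuron, zscore = TRUE) {
  stopifnot(inherits(neuron, "synthetic_neuron"))
  w1 <- as.numeric(neuron$templates[[1]])
  m <- as.numeric(windows %*% w1)
  segs <- attr(windows, "segments")
  y <- switch(neuron$kind,
    linear = m,
    static_nl = {
      mz <- (m - mean(m)) / sd(m)
      double_exponential(mz, neuron$dexp_params)
    },
    gain_adaptive = {
      b <- spectral_balance(windows, neuron$tau_e)
      m * exp(-neuron$eta * (b - mean(b)))
    },
    temporal_hold = {
      out <- m
      off <- 0L
      for (len in segs) {
        seg <- m[off + seq_len(len)]
        held <- seg
        for (j in seq_len(neuron$hold)) {
          if (j >= len) break
          held <- pmax(held, c(rep(-Inf, j), seg[seq_len(len - j)]))
        }
        out[off + seq_len(len)] <- held
        off <- off + len
      }
      out
    },
    multi_template = {
      w2 <- as.numeric(neuron$templates[[2]])
      m2 <- as.numeric(windows %*% w2)
      s <- switch_statistic(windows)
      theta <- neuron$theta %||% median(s)
      ifelse(s > theta, m, m2)
    },
    stop("unknown neuron kind: ", neuron$kind))
  if (zscore) {
    if (sd(y) == 0) stop("degenerate (constant) simulated response")
    y <- (y - mean(y)) / sd(y)
  }
  y
}

# Spectral-balance statistic: the fraction of recent stimulus energy
# (lag j frames back weighted by exp(-j/tau_e)) carried by the upper half
# of the frequency bands.  Driving the gain by a band-energy *ratio*
# rather than an absolute level keeps the planted nonlinearity inside the
# function class of a bias-free rectifier network, which is positively
# homogeneous: it can modulate its response with stimulus direction
# (spectral balance) but not with overall stimulus scale.  Computing the
# state from the window also keeps it fully observable to a windowed
# encoding model.
spectral_balance <- function(windows, tau_e = Inf) {
  wf <- attr(windows, "window_frames")
  nb <- attr(windows, "n_bands")
  hi <- seq(nb %/% 2 + 1, nb)
  back <- (wf - 1):0                     # frames back for lag 1..wf
  wlag <- if (is.finite(tau_e)) exp(-back / tau_e) else rep(1, wf)
  wlag <- wlag / sum(wlag)
  w_hi <- numeric(wf * nb)
  w_hi[as.integer(outer(seq_len(wf), (hi - 1L) * wf, `+`))] <-
    rep(wlag, length(hi)) / length(hi)
  w_all <- rep(wlag, nb) / nb
  e_hi <- as.numeric(windows %*% w_hi)
  e_all <- as.numeric(windows %*% w_all)
  e_hi / pmax(e_all, .Machine$double.eps)
}

# statistic driving template switching: the spectral balance of the
# whole window (uniform lag weighting), so the active template follows
# acoustic context on the window timescale (~400 ms); a band-energy
# ratio, hence scale-free like the network function class
switch_statistic <- function(windows) {
  spectral_balance(windows, tau_e = Inf)
}

#' Assemble a complete synthetic dataset
#'
#' Generates a stimulus, simulates the clean response of one neuron,
#' z-scores it, adds i.i.d. gaussian trial noise to the test segment
#' (`n_repeats` trials), and partitions frames into contiguous
#' train / validation / test splits.
#'
#' @param neuron a [synthetic_neuron()].
#' @param duration_s stimulus duration in seconds.
#' @param n_repeats number of noisy test-trial repeats (default 6).
#' @param fractions split fractions `c(train, validation, test)`
#'   (default `c(0.9, 0.03, 0.07)`).
#' @param seed master seed; stimulus, neuron and noise seeds derive from it.
#' @param window_frames,n_bands windowing / stimulus dimensions.
#' @return a `synthetic_dataset`: list with `spectrogram`, `response`
#'   (per-frame clean response; the first `window_frames - 1` frames are
#'   unpredicted and set to 0), `split` (with `test_repeats` attached),
#'   `neuron`, and `seed`.
#' @export
make_dataset <- function(neuron, duration_s, n_repeats = 6,
                         fractions = c(0.9, 0.03, 0.07), seed = 1,
                         window_frames = 40, n_bands = 32) {
  if (n_repeats < 2 && neuron$noise_sd > 0)
    warning("fewer than 2 repeats: noise-corrected evaluation unavailable")
  spec <- generate_stimulus(duration_s, n_bands = n_bands,
                            seed = child_seed(seed, 1))
  win <- make_windows(spec, window_frames = window_frames)
  clean <- simulate_neuron(win, neuron)
  response <- numeric(nrow(spec))
  response[attr(win, "frame_index")] <- clean
  split <- split_dataset(spec, response, fractions, seed = seed)
  test_clean <- response[split$test]
  reps <- with_seed(child_seed(seed, 2), {
    matrix(rep(test_clean, each = n_repeats) +
             rnorm(n_repeats * length(test_clean), sd = neuron$noise_sd),
           nrow = n_repeats)
  })
  split$test_repeats <- reps
  structure(list(spectrogram = spec, response = response, split = split,
                 neuron = neuron, seed = seed,
                 window_frames = window_frames),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic dataset: %s neuron, %d frames, %s>\n",
              x$neuron$kind, nrow(x$spectrogram),
              paste0(length(x$split$train), "/",
                     length(x$split$validation), "/",
                     length(x$split$test), " train/val/test")))
  invisible(x)
}
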