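# Shared fixtures, built lazily and memoized for the whole test run.
# Small-window networks (12 lags x 10 bands) keep the expensive oracle
# comparisons fast while exercising the full architecture.

.fixtures <- new.env(parent = emptyenv())

with_seed <- dstrf:::with_seed

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

small_template <- function(center_band = 4, peak_lag = 3, phase = "onset") {
  rf_template(n_lags = 12, n_bands = 10, center_band = center_band,
              band_width = 1.5, peak_lag = peak_lag, phase = phase)
}

small_templates <- function() {
  list(small_template(center_band = 3, peak_lag = 2),
       small_template(center_band = 8, peak_lag = 5, phase = "sustained"))
}

small_dataset <- function(kind = "gain_adaptive", seed = 5,
                          duration_s = 40, noise_sd = 0.5) {
  neuron <- synthetic_neuron(kind, templates = small_templates(),
                             noise_sd = noise_sd)
  make_dataset(neuron, duration_s = duration_s, seed = seed,
               window_frames = 12, n_bands = 10)
}

small_config <- function(seed = 1, epochs = 4) {
  training_config(learning_rate = 1e-3, max_epochs = epochs, patience = 3,
                  seed = seed)
}

# a briefly trained small network (enough training to leave the random
# initial region structure behind)
small_trained_cnn <- function(kind = "gain_adaptive", seed = 5) {
  memo(paste0("cnn_", kind, "_", seed), {
    ds <- small_dataset(kind, seed = seed)
    dw <- dataset_windows(ds)
    train_cnn(dw$train$x, dw$train$y, validation = dw$validation,
              config = small_config(seed = seed))
  })
}

small_windows <- function(seed = 5) {
  memo(paste0("win_", seed), {
    ds <- small_dataset(seed = seed)
    dataset_windows(ds)
  })
}
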