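# Convolutional encoding network: architecture spec, initialization, and
# R-level training / prediction wrappers around the compiled core.

#' Describe the convolutional encoding-network architecture
#'
#' The fixed architecture is a feature-extraction stage of three 3x3
#' convolutional layers (`n_kernels` kernels each, stride 1, zero padding
#' preserving shape) followed by 1x1 convolutions reducing the channels to
#' 4 and then 1, and a feature-summation stage of a dense hidden layer and
#' a single linear output node.  All hidden layers are rectified and
#' bias-free (the bias-free property makes the network's locally-linear
#' receptive-field identity exact); only the output node has a bias.
#'
#' @param input_lags,n_bands window dimensions (default 40 x 32).
#' @param n_kernels kernels per 3x3 convolutional layer (default 8).
#' @param reduce channel counts of the two 1x1 layers (default `c(4, 1)`).
#' @param dense hidden units in the feature-summation stage (default 32).
#' @return a `cnn_spec`.
#' @export
cnn_spec <- function(input_lags = 40, n_bands = 32, n_kernels = 8,
                     reduce = c(4, 1), dense = 32) {
  stopifnot(reduce[2] == 1)
  structure(list(input_lags = as.integer(input_lags),
                 n_bands = as.integer(n_bands),
                 n_kernels = as.integer(n_kernels),
                 reduce = as.integer(reduce), dense = as.integer(dense)),
            class = "cnn_spec")
}

#' Training configuration for gradient-fitted models
#'
#' Defaults follow the reference protocol: Adam with learning rate 1e-4,
#' batch size 128, at most 30 epochs with early stopping after 5 epochs
#' without validation improvement, dropout 0.3 after convolutional layers
#' and 0.4 after the first dense layer, L2 penalty 1e-3 on all weights, and
#' the combined `MSE - correlation` loss.  All randomness (initialization,
#' shuffling, dropout masks) derives from `seed`.
#'
#' @param learning_rate,batch_size,max_epochs,patience optimizer settings.
#' @param seed master seed for all stochastic parts of training.
#' @param dropout_conv,dropout_dense dropout probabilities.
#' @param l2 L2 regularization constant.
#' @param w_mse,w_corr weights of the two loss terms.
#' @param lr_decay multiplicative learning-rate reduction applied when the
#'   validation loss has not improved for `lr_patience` epochs (1 = no
#'   reduction, the reference protocol).
#' @param lr_patience epochs of stalled validation before a reduction.
#' @return a `training_config`.
#' @export
training_config <- function(learning_rate = 1e-4, batch_size = 128,
                            max_epochs = 30, patience = 5, seed = 1,
                            dropout_conv = 0.3, dropout_dense = 0.4,
                            l2 = 1e-3, w_mse = 1, w_corr = 1,
                            lr_decay = 1, lr_patience = 2) {
  cfg <- list(learning_rate = learning_rate,
              batch_size = as.integer(batch_size),
              max_epochs = as.integer(max_epochs),
              patience = as.integer(patience), seed = as.integer(seed),
              dropout_conv = dropout_conv, dropout_dense = dropout_dense,
              l2 = l2, w_mse = w_mse, w_corr = w_corr,
              lr_decay = lr_decay, lr_patience = as.integer(lr_patience))
  stopifnot(all(vapply(cfg[c("learning_rate", "batch_size", "max_epochs",
                             "patience")], function(v) v > 0, logical(1))))
  structure(cfg, class = "training_config")
}

#' Initialise network weights
#'
#' He-style initialisation (zero-mean gaussians with variance `2 / fan_in`),
#' appropriate for rectifier networks; the output bias starts at 0.
#'
#' @param spec a [cnn_spec()].
#' @param seed RNG seed for the draw.
#' @return a `cnn_model` (untrained).
#' @export
cnn_init <- function(spec = cnn_spec(), seed = 1) {
  he <- function(nr, nc) matrix(rnorm(nr * nc, sd = sqrt(2 / nr)), nr, nc)
  k <- spec$n_kernels
  mn <- spec$input_lags * spec$n_bands
  weights <- with_seed(seed, list(
    conv1 = he(9 * 1, k),
    conv2 = he(9 * k, k),
    conv3 = he(9 * k, k),
    # the 1x1 reduction layers see nonnegative (rectified) inputs: an
    # all-negative draw would start them inactive with no gradient, so
    # their initial weights are taken positive
    conv4 = abs(he(k, spec$reduce[1])),
    conv5 = abs(he(spec$reduce[1], spec$reduce[2])),
    dense1 = he(mn * spec$reduce[2], spec$dense),
    dense2 = he(spec$dense, 1),
    bias = 0))
  new_cnn(weights, spec, history = NULL, seed = seed)
}

new_cnn <- function(weights, spec, history, seed) {
  structure(list(weights = weights, spec = spec, history = history,
                 seed = seed),
            class = "cnn_model")
}

#' @export
print.cnn_model <- function(x, ...) {
  tr <- if (is.null(x$history)) "untrained"
        else sprintf("trained %d epochs (best %d, val loss %.4f)",
                     x$history$epochs_run, x$history$best_epoch,
                     x$history$best_val_loss)
  cat(sprintf("<CNN encoding model: %dx%d input, %d kernels; %s>\n",
              x$spec$input_lags, x$spec$n_bands, x$spec$n_kernels, tr))
  invisible(x)
}

#' Variance-preserving rescaling of initial weights
#'
#' Rescales each layer of a freshly initialised network so that its
#' pre-activation standard deviation on a sample of real stimulus windows
#' is 1 (the output layer is instead scaled well below the response scale
#' so early optimisation cannot silence the channel bottlenecks).  He
#' initialisation alone assumes uncorrelated inputs; auditory spectrogram
#' windows are strongly correlated and nonnegative, which otherwise lets
#' the forward signal collapse across the bias-free rectifier stack.
#'
#' @param model an untrained `cnn_model`.
#' @param windows sample stimulus windows (a few hundred rows suffice).
#' @param out_scale initial output-layer pre-activation scale (default
#'   0.05).
#' @return the model with rescaled weights.
#' @export
cnn_normalize_init <- function(model, windows, out_scale = 0.05) {
  sp <- model$spec
  x <- unclass(windows)
  if (nrow(x) > 512) x <- x[seq(1, nrow(x), length.out = 512), ]
  nm <- c("conv1", "conv2", "conv3", "conv4", "conv5", "dense1", "dense2")
  for (pass in 1:2) {
    sds <- cpp_cnn_layer_sds(model$weights, x, sp$input_lags, sp$n_bands)
    for (i in seq_along(nm)) {
      target <- if (i == 7) out_scale else 1
      if (sds[i] > 0)
        model$weights[[nm[i]]] <- model$weights[[nm[i]]] * (target / sds[i])
    }
  }
  model
}

#' Train the convolutional encoding network
#'
#' Minimises the combined `MSE - correlation` loss by minibatch Adam with
#' inverted dropout and L2 penalty, evaluating the combined loss on the
#' whole validation set after each epoch.  Training stops after
#' `config$patience` epochs without validation improvement and the
#' epoch-best validation weights are returned.  Fully deterministic given
#' `config$seed`.
#'
#' @param windows training `windowed_stimulus`.
#' @param response aligned training response.
#' @param validation list with `x` (windows) and `y` (response).
#' @param config a [training_config()].
#' @param spec a [cnn_spec()]; inferred from the windows when `NULL`.
#' @param init optional `cnn_model` to start from (defaults to
#'   He-initialised weights drawn from `config$seed`).
#' @param normalize_init apply [cnn_normalize_init()] to the fresh
#'   initialisation (ignored when `init` is given).
#' @return a trained `cnn_model` with a `history` field (per-epoch train
#'   and validation losses, best epoch).
#' @export
train_cnn <- function(windows, response, validation, config = training_config(),
                      spec = NULL, init = NULL, normalize_init = FALSE) {
  dims <- window_dims(windows)
  if (is.null(spec))
    spec <- cnn_spec(input_lags = dims[1], n_bands = dims[2])
  stopifnot(dims[1] == spec$input_lags, dims[2] == spec$n_bands,
            nrow(windows) == length(response),
            length(validation$y) >= 2)
  fresh_init <- is.null(init)
  seed_try <- config$seed
  for (attempt in 1:3) {
    if (fresh_init) {
      init <- cnn_init(spec, seed = seed_try)
      if (normalize_init) init <- cnn_normalize_init(init, windows)
    }
    cfg <- config
    cfg$seed <- seed_try
    fit <- cpp_cnn_train(init$weights, unclass(windows),
                         as.numeric(response), unclass(validation$x),
                         as.numeric(validation$y), dims[1], dims[2], cfg)
    model <- new_cnn(fit$weights,  spec,
                     fit[c("train_loss", "val_loss", "best_epoch",
                           "best_val_loss", "epochs_run")], seed_try)
    # a silent or near-silent network can arise when a channel
    # bottleneck dies during optimisation; refit from a derived seed
    pv <- predict(model, validation$x)
    if (sd(pv) > 0.1 * sd(validation$y) || !fresh_init) break
    seed_try <- child_seed(seed_try, 977L)
  }
  model$config <- config
  model
}

#' @rdname train_cnn
#' @param object trained `cnn_model`.
#' @param newdata windows to predict from.
#' @param ... unused.
#' @export
predict.cnn_model <- function(object, newdata, ...) {
  wf <- attr(newdata, "window_frames") %||% object$spec$input_lags
  nb <- attr(newdata, "n_bands") %||% object$spec$n_bands
  if (wf != object$spec$input_lags || nb != object$spec$n_bands ||
      ncol(newdata) != wf * nb)
    stop("window shape mismatch")
  as.numeric(cpp_cnn_forward(object$weights, unclass(newdata), wf, nb))
}
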