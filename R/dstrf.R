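# DSTRF core: exact locally-linear receptive fields of a trained bias-free
# rectifier network, with a jackknife ensemble for coefficient significance.
#
# A rectifier network with bias-free hidden layers computes, within each
# linear region of input space, an exact linear function: the gradient of
# the output with respect to the input window.  That lag x frequency
# gradient is the dynamic spectrotemporal receptive field (DSTRF) of the
# model at that stimulus instance, and satisfies
#   yhat(x) = <DSTRF(x), x> + output_bias    exactly.

#' Expand a convolution into its locally connected weight matrix
#'
#' Builds the sparse matrix that maps the flattened input of a stride-1,
#' shape-preserving (zero-padded) 2D convolutional layer to its flattened
#' output, so that matrix multiplication reproduces the convolution for
#' every input.  Flattened indices run fastest over rows (lags), then
#' columns (bands), then channels.
#'
#' @param kernels kernel array of dimensions `H x W x C x L` (kernel height,
#'   width, input channels, number of kernels), or an `(H*W*C) x L` matrix
#'   with `kernel_dim = c(H, W)` supplied.
#' @param input_shape spatial input shape `c(M, N)`.
#' @param kernel_dim kernel height/width when `kernels` is a matrix.
#' @param stride must be 1; other strides are rejected.
#' @param padding must be `"same"`.
#' @return a `Matrix::sparseMatrix` of dimension `(M*N*L) x (M*N*C)`.
#' @export
conv_to_locally_connected <- function(kernels, input_shape,
                                      kernel_dim = NULL, stride = 1,
                                      padding = "same") {
  if (stride != 1) stop("only stride-1 convolutions are supported")
  if (padding != "same") stop("only shape-preserving zero padding is supported")
  if (is.matrix(kernels)) {
    if (is.null(kernel_dim)) stop("kernel_dim required for matrix kernels")
    h <- kernel_dim[1]; w <- kernel_dim[2]
    cc <- nrow(kernels) / (h * w); ll <- ncol(kernels)
    kernels <- array(kernels, c(h, w, cc, ll))
  }
  kd <- dim(kernels)
  h <- kd[1]; w <- kd[2]; cc <- kd[3]; ll <- kd[4]
  m <- input_shape[1]; n <- input_shape[2]
  if (h %% 2 == 0 || w %% 2 == 0)
    stop("kernel height/width must be odd for 'same' padding")
  mn <- m * n

  # vectorised triplet construction over output pixels x kernel taps
  grid <- expand.grid(mm = seq_len(m), nn = seq_len(n),
                      dh = seq_len(h), dw = seq_len(w))
  src_m <- grid$mm + grid$dh - (h + 1) / 2
  src_n <- grid$nn + grid$dw - (w + 1) / 2
  ok <- src_m >= 1 & src_m <= m & src_n >= 1 & src_n <= n
  grid <- grid[ok, ]; src_m <- src_m[ok]; src_n <- src_n[ok]
  out_pix <- grid$mm + m * (grid$nn - 1)
  src_pix <- src_m + m * (src_n - 1)
  tap <- grid$dh + h * (grid$dw - 1)

  ii <- jj <- xx <- vector("list", cc * ll)
  kmat <- matrix(kernels, h * w * cc, ll)
  for (l in seq_len(ll)) {
    for (c in seq_len(cc)) {
      idx <- (l - 1) * cc + c
      ii[[idx]] <- out_pix + mn * (l - 1)
      jj[[idx]] <- src_pix + mn * (c - 1)
      xx[[idx]] <- kmat[tap + h * w * (c - 1), l]
    }
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(mn * ll, mn * cc))
}

#' Convert a convolutional encoding model into an equivalent MLP
#'
#' Replaces every convolutional layer by its locally connected (sparse
#' fully connected) equivalent so that the network becomes an ordinary
#' multilayer perceptron over the flattened window, with identical outputs.
#' The 1x1 convolutions become channel-mixing block matrices and dense
#' layers pass through unchanged.
#'
#' @param model a trained `cnn_model`.
#' @return an `equivalent_mlp`: list of layer matrices (sparse for the
#'   convolutional stages) and the output bias.
#' @export
cnn_to_mlp <- function(model) {
  sp <- model$spec
  m <- sp$input_lags; n <- sp$n_bands; mn <- m * n
  w <- model$weights
  k <- sp$n_kernels
  lc1 <- conv_to_locally_connected(w$conv1, c(m, n), kernel_dim = c(3, 3))
  lc2 <- conv_to_locally_connected(w$conv2, c(m, n), kernel_dim = c(3, 3))
  lc3 <- conv_to_locally_connected(w$conv3, c(m, n), kernel_dim = c(3, 3))
  eye <- Matrix::Diagonal(mn)
  lc4 <- Matrix::kronecker(Matrix::t(w$conv4), eye)
  lc5 <- Matrix::kronecker(Matrix::t(w$conv5), eye)
  layers <- list(lc1, lc2, lc3, lc4, lc5,
                 Matrix::Matrix(t(w$dense1)), Matrix::Matrix(t(w$dense2)))
  structure(list(layers = layers, output_bias = w$bias,
                 input_shape = c(m, n)),
            class = "equivalent_mlp")
}

#' @export
print.equivalent_mlp <- function(x, ...) {
  cat(sprintf("<equivalent MLP: %d layers, input %d>\n",
              length(x$layers), ncol(x$layers[[1]])))
  invisible(x)
}

#' Forward pass through an equivalent MLP
#'
#' @param mlp an `equivalent_mlp`.
#' @param x one flattened window (vector) or a windows matrix (rows).
#' @param states if `TRUE`, also return the per-layer active/inactive
#'   pattern of every hidden unit (pre-activation strictly positive).
#' @return predicted value(s), or with `states = TRUE` a list
#'   `list(y, states)`.
#' @export
mlp_forward <- function(mlp, x, states = FALSE) {
  a <- if (is.null(dim(x))) matrix(x, ncol = 1) else t(x)
  st <- list()
  nl <- length(mlp$layers)
  for (l in seq_len(nl - 1)) {
    z <- as.matrix(mlp$layers[[l]] %*% a)
    if (states) st[[l]] <- z > 0
    a <- pmax(z, 0)
  }
  y <- as.numeric(mlp$layers[[nl]] %*% a) + mlp$output_bias
  if (states) list(y = y, states = st) else y
}

#' Exact locally-linear receptive field of a model at one stimulus window
#'
#' Two routes to the same object: `"gradient"` differentiates the network
#' output with respect to the input via backpropagation; `"weight_product"`
#' zeroes the weights into inactive units of the equivalent MLP and
#' multiplies the remaining layer matrices.  For a bias-free rectifier
#' network both give the exact linear function applied within the current
#' linear region, so `<DSTRF(x), x> + output_bias == yhat(x)` holds to
#' machine precision.  Units with pre-activation exactly 0 are treated as
#' inactive (zero derivative).
#'
#' @param model a trained `cnn_model`.
#' @param window one flattened stimulus window (vector of length
#'   `lags * bands`).
#' @param method `"gradient"` (default) or `"weight_product"`.
#' @param mlp optionally a precomputed [cnn_to_mlp()] result (built on the
#'   fly for the weight-product route otherwise).
#' @return a lag x band matrix.
#' @export
compute_dstrf <- function(model, window,
                          method = c("gradient", "weight_product"),
                          mlp = NULL) {
  method <- match.arg(method)
  sp <- model$spec
  window <- as.numeric(window)
  if (!all(is.finite(window))) stop("window contains non-finite values")
  if (length(window) != sp$input_lags * sp$n_bands)
    stop("window shape mismatch")
  if (method == "gradient") {
    g <- cpp_cnn_input_grad(model$weights, matrix(window, 1),
                            sp$input_lags, sp$n_bands)
    return(matrix(g[1, ], sp$input_lags, sp$n_bands))
  }
  if (is.null(mlp)) mlp <- cnn_to_mlp(model)
  fw <- mlp_forward(mlp, window, states = TRUE)
  nl <- length(mlp$layers)
  v <- mlp$layers[[nl]]                  # 1 x H
  for (l in (nl - 1):1) {
    v <- (v * as.numeric(fw$states[[l]])) %*% mlp$layers[[l]]
  }
  matrix(as.numeric(v), sp$input_lags, sp$n_bands)
}

new_dstrf_series <- function(values, dims, model_id = NULL) {
  structure(values, lag_bands = as.integer(dims), model_id = model_id,
            class = c("dstrf_series", "matrix", "array"))
}

#' @export
print.dstrf_series <- function(x, ...) {
  d <- attr(x, "lag_bands")
  cat(sprintf("<DSTRF series: %d slices of %d lags x %d bands>\n",
              nrow(x), d[1], d[2]))
  invisible(x)
}

#' Time series of locally-linear receptive fields
#'
#' One DSTRF per stimulus window, in order, computed by batched
#' backpropagation.
#'
#' @param model a trained `cnn_model`.
#' @param windows `windowed_stimulus` (or plain matrix of flattened
#'   windows).
#' @param model_id optional identifier stored on the result.
#' @return a `dstrf_series`: slices x (lags*bands) matrix; slice `t` equals
#'   `compute_dstrf` on window `t`.
#' @export
compute_dstrf_series <- function(model, windows, model_id = NULL) {
  sp <- model$spec
  g <- cpp_cnn_input_grad(model$weights, unclass(windows), sp$input_lags,
                          sp$n_bands)
  new_dstrf_series(g, c(sp$input_lags, sp$n_bands), model_id)
}

#' Jackknife mean and standard error
#'
#' For leave-one-segment-out estimates `theta_i` returns their average and
#' the jackknife standard error
#' `sqrt((n-1)/n * sum((theta_i - mean)^2))`.  Accepts a vector of scalar
#' estimates or a matrix with one estimate per row (the statistic is then
#' applied per column).
#'
#' @param estimates numeric vector (length n) or n x d matrix.
#' @return list with `mean` and `se`.
#' @export
jackknife_mean_se <- function(estimates) {
  x <- if (is.null(dim(estimates))) matrix(estimates, ncol = 1)
       else as.matrix(estimates)
  n <- nrow(x)
  if (n < 2) stop("jackknife needs at least 2 estimates")
  mu <- colMeans(x)
  se <- sqrt((n - 1) / n * colSums(sweep(x, 2, mu)^2))
  if (is.null(dim(estimates))) list(mean = mu[[1]], se = se[[1]])
  else list(mean = mu, se = se)
}

#' Train a leave-one-segment-out model ensemble
#'
#' Partitions the training frames into `n` contiguous segments of
#' near-equal length (within one frame) and trains one model per held-out
#' segment on the remaining frames, each with a seed derived
#' deterministically from the base seed and the segment index.
#'
#' @param spectrogram stimulus spectrogram (frames x bands).
#' @param response response series (per frame).
#' @param split a `data_split`.
#' @param config a [training_config()].
#' @param n ensemble size (default 20; must be >= 2).
#' @param spec a [cnn_spec()].
#' @param train_stride subsampling stride applied to training windows
#'   (validation windows keep stride 1).
#' @param window_frames window length in frames (defaults to the
#'   spec's input lags, else 40).
#' @return a `jackknife_ensemble`: list of `cnn_model`s plus the held-out
#'   segment ranges.
#' @export
train_jackknife_ensemble <- function(spectrogram, response, split, config,
                                     n = 20, spec = NULL, train_stride = 1,
                                     window_frames = NULL) {
  if (n < 2) stop("jackknife needs at least 2 segments")
  if (is.null(window_frames))
    window_frames <- if (!is.null(spec)) spec$input_lags else 40L
  tr <- split$train
  bounds <- round(seq(0, length(tr), length.out = n + 1))
  val <- windows_for(spectrogram, response, split$validation,
                     window_frames = window_frames)
  models <- vector("list", n)
  held_out <- vector("list", n)
  for (i in seq_len(n)) {
    seg <- tr[(bounds[i] + 1):bounds[i + 1]]
    keep <- setdiff(tr, seg)
    trw <- windows_for(spectrogram, response, keep,
                       window_frames = window_frames)
    sel <- seq(1, nrow(trw$x), by = train_stride)
    cfg <- config
    cfg$seed <- child_seed(config$seed, i)
    models[[i]] <- train_cnn(subset_windows(trw$x, sel), trw$y[sel],
                             validation = val, config = cfg, spec = spec)
    held_out[[i]] <- range(seg)
  }
  structure(list(models = models, held_out = held_out, n = n,
                 seed = config$seed),
            class = "jackknife_ensemble")
}

#' @export
print.jackknife_ensemble <- function(x, ...) {
  cat(sprintf("<jackknife ensemble of %d models>\n", x$n))
  invisible(x)
}

#' Sign-agreement significance mask for an ensemble of DSTRF series
#'
#' A lag-frequency coefficient of a DSTRF slice is deemed significant when
#' at least `min_agree` of the ensemble estimates are strictly positive or
#' at least `min_agree` strictly negative (the 95 % jackknife agreement
#' rule: 19 of 20 at the reference ensemble size, `ceiling(0.95 * n)` in
#' general).  `apply_mask` zeroes insignificant coefficients and replaces
#' kept ones by the ensemble mean.
#'
#' @param series_list list of `n` `dstrf_series` (one per ensemble model,
#'   same shape), or a 3-d array `n x slices x coefficients`.
#' @param min_agree minimum number of same-signed estimates
#'   (default `ceiling(0.95 * n)`).
#' @return a `significance_mask`: logical slices x coefficients matrix with
#'   the ensemble-mean series attached as attribute `"mean_series"`.
#' @export
significance_mask <- function(series_list, min_agree = NULL) {
  if (is.list(series_list)) {
    n <- length(series_list)
    pos <- neg <- 0
    acc <- 0
    for (s in series_list) {
      pos <- pos + (unclass(s) > 0)
      neg <- neg + (unclass(s) < 0)
      acc <- acc + unclass(s)
    }
    mean_series <- acc / n
    dims <- attr(series_list[[1]], "lag_bands")
  } else {
    n <- dim(series_list)[1]
    pos <- apply(series_list > 0, c(2, 3), sum)
    neg <- apply(series_list < 0, c(2, 3), sum)
    mean_series <- apply(series_list, c(2, 3), mean)
    dims <- NULL
  }
  if (is.null(min_agree)) min_agree <- ceiling(0.95 * n)
  if (min_agree > n) stop("min_agree cannot exceed the ensemble size")
  mask <- pos >= min_agree | neg >= min_agree
  structure(mask, mean_series = mean_series, lag_bands = dims,
            min_agree = as.integer(min_agree), n_models = as.integer(n),
            class = c("significance_mask", "matrix", "array"))
}

#' @rdname significance_mask
#' @param series a `dstrf_series` (e.g. the ensemble mean) to mask.
#' @param mask a `significance_mask` of matching shape.
#' @export
apply_mask <- function(series, mask) {
  stopifnot(all(dim(series) == dim(mask)))
  out <- unclass(series) * unclass(mask)
  new_dstrf_series(out, attr(series, "lag_bands") %||% attr(mask, "lag_bands"),
                   attr(series, "model_id"))
}

#' Masked jackknife-mean DSTRF series for an ensemble
#'
#' Convenience wrapper: computes the per-model DSTRF series on the given
#' windows, forms the jackknife mean, and applies the sign-agreement
#' significance mask.
#'
#' @param ensemble a `jackknife_ensemble`.
#' @param windows windows at which to linearize.
#' @param min_agree see [significance_mask()].
#' @param masked if `FALSE`, return the unmasked jackknife mean.
#' @return a `dstrf_series`.
#' @export
ensemble_dstrf <- function(ensemble, windows, min_agree = NULL,
                           masked = TRUE) {
  series <- lapply(ensemble$models, compute_dstrf_series, windows = windows)
  msk <- significance_mask(series, min_agree)
  mean_series <- new_dstrf_series(attr(msk, "mean_series"),
                                  attr(series[[1]], "lag_bands"))
  if (masked) apply_mask(mean_series, msk) else mean_series
}

#' Mean hidden-state switching rate of a rectifier network
#'
#' For consecutive stimulus windows, counts the hidden units whose
#' active/inactive state differs between steps and returns the average
#' count — a direct measure of how often the network hops between linear
#' regions as the stimulus unfolds.
#'
#' @param model a trained `cnn_model`.
#' @param windows consecutive (stride-1) windows of a contiguous stimulus.
#' @return mean number of unit switches per step.
#' @export
count_state_switches <- function(model, windows) {
  if (nrow(windows) < 2) stop("need at least two consecutive windows")
  sp <- model$spec
  sw <- cpp_cnn_state_switches(model$weights, unclass(windows),
                               sp$input_lags, sp$n_bands)
  mean(sw)
}
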