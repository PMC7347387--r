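# End-to-end site analysis: fit encoding models on one dataset, score them
# with noise correction, extract (masked) DSTRFs and the nonlinearity
# profile.

#' Windowed train/validation/test views of a dataset
#'
#' @param dataset a `synthetic_dataset` (or any list with `spectrogram`,
#'   `response`, `split`, `window_frames`).
#' @return list of `train`, `validation`, `test`, each a list `x`, `y`;
#'   `test` also carries `repeats` (columns aligned to the predicted
#'   frames) as an element.
#' @export
dataset_windows <- function(dataset) {
  wf <- dataset$window_frames %||% 40
  sp <- dataset$spectrogram
  rs <- dataset$response
  spl <- dataset$split
  out <- list(train = windows_for(sp, rs, spl$train, wf),
              validation = windows_for(sp, rs, spl$validation, wf),
              test = windows_for(sp, rs, spl$test, wf))
  if (!is.null(spl$test_repeats)) {
    pred_frames <- attr(out$test$x, "frame_index")
    cols <- match(pred_frames, spl$test)
    out$test$repeats <- spl$test_repeats[, cols, drop = FALSE]
  }
  out
}

#' Fit and interpret the encoding models of one neural site
#'
#' Fits the requested models on a dataset's training split (penalty /
#' epoch selection on the validation split), scores each on the held-out
#' test repeats with noise correction, and, for the network model,
#' extracts the DSTRF series on the test windows — from a leave-one-
#' segment-out jackknife ensemble with sign-agreement masking when
#' `jackknife_n >= 2`, otherwise from the single trained network — and
#' summarises it as a nonlinearity profile.
#'
#' @param dataset a `synthetic_dataset` (or compatible list).
#' @param models subset of `c("lin", "ln", "stp", "cnn")`.
#' @param config a [training_config()].
#' @param jackknife_n ensemble size for significance masking (0 = none).
#' @param train_stride subsampling stride over training windows (stride 1
#'   keeps all overlapping windows; larger strides thin the heavily
#'   redundant training set for speed).
#' @param profile_metrics compute the nonlinearity profile (default TRUE
#'   when a network model is fitted).
#' @return a `site_fit`: fitted `models`, `scores`, `predictions`,
#'   `dstrf` (series used for metrics), `profile`, and the `ensemble`
#'   (when jackknifed).
#' @export
fit_site <- function(dataset, models = c("lin", "cnn"),
                     config = training_config(), jackknife_n = 0,
                     train_stride = 1, profile_metrics = TRUE) {
  dw <- dataset_windows(dataset)
  sel <- seq(1, nrow(dw$train$x), by = train_stride)
  trx <- subset_windows(dw$train$x, sel)
  try_ <- dw$train$y[sel]
  fits <- list(); preds <- list(); scores <- list()
  dstrf <- NULL; ens <- NULL; prof <- NULL
  for (m in models) {
    if (m == "cnn" && jackknife_n >= 2) {
      # leave-one-segment-out ensemble: the ensemble-mean prediction
      # scores the network and the masked jackknife-mean DSTRF feeds the
      # metrics; the first fold's network represents the model elsewhere
      ens <- train_jackknife_ensemble(dataset$spectrogram,
                                      dataset$response, dataset$split,
                                      config, n = jackknife_n,
                                      train_stride = train_stride,
                                      window_frames =
                                        dataset$window_frames %||% 40)
      pm <- vapply(ens$models, predict, numeric(nrow(dw$test$x)),
                   newdata = dw$test$x)
      preds[[m]] <- rowMeans(pm)
      fits[[m]] <- ens$models[[1]]
    } else {
      fit <- switch(m,
        lin = fit_strf(trx, try_, validation = dw$validation),
        ln = fit_cascade(subset_windows(dw$train$x, sel), try_, "LN",
                         validation = dw$validation, config = config),
        stp = fit_cascade(subset_windows(dw$train$x, sel), try_, "STP",
                          validation = dw$validation, config = config),
        cnn = train_cnn(trx, try_, validation = dw$validation,
                        config = config),
        stop("unknown model: ", m))
      fits[[m]] <- fit
      preds[[m]] <- predict(fit, dw$test$x)
    }
    if (!is.null(dw$test$repeats))
      scores[[m]] <- noise_corrected_correlation(preds[[m]],
                                                 dw$test$repeats)
  }
  if ("cnn" %in% models) {
    dstrf <- if (!is.null(ens)) ensemble_dstrf(ens, dw$test$x)
             else compute_dstrf_series(fits$cnn, dw$test$x)
    if (profile_metrics && !all(unclass(dstrf) == 0))
      prof <- nonlinearity_profile(dstrf, fits$cnn, dw$test$x)
  }
  structure(list(models = fits, predictions = preds, scores = scores,
                 dstrf = dstrf, ensemble = ens, profile = prof,
                 windows = dw),
            class = "site_fit")
}

# reslice a windowed_stimulus keeping attributes consistent (contiguous
# runs recomputed from the retained frame indices)
subset_windows <- function(windows, sel) {
  fi <- attr(windows, "frame_index")[sel]
  x <- unclass(windows)[sel, , drop = FALSE]
  runs <- rle(cumsum(c(1L, diff(fi) != 1L)))$lengths
  new_windows(x, attr(windows, "window_frames"), attr(windows, "n_bands"),
              1L, frame_index = fi, segments = runs)
}

#' @export
print.site_fit <- function(x, ...) {
  cat("<site fit>\n  models:", paste(names(x$models), collapse = ", "), "\n")
  for (m in names(x$scores))
    cat(sprintf("  %s: noise-corrected R^2 = %.3f\n", m,
                x$scores[[m]]$rho_c_sq))
  if (!is.null(x$profile)) print(x$profile)
  invisible(x)
}
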