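# Linear spectrotemporal receptive field by ridge regression.

#' Fit a linear STRF by ridge regression
#'
#' Solves the regularised least-squares mapping from vectorised stimulus
#' windows to the response.  One eigendecomposition of the design Gram
#' matrix serves the whole penalty grid; the returned solution is the one
#' whose Pearson correlation on the validation set is maximal (the
#' selection criterion used for all models in this package).
#'
#' @param windows training `windowed_stimulus` (or plain matrix).
#' @param response aligned response series.
#' @param validation list with elements `x` (windows) and `y` (response)
#'   used for penalty selection.
#' @param penalties ridge penalty grid (>= 2 values; nonpositive entries
#'   are replaced by the smallest positive one to keep the solve
#'   well-posed).
#' @return an object of class `strf_model` with fields `w` (lag x band
#'   weight matrix), `bias`, `penalty`, and the per-penalty validation
#'   correlations.
#' @export
fit_strf <- function(windows, response, validation,
                     penalties = 10^seq(0, 6, by = 1)) {
  x <- unclass(windows)
  y <- as.numeric(response)
  stopifnot(nrow(x) == length(y), length(penalties) >= 2)
  penalties <- sort(unique(pmax(penalties, min(penalties[penalties > 0]))))
  dims <- window_dims(windows)

  xm <- colMeans(x)
  ym <- mean(y)
  xc <- sweep(x, 2, xm)
  yc <- y - ym
  if (sd(y) == 0) {
    w <- matrix(0, dims[1], dims[2])
    return(new_strf(w, 0, penalties[1], rep(NA_real_, length(penalties)),
                    penalties, dims))
  }
  gram <- crossprod(xc)
  xty <- crossprod(xc, yc)
  eg <- eigen(gram, symmetric = TRUE)
  proj <- crossprod(eg$vectors, xty)

  vx <- unclass(validation$x)
  vy <- as.numeric(validation$y)
  val_cor <- numeric(length(penalties))
  best <- NULL
  for (i in seq_along(penalties)) {
    wi <- eg$vectors %*% (proj / (eg$values + penalties[i]))
    pred <- (sweep(vx, 2, xm) %*% wi) + ym
    val_cor[i] <- if (sd(pred) > 0) cor(vy, pred) else NA_real_
    if (is.null(best) || isTRUE(val_cor[i] > best$cor))
      best <- list(w = wi, cor = val_cor[i], penalty = penalties[i])
  }
  bias <- ym - sum(xm * best$w)
  new_strf(matrix(best$w, dims[1], dims[2]), bias, best$penalty, val_cor,
           penalties, dims)
}

new_strf <- function(w, bias, penalty, val_cor, penalties, dims) {
  structure(list(w = w, bias = bias, penalty = penalty,
                 validation_cor = val_cor, penalties = penalties,
                 dims = dims),
            class = "strf_model")
}

#' @export
print.strf_model <- function(x, ...) {
  cat(sprintf("<STRF model: %d lags x %d bands, ridge penalty %g>\n",
              x$dims[1], x$dims[2], x$penalty))
  invisible(x)
}

#' @rdname fit_strf
#' @param object fitted `strf_model`.
#' @param newdata windows to predict from.
#' @param ... unused.
#' @export
predict.strf_model <- function(object, newdata, ...) {
  x <- unclass(newdata)
  if (ncol(x) != length(object$w)) stop("window shape mismatch")
  as.numeric(x %*% as.numeric(object$w) + object$bias)
}
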