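# shared internal helpers

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so library code never disturbs user-level reproducibility.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Pearson correlation between paired rows of two matrices; rows with zero
# variance give NA.
row_cor <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  ac <- a - rowMeans(a)
  bc <- b - rowMeans(b)
  den <- sqrt(rowSums(ac^2) * rowSums(bc^2))
  num <- rowSums(ac * bc)
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

# derive a reproducible child seed (kept below 2^31)
child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1103L + as.numeric(i) * 7919) %% 2147483629)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Combined mean-squared-error and correlation loss
#'
#' The training loss used by all gradient-fitted encoding models:
#' `w_mse * MSE(y, yhat) - w_corr * cor(y, yhat)`.  When either series has
#' zero variance the correlation term is defined as 0 so the loss stays
#' finite (as can happen early in training).
#'
#' @param y observed response series.
#' @param yhat predicted response series (same length, >= 2).
#' @param w_mse,w_corr loss weights (both default 1).
#' @return a single number; `-w_corr` is the best attainable value at
#'   `yhat = y`.
#' @examples
#' y <- rnorm(100)
#' combined_loss(y, y)  # == -1
#' @export
combined_loss <- function(y, yhat, w_mse = 1, w_corr = 1) {
  stopifnot(length(y) == length(yhat), length(y) >= 2)
  mse <- mean((y - yhat)^2)
  r <- 0
  if (sd(y) > 0 && sd(yhat) > 0) {
    r <- cor(y, yhat)
    if (!is.finite(r)) r <- 0
  }
  w_mse * mse - w_corr * r
}
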