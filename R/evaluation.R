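# Noise-corrected model evaluation and comparison.

#' Noise-corrected correlation between a prediction and repeated responses
#'
#' With repeated presentations of the same test stimulus, splits the
#' trials into odd- and even-numbered halves (1-based numbering), averages
#' each half (`Ro`, `Re`), and estimates the correlation between the
#' prediction `P` and the noiseless response as
#' `rho_c = 0.5 * (cor(P, Re) + cor(P, Ro)) / sqrt(cor(Ro, Re))`.
#' The division by the square root of the half-mean reliability removes
#' the attenuation caused by trial noise, so `rho_c` estimates the
#' correlation attainable against the true signal; its square is the
#' reported noise-corrected R-squared.  Sites whose odd/even reliability
#' is not positive are flagged unreliable rather than scored.
#'
#' @param prediction model prediction aligned to the repeat frames.
#' @param repeats trials x time response matrix (>= 2 trials).
#' @return a `model_score`: `rho_c`, `rho_c_sq`, `raw_corr` (plain Pearson
#'   against the all-trial mean), `reliability` (`cor(Ro, Re)`), and a
#'   `reliable` flag.
#' @export
noise_corrected_correlation <- function(prediction, repeats) {
  repeats <- as.matrix(repeats)
  if (nrow(repeats) < 2) stop("need at least 2 trials")
  if (ncol(repeats) != length(prediction))
    stop("prediction length does not match the repeats")
  odd <- seq(1, nrow(repeats), by = 2)
  even <- seq(2, nrow(repeats), by = 2)
  ro <- colMeans(repeats[odd, , drop = FALSE])
  re <- colMeans(repeats[even, , drop = FALSE])
  rel <- cor(ro, re)
  raw <- cor(prediction, colMeans(repeats))
  if (!is.finite(rel) || rel <= 0) {
    return(new_score(NA_real_, raw, rel, FALSE, repeats))
  }
  rho_c <- 0.5 * (cor(prediction, re) + cor(prediction, ro)) / sqrt(rel)
  new_score(rho_c, raw, rel, TRUE, repeats)
}

new_score <- function(rho_c, raw, rel, reliable, repeats) {
  structure(list(rho_c = rho_c, rho_c_sq = rho_c^2, raw_corr = raw,
                 reliability = rel, reliable = reliable,
                 test_fingerprint = c(dim(repeats), sum(repeats))),
            class = "model_score")
}

#' @export
print.model_score <- function(x, ...) {
  if (x$reliable)
    cat(sprintf(
      "<model score: rho_c = %.3f (R^2 = %.3f), raw r = %.3f, reliability %.3f>\n",
      x$rho_c, x$rho_c_sq, x$raw_corr, x$reliability))
  else
    cat(sprintf("<model score: unreliable site (odd/even r = %.3f)>\n",
                x$reliability))
  invisible(x)
}

#' Improvement of one model over another
#'
#' Difference of noise-corrected R-squared values computed on the same
#' repeat set; scores from different test sets are rejected.
#'
#' @param score_a,score_b `model_score`s on the same repeats.
#' @return `rho_c_sq(a) - rho_c_sq(b)`.
#' @export
compare_models <- function(score_a, score_b) {
  if (!isTRUE(all.equal(score_a$test_fingerprint, score_b$test_fingerprint)))
    stop("scores were computed on different test sets")
  if (!(score_a$reliable && score_b$reliable))
    stop("cannot compare unreliable scores")
  score_a$rho_c_sq - score_b$rho_c_sq
}

#' Prediction-error scaling with training-data duration
#'
#' Fits `1 - rho^2 = intercept + slope * log2(duration)` by least squares;
#' the negated slope is the absolute error reduction per doubling of the
#' training data, also reported as a fraction of the fitted error at the
#' (log-scale) middle duration.
#'
#' @param durations training durations (any consistent unit; >= 3 points,
#'   duplicates allowed and pooled).
#' @param rho_sq noise-corrected R-squared at each duration.
#' @return list with `slope`, `intercept`, `error_reduction_per_doubling`
#'   (`-slope`), and `fractional_reduction_per_doubling`.
#' @export
error_vs_data_curve <- function(durations, rho_sq) {
  stopifnot(length(durations) == length(rho_sq))
  if (length(durations) < 3) stop("need at least 3 duration points")
  err <- 1 - rho_sq
  ld <- log2(durations)
  fit <- lm(err ~ ld)
  slope <- unname(coef(fit)[2])
  mid <- mean(range(ld))
  err_mid <- unname(coef(fit)[1] + slope * mid)
  list(slope = slope, intercept = unname(coef(fit)[1]),
       error_reduction_per_doubling = -slope,
       fractional_reduction_per_doubling =
         if (err_mid > 0) -slope / err_mid else NA_real_)
}
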