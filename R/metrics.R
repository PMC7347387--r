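# Nonlinearity metrics of a DSTRF series: complexity, gain change,
# temporal hold, shape change, and receptive-field subtype clustering.

#' Receptive-field complexity: sum of normalised singular values
#'
#' Stacks the vectorised DSTRF slices as columns of a
#' (lags*bands) x time matrix and returns `sum(sigma) / max(sigma)` over
#' its singular values.  A model applying one fixed template at all times
#' gives 1; `k` mutually orthogonal equal-norm templates in equal
#' proportion give `k`; diverse stimulus-dependent functions give larger
#' values, bounded by `min(lags*bands, time)`.
#'
#' @param series a `dstrf_series` (slices x coefficients matrix).
#' @return complexity, a unitless value >= 1.
#' @export
complexity <- function(series) {
  x <- unclass(series)
  if (nrow(x) < 2) stop("complexity needs at least 2 slices")
  if (all(x == 0)) stop("complexity is undefined for an all-zero series")
  s <- svd(x, nu = 0, nv = 0)$d
  sum(s) / max(s)
}

#' Gain change: variability of the DSTRF magnitude over time
#'
#' The magnitude of each slice is its coefficient standard deviation
#' (per-slice mean removed, `lags*bands - 1` denominator); gain change is
#' the sample standard deviation of these magnitudes over time, capturing
#' adaptation-like rescaling of an otherwise stable receptive field.
#'
#' @param series a `dstrf_series`.
#' @return nonnegative gain-change value (DSTRF-magnitude units); zero iff
#'   all slice magnitudes are equal.
#' @export
gain_change <- function(series) {
  x <- unclass(series)
  if (nrow(x) < 2) stop("gain change needs at least 2 slices")
  sd(apply(x, 1, sd))
}

# displace every slice of a series by `shift` along the lag axis
# (positive = toward larger lag indices, i.e. content moves away from
# "now"); vacated lags are zero-filled
shift_slices <- function(x, shift, dims) {
  if (shift == 0) return(x)
  wf <- dims[1]; nb <- dims[2]
  out <- matrix(0, nrow(x), ncol(x))
  lag_src <- seq_len(wf) - shift
  ok <- lag_src >= 1 & lag_src <= wf
  if (!any(ok)) return(out)
  dst <- as.integer(outer(which(ok), (seq_len(nb) - 1L) * wf, `+`))
  src <- as.integer(outer(lag_src[ok], (seq_len(nb) - 1L) * wf, `+`))
  out[, dst] <- x[, src]
  out
}

#' Temporal hold: duration over which a shifting template persists
#'
#' For each separation `n` in `1..max_shift`, compares the correlation of
#' a DSTRF slice with the slice `n` steps later, either as-is (`alpha`) or
#' with the later slice displaced by `n` along the lag axis so that a
#' stimulus-locked feature stays aligned (`beta`).  A one-tailed Wilcoxon
#' signed-rank test across time asks whether realignment raises the
#' correlation; the temporal hold is the longest persistence run — the
#' largest `n` with every separation `1..n` significant
#' (`p < alpha_level`) — or 0 when realignment never helps.  A held
#' pattern helps realignment at every separation up to its duration, and
#' requiring the full run keeps the false-positive rate of a nonzero hold
#' at the single-test level instead of compounding over `max_shift`
#' separations.  Slices with zero variance are excluded pairwise.
#'
#' @param series a `dstrf_series` of consecutive slices.
#' @param max_shift largest separation tested, in frames (default 30,
#'   i.e. 300 ms at 100 Hz).
#' @param alpha_level significance level of the signed-rank test.
#' @return integer hold duration in frames, in `[0, max_shift]`.
#' @export
temporal_hold <- function(series, max_shift = 30, alpha_level = 0.05) {
  x <- unclass(series)
  tt <- nrow(x)
  if (tt <= max_shift + 1) stop("series too short for the requested shift")
  dims <- attr(series, "lag_bands")
  hold <- 0L
  for (n in seq_len(max_shift)) {
    lead <- x[seq_len(tt - n) + n, , drop = FALSE]
    alpha <- row_cor(x[seq_len(tt - n), , drop = FALSE], lead)
    beta <- row_cor(x[seq_len(tt - n), , drop = FALSE],
                    shift_slices(lead, n, dims))
    ok <- is.finite(alpha) & is.finite(beta)
    if (sum(ok) < 5) break
    diffs <- beta[ok] - alpha[ok]
    if (all(diffs == 0)) break
    p <- suppressWarnings(
      wilcox.test(beta[ok], alpha[ok], paired = TRUE,
                  alternative = "greater", exact = FALSE)$p.value)
    if (!(is.finite(p) && p < alpha_level)) break
    hold <- n
  }
  hold
}

#' Iteratively align DSTRF slices to their running mean
#'
#' Finds an integer lag displacement per slice maximising its correlation
#' with the mean of the currently aligned series; the mean is recomputed
#' after each sweep, until the shifts stop changing or `max_iter` sweeps.
#' Out-of-range lags are zero-filled; ties prefer the smaller absolute
#' shift.  Removing these displacements strips the temporal-hold component
#' from the series.
#'
#' @param series a `dstrf_series`.
#' @param max_iter maximum sweeps (default 50).
#' @param max_shift maximum displacement magnitude in frames (default 30).
#' @return an `alignment_result`: `aligned` series, integer `shifts`,
#'   `converged` flag, `iterations` used, and the per-sweep mean
#'   slice-to-mean correlation (`mean_cor_history`).
#' @export
align_dstrfs <- function(series, max_iter = 50, max_shift = 30) {
  x <- unclass(series)
  dims <- attr(series, "lag_bands")
  tt <- nrow(x)
  shifts <- integer(tt)
  cand <- seq(-max_shift, max_shift)
  ord <- order(abs(cand), cand)     # tie-break: smallest |shift| first
  cand <- cand[ord]
  shifted <- lapply(cand, function(s) shift_slices(x, s, dims))
  converged <- FALSE
  hist_cor <- numeric(0)
  iter <- 0L
  aligned <- x
  for (iter in seq_len(max_iter)) {
    mu <- colMeans(aligned)
    mu_mat <- matrix(mu, tt, length(mu), byrow = TRUE)
    best_cor <- rep(-Inf, tt)
    new_shifts <- integer(tt)
    for (k in seq_along(cand)) {
      cc <- row_cor(shifted[[k]], mu_mat)
      cc[!is.finite(cc)] <- -Inf
      better <- cc > best_cor + 1e-12
      new_shifts[better] <- cand[k]
      best_cor[better] <- cc[better]
    }
    hist_cor <- c(hist_cor, mean(best_cor[is.finite(best_cor)]))
    changed <- !identical(new_shifts, shifts)
    shifts <- new_shifts
    aligned <- x
    for (k in seq_along(cand)) {
      rows <- shifts == cand[k]
      if (any(rows)) aligned[rows, ] <- shifted[[k]][rows, , drop = FALSE]
    }
    if (!changed) { converged <- TRUE; break }
  }
  structure(list(aligned = new_dstrf_series(aligned, dims),
                 shifts = shifts, converged = converged,
                 iterations = iter, mean_cor_history = hist_cor),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment: %d slices, %sconverged in %d sweeps>\n",
              length(x$shifts), if (x$converged) "" else "NOT ",
              x$iterations))
  invisible(x)
}

#' Shape change: complexity after shift alignment
#'
#' The complexity of the time-aligned series: receptive-field diversity
#' that survives removing latency drift, so gain-only and pure-drift
#' series collapse to ~1 while genuine template switching keeps values
#' above 1.
#'
#' @param series a `dstrf_series`.
#' @param max_iter,max_shift passed to [align_dstrfs()].
#' @return shape-change value >= 1.
#' @export
shape_change <- function(series, max_iter = 50, max_shift = 30) {
  complexity(align_dstrfs(series, max_iter, max_shift)$aligned)
}

#' Cluster aligned DSTRFs into receptive-field subtypes
#'
#' K-means on the centred, unit-normalised vectorised slices (so Euclidean
#' distance matches correlation distance), with the number of clusters
#' chosen by the gap statistic against uniform reference draws in the
#' bounding box of the normalised data (first local optimum rule:
#' smallest k with `gap(k) >= gap(k+1) - s(k+1)`).
#'
#' @param series a `dstrf_series` (typically shift-aligned).
#' @param windows optional matching stimulus windows; per-cluster mean
#'   windows are then returned.
#' @param k_range candidate cluster counts (default `1:6`).
#' @param n_ref reference draws for the gap statistic (default 10).
#' @param n_restart seeded k-means restarts (default 10).
#' @param seed RNG seed.
#' @return a `cluster_result`: chosen `k`, per-slice `labels` (`NA` for
#'   all-zero slices), per-cluster mean DSTRFs and mean stimulus windows,
#'   and the gap curve.
#' @export
cluster_dstrfs <- function(series, windows = NULL, k_range = 1:6,
                           n_ref = 10, n_restart = 10, seed = 1) {
  if (length(k_range) == 0) stop("k_range is empty")
  x <- unclass(series)
  live <- apply(x, 1, function(r) sd(r) > 0)
  if (nrow(x[live, , drop = FALSE]) < max(k_range))
    stop("fewer usable slices than the largest candidate k")
  xc <- x[live, , drop = FALSE]
  xc <- xc - rowMeans(xc)
  xn <- xc / sqrt(rowSums(xc^2))

  wss <- function(dat, k, seed_k) {
    if (k == 1) return(sum(sweep(dat, 2, colMeans(dat))^2))
    km <- with_seed(seed_k,
                    kmeans(dat, centers = k, nstart = n_restart,
                           iter.max = 50))
    km$tot.withinss
  }
  log_w <- vapply(k_range, function(k)
    log(wss(xn, k, child_seed(seed, k))), numeric(1))
  lo <- apply(xn, 2, min); hi <- apply(xn, 2, max)
  log_wref <- matrix(0, n_ref, length(k_range))
  for (b in seq_len(n_ref)) {
    ref <- with_seed(child_seed(seed, 100 + b),
                     matrix(runif(length(xn), rep(lo, each = nrow(xn)),
                                  rep(hi, each = nrow(xn))), nrow(xn)))
    log_wref[b, ] <- vapply(seq_along(k_range), function(j)
      log(wss(ref, k_range[j], child_seed(seed, 200 + b * 10 + j))),
      numeric(1))
  }
  gap <- colMeans(log_wref) - log_w
  s_k <- apply(log_wref, 2, sd) * sqrt(1 + 1 / n_ref)
  k_hat <- k_range[length(k_range)]
  for (j in seq_len(length(k_range) - 1)) {
    if (gap[j] >= gap[j + 1] - s_k[j + 1]) { k_hat <- k_range[j]; break }
  }

  labels_live <- if (k_hat == 1) rep(1L, nrow(xn)) else
    with_seed(child_seed(seed, k_hat),
              kmeans(xn, centers = k_hat, nstart = n_restart,
                     iter.max = 50))$cluster
  labels <- rep(NA_integer_, nrow(x))
  labels[live] <- labels_live
  dims <- attr(series, "lag_bands")
  mean_dstrfs <- lapply(seq_len(k_hat), function(g)
    matrix(colMeans(x[which(live)[labels_live == g], , drop = FALSE]),
           dims[1], dims[2]))
  mean_windows <- if (!is.null(windows))
    lapply(seq_len(k_hat), function(g)
      matrix(colMeans(unclass(windows)[which(live)[labels_live == g], ,
                                       drop = FALSE]), dims[1], dims[2]))
  structure(list(k = k_hat, labels = labels, mean_dstrfs = mean_dstrfs,
                 mean_windows = mean_windows, gap = gap, s_k = s_k,
                 k_range = k_range),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<clustering: k = %d (gap statistic over k in %s)>\n", x$k,
              paste(range(x$k_range), collapse = "..")))
  invisible(x)
}

#' Bundle the nonlinearity metrics of one site
#'
#' Computes complexity, gain change, temporal hold, shape change and the
#' mean hidden-state switching rate with one shared configuration.
#'
#' @param series the site's `dstrf_series` (jackknife-mean masked series
#'   in the reference protocol).
#' @param model the site's trained `cnn_model` (for state switches); may
#'   be `NULL` to skip.
#' @param windows the stimulus windows the series was computed on.
#' @param max_shift shift bound shared by temporal hold and alignment.
#' @return a `nonlinearity_profile` (named list of the five scalars).
#' @export
nonlinearity_profile <- function(series, model = NULL, windows = NULL,
                                 max_shift = 30, max_iter = 25) {
  al <- align_dstrfs(series, max_iter = max_iter, max_shift = max_shift)
  structure(list(
    complexity = complexity(series),
    gain_change = gain_change(series),
    temporal_hold = temporal_hold(series, max_shift = max_shift),
    shape_change = complexity(al$aligned),
    mean_switches = if (is.null(model)) NA_real_
                    else count_state_switches(model, windows),
    alignment = al),
    class = "nonlinearity_profile")
}

#' @export
print.nonlinearity_profile <- function(x, ...) {
  cat(sprintf(paste0("<nonlinearity profile: complexity %.2f, gain change ",
                     "%.3g, temporal hold %d, shape change %.2f, ",
                     "switches/step %.1f>\n"),
              x$complexity, x$gain_change, x$temporal_hold, x$shape_change,
              x$mean_switches))
  invisible(x)
}
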