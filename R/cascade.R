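# Linear-nonlinear (LN) and short-term-plasticity (STP) cascade models.
#
# Both are rank-4 time-frequency separable cascades: four gaussian
# frequency-selection kernels, a 40-tap causal FIR filter per channel, and
# a double-exponential output nonlinearity.  The STP variant inserts a
# Tsodyks-Markram plasticity stage between the frequency kernels and the
# FIR filters.  Fitting is full-batch Adam on the combined MSE-correlation
# loss with analytic gradients (backpropagation through time for the
# plasticity recursion).

#' Double-exponential static output nonlinearity
#'
#' `sigma(x) = b + a * exp(-exp(-exp(kappa) * (x - c)))`: a smooth
#' saturating curve with baseline `b`, output range `a`, inflection `c` and
#' log-slope `kappa`.  Monotone increasing in `x` for `a > 0`, with limits
#' `b` as `x -> -Inf` and `b + a` as `x -> +Inf`; at `x = c` the value is
#' `b + a / e`.
#'
#' @param x input (any numeric shape).
#' @param p named vector or list with `a`, `b`, `c`, `kappa`.
#' @return `sigma(x)`, same shape as `x`.
#' @export
double_exponential <- function(x, p) {
  p <- as.list(p)
  p$b + p$a * exp(-exp(-exp(p$kappa) * (x - p$c)))
}

# derivative pieces of the double exponential used by the fitters
dexp_pieces <- function(x, p) {
  p <- as.list(p)
  ek <- exp(p$kappa)
  q <- exp(-ek * (x - p$c))
  e <- exp(-q)
  list(value = p$b + p$a * e,
       d_x = p$a * e * q * ek,
       d_a = e, d_b = rep(1, length(x)),
       d_c = -p$a * e * q * ek,
       d_kappa = p$a * e * q * ek * (x - p$c))
}

#' Tsodyks-Markram short-term plasticity stage
#'
#' Applies the discrete-time plasticity recursion to each input channel:
#' `d(t) = d(t-1) + u * x(t-1) * (1 - d(t-1)) - d(t-1) / tau`, with output
#' `y(t) = d(t) * x(t)` and `d(0) = d0`.  `u` is the release probability
#' (plasticity strength) and `tau` the recovery time constant in frames.
#' Under constant drive `X` the gain state converges to
#' `uX tau / (1 + uX tau)`.
#'
#' @param x nonnegative input series: a length-T vector or T x C matrix.
#' @param u release probability per channel, in `[0, 1]`.
#' @param tau recovery time constant per channel (frames, > 0).
#' @param d0 initial gain state (default 0).
#' @return matrix (or vector) `y` of the same shape, with the gain series
#'   attached as attribute `"gain"`.
#' @export
stp_adaptation <- function(x, u, tau, d0 = 0) {
  vec_in <- is.null(dim(x))
  x <- as.matrix(x)
  if (any(x < 0)) stop("plasticity input must be nonnegative")
  if (any(tau <= 0)) stop("tau must be positive")
  if (any(u < 0 | u > 1)) stop("u must lie in [0, 1]")
  nc <- ncol(x)
  u <- rep_len(u, nc); tau <- rep_len(tau, nc); d <- rep_len(d0, nc)
  n <- nrow(x)
  dmat <- matrix(0, n, nc)
  for (t in seq_len(n)) {
    xp <- if (t == 1) rep(0, nc) else x[t - 1, ]
    d <- d + u * xp * (1 - d) - d / tau
    dmat[t, ] <- d
  }
  y <- dmat * x
  if (vec_in) { y <- as.numeric(y); attr(y, "gain") <- as.numeric(dmat) }
  else attr(y, "gain") <- dmat
  y
}

# ---- parameter packing -----------------------------------------------------

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

cascade_layout <- function(variant, n_bands = 32, n_taps = 40, rank = 4) {
  sizes <- c(mu = rank, rho_sig = rank, amp = rank, fir = n_taps * rank,
             a = 1, b = 1, c = 1, kappa = 1)
  if (variant == "STP") sizes <- c(sizes, rho_u = rank, rho_tau = rank)
  ends <- cumsum(sizes)
  idx <- Map(function(e, s) seq(e - s + 1, e), ends, sizes)
  list(idx = idx, n = ends[[length(ends)]], n_bands = n_bands,
       n_taps = n_taps, rank = rank, variant = variant)
}

cascade_unpack <- function(p, lay) {
  g <- function(nm) p[lay$idx[[nm]]]
  out <- list(mu = g("mu"), sig = softplus(g("rho_sig")) + 0.5,
              amp = g("amp"),
              fir = matrix(g("fir"), lay$n_taps, lay$rank),
              dexp = c(a = g("a"), b = g("b"), c = g("c"),
                       kappa = g("kappa")))
  names(out$dexp) <- c("a", "b", "c", "kappa")
  if (lay$variant == "STP") {
    out$u <- plogis(g("rho_u"))
    out$tau <- softplus(g("rho_tau")) + 1
  }
  out
}

# gaussian frequency kernels, n_bands x rank, plus parameter derivatives
gauss_kernels <- function(mu, sig, amp, n_bands) {
  f <- seq_len(n_bands)
  e <- vapply(seq_along(mu),
              function(i) exp(-0.5 * ((f - mu[i]) / sig[i])^2),
              numeric(n_bands))
  g <- sweep(e, 2, amp, `*`)
  list(g = g, e = e, f = f)
}

# ---- forward passes --------------------------------------------------------

ln_linear_drive <- function(x_mat, fir, g) {
  # s_t = <window_t, sum_i vec(fir_i outer g_i)>
  k_tot <- numeric(ncol(x_mat))
  for (i in seq_len(ncol(fir)))
    k_tot <- k_tot + as.vector(outer(fir[, i], g[, i]))
  as.numeric(x_mat %*% k_tot)
}

# per-segment STP forward: frame series -> channel drive for each window
stp_segment_forward <- function(fr, par, wf) {
  cmat <- fr %*% par$g                 # frames x rank channel series
  y <- stp_adaptation(pmax(cmat, 0), par$u, par$tau)
  dmat <- attr(y, "gain")
  n_win <- nrow(fr) - wf + 1
  s <- numeric(n_win)
  for (i in seq_len(ncol(cmat))) {
    fs <- stats::filter(y[, i], rev(par$fir[, i]), sides = 1)
    s <- s + as.numeric(fs)[wf:nrow(fr)]
  }
  list(s = s, cmat = cmat, y = y, dmat = dmat)
}

cascade_forward <- function(p, lay, x_mat, segments = NULL, frames = NULL,
                            wf = NULL) {
  par <- cascade_unpack(p, lay)
  gk <- gauss_kernels(par$mu, par$sig, par$amp, lay$n_bands)
  par$g <- gk$g
  if (lay$variant == "LN") {
    s <- ln_linear_drive(x_mat, par$fir, par$g)
  } else {
    s <- unlist(lapply(frames, function(fr)
      stp_segment_forward(fr, par, wf)$s))
  }
  list(yhat = double_exponential(s, par$dexp), s = s, par = par, gk = gk)
}

# ---- gradients -------------------------------------------------------------

combined_loss_grad <- function(y, yhat, w_mse = 1, w_corr = 1) {
  n <- length(y)
  g <- w_mse * 2 / n * (yhat - y)
  if (sd(y) > 0 && sd(yhat) > 0) {
    r <- cor(y, yhat)
    if (is.finite(r)) {
      yc <- y - mean(y); hc <- yhat - mean(yhat)
      g <- g - w_corr * (yc / (sd(y) * sd(yhat)) - r * hc / sd(yhat)^2) /
        (n - 1)
    }
  }
  g
}

# full-batch loss and analytic gradient of the packed parameter vector
cascade_loss_grad <- function(p, lay, x_mat, y, w_mse, w_corr,
                              segments = NULL, frames = NULL, wf = NULL) {
  fw <- cascade_forward(p, lay, x_mat, segments, frames, wf)
  loss <- combined_loss(y, fw$yhat, w_mse, w_corr)
  dl_dyhat <- combined_loss_grad(y, fw$yhat, w_mse, w_corr)
  pieces <- dexp_pieces(fw$s, fw$par$dexp)
  pvec <- dl_dyhat * pieces$d_x        # dL/ds_t
  par <- fw$par
  grad <- numeric(lay$n)
  gi <- function(nm) lay$idx[[nm]]

  grad[gi("a")] <- sum(dl_dyhat * pieces$d_a)
  grad[gi("b")] <- sum(dl_dyhat * pieces$d_b)
  grad[gi("c")] <- sum(dl_dyhat * pieces$d_c)
  grad[gi("kappa")] <- sum(dl_dyhat * pieces$d_kappa)

  if (lay$variant == "LN") {
    gk_vec <- crossprod(x_mat, pvec)                  # dL/dk_tot
    gk_mat <- matrix(gk_vec, lay$n_taps, lay$n_bands)
    grad_fir <- gk_mat %*% par$g                      # n_taps x rank
    grad_g <- crossprod(gk_mat, par$fir)              # n_bands x rank
  } else {
    grad_fir <- matrix(0, lay$n_taps, lay$rank)
    grad_g <- matrix(0, lay$n_bands, lay$rank)
    grad_u_rho <- numeric(lay$rank); grad_tau_rho <- numeric(lay$rank)
    off <- 0L
    for (fr in frames) {
      seg <- stp_segment_forward(fr, par, wf)
      n_win <- length(seg$s)
      pseg <- pvec[off + seq_len(n_win)]
      off <- off + n_win
      n_fr <- nrow(fr)
      d_y <- matrix(0, n_fr, lay$rank)                # dL/d(adapted drive)
      for (i in seq_len(lay$rank)) {
        fir_i <- par$fir[, i]
        grad_fir[, i] <- grad_fir[, i] +
          vapply(seq_len(lay$n_taps), function(lag)
            sum(pseg * seg$y[seq_len(n_win) + (lag - 1), i]),
            numeric(1))
        d_y[, i] <- conv_full(pseg, fir_i)[seq_len(n_fr)]
      }
      bp <- stp_backward(pmax(seg$cmat, 0), seg$dmat, d_y, par$u, par$tau)
      d_c <- bp$d_x * (seg$cmat > 0)                  # rectifier gate
      grad_g <- grad_g + crossprod(fr, d_c)
      grad_u_rho <- grad_u_rho + bp$d_u * par$u * (1 - par$u)
      grad_tau_rho <- grad_tau_rho + bp$d_tau * plogis(p[gi("rho_tau")] )
    }
    grad[gi("rho_u")] <- grad_u_rho
    grad[gi("rho_tau")] <- grad_tau_rho
  }

  grad[gi("fir")] <- as.numeric(grad_fir)
  # chain gaussian-kernel gradients to (mu, sig, amp)
  f <- gauss_kernels(par$mu, par$sig, par$amp, lay$n_bands)$f
  for (i in seq_len(lay$rank)) {
    gcol <- par$g[, i]
    grad[gi("amp")][i] <- sum(grad_g[, i] * gcol / par$amp[i])
    grad[gi("mu")][i] <- sum(grad_g[, i] * gcol * (f - par$mu[i]) /
                               par$sig[i]^2)
    dsig <- sum(grad_g[, i] * gcol * (f - par$mu[i])^2 / par$sig[i]^3)
    grad[gi("rho_sig")][i] <- dsig * plogis(p[gi("rho_sig")][i])
  }
  # fix: amp gradient when amp == 0
  if (any(par$amp == 0)) {
    e <- gauss_kernels(par$mu, par$sig, rep(1, lay$rank), lay$n_bands)$g
    for (i in which(par$amp == 0))
      grad[gi("amp")][i] <- sum(grad_g[, i] * e[, i])
  }
  list(loss = loss, grad = grad)
}

# full (zero-padded) convolution: out[k] = sum_j a[j] b[k - j + 1]
conv_full <- function(a, b) {
  out <- stats::convolve(a, rev(b), type = "open")
  out
}

# backpropagation through the plasticity recursion; x is the (rectified)
# input series, dmat the stored gain states, d_y = dL/dy
stp_backward <- function(x, dmat, d_y, u, tau) {
  n <- nrow(x); nc <- ncol(x)
  d_x <- d_y * dmat
  d_u <- numeric(nc); d_tau <- numeric(nc)
  lam_next <- rep(0, nc)
  for (t in n:1) {
    lam <- d_y[t, ] * x[t, ] +
      lam_next * (1 - u * x[t, ] - 1 / tau)
    if (t < n) {
      d_x[t, ] <- d_x[t, ] + lam_next * u * (1 - dmat[t, ])
      d_u <- d_u + lam_next * x[t, ] * (1 - dmat[t, ])
      d_tau <- d_tau + lam_next * dmat[t, ] / tau^2
    }
    lam_next <- lam
  }
  list(d_x = d_x, d_u = d_u, d_tau = d_tau)
}

# ---- fitting ---------------------------------------------------------------

cascade_init <- function(lay, y, seed) {
  with_seed(seed, {
    p <- numeric(lay$n)
    p[lay$idx[["mu"]]] <- seq(4, lay$n_bands - 3, length.out = lay$rank) +
      rnorm(lay$rank, sd = 1)
    p[lay$idx[["rho_sig"]]] <- log(expm1(3))
    p[lay$idx[["amp"]]] <- rnorm(lay$rank, sd = 0.3)
    p[lay$idx[["fir"]]] <- rnorm(lay$n_taps * lay$rank, sd = 0.1)
    p[lay$idx[["a"]]] <- 4 * sd(y)
    p[lay$idx[["b"]]] <- mean(y) - 2 * sd(y)
    p[lay$idx[["c"]]] <- 0
    p[lay$idx[["kappa"]]] <- 0
    if (lay$variant == "STP") {
      p[lay$idx[["rho_u"]]] <- -1.5
      p[lay$idx[["rho_tau"]]] <- log(expm1(9))
    }
    p
  })
}

#' Fit a linear-nonlinear or short-term-plasticity cascade
#'
#' Full-batch Adam on the combined MSE-correlation loss with analytic
#' gradients (including backpropagation through time for the plasticity
#' recursion of the STP variant).  The parameters with the best validation
#' loss over the run are returned; multiple seeded restarts guard against
#' poor initialisation, and a diverging run (non-finite loss) is retried
#' with a smaller step size.
#'
#' @param windows stride-1 training `windowed_stimulus`.
#' @param response aligned training response.
#' @param variant `"LN"` or `"STP"`.
#' @param validation list with `x` (windows) and `y`.
#' @param config a [training_config()] (seed and loss weights are used).
#' @param lr full-batch Adam step size (default 0.02).
#' @param max_iter Adam iterations per restart (default 400).
#' @param n_restarts seeded restarts (default 2).
#' @return an `ln_model` or `stp_model` with fields `params` (unpacked:
#'   gaussian kernels, FIR taps, output nonlinearity, and for STP the
#'   release probabilities `u` and recovery constants `tau`), `val_loss`,
#'   and `history`.
#' @export
fit_cascade <- function(windows, response, variant = c("LN", "STP"),
                        validation, config = training_config(), lr = 0.02,
                        max_iter = 400, n_restarts = 2) {
  variant <- match.arg(variant)
  dims <- window_dims(windows)
  lay <- cascade_layout(variant, n_bands = dims[2], n_taps = dims[1])
  x_mat <- unclass(windows)
  y <- as.numeric(response)
  frames <- if (variant == "STP") frames_from_windows(windows) else NULL
  vframes <- if (variant == "STP") frames_from_windows(validation$x) else NULL
  vx <- unclass(validation$x); vy <- as.numeric(validation$y)

  best <- NULL
  for (r in seq_len(n_restarts)) {
    seed_r <- child_seed(config$seed, r)
    lr_r <- lr
    for (attempt in 1:3) {
      run <- cascade_adam(lay, x_mat, y, vx, vy, frames, vframes, dims[1],
                          config, lr_r, max_iter, seed_r)
      if (!is.null(run)) break
      lr_r <- lr_r / 5   # diverged: restart with a smaller step
    }
    if (is.null(run)) stop("cascade fit diverged repeatedly")
    if (is.null(best) || run$val_loss < best$val_loss) best <- run
  }
  par <- cascade_unpack(best$p, lay)
  par$g <- gauss_kernels(par$mu, par$sig, par$amp, lay$n_bands)$g
  structure(list(params = par, layout = lay, packed = best$p,
                 val_loss = best$val_loss, history = best$history,
                 dims = dims),
            class = c(if (variant == "STP") "stp_model" else "ln_model",
                      "cascade_model"))
}

cascade_adam <- function(lay, x_mat, y, vx, vy, frames, vframes, wf, config,
                         lr, max_iter, seed) {
  p <- cascade_init(lay, y, seed)
  m <- numeric(lay$n); v <- numeric(lay$n)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  best_p <- p; best_val <- Inf
  hist_tr <- numeric(0); hist_val <- numeric(0)
  for (it in seq_len(max_iter)) {
    lg <- cascade_loss_grad(p, lay, x_mat, y, config$w_mse, config$w_corr,
                            frames = frames, wf = wf)
    if (!is.finite(lg$loss) || !all(is.finite(lg$grad))) return(NULL)
    m <- b1 * m + (1 - b1) * lg$grad
    v <- b2 * v + (1 - b2) * lg$grad^2
    p <- p - lr * (m / (1 - b1^it)) / (sqrt(v / (1 - b2^it)) + eps)
    if (it %% 10 == 0 || it == max_iter) {
      fv <- cascade_forward(p, lay, vx, frames = vframes, wf = wf)
      vl <- combined_loss(vy, fv$yhat, config$w_mse, config$w_corr)
      hist_tr <- c(hist_tr, lg$loss); hist_val <- c(hist_val, vl)
      if (is.finite(vl) && vl < best_val) { best_val <- vl; best_p <- p }
    }
  }
  list(p = best_p, val_loss = best_val,
       history = list(train_loss = hist_tr, val_loss = hist_val))
}

#' @export
print.cascade_model <- function(x, ...) {
  cat(sprintf("<%s cascade: rank %d, %d taps, validation loss %.4f>\n",
              x$layout$variant, x$layout$rank, x$layout$n_taps, x$val_loss))
  invisible(x)
}

#' @rdname fit_cascade
#' @param object fitted cascade model.
#' @param newdata stride-1 windows to predict from.
#' @param ... unused.
#' @export
predict.cascade_model <- function(object, newdata, ...) {
  lay <- object$layout
  if (ncol(newdata) != lay$n_taps * lay$n_bands)
    stop("window shape mismatch")
  frames <- if (lay$variant == "STP") frames_from_windows(newdata) else NULL
  cascade_forward(object$packed, lay, unclass(newdata), frames = frames,
                  wf = lay$n_taps)$yhat
}
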