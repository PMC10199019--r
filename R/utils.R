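# Shared numerical helpers: smooth relaxations of max/min/relu used to make
# the observation and flow operators differentiable during training, plus
# small assertion utilities.

#' Smoothed rectifier (softplus of width tau)
#'
#' `relu_smooth(x, tau)` equals `tau * log(1 + exp(x / tau))`, a C-infinity
#' relaxation of `max(0, x)` that converges to it as `tau -> 0`. With
#' `tau = 0` the exact rectifier is returned. Used for glottal gaps and
#' contact penetration so that gradients exist through closure events.
#'
#' @param x numeric vector or matrix.
#' @param tau smoothing width (same units as `x`); `0` gives the exact max.
#' @return object of the same shape as `x`.
#' @keywords internal
relu_smooth <- function(x, tau = 0) {
  if (tau <= 0) return(pmax(x, 0))
  s <- x / tau
  out <- x
  small <- s < 30
  out[small] <- tau * log1p(exp(s[small]))
  out
}

# derivative of relu_smooth w.r.t. x (logistic sigmoid, or indicator at tau=0)
relu_smooth_grad <- function(x, tau = 0) {
  if (tau <= 0) return((x > 0) * 1.0)
  s <- x / tau
  1 / (1 + exp(-pmin(pmax(s, -30), 30)))
}

# Boltzmann (softmax-weighted) minimum: sum(w * x) with w = softmax(-x/tau).
# Exact minimum at tau = 0. Returns value plus weights for the backward pass.
boltzmann_min <- function(x, tau = 0) {
  if (tau <= 0) {
    i <- which(x == min(x))
    i <- i[length(i)]  # ties -> most downstream entry
    w <- numeric(length(x)); w[i] <- 1
    return(list(value = x[i], weights = w))
  }
  s <- -x / tau
  s <- s - max(s)
  w <- exp(s); w <- w / sum(w)
  list(value = sum(w * x), weights = w)
}

# gradient of boltzmann_min value w.r.t. x
boltzmann_min_grad <- function(x, value, weights, tau) {
  if (tau <= 0) return(weights)
  weights * (1 + (value - x) / tau)
}

# Boltzmann maximum along columns of a matrix: for each column k,
# value_k = sum_j w_jk x_jk with w = softmax(x/tau). tau = 0 gives exact max.
boltzmann_max_cols <- function(X, tau = 0) {
  if (tau <= 0) {
    idx <- apply(X, 2, which.max)
    W <- matrix(0, nrow(X), ncol(X))
    W[cbind(idx, seq_len(ncol(X)))] <- 1
    return(list(value = X[cbind(idx, seq_len(ncol(X)))], weights = W))
  }
  S <- X / tau
  S <- sweep(S, 2, apply(S, 2, max), "-")
  W <- exp(S)
  W <- sweep(W, 2, colSums(W), "/")
  list(value = colSums(W * X), weights = W)
}

# gradient matrix d value_k / d X_jk
boltzmann_max_cols_grad <- function(X, value, weights, tau) {
  if (tau <= 0) return(weights)
  weights * (1 + sweep(X, 2, value, "-") / tau)
}

# trapezoid quadrature weights for sorted abscissae
trapz_weights <- function(x) {
  n <- length(x)
  if (n < 2) stop("need at least two abscissae for trapezoid weights")
  w <- numeric(n)
  d <- diff(x)
  w[1] <- d[1] / 2
  w[n] <- d[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (d[-(n - 1)] + d[-1]) / 2
  w
}

# linear-interpolation matrix mapping values at `from` onto points `at`
# (rows: at, cols: from); constant extrapolation beyond the range.
interp_matrix <- function(from, at) {
  n <- length(from)
  S <- matrix(0, length(at), n)
  for (r in seq_along(at)) {
    x <- at[r]
    if (x <= from[1]) { S[r, 1] <- 1; next }
    if (x >= from[n]) { S[r, n] <- 1; next }
    j <- findInterval(x, from)
    t <- (x - from[j]) / (from[j + 1] - from[j])
    S[r, j] <- 1 - t
    S[r, j + 1] <- t
  }
  S
}

stop_if_not <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}
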