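# LSTM encoder-decoder with a fully connected head, implemented directly on
# matrices with hand-derived reverse-mode gradients (no autodiff framework
# is used anywhere in the package; every backward pass is checked against
# finite differences in the test suite).
#
# Architecture: the encoder LSTM consumes the whole profile sequence; its
# final hidden and cell states seed the decoder LSTM, which is additionally
# teacher-forced with the per-step profile features. Each decoder hidden
# vector is mapped by a residual, layer-normalized MLP to the modal
# coefficients of that time step.

#' Network hyperparameters
#'
#' @param hidden LSTM hidden-state width (encoder and decoder).
#' @param lstm_layers number of LSTM layers (currently 1 is supported).
#' @param fc_layers number of residual MLP blocks.
#' @param fc_width MLP width.
#' @param n_modes output dimension (number of modal coefficients).
#' @return object of class `vf_network_config`.
#' @export
network_config <- function(hidden = 128, lstm_layers = 1, fc_layers = 4,
                           fc_width = 128, n_modes = 100) {
  stop_if_not(hidden >= 1 && fc_layers >= 1 && fc_width >= 1 && n_modes >= 1,
              "all network sizes must be positive")
  stop_if_not(lstm_layers == 1, "only single-layer LSTMs are supported")
  structure(list(hidden = hidden, lstm_layers = lstm_layers,
                 fc_layers = fc_layers, fc_width = fc_width,
                 n_modes = n_modes),
            class = "vf_network_config")
}

# uniform init in +-1/sqrt(fan_in) (the convention of standard deep-learning
# libraries for LSTM/linear layers)
init_mat <- function(nr, nc, fan_in) {
  matrix(stats::runif(nr * nc, -1, 1) / sqrt(fan_in), nr, nc)
}

#' Initialize network parameters
#'
#' Deterministic given `seed`. The forget-gate bias is initialized to +1
#' (standard practice: keeps memory open early in training).
#'
#' @param cfg a [network_config()].
#' @param n_features input features per time step (profile stations).
#' @param seed RNG seed.
#' @return nested list of parameter matrices (class `vf_network_params`).
#' @export
network_init <- function(cfg, n_features, seed = 1L) {
  set.seed(seed)
  H <- cfg$hidden; D <- cfg$fc_width
  lstm_init <- function(F_in) {
    b <- numeric(4 * H)
    b[(H + 1):(2 * H)] <- 1                        # forget gate
    list(Wx = init_mat(4 * H, F_in, F_in), Wh = init_mat(4 * H, H, H), b = b)
  }
  blocks <- vector("list", cfg$fc_layers)
  for (l in seq_len(cfg$fc_layers)) {
    blocks[[l]] <- list(gamma = rep(1, D), beta = numeric(D),
                        W = init_mat(D, D, D), c = numeric(D))
  }
  params <- list(enc = lstm_init(n_features),
                 dec = lstm_init(n_features),
                 Win = if (H == D) NULL else init_mat(D, H, H),
                 bin = if (H == D) NULL else numeric(D),
                 blocks = blocks,
                 Wout = init_mat(cfg$n_modes, D, D),
                 bout = numeric(cfg$n_modes))
  structure(params, class = "vf_network_params", cfg = cfg,
            n_features = n_features)
}

sigmoid <- function(x) 1 / (1 + exp(-pmin(pmax(x, -30), 30)))

# single-layer LSTM over a T x F input; returns hidden states and caches
lstm_forward <- function(p, X, h0 = NULL, c0 = NULL) {
  H <- length(p$b) / 4
  T_ <- nrow(X)
  if (is.null(h0)) h0 <- numeric(H)
  if (is.null(c0)) c0 <- numeric(H)
  Hs <- matrix(0, T_, H)
  cache <- vector("list", T_)
  h <- h0; cc <- c0
  ix <- 1:H; fx <- (H + 1):(2 * H); gx <- (2 * H + 1):(3 * H); ox <- (3 * H + 1):(4 * H)
  for (t in seq_len(T_)) {
    x <- X[t, ]
    z <- as.numeric(p$Wx %*% x) + as.numeric(p$Wh %*% h) + p$b
    i <- sigmoid(z[ix]); f <- sigmoid(z[fx]); g <- tanh(z[gx]); o <- sigmoid(z[ox])
    c_new <- f * cc + i * g
    tc <- tanh(c_new)
    h_new <- o * tc
    cache[[t]] <- list(x = x, h_prev = h, c_prev = cc, i = i, f = f, g = g,
                       o = o, c = c_new, tc = tc)
    h <- h_new; cc <- c_new
    Hs[t, ] <- h
  }
  list(H = Hs, h_last = h, c_last = cc, cache = cache, h0 = h0, c0 = c0)
}

# backward through the LSTM: dH is T x H adjoint of the hidden outputs,
# dh_last/dc_last adjoints of the final states. Returns parameter grads,
# input grads, and adjoints of the initial states.
lstm_backward <- function(p, fwd, dH = NULL, dh_last = NULL, dc_last = NULL) {
  H <- length(p$b) / 4
  T_ <- length(fwd$cache)
  dZ_all <- matrix(0, T_, 4 * H)                   # gate adjoints per step
  Xc <- matrix(0, T_, ncol(p$Wx))
  Hp <- matrix(0, T_, H)
  dh_next <- if (is.null(dh_last)) numeric(H) else dh_last
  dc_next <- if (is.null(dc_last)) numeric(H) else dc_last
  for (t in rev(seq_len(T_))) {
    cc <- fwd$cache[[t]]
    dh <- dh_next + if (is.null(dH)) 0 else dH[t, ]
    do <- dh * cc$tc
    dc <- dc_next + dh * cc$o * (1 - cc$tc^2)
    di <- dc * cc$g
    dg <- dc * cc$i
    df <- dc * cc$c_prev
    dc_next <- dc * cc$f
    dz <- c(di * cc$i * (1 - cc$i),
            df * cc$f * (1 - cc$f),
            dg * (1 - cc$g^2),
            do * cc$o * (1 - cc$o))
    dZ_all[t, ] <- dz
    Xc[t, ] <- cc$x
    Hp[t, ] <- cc$h_prev
    dh_next <- as.numeric(crossprod(p$Wh, dz))
  }
  list(grads = list(Wx = crossprod(dZ_all, Xc), Wh = crossprod(dZ_all, Hp),
                    b = colSums(dZ_all)),
       dX = dZ_all %*% p$Wx, dh0 = dh_next, dc0 = dc_next)
}

# layer normalization over the feature dimension of a T x D matrix
layernorm_forward <- function(Z, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(Z)
  Zc <- Z - mu
  v <- rowMeans(Zc^2)
  inv <- 1 / sqrt(v + eps)
  Xhat <- Zc * inv
  A <- sweep(Xhat, 2, gamma, "*")
  A <- sweep(A, 2, beta, "+")
  list(A = A, Xhat = Xhat, inv = inv)
}

layernorm_backward <- function(dA, cache, gamma) {
  D <- ncol(dA)
  dXhat <- sweep(dA, 2, gamma, "*")
  dgamma <- colSums(dA * cache$Xhat)
  dbeta <- colSums(dA)
  # per-row: dZ = inv/D * (D*dXhat - sum(dXhat) - Xhat * sum(dXhat*Xhat))
  s1 <- rowSums(dXhat)
  s2 <- rowSums(dXhat * cache$Xhat)
  dZ <- (dXhat - s1 / D - cache$Xhat * s2 / D) * cache$inv
  list(dZ = dZ, dgamma = dgamma, dbeta = dbeta)
}

# residual layer-normalized MLP head on a T x H matrix of hidden states
fcnn_forward <- function(params, Hs) {
  if (is.null(params$Win)) {
    Z <- Hs
  } else {
    Z <- Hs %*% t(params$Win)
    Z <- sweep(Z, 2, params$bin, "+")
  }
  caches <- vector("list", length(params$blocks))
  for (l in seq_along(params$blocks)) {
    blk <- params$blocks[[l]]
    ln <- layernorm_forward(Z, blk$gamma, blk$beta)
    U_pre <- ln$A %*% t(blk$W)
    U_pre <- sweep(U_pre, 2, blk$c, "+")
    U <- pmax(U_pre, 0)
    caches[[l]] <- list(ln = ln, U_pre = U_pre, Zin = Z)
    Z <- Z + U
  }
  Y <- Z %*% t(params$Wout)
  Y <- sweep(Y, 2, params$bout, "+")
  list(Y = Y, Z = Z, caches = caches, Hs = Hs)
}

fcnn_backward <- function(params, fwd, dY) {
  grads <- list(Wout = crossprod(dY, fwd$Z), bout = colSums(dY),
                blocks = vector("list", length(params$blocks)),
                Win = NULL, bin = NULL)
  dZ <- dY %*% params$Wout
  for (l in rev(seq_along(params$blocks))) {
    blk <- params$blocks[[l]]
    cc <- fwd$caches[[l]]
    dU <- dZ                                        # residual: Z_out = Z_in + U
    dU_pre <- dU * (cc$U_pre > 0)
    dW <- crossprod(dU_pre, cc$ln$A)
    dc <- colSums(dU_pre)
    dA <- dU_pre %*% blk$W
    lb <- layernorm_backward(dA, cc$ln, blk$gamma)
    grads$blocks[[l]] <- list(gamma = lb$dgamma, beta = lb$dbeta, W = dW, c = dc)
    dZ <- dZ + lb$dZ
  }
  if (is.null(params$Win)) {
    dHs <- dZ
  } else {
    grads$Win <- crossprod(dZ, fwd$Hs)
    grads$bin <- colSums(dZ)
    dHs <- dZ %*% params$Win
  }
  list(grads = grads, dHs = dHs)
}

#' Forward pass of the profile-to-modal-coefficients network
#'
#' The encoder LSTM reads the whole feature sequence; its final hidden/cell
#' states seed the decoder LSTM, which is teacher-forced with the same
#' per-step features; the residual MLP head maps decoder hidden states to
#' one row of modal coefficients per time step. Deterministic given the
#' parameters.
#'
#' @param params a `vf_network_params` object.
#' @param X T x F feature matrix (nondimensionalized profiles).
#' @return list with `Y` (T x n_modes output) and `cache` for
#'   [network_backward()].
#' @export
network_forward <- function(params, X) {
  nf <- attr(params, "n_features")
  stop_if_not(ncol(X) == nf,
              "feature width (%d) does not match the trained input layer (%d)",
              ncol(X), nf)
  enc <- lstm_forward(params$enc, X)
  dec <- lstm_forward(params$dec, X, h0 = enc$h_last, c0 = enc$c_last)
  head <- fcnn_forward(params, dec$H)
  list(Y = head$Y, cache = list(enc = enc, dec = dec, head = head, X = X))
}

#' Backward pass: gradients of a scalar loss w.r.t. all parameters
#'
#' @param params a `vf_network_params` object.
#' @param cache the cache from [network_forward()].
#' @param dY T x n_modes adjoint of the network output.
#' @return nested list of gradients with the same structure as `params`.
#' @export
network_backward <- function(params, cache, dY) {
  hb <- fcnn_backward(params, cache$head, dY)
  decb <- lstm_backward(params$dec, cache$dec, dH = hb$dHs)
  # decoder initial states came from the encoder's final states
  encb <- lstm_backward(params$enc, cache$enc, dH = NULL,
                        dh_last = decb$dh0, dc_last = decb$dc0)
  # same structure and order as `params` (required by the optimizer helpers)
  list(enc = encb$grads, dec = decb$grads,
       Win = hb$grads$Win, bin = hb$grads$bin,
       blocks = hb$grads$blocks,
       Wout = hb$grads$Wout, bout = hb$grads$bout)
}

# ---- parameter-structure helpers (flatten / map) --------------------------

# apply f elementwise over two parallel nested lists of numerics
par_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- a
    for (nm in seq_along(a)) {
      if (is.null(a[[nm]])) next
      out[[nm]] <- par_map2(a[[nm]], b[[nm]], f)
    }
    return(out)
  }
  f(a, b)
}

par_map <- function(a, f) {
  if (is.list(a)) {
    out <- a
    for (nm in seq_along(a)) {
      if (is.null(a[[nm]])) next
      out[[nm]] <- par_map(a[[nm]], f)
    }
    return(out)
  }
  f(a)
}

# sum of squares over a nested parameter list without flattening
par_sumsq <- function(a) {
  if (is.list(a)) {
    s <- 0
    for (nm in seq_along(a)) {
      if (is.null(a[[nm]])) next
      s <- s + par_sumsq(a[[nm]])
    }
    return(s)
  }
  sum(a * a)
}

par_flatten <- function(a) {
  if (is.list(a)) return(unlist(lapply(a, function(x) if (is.null(x)) numeric(0) else par_flatten(x))))
  as.numeric(a)
}

par_unflatten <- function(template, v) {
  pos <- 0L
  rec <- function(a) {
    if (is.list(a)) {
      for (nm in seq_along(a)) {
        if (is.null(a[[nm]])) next
        a[[nm]] <- rec(a[[nm]])
      }
      return(a)
    }
    n <- length(a)
    out <- v[(pos + 1L):(pos + n)]
    pos <<- pos + n
    if (is.matrix(a)) out <- matrix(out, nrow(a), ncol(a))
    out
  }
  out <- rec(template)
  stop_if_not(pos == length(v), "parameter vector length mismatch")
  out
}

# ---- Adam optimizer on nested parameter lists -----------------------------

adam_init <- function(params) {
  list(m = par_map(params, function(x) x * 0),
       v = par_map(params, function(x) x * 0),
       t = 0L)
}

adam_step <- function(state, params, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- par_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- par_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- par_map2(state$m, state$v, function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps))
  params <- par_map2(params, upd, function(p, u) p - u)
  list(state = state, params = params)
}
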