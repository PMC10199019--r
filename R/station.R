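# Station operator: the differentiable physics pipeline evaluated on the
# structured medial-surface grid. Given modal coefficients b it produces the
# modal fluid+contact force f(b), the flow state (areas, flow rate,
# pressures), and the projected 2D profile, together with cached
# intermediates for analytic reverse-mode (vector-Jacobian) products.
#
# Sections and stations are fixed at reference (material) positions of the
# medial surface, so the interpolation/quadrature operators are constant
# matrices and only the pointwise nonlinearities (rectified gap, minimum
# area, Bernoulli pressure, penalty contact, Boltzmann projection) carry
# state dependence. Surface loads use reference areas and act along -x,
# consistent with the small-displacement linear elastic structure model.

#' Build the station operator for a mesh/basis pair
#'
#' Precomputes the constant matrices of the differentiable physics: mode
#' x-displacements on the medial-surface grid, section/station interpolation
#' operators, quadrature weights, and tributary surface areas.
#'
#' @param mesh a `vf_mesh`.
#' @param basis a `vf_modal_basis` computed on the same mesh.
#' @param flow a [flow_params()] object.
#' @param contact a [contact_params()] object.
#' @param n_stations number of spanwise observation stations.
#' @param tau_proj Boltzmann projection width (m) used in training mode.
#' @param tau_contact contact rectifier width (m) used in training mode.
#' @return object of class `vf_station_operator`.
#' @export
station_operator <- function(mesh, basis, flow = flow_params(),
                             contact = contact_params(), n_stations = 64,
                             tau_proj = 1e-6, tau_contact = 1e-6) {
  ids <- mesh$medial_grid
  ny1 <- nrow(ids); nz1 <- ncol(ids)
  x0 <- mesh$nodes[as.integer(ids), 1]              # column-major flatten
  Ux <- basis$modes[3 * as.integer(ids) - 2, , drop = FALSE]
  y_rows <- mesh$grid_y
  z_cols <- mesh$grid_z
  y_sec <- seq(min(y_rows), max(y_rows), length.out = flow$n_sections)
  S_y <- interp_matrix(y_rows, y_sec)               # rows -> sections
  S_back <- interp_matrix(y_sec, y_rows)            # sections -> rows
  stations <- seq(min(z_cols), max(z_cols), length.out = n_stations)
  S_z <- interp_matrix(z_cols, stations)
  w_z <- trapz_weights(z_cols)
  w_y <- trapz_weights(y_rows)
  a_med <- as.numeric(outer(w_y, w_z))              # tributary areas, column-major
  structure(list(ny1 = ny1, nz1 = nz1, x0 = x0, Ux = Ux,
                 y_sec = y_sec, S_y = S_y, S_back = S_back,
                 stations = stations, S_z = S_z, w_z = w_z, a_med = a_med,
                 flow = flow, contact = contact,
                 tau_proj = tau_proj, tau_contact = tau_contact,
                 n_modes = ncol(Ux)),
            class = "vf_station_operator")
}

#' Evaluate the station physics at one set of modal coefficients
#'
#' Computes section areas, flow rate, intraglottal pressure, contact
#' pressure, the modal force `f_j = U_j' F`, and the top-view profile for
#' the shape `x = x0 + Ux b`. In `"train"` mode all non-smooth primitives
#' (rectified gap, area floor, minimum area, contact rectifier, projection
#' maximum) use their smooth relaxations so the result is differentiable;
#' `"eval"` mode uses the exact operations.
#'
#' @param so a [station_operator()].
#' @param b modal coefficients (length `n_modes`).
#' @param mode `"eval"` (exact) or `"train"` (smooth).
#' @return list with `f` (modal force), `Q`, `A`, `A_min`, `i_sep`,
#'   `P_sec`, `profile`, and a `cache` for [station_vjp()].
#' @export
station_forward <- function(so, b, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  fl <- so$flow; ct <- so$contact
  tg <- if (mode == "train") fl$tau_gap else 0
  ta <- if (mode == "train") fl$tau_area else 0
  tc <- if (mode == "train") so$tau_contact else 0
  tp <- if (mode == "train") so$tau_proj else 0

  x <- so$x0 + as.numeric(so$Ux %*% b)
  Xm <- matrix(x, so$ny1, so$nz1)
  Xs <- so$S_y %*% Xm                              # sections x nz1
  g <- 2 * relu_smooth(-Xs, tg)
  A_raw <- as.numeric(g %*% so$w_z)
  # smooth floor: A = floor + relu(A_raw - floor)
  A <- fl$area_floor + relu_smooth(A_raw - fl$area_floor, ta)
  bmin <- boltzmann_min(A, ta)
  A_min <- max(bmin$value, fl$area_floor)
  i_min <- which(A == min(A))
  i_sep <- i_min[length(i_min)]
  cq <- sqrt(2 * fl$P_sub / fl$rho_air)
  Q <- cq * A_min
  P_sec <- fl$P_sub - 0.5 * fl$rho_air * (Q / A)^2
  mask <- rep(1, length(A))
  if (i_sep < length(A)) { P_sec[(i_sep + 1):length(A)] <- 0; mask[(i_sep + 1):length(A)] <- 0 }
  P_rows <- as.numeric(so$S_back %*% P_sec)
  # contact on the medial grid
  dxn <- relu_smooth(x - ct$x_mid, tc)
  pc <- ct$k_c1 * dxn * (1 + ct$k_c2 * dxn^2)
  P_grid <- rep(P_rows, times = so$nz1)            # column-major expansion
  load <- (P_grid + pc) * so$a_med
  f <- -as.numeric(crossprod(so$Ux, load))
  # top-view profile
  Xst <- Xm %*% t(so$S_z)                          # ny1 x K
  bmax <- boltzmann_max_cols(Xst, tp)
  cache <- list(mode = mode, tg = tg, ta = ta, tc = tc, tp = tp,
                x = x, Xm = Xm, Xs = Xs, g = g, A_raw = A_raw, A = A,
                bmin = bmin, A_min = A_min, i_sep = i_sep, mask = mask,
                cq = cq, Q = Q, P_sec = P_sec, dxn = dxn, pc = pc,
                Xst = Xst, bmax = bmax)
  list(f = f, Q = Q, A = A, A_min = A_min, i_sep = i_sep, P_sec = P_sec,
       y_sec = so$y_sec, profile = bmax$value, stations = so$stations,
       cache = cache)
}

#' Batched station physics over a coefficient sequence
#'
#' Equivalent to calling [station_forward()] on every row of `B` but with
#' the large linear-operator products hoisted into single matrix
#' multiplications; used by the training loop where it is the inner kernel.
#' Verified against the per-step path in the test suite.
#'
#' @param so a [station_operator()].
#' @param B T x J matrix of modal coefficients (one row per time).
#' @param mode `"eval"` or `"train"`.
#' @return list with `f` (T x J), `profile` (T x K), `Q`, `A_min` (length
#'   T), `A`, `P_sec` (T x n_sections), `i_sep`, and a batched `cache`.
#' @export
station_forward_batch <- function(so, B, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  fl <- so$flow; ct <- so$contact
  tg <- if (mode == "train") fl$tau_gap else 0
  ta <- if (mode == "train") fl$tau_area else 0
  tc <- if (mode == "train") so$tau_contact else 0
  tp <- if (mode == "train") so$tau_proj else 0
  T_ <- nrow(B); J <- ncol(B)
  ny1 <- so$ny1; nz1 <- so$nz1
  nsec <- fl$n_sections; K <- length(so$stations)

  Xall <- so$x0 + so$Ux %*% t(B)                   # n_med x T
  # sections: apply S_y on the y-index for every (z, t) column
  Xarr <- array(Xall, c(ny1, nz1 * T_))
  Xs <- so$S_y %*% Xarr                            # nsec x (nz1 T)
  g <- 2 * relu_smooth(-Xs, tg)
  # areas: contract the z-index with the trapezoid weights
  Garr <- array(g, c(nsec, nz1, T_))
  A_raw <- apply(Garr, 3, function(gm) as.numeric(gm %*% so$w_z))
  A_raw <- matrix(A_raw, nsec, T_)
  A <- fl$area_floor + relu_smooth(A_raw - fl$area_floor, ta)
  if (ta <= 0) {
    i_sep <- apply(A, 2, function(a) { i <- which(a == min(a)); i[length(i)] })
    A_min <- A[cbind(i_sep, seq_len(T_))]
    Wmin <- matrix(0, nsec, T_); Wmin[cbind(i_sep, seq_len(T_))] <- 1
  } else {
    S <- -A / ta
    S <- sweep(S, 2, apply(S, 2, max), "-")
    Wmin <- exp(S); Wmin <- sweep(Wmin, 2, colSums(Wmin), "/")
    A_min <- colSums(Wmin * A)
    i_sep <- apply(A, 2, function(a) { i <- which(a == min(a)); i[length(i)] })
  }
  cq <- sqrt(2 * fl$P_sub / fl$rho_air)
  Q <- cq * A_min
  P_sec <- fl$P_sub - 0.5 * fl$rho_air * sweep(1 / A^2, 2, Q^2, "*")
  mask <- matrix(1, nsec, T_)
  for (t in seq_len(T_)) if (i_sep[t] < nsec) {
    P_sec[(i_sep[t] + 1):nsec, t] <- 0
    mask[(i_sep[t] + 1):nsec, t] <- 0
  }
  P_rows <- so$S_back %*% P_sec                    # ny1 x T
  dxn <- relu_smooth(Xall - ct$x_mid, tc)
  pc <- ct$k_c1 * dxn * (1 + ct$k_c2 * dxn^2)
  P_grid <- P_rows[rep(seq_len(ny1), nz1), , drop = FALSE]
  load <- (P_grid + pc) * so$a_med
  f <- -crossprod(so$Ux, load)                     # J x T
  # projection: apply S_z on the z-index for every (y, t)
  Xp <- array(aperm(array(Xall, c(ny1, nz1, T_)), c(2, 1, 3)), c(nz1, ny1 * T_))
  Xst <- so$S_z %*% Xp                             # K x (ny1 T)
  Xst <- array(Xst, c(K, ny1, T_))
  Xst <- aperm(Xst, c(2, 1, 3))                    # ny1 x K x T
  Xst_mat <- array(Xst, c(ny1, K * T_))
  if (tp <= 0) {
    idx <- max.col(t(Xst_mat), ties.method = "last")
    Wmax <- matrix(0, ny1, K * T_)
    Wmax[cbind(idx, seq_len(K * T_))] <- 1
    prof <- Xst_mat[cbind(idx, seq_len(K * T_))]
  } else {
    Sm <- Xst_mat / tp
    Sm <- sweep(Sm, 2, apply(Sm, 2, max), "-")
    Wmax <- exp(Sm); Wmax <- sweep(Wmax, 2, colSums(Wmax), "/")
    prof <- colSums(Wmax * Xst_mat)
  }
  profile <- t(matrix(prof, K, T_))                # T x K
  cache <- list(mode = mode, tg = tg, ta = ta, tc = tc, tp = tp, T_ = T_,
                Xall = Xall, Xs = Xs, A_raw = A_raw, A = A, Wmin = Wmin,
                A_min = A_min, i_sep = i_sep, mask = mask, cq = cq, Q = Q,
                dxn = dxn, Xst_mat = Xst_mat, Wmax = Wmax, prof = prof)
  list(f = t(f), profile = profile, Q = Q, A_min = A_min, A = A,
       P_sec = t(P_sec), i_sep = i_sep, cache = cache)
}

#' Batched reverse-mode product of the station physics
#'
#' @param so the [station_operator()] of the forward pass.
#' @param cache batched cache from [station_forward_batch()].
#' @param f_bar T x J adjoint of the modal forces, or `NULL`.
#' @param prof_bar T x K adjoint of the profiles, or `NULL`.
#' @return T x J gradient with respect to the coefficient rows.
#' @export
station_vjp_batch <- function(so, cache, f_bar = NULL, prof_bar = NULL) {
  fl <- so$flow; ct <- so$contact
  ny1 <- so$ny1; nz1 <- so$nz1
  nsec <- fl$n_sections; K <- length(so$stations); T_ <- cache$T_
  Xall_bar <- matrix(0, ny1 * nz1, T_)
  if (!is.null(f_bar)) {
    load_bar <- -so$Ux %*% t(f_bar)                # n_med x T
    u_bar <- load_bar * so$a_med
    dpc <- ct$k_c1 * (1 + 3 * ct$k_c2 * cache$dxn^2)
    Xall_bar <- Xall_bar + u_bar * dpc * relu_smooth_grad(cache$Xall - ct$x_mid, cache$tc)
    # sum the pressure adjoint over the span (P constant across z)
    Ub <- array(u_bar, c(ny1, nz1, T_))
    P_rows_bar <- apply(Ub, 3, rowSums)
    P_rows_bar <- matrix(P_rows_bar, ny1, T_)
    P_sec_bar <- crossprod(so$S_back, P_rows_bar)  # nsec x T
    rhoQ2A3 <- fl$rho_air * sweep(1 / cache$A^3, 2, cache$Q^2, "*")
    A_bar <- cache$mask * P_sec_bar * rhoQ2A3
    Q_bar <- -colSums(cache$mask * P_sec_bar * fl$rho_air *
                        sweep(1 / cache$A^2, 2, cache$Q, "*"))
    A_min_bar <- cache$cq * Q_bar
    if (cache$ta <= 0) {
      dmin <- cache$Wmin
    } else {
      dmin <- cache$Wmin * (1 + sweep(-cache$A, 2, -cache$A_min, "-") / cache$ta)
    }
    A_bar <- A_bar + sweep(dmin, 2, A_min_bar, "*")
    A_raw_bar <- A_bar * relu_smooth_grad(cache$A_raw - fl$area_floor, cache$ta)
    # scatter the area adjoint back over the span and the y-interpolation
    g_bar <- array(0, c(nsec, nz1, T_))
    for (t in seq_len(T_)) g_bar[, , t] <- outer(A_raw_bar[, t], so$w_z)
    g_bar <- array(g_bar, c(nsec, nz1 * T_))
    Xs_bar <- g_bar * (-2 * relu_smooth_grad(-cache$Xs, cache$tg))
    Xall_bar <- Xall_bar + array(crossprod(so$S_y, Xs_bar), c(ny1 * nz1, T_))
  }
  if (!is.null(prof_bar)) {
    if (cache$tp <= 0) {
      dmax <- cache$Wmax
    } else {
      dmax <- cache$Wmax * (1 + sweep(cache$Xst_mat, 2, cache$prof, "-") / cache$tp)
    }
    pb <- as.numeric(t(prof_bar))                  # K*T, station-major per time
    Xst_bar <- sweep(dmax, 2, pb, "*")             # ny1 x (K T)
    Xst_bar <- aperm(array(Xst_bar, c(ny1, K, T_)), c(2, 1, 3))
    Xz_bar <- crossprod(so$S_z, array(Xst_bar, c(K, ny1 * T_)))  # nz1 x (ny1 T)
    Xz_bar <- aperm(array(Xz_bar, c(nz1, ny1, T_)), c(2, 1, 3))
    Xall_bar <- Xall_bar + array(Xz_bar, c(ny1 * nz1, T_))
  }
  crossprod(Xall_bar, so$Ux)                       # T x J
}

#' Reverse-mode (vector-Jacobian) product of the station physics
#'
#' Given adjoints of the modal force (`f_bar`) and/or of the projected
#' profile (`prof_bar`), returns the corresponding gradient contribution
#' with respect to the modal coefficients `b`. Exact for the smooth
#' (`"train"`) forward pass; verified against finite differences in the
#' test suite.
#'
#' @param so the [station_operator()] used in the forward pass.
#' @param cache the `cache` element returned by [station_forward()].
#' @param f_bar adjoint of the modal force (length `n_modes`) or `NULL`.
#' @param prof_bar adjoint of the profile (length `n_stations`) or `NULL`.
#' @return gradient vector of length `n_modes`.
#' @export
station_vjp <- function(so, cache, f_bar = NULL, prof_bar = NULL) {
  fl <- so$flow; ct <- so$contact
  Xm_bar <- matrix(0, so$ny1, so$nz1)
  x_bar <- numeric(length(cache$x))

  if (!is.null(f_bar)) {
    load_bar <- -as.numeric(so$Ux %*% f_bar)       # d f / d load = -Ux'
    u_bar <- load_bar * so$a_med                   # u = P_grid + pc
    # contact branch
    dpc <- ct$k_c1 * (1 + 3 * ct$k_c2 * cache$dxn^2)
    x_bar <- x_bar + u_bar * dpc * relu_smooth_grad(cache$x - ct$x_mid, cache$tc)
    # pressure branch (P constant across span)
    P_rows_bar <- rowSums(matrix(u_bar, so$ny1, so$nz1))
    P_sec_bar <- as.numeric(crossprod(so$S_back, P_rows_bar))
    # P_i = P_sub - 0.5 rho Q^2 / A_i^2 on unmasked sections
    A_bar <- cache$mask * P_sec_bar * (fl$rho_air * cache$Q^2 / cache$A^3)
    Q_bar <- -sum(cache$mask * P_sec_bar * fl$rho_air * cache$Q / cache$A^2)
    A_min_bar <- cache$cq * Q_bar
    dmin <- boltzmann_min_grad(cache$A, cache$bmin$value, cache$bmin$weights, cache$ta)
    A_bar <- A_bar + A_min_bar * dmin
    A_raw_bar <- A_bar * relu_smooth_grad(cache$A_raw - fl$area_floor, cache$ta)
    g_bar <- outer(A_raw_bar, so$w_z)
    Xs_bar <- g_bar * (-2 * relu_smooth_grad(-cache$Xs, cache$tg))
    Xm_bar <- Xm_bar + crossprod(so$S_y, Xs_bar)
  }
  if (!is.null(prof_bar)) {
    dmax <- boltzmann_max_cols_grad(cache$Xst, cache$bmax$value,
                                    cache$bmax$weights, cache$tp)
    Xst_bar <- sweep(dmax, 2, prof_bar, "*")
    Xm_bar <- Xm_bar + Xst_bar %*% so$S_z
  }
  x_bar <- x_bar + as.numeric(Xm_bar)
  as.numeric(crossprod(so$Ux, x_bar))
}
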