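# PINN losses. The equation loss penalizes the residual of the modal
# dynamics equation
#   r_j(t_i) = b''_j + (alpha + beta w_j^2) b'_j + w_j^2 b_j - U_j' F(b(t_i))
# with time derivatives taken by central finite differences on the (uniform)
# observation grid, wrapping periodically because the observations span one
# vibration cycle. The data loss is the mean squared mismatch between the
# projected and observed 2D profiles, nondimensionalized by a reference
# length. The total loss is the weighted sum L_f = W_e L_e + W_d L_d.

# circular shift of the rows of a matrix by k (positive: towards the start)
row_shift <- function(M, k) {
  n <- nrow(M)
  idx <- ((seq_len(n) - 1 + k) %% n) + 1
  M[idx, , drop = FALSE]
}

# finite-difference time derivatives of a coefficient sequence
fd_derivatives <- function(b, dt, periodic = TRUE) {
  n <- nrow(b)
  stop_if_not(n >= 3, "need at least three time samples for derivatives")
  if (periodic) {
    bdot <- (row_shift(b, 1) - row_shift(b, -1)) / (2 * dt)
    bddot <- (row_shift(b, 1) - 2 * b + row_shift(b, -1)) / dt^2
  } else {
    bdot <- b; bddot <- b
    bdot[2:(n - 1), ] <- (b[3:n, , drop = FALSE] - b[1:(n - 2), , drop = FALSE]) / (2 * dt)
    bdot[1, ] <- (b[2, ] - b[1, ]) / dt
    bdot[n, ] <- (b[n, ] - b[n - 1, ]) / dt
    bddot[2:(n - 1), ] <- (b[3:n, , drop = FALSE] - 2 * b[2:(n - 1), , drop = FALSE] +
                             b[1:(n - 2), , drop = FALSE]) / dt^2
    bddot[1, ] <- bddot[2, ]
    bddot[n, ] <- bddot[n - 1, ]
  }
  list(bdot = bdot, bddot = bddot)
}

#' Equation (physics residual) loss
#'
#' Mean squared residual of the modal dynamics equation over modes and
#' times. Time stamps must be uniform; derivatives are central differences
#' with periodic wrap by default (the observations span one cycle).
#'
#' @param b T x J modal coefficient matrix.
#' @param omega eigenfrequencies (rad/s).
#' @param cdamp per-mode damping coefficients (1/s).
#' @param f T x J matrix of modal forces `U_j' F(t_i)`.
#' @param dt sampling interval (s).
#' @param periodic wrap derivatives periodically.
#' @return list with `L_e` (scalar) and `residual` (T x J).
#' @export
equation_loss <- function(b, omega, cdamp, f, dt, periodic = TRUE) {
  d <- fd_derivatives(b, dt, periodic)
  r <- d$bddot + sweep(d$bdot, 2, cdamp, "*") + sweep(b, 2, omega^2, "*") - f
  list(L_e = mean(r^2), residual = r)
}

# adjoint of the finite-difference residual operator: given r_bar (T x J),
# return the contribution to b_bar from the derivative and stiffness terms
# (the -f term is handled through the physics VJP separately).
equation_loss_badjoint <- function(r_bar, omega, cdamp, dt, periodic = TRUE) {
  if (!periodic) stop("adjoint implemented for the periodic stencil used in training")
  rc <- sweep(r_bar, 2, cdamp, "*")
  (row_shift(r_bar, -1) - 2 * r_bar + row_shift(r_bar, 1)) / dt^2 +
    (row_shift(rc, -1) - row_shift(rc, 1)) / (2 * dt) +
    sweep(r_bar, 2, omega^2, "*")
}

#' Total PINN loss
#'
#' `L_f = W_e * L_e + W_d * L_d`.
#'
#' @param L_e equation loss.
#' @param L_d data loss.
#' @param cfg a [train_config()] (or any list with `W_e`, `W_d`).
#' @return scalar total loss.
#' @export
total_loss <- function(L_e, L_d, cfg) {
  stop_if_not(L_e >= 0 && L_d >= 0, "losses must be non-negative")
  cfg$W_e * L_e + cfg$W_d * L_d
}

#' Full training loss and its gradient w.r.t. the coefficient sequence
#'
#' Runs the differentiable physics (smooth mode) at every observation time:
#' modal forces for the equation loss and projected profiles for the data
#' loss, then assembles `L_f = W_e L_e + W_d L_d` and the analytic gradient
#' `dL_f/db` by reverse mode through the finite-difference stencil and the
#' station-operator vector-Jacobian products.
#'
#' @param so a [station_operator()].
#' @param b T x J coefficient matrix.
#' @param obs_edges T x K observed profile matrix (m).
#' @param dt observation interval (s).
#' @param omega,cdamp modal frequencies and damping coefficients.
#' @param W_e,W_d loss weights.
#' @param L_ref reference length (m) nondimensionalizing the data loss.
#' @param mode physics mode, `"train"` (smooth) or `"eval"`.
#' @return list with `L_f`, `L_e`, `L_d`, `grad_b` (T x J), `f`, `profiles`.
#' @export
pinn_loss <- function(so, b, obs_edges, dt, omega, cdamp,
                      W_e = 1e4, W_d = 1e-5, L_ref = 1, mode = "train") {
  T_ <- nrow(b); J <- ncol(b); K <- ncol(obs_edges)
  bf <- station_forward_batch(so, b, mode = mode)
  f <- bf$f
  prof <- bf$profile
  eq <- equation_loss(b, omega, cdamp, f, dt, periodic = TRUE)
  dprof <- (prof - obs_edges) / L_ref
  L_d <- mean(dprof^2)
  L_f <- W_e * eq$L_e + W_d * L_d

  r_bar <- (2 / (T_ * J)) * eq$residual * W_e
  grad_b <- equation_loss_badjoint(r_bar, omega, cdamp, dt)
  prof_bar_all <- (2 / (T_ * K)) * dprof / L_ref * W_d
  grad_b <- grad_b + station_vjp_batch(so, bf$cache, f_bar = -r_bar,
                                       prof_bar = prof_bar_all)
  list(L_f = L_f, L_e = eq$L_e, L_d = L_d, grad_b = grad_b, f = f,
       profiles = prof)
}
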