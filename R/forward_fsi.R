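# Forward modal FSI simulator: time-integrates the decoupled modal ODEs
#   b''_j + (alpha + beta w_j^2) b'_j + w_j^2 b_j = f_j(b)
# with the fluid + contact loading recomputed each step from the current
# reconstructed shape (explicit force coupling, central-difference scheme).
# Generates the synthetic ground truth: modal trajectories, flow waveforms,
# and time-labeled 2D profiles over one steady vibration cycle.

#' Forward simulation configuration
#'
#' @param dt time step (s). Must resolve the highest retained eigenfrequency
#'   (`dt <= 0.1 * 2 pi / omega_max` is enforced).
#' @param duration total simulated time (s); default 0.2 s spans tens of
#'   vibration cycles at phonation frequencies.
#' @param stride store every `stride`-th step.
#' @param b0_scale amplitude (m-sqrt(kg) scale) of the random initial modal
#'   perturbation that breaks symmetry and triggers oscillation.
#' @param seed RNG seed for the initial condition.
#' @return object of class `vf_sim_config`.
#' @export
sim_config <- function(dt = 1e-5, duration = 0.2, stride = 1L,
                       b0_scale = 1e-8, seed = 1L) {
  stop_if_not(dt > 0, "dt must be positive")
  stop_if_not(duration > 0, "duration must be positive")
  stop_if_not(stride >= 1, "stride must be >= 1")
  structure(list(dt = dt, duration = duration, stride = as.integer(stride),
                 b0_scale = b0_scale, seed = as.integer(seed)),
            class = "vf_sim_config")
}

#' Integrate decoupled modal oscillators
#'
#' Explicit central-difference scheme on
#' `b'' + c b' + omega^2 b = f(b, t)`, with the force lagged one step
#' (evaluated at the current state). Unconditionally second-order; stability
#' requires `omega_max * dt < 2`, which the configured `dt` check enforces
#' with margin.
#'
#' @param omega eigenfrequencies (rad/s).
#' @param cdamp per-mode damping coefficients (1/s).
#' @param force_fn function `(b, t, step) -> modal force vector` (or `NULL`
#'   for free vibration).
#' @param dt time step (s).
#' @param n_steps number of steps.
#' @param b0,bdot0 initial coefficients and velocities.
#' @param stride store every `stride`-th step (step 0 always stored).
#' @return list with `t`, `b` (T x J), `bdot` (T x J), `f` (T x J).
#' @export
modal_integrate <- function(omega, cdamp, force_fn, dt, n_steps,
                            b0 = NULL, bdot0 = NULL, stride = 1L) {
  J <- length(omega)
  if (is.null(b0)) b0 <- numeric(J)
  if (is.null(bdot0)) bdot0 <- numeric(J)
  stop_if_not(max(omega) * dt < 2, "dt too large for the highest mode (omega*dt >= 2)")
  if (is.null(force_fn)) force_fn <- function(b, t, step) numeric(J)
  w2 <- omega^2
  denom <- 1 + dt * cdamp / 2
  keep_steps <- unique(c(seq(0L, n_steps, by = stride), n_steps))
  keep_at <- integer(n_steps + 1L)            # step -> storage row (0 if dropped)
  keep_at[keep_steps + 1L] <- seq_along(keep_steps)
  n_keep <- length(keep_steps)
  bt <- matrix(0, n_keep, J); ff <- matrix(0, n_keep, J)
  f0 <- force_fn(b0, 0, 0L)
  bddot0 <- f0 - cdamp * bdot0 - w2 * b0
  b_prev <- b0 - dt * bdot0 + dt^2 / 2 * bddot0
  b_cur <- b0
  bt[1, ] <- b0; ff[1, ] <- f0
  f_cur <- f0
  for (s in seq_len(n_steps)) {
    b_next <- (dt^2 * f_cur + (2 - dt^2 * w2) * b_cur - (1 - dt * cdamp / 2) * b_prev) / denom
    if (any(!is.finite(b_next)) || max(abs(b_next)) > 1e6) {
      stop("modal integration diverged at step ", s,
           "; reduce dt or check forcing/damping")
    }
    b_prev <- b_cur
    b_cur <- b_next
    f_cur <- force_fn(b_cur, s * dt, s)
    k <- keep_at[s + 1L]
    if (k > 0L) { bt[k, ] <- b_cur; ff[k, ] <- f_cur }
  }
  tk <- keep_steps * dt
  # velocities by central differences on the stored trajectory (exactly the
  # scheme's centered velocity when stride = 1)
  bd <- matrix(0, n_keep, J)
  if (n_keep >= 3) {
    bd[2:(n_keep - 1), ] <- (bt[3:n_keep, , drop = FALSE] -
                               bt[1:(n_keep - 2), , drop = FALSE]) /
      (tk[3:n_keep] - tk[1:(n_keep - 2)])
  }
  if (n_keep >= 2) {
    bd[1, ] <- if (sum(abs(bdot0)) > 0) bdot0 else (bt[2, ] - bt[1, ]) / (tk[2] - tk[1])
    bd[n_keep, ] <- (bt[n_keep, ] - bt[n_keep - 1, ]) / (tk[n_keep] - tk[n_keep - 1])
  }
  list(t = tk, b = bt, bdot = bd, f = ff)
}

#' Assemble nodal forces from intraglottal and contact pressures
#'
#' Mesh-level load assembly: for every medial-surface face, the intraglottal
#' pressure at the face centroid's section plus the face's contact pressure
#' is integrated over the face area (one-point quadrature) along the inward
#' face normal and lumped equally to the three face nodes.
#'
#' @param mesh a `vf_mesh`.
#' @param X current node positions (n x 3).
#' @param P section pressures (Pa) at heights `y_sec`.
#' @param y_sec section heights (m).
#' @param contact a [contact_params()] object (or `NULL` to skip contact).
#' @return nodal force vector of length 3n (node-major DOF ordering).
#' @export
assemble_nodal_forces <- function(mesh, X, P, y_sec, contact = contact_params()) {
  stop_if_not(!is.null(mesh$medial_faces) && nrow(mesh$medial_faces$faces) > 0,
              "mesh has no tagged medial faces")
  faces <- mesh$medial_faces$faces
  fa <- face_areas_normals(X, faces)
  cy <- (X[faces[, 1], 2] + X[faces[, 2], 2] + X[faces[, 3], 2]) / 3
  Sf <- interp_matrix(y_sec, cy)
  p_face <- as.numeric(Sf %*% P)
  if (!is.null(contact)) {
    cx <- (X[faces[, 1], 1] + X[faces[, 2], 1] + X[faces[, 3], 1]) / 3
    p_face <- p_face + contact_pressure(penetration_depth(cx, contact), contact)
  }
  Fv <- numeric(3 * nrow(X))
  load <- -p_face * fa$area / 3                    # pressure along inward normal
  # accumulate with duplicate-safe summation (nodes are shared across faces)
  dof_all <- integer(0); val_all <- numeric(0)
  for (c_ in 1:3) {
    for (v in 1:3) {
      dof_all <- c(dof_all, 3L * (faces[, v] - 1L) + c_)
      val_all <- c(val_all, load * fa$normal[, c_])
    }
  }
  agg <- rowsum(val_all, dof_all)
  Fv[as.integer(rownames(agg))] <- agg[, 1]
  Fv
}

#' Run the coupled forward FSI simulation
#'
#' Couples the modal structure to the Bernoulli flow and penalty contact via
#' the station operator in exact (evaluation) mode. The initial condition is
#' a small seeded random modal perturbation; the flow then drives the fold
#' into flow-induced oscillation.
#'
#' @param mesh a `vf_mesh`.
#' @param basis a `vf_modal_basis`.
#' @param flow a [flow_params()] object.
#' @param contact a [contact_params()] object.
#' @param cfg a [sim_config()] object.
#' @param n_stations observation stations carried by the station operator.
#' @return object of class `vf_fsi_result`: time series `t`, `b`, `bdot`,
#'   `Q`, `A_min`, the station operator, and the configuration.
#' @export
fsi_simulate <- function(mesh, basis, flow = flow_params(),
                         contact = contact_params(), cfg = sim_config(),
                         n_stations = 64) {
  stop_if_not(cfg$dt <= 0.1 * 2 * pi / max(basis$omega),
              "dt does not resolve the highest retained mode (need dt <= 0.1*2*pi/omega_max)")
  so <- station_operator(mesh, basis, flow, contact, n_stations = n_stations)
  n_steps <- as.integer(round(cfg$duration / cfg$dt))
  Qv <- numeric(n_steps + 1L); Av <- numeric(n_steps + 1L)
  step_env <- new.env()
  step_env$Q <- Qv; step_env$A <- Av
  force_fn <- function(b, t, step) {
    st <- station_forward(so, b, mode = "eval")
    step_env$Q[step + 1L] <- st$Q
    step_env$A[step + 1L] <- st$A_min
    st$f
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(cfg$seed)
  b0 <- stats::rnorm(basis$n_modes) * cfg$b0_scale
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  res <- modal_integrate(basis$omega, modal_damping(basis), force_fn,
                         cfg$dt, n_steps, b0 = b0, stride = cfg$stride)
  keep_steps <- as.integer(round(res$t / cfg$dt)) + 1L
  structure(list(t = res$t, b = res$b, bdot = res$bdot,
                 Q = step_env$Q[keep_steps], A_min = step_env$A[keep_steps],
                 so = so, cfg = cfg, mesh = mesh, basis = basis,
                 flow = flow, contact = contact),
            class = "vf_fsi_result")
}

#' Detect a steady vibration cycle
#'
#' Finds peaks of the minimum-area waveform and declares the oscillation
#' steady once the peak-to-peak amplitude of consecutive cycles changes by
#' less than `tol` (relative). Returns the last full cycle.
#'
#' @param t time stamps (s).
#' @param x oscillatory scalar signal (typically `A_min(t)`).
#' @param tol relative amplitude-change tolerance between consecutive
#'   cycles.
#' @return list with `start`, `end` (indices), `period` (s), `steady`
#'   (logical), `amp_change` (relative change of the last two cycles).
#' @export
detect_steady_cycle <- function(t, x, tol = 0.02) {
  n <- length(x)
  stop_if_not(n >= 5, "signal too short for cycle detection")
  mid <- (max(x) + min(x)) / 2
  pk <- which(diff(sign(diff(x))) == -2) + 1L
  pk <- pk[x[pk] > mid]
  if (length(pk) < 3) {
    return(list(start = NA, end = NA, period = NA, steady = FALSE, amp_change = NA))
  }
  cyc_amp <- function(i1, i2) max(x[i1:i2]) - min(x[i1:i2])
  a_last <- cyc_amp(pk[length(pk) - 1], pk[length(pk)])
  a_prev <- cyc_amp(pk[length(pk) - 2], pk[length(pk) - 1])
  change <- abs(a_last - a_prev) / max(a_prev, .Machine$double.eps)
  list(start = pk[length(pk) - 1], end = pk[length(pk)],
       period = t[pk[length(pk)]] - t[pk[length(pk) - 1]],
       steady = change < tol, amp_change = change)
}

#' Extract the training set from a forward simulation
#'
#' Samples `n_profiles` equispaced time points over the last steady cycle,
#' interpolates the modal trajectory to those times, projects the exact 2D
#' top-view profiles (the observable fed to the trainer), and retains the
#' full 3D ground truth for evaluation only.
#'
#' @param sim a `vf_fsi_result`.
#' @param n_profiles profiles per cycle (the sampling rate is
#'   `n_profiles / period`).
#' @param n_stations spanwise stations of the extracted profiles.
#' @param cycle optional cycle description (as returned by
#'   [detect_steady_cycle()]); detected from `A_min` by default.
#' @return list with `profiles` (a `vf_profile_sequence`), `truth` (list:
#'   `b`, `bdot`, `Q`, `A_min`, `P_sec`, `times`, `period`, `f0`), and the
#'   cycle info.
#' @export
extract_training_set <- function(sim, n_profiles = 20, n_stations = 64,
                                 cycle = NULL) {
  if (is.null(cycle)) cycle <- detect_steady_cycle(sim$t, sim$A_min)
  if (!isTRUE(cycle$steady)) {
    stop("no steady vibration cycle detected; simulate for a longer duration")
  }
  t0 <- sim$t[cycle$start]
  times <- t0 + cycle$period * (seq_len(n_profiles) - 1) / n_profiles
  J <- ncol(sim$b)
  b_s <- sapply(seq_len(J), function(j) stats::approx(sim$t, sim$b[, j], xout = times)$y)
  bdot_s <- sapply(seq_len(J), function(j) stats::approx(sim$t, sim$bdot[, j], xout = times)$y)
  b_s <- matrix(b_s, nrow = n_profiles)
  bdot_s <- matrix(bdot_s, nrow = n_profiles)
  so <- station_operator(sim$mesh, sim$basis, sim$flow, sim$contact,
                         n_stations = n_stations)
  edges <- matrix(0, n_profiles, n_stations)
  Qv <- numeric(n_profiles); Am <- numeric(n_profiles)
  Pm <- matrix(0, n_profiles, sim$flow$n_sections)
  for (i in seq_len(n_profiles)) {
    st <- station_forward(so, b_s[i, ], mode = "eval")
    edges[i, ] <- st$profile
    Qv[i] <- st$Q; Am[i] <- st$A_min; Pm[i, ] <- st$P_sec
  }
  profiles <- profile_sequence(times, so$stations, edges, view = "top")
  list(profiles = profiles,
       truth = list(b = b_s, bdot = bdot_s, Q = Qv, A_min = Am, P_sec = Pm,
                    times = times, period = cycle$period, f0 = 1 / cycle$period,
                    y_sec = so$y_sec),
       cycle = cycle)
}

#' Total modal energy of a trajectory
#'
#' `E(t) = sum_j (bdot_j^2 + omega_j^2 b_j^2) / 2`; non-increasing for free
#' damped vibration.
#'
#' @param b,bdot T x J coefficient and velocity matrices.
#' @param omega eigenfrequencies (rad/s).
#' @return numeric vector of energies per stored time.
#' @export
modal_energy <- function(b, bdot, omega) {
  0.5 * rowSums(sweep(b^2, 2, omega^2, "*") + bdot^2)
}
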