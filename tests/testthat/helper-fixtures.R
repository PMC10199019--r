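# Shared fixtures, built in code. Small meshes and modal bases reused across
# test files; memoized in this environment so each is built once per run.

.fixtures <- new.env(parent = emptyenv())

fix_get <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

soft_materials <- function() {
  list(cover = material(E_t = 2e3, E_l = 20e3, G_l = 6e3),
       body = material(E_t = 6e3, E_l = 40e3, G_l = 12e3))
}

# coarse fold mesh + 6-mode basis for physics/gradient tests
tiny_model <- function() {
  fix_get("tiny_model", function() {
    mesh <- build_vocal_fold_mesh(geometry_params(n_cells = c(3, 3, 4)))
    sys <- assemble_mass_stiffness(mesh, soft_materials())
    basis <- solve_eigenmodes(sys, 6)
    list(mesh = mesh, sys = sys, basis = basis)
  })
}

# medium fold mesh + 40-mode basis, used by the forward-simulation tests
small_model <- function() {
  fix_get("small_model", function() {
    mesh <- build_vocal_fold_mesh(geometry_params(n_cells = c(5, 4, 6)))
    sys <- assemble_mass_stiffness(mesh, soft_materials())
    basis <- solve_eigenmodes(sys, 40)
    list(mesh = mesh, sys = sys, basis = basis)
  })
}

# steady self-oscillating forward simulation on the small model
steady_sim <- function() {
  fix_get("steady_sim", function() {
    sm <- small_model()
    fsi_simulate(sm$mesh, sm$basis, flow_params(), contact_params(),
                 sim_config(duration = 0.15, seed = 1), n_stations = 24)
  })
}

# rectangular-channel fold (no bulge): uniform rest gap, handy for analytic
# checks of areas and projections
rect_model <- function(half_gap = 0.2e-3) {
  mesh <- build_vocal_fold_mesh(
    geometry_params(half_gap = half_gap, bulge_y = 0, bulge_z = 0,
                    n_cells = c(3, 3, 4)))
  mesh
}

# full scaled replication (forward simulation + training at 20 and 100
# modes + evaluation); built once and shared by the acceptance blocks
replication_sweep <- function() {
  fix_get("replication_sweep", function() {
    mode_sweep(default_config(), counts = c(20, 100), seed = 1)
  })
}

# two-mode parameter recovery with manufactured analytic forcing; memoized
# so the training and acceptance suites share one run
two_mode_recovery <- function() {
  fix_get("two_mode_recovery", function() {
    toy <- make_toy_problem()
    so <- toy$so
    omega <- toy$basis2$omega; cd <- modal_damping(toy$basis2)
    dt <- toy$profiles$times[2] - toy$profiles$times[1]
    dfd <- vfpinn:::fd_derivatives(toy$b_true, dt, periodic = TRUE)
    f_known <- dfd$bddot + sweep(dfd$bdot, 2, cd, "*") +
      sweep(toy$b_true, 2, omega^2, "*")
    edges <- toy$profiles$edges
    scal <- vfpinn:::make_scaling(toy$tm$mesh, toy$basis2, so)
    b_sc <- scal$b_scale[1]
    X <- vfpinn:::profile_features(edges, scal)
    params <- network_init(network_config(hidden = 32, fc_layers = 2,
                                          fc_width = 32, n_modes = 2),
                           n_features = ncol(X), seed = 4)
    opt <- vfpinn:::adam_init(params)
    W_e <- 1 / mean(f_known^2); W_d <- 1e4
    lr <- 1e-2; best <- Inf; best_params <- params
    for (ep in 1:4000) {
      out <- network_forward(params, X)
      b <- out$Y * b_sc
      eq <- equation_loss(b, omega, cd, f_known, dt)
      bf <- station_forward_batch(so, b, mode = "train")
      dprof <- (bf$profile - edges) / scal$L_ref
      L <- W_e * eq$L_e + W_d * mean(dprof^2)
      gb <- vfpinn:::equation_loss_badjoint(
        (2 / length(eq$residual)) * eq$residual * W_e, omega, cd, dt)
      gb <- gb + station_vjp_batch(so, bf$cache,
                                   prof_bar = (2 / length(dprof)) * dprof /
                                     scal$L_ref * W_d)
      grads <- network_backward(params, out$cache, gb * b_sc)
      gn <- sqrt(vfpinn:::par_sumsq(grads))
      if (gn > 1) grads <- vfpinn:::par_map(grads, function(g) g / gn)
      stp <- vfpinn:::adam_step(opt, params, grads, lr)
      opt <- stp$state; params <- stp$params
      if (L < best) { best <- L; best_params <- params }
      if (ep %% 500 == 0) lr <- max(lr * 0.6, 1e-4)
    }
    b_hat <- network_forward(best_params, X)$Y * b_sc
    list(rel = sqrt(sum((b_hat - toy$b_true)^2)) / sqrt(sum(toy$b_true^2)),
         b_hat = b_hat, toy = toy)
  })
}

# the miniature inverse problem shared by the training tests
make_toy_problem <- function() {
  fix_get("toy_train", function() {
    tm <- tiny_model()
    basis2 <- truncate_basis(tm$basis, 2)
    fl <- flow_params(n_sections = 12)
    ct <- contact_params()
    so <- station_operator(tm$mesh, basis2, fl, ct, n_stations = 10)
    T_ <- 20; f0 <- 150
    tt <- (0:(T_ - 1)) / (T_ * f0)
    b_true <- cbind(3e-6 * sin(2 * pi * f0 * tt),
                    1.5e-6 * cos(2 * pi * f0 * tt))
    edges <- t(sapply(seq_len(T_), function(i)
      station_forward(so, b_true[i, ], mode = "eval")$profile))
    profiles <- profile_sequence(tt, so$stations, edges)
    list(tm = tm, basis2 = basis2, fl = fl, ct = ct, so = so,
         b_true = b_true, profiles = profiles)
  })
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected)) / max(abs(expected), .Machine$double.eps),
            tol)
}
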