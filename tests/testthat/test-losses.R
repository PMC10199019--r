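test_that("equation loss vanishes for trivial and static solutions", {
  omega <- c(10, 20); cdamp <- c(0.5, 1)
  T_ <- 8; dt <- 1e-3
  b0 <- matrix(0, T_, 2)
  f0 <- matrix(0, T_, 2)
  expect_equal(equation_loss(b0, omega, cdamp, f0, dt)$L_e, 0)
  # static equilibrium: b_j = f_j / omega_j^2 under constant force
  f <- matrix(rep(c(3, -2), each = T_), T_)
  b_static <- sweep(f, 2, omega^2, "/")
  expect_lt(equation_loss(b_static, omega, cdamp, f, dt)$L_e, 1e-20)
})

test_that("manufactured solution converges at second order in the sampling", {
  # b(t) = cos(w t) with F from the governing ODE evaluated analytically;
  # the FD residual must shrink ~4x per halving of dt
  omega <- 2 * pi * 7; cdamp <- 3
  w <- 2 * pi                                        # one-cycle periodic signal
  errs <- vapply(c(16, 32, 64), function(T_) {
    tt <- (0:(T_ - 1)) / T_
    b <- matrix(cos(w * tt), ncol = 1)
    f <- matrix(-w^2 * cos(w * tt) + cdamp * (-w * sin(w * tt)) +
                  omega^2 * cos(w * tt), ncol = 1)
    equation_loss(b, omega, cdamp, f, 1 / T_)$L_e
  }, 0)
  expect_gt(errs[1] / errs[2], 3.4 * 3.4)            # L_e is squared residual
  expect_gt(errs[2] / errs[3], 3.4 * 3.4)
})

test_that("total loss is the exact weighted sum with the configured weights", {
  cfg <- train_config(W_e = 1e4, W_d = 1e-5)
  expect_equal(total_loss(0, 0, cfg), 0)
  expect_equal(total_loss(2, 3, cfg), 20000.00003)
  expect_equal(total_loss(2, 3, list(W_e = 2e4, W_d = 2e-5)),
               2 * total_loss(2, 3, cfg))
  expect_error(total_loss(-1, 0, cfg), "non-negative")
})

test_that("pinn_loss gradient matches finite differences end to end", {
  tm <- tiny_model()
  fl <- flow_params(n_sections = 10)
  so <- station_operator(tm$mesh, tm$basis, fl, contact_params(), n_stations = 6)
  set.seed(13)
  T_ <- 5
  b <- matrix(rnorm(T_ * 6) * 2e-6, T_, 6)
  obs <- matrix(-2e-4 + rnorm(T_ * 6) * 1e-5, T_, 6)
  dt <- 3e-4
  cd <- modal_damping(tm$basis)
  args <- list(so = so, obs_edges = obs, dt = dt, omega = tm$basis$omega,
               cdamp = cd, W_e = 1e-9, W_d = 1, L_ref = 2e-4)
  pl <- do.call(pinn_loss, c(list(b = b), args))
  expect_equal(pl$L_f, 1e-9 * pl$L_e + 1 * pl$L_d, tolerance = 1e-12)
  lfun <- function(bm) do.call(pinn_loss, c(list(b = bm), args))$L_f
  h <- 1e-9
  for (probe in list(c(1, 1), c(3, 4), c(5, 6))) {
    bp <- b; bm <- b
    bp[probe[1], probe[2]] <- bp[probe[1], probe[2]] + h
    bm[probe[1], probe[2]] <- bm[probe[1], probe[2]] - h
    gfd <- (lfun(bp) - lfun(bm)) / (2 * h)
    expect_lt(abs(pl$grad_b[probe[1], probe[2]] - gfd) / max(abs(gfd), 1e-8),
              1e-3)
  }
})

test_that("end-to-end network gradient matches finite differences", {
  tm <- tiny_model()
  fl <- flow_params(n_sections = 10)
  so <- station_operator(tm$mesh, tm$basis, fl, contact_params(), n_stations = 6)
  cfgn <- network_config(hidden = 6, fc_layers = 2, fc_width = 6, n_modes = 6)
  params <- network_init(cfgn, n_features = 6, seed = 3)
  set.seed(14)
  T_ <- 5
  X <- matrix(rnorm(T_ * 6), T_, 6)
  obs <- matrix(-2e-4 + rnorm(T_ * 6) * 1e-5, T_, 6)
  b_scale <- 4e-6
  cd <- modal_damping(tm$basis)
  loss_of <- function(p) {
    b <- network_forward(p, X)$Y * b_scale
    pinn_loss(so, b, obs, 3e-4, tm$basis$omega, cd,
              W_e = 1e-9, W_d = 1, L_ref = 2e-4)$L_f
  }
  out <- network_forward(params, X)
  pl <- pinn_loss(so, out$Y * b_scale, obs, 3e-4, tm$basis$omega, cd,
                  W_e = 1e-9, W_d = 1, L_ref = 2e-4)
  grads <- network_backward(params, out$cache, pl$grad_b * b_scale)
  th <- vfpinn:::par_flatten(params)
  gv <- vfpinn:::par_flatten(grads)
  set.seed(15)
  idx <- sample(length(th), 20)
  gfd <- vapply(idx, function(k) {
    h <- 1e-6 * max(1, abs(th[k]))
    tp <- th; tm2 <- th
    tp[k] <- tp[k] + h; tm2[k] <- tm2[k] - h
    (loss_of(vfpinn:::par_unflatten(params, tp)) -
       loss_of(vfpinn:::par_unflatten(params, tm2))) / (2 * h)
  }, 0)
  rel <- abs(gv[idx] - gfd) / pmax(abs(gfd), 1e-12)
  expect_lt(max(rel), 1e-3)
})
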