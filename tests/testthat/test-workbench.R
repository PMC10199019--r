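test_that("displacement error matches hand-computable cases and a naive oracle", {
  set.seed(16)
  n <- 12; T_ <- 5
  X0 <- matrix(rnorm(3 * n), n, 3)
  U <- lapply(1:T_, function(i) matrix(rnorm(3 * n), n, 3) * 1e-3)
  X_true <- lapply(U, function(u) X0 + u)
  # identical prediction: zero error
  de0 <- displacement_error(X_true, X_true, X0)
  expect_equal(de0$per_time, rep(0, T_))
  # 1.1x displacement: 10 percent everywhere
  X_scaled <- lapply(U, function(u) X0 + 1.1 * u)
  de1 <- displacement_error(X_scaled, X_true, X0)
  expect_equal(de1$per_time, rep(10, T_), tolerance = 1e-9)
  expect_equal(de1$sd, 0, tolerance = 1e-9)
  # random pair equals the brute-force elementwise computation
  X_pred <- lapply(U, function(u) X0 + u + matrix(rnorm(3 * n), n, 3) * 1e-4)
  de2 <- displacement_error(X_pred, X_true, X0)
  oracle <- vapply(1:T_, function(i) {
    dp <- as.numeric(X_pred[[i]] - X0) - as.numeric(X_true[[i]] - X0)
    100 * sqrt(sum(dp^2)) / sqrt(sum(as.numeric(X_true[[i]] - X0)^2))
  }, 0)
  expect_equal(de2$per_time, oracle, tolerance = 1e-12)
  # scale consistency: converting to millimeters leaves percentages unchanged
  de3 <- displacement_error(lapply(X_pred, function(m) m * 1e3),
                            lapply(X_true, function(m) m * 1e3), X0 * 1e3)
  expect_equal(de3$per_time, de2$per_time, tolerance = 1e-9)
  # zero-displacement times are excluded with a warning
  X_zero <- c(list(X0), X_true[-1])
  expect_warning(displacement_error(X_zero, X_zero, X0), "zero true displacement")
})

test_that("scalar error suite reproduces constant-scaling cases and a naive oracle", {
  set.seed(17)
  T_ <- 16
  Q_true <- abs(rnorm(T_)) * 1e-4 + 1e-4
  P_true <- matrix(abs(rnorm(T_ * 10)) * 100 + 50, T_, 10)
  truth <- list(Q = Q_true, P_sec = P_true)
  same <- scalar_error_suite(truth, truth)
  expect_equal(same$flow_rate_err_mean, 0)
  expect_equal(same$pressure_err_mean, 0)
  expect_equal(same$peak_flow_err, 0)
  # truth scaled by 1.02: constant 2 percent errors
  pred <- list(Q = 1.02 * Q_true, P_sec = 1.02 * P_true)
  sc <- scalar_error_suite(pred, truth)
  expect_equal(sc$flow_rate_err_mean, 2, tolerance = 1e-9)
  expect_equal(sc$flow_rate_err_sd, 0, tolerance = 1e-9)
  expect_equal(sc$peak_flow_err, 2, tolerance = 1e-9)
  # randomized series equal the brute-force per-sample relative-error mean
  Q_pred <- Q_true * (1 + rnorm(T_) * 0.03)
  r <- scalar_error_suite(list(Q = Q_pred, P_sec = P_true), truth)
  expect_equal(r$flow_rate_err_mean,
               mean(100 * abs(Q_pred - Q_true) / Q_true), tolerance = 1e-12)
  expect_error(scalar_error_suite(list(Q = Q_true[-1]), truth), "misaligned")
})

test_that("configuration round-trips through YAML with defaults filled in", {
  cfg <- default_config()
  path <- tempfile(fileext = ".yaml")
  write_config(cfg, path)
  back <- read_config(path)
  expect_equal(back$geometry$span, cfg$geometry$span)
  expect_equal(back$material$cover$E_t, cfg$material$cover$E_t)
  # partial configs inherit defaults
  writeLines("flow:\n  P_sub: 800.0\n", path)
  part <- read_config(path)
  expect_equal(part$flow$P_sub, 800)
  expect_equal(part$flow$rho_air, 1.1)
  unlink(path)
})

test_that("system matrices export to MatrixMarket and read back", {
  tm <- tiny_model()
  dir <- tempfile()
  export_system_matrices(tm$sys, dir)
  M2 <- Matrix::readMM(file.path(dir, "M.mtx"))
  expect_equal(dim(M2), dim(tm$sys$M))
  expect_lt(max(abs(M2 - tm$sys$M)), 1e-18)
  unlink(dir, recursive = TRUE)
})
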