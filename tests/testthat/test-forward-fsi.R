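test_that("undamped single mode reproduces the closed-form cosine", {
  omega <- 2 * pi * 100
  dt <- 1 / (100 * 400)                              # 400 steps per period
  n <- 5 * 400                                       # five periods
  res <- modal_integrate(omega, 0, NULL, dt, n, b0 = 1, bdot0 = 0)
  expect_lt(max(abs(res$b[, 1] - cos(omega * res$t))), 0.005)
})

test_that("constant modal force relaxes to the static limit f / omega^2", {
  omega <- 2 * pi * 120
  f <- 3.7
  res <- modal_integrate(omega, 2 * 0.3 * omega,     # heavy damping
                         function(b, t, step) f, dt = 1e-5, n_steps = 20000)
  expect_equal(res$b[nrow(res$b), 1], f / omega^2, tolerance = 1e-4)
})

test_that("Rayleigh-damped free vibration matches the log-decrement closed form", {
  omega <- 2 * pi * 150
  alpha <- 60; beta <- 6e-5
  zeta <- (alpha / omega + beta * omega) / 2
  res <- modal_integrate(omega, alpha + beta * omega^2, NULL,
                         dt = 1e-6, n_steps = 60000, b0 = 1)
  pk <- which(diff(sign(diff(res$b[, 1]))) == -2) + 1
  ratios <- res$b[pk[-1], 1] / res$b[pk[-length(pk)], 1]
  delta <- -mean(log(ratios))
  zeta_measured <- delta / sqrt(4 * pi^2 + delta^2)
  expect_lt(abs(zeta_measured - zeta) / zeta, 0.02)
})

test_that("free damped vibration never gains modal energy", {
  tm <- tiny_model()
  fl0 <- flow_params(P_sub = 0, n_sections = 10)
  # contact off: the invariant concerns the elastic/kinetic energy budget,
  # which a penalty spring would transiently store and return
  so <- station_operator(tm$mesh, tm$basis, fl0, contact_params(k_c1 = 0, k_c2 = 0),
                         n_stations = 6)
  set.seed(21)
  b0 <- rnorm(6) * 1e-6
  res <- modal_integrate(tm$basis$omega, modal_damping(tm$basis),
                         function(b, t, step) station_forward(so, b, "eval")$f,
                         dt = 5e-6, n_steps = 2000, b0 = b0)
  E <- modal_energy(res$b, res$bdot, tm$basis$omega)
  # the central-difference scheme conserves a slightly modified energy, so
  # the continuous-energy monitor may fluctuate at O((omega dt)^2) while the
  # cycle-averaged trend is strictly dissipative
  expect_true(all(diff(E) <= 1e-3 * E[1]))
  expect_lt(E[length(E)], 0.3 * E[1])
})

test_that("nodal force assembly matches the constant-pressure and face-loop oracles", {
  mesh <- rect_model()
  X <- mesh$nodes
  y_sec <- seq(0, mesh$params$thickness, length.out = 10)
  # uniform pressure on the flat medial patch: total force = -p * A along x
  p0 <- 123.4
  Fv <- assemble_nodal_forces(mesh, X, rep(p0, 10), y_sec, contact = NULL)
  fa <- vfpinn:::face_areas_normals(X, mesh$medial_faces$faces)
  A_patch <- sum(fa$area)
  Fx <- sum(Fv[seq(1, length(Fv), by = 3)])
  expect_equal(Fx, -p0 * A_patch, tolerance = 1e-12 * p0 * A_patch)
  # zero pressure -> zero force
  expect_equal(assemble_nodal_forces(mesh, X, rep(0, 10), y_sec, contact = NULL),
               numeric(3 * nrow(X)))
  # random pressure: matches a brute-force one-point-quadrature face loop
  set.seed(6)
  P <- rnorm(10) * 100
  Fr <- assemble_nodal_forces(mesh, X, P, y_sec, contact = NULL)
  F_oracle <- numeric(3 * nrow(X))
  faces <- mesh$medial_faces$faces
  for (r in seq_len(nrow(faces))) {
    v <- faces[r, ]
    cen <- colMeans(X[v, ])
    pf <- stats::approx(y_sec, P, xout = cen[2], rule = 2)$y
    e1 <- X[v[2], ] - X[v[1], ]; e2 <- X[v[3], ] - X[v[1], ]
    nrm <- c(e1[2] * e2[3] - e1[3] * e2[2], e1[3] * e2[1] - e1[1] * e2[3],
             e1[1] * e2[2] - e1[2] * e2[1])
    area <- sqrt(sum(nrm^2)) / 2
    nhat <- nrm / (2 * area)
    for (a in 1:3) {
      F_oracle[3 * (v[a] - 1) + 1:3] <- F_oracle[3 * (v[a] - 1) + 1:3] -
        pf * area / 3 * nhat
    }
  }
  expect_equal(Fr, F_oracle, tolerance = 1e-12)
})

test_that("default configuration self-oscillates into a steady cycle", {
  sim <- steady_sim()
  cyc <- detect_steady_cycle(sim$t, sim$A_min)
  expect_true(cyc$steady)
  expect_lt(cyc$amp_change, 0.05)
  f0 <- 1 / cyc$period
  expect_gt(f0, 80); expect_lt(f0, 400)              # phonation range
  # flow-tissue consistency: Q = sqrt(2 P/rho) A_min at every stored step
  expect_equal(sim$Q, sqrt(2 * 1000 / 1.1) * sim$A_min, tolerance = 1e-12)
})

test_that("training-set extraction is deterministic with correct time labels", {
  sim <- steady_sim()
  tr <- extract_training_set(sim, n_profiles = 20, n_stations = 24)
  dt_lab <- diff(tr$profiles$times)
  expect_equal(dt_lab, rep(tr$truth$period / 20, 19), tolerance = 1e-9)
  # one profile: single time at cycle start
  tr1 <- extract_training_set(sim, n_profiles = 1, n_stations = 24)
  expect_equal(tr1$profiles$times, sim$t[tr$cycle$start])
  # bit-for-bit reproducibility
  tr2 <- extract_training_set(sim, n_profiles = 20, n_stations = 24)
  expect_identical(tr$profiles$edges, tr2$profiles$edges)
  expect_identical(tr$truth$b, tr2$truth$b)
})

test_that("unsteady signals are refused by the extraction step", {
  t <- seq(0, 0.02, by = 1e-4)
  sim_fake <- structure(list(t = t, A_min = exp(-100 * t) * (1.1 + sin(2 * pi * 200 * t))),
                        class = "vf_fsi_result")
  expect_error(extract_training_set(sim_fake, 5, 8), "steady|longer")
})
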