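test_that("undeformed rectangular fold projects to a flat edge at -g0", {
  g0 <- 0.2e-3
  mesh <- rect_model(half_gap = g0)
  pr <- project_top_view(mesh, n_stations = 9)
  expect_equal(pr$edge, rep(-g0, 9), tolerance = 1e-15)
})

test_that("top view is invariant to pure vertical motion", {
  mesh <- rect_model()
  X <- mesh$nodes
  X[, 2] <- X[, 2] + 0.5e-3                         # shift everything up
  pr0 <- project_top_view(mesh, n_stations = 12)
  pr1 <- project_top_view(mesh, X, n_stations = 12)
  expect_equal(pr1$edge, pr0$edge, tolerance = 1e-15)
})

test_that("exact projection matches a dense-sampling oracle for a smooth deformation", {
  tm <- tiny_model()
  mesh <- tm$mesh
  set.seed(11)
  b <- rnorm(6) * 3e-6
  X <- reconstruct_displacement(tm$basis, b, mesh$nodes)
  n_st <- 15
  pr <- project_top_view(mesh, X, n_stations = n_st)
  # oracle: brute-force max over densely interpolated surface points per station
  ids <- mesh$medial_grid
  Xm <- matrix(X[ids, 1], nrow(ids), ncol(ids))
  stations <- seq(min(mesh$grid_z), max(mesh$grid_z), length.out = n_st)
  edge_oracle <- vapply(stations, function(zk) {
    vals <- apply(Xm, 1, function(row) stats::approx(mesh$grid_z, row, xout = zk)$y)
    max(vals)
  }, 0)
  g0 <- mesh$params$half_gap
  expect_lt(max(abs(pr$edge - edge_oracle)), 0.01 * g0)
})

test_that("smooth projection converges to the exact maximum as tau shrinks", {
  tm <- tiny_model()
  set.seed(2)
  b <- rnorm(6) * 3e-6
  X <- reconstruct_displacement(tm$basis, b, tm$mesh$nodes)
  exact <- project_top_view(tm$mesh, X, n_stations = 10, tau = 0)$edge
  gaps <- vapply(c(1e-5, 1e-6, 1e-7), function(tau) {
    max(abs(project_top_view(tm$mesh, X, n_stations = 10, tau = tau)$edge - exact))
  }, 0)
  expect_true(all(diff(gaps) < 0))                  # monotone in tau
  expect_lt(gaps[3], 1e-8)
})

test_that("projection gradients match finite differences for tau > 0", {
  tm <- tiny_model()
  fl <- flow_params(n_sections = 10)
  so <- station_operator(tm$mesh, tm$basis, fl, contact_params(), n_stations = 7)
  set.seed(8)
  b <- rnorm(6) * 2e-6
  v_p <- rnorm(7)
  st <- station_forward(so, b, mode = "train")
  g <- station_vjp(so, st$cache, prof_bar = v_p)
  phi <- function(b) sum(v_p * station_forward(so, b, mode = "train")$profile)
  h <- 1e-9
  gfd <- vapply(1:6, function(j) {
    e <- numeric(6); e[j] <- h
    (phi(b + e) - phi(b - e)) / (2 * h)
  }, 0)
  expect_lt(max(abs(g - gfd)) / max(abs(gfd)), 1e-4)
})

test_that("profile distance is an exact stationwise MSE", {
  times <- seq(0, 1e-2, length.out = 5)
  stations <- seq(0, 1e-2, length.out = 8)
  set.seed(4)
  A <- matrix(rnorm(40), 5, 8) * 1e-4
  B <- matrix(rnorm(40), 5, 8) * 1e-4
  pa <- profile_sequence(times, stations, A)
  pb <- profile_sequence(times, stations, B)
  expect_equal(profile_distance(pa, pa)$mean, 0)
  # constant offset delta -> MSE = delta^2
  pc <- profile_sequence(times, stations, A + 3e-5)
  expect_equal(profile_distance(pa, pc)$mean, (3e-5)^2, tolerance = 1e-12)
  # random pair: equals the brute-force double loop
  d <- profile_distance(pa, pb)
  acc <- 0
  for (i in 1:5) {
    s <- 0
    for (k in 1:8) s <- s + (A[i, k] - B[i, k])^2
    acc <- acc + s / 8
  }
  expect_equal(d$mean, acc / 5, tolerance = 1e-14)
  expect_equal(profile_distance(pb, pa)$mean, d$mean)   # symmetric
  # misaligned times error out
  pbad <- profile_sequence(times + 1e-3, stations, B)
  expect_error(profile_distance(pa, pbad), "resample")
})

test_that("profile sequences survive CSV and JSON round trips and resampling", {
  times <- seq(0, 4e-3, length.out = 4)
  stations <- seq(0, 1e-2, length.out = 6)
  set.seed(9)
  E <- matrix(rnorm(24) * 1e-4, 4, 6)
  pr <- profile_sequence(times, stations, E)
  fc <- tempfile(fileext = ".csv"); fj <- tempfile(fileext = ".json")
  write_profiles_csv(pr, fc)
  back_c <- read_profiles_csv(fc)
  expect_equal(back_c$edges, pr$edges, tolerance = 1e-12)
  write_profiles_json(pr, fj)
  back_j <- read_profiles_json(fj)
  expect_equal(back_j$edges, pr$edges, tolerance = 1e-12)
  rs <- resample_profiles(pr, seq(0, 1e-2, length.out = 11))
  expect_equal(rs$edges[, 1], pr$edges[, 1])         # endpoints preserved
  expect_equal(rs$edges[, 11], pr$edges[, 6])
  unlink(c(fc, fj))
})
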