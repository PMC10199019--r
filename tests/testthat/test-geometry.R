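test_that("cuboid mesh conserves volume exactly and has the expected tet count", {
  p <- geometry_params(span = 4e-3, depth = 3e-3, thickness = 2e-3,
                       half_gap = 0.5e-3, bulge_y = 0, bulge_z = 0,
                       n_cells = c(2, 2, 2))
  mesh <- build_vocal_fold_mesh(p)
  expect_equal(nrow(mesh$tets), 48)                 # 8 hexes x 6 tets
  vol <- tet_volumes(mesh$nodes, mesh$tets)
  expect_true(all(vol > 0))
  analytic <- (p$depth - p$half_gap) * p$thickness * p$span
  expect_lt(abs(sum(vol) - analytic) / analytic, 1e-12)
})

test_that("refinement preserves box volume exactly and converges for the bulged fold", {
  # box-like fold: volume is exact at any resolution
  pb <- function(n) geometry_params(bulge_y = 0, bulge_z = 0, n_cells = c(n, n, n))
  vol_of <- function(p) {
    m <- build_vocal_fold_mesh(p)
    sum(tet_volumes(m$nodes, m$tets))
  }
  v_box <- (8e-3 - 0.2e-3) * 6e-3 * 10e-3
  expect_lt(abs(vol_of(pb(2)) - v_box) / v_box, 1e-12)
  expect_lt(abs(vol_of(pb(4)) - v_box) / v_box, 1e-12)
  # bulged fold: faceted volume converges to the analytic value (second order)
  p <- geometry_params()
  v_exact <- p$depth * p$thickness * p$span -
    (p$half_gap + p$bulge_y / 3 + p$bulge_z / 3) * p$thickness * p$span
  e2 <- abs(vol_of(geometry_params(n_cells = c(2, 2, 2))) - v_exact)
  e4 <- abs(vol_of(geometry_params(n_cells = c(4, 4, 4))) - v_exact)
  expect_lt(e4, e2 / 3)
  m2 <- build_vocal_fold_mesh(geometry_params(n_cells = c(4, 4, 4)))
  expect_equal(nrow(m2$nodes), 125)                 # node count doubles per axis
})

test_that("cover thickness zero labels every element body", {
  p <- geometry_params(cover_thickness = 0, n_cells = c(2, 2, 2))
  mesh <- build_vocal_fold_mesh(p)
  expect_true(all(mesh$layer == "body"))
  p2 <- geometry_params(cover_thickness = 1.5e-3, n_cells = c(4, 3, 4))
  m2 <- build_vocal_fold_mesh(p2)
  expect_true(any(m2$layer == "cover") && any(m2$layer == "body"))
})

test_that("medial faces exist, face the midline, and boundary sets are disjoint", {
  mesh <- build_vocal_fold_mesh(geometry_params(n_cells = c(3, 3, 4)))
  fa <- vfpinn:::face_areas_normals(mesh$nodes, mesh$medial_faces$faces)
  expect_true(all(fa$normal[, 1] > 0))              # outward normals point +x
  expect_length(mesh$medial_faces$tet, nrow(mesh$medial_faces$faces))
  expect_length(intersect(mesh$fixed_nodes, mesh$medial_nodes), 0)
  # every medial face belongs to exactly one tet
  expect_false(any(duplicated(apply(mesh$medial_faces$faces, 1,
                                    function(v) paste(sort(v), collapse = "-")))))
})

test_that("mesh quality report matches a direct determinant oracle", {
  # regular reference tet: V = |det([v2-v1; v3-v1; v4-v1])| / 6
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  tets <- matrix(1:4, 1)
  rep1 <- mesh_quality_report(list(nodes = nodes, tets = tets))
  expect_equal(rep1$total_volume, abs(det(rbind(nodes[2, ] - nodes[1, ],
                                                nodes[3, ] - nodes[1, ],
                                                nodes[4, ] - nodes[1, ]))) / 6)
  # one inverted tet is flagged
  tets2 <- rbind(tets, c(1, 3, 2, 4))
  rep2 <- mesh_quality_report(list(nodes = nodes, tets = tets2))
  expect_equal(rep2$n_inverted, 1)
  # empty mesh errors
  expect_error(mesh_quality_report(list(nodes = nodes, tets = tets[0, , drop = FALSE])),
               "no elements")
})

test_that("degenerate geometry parameters are rejected", {
  expect_error(geometry_params(span = 0), "positive")
  expect_error(geometry_params(half_gap = -1e-4), "half-gap")
  expect_error(geometry_params(cover_thickness = 9e-3), "cover thickness")
  expect_error(geometry_params(depth = 3e-3, bulge_z = 4e-3,
                               cover_thickness = 1e-3), "invert")
})

test_that("VTK round trip preserves nodes, tets and layers", {
  mesh <- build_vocal_fold_mesh(geometry_params(n_cells = c(2, 2, 3)))
  path <- tempfile(fileext = ".vtk")
  write_vtk(mesh, path)
  back <- read_vtk(path)
  expect_equal(back$nodes, mesh$nodes, tolerance = 1e-14)
  expect_identical(back$tets, mesh$tets)
  expect_identical(back$layer, as.character(mesh$layer))
  unlink(path)
})
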