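# Parameterized two-layer (cover/body) vocal-fold solid: a generic extruded
# cross-section with a convex medial bulge, meshed with 4-node tetrahedra on
# a structured grid (6 tets per hex, Kuhn template, deterministic).
#
# Coordinate convention (shared by every module):
#   x : medial-lateral, midline symmetry plane at x = 0, tissue at x < 0
#   y : inferior -> superior (flow direction)
#   z : anterior -> posterior (longitudinal / fiber direction)
# Only the left fold is modeled; the right fold is its mirror image.

#' Geometry parameters for the synthetic vocal fold
#'
#' All lengths in meters. The medial surface sits at
#' `x = -(half_gap + bulge(y, z))` with a convex parabolic recession
#' `bulge = bulge_y * (2y/thickness - 1)^2 + bulge_z * (2z/span - 1)^2`,
#' so the fold is closest to the midline (gap `half_gap`) at mid-height and
#' mid-span and recedes towards the attachments. Defaults are in the
#' physiological canine/human size range.
#'
#' @param span anterior-posterior length (m).
#' @param depth medial-lateral depth from the medial surface apex to the
#'   fixed lateral boundary (m).
#' @param thickness inferior-superior height (m).
#' @param half_gap rest half-width of the glottal gap at the bulge apex (m).
#' @param bulge_y,bulge_z parabolic recession depths (m) of the medial
#'   surface towards the inferior/superior edges and anterior/posterior ends.
#' @param cover_thickness thickness of the cover layer measured from the
#'   medial surface (m); tets whose centroid is closer than this are labeled
#'   `"cover"`, the rest `"body"`.
#' @param element_size target edge length (m) used to pick grid resolution.
#' @param n_cells optional integer vector `c(nx, ny, nz)` overriding
#'   `element_size`.
#' @return object of class `vf_geometry_params`.
#' @export
geometry_params <- function(span = 10e-3,
                            depth = 8e-3,
                            thickness = 6e-3,
                            half_gap = 0.2e-3,
                            bulge_y = 0.1e-3,
                            bulge_z = 1.0e-3,
                            cover_thickness = 1.5e-3,
                            element_size = 1.0e-3,
                            n_cells = NULL) {
  stop_if_not(span > 0 && depth > 0 && thickness > 0,
              "span, depth and thickness must be positive")
  stop_if_not(half_gap >= 0, "rest half-gap must be non-negative")
  stop_if_not(bulge_y >= 0 && bulge_z >= 0, "bulge coefficients must be non-negative")
  stop_if_not(cover_thickness >= 0 && cover_thickness < depth,
              "cover thickness must be in [0, depth)")
  stop_if_not(element_size > 0, "element size must be positive")
  stop_if_not(depth > half_gap + bulge_y + bulge_z,
              "depth too small for the requested bulge: elements would invert")
  if (!is.null(n_cells)) {
    stop_if_not(length(n_cells) == 3 && all(n_cells >= 1),
                "n_cells must be three positive integers")
  }
  structure(list(span = span, depth = depth, thickness = thickness,
                 half_gap = half_gap, bulge_y = bulge_y, bulge_z = bulge_z,
                 cover_thickness = cover_thickness,
                 element_size = element_size, n_cells = n_cells),
            class = "vf_geometry_params")
}

# medial-surface x-coordinate at material point (y, z)
medial_surface_x <- function(params, y, z) {
  eta <- 2 * y / params$thickness - 1
  zeta <- 2 * z / params$span - 1
  -(params$half_gap + params$bulge_y * eta^2 + params$bulge_z * zeta^2)
}

#' Build the two-layer vocal-fold tetrahedral mesh
#'
#' Generates a structured hexahedral grid over the fold cross-section, warps
#' the medial face onto the bulged medial surface, and splits every hex into
#' six tetrahedra with the Kuhn (permutation) template, which is conforming
#' across neighboring cells and fully deterministic. Boundary sets:
#' `fixed_nodes` (lateral plane plus anterior/posterior planes),
#' `medial_faces` (boundary triangles on the medial surface, outward normals
#' facing the midline), `inferior_nodes`, `superior_nodes`.
#'
#' @param params a [geometry_params()] object.
#' @return object of class `vf_mesh` with fields `nodes` (n x 3 matrix),
#'   `tets` (m x 4 integer matrix, positive signed volume), `layer`
#'   (factor `"cover"`/`"body"` per tet), boundary sets, and the structured
#'   medial-surface node grid used by the flow/observation operators.
#' @export
build_vocal_fold_mesh <- function(params) {
  stop_if_not(inherits(params, "vf_geometry_params"), "params must come from geometry_params()")
  p <- params
  if (is.null(p$n_cells)) {
    nx <- max(2L, as.integer(round(p$depth / p$element_size)))
    ny <- max(2L, as.integer(round(p$thickness / p$element_size)))
    nz <- max(2L, as.integer(round(p$span / p$element_size)))
  } else {
    nx <- as.integer(p$n_cells[1]); ny <- as.integer(p$n_cells[2]); nz <- as.integer(p$n_cells[3])
  }
  ys <- seq(0, p$thickness, length.out = ny + 1)
  zs <- seq(0, p$span, length.out = nz + 1)
  ss <- seq(0, 1, length.out = nx + 1)         # 0: lateral, 1: medial

  nid <- function(i, j, k) 1L + i + (nx + 1L) * (j + (ny + 1L) * k)  # i,j,k 0-based
  n_nodes <- (nx + 1L) * (ny + 1L) * (nz + 1L)
  nodes <- matrix(0, n_nodes, 3)
  for (k in 0:nz) for (j in 0:ny) {
    xm <- medial_surface_x(p, ys[j + 1], zs[k + 1])
    idx <- nid(0:nx, j, k)
    nodes[idx, 1] <- (1 - ss) * (-p$depth) + ss * xm
    nodes[idx, 2] <- ys[j + 1]
    nodes[idx, 3] <- zs[k + 1]
  }

  # Kuhn 6-tet split: paths from corner (0,0,0) to (1,1,1) over axis permutations
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  steps <- diag(3)
  tets <- matrix(0L, 6L * nx * ny * nz, 4)
  row <- 0L
  for (k in 0:(nz - 1)) for (j in 0:(ny - 1)) for (i in 0:(nx - 1)) {
    for (pm in perms) {
      corner <- c(i, j, k)
      v <- integer(4)
      v[1] <- nid(corner[1], corner[2], corner[3])
      for (s in 1:3) {
        corner <- corner + steps[pm[s], ]
        v[s + 1] <- nid(corner[1], corner[2], corner[3])
      }
      row <- row + 1L
      tets[row, ] <- v
    }
  }
  # orient all tets to positive signed volume (deterministic swap of last two)
  vol <- tet_volumes(nodes, tets)
  neg <- vol < 0
  if (any(neg)) tets[neg, c(3, 4)] <- tets[neg, c(4, 3)]
  vol <- abs(vol)
  if (any(vol <= 0)) stop("meshing produced a degenerate (zero-volume) element")
  storage.mode(tets) <- "integer"

  ii <- (seq_len(n_nodes) - 1L) %% (nx + 1L)
  jj <- ((seq_len(n_nodes) - 1L) %/% (nx + 1L)) %% (ny + 1L)
  kk <- (seq_len(n_nodes) - 1L) %/% ((nx + 1L) * (ny + 1L))

  medial_all <- which(ii == nx)
  fixed <- which(ii == 0L | kk == 0L | kk == nz)
  medial_nodes <- setdiff(medial_all, fixed)
  inferior_nodes <- which(jj == 0L)
  superior_nodes <- which(jj == ny)

  # layer label by centroid distance (along x) from the medial surface
  cx <- (nodes[tets[, 1], 1] + nodes[tets[, 2], 1] + nodes[tets[, 3], 1] + nodes[tets[, 4], 1]) / 4
  cy <- (nodes[tets[, 1], 2] + nodes[tets[, 2], 2] + nodes[tets[, 3], 2] + nodes[tets[, 4], 2]) / 4
  cz <- (nodes[tets[, 1], 3] + nodes[tets[, 2], 3] + nodes[tets[, 3], 3] + nodes[tets[, 4], 3]) / 4
  dist_med <- medial_surface_x(p, cy, cz) - cx
  layer <- ifelse(p$cover_thickness > 0 & dist_med < p$cover_thickness, "cover", "body")

  medial_faces <- extract_surface_faces(nodes, tets, medial_all)

  # structured medial-surface grid (node ids), rows: y (ny+1), cols: z (nz+1)
  med_grid <- matrix(0L, ny + 1L, nz + 1L)
  for (k in 0:nz) med_grid[, k + 1L] <- nid(nx, 0:ny, k)

  structure(list(nodes = nodes, tets = tets, layer = layer,
                 fixed_nodes = fixed, medial_nodes = medial_nodes,
                 medial_faces = medial_faces,
                 inferior_nodes = inferior_nodes, superior_nodes = superior_nodes,
                 medial_grid = med_grid, grid_y = ys, grid_z = zs,
                 dims = c(nx = nx, ny = ny, nz = nz),
                 params = p),
            class = "vf_mesh")
}

#' Signed volumes of tetrahedra
#'
#' @param nodes n x 3 coordinate matrix.
#' @param tets m x 4 index matrix.
#' @return numeric vector of signed volumes (positive for right-handed tets).
#' @export
tet_volumes <- function(nodes, tets) {
  a <- nodes[tets[, 2], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  b <- nodes[tets[, 3], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  c_ <- nodes[tets[, 4], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  (a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
     a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
     a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

# boundary triangles of the tet mesh whose three vertices all lie in
# `node_set`, oriented outward (away from the opposite vertex of the owner
# tet). Returns a list(faces = f x 3 node ids, tet = owner tet index).
extract_surface_faces <- function(nodes, tets, node_set) {
  in_set <- logical(nrow(nodes)); in_set[node_set] <- TRUE
  local_faces <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
  opp <- c(4, 3, 2, 1)
  m <- nrow(tets)
  all_faces <- matrix(0L, 4L * m, 3)
  owner <- integer(4L * m); opposite <- integer(4L * m)
  r <- 0L
  for (f in 1:4) {
    idx <- (r + 1L):(r + m)
    all_faces[idx, ] <- cbind(tets[, local_faces[f, 1]], tets[, local_faces[f, 2]],
                              tets[, local_faces[f, 3]])
    owner[idx] <- seq_len(m)
    opposite[idx] <- tets[, opp[f]]
    r <- r + m
  }
  key <- apply(all_faces, 1, function(v) paste(sort(v), collapse = "-"))
  tab <- table(key)
  on_boundary <- tab[key] == 1
  sel <- which(on_boundary & in_set[all_faces[, 1]] & in_set[all_faces[, 2]] &
                 in_set[all_faces[, 3]])
  faces <- all_faces[sel, , drop = FALSE]
  own <- owner[sel]
  # orient outward: normal . (centroid_face - opposite_vertex) > 0
  for (r in seq_len(nrow(faces))) {
    p1 <- nodes[faces[r, 1], ]; p2 <- nodes[faces[r, 2], ]; p3 <- nodes[faces[r, 3], ]
    nrm <- pracma_cross(p2 - p1, p3 - p1)
    dirv <- (p1 + p2 + p3) / 3 - nodes[opposite[sel[r]], ]
    if (sum(nrm * dirv) < 0) faces[r, c(2, 3)] <- faces[r, c(3, 2)]
  }
  list(faces = faces, tet = own)
}

# plain cross product (avoid pulling in pracma for one-liners)
pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

# areas and outward unit normals of oriented triangles
face_areas_normals <- function(nodes, faces) {
  e1 <- nodes[faces[, 2], , drop = FALSE] - nodes[faces[, 1], , drop = FALSE]
  e2 <- nodes[faces[, 3], , drop = FALSE] - nodes[faces[, 1], , drop = FALSE]
  nx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  ny <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  nz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  nrm <- cbind(nx, ny, nz)
  len <- sqrt(rowSums(nrm^2))
  list(area = len / 2, normal = nrm / len)
}

#' Mesh quality summary
#'
#' Deterministic report: element count per layer, node count, min/max signed
#' volume, total volume, minimum dihedral angle (degrees), and the number of
#' inverted (non-positive volume) elements.
#'
#' @param mesh a `vf_mesh` (or any list with `nodes` and `tets`).
#' @return a list of summary scalars.
#' @export
mesh_quality_report <- function(mesh) {
  stop_if_not(!is.null(mesh$tets) && nrow(mesh$tets) > 0, "mesh has no elements")
  vol <- tet_volumes(mesh$nodes, mesh$tets)
  edges_of <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  min_dihedral <- Inf
  for (t in seq_len(nrow(mesh$tets))) {
    v <- mesh$tets[t, ]
    # dihedral along each edge = angle between the two faces sharing it
    for (e in seq_len(6)) {
      a <- edges_of[e, 1]; b <- edges_of[e, 2]
      others <- setdiff(1:4, c(a, b))
      pa <- mesh$nodes[v[a], ]; pb <- mesh$nodes[v[b], ]
      p1 <- mesh$nodes[v[others[1]], ]; p2 <- mesh$nodes[v[others[2]], ]
      n1 <- pracma_cross(pb - pa, p1 - pa)
      n2 <- pracma_cross(p2 - pa, pb - pa)
      cs <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
      ang <- acos(pmin(pmax(-cs, -1), 1)) * 180 / pi
      if (ang < min_dihedral) min_dihedral <- ang
    }
  }
  list(n_tets = nrow(mesh$tets), n_nodes = nrow(mesh$nodes),
       n_cover = sum(mesh$layer == "cover"), n_body = sum(mesh$layer == "body"),
       min_volume = min(vol), max_volume = max(vol), total_volume = sum(vol),
       min_dihedral_deg = min_dihedral, n_inverted = sum(vol <= 0))
}
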