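# Differentiable observation operator: project the deformed 3D fold onto the
# 2D profile seen by an endoscope. Top view: for each spanwise station z_k,
# the visible edge is the medial-most (maximum-x) point of the medial
# surface over the vertical direction. The frontal (ventral-dorsal) variant
# reports the height of that leading edge instead.

#' Construct a time-labeled 2D profile sequence
#'
#' @param times strictly increasing time stamps (s).
#' @param stations strictly increasing spanwise station coordinates (m).
#' @param edges T x K matrix of edge coordinates (m), one row per time.
#' @param view `"top"` or `"frontal"`.
#' @return object of class `vf_profile_sequence`.
#' @export
profile_sequence <- function(times, stations, edges, view = "top") {
  edges <- as.matrix(edges)
  stop_if_not(all(diff(times) > 0), "time stamps must be strictly increasing")
  stop_if_not(all(diff(stations) > 0), "stations must be strictly increasing")
  stop_if_not(nrow(edges) == length(times) && ncol(edges) == length(stations),
              "edge matrix must be n_times x n_stations")
  stop_if_not(view %in% c("top", "frontal"), "view must be 'top' or 'frontal'")
  structure(list(times = times, stations = stations, edges = edges, view = view),
            class = "vf_profile_sequence")
}

# core reduction: medial-surface sample grid (ny x nz matrix of values,
# z columns) -> per-station smooth/exact max over the vertical direction.
project_grid_top <- function(Xm, z, stations, tau = 0) {
  Sz <- interp_matrix(z, stations)
  Xst <- Xm %*% t(Sz)                      # ny x K
  bm <- boltzmann_max_cols(Xst, tau)
  list(edge = bm$value, Xst = Xst, weights = bm$weights, Sz = Sz)
}

#' Project the deformed fold to its top-view 2D profile
#'
#' For each of `n_stations` spanwise stations (uniform in z over the mesh
#' span), the edge coordinate is the maximum medial-surface x over the
#' vertical direction: the point visible from above. A Boltzmann
#' (softmax-weighted) maximum of width `tau` is used during training; with
#' `tau = 0` the exact maximum is returned.
#'
#' @param mesh a `vf_mesh` (provides the structured medial-surface grid).
#' @param X current node positions (n x 3 matrix); defaults to rest.
#' @param n_stations number of spanwise stations.
#' @param tau smoothing width (m); `0` = exact.
#' @param view `"top"` (edge = x) or `"frontal"` (edge = height y of the
#'   medial-most point, axes permuted).
#' @return list with `stations` (m) and `edge` (m).
#' @export
project_top_view <- function(mesh, X = mesh$nodes, n_stations = 64, tau = 0,
                             view = "top") {
  ids <- mesh$medial_grid
  stations <- seq(min(mesh$grid_z), max(mesh$grid_z), length.out = n_stations)
  Xm <- matrix(X[ids, 1], nrow(ids), ncol(ids))
  pr <- project_grid_top(Xm, mesh$grid_z, stations, tau)
  if (view == "top") {
    return(list(stations = stations, edge = pr$edge))
  }
  # frontal: report the height of the leading (medial-most) edge
  Ym <- matrix(X[ids, 2], nrow(ids), ncol(ids))
  Yst <- Ym %*% t(pr$Sz)
  list(stations = stations, edge = colSums(pr$weights * Yst))
}

#' Mean squared distance between two profile sequences
#'
#' MSE over stations per time and its mean over times; symmetric in the two
#' arguments. Sequences must share stations and (within `tol`) time stamps;
#' use [resample_profiles()] first otherwise.
#'
#' @param pred,obs `vf_profile_sequence` objects.
#' @param tol time alignment tolerance (s).
#' @return list with `per_time` (vector, m^2) and `mean` (scalar, m^2).
#' @export
profile_distance <- function(pred, obs, tol = 1e-9) {
  stop_if_not(length(pred$times) == length(obs$times) &&
                all(abs(pred$times - obs$times) <= tol),
              "time stamps do not match (resample first)")
  stop_if_not(length(pred$stations) == length(obs$stations) &&
                max(abs(pred$stations - obs$stations)) <= 1e-12,
              "stations do not match (resample first)")
  d2 <- (pred$edges - obs$edges)^2
  per_time <- rowMeans(d2)
  list(per_time = per_time, mean = mean(per_time))
}

#' Resample a profile sequence onto new stations
#'
#' Linear interpolation per time step; used to align externally observed
#' profiles with the trainer's station grid.
#'
#' @param profiles a `vf_profile_sequence`.
#' @param stations new strictly increasing station coordinates (m).
#' @return a `vf_profile_sequence` on the new stations.
#' @export
resample_profiles <- function(profiles, stations) {
  S <- interp_matrix(profiles$stations, stations)
  profile_sequence(profiles$times, stations, profiles$edges %*% t(S),
                   view = profiles$view)
}
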