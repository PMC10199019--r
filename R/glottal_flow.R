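# Differentiable 1D Bernoulli glottal-flow solver. The glottal channel is
# discretized into horizontal sections along y (inferior -> superior); each
# section's area follows from the deformed medial surface with symmetry
# doubling (only the left fold is modeled). Flow separates at the
# minimum-area section; pressure is zero gage downstream of separation:
#   P(y) = P_sub - 1/2 rho (Q / A(y))^2,   Q = sqrt(2 P_sub / rho) * A_min.

#' Glottal flow parameters
#'
#' @param P_sub subglottal driving pressure (Pa).
#' @param rho_air air density (kg/m^3).
#' @param n_sections number of horizontal sections along the flow direction.
#' @param area_floor minimum admissible section area (m^2); prevents
#'   division blow-up during glottal closure. Far below physiological open
#'   areas, so it binds only when the glottis is (nearly) closed.
#' @param tau_gap smoothing width (m) of the rectified gap during training;
#'   `0` = exact.
#' @param tau_area smoothing width (m^2) of the minimum-area selection
#'   during training; `0` = exact minimum.
#' @return object of class `vf_flow_params`.
#' @export
flow_params <- function(P_sub = 1000, rho_air = 1.1, n_sections = 100,
                        area_floor = 1e-8, tau_gap = 1e-6, tau_area = 5e-8) {
  stop_if_not(P_sub >= 0, "subglottal pressure must be non-negative")
  stop_if_not(rho_air > 0, "air density must be positive")
  stop_if_not(n_sections >= 2, "need at least two flow sections")
  stop_if_not(area_floor > 0, "area floor must be positive")
  structure(list(P_sub = P_sub, rho_air = rho_air, n_sections = n_sections,
                 area_floor = area_floor, tau_gap = tau_gap, tau_area = tau_area),
            class = "vf_flow_params")
}

#' Cross-sectional areas of the glottal channel
#'
#' The deformed medial surface is supplied as a structured sample grid:
#' `surface$x` is an ny x nz matrix of medial-surface x-coordinates at
#' heights `surface$y` (rows) and spanwise positions `surface$z` (columns).
#' The local half-gap is `max(0, -x)` (tissue at x < 0, midline at x = 0);
#' the full-channel gap doubles it by left-right symmetry. Section areas are
#' the spanwise trapezoid integral of the gap, evaluated at `n_sections`
#' heights equispaced over the sampled extent (linear interpolation in y),
#' clamped to at least `area_floor`.
#'
#' @param surface list with `x` (ny x nz matrix), `y` (ny heights), `z`
#'   (nz spanwise positions), all in meters.
#' @param params a [flow_params()] object.
#' @param tau rectifier smoothing width (m); `0` (default) is exact, a
#'   positive value gives the smooth relaxation used in training.
#' @return list with `y` (section heights) and `A` (section areas, m^2).
#' @export
section_areas <- function(surface, params, tau = 0) {
  stop_if_not(is.matrix(surface$x) && nrow(surface$x) >= 2 && ncol(surface$x) >= 2,
              "surface must carry a matrix of x-samples (>= 2 x 2)")
  stop_if_not(length(surface$y) == nrow(surface$x) && length(surface$z) == ncol(surface$x),
              "surface y/z vectors must match the sample matrix")
  ys <- seq(min(surface$y), max(surface$y), length.out = params$n_sections)
  S <- interp_matrix(surface$y, ys)
  Xs <- S %*% surface$x
  g <- 2 * relu_smooth(-Xs, tau)
  w <- trapz_weights(surface$z)
  A_raw <- as.numeric(g %*% w)
  A <- pmax(A_raw, params$area_floor)
  list(y = ys, A = A)
}

#' Glottal flow rate from the minimum area
#'
#' `Q = sqrt(2 P_sub / rho_air) * A_min` (flow separation at the minimum
#' glottal area).
#'
#' @param A_min minimum glottal area (m^2), at least the area floor.
#' @param params a [flow_params()] object.
#' @return flow rate (m^3/s).
#' @export
flow_rate <- function(A_min, params) {
  stop_if_not(params$P_sub >= 0, "subglottal pressure must be non-negative")
  sqrt(2 * params$P_sub / params$rho_air) * A_min
}

#' Intraglottal pressure profile with flow separation
#'
#' Bernoulli pressure `P_i = P_sub - 1/2 rho (Q / A_i)^2` at and upstream of
#' the separation section; zero gage pressure downstream. Separation is at
#' the minimum-area section (ties resolved to the most downstream section).
#' With `Q` from [flow_rate()], the pressure at the separation section is
#' exactly zero.
#'
#' @param A section areas (m^2), ordered inferior (upstream) to superior.
#' @param Q flow rate (m^3/s).
#' @param params a [flow_params()] object.
#' @return list with `P` (pressures, Pa) and `i_sep` (separation index).
#' @export
pressure_profile <- function(A, Q, params) {
  stop_if_not(all(A > 0), "section areas must be positive")
  i_min <- which(A == min(A))
  i_sep <- i_min[length(i_min)]
  P <- params$P_sub - 0.5 * params$rho_air * (Q / A)^2
  if (i_sep < length(A)) P[(i_sep + 1):length(A)] <- 0
  list(P = P, i_sep = i_sep)
}
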