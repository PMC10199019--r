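# Midline penalty contact. Left-right symmetry turns the opposing fold into
# the rigid plane x = x_mid; a node crossing it by dx feels the restoring
# pressure p_c = k_c1 * dx * (1 + k_c2 * dx^2) along the lateral (-x)
# direction.

#' Contact model parameters
#'
#' @param k_c1 linear penalty coefficient (Pa/m).
#' @param k_c2 cubic hardening coefficient (1/m^2).
#' @param x_mid midline plane location (m); 0 in the package convention.
#' @return object of class `vf_contact_params`.
#' @export
contact_params <- function(k_c1 = 5e5, k_c2 = 1e6, x_mid = 0) {
  stop_if_not(k_c1 >= 0 && k_c2 >= 0, "contact coefficients must be non-negative")
  structure(list(k_c1 = k_c1, k_c2 = k_c2, x_mid = x_mid),
            class = "vf_contact_params")
}

#' Penetration depth past the midline
#'
#' `dx = max(0, x - x_mid)` per node, with an optional smooth rectifier of
#' width `tau` for training (exact at evaluation).
#'
#' @param x node x-coordinates (m), tissue at `x < x_mid`.
#' @param params a [contact_params()] object.
#' @param tau smoothing width (m); `0` = exact.
#' @return penetration depths (m), same shape as `x`.
#' @export
penetration_depth <- function(x, params = contact_params(), tau = 0) {
  relu_smooth(x - params$x_mid, tau)
}

#' Penalty contact pressure
#'
#' `p_c = k_c1 * dx * (1 + k_c2 * dx^2)`; zero iff `dx = 0`, monotonically
#' increasing and C1 for `dx > 0`.
#'
#' @param dx penetration depths (m), non-negative.
#' @param params a [contact_params()] object.
#' @return contact pressures (Pa), acting along -x.
#' @export
contact_pressure <- function(dx, params = contact_params()) {
  stop_if_not(all(dx >= 0), "penetration depths must be non-negative")
  params$k_c1 * dx * (1 + params$k_c2 * dx^2)
}
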