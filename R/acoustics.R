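# Acoustic post-processing of the glottal flow waveform: monopole source
# pressure p' = rho/(4 pi r) dQ/dt, sound pressure level with a
# transmission-loss correction, and radiated acoustic power.

#' Acoustic analysis configuration
#'
#' @param r distance from the monopole source at which `p'` is evaluated (m).
#' @param d reference distance of the transmission-loss correction (m).
#' @param p_ref reference pressure (Pa), 20 micropascal.
#' @param fs processing sample rate (Hz); the flow waveform is resampled to
#'   this rate before filtering/differentiation.
#' @param cutoff low-pass cutoff (Hz), must be below `fs/2`.
#' @param rho_air air density (kg/m^3).
#' @param c_sound speed of sound (m/s), used in the intensity
#'   `I = p_rms^2 / (rho c)`.
#' @return object of class `vf_acoustic_config`.
#' @export
acoustic_config <- function(r = 1, d = 0.12, p_ref = 2.0e-5, fs = 48000,
                            cutoff = 20000, rho_air = 1.1, c_sound = 343) {
  stop_if_not(r > 0 && d > 0, "distances must be positive")
  stop_if_not(cutoff < fs / 2, "low-pass cutoff must be below Nyquist")
  structure(list(r = r, d = d, p_ref = p_ref, fs = fs, cutoff = cutoff,
                 rho_air = rho_air, c_sound = c_sound),
            class = "vf_acoustic_config")
}

#' Tile one cycle of a waveform
#'
#' Repeats a single-cycle sample (no endpoint duplication) `n_cycles` times;
#' used to build an audio-rate record from the reconstructed cycle.
#'
#' @param x one cycle of samples.
#' @param n_cycles repetitions.
#' @return numeric vector of length `length(x) * n_cycles`.
#' @export
tile_cycle <- function(x, n_cycles) rep(x, n_cycles)

#' Acoustic pressure of the monopole source
#'
#' Resamples `Q(t)` to the processing rate (cubic-spline interpolation onto
#' the target grid; glottal flow waveforms are smooth and heavily
#' oversampled relative to the audio band, where spline resampling is
#' accurate to well below the filter ripple), applies a zero-phase 4th-order
#' Butterworth low-pass at the cutoff, differentiates by central
#' differences, and scales by `rho_air / (4 pi r)`.
#'
#' @param Q uniformly sampled flow-rate waveform (m^3/s).
#' @param fs_in input sample rate (Hz).
#' @param cfg an [acoustic_config()].
#' @return list with `p` (acoustic pressure, Pa) and `fs` (its rate, Hz).
#' @export
acoustic_pressure <- function(Q, fs_in, cfg = acoustic_config()) {
  stop_if_not(length(Q) >= 8, "flow waveform too short for filtering")
  if (abs(fs_in - cfg$fs) > 1e-9) {
    t_in <- (seq_along(Q) - 1) / fs_in
    t_out <- seq(0, t_in[length(t_in)], by = 1 / cfg$fs)
    Q <- stats::spline(t_in, Q, xout = t_out, method = "fmm")$y
  }
  # the mean flow carries no sound and only feeds filter edge transients
  Q <- Q - mean(Q)
  if (cfg$cutoff < cfg$fs / 2 * 0.999 && length(Q) > 24) {
    bf <- signal::butter(4, cfg$cutoff / (cfg$fs / 2), type = "low")
    Q <- signal::filtfilt(bf, Q)
  }
  n <- length(Q)
  dQ <- numeric(n)
  dQ[2:(n - 1)] <- (Q[3:n] - Q[1:(n - 2)]) * cfg$fs / 2
  dQ[1] <- (Q[2] - Q[1]) * cfg$fs
  dQ[n] <- (Q[n] - Q[n - 1]) * cfg$fs
  list(p = cfg$rho_air / (4 * pi * cfg$r) * dQ, fs = cfg$fs)
}

#' Sound pressure level
#'
#' `SPL = 20 log10(p_rms / p_ref) + TL` with the transmission loss
#' `TL = 20 log10(d)`.
#'
#' @param p acoustic pressure series (Pa).
#' @param cfg an [acoustic_config()].
#' @return SPL in dB.
#' @export
compute_spl <- function(p, cfg = acoustic_config()) {
  p_rms <- sqrt(mean(p^2))
  stop_if_not(p_rms > 0, "all-zero pressure series has no finite SPL")
  20 * log10(p_rms / cfg$p_ref) + 20 * log10(cfg$d)
}

#' Radiated acoustic power
#'
#' `P_A = A I` with the radiation area `A = 4 pi d^2` and the far-field
#' intensity `I = p_rms^2 / (rho_air c)`.
#'
#' @param p acoustic pressure series (Pa).
#' @param cfg an [acoustic_config()].
#' @return list with `P_A` (W) and `dB` (re 1e-12 W).
#' @export
acoustic_power <- function(p, cfg = acoustic_config()) {
  p_rms2 <- mean(p^2)
  I <- p_rms2 / (cfg$rho_air * cfg$c_sound)
  P_A <- 4 * pi * cfg$d^2 * I
  list(P_A = P_A, dB = 10 * log10(max(P_A, .Machine$double.xmin) / 1e-12))
}
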