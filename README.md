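# vfpinn

Reconstruction of 3D flow-induced vocal-fold dynamics, glottal
aerodynamics, and voice acoustics from sparse, time-labeled 2D edge
profiles — the kind of observation a laryngeal endoscope provides. The
package is aimed at voice scientists and biomechanics researchers who have
projection-only imaging of a vibrating fold (or a syrinx-style analog) and
want the full 3D fields behind it.

## The method

The fold is a linear elastic two-layer (cover/body, transversely isotropic)
continuum with Rayleigh damping. Expanding the displacement in the lowest
mass-orthonormal eigenmodes, `U(t) = Σ_j b_j(t) U_j`, reduces the dynamics
to decoupled modal oscillators

```
b̈_j + (α + β ω_j²) ḃ_j + ω_j² b_j = U_jᵀ F(t),
```

where the load `F` combines the intraglottal pressure of a 1D Bernoulli
glottal-flow model with separation at the minimum area,

```
Q = √(2 P_sub / ρ_air) · A_min,    P(y) = P_sub − ½ ρ_air (Q / A(y))²
```

(zero gage pressure downstream of separation), and a midline penalty
contact pressure `p_c = k_c1 dx (1 + k_c2 dx²)`.

The inverse engine is a hybrid physics-informed neural network: an LSTM
encoder reads the whole observed 2D profile sequence, its final state seeds
an LSTM decoder (teacher-forced with the per-step profiles), and a residual
MLP head maps each decoder state to the modal coefficients `b_j(t_i)`. The
training loss `L_f = W_e L_e + W_d L_d` combines the residual of the modal
equation (with `F` recomputed from the reconstructed shape through a
differentiable flow + contact solver) and the mismatch between the
projected and observed 2D profiles. Every primitive in that chain —
rectified gaps, minimum-area selection, Bernoulli pressures, penalty
contact, the top-view projection, the LSTM/MLP — has a hand-derived,
finite-difference-verified backward pass, so the gradient reaches every
network parameter through the physics.

The package also ships the forward modal FSI simulator used to generate
synthetic ground truth (the packaged two-layer fold self-oscillates at
about 157 Hz under 1 kPa subglottal pressure), monopole-source acoustics
(SPL and acoustic power at 48 kHz with a 20 kHz low-pass), and an
evaluation workbench (normalized L2 displacement error, flow/pressure error
suites, mode-count sweeps).

## Worked example

```r
library(vfpinn)

mesh  <- build_vocal_fold_mesh(geometry_params())
sys   <- assemble_mass_stiffness(mesh, list(
           cover = material(E_t = 2e3, E_l = 20e3, G_l = 6e3),
           body  = material(E_t = 6e3, E_l = 40e3, G_l = 12e3)))
basis <- solve_eigenmodes(sys, n_modes = 100)
round(basis$omega[1:3] / (2 * pi), 1)
#> [1] 115.2 143.6 167.6

sim <- fsi_simulate(mesh, basis, flow_params(), contact_params(),
                    sim_config(duration = 0.2, seed = 1))
tr  <- extract_training_set(sim, n_profiles = 20, n_stations = 64)
round(tr$truth$f0, 1)     # steady-cycle fundamental (Hz)
#> [1] 156.7

ck  <- train_pinn(tr$profiles, mesh, basis,
                  net_cfg = network_config(hidden = 64, fc_width = 64,
                                           n_modes = 100),
                  tr_cfg = train_config(epochs = 20000, auto_balance = TRUE,
                                        patience = 1000, rel_tol = 1e-4,
                                        converge_patience = 20000))
rec <- reconstruct_and_postprocess(ck, mesh, basis)

X_true <- lapply(seq_len(20), function(i)
  reconstruct_displacement(basis, tr$truth$b[i, ], mesh$nodes))
de <- displacement_error(rec$X, X_true, mesh$nodes)
round(c(mean = de$mean, sd = de$sd), 2)
#> mean   sd
#> 1.73 0.68
```

The final numbers say the network reconstructed the full 3D displacement
field over one vibration cycle with a cycle-mean normalized L2 error of
1.73% (SD 0.68%) from 20 top-view profiles alone; the reconstructed flow
rate tracks the ground truth to well under 1%. A run of this size takes
roughly ten minutes on one CPU core.

`run_pipeline()` wraps all of the above (plus acoustics and the error
suite) in one call, and `mode_sweep()` repeats it over mode counts. A thin
command-line wrapper is installed at `inst/cli/vfpinn.R`
(`simulate | train | evaluate | mode-sweep`, YAML-configured).

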