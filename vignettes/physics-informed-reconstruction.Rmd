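---
title: "Reconstructing 3D vocal-fold dynamics from 2D profiles: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing 3D vocal-fold dynamics from 2D profiles: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Endoscopic imaging of the larynx sees the vibrating vocal folds from above:
per video frame it yields a 2D curve (the glottal edge), while the quantity
of clinical and scientific interest is the full 3D flow-induced motion of
the tissue, together with the glottal airflow, intraglottal pressure, and
the radiated sound. `vfpinn` implements a hybrid physics-informed
neural-network (PINN) approach to this inverse problem: a recurrent network
maps the observed 2D profile sequence to the time histories of modal
coefficients of a finite-element model of the fold, and the training loss
penalizes both the mismatch with the observed profiles and the residual of
the structural dynamics equation, with the aerodynamic load supplied by a
differentiable glottal-flow solver. Everything the loss touches is
differentiable, so the gradient reaches every network parameter through the
physics.

The package contains the complete study apparatus: a synthetic two-layer
vocal-fold generator and forward fluid-structure-interaction (FSI)
simulator that produce the ground-truth data, the inverse engine itself,
acoustic post-processing, and an evaluation workbench.

# Structural model

The fold is linear elastic with Rayleigh damping,

$$ M \ddot U + C \dot U + K U = F(t), \qquad C = \alpha M + \beta K. $$

Displacements are expanded in the lowest mass-orthonormal eigenmodes
$U(t) = \sum_j b_j(t)\, U_j$ with $K U_j = \omega_j^2 M U_j$ and
$U_i^\top M U_j = \delta_{ij}$, which decouples the dynamics into scalar
oscillators

$$ \ddot b_j + (\alpha + \beta\omega_j^2)\,\dot b_j + \omega_j^2 b_j
   = U_j^\top F(t). $$

Mass-orthonormality is required for this reduction and is enforced
explicitly (Gram correction after the iterative eigensolve). Dirichlet
constraints are applied by row/column elimination so the eigenproblem stays
clean and symmetric positive definite; the shift-invert Lanczos iteration
(through ARPACK, with a dense reduction for small systems) targets the
lowest modes. Mode signs are fixed deterministically (largest-magnitude
entry positive).

The elasticity is transversely isotropic with the fiber axis along the
anterior-posterior direction, assembled on 4-node tetrahedra (strain is
constant per element, so one-point integration is exact); the consistent
mass matrix is used.

The Rayleigh parameters default to $\alpha = 60\ \mathrm{s^{-1}}$ and
$\beta = 6\times10^{-5}\ \mathrm{s}$, conventional units. Note the two
numbers give a damping-ratio minimum of about 6% near 160 Hz, i.e. the
model is most weakly damped exactly in the phonation range.

# Flow and contact models

The glottal channel is discretized into `n_sections` horizontal sections
(default 100). Per section the gap between the medial surface and the
midline is doubled (left-right symmetry; only the left fold is modeled) and
integrated over the span to give the area $A(y)$. The flow model is the
quasi-steady 1D Bernoulli description with separation at the minimum area:

$$ Q = \sqrt{2 P_\mathrm{sub} / \rho_\mathrm{air}}\; A_\mathrm{min}, \qquad
   P(y) = P_\mathrm{sub} - \tfrac12 \rho_\mathrm{air} (Q/A(y))^2 $$

upstream of the separation section and $P = 0$ (gage) downstream. With this
$Q$, the pressure at the separation section is exactly zero — an algebraic
identity the tests assert. Defaults: $P_\mathrm{sub} = 1.0$ kPa,
$\rho_\mathrm{air} = 1.1\ \mathrm{kg/m^3}$.

Closure is handled by a midline penalty: penetration $dx = \max(0, x)$
produces the contact pressure $p_c = k_{c1} dx (1 + k_{c2} dx^2)$ along the
lateral direction. The coefficients default to $k_{c1} = 5\times10^5$ Pa/m
and $k_{c2} = 10^6\ \mathrm{m^{-2}}$, chosen so that closed-phase
penetration stays at a small fraction of the rest gap.

## Differentiability and the station operator

Both the observation operator (top-view projection) and the load operator
(sections, areas, pressures, contact) are evaluated on the structured
medial-surface grid of the packaged mesh. Sections and spanwise stations
are fixed at *reference* (material) heights, so interpolation and
quadrature are constant linear operators and only pointwise nonlinearities
depend on the state. This is a deliberate design choice: it makes the whole
chain a composition of fixed matrices and smooth scalar maps with
hand-derived vector-Jacobian products, at the price of ignoring the small
vertical excursion of the section planes (consistent with the
small-displacement structural model, which likewise applies loads on the
reference configuration).

During training the non-smooth primitives are relaxed:

* rectified gap and contact penetration: softplus of width `tau_gap`,
  `tau_contact` (default $10^{-6}$ m, 0.5% of the rest gap);
* minimum area: Boltzmann (softmax-weighted) minimum of width `tau_area`
  (default $5\times10^{-8}\ \mathrm{m^2}$, about 1% of a typical open
  area);
* projection maximum: Boltzmann maximum of width `tau_proj`
  ($10^{-6}$ m).

At evaluation the exact operations are used. The Boltzmann forms were
preferred over log-sum-exp because their bias vanishes with the weight
concentration rather than growing as $\tau \log n$. The separation index
and the downstream zero-pressure mask are kept hard (piecewise constant)
even in training; they are locally constant almost everywhere, so the
gradient is exact wherever it exists. All backward passes are verified
against central finite differences in the test suite (relative error
$\le 10^{-3}$ asserted; observed $\sim 10^{-6}$).

# Forward FSI simulator (ground-truth generator)

The forward model integrates the modal oscillators with an explicit
central-difference scheme, the fluid and contact load recomputed from the
current reconstructed shape each step (the modal system is diagonal, so a
step is one station-operator evaluation). The default $dt = 10^{-5}$ s
resolves the highest retained mode with a large margin (the solver refuses
$dt > 0.1 \cdot 2\pi/\omega_{\max}$). The initial condition is a small
seeded random modal perturbation; with the default configuration the flow
then amplifies the perturbation into a self-sustained oscillation that
reaches a steady limit cycle well within the default 200 ms. Steadiness is
declared when the peak-to-peak amplitude of consecutive cycles of
$A_\mathrm{min}(t)$ changes by less than 2%; the last full cycle is the
study cycle, from which 20 equispaced time-labeled profiles are extracted
as the observable.

## Study conditions of the packaged synthetic fold

The generator's defaults are the packaged study conditions, chosen once:

* geometry: span 10 mm, depth 8 mm, thickness 6 mm, rest half-gap 0.2 mm,
  a 0.1 mm vertical and 1.0 mm spanwise parabolic medial bulge, cover layer
  1.5 mm — generic dimensions in the canine/human physiological range;
* materials (transversely isotropic, fiber along the fold axis): cover
  $E_t = 2$ kPa, $E_\ell = 20$ kPa, $G_\ell = 6$ kPa; body $E_t = 6$ kPa,
  $E_\ell = 40$ kPa, $G_\ell = 12$ kPa; $\nu_t = \nu_{\ell t} = 0.3$,
  density 1040 kg/m³. The cover is softer than the body, as in layered
  vocal-fold models; the values put the fundamental eigenfrequency near
  115 Hz and, more importantly, below the phonation-onset threshold at
  $P_\mathrm{sub} = 1$ kPa under the prescribed Rayleigh damping, so the
  fold self-oscillates. A nearly flat vertical channel profile (small
  `bulge_y`) matters for onset: it lets the separation point travel
  between the inferior and superior margins during the cycle
  (convergent-divergent alternation), which is the energy-transfer
  mechanism that sustains the vibration.

With these conditions the packaged fold oscillates at about 157 Hz without
full glottal closure (the minimum area modulates by roughly a factor of
four to five over the cycle).

What the generator deliberately does **not** emulate: subject-specific
anatomy, measurement noise and segmentation error in the 2D profiles,
camera calibration and perspective, vocal-tract acoustic loading, and
viscous or 3D flow features. Passing the packaged replication therefore
demonstrates that the inverse engine recovers fields generated by *its own
physics class* from projection-only data; it does not by itself establish
accuracy on real endoscopic recordings.

# The inverse engine

The observed profile sequence (deviations from the rest profile,
nondimensionalized by the rest half-gap) is consumed by an LSTM encoder;
its final hidden and cell states seed an LSTM decoder that is additionally
teacher-forced with the per-step profile; a four-block residual MLP with
layer normalization maps each decoder state to the modal coefficients of
that time step (the packaged replication uses hidden width 64 and MLP
width 64; ReLU throughout). The network output is scaled per mode by
$b_{\mathrm{ref},j} = g_0 \sqrt{\rho_s V}\,(\omega_1/\omega_j)^2$ — a
characteristic amplitude (one rest gap carried by a mass-orthonormal mode
of the fold's mass) rolled off with the static-response scaling — so every
modal coefficient is an O(1) network output. This is a pure
reparameterization (the losses are unchanged), but it conditions the
optimization dramatically: without it, training plateaus one to two orders
of magnitude above the loss attained at the ground truth; with it the same
budget descends to within a factor of a few of that level.

The loss is $L_f = W_e L_e + W_d L_d$: $L_e$ is the mean squared residual
of the modal dynamics equation over modes and observation times, with
$\dot b, \ddot b$ from central differences wrapped periodically (the
observations span exactly one cycle; one-sided stencils are available for
non-periodic data), and the modal force recomputed from the reconstructed
shape through the differentiable flow and contact operators at every
evaluation; $L_d$ is the mean squared profile mismatch. Because the raw
magnitudes of the two terms depend on the unit system, the default
configuration auto-balances the weights at epoch 0 (each term normalized by
its initial value; the `balance_ratio` knob can additionally emphasize the
data term). The fixed weight pair $(10^4, 10^{-5})$ is retained as the
no-auto-balance default.

Training is full-batch (a single observed cycle) Adam from a $10^{-2}$
initial learning rate with reduce-on-plateau decay to $5\times10^{-5}$,
global gradient-norm clipping at 1.0 (the equation term is stiff and
occasionally produces spikes that would otherwise derail the run), and
best-checkpoint selection on $L_f$. Determinism: parameter initialization
and every stochastic choice derive from the configured seed; repeated runs
reproduce the loss history bit for bit.

Identifiability deserves a note: the top view is a maximum over the
vertical direction, so the data loss alone cannot separate modes that
differ mainly in their vertical structure — the equation residual is what
ties the hidden content to the observed motion. The test suite demonstrates
this on a two-mode problem (data-only training fails; adding the equation
residual recovers the coefficients to well under 5%).

# Acoustics

The radiated sound is modeled as a monopole source,
$p' = \rho_\mathrm{air}/(4\pi r)\; dQ/dt$. The flow waveform is resampled
to 48 kHz (cubic-spline interpolation; the waveforms are smooth and heavily
oversampled relative to the audio band, where spline resampling is accurate
far below the subsequent filter's ripple), low-pass filtered at 20 kHz with
a zero-phase 4th-order Butterworth filter (zero-phase so the derivative is
not lagged), and differentiated by central differences. The mean flow is
removed before filtering: it carries no sound and only feeds filter edge
transients. Then

$$ \mathrm{SPL} = 20\log_{10}(p_\mathrm{rms}/p_\mathrm{ref}) +
   20\log_{10}(d), \qquad
   P_A = 4\pi d^2 \cdot \frac{p_\mathrm{rms}^2}{\rho_\mathrm{air} c}, $$

with $p_\mathrm{ref} = 20\ \mu$Pa, $d = 12$ cm, and the plane-wave
intensity convention $I = p_\mathrm{rms}^2/(\rho c)$, $c = 343$ m/s
(configurable; the intensity convention affects absolute power only, not
relative comparisons between prediction and truth).

# Evaluation

The workbench compares a reconstruction with the forward ground truth at
the observation times: the normalized L2 displacement error
$100\,\lVert U_\mathrm{pred}-U_\mathrm{true}\rVert_2 /
\lVert U_\mathrm{true}\rVert_2$ per time step with mean and SD over 16
evaluation times within the cycle; time-mean relative errors (and SDs) of
the flow rate and of the mean intraglottal pressure; signed relative errors
of the peak and mean flow; SPL and acoustic-power differences. A mode-count
sweep retrains the network for each count on a shared ground truth and
tabulates the error against the number of modes; the error is expected to
be largest at 20 modes and to decrease towards 100.

A property of the packaged fold worth knowing when reading mode-sweep
results: its steady-cycle dynamics carry substantial energy above mode 20,
so the pure truncation floor — projecting the true displacement onto the
first 20 of 100 modes — is already a cycle-mean error of about 14%. A
20-mode reconstruction can therefore never be better than that on this
geometry, however well it trains; subject geometries whose spectra
concentrate lower will show much smaller 20-mode errors. The monotone
decrease of the error with the mode count is the generic behavior; its
absolute level at small counts is geometry-specific.

## Problem sizes of the packaged replication

The packaged end-to-end experiment (also what `scripts/acceptance.R` runs)
uses the default fold meshed at 1 mm (2880 tets, 693 nodes), a 100-mode
basis, a 200 ms forward simulation at $dt = 10^{-5}$ s, 20 profiles at 64
stations over one steady cycle, and a training budget of 20,000 epochs with
auto-balanced weights — sizes chosen so the whole study runs in tens of
minutes on one CPU while reproducing the qualitative and quantitative
behavior of a much larger GPU-scale run of the same architecture.

# Numerical choices and edge cases

* Section areas are clamped to `area_floor` ($10^{-8}\ \mathrm{m^2}$) so a
  fully closed glottis produces zero-ish flow rather than a division
  blow-up; the floor is far below any physiological open area.
* Minimum-area ties resolve to the most downstream section, making the
  separation index deterministic.
* The central-difference integrator stores velocities centered on the
  stored trajectory; the discrete scheme conserves a slightly modified
  energy, so the continuous-energy monitor may fluctuate at
  $O((\omega\,dt)^2)$ around its dissipative trend.
* Degenerate inputs (inverted elements, non-SPD elasticity, empty meshes,
  non-uniform observation times, mismatched station grids) are rejected at
  the module boundary with specific errors.
* The eigensolver refuses to return non-positive Ritz values; the
  mass-orthonormality of the returned basis is enforced to round-off by a
  Cholesky Gram correction, which also refreshes the Rayleigh-quotient
  frequencies.

# Known limitations

* The flow model is quasi-steady 1D Bernoulli with a fixed
  separation-at-minimum rule; no viscous losses, no moving separation
  model, no vocal-tract coupling. The rule is discontinuous when two
  sections compete for the global area minimum: near the maximum-opening
  frame of the packaged fold the two candidate minima differ by under
  0.2%, so a reconstruction whose areas are accurate to a few tenths of a
  percent can still pick the other branch and inherit a large
  mean-intraglottal-pressure discrepancy at that single frame. Flow rate
  and SPL are insensitive to the branch (they depend only on the minimum
  value, not its location).
* Loads (fluid and contact) are applied on the reference configuration,
  consistent with linear elasticity but inaccurate at very large
  amplitudes.
* Material constants must be known a priori; the package does not infer
  them during training.
* Only the generic parameterized geometry is packaged; external meshes can
  be supplied in the legacy VTK format but must carry the structured
  medial-surface grid for the station operator.
* The frontal-view variant reports the height of the medial-most edge per
  spanwise station — a simplified silhouette suitable for the syrinx-style
  ventral-dorsal view, not a full occluding-contour model.
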