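---
title: "Comparing inlet velocity boundary conditions for aortic hemodynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing inlet velocity boundary conditions for aortic hemodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aortaBC)
```

## The problem

Image-based computational studies of thoracic-aorta hemodynamics need a
velocity boundary condition at the ascending-aorta inlet. Phase-contrast MRI
(PC-MRI) can measure all three velocity components on an acquisition plane
above the aortic root, but clinical protocols often record only the
through-plane component, and many modelling studies fall back on an idealized
flat profile scaled to the measured flow waveform. In patients with an
abnormal aortic valve — a stenotic valve or a mechanical prosthesis — the
inflow jet is skewed and carries strong secondary (in-plane) velocities, so
the choice among these three inlet boundary conditions (BCs) can dominate the
computed hemodynamics.

`aortaBC` implements the comparison pipeline for the three standard variants:

* **3D**: all three measured components, mapped onto the inlet patch;
* **TP**: the through-plane component alone (the scalar product of the
  plane normal and the 3D velocity vector), imposed along the patch normal;
* **FLAT**: a spatially uniform normal velocity `Q(t) / A`.

The 3D variant is the benchmark; differences are reported as
`100 (variant − 3D) / 3D`.

Because patient acquisitions and a Navier–Stokes solver are out of scope, the
package ships a synthetic-data module that generates analytic, time-periodic
tube flows with the statistical structure the analysis assumes, and a
kinematic downstream surrogate that stands in for the flow solver. Every
descriptor in the pipeline is thereby exercisable and testable against closed
forms.

## Pipeline components

### Synthetic flow fields and PC-MRI emulation

`make_straight_tube_mesh()` builds a structured polar-hexahedral tube
(default radius 15 mm, length 150 mm for study runs), partitioned by arc
length into `AAo`, `AA` and `DAo` regions (default thirds, configurable) so
regional summaries have the familiar anatomical labels.

Four generators provide velocity fields with attached closed-form
evaluators:

* `poiseuille_field()` — steady parabolic flow; the wall-shear oracle
  (`|tau_w| = 4 mu Q / (pi R^3)`).
* `swirling_poiseuille_field()` — solid-body swirl on a parabolic axial
  profile; for an axially uniform swirl the helicity density is exactly
  `Hk = 2 Omega W0`, the helicity oracle.
* `womersley_field()` — the classical Bessel-function solution for
  sinusoidally pulsatile pipe flow, superposed on steady Poiseuille flow.
  The complex-argument `J0`/`J1` are evaluated by power series (accurate to
  machine precision for the physiological Womersley-number range; the
  series is hand-written because no installed package offers
  complex-argument Bessel functions).
* `valve_jet_field()` — the abnormal-valve scenario: an off-center Gaussian
  axial jet, flux-normalized to the waveform at every cross-section, plus
  in-plane solid-body swirl about the jet center and a uniform cross-flow
  drift. Downstream the jet recenters and widens and the swirl decays with
  prescribed e-folding lengths: a frozen-kinematics surrogate, not a flow
  solve.

`cardiac_waveform()` supplies the flow waveform: a half-sine-squared
systolic pulse (period 1 s, systole 0.35 s, peak 420 ml/s, ~74 ml stroke
volume — normal adult values) over a small diastolic baseline (2% of peak),
with four release markers equally distributed across systole. The baseline
keeps diastolic statistics well defined; the in-plane components are
modulated by `(Q/Q_peak)^0.5` so secondary flow persists into diastole,
where its share of the total velocity peaks, as observed in valve-disease
acquisitions.

The jet's `swirl_strength` is calibrated by `calibrate_swirl_strength()` so
that the cycle-average ratio of in-plane to total velocity magnitude on the
inlet plane hits a target (default 51%, the secondary-flow share typical of
a stenotic-valve jet). The eccentricity (0.35 R) and jet width (sigma =
0.4 R) defaults give peak jet velocities near 2.5 m/s at the default
waveform — the right order for aortic stenosis.

`acquire_plane()` emulates the PC-MRI acquisition: 1.4 mm pixels and a
10 mm slab (typical PC-MRI voxels), velocity re-expressed along the two
in-plane axes and the normal, 100 phases per cycle, per-component VENC set
10% above the noise-free peak, additive Gaussian noise (default sd 5% of
VENC; the noise model is a placeholder — real PC-MRI noise enters through
the phase difference and is velocity-dependent), and aliasing emulated by a
single ±2 VENC fold. Slab averaging uses 5-point Gauss–Legendre quadrature
across the thickness; real thick-slab PC-MRI averages the excited spins in
a scanner-dependent way, so this too is a documented idealization.

### Inlet-profile construction

`fit_plane_to_inlet_transform()` solves the four-reference-point
registration between the imaging plane and the model inlet as a closed-form
least-squares rigid transform (SVD/Kabsch; uniform scale behind a flag for
anisotropic-voxel corrections).

`build_inlet_bc()` samples the map at the projected inlet nodes. Spatial
interpolation is bilinear between pixel centers; before sampling, the
masked values are extended into a 2.5-pixel rim outside the lumen by local
linear least-squares extrapolation (nearest-pixel fallback). The extension
matters: a renormalized bilinear stencil at the mask boundary is biased
toward the lumen interior and leaves ~19% local error at wall-adjacent
nodes (2.4% relative L2 over the inlet), whereas the first-order-accurate
extension brings the noise-free acquisition round trip below 1%. Beyond the
rim, nodes get zero velocity. Temporal interpolation is periodic linear
between phases — cubic schemes overshoot near the systolic jet.

After interpolation, the 3D and TP profiles are rescaled by a single
per-time scalar so that the integrated patch-normal flux equals the
waveform `Q(t)` exactly (to 1e-6 relative). Without this normalization,
inter-variant differences would confound profile shape with flow volume;
with it, all three variants carry identical `Q(t)` and differ only in
shape, which is the controlled-comparison premise. The applied factors are
recorded in the returned object.

`decomposition_stats()` reports, per phase over lumen pixels, the spatial
mean and maximum of the total and normal velocity magnitudes and the
in-plane fraction. The fraction is computed both as the ratio of spatial
mean magnitudes (default, reported) and as the pixelwise-averaged ratio;
the two differ for non-uniform maps and the choice is surfaced rather than
hidden. `underestimation_percent()` turns a normal/total pair into the
percent by which the normal component alone underestimates the statistic,
rounded to integer percent for reporting with the exact value attached.
For printed two-decimal table values of the maximum velocity this rounding
can differ by one percent from a computation on unrounded data
(e.g. 0.66/0.82 gives 19.5%); `table1_analogue()` therefore reports both
the rounded and the exact value.

### Windkessel outlet

`simulate_windkessel()` integrates the three-element (RCR) model
`P + Rd C dP/dt = (Rp + Rd) Q + Rp Rd C dQ/dt` with an implicit trapezoidal
step (A-stable, second order; verified against `deSolve::lsoda` and the
analytic impedance `Z(omega) = Rp + Rd / (1 + i omega Rd C)`), repeating
cycles until consecutive cycles agree within 1 Pa (max-norm), cap 50
cycles. `dQ/dt` comes from periodic central differences of the sampled
waveform. Default parameters (`Rp = 1.4e7`, `C = 1e-8`, `Rd = 1.25e8` in SI
units) give a mean pressure near 80 mmHg at the default waveform;
patient-specific tuning is out of scope, so parameters are user-supplied.

### Wall shear stress

`compute_wss()` evaluates the viscous traction
`tau_w = tangential part of mu (grad v + grad v^T) n` at wall-face
centroids. Velocity gradients are reconstructed by directional finite
differences on the structured grid — central (second-order) along the
circumferential, interior radial and interior axial lines, each equivalent
to a least-squares linear fit along that line; a closed-form least-squares
ring fit at the axis; and a two-point one-sided radial stencil at the wall.
The one-sided wall stencil is deliberately first order, matching the
near-wall linear reconstruction of finite-volume practice: on the
Poiseuille oracle it leaves a measurable `dr/(2R)` relative error (4.6% at
the default 12-ring resolution) that converges at order ~1 under
refinement, so the refinement study verifies a real property instead of
differencing rounding noise.

`compute_indices()` forms TAWSS (periodic-trapezoid time average of
`|tau_w|`), OSI (`0.5 (1 − |∫tau dt| / ∫|tau| dt)`, defined as 0 where the
magnitude integral vanishes), area-weighted surface means (whole and per
region), and an area-weighted interpolated 99th-percentile TAWSS — the
percentile, not the maximum, so isolated spurious faces cannot dominate.
Whether surface summaries should be area-weighted or node-averaged is an
open choice; area weighting is used because the percentile's purpose is
robustness to sharp-corner artefacts, and mesh-independent summaries
require weights. `diff_maps()` produces per-face absolute differences and
signed regional percent differences; `spatiotemporal_map()` unwraps the
wall ring cut by a transverse plane into a normalized-circumference × time
matrix of `|tau_w|`.

### Helicity

`compute_helicity()` computes vorticity with the same gradient
reconstruction, then helicity density `Hk = v · curl v` and local
normalized helicity `LNH = Hk / (|v| |omega|)` with `LNH = 0` at degenerate
points. `threshold_volumes()` quantifies the volume fractions with
`Hk >= theta` and `Hk <= −theta` separately (default threshold 200 m/s²,
the conventional display level for high helicity in the aorta; both signs
are reported because a display convention does not decide whether the
threshold applies to the signed density or its magnitude).

`trace_particles()` advects massless particles with classical RK4 through
the time-periodic field — the closed-form evaluator when the field has
one, otherwise trilinear-in-space, periodic-linear-in-time interpolation —
sampling LNH each accepted step. Particles keep partial traces on domain
exit (minimum 10 accepted samples to count) and are capped at 3 cycles by
default. `compute_hfi()` averages `|LNH|` along each trace, over particles,
then over the four systolic release times with equal weight; the signed
variant is available behind a flag. Equal weighting across release times
and `|LNH|` (rather than signed LNH) follow the descriptor's standard
Lagrangian definition; `Np = 500` seeds on a uniform inlet-disc grid is the
package default where no value is prescribed (study runs use 150 to keep
the default configuration fast; HFI changes by well under 1% between the
two on the jet fixture).

### The study driver

`run_study()` executes the full comparison from a single `study_config()`
and returns a `comparison_report` with a velocity-decomposition table,
in-plane-fraction trace, HFI per variant × release time with percent
differences, TAWSS/OSI summaries and difference maps, helicity threshold
volumes, the Windkessel pressure trace, and provenance (seed, scenario,
package version). All randomness — jet azimuth, cross-flow direction,
acquisition noise — derives from the config seed, and identical configs
reproduce byte-identical reports. `write_report()` serializes the report
as a CSV set plus a JSON summary.

```{r study, eval = FALSE}
cfg <- study_config(scenario = "jet", seed = 1)
report <- run_study(cfg)
print(report)
write_report(report, "study_out")
```

## What the synthetic scenario does and does not show

The generator reproduces the features the comparison is sensitive to: an
eccentric systolic jet with a calibrated secondary-flow share, pulsatile
waveform, PC-MRI-like pixelization, slab averaging, noise and aliasing, and
downstream decay of inlet structure. Passing tests therefore demonstrate
that the *pipeline* — acquisition, registration, profile construction, flux
normalization and every descriptor — is implemented correctly against
closed forms and conservation properties.

They do not demonstrate patient-level predictions. Two limitations matter
most:

* **Straight tube.** Without curvature, torsion or branches, an axial-only
  inlet profile generates no secondary flow downstream: the FLAT and TP
  variants carry exactly zero helicity and zero OSI in this geometry, so
  their HFI percent difference is −100% by construction. In a curved aorta
  the geometry itself creates helical flow from any inflow, which is why
  measured TP-vs-3D HFI differences in patients are tens of percent rather
  than total. The package's HFI comparison shows the full sensitivity range
  of the descriptor, not a patient-calibrated magnitude.
* **Kinematic surrogate.** The downstream evolution (`surrogate_field()`)
  prescribes relaxation toward a parabolic profile and exponential swirl
  decay with mass conservation enforced per cross-section; it has no
  momentum dynamics. Regional TAWSS/OSI differences therefore decay
  monotonically from inlet to outlet — qualitatively the right pattern
  (inlet-BC influence is largest in the ascending aorta and smallest in the
  descending aorta) with magnitudes set by the chosen e-folding lengths
  (profile development L/2, swirl decay 0.35 L).

## Numerical choices and degenerate inputs

* Cross-section quadrature uses exact annulus areas (midpoint rule in
  radius), so the quadrature area equals `pi R^2` exactly and FLAT profiles
  carry their flux exactly; point-sampled analytic profiles have O(dr²)
  quadrature flux error (~0.3% at default resolution), while all
  waveform-driven fields are discretely flux-normalized to 1e-6.
* Aliasing wraps only out-of-range values, so in-range velocities are
  bit-identical (idempotent fold).
* OSI is clamped to [0, 0.5] and defined as 0 where `∫|tau| dt = 0`; LNH is
  0 where `|v| |omega| = 0`; percent differences with a zero reference are
  0 when the other variant is also zero and flagged `NA` otherwise.
* Degenerate meshes (any count < 2), non-intersecting acquisition planes,
  collinear reference points, empty mask overlap, target times outside the
  cycle, and non-dividing Windkessel steps are all rejected with explicit
  messages; Windkessel non-convergence within the cycle cap returns the
  trace with a warning and the residual.
* Default problem sizes — 12–24 rings for oracle refinement studies, a
  10 × 24 × 20 mesh with 40 time points and 150 particles for study runs —
  keep a full study under a minute on one core while holding every oracle
  check at its stated tolerance.

## Reproducing the packaged results

`scripts/acceptance.R` recomputes every headline quantity from scratch
through the installed package (worked-example arithmetic, oracle errors and
convergence orders, Windkessel agreement, tracer order, transform recovery,
round-trip error, the pipeline null check, and the jet-scenario study) and
writes them as JSON. The test suite (`tests/testthat/`) covers the same
ground plus the property-style invariants per module.
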