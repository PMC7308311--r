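---
title: "Models and numerics of perivascular CSF flow in pvsflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerics of perivascular CSF flow in pvsflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(pvsflow)
```

## The physical problem

The perivascular space (PVS) is a fluid-filled sleeve around cerebral
arteries, bounded on the inside by the arterial wall and on the outside by
brain tissue and subarachnoid structures. Cerebrospinal fluid (CSF) in the
PVS of the mouse middle cerebral artery (MCA) moves with a mean downstream
speed of roughly 20 µm/s plus a cardiac-frequency oscillation of roughly
10 µm/s that is in phase with the arterial wall. `pvsflow` models the two
candidate driving mechanisms — peristaltic pumping by the traveling arterial
pulse wave, and a quasi-static end-to-end pressure difference — with enough
numerical care that the phase relations and the mean/oscillatory
decomposition can be compared against measurement.

CSF is treated as an incompressible Newtonian fluid
(µ_f = 10⁻³ Pa·s, ρ_f = 1000 kg/m³). The governing equations are the
incompressible Navier–Stokes equations with the Cauchy stress
σ = −pI + µ(∇v + ∇vᵀ), solved on a domain whose walls move in a prescribed
way: the package never models the wall's elasticity (no fluid–structure
interaction); wall motion is data, as in the experimental recordings.

Default physical parameters:

| parameter | symbol | default | unit |
| --- | --- | --- | --- |
| arterial radius | R₁ | 30 | µm |
| PVS width | wd | 40 | µm |
| outer radius | R₂ = R₁ + wd | 70 | µm |
| CSF viscosity | µ_f | 1e-3 | Pa·s |
| CSF density | ρ_f | 1000 | kg/m³ |
| pulse frequency | f | 8.67 | Hz |
| pulse wave speed | c | 1 | m/s |
| wavelength | λ = c/f | 0.1153 | m |
| MCA length | L_a | 5 | mm |
| tracer diffusivity (amyloid-β) | D | 1.4e-10 | m²/s |

The wavelength is computed as `c/f` exactly (`wave_spec()` enforces
λ·f = c); at the defaults this is 0.11534 m, i.e. ~115 mm, some 3000 times
the PVS gap width — the disparity that drives both the numerical design and
the physical conclusions.

## The deforming-domain (ALE) solver

`run_transient()` integrates the Navier–Stokes equations in arbitrary
Lagrangian–Eulerian form: all fields live on a mesh that follows the walls,
and the convective velocity is measured relative to the mesh velocity. The
mesh displacement solves a componentwise Laplace problem (harmonic
extension of the boundary displacement, `solve_mesh_motion()`); because the
Laplace operator is linear and time enters only through the boundary data,
the mesh velocity is the harmonic extension of the analytic boundary
velocity — exactly the time derivative of the node positions, which is what
makes the discrete geometric conservation test in the suite pass at the
1e-8 level.

Discretisation choices:

* **Mixed Q2/Q1 elements** (biquadratic velocity and mesh displacement,
  bilinear pressure) on structured quadrilateral meshes — an inf-sup-stable
  Taylor–Hood-type pair. Annulus meshes use 5·m radial × 50·m axial
  elements with radial grading toward both walls (largest/smallest element
  ratio 3); the production resolution is m = 2 (10 × 100), chosen by the
  convergence ladder below.
* **Time stepping**: backward Euler for the first step, then BDF2, at a
  fixed step of 1/1000 of the cycle. A fixed-order, fixed-step scheme was
  preferred over an adaptive-order BDF for bit-for-bit reproducibility;
  halving the step changes the solution negligibly at these Womersley
  numbers (α ≈ 0.15).
* **Convective term**: treated explicitly with second-order extrapolation,
  `ρ((2uⁿ−uⁿ⁻¹−w)·∇)(2uⁿ−uⁿ⁻¹)`. At PVS Reynolds numbers (Re ≪ 1 through
  ~10) the term is a small regular perturbation; explicit treatment is
  stable at the cardiac time step and keeps the system matrix independent
  of the unknown, so static-wall runs factorise it once. A test verifies
  that dropping the term entirely changes centerline velocities by < 2%.
* **Pressure gauge**: with periodic ends the pressure is defined up to a
  constant; a scalar Lagrange multiplier enforces ∫p dΩ = 0 exactly.
  Traction ends (σ·n = −p₁n) are natural boundary conditions of the
  stress-form weak formulation and exclude the gauge.
* **Initial condition**: rest. The viscous relaxation time of the 40 µm gap
  (~h²/ν ≈ 1.6 ms) is far below the cycle period, so the start-up transient
  is short; `run_transient()` flags the first cycle at which the relative
  L2 change of the velocity field between cycles falls below 1e-4.

Validation inside the test suite: oscillatory channel flow against the
analytic Womersley solution (< 1% at α = 0.147 and α = 3), steady annular
Poiseuille against the closed form (< 0.5% across radius ratios 0.1–0.9),
and exact volume conservation on a squeezed annulus.

## The traveling-wave route for the one-wavelength model

The idealised peristalsis model is an axially periodic annulus one
wavelength long whose inner wall carries
u_mr = φ₀R₁ sin(2π(z−ct)/λ). Its time-periodic solution is an exact
traveling wave: in the frame moving at c the domain shape is frozen,
r₁(ξ) = R₁(1 + φ₀ sin(2πξ/λ)) with ξ = z − ct, and the flow is steady with
wall velocities (∂u_mr/∂t, −c) on the inner wall and (0, −c) on the outer —
both tangent to the frozen walls. `solve_traveling_wave()` solves this
steady problem (Picard iteration on the convective term, which here carries
the physics of the lab-frame time derivative) and recovers lab fields via
v_lab = v_wave + c e_z. One steady solve replaces thousands of transient
steps; the equivalence is checked in the suite by initialising the transient
ALE solver from the wave-frame solution and confirming the probe series
agree within discretisation error on a shared coarse mesh.

Because the axial length is ~3000 gap widths, the package also carries the
anisotropic non-dimensionalisation X_m = L₀·diag(1,1,g₃)·X_c with L₀ = R₁
and g₃ = λ/(10L₀) ≈ 385 (`scaling_spec()`). The assembled systems are
solved by direct sparse LU with partial pivoting, which is insensitive to
the coordinate anisotropy, so the scaling is exposed as a diagnostic
(`gradient_anisotropy()`: the radial/axial gradient ratio collapses from
~10³ in mesh coordinates to order 1 in computational coordinates) and as a
coordinate transform, rather than being baked into the assembly.

### Amplitude bookkeeping

Pulsation amplitudes are quoted in three ways in the literature, and the
conversions are centralised to avoid the half-wave/peak-to-peak confusion:
with half-wave amplitude φ₀ (fraction of R₁), the peak-to-peak radius
excursion is 2φ₀R₁, so *pp % of radius* = 200·φ₀ and *pp % of diameter*
(equal to the half-wave % of radius) = 100·φ₀. Quoted percentages are read
as peak-to-peak of the radius by default (`amp_from_pp_radius_pct()`):
under this reading "half-wave 0.5–2%" and "1–4% peak-to-peak" describe the
same physiological band (φ₀ = 0.005–0.02), and the package's own sweep
reproduces the two-to-three-orders oscillation dominance across that whole
band, which the alternative (half-wave) reading would not.

### Mean flow: Eulerian vs Lagrangian

Peristaltic mean flow is second order in amplitude, and at that order the
two natural definitions differ: the Eulerian mean (time average of axial
velocity at the fixed mid-gap probe) and the Lagrangian mean (net particle
drift per cycle × f) are separated by the Stokes drift of the oscillation,
which is of the same order as the mean itself. Both are computed
(`wave_frame_metrics()` reports `mean_eulerian` and `mean_lagrangian`; both
are anterograde, the Lagrangian roughly 1.5× the Eulerian at small
amplitude). Summary ratios use the Eulerian mean — "cycle-averaged mean
flow speed" at a probe — while trajectory figures use the particle drift.
For the pressure-driven short-domain flow the two agree to a few percent,
and a test asserts that agreement; for the pure peristalsis model no
near-equality should be expected, for the reason above.

An independent long-wavelength (lubrication) oracle — closed-form annular
resistance and profile plus the periodic-pressure constraint, no finite
elements — pins the oscillatory amplitude, the mean flow and the 270° phase
of the wave-frame solution in the tests.

## The realistic cross-section

The PVS around pial arteries is not annular: it is the region between the
arterial circle (radius R₁) and an outer ellipse with semi-axes 7/3·R₁
along the major axis and 0.8·R₁ along the minor axis. Because the minor
semi-axis is smaller than R₁, circle and ellipse intersect and the fluid
domain splits into two mirror-image lobes; the four junctions are smoothed
by fillet arcs of radius 0.08·R₁ found by tangency (centre at distance
R₁ + r_f from the origin and distance r_f from the ellipse). The ellipse
axes are read as semi-axes — the only reading under which the curves
intersect to produce the observed two-lobed shape. One lobe is meshed by
transfinite (Coons) interpolation between the four boundary arcs; meshed
area agrees with the closed-form circle/ellipse segment area
(a·b·φᵢ − R₁²·θᵢ) to a few 10⁻⁷ in the sharp-corner limit.

Steady axial flow solves µ∇²w = ∂p/∂z with no-slip walls
(`solve_section_poiseuille()`); the mid-gap probe sits on the major axis at
x = (R₁ + a_out)/2, matching where in-vivo particle speeds are read. The
solution is refinement-converged below 0.5% at the default edge length of
2 µm.

## The short (MCA-length) domain

The pulse wavelength (~115 mm) is more than twenty times the 5 mm MCA, so
along the vessel the walls move essentially in phase and peristaltic
rectification collapses. `short_domain_model()` exploits this with a
quasi-1D reduction: wall motion a·an(t − z/c) changes the section area at
rate S·a·an′ (S is the closed boundary integral of the displacement
coefficient: −1 on the inner wall, +φ_sas on the outer, quintic-smooth-step
blended across the fillets), mass conservation gives the axial flux, the
end pressures close the system through the section resistance, and the
mid-gap speed is the section's speed-per-flux factor times the local flux.
Inertia is neglected (α² ≈ 0.02) and the resistance and profile factor are
frozen at the base geometry — the induced error on the oscillatory
component is of order a/R₁, well below a percent at the amplitudes used.
The reduction is validated against the full transient ALE solver on the
annular variant (agreement within a few percent of the oscillation
amplitude).

The wall amplitude is not printed in the source measurements; it is tuned
so the oscillatory mid-gap velocity at the probe (z = 4 mm, 1 mm from the
open distal end) matches the in-vivo 10–20 µm/s range. Because the model
is exactly linear in the amplitude, the tuning is a single trial run plus
scaling — equivalent to, but more direct than, bisection. The compliant
outer wall uses φ_sas = 0.368; φ_sas = 0 gives the rigid-outer-wall
variant.

## The synthetic cardiac waveform

The measured arterial pulsation is available only graphically, so
`synth_pulse_waveform()` stands in for it: a truncated Fourier series
(3 harmonics) fitted to a piecewise-cosine pulse with a fast systolic
upstroke over 25% of the cycle and a slower decay, normalised to
max|an| = 1 and zero time average. It is C^∞, exactly periodic, and has an
analytic derivative (used for wall velocities). What it emulates: the
single systolic peak, the upstroke/decay asymmetry, the cardiac frequency.
What it does not: beat-to-beat variability, the dicrotic notch, and the
exact measured harmonic content — so tests that pass with this waveform
demonstrate the mechanism (phase relations, linear scalings, orders of
magnitude), not a fit to any particular recording. Digitised waveforms can
be imported via `read_waveform_csv()` and used everywhere the synthetic one
is.

## Numerical bookkeeping

* Quadrature: 3 × 3 Gauss per element everywhere; boundary integrals use
  3-point Gauss per face with the axisymmetric 2πr measure where relevant.
* Linear algebra: `Matrix` sparse LU; mesh-motion operators and static-wall
  step matrices are factorised once and reused.
* Picard iteration (wave frame): relative-update tolerance 1e-9, at most 6
  iterations; 2–3 suffice at these Reynolds numbers.
* Particle tracking: classical RK4 in physical coordinates with the
  physical-frame velocity (pathlines are frame-independent, so no
  ALE-specific transport is needed); step ≤ 1/1000 cycle.
* Phase: fundamental-harmonic projection; the value reported is the lag of
  the fluid behind the wall in [0°, 360°) — a quarter-period delay of the
  fluid reads 90°. Under this convention the one-wavelength model gives
  270° (fluid leads by a quarter cycle) and the short domain gives ~0°.
* Convergence norms: relative L2 norms of the velocity-vector and pressure
  difference fields between meshes at m and 2m, integrated on the finer
  mesh's quadrature at matched material points (the structured meshes share
  logical coordinates across refinement levels).

Problem sizes: the production one-wavelength runs use the m = 2 mesh
(10 × 100 elements, ~9.5k degrees of freedom); the convergence ladder adds
m = 1 and m = 4 (~37k DOF); solver-validation runs use coarser meshes where
the comparison target is analytic. These choices are the package's own: the
m = 2 level is where the refinement norms drop below 0.1%.

## Known limitations

* The full 3D lobed-section peristalsis run is represented by its
  axisymmetric analog plus the steady lobed-section solver; the package
  contains no 3D element machinery. The physics the 3D run demonstrates —
  mean ≪ oscillatory, 270° phase at one-wavelength scale — is carried by
  the axisymmetric model.
* Wall motion is always prescribed; there is no poroelastic tissue, no
  fluid–structure coupling, and no AQP4/choroid-plexus physiology.
* Transport is summarised by the Péclet number only; shear-augmented
  dispersion is out of scope.
* The wave-frame shortcut applies to the periodic sinusoidal-wave
  configuration; waveforms that are not single traveling sinusoids run
  through the transient ALE path.
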