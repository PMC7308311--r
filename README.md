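# pvsflow

Finite-element simulation of cerebrospinal fluid (CSF) flow in the
perivascular spaces (PVS) that surround cerebral arteries, built to answer a
specific physiological question: **can heart-beat arterial pulsations pump
CSF along the PVS, or must the directed flow observed in vivo be driven by a
pressure difference?**

In-vivo particle tracking around the mouse middle cerebral artery (MCA)
shows CSF moving with a mean speed of ~20 µm/s in the direction of blood
flow, plus an oscillation of ~10 µm/s in phase with the arterial wall. The
popular explanation is peristaltic pumping by the traveling arterial pulse
wave. `pvsflow` implements the fluid mechanics needed to test that
explanation quantitatively:

* **ALE Navier–Stokes solver** — the incompressible Navier–Stokes equations
  in arbitrary Lagrangian–Eulerian form on a deforming annular or planar
  domain (Q2/Q1 mixed elements, BDF time stepping, harmonic-extension mesh
  motion), with no-slip moving walls, periodic or pressure-traction ends and
  a zero-mean pressure gauge.
* **Traveling-wave (wave-frame) solver** — for the axially periodic
  one-wavelength model with a sinusoidal wall wave, the time-periodic
  solution is an exact traveling wave; solving the steady problem in the
  frame moving with the wave reproduces the whole cycle at the cost of one
  steady solve. The two routes are cross-validated in the test suite.
* **Steady section solvers** — the closed-form hydraulic resistance of a
  concentric annulus,

  $$Q = \frac{-\partial p/\partial z}{R_{flow}},\qquad
    R_{flow} = \frac{8\mu}{\pi}\left[r_2^4 - r_1^4 -
    \frac{(r_2^2-r_1^2)^2}{\ln(r_2/r_1)}\right]^{-1},$$

  and a numeric Poisson solver for realistic cross-sections, in particular
  the two-lobed PVS bounded by the arterial circle (R₁ = 30 µm) and an
  outer ellipse (70 µm × 24 µm semi-axes) with 2.4 µm fillets.
* **Wall kinematics** — traveling sinusoidal waves, a synthetic cardiac
  pulse waveform (fast systolic upstroke, slow decay, C¹-periodic), and the
  region-resolved normal-direction displacement of the lobed wall (inner
  wall, outer wall, smooth-step fillet transition).
* **Tracking and metrics** — RK4 pathlines, mean-vs-oscillatory flow
  decomposition, wall-to-fluid phase, Re/Pe, and mesh-convergence L2 error
  norms.

All lengths, times and pressures are SI internally; µm/s and mmHg appear at
the I/O boundary.

## Worked example

Steady flow through the realistic two-lobed section under a small pressure
difference, then the peristalsis question:

```r
library(pvsflow)

built <- build_lobed_section(30e-6)                    # R1 = 30 um PVS
lp <- lobed_poiseuille(built, mu = 1e-3,
                       dp = 0.01 * 133.322, L = 5e-3)  # 0.01 mmHg over 5 mm
lp$v_mid * 1e6
#> [1] 23.84

sol  <- solve_traveling_wave(wave_spec(amp_from_pp_radius_pct(1)), m = 2)
mets <- wave_frame_metrics(sol)
c(mean = mets$mean_eulerian, osc = mets$oscillatory) * 1e6
#>      mean       osc
#>      12.1      6770
mets$phase_deg
#> [1] 270.02
```

A pressure difference of 0.01 mmHg across the 5 mm MCA segment drives a
mid-gap speed of ~24 µm/s — the directed speed seen in vivo. A
physiological peristaltic wave (1% peak-to-peak of the arterial radius), by
contrast, produces a large oscillation (≈ 6.8 mm/s here) but a mean flow
almost three orders of magnitude smaller, and the fluid velocity lags the
wall velocity by 270° — the opposite of the in-phase relation measured in
vivo. Shortening the domain to the 5 mm MCA (wavelength ≈ 115 mm ≫ vessel
length) restores the in-phase relation but leaves the wall-driven mean flow
below 0.001 µm/s (`analysis/03_short_domain.R`).

## The analysis workflow

The numbered scripts under `analysis/` reproduce the study end to end; each
writes CSV tables and a config echo under `results/`:

| script | what it computes |
| --- | --- |
| `01_steady_lobed.R` | pressure sweep through the lobed section (flow rate, mid-gap speed, Re, Pe) |
| `02_peristalsis_amplitude.R` | one-wavelength peristalsis amplitude sweep: mean vs oscillatory flow, phase, quadratic amplitude scaling |
| `03_short_domain.R` | MCA-length segment: tuned wall motion plus applied pressure; phase and pressure-linearity of the mean flow |
| `04_convergence.R` | mesh-refinement ladder with relative L2 error norms |
| `05_channel_demo.R` | 2D channel peristalsis mechanism demo: neck pressure peak, anterograde/retrograde flux split vs lubrication theory |

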