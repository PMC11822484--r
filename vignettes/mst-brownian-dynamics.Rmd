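---
title: "Simulating microscale thermophoresis: model, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating microscale thermophoresis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The physical problem

A continuous-wave near-infrared laser focused into a thin water film heats
a micron-scale spot. Suspended colloids (here 500 nm polystyrene
nanoparticles, PSNPs) drift along the resulting temperature gradient —
thermophoresis, or the Soret effect — and, being thermophobic in water
near room temperature, deplete the heated region. The steady-state
depletion obeys, to leading order,

$$ \frac{c}{c_0} = \exp\!\big[-S_T\,(T - T_0)\big], $$

with $S_T = D_T/D$ the Soret coefficient, $D_T$ the thermophoretic
mobility and $D$ the Stokes–Einstein diffusion coefficient. `mstbds`
simulates this experiment end to end at the single-particle level:

1. **Heat stage.** Steady-state conduction
   $\nabla\!\cdot\!\big(k(T)\nabla T\big) + Q = 0$ on the layered chamber
   (8 µm water between two 150 µm borosilicate coverslips), with the
   laser modelled as a uniform cylindrical volumetric source of diameter
   equal to the in-plane FWHM of the focus (27.6 µm) spanning the full
   water thickness. The deposited power follows Beer–Lambert absorption,
   $P_\mathrm{abs} = P_\mathrm{in}(1 - e^{-\alpha L})$ with
   $\alpha = 967\,\mathrm{m^{-1}}$ (water at 1560 nm) and $L = 8$ µm;
   dividing by the cylinder volume gives $Q_V$.
2. **Particle stage.** The overdamped Langevin equation
   $\gamma \dot{\mathbf r} = \mathbf F_B + \mathbf F_\mathrm{tph}$,
   discretised as
   $\mathbf r_{i+1} = \mathbf r_i - D_T(T_i)\nabla T_i\,\Delta t +
   \Delta\mathbf r^B$, with Gaussian Brownian steps of per-axis variance
   $2 k_B T_\mathrm{room}\Delta t/\gamma$ generated by the Box–Muller
   transform. Dynamics are two-dimensional on the chamber mid-plane; the
   temperature and its gradient are obtained by first-order (bilinear)
   interpolation of the mid-plane field. Particles are non-interacting.
3. **Analysis stage.** Radial occupancy histograms of the thermophoretic
   run normalised bin-by-bin by a seed-matched Brownian-only control give
   $c/c_0$ versus radius; inverting the depletion law at the spot centre
   yields $S_T$ and, through $D$, the mobility $D_T$. The local
   thermophoretic force
   $\mathbf F_\mathrm{tph} = \gamma(T)\,D_T(T)\,\nabla T$ is binned the
   same way.

## Heat solver

**Axisymmetric formulation.** The chamber and source are rotationally
symmetric, so the solver works in $(r, z)$ on the upper half of the
chamber (the mid-plane is a symmetry plane) and the 2D Cartesian maps
used by the particle stage are produced by revolving the mid-plane radial
profile. This is orders of magnitude cheaper than a 3D solve with no loss
of generality for this geometry.

**Discretisation.** Cell-centred finite volumes on a graded tensor mesh:
uniform cells inside the source radius, geometrically refined cells at
the source rim (where the gradient peaks) and at the water/glass
interface, geometric coarsening towards the far boundaries. Mesh faces
coincide with the source rim and the material interface, so the source
volume and layer assignment are exact. Interface conductivities use the
distance-weighted harmonic mean. The default mesh (72 × 36 cells) changes
the hot-spot rise by less than 0.1 % when every count is doubled, and the
discrete energy balance (boundary flux versus injected power) closes to
~1e-9; both are enforced by tests at 1 %.

**Nonlinearity.** Water conductivity is
$k_w(T) = 0.61 + 0.0012\,(T - 298\,\mathrm{K})\ \mathrm{W\,m^{-1}K^{-1}}$.
Picard (fixed-point) iteration re-assembles the operator with the current
temperature until the maximum update falls below $10^{-6}$ K (3–4
iterations in practice; hard failure with a residual report if 100
iterations do not converge).

**Choices the problem statement leaves open.**

* *Glass conductivity*: not printed in the source material; we default to
  1.14 W m⁻¹K⁻¹ (borosilicate, temperature-independent), exposed as
  `thermal.k_glass`. Across plausible values (1.0–1.3) the hot-spot rise
  moves by roughly ±9 % and the rim gradient by ±4 %, which is why the
  printed temperature rises are matched at the 10 % level rather than
  exactly.
* *Lateral extent*: Dirichlet ambient at 300 µm radius by default.
  Doubling the radius to 600 µm changes the hot-spot rise by < 0.1 %
  (sensitivity run included in the solver tests at the 2 % level).
* *Ambient*: boundaries at 24 °C (297.15 K); the particle-stage formulas
  use the room temperature 297 K, both configurable.
* *Gradients*: computed once on the Cartesian mid-plane grid by
  second-order central differences, then bilinearly interpolated — i.e.
  the map is differentiated first and sampled second, never the reverse.

With the defaults, 20.5 mW gives $Q_V = 3.30\times10^{10}$ W m⁻³ and a
hot-spot rise of 1.66 K; 79.8 mW gives 6.43 K. The mid-plane gradient
peaks at $1.3\times10^5$ K m⁻¹ just outside the source rim and is of
order $10^4$ K m⁻¹ within 50 µm — the regime where thermophoresis is
observable.

## Particle model

The thermophoretic mobility is temperature-dependent. Measured mobilities
of bare aqueous polystyrene colloids grow roughly linearly with
temperature and extrapolate to zero near a common crossover at ~286 K;
the shipped default table is that linear family,
$D_T(T) = 0.1\times10^{-12}\,(T - 286.2\,\mathrm{K})\ \mathrm{m^2K^{-1}s^{-1}}$,
anchored at $D_T(297\,\mathrm{K}) = 1.08\times10^{-12}$ — the value
consistent with the measured depletion of this particle size at room
temperature — tabulated at 290/297/310/320 K. Interpolation is piecewise
linear and exact at the nodes; outside the tabulated range the end values
are clamped (constant extrapolation), which avoids spurious sign flips
from short tables. Any published $D_T(T)$ model can be substituted as a
two-column table (`particle.dt_table`, or `read_dt_table()`).

Viscosity uses the Andrade-type fit
$\mu = 2.761\times10^{-6}\exp(1713/T)$ Pa s, friction is Stokes drag
$6\pi\mu a$, and $D = k_BT/\gamma$ with CODATA
$k_B = 1.380649\times10^{-23}$ J K⁻¹.

## Langevin integrator

* **Time step** $\Delta t = 0.05$ s by default: the RMS Brownian step is
  ~0.31 µm and the largest drift step ~8 nm, both far below the ~14 µm
  field length scale. A warning fires if the worst-case drift step
  exceeds one field cell, and a test verifies the central depletion is
  unchanged (within Monte-Carlo error) when $\Delta t$ is halved.
* **Random force at room temperature.** The Brownian variance uses
  $T_\mathrm{room} = 297$ K everywhere, not the local temperature — the
  stated approximation of the method being reproduced. Consequently a
  constant $D_T$ corresponds to an exactly constant Soret number
  $S_T = D_T / D(T_\mathrm{room})$, which the steady-state tests exploit.
* **Box–Muller.** Normal deviates are generated from R's seeded uniform
  stream via the Box–Muller transform, making runs bit-reproducible for a
  fixed seed; the thermophoretic run and its Brownian-only control use
  the same seed and therefore the identical random-displacement sequence.
* **Walls.** The domain box is closed with specular reflection. The
  initialisation region is the 100 × 100 µm² square of the reference
  runs, but the default *domain* extends to ±150 µm: the physical chamber
  is laterally macroscopic, and closing the box at the initialisation
  square would force particle conservation inside an entirely heated
  region, inflating the far-field reference density and biasing the
  central concentration ratio upward by a factor ~2.5. With walls at
  ±150 µm the unheated margin acts as the reservoir the experiment
  provides. (The field grid always covers the domain; this is validated
  before stepping.)

## Analysis conventions

Occupancies are pooled over all recorded frames in the 600–1200 s window
(1 Hz recording), mirroring the equilibrium time-averaging of the
experimental images. The "centre value" of a profile is the ratio in the
innermost bin with nonzero reference counts; occupancies near $r = 0$ are
small (the innermost of 100 bins over 0–100 µm collects ~150 reference
counts), so a pooled-3-bins option exists and is flagged in the output.
At $N = 1000$ the single-bin centre ratio carries a counting standard
error of ~0.035, and because occupancy frames are correlated on the
core-residence timescale the observed seed-to-seed spread is closer to
±0.05 — that sets the reproducibility of the headline $c/c_0$. The radial origin is the heat-source axis, not the particle
centroid.

The force profile samples 3000 uniform positions in a 50 × 50 µm² region,
evaluates $\gamma(T) D_T(T)\,|\nabla T|$ at each, and averages within 100
equal bins over 0–50 µm; bins beyond the sampled square are reported as
undefined rather than zero.

## What the simulations do and do not establish

The generator reproduces the *study conditions*: laser powers
20.5/40.5/79.8/114 mW, 1000 particles started uniformly in 100 × 100 µm²,
1200 s of dynamics, the default mobility table. Passing tests show the
coupled pipeline is internally consistent (energy balance, Einstein
relation, Boltzmann steady state, parameter recovery) and matches the
published simulated observables at their stated tolerances. They do not
validate the mobility table against new experiments, nor cover natural
convection (relevant above ~80 mW in this chamber, deliberately out of
scope), hydrodynamic or interparticle interactions, optical forces,
transient heating, or 3D effects beyond the mid-plane approximation.

Known quantitative limits: the hot-spot rise is reproduced at ~6 % below
the published FEM values (unprinted glass conductivity and mesh), and the
peak of the binned force profile computes to ~0.6 fN against a published
~0.8 fN — our grid-converged rim gradient is $1.3\times10^5$ K m⁻¹, and
reproducing 0.8 fN would require ~$1.7\times10^5$ K m⁻¹ at the same
mobility. Both numbers are recomputed, not asserted, by the test suite
and the acceptance script.

## Problem sizes used in the test suite

Unit tests run the solver at a coarsened mesh (~40 × 20 cells) and the
integrator at 40–100 particles for seconds-long runs; the statistical
invariants use 500–1500 particles over 150–1500 s windows chosen so each
check resolves its tolerance at ≥3 counting standard errors; the
acceptance checks run the full reference configuration (1000 particles,
1200 s, Δt = 0.05 s). All fixtures are generated in code; no data files
ship with the package.
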