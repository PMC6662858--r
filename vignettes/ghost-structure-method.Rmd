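---
title: "The ghost-structure monodomain method: models, numerics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The ghost-structure monodomain method}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Cardiac tissue is an excitable medium: a cardiomyocyte that is driven past
its threshold fires an action potential (AP) — a stereotyped
depolarization–plateau–repolarization excursion of its transmembrane
potential — and then cannot be re-excited for a refractory period.  At
tissue scale the potential obeys the monodomain reaction–diffusion
equation,

$$\frac{\partial V_m}{\partial t}
  = \frac{1}{C_m}\left\{\frac{1}{A_m}\,\nabla\!\cdot\!\big(\sigma\,\nabla V_m\big)
  - \big(I_{ion} + I_s\big)\right\},$$

where $C_m$ is the membrane capacitance per area, $A_m$ the
surface-to-volume ratio, $\sigma$ the effective tissue conductivity tensor,
$I_{ion}$ the membrane ionic current from a cell model, and $I_s$ an
imposed stimulation current.  Real tissue domains are irregular (ventricle
cross-sections) and may move; finite-difference discretization of the
diffusion operator on such domains is awkward.

The ghost-structure (GS) method sidesteps the irregular boundary the way
immersed-boundary methods do in fluid–structure interaction: the potential
$V_m$ lives on a regular Cartesian "ghost" box $\Omega$ that contains the
tissue, while the membrane state lives on a triangulated Lagrangian mesh of
the tissue region $\Omega_c$ with a motion map $\chi(X,t)$.  The two
representations exchange information through a smoothed delta kernel:

* interpolation $\tilde V_m(X) = \sum_{i,j} V_m(x_{ij})\,
  \delta_h(x_{ij}-\chi(X))\,\Delta x_1 \Delta x_2$ brings the potential to
  Lagrangian quadrature points;
* the cell model evaluates $\tilde I_{ion} = g(\tilde V_m, y)$ and
  $\partial y/\partial t = f(\tilde V_m, y)$ there;
* spreading $I_{ion}(x) = \sum_e \sum_Q \tilde I_{ion}(X^e_Q)\,
  \delta_h(x - \chi(X^e_Q))\,\omega^e_Q$ returns the reaction current to
  the grid.

Nodal membrane states are recovered from quadrature values by an $L^2$
projection with the finite-element mass matrix.  The kernel is the
four-point piecewise cubic

$$\Psi(r) = \begin{cases}
\tfrac12 (|r|+1)(|r|-1)(|r|-2) & |r| \le 1\\[2pt]
-\tfrac16 (|r|-1)(|r|-2)(|r|-3) & 1 < |r| < 2\\[2pt]
0 & \text{otherwise,}
\end{cases}$$

with the two-dimensional tensor product
$\delta_h(x) = \Psi(x_1/\Delta x_1)\Psi(x_2/\Delta x_2)/(\Delta x_1 \Delta
x_2)$.  The $1/(\Delta x_1\Delta x_2)$ normalization is essential: it is
what makes spreading and interpolation mutually adjoint, exactly
conservative, and exact on constants (partition of unity) and linear fields
(first moment condition) — all of which the test suite verifies to
$10^{-10}$ or better.

Both the membrane ODE system and the reaction–diffusion PDE are advanced by
the explicit three-stage third-order TVD (Shu–Osher) Runge–Kutta scheme; the
diffusion term uses the standard staggered-grid five-point stencil with
axis-aligned anisotropy $(\sigma_l, \sigma_t)$.

## Orientation conventions

Fields are `n1 x n2` matrices with `V[i, j]` the cell centered at
`lo + ((i-1/2) dx1, (j-1/2) dx2)`; all geometry uses the standard
mathematical orientation (x right, y up, angles counter-clockwise).  Raster
images of fields (and most figure conventions with the y axis pointing
down) mirror that orientation: a spiral that `rotation_sense()` reports as
counter-clockwise appears clockwise in a y-down image.  The spiral-wave
benchmark with the cross-field initial conditions produces exactly that:
counter-clockwise in mathematical orientation, clockwise as a y-down
raster.

## The coupled step

One `gs_step()` executes, in order:

1. if the structure moves and $t$ is inside the motion window: advance the
   current positions of nodes and quadrature points by explicit Euler with
   the *material* velocity $k(X)\,n(X)$, re-derive element areas and
   quadrature weights, and rebuild the transfer stencils;
2. evaluate $\tilde I_{ion}$ at the quadrature points (nodal states
   interpolated through the P1 basis, potential interpolated through the
   kernel), add $\tilde I_s$ if the stimulus window is active, and spread to
   the Eulerian reaction field;
3. advance $V_m$ with TVD-RK3 (see *Reaction evaluation modes* below);
4. interpolate the fresh $V_m$ to quadrature points and project onto the
   mesh nodes ($L^2$ projection);
5. advance the nodal states with TVD-RK3, the freshly projected potential
   held frozen across the three stages (the gates are updated *after* the
   potential, which is the only explicit reading of the published step
   ordering);
6. ghost refresh: reset non-tissue cells to the resting potential.

Determinism is absolute: there is no randomness anywhere, and the compiled
benchmark loop reproduces the reference R implementation to the last bit
on the cases the suite compares.

## Tunable numerical choices (and their defaults)

**Reaction evaluation mode** (`reaction_mode`).  `"per_stage"` (default)
re-evaluates the interpolate → react → spread chain at every RK3 stage and
retains the scheme's design accuracy for the reaction term; `"frozen"`
evaluates it once per step, which makes the reaction update effectively
first order (the three stages telescope to forward Euler for a frozen
source) but costs one transfer pair instead of three.  With the benchmark
time step ($\Delta t = 0.1$, upstroke spanning many steps) the two modes
differ by $\lesssim 5\times10^{-3}$ in the potential; the shipped benchmark
presets therefore use `"frozen"`, and the tests compare both modes.

**Projection** (`projection`).  `"consistent"` (default) solves the sparse
mass system with a cached Cholesky factorization; `"lumped"` divides by the
row-sum diagonal.  On the structured meshes used here the two are
indistinguishable in the verification comparisons (differences below the
other error sources), so the presets use the lumped form in the compiled
loop.

**Quadrature** (`quad_order`).  Degree-2 (three mid-edge points, default),
degree-1 (centroid) and degree-4 (six points) rules are provided.
Spreading accuracy at the benchmark refinement is insensitive to the rule
(verified in the conforming comparison), so the large presets use the
centroid rule, which also sets the quadrature-point count equal to the
element count.

**Leak guard** (`refinement_factor`, default 0.5).  Lagrangian edges must
not exceed half the Eulerian spacing, the conventional immersed-boundary
margin against coverage gaps; construction fails loudly otherwise.  For
moving structures the presets refine the material mesh by the final
stretch factor so the constraint holds in the *deformed* configuration
throughout the motion window.

**Ghost refresh** (`refresh_every`, `refresh_region`).  The refresh resets
non-tissue cells to rest every step by default.  Two region conventions are
provided: `"far"` (default) spares a two-cell halo around the structure so
the kernel support never reads freshly reset cells; `"outside"` resets
every cell whose kernel coverage by the structure is below one half, which
places the effective homogeneous-Dirichlet wall at the structure boundary
itself.  The conforming-grid verification uses `"outside"`, because the
halo convention displaces the wall by two cells and caps the achievable
agreement with a boundary-fitted solve; the spiral benchmarks keep `"far"`
(the boxes have ample margin and the spiral never reaches the wall region,
so the choice is immaterial there).

**Motion window** (`t_stop`).  The radial expansion
$k(X) = \mathrm{rate}\,\lVert X - X_c\rVert$ applied to material
coordinates grows every point's radius linearly, so boundary points leave
any finite ghost box in finite time (for the published boxes, at
$t \approx 1.9$).  How long the motion was meant to act is not derivable
from the setup; the presets stop it at $t = 1.25$, which keeps the
expanded structure (stretch factor 1.5) safely inside the box with a
kernel-width margin.  The stop time is ordinary configuration.

## Unit systems

The solver runs in one of two unit systems, centralized in
`monodomain_coefficients()`:

* *dimensionless*: $C_m = A_m = 1$ and the diffusion coefficients are used
  as given, which makes the normalized two-variable excitable model
  (potential $u$, recovery $v$, cubic ionic term $u(1-u)(u-a) - v$) a
  literal special case of the monodomain equation;
* *physiological*: (mV, ms, mm, S/m, µF/cm², µm⁻¹), with
  $D = \sigma_{mono}/(A_m C_m)$ converted to mm²/ms and currents in µA/cm²
  scaled by $1/C_m$.

Measured human ventricular conductivities violate the equal-anisotropy
assumption $\sigma_e = \lambda\sigma_i$ under which the bidomain model
reduces to the monodomain form, so the effective conductivity is combined
per direction as $\sigma = \sigma_i\sigma_e/(\sigma_i+\sigma_e)$, which
reduces exactly to $\frac{\lambda}{1+\lambda}\sigma_i$ whenever equal
anisotropy does hold.  With the tabulated ventricular values
(0.3/0.03 intracellular, 0.3/0.12 extracellular S/m), $C_m = 1$ µF/cm² and
$A_m = 0.24$ µm⁻¹ this gives $D_l = 0.0625$, $D_t = 0.01$ mm²/ms.

## Cell models

The cell-model contract is two vectorized functions: `rhs(vtilde, y, t)`
for the state and `current(vtilde, y)` for the ionic current in the
solver's subtract-the-current convention, plus metadata (resting potential,
initial state, observables).  `current_sign` records the native sign
convention of the underlying model so adapters negate explicitly rather
than silently: the normalized cubic model *adds* its ionic term, so its
adapter registers the negated cubic and the generic solver update
reproduces the native equations exactly.

Two models ship:

* the two-variable FitzHugh–Nagumo model (benchmark defaults $a = 0.1$,
  $\varepsilon = 0.01$, $\beta = 0.5$, $\gamma = 1$, $\sigma = 0$);
* a *surrogate ventricular model* for tissue-scale activation studies: a
  Mitchell–Schaeffer-style two-current formulation (fast inward, slow
  outward, one recovery gate) in dimensional millivolts, which produces a
  plateau-shaped AP with upstroke, $\sim$300 ms plateau, repolarization and
  an effective refractory period, plus a phenomenological intracellular
  calcium pulse that tracks the upstroke (the excitation–contraction
  observable).  It is deliberately *not* a biophysically detailed human
  ionic model — detailed models plug into the same contract — and its
  parameters (thresholds, time constants, stimulus amplitude of
  −30 µA/cm² for 2 ms ≈ twice diastolic threshold) are package choices
  documented in the function reference, since no published values exist
  for this synthetic setting.

## What the fixtures emulate — and what they do not

The spiral-wave benchmarks (`benchmark_spec()`) reproduce published setup
values exactly: ghost boxes $[-0.1,2.6]^2$ (275² cells, stationary) and
$[-0.75,3.25]^2$ (408², moving), $\Delta t = 0.1$, $K = 10^{-4}$, the
cross-field initial conditions on the rectangle $[0,2.5]^2$ and the
arc-bounded analogues on the disc of radius 1.25.

The ventricular sections are *synthetic idealized geometry*: a thick LV
ring plus thin RV crescent (transverse, 130 × 110 mm box) and a U-shaped
biventricular outline (longitudinal, 140 × 140 mm), parameterized by wall
thicknesses and chamber radii.  They are stand-ins for patient-derived
sections, so ventricular results are *qualitative activation orderings*
(healthy vs left-bundle-branch-block), never absolute completion times:
with complete LBBB the stimulus reaches only the right-ventricular
endocardium (including the septal surface the right bundle feeds), the
septum activates on the same schedule as in the healthy state, and the
left-ventricular lateral wall activates strictly later.  The packaged
study runs at 1 mm spacing — far coarser than a clinical-resolution
simulation — where excitation fronts are under-resolved and conduction
velocities are numerically inflated; orderings are robust to this,
absolute times are not, which is exactly why only orderings are asserted.

## Verification strategy and known limitations

The solver is verified three ways:

1. *identities*: kernel partition of unity, spread/interpolate adjointness
   and conservation, exactness of the projection on linears, dense-matrix
   equality of the diffusion stencil, RK3 amplification and order;
2. *conforming oracle*: on a grid-aligned rectangle the GS solution is
   compared with an independent boundary-fitted finite-difference solve of
   the same reaction–diffusion system (`fd_monodomain_solve()`, a separate
   code path with no Lagrangian structure).  In a front-resolved regime
   ($K = 2\times10^{-3}$ on a 60² box, $\Delta t = 0.03$, $t = 10$) the
   max-norm disagreement falls 3.6 % → 1.8 % → 1.1 % as the Lagrangian edge
   is refined from $\Delta x$ to $\Delta x/4$.  At the spiral benchmark's
   $K = 10^{-4}$ the upstroke front spans roughly one cell and max-norm
   agreement saturates at a few percent — a front-position sensitivity of
   the comparison norm, not a convergence failure;
3. *cross-domain consistency*: rectangle and circle benchmarks yield front
   speeds and arm widths equal to within a few percent of each other, and
   the measured front speed (≈ 0.0045) sits just below the analytic
   traveling-front bound $\sqrt{2K}\,(1/2 - a) \approx 0.00566$ for the
   cubic nonlinearity, as a spiral front must.

Measurement estimators are deliberately simple and documented: front speed
is the inverse norm of the upstroke-time slowness vector from the four
straddling cells (exact for plane waves at any inclination); arm width is
the super-threshold chord along the front normal (gradient direction,
iteratively refined, sub-cell endpoints by bisection), averaged over the
two arm crossings nearest the domain centroid; the half-amplitude
threshold $u = 0.5$ (or $V = 0$ mV for dimensional models) is used unless
configured otherwise.  Published reference values for these observables
depend strongly on the exact, unstated measurement protocol; the package
reports what its own documented estimators compute.

Known limitations: axis-aligned anisotropy only (no rotating fiber
fields); explicit time stepping only (stability bounds the time step); the
kernel boundary treatment carries the usual immersed-boundary $O(\Delta x)$
wall error; 2-D only.

## Problem sizes used by the shipped studies

The full-resolution stationary benchmarks run 10⁴ steps on 275² grids with
about 1.0–1.3 million quadrature points (structured four-way split
triangulations at half the grid spacing).  The moving-domain ordering
study uses coarsened variants (138²/204² grids at equal spacing,
$\Delta t = 0.2$, $t = 800$).  The ventricular study uses the transverse
section at 1 mm spacing, $\Delta t = 0.25$ ms, 120 ms of activity.  All
sizes are set in the presets and are ordinary configuration.
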