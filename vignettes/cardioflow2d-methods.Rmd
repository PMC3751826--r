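---
title: "Methods: moving-domain hemodynamics of the embryonic heart"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: moving-domain hemodynamics of the embryonic heart}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

The embryonic zebrafish heart pumps blood before valves exist: a traveling
contraction of the myocardial wall (peristalsis in the early tube, and
sequenced chamber contraction once atrium, ventricle and AV canal have
formed) drives flow through a lumen tens of micrometers across.  The wall
shear stress (WSS) and pressure gradients this flow exerts on the
endocardium are mechanotransduction signals for valve and chamber
morphogenesis, but they cannot be measured directly at this scale.  They
can, however, be computed: the moving endocardial boundary is visible in
fluorescence microscopy, so one can prescribe the imaged wall motion to a
flow solver and read the stresses off the solution.

`cardioflow2d` implements that image-to-hemodynamics pipeline in two
dimensions:

1. **wall motion** — per-frame boundary traces are smoothed, resampled to a
   fixed number of Lagrangian nodes, and interpolated in time to the solver
   rate;
2. **meshing** — the most-contracted configuration is triangulated once and
   deformed every step by pseudo-solid elasticity;
3. **flow** — the incompressible Navier–Stokes equations are advanced on
   the moving mesh in arbitrary Lagrangian–Eulerian (ALE) form;
4. **read-outs** — WSS, inter-chamber pressure difference, stream
   functions, ellipsoid-model ejection fraction, Reynolds and Womersley
   numbers;
5. **PIV** — FFT cross-correlation velocimetry of labeled blood cells
   supplies measured inlet velocities and independent validation.

All quantities are CGS: centimeters, seconds, grams; stresses and
pressures in dyn/cm².

## Flow model

On the moving domain $\Omega(t)$ the fluid satisfies

$$\rho \dot{u} + \rho\,(u - \tilde{u})\cdot\nabla u - \nabla\cdot T = f,
\qquad \nabla\cdot u = 0,
\qquad T = -pI + \mu\left(\nabla u + \nabla u^{\mathsf T}\right),$$

where $\tilde{u}$ is the mesh velocity, $\dot u$ the time derivative
following the mesh, and the convective velocity $u - \tilde u$ carries the
ALE correction.  Blood is treated as incompressible and Newtonian with
defaults $\rho = 1.06\ \mathrm{g/cm^3}$ and $\mu = 0.07$ P (7 cP,
an estimate for embryonic zebrafish blood from relative viscosity and
hematocrit).  At Reynolds numbers well below one this is a safe rheological
idealization; shear-thinning corrections would matter only at far higher
shear-rate contrast.

Boundary conditions partition the lumen boundary by tag:

* **wall** — no-slip against the imaged wall motion: $u = g(x,t)$ with $g$
  the analytic time-derivative of the per-node position splines;
* **inlet** — either a Dirichlet velocity profile (parabolic by default,
  justified a posteriori by Womersley numbers $\approx 0.1$), a measured
  PIV waveform, or an open traction boundary for fixtures driven purely by
  wall motion;
* **outlet** — zero traction $T\cdot n = 0$ plus backflow stabilization:
  the weak form gains $-\beta\,\tfrac{\rho}{2}\,(u\cdot n)_-\,(u\cdot w)$
  on outflow edges, $\beta = 0.2$ by default.  The term vanishes when flow
  exits and removes the destabilizing energy inflow when it reverses; the
  regurgitant phases of the embryonic cycle make this essential.

## Discretization

**Space.** Linear (P1/P1) triangles with SUPG/PSPG stabilization, which
permits equal-order velocity–pressure interpolation and suppresses
convective oscillation.  The element stabilization parameter is

$$\tau_M = \left[\left(\tfrac{2}{\Delta t}\right)^2
  + c\cdot G c + C_I\,\nu^2\, G\!:\!G\right]^{-1/2},
\qquad \tau_C = (\tau_M\,\mathrm{tr}\,G)^{-1},$$

with $G$ the element metric tensor, $c = u - \tilde u$ frozen at the
element centroid, and $C_I = 36$.  $\tau_C$ weights a grad-div (LSIC) term
that tightens element-level mass conservation; both constants are exposed
in `time_config()`.  A three-point edge-midpoint quadrature rule (exact to
degree 2) integrates all element terms; two-point Gauss handles boundary
edges.

**Time.** The second-order generalized-$\alpha$ method for first-order
systems, parameterized by the spectral radius $\rho_\infty$
($\alpha_m = \tfrac{3-\rho_\infty}{2(1+\rho_\infty)}$,
$\alpha_f = \tfrac{1}{1+\rho_\infty}$,
$\gamma = \tfrac12 + \alpha_m - \alpha_f$).  The default
$\rho_\infty = 0.5$ damps spurious high-frequency content while retaining
second order; the acceptance suite verifies the $\approx 4\times$ error
reduction under $\Delta t$ halving.  One numerical subtlety documented
here because it bites anyone doing refinement studies: $\tau_M$ contains
$\Delta t$, so halving the step also perturbs the spatial operator.
`time_config(tau_dt = )` pins the transient scale of $\tau$ so that
temporal refinement isolates the integrator error; production runs leave
it at the default (the step size).

**Linearization.** Modified Newton–Raphson: the tangent is assembled and
factorized at the first iteration of each step and reused, matching the
convergence protocol of stopping when the residual norm falls below
$10^{-3}$ (relative to the step's initial residual — the robust reading of
an absolute threshold whose scale depends on units) or after 5 iterations.
A full-tangent mode exists for the steady solves used in verification.
The dropped $\tau$- and backflow-switch derivatives cost nothing
observable at these Reynolds numbers; the tangent test in the suite checks
the assembled Jacobian against a finite-difference probe to 5%.

**Linear solver.** A sparse LU factorization of the coupled
velocity–pressure tangent.  Every problem this package targets is
desk-scale (≤ ~10⁴ unknowns), where a direct solve is faster and more
robust than an iterative Schur-complement pass; the factorization is
reused across the modified-Newton iterations of a step.

**Mesh motion.** Plane-strain linear elasticity on the reference
(most-contracted) triangulation with Dirichlet data equal to the
prescribed boundary displacement, and Jacobian stiffening: element
Young's modulus $E_e = E_0 / \det(J_e)^{\chi}$ with $\chi = 1$ and
$\det J_e$ taken on the reference mesh, so small elements near the wall
deform least.  Poisson ratio 0.3.  Because the reference configuration and
stiffening field are fixed, the elasticity operator is factorized once per
simulation.  Because the wall motion is prescribed rather than
fluid-driven, the quasi-direct coupling sweep converges at the first
iteration by construction; the loop verifies this rather than assuming it.
There is no remeshing: element inversion aborts the run naming the worst
element, which is the honest failure mode for a prescribed-motion code.

**Meshing.** Bowyer–Watson Delaunay triangulation of the boundary loop
plus an interior hexagonal point grid at the target edge length, jittered
by $10^{-3} h$ to break cocircular degeneracies, clipped to the polygon
with a 0.55 h standoff from the boundary.  All boundary nodes enter the
mesh unchanged (node 1..n in loop order), and generation fails loudly if
any boundary segment is not recovered as a mesh edge.

## Wall motion

Traces are ordered point lists with `wall`/`inlet`/`outlet` tags.
Per-coordinate cubic splines over the chord-length parameter give a smooth
curve (smoothing splines with exactly pinned endpoints when the points are
noisy; a polyline parameterization is available when fidelity to the
digitized vertices matters).  Equidistant resampling places N nodes at
equal arc-length fractions — arc length by dense composite Simpson
quadrature polished with Newton steps to ~10⁻⁹ relative gap uniformity —
and node k of every frame is the same material point by the
equal-arc-fraction correspondence, the simplest reproducible Lagrangian
proxy (the matching rule is a modeling choice; nothing in a 20 fps video
identifies material points on a smooth wall).  Natural cubic splines in
time then give C² trajectories sampled at 100 Hz, and their analytic
derivative is the wall Dirichlet velocity — so the velocity the solver
sees is exactly consistent with the geometry it deforms to.

## Hemodynamic read-outs

* **WSS**: $\tau_w = t\cdot\mu(\nabla u + \nabla u^{\mathsf T})\cdot n$
  per wall node, with the P1 element gradients area-averaged over the
  node's patch, $t$ the boundary tangent and $n$ the into-fluid normal.
  On a straight wall this is $\mu\,\partial u_t/\partial n$, positive when
  the fluid drags the wall forward.  The near-canal summary is the mean of
  the 10 largest $|\tau_w|$ in the region of interest, computed per time
  step.  The region itself automates the manual crop: the throat is the
  minimum wall-to-wall gap (excluding a margin near the open ends, where
  inflow/outflow tracts can be narrower than the canal), and the region is
  all wall nodes within a configurable window of it.
* **Pressure gradient**: mean pressure over the 10 nodes nearest each
  chamber center, ventricle minus atrium; pressure is only defined up to
  the outlet traction datum, so only differences are reported.
* **Stream function**: least-squares $\nabla\psi = (-u_y, u_x)$ via the P1
  Poisson normal equations, gauge-fixed at a reference wall node; contours
  are instantaneous streamlines, and every derived quantity is invariant
  to the gauge node.
* **Ellipsoid ventricle**: $V = \tfrac{\pi}{6} L D_1 D_2$ (with
  $D_1 = D_2$ when only one minor axis is measurable) and
  $\mathrm{VEF} = (\mathrm{EDV}-\mathrm{ESV})/\mathrm{EDV}$.
* **Dimensionless numbers**: $Re = \rho u D/\mu$ with $u$ the cycle-peak
  section-mean velocity at the throat and $D$ the throat width;
  $\alpha = \sqrt{\rho\omega R^2/\mu}$ with $\omega = 2\pi f_\text{beat}$
  and $R$ the inflow-tract radius.

## PIV

FFT cross-correlation with window-mean subtraction, three-point Gaussian
subpixel peak fit (parabolic fallback where a log is undefined), and a
peak-ratio quality measure.  Multi-pass refinement (default 64/32/16 px at
50% overlap) offsets the second frame's windows by the previous pass's
rounded displacement — discrete window offset rather than full image
deformation, which addresses the in-plane-loss motivation at minimal
complexity but leaves the known gradient bias of top-hat windows (~0.1–0.2
px where the displacement varies across a window).  Vectors are screened
by the normalized-median test (threshold 2, noise floor 0.1 px) and a
peak-ratio cutoff of 1.2; outliers are replaced by the local median, and
border windows whose predictor offset cannot be applied are flagged
invalid rather than silently measured with in-plane loss.  The inlet
waveform is the per-frame mean of the velocity component normal to a user
line, with gap frames linearly interpolated and flagged.

## Synthetic study conditions

No imaging data ship with the package; the generators reproduce the
*conditions* of the embryonic measurements so that the physics regime —
not any specific embryo — is exercised:

* **Peristaltic tube** (early heart-tube analogue): half-width
  $h(x,t) = w_0\,(1 - \mathrm{occ}\,\sin^2(\pi(x - ct)/\lambda))$ with
  $w_0 = 0.01$ cm, occlusion 0.6, length $\lambda = L = 0.15$ cm, and beat
  frequency 0.9 Hz (54 bpm, the early-stage heart rate), giving wave speed
  $c = f\lambda$.  These dimensions put the computed flow at
  $Re \sim 10^{-2}$ and $\alpha \approx 0.09$ — creeping, quasi-steady,
  the regime of the organism.  The sin² wave keeps the lumen area exactly
  constant in time, which makes the fixture a sharp conservation test
  (net open-boundary flux must vanish step by step).
* **Two-chamber geometry** (late-stage analogue): Gaussian chamber bumps
  over a constant-width throat, radii modulated sinusoidally at 2.5 Hz
  (150 bpm) with a 0.3-cycle atrium-to-ventricle phase lag.
* **Closed-end piston**: a box with one outlet and a
  $\sin^2$-stroke piston wall, whose displaced area is known in closed
  form — the moving-domain mass-conservation oracle.
* **Particle videos**: Gaussian spots advected by a closed-form pixel
  displacement field, seeded at 0.04 particles/px² (≥ 10 particles in a
  16 px window, the standard seeding rule), deterministic under a seed.

What the generators deliberately do **not** emulate: out-of-plane motion,
image noise statistics of a real camera beyond additive Gaussian noise,
wall-segmentation error, or embryo-to-embryo variability.  Passing tests
therefore demonstrate the numerics and the pipeline plumbing on truthful
geometry and optics idealizations — not agreement with any particular
animal's hemodynamics.

## Verification

The test suite runs the pipeline against independent oracles at desk
scale (all sizes chosen so the full suite completes in about a minute):

* steady Poiseuille (H = 0.01 cm, U = 0.1 cm/s, 25×80 channel):
  centerline within 1% of 1.5 U, wall WSS within 2% of
  $6\mu U/H = 4.2\ \mathrm{dyn/cm^2}$;
* oscillatory channel at $\alpha = 0.13$: mid-channel waveform within 2%
  RMS of the quasi-steady response;
* piston and peristaltic fixtures: per-step mass imbalance below 10⁻³ of
  the flow scale;
* free-stream preservation under prescribed interior mesh motion to 10⁻⁶;
* manufactured solutions: velocity L² order extrapolating to 2, pressure
  above 1 (8→64 squares), temporal halving ratio ≈ 4 (16² square, Δt
  0.04→0.005 s);
* every step of the benchmarks converges below the 10⁻³ residual within
  5 Newton iterations at Δt = 2 ms;
* PIV: integer circular shifts exact, subpixel within 0.1 px, rendered
  Poiseuille advection within 5% RMS of full scale;
* the peristaltic fixture shows one forward and one reversed throat phase
  per cycle with the reversed peak smaller than the forward peak — the
  bidirectional, laminar behavior of the valveless stage — at $Re < 1$ and
  $\alpha < 1$.

`scripts/acceptance.R` recomputes these quantities from scratch and writes
them to JSON; the README describes how to run it.

## Known limitations

* Planar 2-D: no out-of-plane flow, no axisymmetric correction; absolute
  WSS magnitudes in a real tube differ from the mid-plane 2-D idealization.
* Prescribed wall motion: no fluid–structure feedback; the wall does what
  the segmentation says regardless of the load.
* No remeshing: motions violent enough to entangle the pseudo-solid mesh
  abort (by design, loudly).
* Discrete-offset PIV: displacement-gradient bias of order 0.1–0.2 px in
  strongly sheared regions.
* The AV-canal locator assumes the canal is the interior minimum-width
  throat; exotic geometries may need the window and end-margin parameters
  adjusted.
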