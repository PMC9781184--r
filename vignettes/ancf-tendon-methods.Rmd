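---
title: "Methods: ANCF continuum-beam mechanics of the Achilles subtendons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ANCF continuum-beam mechanics of the Achilles subtendons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science and of the
numerical choices behind it. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## 1. The mechanical problem

The Achilles tendon is a composite of three subtendons (from the soleus and
the medial and lateral gastrocnemius heads) that twist around one another
and can slide relative to each other. The package models a Type III tendon:
three beams of length $L = 70$ mm with cross-section areas
$16.31 / 15.98 / 19.57\ \mathrm{mm^2}$, pretwisted by
$\psi \in \{0°, 15°, 45°\}$ about the common central axis, loaded axially at
the free end of the soleus up to 400 N (roughly 10% stretch), with the
first node of every subtendon held.

## 2. Element and kinematics

The three-node 3363 ANCF continuum beam element interpolates the global
position field as $r(\xi,\eta,\zeta) = N_m(\xi,\eta,\zeta)\,q$, quadratic in
the axial coordinate and a complete quadratic in the two cross-section
coordinates. Each node carries the position $r$ and the derivative vectors
$r_y, r_z, r_{yz}, r_{yy}, r_{zz}$ (18 scalar dofs per node, 54 per
element). Because the unknowns are global positions and their material
derivatives, no rotation parameters appear, and cross-sections can contract,
shear and warp — essential for a near-incompressible solid, where uniaxial
stretch forces ~50% of the strain into the transverse directions.

The deformation gradient is evaluated against the interpolated reference:
$F = (\partial r/\partial\boldsymbol{\xi})
     (\partial \bar r/\partial\boldsymbol{\xi})^{-1}$,
computed internally from nodal displacements so that the reference state
yields $F = I$ exactly (to machine precision); $J = \det F > 0$ is enforced,
and violations are signalled as a recoverable condition that triggers load
step cuts.

**Centerline placement.** Each subtendon beam carries its own centerline
through its section centroid; the common tendon axis is only the axis the
pretwist winds around. This was a genuinely open design point, and the
alternative — all three beams sharing the central axis as their element
centerline, with sections offset in $(\eta,\zeta)$ — was implemented first
and rejected on quantitative grounds: an axial tip load applied on the
shared axis is then eccentric with respect to each section's centroid and
bends the beams, which inflates the 10 N elongation of the straight model
by roughly 75% relative to both the incompressible closed form and the
published tendon response, and destroys the conditioning of the static
problem (a soft bending mode under a stiff volumetric penalty). With
centroidal centerlines the straight configuration is a clean tension test,
and a pretwisted subtendon's centerline becomes a helix — which is also
what produces the (small, positive) extra elongation of twisted tendons
that the model reproduces.

## 3. Cross-sections and cubature

Cross-sections are closed, counterclockwise, piecewise spline boundaries
under the cumulative chordal parametrization. Integrals over the enclosed
domain use a Gauss–Green cubature of prescribed exactness $2n-1$: Green's
theorem converts $\iint_\Omega f$ into a boundary integral; for every
boundary Gauss point, an inner Gauss rule integrates from a vertical
reference line $\Xi$ to the boundary abscissa. The boundary rule order per
segment is $n_i = n p_i + \lceil p_i/2\rceil$ for spline degree $p_i$
(validated by the polynomial-exactness property tests rather than trusted
from typography). The choice of $\Xi$ provably does not affect integrals;
the default is the bounding-box mid-abscissa, and $\Xi$-independence is
tested separately. Clockwise boundaries are rejected, not silently flipped,
because all cubature weights change sign with orientation.

Element integration combines the section rule (exactness parameter
$n = 2$ by default) with 4 axial Gauss points per element; the quadrature
reproduces reference volumes to 0.1% in the tests, including pretwisted
references.

**Synthetic sections.** Published data gives reliable areas but no
vertex-level outlines, so the default Type III layout uses annular-sector
polygons arranged around the axis, with angular spans proportional to the
target areas and each sector shrunk about its own centroid to the exact
target area — which simultaneously opens small positive clearances
(~0.08 mm, about 1–2% of a section diameter) at the shared borders. Shape
realism is deliberately secondary to area fidelity: for a straight
prismatic bar the axial response depends on the area, not the outline, so a
green straight-tendon test validates areas, material and solver, *not* the
outline geometry. Users with real outlines supply them as vertex lists.

## 4. Material

The isochoric/volumetric split $F = J^{1/3}\bar F$,
$\bar C = J^{-2/3} C$ gives
$\Psi = \frac{\mu}{2}(\bar I_1 - 3) + k (J-1)^2$ and
$S = \mu J^{-2/3}\!\left(I - \tfrac13 \bar I_1 \bar C^{-1}\right)
   + 2k(J-1)J\,C^{-1}.$

Two parameter conventions circulate for the one-term neo-Hookean solid. The
tendon literature that this model targets quotes "shear modulus
$c_{10} = 103.1$ MPa"; the package therefore uses $\mu = c_{10}$
(energy $\frac{c_{10}}{2}(\bar I_1 - 3)$), which the incompressible
uniaxial closed form $\mu(\lambda - \lambda^{-2}) = F/A_0$ confirms
independently: it predicts 6.01 mm at 400 N against the published
6.15 mm, whereas the literal one-parameter energy
$c_{10}(\bar I_1 - 3)$ (i.e. $\mu = 2c_{10}$) would predict ~2.9 mm. The
literal reading stays available as `convention = "literal"`.

The penalty is $k = 1000\,c_{10}$ by default (bulk/shear ratio 2000,
Poisson ratio ≈ 0.49975). Doubling $k$ changes the uniaxial stiffness by
under 0.1%, far below every tolerance used; the property tests verify that
the lateral contraction approaches $\lambda^{-1/2}$ monotonically as
$k$ grows. A caveat documented for users: very stiff penalties make the
residual violently nonlinear (its third derivative scales with $k$), which
is harmless on the straight tension path but slows the solver on strongly
bent or twisted low-tension states.

## 5. Contact

Contact couples beam pairs through surface samples on the "slave" beam:
axial Gauss stations × arc points on the sector of its boundary that faces
the neighbour in the reference (within 0.5 mm by default). Each sample is
projected onto the neighbour's lateral surface by a warm-started, damped,
clamped Gauss–Newton search over the axial coordinate and a cyclic
boundary-arc parameter; the gap is the distance resolved along the
neighbour's outward normal. Because subtendons are closely packed and only
sliding is admissible, the default enforcement is a *sliding tie*: a
bilateral penalty on the gap change $g - g_0$ from the reference, making
the reference exactly stress-free; a unilateral (penetration-only) mode is
available. At an exact projection the gap variation reduces to
$n\cdot(\delta x_A - \delta x_B)$, giving equal-and-opposite nodal forces —
action–reaction holds to machine precision in the tests.

Three numerical choices matter here:

* **Smooth projection surface.** The projection target is a $C^2$ periodic
  cubic spline through a dense resampling of the neighbour's outline, even
  when the section itself is polygonal. Projections onto polygon corners
  have no well-defined normal; samples that ride such ridges make the
  contact energy non-differentiable and stall any solver. With the smooth
  surface the energy is consistent; in tie mode the smoothing is force-free
  at the reference since only gap changes are penalized. Samples whose
  *reference* projection still lands on a kink are flagged inactive at pair
  creation.
* **End extrapolation.** A projection may overshoot the neighbour's end by
  up to half an element (the element polynomials extend smoothly). Without
  this, samples sliding past the partner's end — the loaded soleus extends
  ~6 mm past its unloaded neighbours — produce a kinked gap function.
  Physically this continues the neighbour's surface, reasonable for a
  sliding tie.
* **Penalty magnitude.** Default $p_n = 5\ \mathrm{N/mm^3}$. At 400 N the
  maximum gap deviation is ~0.06 mm and is dominated by the Poisson
  contraction of the loaded soleus (≈ 3% lateral strain × 4 mm section),
  which the neighbours' sections can only partially follow; raising $p_n$
  to 40 reduces it only to ~0.05 mm while changing the reported elongation
  by <0.1%. The penalty-consistency property (gap deviation decreasing in
  $p_n$) is tested; a hard "gap < 1% of section diameter" target would
  require penalties that crush the neighbouring sections without affecting
  any reported quantity, and is deliberately not enforced.

The solver uses the standard fixed-projection Gauss-sum penalty stiffness
(`ancftendon:::.contact_tangent_fixed`); the full finite-difference
linearization with re-solved projections is exported as
`contact_tangent()` and verified against an independent differencing of the
residual.

## 6. Static solution

Equilibrium (no inertia) is found per load level by damped Newton
(Levenberg–Marquardt) on the total potential energy
$\Pi = U_{\text{int}} + U_{\text{contact}} - P\, f_{\text{ext}}\cdot(q-q_0)$:
the residual is $\nabla\Pi$ and the tangent $\nabla^2\Pi$ (element tangents
by central finite differences of the analytic internal force, batched in
compiled code; the differencing step is scaled per dof). When the full
Newton step fails to lower the energy the damping $\tau$ is raised until it
does; projection warm starts are snapshotted and restored around rejected
trials so that far trial states cannot strand them in another basin. Load
levels are bisected automatically on non-convergence (up to 5 levels).

Convergence is declared at residual norm $\le 10^{-4}$ N (about
$2.5\times10^{-7}$ relative at 400 N). The initially intended $10^{-6}$ N
proved to sit below the formulation's noise floor once penalty contact is
active; at $10^{-4}$ N the induced displacement uncertainty is orders of
magnitude below every comparison tolerance. A second, *energy-stationarity*
exit accepts a state when eight consecutive accepted iterations gain less
than $10^{-7}$ relative energy: the volumetric penalty keeps force
residuals alive in ultra-stiff modes whose displacement impact is
residual/stiffness ≈ micrometres; such states are equilibria to energy
precision, and their residual norm is reported honestly in the sweep
tables (the straight-tendon tables converge to $10^{-4}$ N proper; only
some low-load twisted levels use the stationarity exit).

Boundary conditions: each subtendon's first node is fixed in position and
its root cross-section orientation is clamped (the $x$ components of both
slope vectors plus the $z$ component of $r_y$ and $y$ component of $r_z$),
which removes the rigid swing and spin modes while leaving in-plane
contraction free. Removing the orientation clamp makes the tangent
numerically singular — covered by a test.

## 7. What the synthetic world does and does not establish

The generator emulates: exact published cross-section areas, the three
published shear moduli, the tendon length, linear pretwist, positive
inter-subtendon clearances, and a load schedule to 400 N. It does **not**
emulate: real outline shapes (sector polygons stand in), along-length area
variation (sections are prismatic), anisotropy or viscoelasticity of the
tissue, or the real insertion geometry (point load and clamped root
instead). A green acceptance suite therefore establishes that the element,
material, cubature, contact and solver reproduce published
load–elongation behaviour *for the published areas and moduli* — it does
not validate subject-specific geometry.

Known limitations, in the package's own terms:

* ψ ≠ 0 absolute elongations depend on the unpublished outline shapes and
  clearances; only the ordering (more twist → more elongation) and the
  smallness of the twist effect are meaningful, and only those are tested.
* The mesh study on the straight model shows a very small spread
  (the per-beam tension state is exactly representable by one element;
  only contact coupling is mesh-sensitive), unlike published solid-model
  studies where bending/twist resolution dominates.
* The sliding tie keeps surfaces paired even where real subtendons might
  locally separate; the unilateral mode exists for such studies.
* Degree-2 boundary segments are supported only with exactly three control
  points (an exact quadratic); degrees 1 and 3 are general.
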