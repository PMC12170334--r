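---
title: "Methods: from atrial geometry to regional shear-fibrosis statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from atrial geometry to regional shear-fibrosis statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`lashear` studies the association between regional left-atrial wall shear
stress and atrial fibrosis/electrical scar with a fully synthetic,
desk-scale pipeline. This vignette records the model, its assumptions,
the tunable parameters and the design decisions, in the order the
pipeline runs.

## Synthetic atrium

`build_idealized_atrium()` composes a subdivided icosphere scaled to an
ellipsoid (default semi-axes 35 × 30 × 28 mm, a normal-to-mildly-dilated
adult left atrium), four cylindrical pulmonary-vein (PV) tubes of radius
5.5 mm and length 40 mm, a bent, capped appendage pouch and an open,
near-circular mitral orifice (radius 0.45 of the mean semi-axis). Wall
sectors (roof, posterior, anterior, lateral, septal, floor) are labeled
by direction on the generating sphere; a seeded 3 % smooth radial
perturbation breaks exact symmetry so no downstream step can rely on
ideal geometry. The construction is checked by Euler characteristic:
genus 0 with five boundary loops (four PV rims, one mitral) gives
V − E + F = −3.

Geometry standardization follows the clinical processing constants:
flow extensions of length ten equivalent diameters
(`d_eq = sqrt(4A/π)`, with A the boundary-loop area on its best-fit
plane — the hydraulic-diameter convention, adopted because no formula is
standard for non-circular orifices), and PV clipping to a 10 mm residual
geodesic length before unfolding.

## Flow surrogate and blood age

A patient-grade viscous CFD solve is out of scope by design; blood-age
transport and traction-pattern testing only require a divergence-free,
waveform-driven velocity field. `prescribe_flow()` therefore solves one
discrete Laplace (potential-flow) problem on the voxelized chamber
(`voxelize()`, ray-parity interior test, default spacing 2–3 mm) with
flux boundary conditions — the mitral outlet carries the waveform
velocity, the four PV inlets split the flux (equal quarters by default,
matching a shared inflow profile) — and scales the unit solution by the
mitral waveform at each instant. Walls are rigid, consistent with the
limited atrial wall motion in fibrillation.

The inflow waveform (`generate_mitral_waveform()`) is a smooth two-bump
(E/A) profile; `remove_a_wave()` emulates fibrillation by replacing
everything after diastasis (the minimum between the peaks) with a cubic
Hermite branch whose value and slope match both at the splice and at the
cycle boundary, making the result C1 and periodic — the C1 requirement is
stated clinically but not operationalized, and the Hermite construction
is this package's concrete choice.

Blood age obeys `∂a/∂t + u·∇a = D∇²a + 1` with a = 0 at the inlets,
zero-gradient outflow, no-flux walls and zero initial condition — the
unit source means resident blood ages one second per second. Advection is
first-order upwind, diffusion central, backward Euler by default
(unconditionally stable at any step, including the reference 0.25 ms;
the desk-scale presets use 5–50 ms steps on a coarse grid and state so
here rather than pretending to CFD resolution). The diffusivity is not a
measured quantity; the default 1 mm²/s is a numerical regularization and
is a visible parameter. The boundary conditions of the age equation are
this package's interpretation (inlet age zero, free outflow), as the
clinical description does not pin them down. The solver's analytic
limits — age = elapsed time in a closed quiescent domain, a(x) = x/u in
steady plug flow, a(x) = x(L−x)/2D in pure diffusion with zero-age
ends — are acceptance-tested. Blood age is sampled 1 mm inside the wall
(trilinear interpolation) to avoid the wall boundary layer.

`estimate_wall_traction()` is a near-wall finite-difference surrogate,
τ ≈ μ·u_t(offset)/offset: it produces traction fields with realistic
spatial structure, not Navier–Stokes tractions, and is documented as
such. For parameter-recovery studies `synthesize_traction_series()` is
preferred: it prescribes the TAWSS field exactly (piecewise-constant
magnitude, tangential direction, sign reversal for a controlled fraction
of the cycle so OSI = oscillation/2 up to time discretization).

## Shear indices

`compute_shear_indices()` uses periodic trapezoidal quadrature (the
series spans exactly one period; the first sample closes the cycle). Two
published ambiguities are resolved explicitly:

* The printed OSI formula is dimensionally inconsistent (a time
  *integral* over a time *average*); the implemented numerator is the
  time-averaged vector `‖(1/T)∫τ dt‖`, the standard definition, which
  makes OSI dimensionless in [0, 0.5] and preserves the identity
  `RRT · TAWSS · (1 − 2·OSI) = 1`.
* The WSSG expression `τ × g / ‖τ‖` is read as the *projection* (dot
  product) of the surface gradient of `‖τ‖` onto the unit traction
  direction, not a cross product — a cross product would be a vector and
  contradicts the accompanying text. Whether the direction is
  instantaneous or time-averaged is also ambiguous; the instantaneous
  reading is the default and `direction = "mean"` provides the variant.

Vertices with zero mean traction get RRT = ∞ with a defined-mask rather
than a cap, so downstream statistics exclude rather than distort them.
The surface gradient is the per-face linear-shape-function gradient,
area-averaged to vertices; it is exact for linear fields on flat patches
and first-order convergent on curved surfaces.

## Clinical-field stand-ins and mapping

`synthesize_wall_fields()` draws bipolar voltage (BV) and image intensity
ratio (IIR) by a Gaussian copula against the TAWSS normal scores, with
two deliberate features. First, the noise component is a *spatially
smooth* Gaussian random field (random Fourier features; default
correlation length 4 mm) rather than vertex-wise white noise: fibrosis
and scar are patchy at the millimetre-to-centimetre scale, and a
spatially white field would be unrecoverable by any scattered-data
transfer, making mapping tests vacuous. Second, the noise is
orthogonalized in-sample against both the scores and the raw TAWSS
values, so the realized correlation equals the prescribed ρ exactly
before range mapping — the generator injects the condition it claims to
inject. The second projection matters precisely because the noise is
smooth: two smooth fields on a chamber-sized domain share only a few
hundred independent patches, so their chance correlation is of order
0.05–0.1, which would otherwise dominate the seed-to-seed variability of
the realized correlation. Marginals are linear maps
into clinically sensible ranges (BV into 0–2.6 mV, IIR into 0.5–1.7,
at ±2.5 SD), chosen so the diagnostic thresholds (BV < 0.5 mV for scar,
IIR ≥ 1.2 for fibrosis) flag realistic fractions of the wall (roughly
5–10 % scar, 30–40 % fibrosis, in the range reported for fibrillation
cohorts).

Transfer onto the hemodynamic mesh mirrors the clinical procedure:
point-to-point ICP (SVD/Kabsch fit; rigid only, no scaling, since the
alignment is described as rigid) followed by RBF interpolation with an
affine polynomial term (thin-plate default, λ = 1e-8, seeded subsampling
above the site budget). The kernel, smoothing and any subsampling used
clinically are unstated; these defaults are interpretations and are
recorded in each mapped field's provenance attribute.

## Unfolding and the 24 regions

`unfold_to_2d()` computes a harmonic parameterization with mean-value
weights, pinning the mitral rim to the unit-circle template perimeter by
arc-length proportion anchored at the rim point nearest the septal
centroid; PV rims and the appendage are free (natural) holes. Positive
weights with a convex pinned boundary make the embedding fold-free; the
flip count is asserted zero on every fixture rather than assumed. The
area-distortion comparison in the tests uses mean |log| area ratio,
which is minimized when the template scale matches the rim length.

The exact 24-region template of the clinical atlas is not reproducible
from its description, so the package defines an explicit stand-in: a PV
disk plus an ostial ring per vein, an appendage disk, and 15 body sectors
(roof ×3 and posterior ×3 in an inner radial band; anterior ×3,
lateral ×2, septal ×2, floor ×2 in the outer band). Anchors default to
the unfolded centroids of the mesh's own labels, so every region is
populated on any labeled input; PV-labeled vertices are always assigned
to their own PV region (anchor consistency). The template serializes to
JSON and is user-replaceable.

## Statistics

The analysis plan is reproduced as stated: per-case Pearson correlations
with pairwise deletion; TAWSS quartiles at the empirical 25/50/75
percentiles with boundary ties to the lower quartile (the tie rule is
unstated clinically; this one keeps assignment deterministic and
shift-invariant); Kruskal–Wallis across quartiles; 4 × 2 chi-square
without continuity correction, pooled over cases; Shapiro–Wilk →
Levene (Brown–Forsythe) → ANOVA / Welch / Kruskal–Wallis selection; and
Fisher z-transformed correlations compared across groups by a Welch
t-test on the transformed values (the comparison method is unstated
clinically; Welch-on-z is the package's documented, swappable choice).
Significance is two-sided 0.05 with no multiplicity correction, matching
the plan being mirrored. Treating vertices as independent observations
in the quartile tests mirrors the clinical analysis but is
pseudo-replication; the package reports it as such rather than
correcting it.

## Problem sizes and what passing tests show

The validation case (`synthesize_case()`) uses a ~13,000-vertex mesh
(1.8 mm edges) clipped to the analysis region before injection, an
8,000-point electroanatomical cloud with 0.5 mm jitter, a 6,000-site RBF
budget, a 2 mm field patch scale and ρ(TAWSS, BV) = −0.4,
ρ(TAWSS, IIR) = +0.3. Three aspects of this design are deliberate.
The ground truth is laid down on the clipped wall because that is where
recovery is measured; injecting on the full mesh and then discarding the
(systematically high-shear) PV tubes would change the target correlation
by the region mismatch alone. The TAWSS marginal is kept near-Gaussian
(tanh-bounded smooth variation plus a mild ostial elevation) so the
value-scale Pearson correlation the analysis reports and the score-scale
correlation the copula prescribes coincide. And the 2 mm patch scale is
a power choice: the monotone quartile-mean signature at ρ = 0.3 needs
the middle-quartile mean gaps (≈ 0.19 noise SD) to exceed their sampling
noise, which requires several hundred independent noise patches per
quartile — at 2 mm the clipped wall supplies roughly 300 per quartile,
at 8 mm only a few tens. The smaller fixtures in the unit tests (3 mm
meshes, 1D channels) exist for speed and analytic comparability.

What the synthetic pipeline does *not* emulate: viscous flow structure
(vortices, jets, boundary layers — the potential surrogate is
irrotational), wall motion and mitral leaflet dynamics, measurement
physics of electrograms and CMR (fields are statistical stand-ins), and
cohort-level clinical heterogeneity. Passing tests therefore demonstrate
that the *processing chain* — geometry standardization, transport
numerics, index formulas, registration, transfer, unfolding and
statistics — is correct and recovers known ground truth; they say
nothing about hemodynamic realism in patients.

## Numerical choices

Degenerate inputs are contracts, not corner cases: zero-area triangles
are skipped (and logged) by the gradient; vertices whose near-wall sample
stencil leaves the interior fall back to the nearest interior voxel with
a count; duplicate RBF sites with λ = 0 raise an error advising λ > 0;
collinear ICP inputs raise a rank error; an atrium whose PVs are too
coarse for the voxel spacing refuses to voxelize. The implicit blood-age
solver quantizes the waveform factor to a 1e-4 relative grid so repeated
levels share one LU factorization; the explicit scheme exists for
reference and sub-steps automatically under its CFL bound with a
warning. All randomness flows through one integer seed per operation via
labeled substreams, so stages are individually reproducible and a change
in one stage's draws cannot silently shift another's.
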