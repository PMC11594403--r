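---
title: "Methods: from wing-vein landmarks to wind-load deformation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from wing-vein landmarks to wind-load deformation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wingfem)
```

wingfem compares the structural robustness of insect wings across groups
that differ in venation shape. Its motivating system is the western corn
rootworm (WCR), whose Bt-Corn-resistant and rotation-resistant variants
carry shorter, more rounded hindwings than their susceptible conspecifics.
The package turns 2D vein landmarks into 3D vein-skeleton frame models,
loads them with dynamic wind pressure, and reports each group's maximum
static deformation across a wind-speed sweep. This vignette records the
model, its assumptions, the parameters that matter, and the design choices
made where the problem was genuinely open.

## The structural model and its assumptions

The wing is idealized as its vein skeleton: the 14 consensus landmarks of a
group, joined by vein-segment edges, embedded flat at z = 0 and meshed into
two-node 3D Euler–Bernoulli frame elements with six degrees of freedom per
node. Each element carries axial stiffness EA/L, bending EI about both
transverse axes with cubic Hermite shape functions, and torsion GJ/L with
G = E/2(1+ν). The assumptions this buys:

* **Slender members.** Shear deformation (Timoshenko) is omitted: vein
  segments are hundreds of microns to millimeters long against a 45 µm
  section, so shear flexibility is negligible at the reported precision.
* **No membrane.** The wing blade itself carries no stiffness in the model;
  its aerodynamic load is lumped onto the skeleton (below). Absolute
  deformations therefore overestimate a real membrane-stiffened wing — and,
  for the same reason, sit orders of magnitude above values obtained from
  solid-meshed CAD geometry of the same wings. Cross-group *ratios* are the
  meaningful output: in the linear path a common stiffness factor cancels
  exactly from shares and ordering.
* **Static, steady wind.** Loading is the dynamic pressure P = ½ρ_air v²
  applied normal to the undeformed wing plane (+z). No lift/drag
  decomposition, no flapping kinematics, no gusts. This treats the wing as
  a rigid-membrane static structure, which is the regime the comparison is
  about; it cannot say anything about aeroelastic or inertial effects.
* **Clamped base.** The humeral/axillary landmarks (template landmarks 1–2)
  are fixed in all six DOF ("fixed support, no rotation"). The model with
  supports removed has exactly six rigid-body modes — a tested invariant.

Element local axes: local x runs along the element; local z is global z
projected orthogonal to the axis (the wing is initially planar, so local z
is the out-of-plane direction); for the degenerate case of an element
parallel to global z the reference falls back to global y.

## Parameters, units, defaults

| parameter | default | unit | rationale |
|---|---|---|---|
| Young's modulus E | 150e6 | Pa | insect-cuticle vein stiffness used for these wing models |
| Poisson's ratio ν | 0.3 | — | isotropic elastic cuticle |
| material density ρ | 1200 | kg/m³ | cuticle density; unused under wind-only loading, kept for self-weight extensions |
| vein diameter d | 45e-6 | m | the models' "element thickness"; read as the solid-circular vein diameter, since a skeleton-of-beams needs exactly one section parameter |
| air density ρ_air | 1.225 | kg/m³ | sea-level standard; the source analyses never state a value |
| reference speed | 4.2 | m/s | twice the field wind speed above which rotation-resistant WCR were observed not to fly |
| speed grid | 0–4.2, 22 pts | m/s | dense enough to draw the quadratic curve; an `extended` preset covers 10–100 km/h, a second range quoted for the same analyses — the conflict is left to configuration, and every reported comparison uses 4.2 m/s |
| subdivisions | 2 | — | beam elements per vein segment; see convergence below |
| lumping scheme | tributary_length | — | see loading below |

Section constants follow the solid circle: A = πd²/4, I = πd⁴/64,
J = πd⁴/32. All defaults live in `default_config()` and can be overridden
from YAML (`load_config()`).

## Synthetic data: what it emulates, what it does not

The raw specimens behind the motivating study are not publicly deposited,
so the package generates groups with the statistical structure the analysis
assumes (`variant_spec()`, `generate_landmarks()`,
`generate_measurements()`):

* the three study groups at their real sizes (35 / 120 / 70);
* a shared 14-landmark hindwing template with a plausible three-vein
  topology (18 segments), stretched along the length axis per group —
  elongation 1.12 (susceptible) > 1.00 (rotation-resistant) ≥ 0.94
  (Bt-resistant) — encoding the documented "longer and thinner" versus
  "shorter and more rounded" contrast;
* isotropic Gaussian landmark noise, sd = 2% of centroid size — a typical
  digitization + individual-variation scatter for wing landmarks — plus a
  random similarity transform per specimen (uniform rotation, uniform
  translation, lognormal scale with sdlog 0.05) emulating arbitrary
  digitization frames;
* wing measurements drawn lognormally (CV 5%) around group means
  (9.1/3.00/13.80, 8.8/2.95/12.91, 8.4/2.70/10.08 mm–mm–mm² for
  susceptible, rotation-resistant, Bt-resistant) chosen once so the implied
  mean aspect ratios sit at 6, 6 and 7 — the reported group values.

What passing tests on these data show: that the *pipeline* recovers
generating shapes, orders groups correctly when shapes and sizes differ as
documented, and scales exactly as the physics dictates. What they cannot
show: anything about true WCR vein anatomy (the template topology is
synthetic), about landmark-noise anisotropy or allometry in real beetles,
or about the absolute deformation of real wings. Measurement triples are
drawn independently per specimen, so length–area covariance in real wings
is not emulated; only group means enter the structural pipeline.

Seeding: one top-level seed; each specimen draws from a deterministic
substream (`seed + 1000003·i + 7919·stream`), so enlarging a group extends
it without reshuffling earlier specimens, and landmark and measurement
draws never share a stream.

## Procrustes alignment choices

`gpa_align()` implements full generalized Procrustes analysis — center,
scale to unit centroid size, iteratively rotate to the re-estimated
consensus — matching the default superimposition of the standard
morphometrics tools; partial Procrustes (no unit scaling) sits behind
`scale = FALSE`. Numerical specifics:

* optimal rotations by 2×2 SVD with the reflection branch excluded (wings
  are chiral; left wings must be pre-reflected by the user);
* the first specimen seeds the consensus; convergence when successive
  consensus estimates differ by < 1e-10 in Procrustes distance, cap 100
  iterations (typical data converge in < 10);
* the consensus is re-centered and re-normalized each iteration, so its
  centroid is at the origin and its centroid size is 1 by construction;
* tangent-space projection is deliberately omitted: downstream use is a
  single mean shape, not shape statistics;
* degenerate inputs (zero centroid size, mismatched landmark counts) are
  hard errors, not warnings.

Physical rescaling: FEM needs absolute dimensions, and a unit-size
consensus has none, so the mean shape is multiplied by the grand mean
centroid size of the raw specimens (mm) before frame building. This is a
package choice — the upstream morphometrics-to-CAD handoff it replaces does
not document one.

## Wind loading

The only load is dynamic pressure along +z. Because the model is a bare
skeleton, the membrane's share of the pressure must be lumped onto the
veins: total force = P × reference planform area (the group's mean measured
wing area), split across nodes. This lumping is the single largest
under-specification in the workflow the package reimplements, so both
plausible schemes are implemented and the choice is a recorded config
entry:

* `tributary_length` (default): each node takes the share proportional to
  half the length of its adjacent elements; supported nodes receive load
  (their share passes into the reactions);
* `uniform_nodal`: equal split over free nodes only.

`analysis/04_convergence.R` quantifies the scheme sensitivity on the
fixture wing; shares and ordering are essentially unaffected because the
same scheme is applied to every group.

## Solvers and numerical choices

* **Linear path** (all headline comparisons): sparse Cholesky on the
  support-eliminated system. Boundary conditions are applied by row/column
  elimination, not penalties, for conditioning transparency. One step of
  iterative refinement follows each solve: at a 45 µm section the axial and
  bending stiffnesses differ by ~10⁴–10⁷, and refinement keeps residuals —
  and hence the work–energy identity fᵀu = uᵀKu — at the 1e-9 relative
  level the test suite demands. Factorizations are cached across a speed
  sweep.
* **Nonlinear path** (optional, `solver: nonlinear`): corotational
  formulation — natural deformations (cancellation-free axial elongation
  (ln²−l0²)/(ln+l0), twist, chord-relative end rotations extracted through
  a minimal chord rotation and multiplicative nodal rotation updates) drive
  the same natural stiffness; Newton–Raphson with equal load increments
  (default 5), convergence at residual < 1e-8 × load norm, 50-iteration
  cap with the last residual reported on failure. The tangent adds a
  string-type geometric stiffness; since the residual is exact, the tangent
  approximation affects iteration count only. Tests verify the small-load
  limit against the linear solver and the moderate-load cantilever against
  an elastica ODE oracle. The headline comparisons stay linear: at the
  deformations the skeleton model produces the nonlinear path is the
  physically honest one for absolute values, but the cross-group shares are
  defined on the linear response, where the v² law is exact and
  section-scale factors cancel.
* **Discretization**: every vein segment is subdivided into collinear beam
  elements. Euler–Bernoulli elements are nodally exact for point loads, so
  refinement matters only through the load lumping; the fixture-wing study
  at levels 1/2/4/8 (`analysis/04_convergence.R`, also an acceptance test)
  settles below 1% change between the two finest levels. The default level
  2 is the coarsest level inside the 1% band of the level-8 answer.
* **Ties and degenerate cases**: `compare_variants()` flags exact
  deformation ties instead of breaking them silently; share-of-sum on an
  all-zero triple returns NA; zero wind speed is a legitimate load case
  returning exact zeros.

## Comparison conventions

* **Aspect ratio**: AR = span²/area with span = the measured length of the
  dissected wing (measurements are per wing). The alternative full-span
  reading (2× length) is implemented behind `convention = "full_span"`;
  with per-wing areas it would quadruple the values out of the reported
  6–7 range, which is why single-wing length is the default.
* **Percentage shares**: each variant's deformation as a percent of the sum
  over the three variants, rounded to integers. This share-of-sum reading
  is adopted because it is the only arithmetic under which the published
  deformation triple (0.0077, 0.0083, 0.0107 mm) maps exactly onto its
  published percentages (29, 31, 40) — reproduced as an acceptance test.
* **Reference speed**: 4.2 m/s, the top of the default sweep.

## Problem sizes

The shipped analyses and tests run at the study's group sizes (35/120/70),
with 500-specimen groups for consensus-recovery checks, subdivision levels
1–8 (up to ~140 nodes, ~850 DOF), and 22-point speed sweeps; everything
completes in seconds on a laptop-class machine. Larger landmark sets and
meshes are limited only by the sparse solver.

## Known limitations

* The vein template is synthetic: topology-plausible, not anatomical.
  Real-data users should supply their own TPS landmarks and edge list.
* Absolute deformations are conditional on the solid-circular 45 µm section
  and on skeleton-only stiffness; they are not comparable to solid-geometry
  models of the same wings. Shares and ordering are the robust outputs.
* Uniform section along all veins by default; real veins taper. Per-edge
  sections are accepted via the model structure but no tapering default is
  shipped.
* No stress recovery, buckling, modal or aeroelastic analysis; the output
  is the static deformation field only.
* Left/right wing pooling is the user's responsibility (reflection is never
  applied automatically).
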