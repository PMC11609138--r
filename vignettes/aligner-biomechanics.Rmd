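---
title: "Staged clear-aligner biomechanics: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staged clear-aligner biomechanics: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alignersim)
```

## The problem

During clear-aligner dentition distalization the molars are moved distally
first; the premolars then follow into the space that was created, while the
molars are supposed to stand still ("anchorage"). In practice the aligner
itself betrays the anchorage: each staged aligner is slightly shorter between
the second premolar and first molar than the dentition it is seated on, and
the distal wall of the molar sockets therefore pushes the molars mesially at
every step. Cutting the aligner back to a half-wrap on the molars (removing
the distal walls) removes that pathway by construction: an aligner wall is a
unilateral contact, and an absent wall can push nothing.

`alignersim` is a reduced-order (desk-scale) mechanical model of exactly this
stage: a parametric right maxillary quadrant with a 2 mm space between the
second premolar and first molar, a staged aligner driven through ten 0.2 mm
steps of premolar distalization with skeletal (TAD) traction, and three
trimline designs:

* **con** - conventional full coverage;
* **smhw** - second-molar half wrap (distal wall removed at position 7);
* **mhw** - all-molar half wrap (distal walls removed at positions 6 and 7).

## Mechanical model

### Teeth and periodontal ligament

Teeth are rigid bodies. The periodontal ligament (PDL), a compliant layer of
nominal thickness $t = 0.30$ mm between root and alveolar bone, is modelled
as a Winkler foundation: a field of surface springs on the sampled root
surface, grounded on the bone side. The thin-layer reduction of an elastic
layer with modulus $E$ and Poisson ratio $\nu$ gives the per-area moduli

$$k_n = \frac{E\,(1-\nu)}{(1+\nu)(1-2\nu)\,t}, \qquad
  k_t = \frac{E}{2(1+\nu)\,t},$$

the confined (oedometric) modulus acting normal to the surface and the shear
modulus acting tangentially. With the standard linear PDL constants
$E = 0.67$ MPa, $\nu = 0.45$ this yields $k_n \approx 8.47$ and
$k_t \approx 0.77$ N/mm^3^. The six-degree-of-freedom support stiffness of a
tooth about a reference point $r$ is assembled by congruence,

$$K \;=\; \sum_i a_i\, J_i^{\top} \big(k_n\, n_i n_i^{\top}
        + k_t (I - n_i n_i^{\top})\big) J_i,
  \qquad J_i = [\,I,\; -[p_i - r]_\times\,],$$

over samples with position $p_i$, outward normal $n_i$ and tributary area
$a_i$. `assemble_stiffness()` is verified in the test suite against an
independent oracle: the central-difference Hessian of the total spring energy
evaluated with finite rotations. The center of resistance is obtained in
closed form as the reference shift minimizing the Frobenius norm of the
translation-rotation coupling block of $K$.

The PDL strain of a spring is its elongation magnitude over the layer
thickness (engineering strain); tractions are reported with compression
positive.

### Aligner

The aligner is reduced to a **rigid frame** carrying one socket per tooth. A
socket stores its staged rest pose and couples to its tooth through:

* a **unilateral mesio-distal wall pair**: the mesial wall transmits only
  distally-directed push, the distal wall only mesially-directed push, and an
  absent wall transmits nothing (this is the trimline mechanism);
* bilateral wrap springs for the bucco-lingual, vertical and three rotational
  components.

Stiffness magnitudes are calibration parameters - the full-shell contact
stiffness of a thermoformed aligner is not recoverable from printed material
constants alone. The default heuristic treats each engaged crown face as
shell material in through-thickness compression,
$k_{\mathrm{wall}} = E_a\, h_c\, w_{bl} / t_s$ (with $E_a = 1500$ MPa,
$t_s = 0.7$ mm), uses the same value for all three translations and
$k_{\mathrm{wall}} h_c^2/2$ for rotations; a rectangular attachment
multiplies the vertical and rotational components by a grip factor (default
1.5), and half-wrap sockets scale everything by 0.5 (half the crown surface
engaged). These defaults make the aligner-tooth coupling one to two orders
of magnitude stiffer than the PDL, which reproduces the near-complete
per-step expression and the rapid iteration-to-iteration stabilization that
full contact finite-element models of aligner seating exhibit. All components
can be overridden via `build_aligner(stiffness = ...)`.

Staging moves the premolar sockets (positions 4 and 5) distally by
$0.2\,\mathrm{mm} \times \mathrm{step}$ along their local mesio-distal axes:
the rest span (5,6) shrinks and the span (3,4) grows by the increment, with
no bucco-lingual or vertical component. The equivalent temperature-changing
bookkeeping - imposing the outstanding deformation $U - \Delta$ by heating a
zone of width $d$ with expansion coefficient $k$ to
$t = (U - \Delta)/(k\,d)$ - is provided by `tcm_temperature()` and logged per
step. The engine consumes the rest-geometry change directly; the thermal
formulation is geometry control, not physics, so it is reproduced as
bookkeeping only.

### Symmetry and traction

Only the right quadrant is modelled. The aligner frame, which crosses the
midline, is restricted to the mirror-invariant rigid motions of the median
sagittal plane: translations within the plane and rotation about its normal
(3 DOF). Elastic traction of 150 gf (1.4710 N at $g = 9.80665$ m/s^2^) acts
on the aligner from the buccal mesial cervical point of the canine socket
toward the TAD placed buccally between the molar roots, 4 mm apical of the
alveolar crest; the direction is recomputed from current geometry before
every solve. The 150 gf is interpreted per side, the straightforward reading
of a right-side-only model with one elastic per side.

### Equilibrium and remodeling

Each solve is one symmetric linear system over $7 \times 6$ tooth twists
plus the reduced aligner twist, balancing every tooth's PDL wrench against
its socket wrench and the aligner's socket reactions against the traction.
The unilateral walls are handled by active-set sweeps: all present walls
start engaged, walls whose contact would carry tension are released, and the
system is re-solved until the set is stable (deterministic socket order,
default cap 50 sweeps, oscillations reported by wall id). Singular systems
are reported with the unconstrained direction, never regularized silently.

Bone remodeling is the standard iterative surrogate: after each equilibrium
the tooth poses are adopted as the new stress-free poses and the PDL spring
field is regenerated about them (sample areas live in body coordinates, so
regeneration preserves them exactly). Each staging step runs two
solve/remodel iterations; `convergence_diagnostic()` runs extra iterations
on a copy of the state to verify stabilization without advancing the
protocol. After the ten planned steps, identical 0.2 mm extension steps
continue until the inter-proximal gap (signed projection between the facing
contact points of positions 5 and 6) falls below 0.01 mm.

Under a constant staged mismatch the displacement increments contract
geometrically, because the socket springs are much stiffer than the PDL.
One caveat is intrinsic to the algorithm and worth stating plainly: a
**sustained external force has no remodeling fixpoint**. The TAD traction
keeps producing a per-iteration displacement increment of roughly
$F/K_{\mathrm{system}}$ however many iterations are run - which is also the
clinical point of skeletal anchorage (sustained force keeps moving teeth).
In this reduced model that floor sits at the edge of the 0.1 %
third-iteration strain threshold used as the stabilization criterion; the
diagnostic in the acceptance suite documents the measured value rather than
hiding the effect.

## Measurement and metrics

Displacements are reported for the crown point (CP, occlusal-surface
midpoint), rotations for the rigid body, in fixed per-tooth local frames:
$X$ mesial (+), $Y$ lingual (+, buccal $-$), $Z$ gingival (+), with $Z$ equal
to the global occluso-gingival axis and $X$ the arch tangent at the tooth.
Rotations use the rotation-vector components in the local frame (order-free;
for the <6 degree rotations arising here any Euler sequence agrees to well
below reporting precision): $X$-component = bucco-lingual torque (lingual +),
$Y$-component = mesio-distal tipping (distal +), $Z$-component = axial
rotation (mesial +). Landmarks follow the clinical definitions: root point =
apex (or midpoint of apexes), resistance-center landmark at the 1/3 root
level for single roots or 1 mm apical of the furcation for molars.

Distalization efficiency and anchorage loss are percentages of the 2 mm
prescription:

$$\mathrm{eff} = 100\,\frac{\max(0, -\Delta x_{md})}{2.0}, \qquad
  \mathrm{loss} = 100\,\frac{\max(0, +\Delta x_{md})}{2.0},$$

clamped at zero for wrong-direction motion (signed values available via
`signed = TRUE`); the improvement between designs is the difference of their
losses in percentage points.

## The synthetic dentition

The generator replaces patient imaging with a parametric quadrant: a quartic
arch curve $y = D\,(1 - (x/x_m)^4)$ in the occlusal plane (defaults
$D = 46$ mm depth, 64 mm width), seven teeth placed by arc length so that
all neighbours touch except for the 2 mm space at (5,6), box crowns, and
tapered-cone roots (three cones sharing a furcation 3 mm apical of the
cervix for the molars). Crown widths, heights and root lengths default to
typical adult maxillary dimensions and are config-exposed.

Smooth cones under-represent the oval, curved surfaces of real roots, so the
tributary areas of the sampled spring field are scaled per tooth to standard
published mean root-surface areas of maxillary teeth
(204/179/273/234/220/433/431 mm^2^ for positions 1-7). This anchors both the
absolute tooth mobility and everything downstream of it (forces, strains,
traction-driven drift) to physiological magnitudes; without it the dentition
is roughly twice too mobile.

What the generator does **not** emulate: patient-specific crown and root
morphology, curved or dilacerated roots, inter-proximal tooth-to-tooth
contact mechanics (teeth may marginally overlap at closure), a deformable
aligner shell (the rigid-frame reduction transfers force along the arch but
cannot bend between teeth), occlusal loads, or nonlinear/viscoelastic PDL
response. Passing tests therefore demonstrate the *mechanism* - load
redistribution by unilateral wall removal - and the internal consistency of
the solver, not patient-level predictive accuracy. Consistent with that, the
rigid frame expresses nearly all of each staged increment, so absolute
efficiencies run higher than in a deformable-shell model, while the
between-design orderings (which teeth drift, which flare, which design
protects the molars) are the robust output.

## Numerical choices

* Solves are dense ($45 \times 45$) and direct; residual tolerance
  $10^{-6}$ N / N·mm, checked per tooth and on the aligner subspace.
* Active-set tie-breaking is deterministic (sockets 1 to 7, mesial before
  distal); all present walls start engaged.
* PDL sampling: 400 springs per tooth by default (counts proportional to
  surface area, midpoint quadrature with exact strip areas); the assembled
  stiffness changes by <1 % when the count is doubled.
* Small-displacement kinematics within a solve; finite rigid pose updates
  between solves, so geometric nonlinearity is recovered across iterations
  and steps.
* Degenerate inputs (zero-length roots, zero areas, $\nu = 0.5$, singular
  supports, rotations beyond 30 degrees) are rejected with specific errors.
* Everything is deterministic given the scenario seed; trajectory re-runs
  are bit-identical.

## Problem sizes

The shipped configuration - 7 teeth x 400 springs, 3 designs, 10 staged
steps plus extensions at 2 remodeling iterations each - runs the full
three-design comparison in a few seconds on one CPU core, which is the scale
all examples, tests and the acceptance script use.

## Worked example

```{r example, eval = FALSE}
scenario <- scenario_config(seed = 1)
runs <- compare_designs(scenario)
report <- build_report(runs)
glance(report)
autoplot(runs$mhw)
autoplot(report)
```

## Known limitations

* The rigid aligner frame cannot reproduce within-arch shell bending, so
  per-tooth force distribution anterior of the moving premolars is stiffer
  (more uniform) than a deformable shell would give.
* Anchorage metrics at space closure depend on the closure tolerance
  (default 0.01 mm) when designs close in the same step.
* The remodeling loop has no fixpoint under sustained net load (see above);
  stabilization criteria based on a fixed iteration count inherit that
  floor.
* No relapse modeling: the simulation ends at space closure.
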