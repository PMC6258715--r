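---
title: "Multibody modelling of an elastic intramedullary nail: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multibody modelling of an elastic intramedullary nail}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mvnail)
```

## The system being modelled

The Marchetti–Vicenzi nail is an elastic intramedullary implant: six
pre-curved steel blades ("nails") are clamped to a common stub and held
straight by a sliding retention ring so the closed bundle can be inserted
into the medullary canal of a long bone. Withdrawing the ring lets the
blades expand elastically against the cortical wall, stabilizing a
fracture. The quantities a designer needs are the contact forces between
blades, ring and bone during closure and expansion, and the stiffening the
expanded device provides against external load.

`mvnail` is a desk-scale flexible-multibody simulator of this device. It
provides

* a lumped sphere–beam model of each blade (`discretize()`,
  `lump_masses()`, `beam_stiffness()`, `chain_internal_forces()`),
* penalty contacts with Hertz-type stiffness and cubically smoothed
  damping for every contact class (`impact_force()`, the gap kernels,
  `default_contact_params()`),
* rigid retention-ring models in segmented and "conceptual" variants
  (`ring_model()`), a parametric fractured canal (`canal_model()`), the
  quintic prescribed ring motion and fracture bushing (`quintic_motion()`,
  `bushing_element()`),
* a stiff quasi-static time integrator (`assemble_system()`,
  `simulate()`, `settle_static()`),
* an independent geometrically nonlinear static curved-beam benchmark
  (`beam_mesh()`, `static_solve()`, `sweep_node_pull()`), and
* scenario drivers and a CLI for the standard analyses
  (`run_withdrawal_validation()`, `run_ring_comparison()`,
  `run_expansion()`, `run_perturbation_study()`, `run_loading()`).

## The blade model: lumped sphere–beam chains

Each blade is a slender AISI 316 LVM rod (radius 1.5 mm, E = 200 GPa,
rho = 8000 kg/m^3, nu = 0.3) whose stress-free shape is pre-curved. The
flexible blade is discretized as rigid spheres joined by massless linear
beam segments: sphere spacing is at most 3.5 mm so that at least two
spheres are always engaged in the 7 mm guide hole of the ring, which gives
41 spheres on the 140 mm reference blade. End spheres carry half of the
adjacent segment's mass, interior spheres two half-segments; rotational
inertia comes from the cylinder slice each sphere replaces.

Each segment stores the stress-free relative pose of its two end frames,
taken from the curved reference centreline, and measures strain in the
body frame of its proximal sphere (a corotational formulation): rigid
motions of the whole chain produce exactly zero wrench, and the pre-curved
shape is exactly stress-free without meshing a curved element. The segment
stiffness is the standard two-node 12-DOF Timoshenko matrix (axial EA/L,
torsion GJ/L, coupled bending/shear with shear correction kappa = 10/9 for
the circular section; `kappa = Inf` degenerates to Euler–Bernoulli — at
slenderness 140/3 the difference is negligible, and the Timoshenko form is
the default because it matches the commercial beam elements this model
emulates). Damping is stiffness-proportional, `C = beta K` with
`beta = 1e-4` s by default; all production results are quasi-static and
must be beta-insensitive, which the test suite checks by halving beta.

## Contact model

All normal contacts follow the penalty law

    Fn = K g^e + STEP(g; 0, 0, d_max, C_max) * dg/dt,      g > 0

where `g` is the penetration, `dg/dt` its rate (positive when deepening),
and STEP is the cubic smooth step `h0 + (h1-h0) d^2 (3 - 2 d)` between the
bracket ends — so the damping coefficient ramps from 0 at first touch to
`C_max` at depth `d_max` and the total force is continuous and once
differentiable in `g`. Two conventions close the law where its printed
form is silent: the force is zero for `g <= 0`, and the total normal force
is floored at zero so damping can never produce adhesion. The identified
per-class parameter sets (single-/two-/six-blade real-ring values and the
conceptual-ring classes central cylinder / cylinders / boxes /
blade-to-blade) are available from `default_contact_params()`; the canal
class reuses the six-blade blade-to-ring set. Friction is deliberately
absent everywhere (a conservative choice for stability estimates).

The blade side of each contact is sampled at collocation points: the
sphere centers plus, by default, one interpolated point per segment
midpoint (`subdiv = 2`), with forces distributed to the two parent spheres
by the lever rule. `subdiv = 1` reproduces the classical spiky
sphere-contact signal, in which case the 1 Hz zero-phase Butterworth
filter (`butterworth_lowpass()`) recovers the quasi-static pattern. This
collocation refinement replaces a full capsule-geometry contact model: it
smooths the signal the same way while reusing the sphere kernels.

Penetration is monitored per class; a run aborts with status
`excessive_penetration` when any contact exceeds
`max(10 d_max, min_abort_depth)`. The absolute floor (default 1 mm) is
needed because two identified classes use `d_max = 1e-6` m — a damping
saturation depth, not a penetration allowance; ten times that value is
crossed in perfectly healthy operation.

## Ring, canal, constraints and stages

The ring is rigid and slides along the device axis following the quintic
smooth-step law (zero velocity and acceleration at both ends; the
reference schedule covers 33 cm in 5 s). Its motion is rheonomic — the
position is substituted directly, and the contact reaction it transmits is
reported. Three contact representations are provided:

* **segmented**: each 7 mm guide-hole wall split into 8 bounded wall
  patches (45 degrees each), the faithful "real geometry" reference;
* **conceptual**: localized contacts replace the distributed wall — one
  shared central core cylinder whose surface coincides with the holes'
  inner wall, three rim circles per guide (both mouths and mid-hole,
  rounded to a 0.1 mm edge radius), and two lateral boxes per guide;
* **pin**: a single rim circle per guide — a knife-edge guide used by the
  oracle-validation scenario (below).

The number of rim circles is a design choice of the surrogate itself: with
mouth rims only, the wall's interior support is missing entirely and the
closed device's hold forces disagree with the segmented reference far
more than with the mid-hole circle included; adding further circles does
not systematically improve the agreement, so three is the default.

How far the two ring representations agree depends on the mechanical
regime, and the package's own comparison (`run_ring_comparison()`, also
exercised by the test suite) quantifies it. While a blade merely slides
through its guide and the guide acts as a position constraint — the
pin-like regime, which covers the low-force part of the stroke — the two
constraint-force curves agree to within about a percent. Near the closed
configuration, however, the strongly pre-curved reference blade loads the
guide with internal couples, and there the representations differ
structurally, by ten to twenty-five percent at the curve peak: the
localized rim circles quantize the axial position at which the blade can
bear on the wall, and the shared core's contact normals point along the
ring radius where the true hole's inner wall points along the guide
radius. Increasing the number of rim circles, refining the chain, or
rounding the rims differently does not close this gap. A gently curved
blade (for which the guide is a near-pin over the whole stroke, as in the
original device this model emulates) does not enter the couple regime at
all, which is why equivalence within a few percent is attainable there
but not on this deliberately aggressive reference fixture.

The guide holes sit 4 mm from the ring axis, matching the circle on which
the blade bases are clamped. The hole radius default is 2.2 mm (0.7 mm
radial clearance). This clearance is a mechanical necessity, not a loose
tolerance: a blade with pre-curvature kappa crosses the hole at a slope of
order kappa s / 4, and the hole can only accommodate that slope — i.e. the
collar can only slide without jamming — if the clearance exceeds roughly
`slope * hole_length / 2`. For the reference blade (kappa = 4.6 1/m) that
bound is ~0.6 mm. With smaller clearances the hole acts as a slope clamp
and transmits large internal couples; the real device must be assemblable
by hand, so the pin-like regime is the physical one.

The canal is a parametric stand-in for the (unavailable) femoral
geometry: an inner cortical tube along the device axis, radius 6.5 mm
along the proximal fragment and tapering 6.5 to 5.5 mm along the distal
fragment, split by an oblique fracture plane through the axis at the
fracture station. An optional single-plane bow of the tube axis (sine
bump, default sagitta 0.8 mm in the expansion scenarios) emulates the
anterior bow of a femoral shaft (the default is the largest bow that still admits the closed bundle: guide circle + blade radius + bow must clear the canal wall); it is what makes the six blades
non-equivalent and lets them load one another — in a perfectly
axisymmetric canal the ideal assembly develops no blade-to-blade force at
all, by symmetry. Both fragments are clamped during closure and
expansion. In the loading stage the proximal fragment is released, held
only by a massless 6-DOF fracture bushing (defaults 1e3 N/m translational,
10 N m/rad rotational, soft enough not to mask the device's stiffening)
and by the expanded blades, and a horizontal force ramps 0 to 200 N with
the quintic law, along the fracture dip direction by default (the load
azimuth is not otherwise determined; it is config-exposed).

Stages are described by `sim_stage()` / `stage_schedule()`; closure is
simulated with the assembly already coaxial with the canal (the surgical
insertion translation itself is out of scope). Expansion scenarios start
from the analytic closed state (`closed_state()`: blades laid straight
along their guide axes, pre-curvature stored as bending strain) followed
by a short settle, which is equivalent to, and much cheaper than,
simulating the full closure stroke first.

## Assembly tolerance

The tolerance study (`run_perturbation_study()`) emulates manufacturing
error by rotating each whole blade (base position and curvature plane)
about the device axis by an independent uniform draw from 0 to 10 degrees,
while the ring's guide holes stay at the ideal 60 degree stations; at 10
degrees the base sits 0.7 mm off its guide axis, exactly within the
guide clearance, so every perturbed device remains assemblable. Each
perturbed assembly runs the expansion scenario, and the peak blade-to-
blade contact force of each adjacent pair (peak of the 1 Hz filtered
series) is compared with the ideal assembly's. The study reports the full
per-seed distribution and the maximum relative difference over pairs and
seeds.

## The integrator

The identified contact parameters make the equations extremely stiff: the
saturated damping (`C_max` up to 1e4 N s/m) acting on ~2e-4 kg spheres
gives decay rates of order 5e7 1/s, far beyond explicit integration. The
solver is a linearly-implicit (semi-implicit) Euler scheme: each step
solves `(M + h C + h^2 K) dv = h F - h^2 K v`, where `K` and `C` collect
the beam stiffness/damping blocks (world-rotated element matrices,
banded per chain with bandwidth 11) and the contact stiffness/damping
projectors `k_n n n^T`, `c_n n n^T` on each sphere's own block. Each
blade's system is a banded symmetric positive-definite matrix solved by a
banded Cholesky factorization; blade-to-blade and blade-to-fragment
couplings enter the right-hand side and each body's own diagonal (which
only adds numerical stiffness damping, never instability). The proximal
fragment contributes a separate 6-DOF block. Orientations are quaternions
updated by the exponential map.

Steps are adaptive: the local error estimate `h |a_(n+1) - a_n| / 2` per
velocity DOF is tested against `atol + rtol |v|` (defaults
`rtol = 1e-3`, `atol_v = 1e-3` m/s, `atol_w = 0.1` rad/s); rejected steps
shrink `h`, accepted ones may grow it up to `hmax = 5` ms. These
tolerances are chosen for quasi-static tracking — what matters is that the
reported force curves are converged, which the suite verifies by
tightening the tolerance tenfold and comparing peaks (< 0.5% change), not
that individual micro-oscillations are resolved (implicit Euler damps
them, which is desirable here). Output is resampled at 100 samples/s;
each sample triggers one dedicated force evaluation that also logs
energies, per-class penetrations and the per-pair force aggregates.
`settle_static()` performs dynamic relaxation (mass-proportional drag)
until the kinetic energy and the static residual fall below their floors.

Gravity is off by default (its effect on these forces is negligible and
the reference analyses omit it); a config flag enables it. Identical
configuration and seed give bit-identical results on the same platform —
there is no randomness anywhere in the solver.

## The independent static benchmark

The validation oracle is a separate, independently coded geometrically
nonlinear static beam model: the blade centreline meshed by 50 (default)
two-node elements, solved by incremental Newton continuation with a
corotational kinematics. Because the reference centreline is planar and
the node-pull procedure keeps deformation in that plane, the benchmark
works in the curvature plane with three DOF per node; this is exact for
the planar problem and removes the torsional DOF that never engage. The
element tangent is obtained by finite differences of the analytic internal
force — robustness was preferred over assembly speed, and consecutive
node-pull solves warm-start from each other. The sweep
(`sweep_node_pull()`) imposes, node by node, a transverse displacement
that brings the node onto the device axis and records the constraining
force; by default only the examined node is constrained (the literal
sequential procedure), and `cumulative = TRUE` additionally holds all
previous nodes on the axis (a ring-like reading). The resulting curve
rises from zero along the straight run, reaches an interior maximum, and
falls toward the tip.

The simulator is validated against this benchmark by
`run_withdrawal_validation()`: the single blade is closed and re-released
by the sliding ring while the transverse base-clamp reaction is recorded
against ring position. Two deliberate choices make this comparison measure
*model agreement* rather than artifacts:

* the guide is the knife-edge **pin** variant, because the benchmark's
  node pull is a pure position constraint — a full-length hole would add
  slope coupling that the benchmark, by construction, does not have;
* the contact set is penalty-converged (K = 1e10, light damping), because
  the benchmark's constraint is rigid; at the production stiffness the
  ~0.5 mm penetration alone would contribute several percent of apparent
  disagreement that says nothing about either model.

At discretization-converged resolution (81 spheres vs an 80-element
benchmark mesh) the two peaks agree to within a few percent and at the
same arclength station, to within the benchmark peak's own flatness.

## Scenario problem sizes

The shipped scenarios use: 41 spheres per blade (81 for the validation
scenario), 50–80 benchmark elements, six blades, a 33 cm / 5 s ring
stroke, and 20 perturbed assemblies plus the ideal one in the tolerance
study. The expansion stage is integrated until the ring has fully
disengaged from the blades (3.2 s of the 5 s stroke) plus a dwell; the
motion law itself is always the full 33 cm / 5 s quintic, and curves are
reported against ring position so the law cancels from comparisons.

## What the synthetic fixtures do and do not show

Every geometric input is generated parametrically, because the real
device's centreline curvature, ring dimensions and the femoral canal are
not published. The reference blade (140 mm arclength, 25% straight run,
25 mm tip offset, single-curvature arc) is a declared stand-in chosen so
the discretization rule reproduces the documented 41-sphere chain; the
canal is an axisymmetric tube with an optional anatomical bow. Passing
tests therefore demonstrate the *solver physics* — beam mechanics against
closed forms and an independent nonlinear benchmark, contact-law
evaluations against hand calculations, action–reaction, energy decay,
symmetry, and the equivalence of ring representations — on fixtures whose
scales are realistic for this device class. They do not reproduce the
patient-specific magnitudes that depend on real femoral geometry (final
distal forces, loading-stage force levels, the rotation-load curve);
those quantities are produced by the same machinery but should be read as
fixture-dependent outputs, not clinical predictions.

One emergent behavior deserves a note. In the perfectly axisymmetric
canal with an ideal assembly, one might expect all six blades to share the
wall load equally. They do when mutual blade contact is disabled (the
suite verifies equality to well under a percent — a solver symmetry
check), but with frictionless blade-to-blade contact the six-fold
symmetric equilibrium is *unstable*: a blade pressed radially against a
frictionless wall is circumferentially neutral, so the bundle clumps into
an alternating pattern in which roughly half the blades carry the wall
load and lean on their neighbors. The realized state still respects the
120 degree subgroup (the carriers agree among themselves), and the
clumped wedge presses the wall substantially harder per carrying blade
than the independent solution. With friction — absent by design — the
symmetric state would be frozen in; this is a real consequence of the
frictionless modelling assumption, not a numerical artifact.

## Known limitations

* Frictionless contacts only; friction would stabilize the expanded
  device further (the frictionless estimate is conservative).
* No trabecular bone, no plasticity of the pre-bending process (the
  curved shape is simply the stress-free reference), no bone-to-bone
  contact across the fracture.
* The blade-to-blade contact acts at sphere level (collocation refinement
  applies to ring and canal surfaces).
* The ring is rigid; its elastic compliance is not modelled.
* Quasi-static scenarios only; the integrator's accuracy targets tracking
  of equilibria, not impact dynamics.
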