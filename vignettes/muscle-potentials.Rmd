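---
title: "Induced-acceleration muscle potentials on a planar four-link model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Induced-acceleration muscle potentials on a planar four-link model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iaa2d)
```

## The question the method answers

During the momentum-transfer phase of the sit-to-stand (STS) transfer — from
seat-off to peak ankle dorsiflexion — the body relies on muscles to
accelerate its centre of mass (COM) upward (*support*) and to control its
forward motion (*progression*). Which muscles *can* contribute, and how
much, depends on the body's kinematic state: joint positions set both the
system's inertia coupling and the muscles' moment arms. Traditional
muscle-induced-acceleration analyses answer this post hoc from motion
capture and full dynamic simulation; `iaa2d` instead computes, for *any*
sagittal-plane posture, each muscle's **potential**: the COM acceleration it
would induce per Newton of force, in m/(N s²). Potentials are a property of
posture and anthropometry alone — independent of activation, force-length
effects and gravity — which is what makes a systematic sweep over thousands
of candidate postures feasible in minutes.

## The model

The body is a chain of four rigid links pinned to the ground at the toe
pivot O: a triangular foot (vertices at the calcaneus C, toe T and ankle A,
with OA perpendicular to CT), a shank A→K, a thigh K→H, and a lumped
head–arms–torso (HAT) segment that also carries the pelvis mass. Four
generalized coordinates θ0..θ3 measure each link's rotation relative to its
parent, with +X anterior, +Y superior, and counter-clockwise rotations
positive; θ0 is pinned to 0 (foot flat) throughout the state enumeration.

For a state q the equations of motion are M(q) q̈ = G + V + R f. Muscle
potentials need only the force term: per unit force of muscle m,

* joint potential:  P = M(q)⁻¹ R[, m]   (rad/(N s²)),
* task potential:   ẍ_COM = J_COM(q) P  (m/(N s²)),

where R collects generalized moment arms and J_COM is the whole-body COM
Jacobian. Because potentials are defined at zero joint velocity, the
J̇ θ̇ term of the Cartesian acceleration vanishes and the projection is
exact. The mass matrix is assembled analytically from link Jacobians
(`mass_matrix()`, Lagrangian form Σ mᵢ Jᵥᵢᵀ Jᵥᵢ + Iᵢ Jωᵢᵀ Jωᵢ with the
planar scalar reduction of the angular terms), and the solve is a guarded
Cholesky factorization (condition-number limit 1e12), never an explicit
inverse. Gravity and Coriolis terms exist only in a separate oracle API
(`eom_terms()`) used by the verification tests; the potential pipeline never
touches them.

## Angle conventions

Two conventions coexist and are converted exactly (`to_msk()`,
`from_msk()`): the chain coordinates θ0..θ3, and anatomical (MSK) angles
with positive = ankle dorsiflexion, knee extension, hip flexion, lumbar
extension and posterior pelvic tilt:

* ankle = −θ1, knee = −θ2,
* hip = θ0 + θ1 + θ2 − pelvic tilt,
* lumbar = hip + θ3.

Pelvic tilt is a posture parameter, not a degree of freedom of the chain:
the pelvis frame rides on the hip point H with a ground-fixed orientation.
One documented wrinkle: the source analysis's figure captions label
positive lumbar values as *flexion* while the angle definition above is
*extension*-positive; this package keeps the extension-positive angle in
all state tables and uses an explicitly named `lumbar_flexion` (= −lumbar)
modifier in the sensitivity analyses, so the reported correlation signs
follow the flexion-positive reading.

## The kinematic state space

`enumerate_states()` builds the momentum-transfer-phase state space: θ1 ∈
[−40°, 0°], θ2 ∈ [75°, 100°], θ3 ∈ [−150°, −60°] and pelvic tilt ∈
[−60°, 20°] on an inclusive 5° grid with θ0 = 0, retaining states whose
anatomical hip lies in [15°, 120°] and lumbar in [−90°, 60°]. Grid
arithmetic is integer-degree, so the count is exact and the lexicographic
ordering reproducible: the default grid yields **14,758** states from
17,442 candidates. Two normalized posture metrics are attached per state:

* **foot position** — the signed horizontal hip→ankle offset,
  (L2 sin(hip + tilt) − L1 sin(ankle)) / (L1 + L2); 0 puts the ankle
  directly below the hip, positive is anterior.
* **pelvis height** — the vertical ankle→hip distance,
  (L2 cos(hip + tilt) + L1 cos(ankle)) / (L1 + L2).

The minus sign in the foot-position formula is deliberate: with the foot
flat, dorsiflexion carries the knee (and hip) anterior over the planted
foot, i.e. moves the ankle *posterior relative to the hip*. Writing the
ankle term with a plus sign (as a dorsiflexion-positive transcription of
the same geometry might suggest) contradicts both the metric's definition
("0 = ankle in line with the hip") and the sensitivity-analysis signs it
feeds; the package tests pin the implemented form to the forward
kinematics (`|x_A − x_H|` agreement at machine precision).

## Anthropometry

Per-link masses, lengths, COM offsets and inertias are not individually
published for the reference model; only two totals are: 75.2 kg body mass
and 0.826 m leg length (L1 + L2). The bundled parameter file
(`generic_model.yaml`) therefore derives per-link values from standard
anthropometric proportion tables (segment mass fractions 2×0.0145 foot,
2×0.0465 shank, 2×0.100 thigh, 0.678 HAT-with-pelvis; radius-of-gyration
based inertias), lumping both legs into the single modeled limb, and is
constrained to reproduce the two published totals exactly. It is a
documented synthetic fixture, overridable via `read_model_params()`.
`lump_segments()` implements the mass-weighted-COM / parallel-axis rule
used to fold pelvis+torso into the HAT and the foot bones into link 0.

## Moment arms

The reference analysis took muscle moment arms from a full musculoskeletal
model in external simulation software. This package replaces that
dependency with two pluggable providers behind one interface (a function
from an MSK state to the 4 × m anatomical moment-arm matrix):

1. **Geometric** (`geometric_provider()`): muscles are polyline paths over
   the segment frames (foot, shank, thigh, pelvis, HAT). Moment arms follow
   the tendon-excursion definition, −∂(path length)/∂(joint angle),
   evaluated analytically for polylines (each joint rotation moves distal
   attachment points along circles about the joint centre); a 0.1°
   central-difference mode exists for cross-checks.
2. **Tabulated** (`tabulated_provider()`): a long-format CSV of moment arms
   on joint-angle grids — e.g. exported from any musculoskeletal tool —
   queried by multilinear interpolation, exact at nodes, with refusal to
   extrapolate.

Anatomical moment arms map to generalized coordinates through the constant
Jacobian of the angle conversion (`map_to_generalized()`): an ankle muscle
with moment arm r contributes (0, −r, 0, 0), a hip muscle (r, r, r, 0), a
lumbar-crossing muscle additionally loads θ3. This is the virtual-work
consistent choice for a pelvis whose orientation is fixed at the state's
tilt: the strongest internal check in the test suite verifies, for every
bundled muscle at 100 random states, that the mapped generalized column
equals −∂(musculotendon length)/∂q differentiated directly through the
chain's forward kinematics (agreement ~1e-10 m/rad).

### The bundled synthetic muscle set

Eight actuators cover the seven analyzed muscle groups (gluteus maximus;
biceps femoris long head; rectus femoris; lumped vasti; medial and lateral
gastrocnemius, reported as one group by averaging; soleus; tibialis
anterior). Attachment coordinates are original approximations — *not*
taken from any subject or published model — chosen for (a) correct joint
crossings and torque signs, (b) lever-arm magnitudes inside published
anatomical ranges across the enumerated posture range, and (c) stable
profiles where straight lines would degenerate: wrap-approximation via
points stand in for tissue wrapping (a retro-malleolar point keeps the
Achilles lever at ~3.4–4.5 cm across 0–40° dorsiflexion; a sacrotuberous
point keeps the gluteal path off the hip centre in deep flexion; the
patella via point preserves the knee-extensor lever at 75–100° knee
flexion). Grouped actuators report the mean of their component potentials
(configurable to sum in `collapse_groups()`).

## The sensitivity analysis

`sweep_potentials()` evaluates potentials for every state (uniform state
weighting), and `correlation_analysis()` reproduces the reference
statistical procedure: both the potential and the kinematic modifier (foot
position, pelvis height, lumbar flexion, pelvic tilt) receive a rank-based
inverse normal transform before a Pearson correlation — 7 muscles × 2 tasks
× 4 modifiers = 56 coefficients with t-based p-values and the strength
bands very weak (<0.2), weak (≤0.39), moderate (≤0.59), strong (≤0.79),
very strong (≥0.8), applied to |r| with the sign reported alongside. The
transform uses the Blom offset 3/8 with average ranks for ties — the
standard default among rank-based inverse normal variants, and the choice
matters little at n = 14,758. A Lilliefors normality check is available
(`lilliefors_test()`) as a diagnostic; the pipeline transforms regardless,
matching the reference procedure's final path.

## What the fixtures can and cannot show

With the bundled geometry the analysis reproduces the reference results
qualitatively: of the sixteen published coefficients with |r| ≥ 0.8, signs
agree for fifteen, including the complete set of very strong
foot-position relationships (all five extensor/plantarflexor progression
potentials negative, tibialis anterior positive and opposite to the
plantarflexors in both tasks) and the pelvic-tilt structure (gluteus
maximus and biceps femoris support potentials rising, rectus femoris
falling, with posterior tilt). The one disagreement is the gluteus maximus
support-vs-pelvis-height coefficient (published +0.855; near zero to
weakly negative here). The mechanics itself is not in question — at fixed
foot position this package, too, shows gluteus maximus support potential
increasing with pelvis height — but the *marginal* correlation over the
whole grid depends on how steeply the hip-extension moment arm decays with
hip flexion, a property of the unpublished source-model moment arms that
an anatomically constrained polyline cannot be pushed to without becoming
implausible. Exact coefficient reproduction is likewise out of scope by
design: it would require the source musculoskeletal model itself. Users
with access to such a model can inject its moment arms through the
tabulated provider and rerun the identical pipeline.

## Numerical choices

* Internal angles in radians, every interface in degrees; derivative
  quantities per radian.
* Cholesky solve with a 1e12 condition-number guard (the enumerated grid
  stays far below it; the guard exists for user-supplied states).
* Analytic Jacobians and moment arms; finite differences appear only in
  oracles (tests) and the optional `method = "fd"` cross-check.
* Integer-degree grid arithmetic in the enumerator; derived continuous
  metrics grouped after rounding to 6 decimals in `aggregate_potentials()`.
* Degenerate inputs fail loudly: zero lumped mass, non-perpendicular foot
  geometry, non-factorial moment-arm tables, extrapolation requests,
  all-tied vectors in the rank transform, singular mass matrices.

## Problem sizes used in the shipped tests

The test suite exercises the full 14,758-state enumeration, a full-grid
potential sweep (118,064 state-muscle rows, under a minute on one core)
and the 56-coefficient correlation table; oracle comparisons (energy
Hessians, finite-difference Jacobians, forward-integration induced
accelerations at dt = 1e-4 s) run on 20–100 random states each, sizes at
which the oracles are numerically at their best and the suite stays fast.

## Limitations

* Sagittal plane only; no frontal-plane or 3-D mechanics.
* Static by construction: joint velocities are assumed zero, so the method
  ranks postures, not trajectories.
* No ground-contact constraint forces: the foot is pinned at the toe
  pivot, and foot-flat is a state-selection rule, not a dynamic constraint.
* No muscle force, activation or force–length–velocity modeling:
  potentials deliberately isolate the kinematic factor of muscle function.
* The bundled muscle geometry is synthetic; quantitative results with it
  are illustrative, and its analyses are interpreted at the level of signs
  and trends.
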