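---
title: "Reconstructing car collisions with running pedestrians"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing car collisions with running pedestrians}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Forensic reconstruction of a car striking a *running* pedestrian has to
answer two coupled questions: what was the pedestrian's body doing at the
instant of impact (posture and per-segment velocities, not just a bulk
translation), and what injuries and rest position follow from that state.
Multibody crash codes answer the second question well but are usually fed a
static dummy posture; gait-capture pipelines answer the first but do not
simulate impacts. `pedrecon` chains the two: a humanoid-robot-style gait
generator supplies a physically consistent collision-moment state, and an
articulated rigid–flexible multibody model carries it through the impact.

The pipeline has two stages, mirroring forensic practice:

1. **Stage 1 (pre-simulation).** A spring-loaded inverted pendulum
   ("virtual leg") model produces a periodic running gait at the commanded
   speed; cubic-spline limb planning plus two-link inverse kinematics turn
   the centroid path into joint angle/velocity series; the collision-moment
   pose is sampled from these series.
2. **Stage 2 (collision).** The pose initialises a 15-segment articulated
   pedestrian which is advanced through vehicle and ground contact until it
   comes to rest; injury criteria and throw/rest metrics are evaluated.

## Stage 1: the virtual-leg gait model

During stance the centre of mass (COM) is a point mass `m` on a massless
prismatic spring leg (stiffness `k_r`, rest length `q_r0`) pinned at the
foothold. With `q_r` the leg length and `q_theta` the angle from the plumb
line (positive when the foothold trails the COM), the stance equations are

$$\ddot q_\theta = \frac{g\sin q_\theta - 2\dot q_\theta\dot q_r}{q_r},
\qquad
\ddot q_r = q_r\dot q_\theta^2 - g\cos q_\theta - \frac{k_r}{m}(q_r - q_{r0}).$$

This system is conservative; the stance integrator (adaptive multistep with
root-finding event location, relative tolerance `1e-8`) keeps the relative
energy drift below `1e-6` per stance phase. Flight is ballistic. Lift-off is
the event `q_r = q_r0` with `dq_r > 0` (zero spring force); touchdown occurs
when the leg, swung forward to the touchdown angle at rest length, reaches
the ground.

A running gait is a limit cycle of this hybrid system. `slip_gait()` finds
it by double shooting: for a candidate touchdown angle the apex forward
speed is solved so the apex height recurs step to step (energy conservation
then forces full apex-state recurrence), and the touchdown angle is solved
so the mean forward speed hits the target within 1 %. The touchdown angle is
the primary control; this is the classic fixed-touchdown-angle policy for
spring-mass running.

Parameter defaults (all overridable):

| parameter | default | unit | rationale |
|---|---|---|---|
| `q_r0` | `0.53 * stature` | m | standard leg-length/stature ratio (COM-to-ground virtual leg) |
| `k_r` | `4e4` | N/m | stance compression 5–10 % of leg length at 4.5 m/s |
| `hop` | 0.045 | m | apex clearance above touchdown height; sets flight intensity |
| gravity | 9.81 | m/s² | |

For the shipped 1.74 m / 68 kg adult at 4.5 m/s the solved gait has a duty
factor of about 0.37 and 7–8 % leg compression, in the physiological range
for moderate running.

## Stage 1: joint planning

The planner converts the centroid path into joint channels:

* **Feet.** The stance ankle is pinned over its foothold. The swing ankle
  follows clamped cubic splines (zero velocity at lift-off and touchdown)
  whose mid-swing knot sits exactly `swing_clearance` (default 0.10 m)
  above stance height. The forward-progress knots are placed near-linearly
  in time — a pure smooth-step profile lets the swing ankle lag the
  advancing hip beyond leg reach.
* **Legs.** Planar two-link inverse kinematics (knee-forward branch, law of
  cosines) from pelvis to ankle target. The pelvis is positioned by a
  fixed-point iteration so that the *posed whole-body* mass-weighted COM
  tracks the virtual-leg centroid (the IK is re-solved after every pelvis
  shift so the stored state is self-consistent).
* **Arms.** Shoulders swing sinusoid-like (spline through sinusoid knots),
  anti-phase with the ipsilateral leg; the elbow degree of freedom is
  frozen at a running carry (default −1.45 rad) and the shoulders hold a
  small constant adduction (0.25 rad) so the forearms ride near the body
  rather than protruding laterally.
* **Trunk.** Constant forward lean (default 0.1 rad).

Every channel is interpolated by a C2 cubic spline whose *analytic*
derivatives provide angular velocities and accelerations; `sample_pose()`
packages a time slice in the two-table collision-pose layout (per-joint
R1/R2/R3 angles about the body-fixed ξ, η, ζ axes plus per-body-part
angular speeds), and `pose_strip()` returns the customary strip of 10
postures per stride.

Angle conventions: sagittal rotations are about +y (left); positive swings
a limb backward; knee flexion is positive; the rotation order for
three-axis joints is intrinsic R1→R2→R3 about ξ, η, ζ. Published pose
tables name the flexion axis R2 at the hip but R1 at the knee; the skeleton
therefore assigns per-joint axis meanings rather than one global mapping.

## Stage 2: articulated multibody dynamics

The pedestrian is a kinematic tree of 15 segments (pelvis, lower/upper
trunk, neck, head, paired upper/lower arms, thighs, calves, feet) and 14
joints carrying all the standard pose-table joint names. Segment lengths
are stature fractions, masses are body-mass fractions (Winter-style table,
trunk split pelvis/abdomen/thorax; they sum to the total mass exactly), and
inertia comes from solid-primitive formulas. The standing COM sits at
0.57 × stature, inside the anthropometric 0.55–0.60 band.

Dynamics are reduced-coordinate: every joint is a chain of 1-DOF revolute
sub-joints (massless intermediate bodies), the floating base is three
prismatic plus three revolute DOFs (x, z, y order, so the gimbal-singular
middle axis is vertical yaw, which stays small in mostly-sagittal impacts),
and accelerations come from the articulated-body algorithm in spatial 6-D
algebra. Joint spring–dampers with range-limit stops supply passive
physiology-scale resistance; two lumped flexible modes on the tibiae carry
the elastic force `-K a - C a'` and are excited by leg contact forces.

Numerical choices worth knowing:

* **Integrator.** Semi-implicit Euler at `dt = 1e-4` s for collisions
  (contact-robust); classical RK4 for smooth-force verification runs.
* **Damping stability cap.** Joint viscous coefficients are capped at
  `0.25 d_i / dt` inside the articulated-body backward pass, where `d_i`
  is the DOF's articulated inertia — explicit damping on a near-massless
  axial DOF would otherwise diverge.
* **Armature.** Each joint DOF (never the base) carries a small reflected
  inertia (0.01 kg m²). Chained-revolute ball joints have a near-singular
  "gimbal" mode when two axes align; armature bounds that mode's
  acceleration. Base DOFs are exempt, so rigid-body momentum behaviour is
  exact.
* **Angle wrapping.** Revolute coordinates are wrapped to (−π, π] after
  each step: a ball joint has no winding number, and all joint limits lie
  inside ±π.
* **Contact application point.** Contact wrenches act at the capsule-axis
  sample point rather than the surface point, so rubbing cannot torque a
  segment about its own long axis (whose inertia is tiny). This sacrifices
  spin from tangential friction — negligible for blunt-impact kinematics.
* **Friction impulse cap.** The regularized Coulomb force is additionally
  capped so one step's friction impulse cannot exceed what would null the
  contact-point velocity, using an effective mass that is the smaller of
  the segment mass and its rotational equivalent.

## Contact model

The vehicle front is a planar outline (bumper, hood, windshield stations)
extruded across the width — a facet-style surface carrying per-region
penetration–force curves rather than structural elements. The shipped
sedan preset (geometry and the bumper-stiff / hood-medium /
windshield-compliant curves, each with a saturating final segment) is a
documented synthetic preset: published case reports show such curves but do
not tabulate them, so no preset value is claimed to be a measured vehicle
characteristic; user curves load from CSV. Normal force follows the
loading curve, or `hysteresis x loading` when the penetration rate is
negative, so every load/unload cycle dissipates a non-negative loop area
and a dropped sphere rebounds to at most `hysteresis x` drop height.
Friction is Coulomb with a linear viscous regularization below 0.01 m/s
slip. Curves are rate-independent. The vehicle is a prescribed-motion body
(the reconstructed case has no pre-impact braking); scene friction
defaults are 0.7 (car–ground), 0.6 (pedestrian–ground), 0.3
(car–pedestrian).

## Injury criteria

* **HIC** on the resultant head-COM proper acceleration (in g):
  exhaustive search over all sample-pair windows up to 36 ms (15 ms
  selectable) with trapezoidal integrals; search resolution is the trace
  sampling interval. HIC is invariant under time shift and scales as
  `s^2.5` under amplitude scaling.
* **Chest 3 ms clip**: the largest level sustained continuously for 3 ms,
  computed as the max over 3 ms windows of the in-window minimum, on the
  thorax trace.
* **Long-bone stress proxy**: peak transverse contact force applied
  mid-span to a simply supported tube, `sigma = (F L / 4) c / I`. This
  replaces finite-element tissue stress and systematically *overestimates*
  it (the full peak force is assumed to bend the bone mid-span with no
  load sharing by soft tissue), so its value is meaningful for
  threshold-exceedance flags (124 MPa fracture tolerance), not as a
  tissue-stress estimate.

Tolerance limits: HIC 1000; bone 124 MPa; the chest clip has no universal
numeric limit and its threshold is configurable.

Proper acceleration (kinematic minus gravity) is used so free flight reads
0 g and rest reads 1 g, matching what an accelerometer at the segment COM
would record. Filtering is off by default.

## The reconstruction and its metrics

`run_stage2()` aims the vehicle so its bumper reference reaches the
pedestrian's predicted position after `t_lead` (0.06 s) and integrates
until the whole-body kinetic energy stays below 1 J for 0.2 s (rest), or
the horizon ends (flagged partial). The event log records the first touch
of every (segment, surface-region) pair. Metrics: maximum airborne height
(highest segment COM between vehicle separation and landing), slide
distance (COM travel from first post-flight ground contact to rest), thrown
distance (first vehicle-contact point to final head position, projected to
ground — the measurement convention is a package choice), rest position and
body heading. `compare_cases()` reports `|x_k - x_1| / x_1` relative errors
of HIC, chest clip and lower-limb stress plus the rest-position offset, in
the customary two-row (case 2 vs 1, case 3 vs 1) layout for the three
initial-state modes: full running dynamics, translating static posture,
static.

## What the defaults reproduce, and what they do not

With the shipped `case1.yaml` (18.5 m/s sedan, 4.5 m/s runner struck
mid-stance at 2.7°), the simulation reproduces the qualitative collision
fingerprint of a real crossing case: first contact on a lower-limb segment
at the bumper, the head striking the windshield region ~0.06 s later, an
airborne phase peaking above 4 m, then landing, sliding and rest. The
quantitative injury values depend strongly on the synthetic contact curves
and the beam proxy and are *not* calibrated to any measured vehicle;
they are reported for threshold flags and cross-case comparison, both of
which are far less preset-sensitive than the raw magnitudes.

Known limitations: sphere-sampled capsules (three samples per segment)
coarsen contact geometry; no self-contact between limbs; no driver or
pedestrian pre-impact reaction; the pose-table angular speeds are stored as
magnitudes, so poses loaded from file use a toward-neutral sign heuristic
(poses sampled internally carry exact signed rates); yaw-heavy impacts
approach the base parameterization's singular axis. Problem sizes used
throughout the tests — one full case at `dt = 1e-4` over ≤ 4.5 s and
scaled 0.9 s three-case comparisons — were chosen to exercise every phase
of the collision on desk hardware.
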