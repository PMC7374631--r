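---
title: "Methods: work-loop energetics of simulated and measured jumps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: work-loop energetics of simulated and measured jumps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, numerical choices and design decisions
behind `jumpwork`, and — importantly — what its synthetic-data generator does
and does not establish. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The analysis model

### COM energetics from plate force

The whole-body centre of mass (COM) obeys `m a = F_z − m g` vertically, so
plate force alone determines COM kinematics once an initial velocity is
fixed. We integrate acceleration twice with the trapezoidal rule (error
O(h²), negligible at 1 kHz). Initial conditions define the analysis window:

* CMJ: `v = 0` at movement onset — the subject stands still first;
* drop jump from height `h`: `v = −√(2gh)` at first ground contact.

The drop-jump initial condition is nominal: jumpers are known to step *down*
off boxes, arriving slower than `√(2gh)`. A multiplicative
`dj_velocity_scale` (default 1) exposes this known bias without changing the
default world.

COM power is **total** vertical GRF times COM velocity, `P = F_z v`, not net
force `(F_z − mg) v`. With this convention the energy balance closes through
the displacement term — net COM work between contact and takeoff equals
`Δ(½v² + g x)` identically — and the work-loop drive is the measured plate
force, which is what force-plate work loops display. A net-force variant is
available behind `com_mode = "net"`.

Negative and positive work partition by the **sign of instantaneous power**,
not by descent/ascent phase. The two coincide for monotone phases; the power
rule is robust to the small velocity reversals real traces contain. Because
`pmin(P,0) + pmax(P,0) = P` pointwise and the trapezoidal rule is linear,
`W⁻ + W⁺ = W_net` holds to machine precision — this identity is asserted, not
assumed.

Only the vertical axis enters COM work: the method derives COM motion from
plate force, and vertical jumping is vertically dominated. Anterior-posterior
force is carried through the pipeline for centre-of-pressure use in inverse
dynamics only.

### Phase events

All events come from the total vertical force:

* contact/takeoff threshold: 20 N (a common plate-noise floor; configurable);
* a transition must persist ≥ 40 ms to count as flight or contact, so
  transient unloading dips during vigorous extension are not mistaken for
  takeoffs (the shortest real flights in weak simulated drop jumps are
  ~60 ms, so the margin is safe on both sides);
* CMJ onset: force deviating from body weight by > 5 % of body weight for
  ≥ 50 ms, then walked back to the last body-weight crossing — a standard
  onset rule; body weight itself is measured from a quiet-standing window;
* the lowest-COM event is the minimum of the doubly integrated displacement
  within the window.

Event thresholding uses the **raw** force. A zero-phase 11 Hz filter smears a
contact step symmetrically ~15–30 ms into the past, which would corrupt
contact timing against the simulator's exact event; the 20 N threshold
already rides above plate noise.

### Joint kinetics

Per side, a bottom-up planar Newton–Euler recursion (foot → shank → thigh)
computes net ankle, knee and hip moments from that side's plate force and
centre of pressure, with the foot assumed flat and stationary — valid during
contact, which is exactly the analysis window. Conventions: moments
extensor-positive, angular velocities extension-positive, so `P_j = M_j ω_j`
is positive when the joint generates energy. The sign-partitioned time
integral of `M_j ω_j` is mathematically identical to the area under the
moment–angular-displacement curve for sampled data; we integrate in time.

Angles are filtered (zero-lag Butterworth, 11 Hz), resampled 200 → 1,000 Hz
with a cubic spline, and differentiated by central differences. Segment
inertial parameters come from the Winter anthropometric table by default (de
Leva selectable); the tables give per-segment mass fractions, COM positions
and radii of gyration, and the head-arms-trunk segment closes the mass budget
so segment masses always sum to body mass.

Left and right joint work are averaged arithmetically; the negative:positive
ratio of the average is recomputed from the averaged components (the ratio of
averages), since the average of ratios is a different — and less stable —
estimator. Group tables report both mean-of-ratios (the reporting convention
for group mean ± SD) and ratio-of-means.

### Filtering

"Zero-lag fourth-order, 11 Hz Butterworth" is realized as a dual
(forward–backward) pass of a second-order design — the conventional reading
of filter order for zero-lag filters in movement analysis; `order = 8`
selects a dual-passed fourth-order design instead. The cutoff is interpreted
as the design cutoff of each pass (the effective −3 dB point of the dual pass
is slightly lower); no dual-pass cutoff correction is applied, matching
common practice. The implementation (bilinear-transform design, steady-state
initial conditions, odd-reflection padding scaled to `rate/cutoff`) is tested
against the analytic Butterworth magnitude response, and the design
coefficients agree with standard signal-processing references to full float
precision.

## 2. The simulator: a stated world

The generator exists to provide ground truth, not to imitate every feature of
human jumping. It is a planar (sagittal) four-segment chain —
foot, shank, thigh, head-arms-trunk (HAT) — with both legs lumped (leg
segments doubled, one equivalent leg; outputs are split 50/50 across two
plates and mirrored to left/right channels). Vertical jumping work is
sagittal-dominated, and a 2-D model is the only way to have exactly known
joint torques.

* **Contact** is torque-driven forward dynamics of the shank–thigh–HAT triple
  pendulum on a fixed flat foot, integrated with fixed-step RK4 at ≥ 1 kHz.
  The equations of motion are a closed-form Lagrangian formulation — written
  independently of the analysis-side Newton–Euler recursion, so torque
  recovery is a genuine two-route cross-check (the chain is additionally
  validated against the textbook double pendulum in the test suite).
* **Actuation** is a PD servo around keyframed joint-angle templates
  (countermovement depth, drop-dependent landing depth, push to extension)
  with gravity feedforward and a smooth `tanh` torque saturation whose caps
  scale with body mass and relative strength — weaker subjects saturate
  earlier and absorb relatively more energy, which is the behavioural axis
  the cohort statistics exercise. Passive joint-limit structures (quadratic
  spring + penetration-scaled damping outside the range of motion) bound
  collapse exactly as ligaments and soft tissue do, and an ankle-strategy
  balance feedback engages — again quadratically — only when the whole-body
  COM leaves the foot's support region, standing in for the heel/forefoot
  contact mechanics a point-contact model lacks. Neither is strength-capped,
  and both are part of the recorded net joint torque, so inverse dynamics
  recovers them like any other moment.
* **Flight** is kinematic: ballistic COM and smooth joint templates with GRF
  identically zero. Drop-jump touchdown is constructed so the ankle point has
  *zero world velocity* at contact — the joint angular velocities are the
  least-norm solution of the COM-velocity constraint — so the model switch
  involves no impulsive collision and impulse–momentum closes exactly over
  contact. Flight templates are quintic with endpoint accelerations matched
  to the contact dynamics, keeping sampled kinematics twice differentiable
  through touchdown and takeoff (a C² boundary is what lets finite-difference
  inverse dynamics recover torques within 2 % of peak at a 200 Hz kinematic
  rate).
* **Events**: takeoff is the force-zero crossing while the COM moves upward;
  transient unloading dips with a descending COM are not takeoffs. The
  drop-jump push begins once the descent is essentially arrested (COM
  velocity above −0.1 m/s, with a hard time bound so an unbalanced chain
  never settles into a toppled rest first) and starts from whatever state
  absorption actually reached. If a push is too leisurely to unload the
  plates (the chain just stands up), the simulator retries it faster, the
  last resorts driving slightly "through" full extension into the passive
  limits — a more vigorous attempt, as a jumper would make — before
  declaring failure.
* **Quiet standing** (CMJ) is emitted as exact static equilibrium, so
  measured body weight is `m g` to machine precision and onset detection has
  a clean baseline.
* **Truth channels**: per-side joint torques (NA during flight, where
  plate-based inverse dynamics is undefined), COM position/velocity/
  acceleration, segment angles and rates, and exact event times.

Cohort generation draws per-sex body mass, height and squat 1RM from normal
distributions truncated at ±3 SD, with defaults matching the emulated
9-men / 12-women recreational cohort (men 79 ± 7 kg, 1.77 ± 0.06 m,
1RM 116 ± 25 kg; women 63 ± 11 kg, 1.66 ± 0.06 m, 1RM 66 ± 22 kg). Squat 1RM
is additionally floored at half body weight: the normal tail below that is
unphysiological for recreationally active adults (the weakest tertile of the
emulated cohort averages 0.83 ± 0.14 1RM/BM). Trial seeds add small (3 %)
deterministic jitter to template depth and timing.

### What a green test does and does not establish

The simulator shares the qualitative physiology of interest — |W⁻| grows
monotonically with drop height; ratios exceed 100 % at higher drops; weaker
subjects and (through the strength distributions) women return less of the
absorbed energy; reduced hip capacity shifts negative work to the knee. It
does **not** reproduce: arm swing, heel rise/toe-off (the flat-foot model
underrepresents late ankle push-off), frontal/transverse-plane mechanics,
muscle–tendon elasticity (energy is absorbed by the servo and passive
structures, not stored and returned by tendons), bilateral asymmetry, or the
specific group means of any laboratory study. Simulated drop-jump ratios
therefore run higher than typical trained-human values. Green acceptance
tests establish that the *pipeline's mechanics are exact* (Newton
consistency, energy and impulse closure, torque recovery) and that the
*statistical machinery is calibrated* — not that the synthetic cohort equals
any particular human cohort.

## 3. Numerical choices

* Gravity 9.81 m/s²; SI units; time origin 0 at recording start.
* Trapezoidal integration throughout (O(h²) at 1 kHz).
* RK4 fixed step at the simulation rate (default 1 kHz); contact/flight
  transitions bookkept at force-rate samples, with the crossing sample
  belonging to flight.
* Centre of pressure is written moment-equivalent and unclipped: near
  takeoff, where `F_z → 0`, it runs outside the foot outline exactly as real
  plate CoP becomes unreliable at low load; inverse dynamics consumes the
  product `CoP × F_z`, which stays finite and exact.
* Tertile ties break lexicographically by subject id — deterministic and
  permutation-invariant.
* The two-way ANOVA computes SPSS-style marginal (type III) F tests from
  sum-to-zero contrasts by explicit design-column removal (R's formula
  marginality rules silently re-absorb dropped main effects, so
  `y ~ A*B - A` cannot be used). On balanced designs it agrees with
  `stats::aov` to machine precision; the Monte-Carlo null calibration
  (10,000 replicates at the 9/12 × 6 design) rejects at 0.050 ± 0.01.
  Jump type is treated as a plain fixed factor, matching the stated
  general-linear-model analysis; a repeated-measures treatment would need a
  mixed model and is deliberately out of scope.
* Bonferroni post-hoc: pairwise Welch t tests, p × (number of pairs), capped
  at 1, gated on a significant main effect at α = 0.05.
* "Down-sampled to 100 Hz" ensemble curves are interpreted as 100-point
  curves resampled on normalized path length: force–displacement loops are
  curves, not time series, and path-length parameterization makes member
  curves commensurable before point-wise averaging.

## 4. Open design points, resolved

* **Countermovement depth** was not standardized in the emulated protocol
  ("jump as high as possible" was the only instruction); templates expose
  depth as a free parameter with a realistic default (~0.23 m COM descent).
* **Filtered vs raw force for COM work**: the default follows the filtered
  convention (`com_filter = TRUE`); the physics acceptance checks run with
  filtering disabled because their tolerances (1 %) are tighter than the
  filter's passband ripple on impact-rich drop-jump force.
* **Mean-of-ratios vs ratio-of-means**: group tables report mean ± SD of
  per-subject ratios (matching the reporting convention), with
  ratio-of-means emitted alongside; the two differ on asymmetric groups and
  the tests construct such a counterexample.
* **Config format** is JSON (not YAML): no YAML parser is part of the
  package's minimal dependency set, and `jsonlite` round-trips the config
  losslessly for hashing and provenance.

## 5. Known limitations

Planar inverse dynamics against a 3-D functionally calibrated model has an
unquantifiable residual here; it is acknowledged, not modeled. The foot never
leaves flat contact before takeoff, so ankle work is underrepresented
relative to human push-off. The simulator's controller is a servo, not a
muscle model: no activation dynamics, no tendon elasticity, no
stretch-shortening potentiation — drop-jump performance gains from elastic
return are absent by construction, which is precisely why the negative work
bookkeeping is clean.
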