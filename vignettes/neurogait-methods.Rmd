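---
title: "neurogait: model, controller, reward, and numerical methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{neurogait: model, controller, reward, and numerical methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurogait)
```

neurogait simulates human walking predictively: a planar musculoskeletal
plant is driven by a reflex controller whose 37 parameters — together with
12 initial-state parameters — are found by CMA-ES against a footstep-based
reward. No reference trajectories enter anywhere; gait emerges from the
interaction of muscle mechanics, reflex laws, contact, and the reward. This
vignette records the model equations, every tunable that matters, the
numerical choices, and the design decisions that were genuinely open.

## The plant

### Skeleton

Seven rigid segments — HAT (head, arms, trunk and pelvis as one body),
left/right thigh, shank and foot — connected by frictionless revolute
joints. Generalized coordinates (9):

| index | coordinate | unit | convention |
|---|---|---|---|
| 1–2 | pelvis x, y | m | hip joint centre in the world frame |
| 3 | pelvis pitch | rad | anterior tilt positive |
| 4–6 | right hip, knee, ankle | rad | flexion / dorsiflexion positive |
| 7–9 | left hip, knee, ankle | rad | flexion / dorsiflexion positive |

The three base coordinates are the planar floating base; the six joint
angles are the internal DOF. Knee flexion is positive with the
hyperextension stop at 0° (range 0–120°); hips move in −30–120° and ankles
in −60–40°. Outside these ranges a soft stop applies a linear restoring
torque (300 N·m/rad) with resisting damping (5 N·m·s/rad) — walking
controllers rely on the hyperextension stop for stance-knee support, and a
smooth penalty keeps the dynamics integrable.

Segment orientations are linear in `q`, so the angular Jacobians are
constant and the equations of motion `M(q) q̈ = τ` are assembled from COM
Jacobians by plain summation (`M = Σ mᵢ JᵢᵀJᵢ + Iᵢ wᵢwᵢᵀ`); the velocity
bias enters through the rotated-chain second derivatives. The mass matrix
is verified in the tests against an independent finite-difference Jacobian
oracle at random configurations.

Default anthropometry is a 1.80 m, 75 kg adult. Segment masses must close
to total body mass, which fixes the HAT (including pelvis) at ≈ 46 kg
(≈ 61%) once standard thigh/shank/foot fractions are used — the values
match the planar 18-muscle gait-model family in common use. All defaults
live in `default_model_config()` and are plain list entries.

### Contact

Two contact points per foot (heel at (−0.06, −0.07) m and toe at
(0.19, −0.07) m in the ankle frame). Normal force is Hunt–Crossley,
`k·δ^1.5·(1 + c·δ̇)` clamped at ≥ 0, with k = 8·10⁴ N/m^1.5 and
c = 1.0 s/m; friction is Coulomb regularized by a tanh in the sliding
velocity (μ = 0.9, v_smooth = 0.05 m/s). These are conventional gait-
simulation values: k gives ~6 mm static penetration under body weight,
and the tests require standing GRF to balance weight within 1%. No claim
is made of matching any particular engine's contact response.

### Muscles

18 Hill-type muscle-tendon units with rigid (non-compliant) tendons:
fiber length is `l_mt − l_slack` with `l_mt` linear in the joint angles
through constant signed moment arms. Force:

`F = MIF · ( a · f_L(l̃) · f_V(ṽ) + f_PE(l̃) )`, clamped at ≥ 0,

with `l̃ = (l_mt − l_slack)/l_opt` and `ṽ = v_mt/(v_max · l_opt)`
(shortening negative).

* `f_L`: Gaussian `exp(−((l̃−1)/0.45)²)`.
* `f_V`: Hill hyperbola `(1+ṽ)/(1−ṽ/K)` for ṽ ∈ [−1, 0] with K = 0.25,
  and a slope-matched saturating eccentric branch with plateau 1.5.
* `f_PE`: exponential engaging at l̃ > 1, reaching one normalized force at
  strain 0.6 (shape constant 4).
* Activation: first-order dynamics `ȧ = (e − a)/τ`, τ_act = 10 ms rising,
  τ_deact = 40 ms falling, integrated by its exact exponential solution.
  Pennation is neglected (2-D model, rigid tendon, second-order effect).
* `v_max` = 10 optimal lengths/s for all muscles.

**Operating ranges with rigid tendons.** With a rigid tendon every
millimetre of MTU excursion strains the fiber, so where each muscle sits on
its force–length curve at the reference posture is a first-order modelling
decision. `standing_lnorm` anchors it: extensors that are stretched by
flexion (VAS 0.80, RF 0.80, GMAX 0.85) start on the ascending limb so that
physiological excursions (knee to 120° flexion, hip to 0.8 rad) end near
l̃ ≈ 1.3–1.5 rather than deep in the exponential passive region; muscles
whose excursions are small or bidirectional sit near optimal (ILPSO 1.00,
TA 0.95, BFSH 1.05). Optimal fiber lengths were chosen jointly with these
anchors (e.g. VAS l_opt = 0.11 m) so passive forces at extreme postures
stay in the hundreds of newtons, which is the physiological order. The
`tune_ref_lengths()` utility renormalizes the anchors for any other
posture.

## The controller

A deterministic reflex policy maps delayed proprioception (per-muscle
normalized force and fiber length, delayed one 10 ms control step — the
hallmark latency of spinal feedback), trunk pitch and pitch rate, joint
angles/rates and per-leg contact load share to 18 excitations, clamped to
[0.01, 1] (a small tonic floor keeps muscles numerically alive). The 37
bilaterally shared parameters and the laws they enter are listed in
`?controller_param_names` and `?compute_excitations`. In brief:

* **Stance**: positive force feedback on SOL, GAS, VAS (load-bearing
  reflexes); a VAS overextension guard and knee-extension damping; TA
  length feedback with reciprocal inhibition from SOL force; HAM/GMAX
  force feedback; a trunk PD signal scaled by leg load and routed to hip
  extensors (HAM, GMAX) when the trunk is forward of its target and to
  ILPSO when behind; a push-off boost to the trailing leg's SOL/GAS/ILPSO
  in double support.
* **Swing**: ILPSO length feedback (fires as the hip extends), HAM force
  feedback, BFSH damping of fast knee extension, and PD tracking of swing
  knee and ankle targets through the VAS/BFSH and SOL/TA antagonist pairs.

Bilateral sharing is assumed (the odd parameter count is naturally
explained by shared scalars), and there are no hip ab/adduction channels
in a sagittal model. Stance/swing switching is a 20 N threshold on the
vertical GRF; in double support, the trailing leg is the one loaded
longer (tie-break: the right leg). The controller is a pure function —
identical inputs give bit-identical outputs — and leg-mirrored inputs give
leg-mirrored outputs, both enforced by tests.

## The MDP and reward

One control step is Δt = 0.01 s (10 integrator substeps). An episode:
`reset` poses the skeleton from the 12 initial-state parameters (forward
and rightward speed, pelvis height, trunk lean, bilateral hip
abduction/flexion, knee, ankle; the planar plant documents rightward speed
and hip abduction as no-ops), initializes activations at the controller's
baseline excitations, and runs until the horizon or until pelvis height
< 0.6 m. Per step the survival reward Δt accrues; at each completed
footstep — the interval between initial contacts of alternating feet
(20 N rising crossing after ≥ 50 ms unloaded) — the footstep reward is
added:

`w_steps·Σ Δt − w_vel·|Σ(v_pel − v_tgt)Δt| − w_pel·Σ θ_pel²Δt − w_mul·Σ_k Σ e_k²Δt`

with weights (10, 60, 20, 1). Two wordings of the velocity cost are
defensible — the integrated signed deviation (deviation of distance
travelled) or the integral of the absolute deviation; the signed form is
implemented as the primary definition since it is the one the closed-form
fixture uses, and the trailing partial footstep is always discarded. The
survival term carries no weight of its own. `v_pel` is the horizontal
pelvis velocity and `θ_pel` the pelvis pitch from vertical — the only
planar readings consistent with "pelvis tilt". When no target speed is
set (self-selected protocol) the velocity cost is omitted entirely.

The accounting identity `total = R_alive + Σ footstep rewards` holds to
1e-12 on every trace, and a 50-step hand-computable footstep fixture pins
the arithmetic (components 0.5 / 0.125 / 0.005 / 0.36, reward −2.96).

## Optimization

Standard (μ/μ_w, λ) CMA-ES (full covariance, cumulative step-size
adaptation, rank-one + rank-μ updates) maximizing episode reward over the
49 parameters in a normalized [0,1]⁴⁹ box mapped affinely to physical
bounds (gains [0,3], length offsets [0.5,1.5] l_opt, target angles within
joint ranges, baselines [0,0.3], initial speed [0.5,2.0] m/s, pelvis
height [0.85,1.05] m). Normalization matters: CMA-ES adapts fastest when
coordinates share scale. σ₀ = 0.25 for cold starts (mean drawn uniformly
in the box under the run seed) and 0.05 for warm starts. Candidates are
clamped onto the box before evaluation; the distribution is updated with
the unclamped samples. A diverged simulation returns the sentinel −10⁶ so
optimization continues. All candidates of a generation are sampled before
any is evaluated, and the objective is deterministic, so results are
bit-identical for any worker count; parallel evaluation uses forked
workers. Single-process CMA-ES with parallel candidate evaluation replaces
cloud-style island schemes — determinism and desk reproducibility are worth
more here than wall-clock.

Protocols: the self-selected-speed run drops the velocity cost over a 20 s
horizon and reports the mean speed over the final 10 s (the steady
portion; startup is excluded by construction). The speed sweep solves the
1.45 m/s anchor cold, then warm-starts outward neighbor-by-neighbor across
{1.10, 1.27, 1.45, 1.62, 1.80} m/s — the named grid points plus a fifth
interpolated symmetrically into the stated 1.1–1.8 m/s range. The weakness
protocol scales SOL or GAS MIF bilaterally to 0.8 or 0.6 (one muscle per
run, four runs), warm-starts from the 1.45 m/s solution, and refuses to
run cold — re-learning from scratch would confound the weakness effect
with optimization noise. Every run's manifest (config snapshot + hash,
master seed, package version) suffices to re-run it bit-identically.

## Numerical choices

* **Integrator**: fixed-step semi-implicit Euler, h = 1 ms, 10 substeps
  per control interval — deterministic and robust with stiff contact. The
  contact and joint-stop *damping* terms are treated implicitly:
  `(M − hD)Δv = h·rhs` with `D = ∂F/∂q̇` (negative semidefinite, so the
  system stays SPD). This matters because the tanh friction
  regularization has slope μN/v_smooth ≈ 3·10³ N·s/m under body weight,
  which an explicit update at h = 1 ms cannot stabilize on the 1.25 kg
  foot; the implicit treatment leaves the conservative (contact-free)
  dynamics untouched.
* **Conservation audit**: with contact and stops disabled and the pelvis
  pinned (the `base_pinned` flag realizes a suspension), the passive chain
  is conservative; the tests require < 0.1% energy drift over 5 s at
  h = 10⁻⁴ s (measured: ~0.004%). An unpinned "suspended" model free-falls,
  where the staggered velocity grid of symplectic Euler shows the textbook
  ½g²ht energy offset — pinning is what makes the test measure integrator
  quality rather than that bookkeeping artifact.
* **Static equilibrium**: found by root-solving the generalized passive
  force residual (not accelerations) over the symmetric coordinates, with
  a 1-D vertical pre-solve sinking the pelvis until contact carries body
  weight. Force residuals avoid two traps: the light foot's row of M⁻¹
  amplifies noise, and above ground the acceleration residual is a flat
  free-fall plateau that strands local search.
* **Degenerate inputs**: airborne feet produce exactly zero force; a
  non-positive fiber length produces zero active force plus a geometry
  flag; zero-variance curves make correlation an explicit error, never a
  silent 0; traces with fewer than two initial contacts yield an empty
  cycle list with a notice; episodes stepped past `done` raise a contract
  error.
* **Events**: all gait events come from GRF threshold crossings (20 N,
  50 ms debounce) — GRF is exact in simulation, so kinematic event
  heuristics would only add noise. The first gait cycle is discarded as a
  startup transient; toe-off within a cycle is the last unloading not
  followed by reloading (which collapses threshold chatter to one event).

## The synthetic-trace generator

`make_trace()` builds episode traces with alternating square-wave GRFs
(integer control-step arithmetic, so loaded/unloaded boundaries never
jitter by a float rounding), prescribed pelvis speed/tilt profiles and
excitation levels, plus ground-truth labels (initial-contact rows, cycle
count, toe-off fraction) known by construction. It deliberately bypasses
the physics: it exercises the reward, footstep, segmentation and ensemble
bookkeeping in isolation, which is what makes their tests exact. A passing
analysis suite therefore certifies the *bookkeeping*, not the realism of
simulated gait; the physics layer is certified separately (conservation,
balance, oracle comparisons), and the realism of full-scale optimized gait
is a multi-hour empirical question outside the test suite's scope.

## Problem sizes in the shipped tests

The suite runs in a few minutes on one CPU: mass-matrix checks at 100
random configurations (oracle comparison on 10), 5 s conservation at
h = 10⁻⁴, 1 s standing hold, CMA-ES quadratic recovery in 10-D at λ = 16
for 200 generations, and a reduced training run (popsize 8, 30
generations, 4 s horizon, v_tgt = 1.3 m/s) asserting only a learning
signal: the best reward strictly improves on generation 0 and the best
episode outlives the generation-0 mean survival. Walking quality is not
asserted at this budget. `scripts/acceptance.R` recomputes all of these
from scratch under a caller-supplied seed.

## Known limitations

Sagittal plane only — no frontal/transverse DOF, arms, or compliant spine,
so balance in 3-D is out of reach by construction. Constant moment arms
make MTU lengths linear in joint angles; real moment arms vary with
posture, which mostly matters at extreme flexion. Rigid tendons transfer
all excursion to the fibers (addressed via the operating-range anchors
above, but a compliant-tendon equilibrium would be the higher-fidelity
choice). Reflex-driven planar models are known to reproduce hip and knee
kinematics far better than ankle kinematics, and nothing here exempts this
implementation. Metabolic cost, joint reaction forces, and noisy
experimental event detection are out of scope.
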