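# neurogait

Predictive, reference-free simulation of human walking in R: a planar
musculoskeletal model driven by a spinal-reflex controller, trained by
evolutionary search against a footstep-based reward — no motion-capture
data anywhere in the loop.

## Who this is for

Biomechanists and neuromechanics researchers who want a desk-scale,
fully-reproducible sandbox for predictive gait simulation: how reflex gains
shape kinematics, how walking adapts to imposed speeds, and how muscle
weakness (e.g. plantarflexor weakness relevant to many gait pathologies)
propagates into compensation patterns — all without tracking experimental
trajectories.

## The model

**Plant.** A sagittal-plane skeleton with 7 segments (head-arms-trunk-pelvis,
thighs, shanks, feet), 9 degrees of freedom (planar floating base x/y/pitch
plus flexion-extension at hips, knees, ankles), compliant Hunt–Crossley
contact at a heel and toe point per foot, and soft physiological joint
stops. 18 Hill-type muscle-tendon units (ILPSO, GMAX, HAM, RF, VAS, BFSH,
GAS, SOL, TA per leg) with first-order activation dynamics, rigid tendons,
Gaussian force–length, Hill force–velocity, exponential passive curves, and
constant signed moment arms:

F = MIF · ( a · f_L(l̃) · f_V(ṽ) + f_PE(l̃) ),  τ_j = Σ_k r_kj · F_k

**Policy.** A deterministic reflex controller π : S → A with exactly 37
bilaterally shared parameters — stance force feedback (SOL, GAS, VAS, HAM,
GMAX), swing length feedback (ILPSO, TA), velocity feedback, a trunk-balance
PD law distributed over hip muscles by leg load, swing knee/ankle PD
targets, per-muscle co-stimulation, and a double-support push-off boost.
Sensory force/length channels are delayed by one 10 ms control step.

**Reward.** Episodes accrue a survival reward of Δt = 0.01 s per step and a
reward per completed footstep (interval between alternating initial
contacts):

r = R_alive + Σ_steps ( w_steps·r_steps − w_vel·J_vel − w_pel·J_pel − w_mul·J_mul )

with r_steps = Σ Δt, J_vel = |Σ (v_pel − v_tgt) Δt|, J_pel = Σ θ_pel² Δt,
J_mul = Σ_k Σ e_k² Δt and default weights (10, 60, 20, 1). Episodes end at
the horizon or when the pelvis drops below 0.6 m.

**Optimization.** CMA-ES over the 49-dimensional vector (37 controller + 12
initial-state parameters) in a normalized unit box, population 16,
deterministic under a single master seed, with warm-start seeding between
protocol stages (speed sweep neighbors, weakness runs).

**Analysis.** Gait-cycle segmentation from GRF threshold crossings (20 N,
50 ms debounce), 101-point normalization to percent gait cycle,
stance-normalized vertical GRF in body-weight units, ensemble mean ± SD,
toe-off timing, and Pearson correlation against user-supplied reference
kinematics (CSV).

## Worked example

```r
library(neurogait)

model <- build_model()                      # default 75 kg / 1.80 m adult
model
#> <gait_model> planar biped
#>   segments: 7 (total mass 74.5 kg)
#>   DOF: 9 (3 floating base + 6 internal)
#>   muscles: 18 Hill-type, rigid tendon
#>   contact: Hunt-Crossley, k = 8e+04 mu = 0.9

# reduced-budget training (popsize 8, 30 generations, 4 s horizon)
sm  <- smoke_opt_config()
opt <- optimize_gait(model, v_tgt = 1.3, horizon = sm$horizon,
                     popsize = sm$popsize, generations = sm$generations,
                     seed = 1)
opt$reward_history$best[1]   # generation-0 best:   0.89
opt$best_reward              # final best-ever:     4.1215

tr <- run_episode(model, opt$controller, opt$init, sm$horizon, v_tgt = 1.3)
max(tr$time)                 # best episode survives the full 4 s horizon
```

The generation-0 candidates fall after ~0.8 s on average; after 30
generations the best candidate stands/steps through the whole horizon and
begins collecting footstep reward (best reward 4.12 > the 4.0 ceiling of
pure survival). Full-scale budgets (popsize 16, 1000 generations, 10–20 s
horizons — hours of CPU) are what the walking protocols
`run_self_selected()`, `run_speed_sweep()` and `run_weakness()` are built
for; all are deterministic given their master seed.

The reward arithmetic is exactly checkable by hand: a 50-step footstep at
v_pel ≡ 1.2 m/s against v_tgt = 1.45, θ_pel ≡ 0.1 rad, all excitations 0.2
gives r_steps = 0.5, J_vel = 0.125, J_pel = 0.005, J_mul = 0.36, reward
10·0.5 − 60·0.125 − 20·0.005 − 0.36 = **−2.96** (see
`reference_footstep_fixture()`).

## Command line

```sh
Rscript inst/cli/neurogait.R train    --target-speed 1.45 --full --out run_145
Rscript inst/cli/neurogait.R sweep    --speeds 1.10,1.27,1.45,1.62,1.80 --full
Rscript inst/cli/neurogait.R weakness --muscle SOL --mif-scale 0.8 \
        --seed-solution run_145/params.json
Rscript inst/cli/neurogait.R simulate --params run_145/params.json
Rscript inst/cli/neurogait.R analyze  --trace run_145/trace.csv --reference ref.csv
```

Every run writes a `manifest.json` (config snapshot + hash, master seed,
package version) sufficient to re-run it bit-identically.

## Limitations

Sagittal plane only (no hip ab/adduction, no arms); constant moment arms
and rigid tendons; ankle kinematics of reflex-driven planar models are
known to be less realistic than hip/knee. The methods vignette
(`vignettes/neurogait-methods.Rmd`) documents the model, the parameter
choices and their rationale, and what the test suite does and does not
establish about real gait.
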