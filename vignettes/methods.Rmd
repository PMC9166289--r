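---
title: "Models and methods: actor-critic agents, decision-variable maps, and encoding models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rlrep)
```

`rlrep` implements, end to end, the computational pipeline of a comparative
study of representation learning: advantage actor-critic (A2C) agents are
trained on a simulated object-manipulation task, decision variables
(state value, policy, diverse-density subgoal) are estimated from
trajectories, hidden-unit and neuronal tuning is classified against those
variables with permutation nulls, and a Poisson encoding model relates
activity to task predictors. A synthetic-data module generates mouse-like
behavioral sessions and neural populations with planted ground truth so
that every stage can be validated without any recorded data.

This vignette documents the models, the tunable parameters and their
defaults, the numerical choices, and the places where the design was
genuinely open and a decision had to be made. It states no empirical
result beyond what the package's tests and acceptance script compute.

## The task environment

The base task is a 1.0 x 1.0 arena with a central 0.4 x 0.4 reward zone
(reward 1). The state is the object's position and its previous
displacement, a 4-vector `(x, y, vx, vy)`. The action space has 65
entries: a no-movement action plus 8 directions x 8 speeds. Per-direction
speed multipliers `(0.6, 0.2, 0.6, 1.0, 0.6, 0.2, 0.6, 1.0)` (for angles
0..315 degrees) reproduce the anisotropy of a joystick rig in which
movement is easiest along the top-left/bottom-right diagonal. Positions
are clamped at the arena edge; trials end on reward-zone entry or at a
300-step cap.

**Speed scale.** Speed magnitudes are a free parameter of the simulation.
The default is 8 evenly spaced values in `[0.02, 0.15]` arena units per
step, so a straight crossing takes roughly 7-50 steps. This scale is a
deliberate choice: with much slower speeds, trials last hundreds of steps,
discounted returns are of order `gamma^150 ~ 1e-3`, and the policy-gradient
signal is orders of magnitude smaller than the entropy bonus at the
grid's entropy coefficients -- the policy then provably equilibrates at
uniform (we verified this with full-length training runs and an exact
finite-difference gradient check). At the default scale expert agents
finish trials in a handful of steps and discounted returns approach 1,
the regime the training recipe assumes.

Variants: `two_reward` splits the zone into a right half (reward 1) and a
left half (reward 0.1); `subgoal` adds a 0.2 x 0.2 zone whose intrinsic
reward of 1 is collectable once per trial without ending it; `two_room`
is a 2.0 x 4.0 arena split by a 0.2-thick vertical divider with a
0.4-long door at its middle (door region x in [0.9, 1.1], y in
[1.8, 2.2]), reward zone at the bottom-right corner, and starts confined
to the left room. Wall collisions stop motion at the earliest
segment-rectangle intersection (a slab test), so the divider can never be
crossed outside the door. The two-room arena uses a 1500-step cap: its
shortest start-to-goal path is ~3.5 units, which no exploratory
trajectory completes in 300 steps; the cap extension plays the same role
as the two-room discount adjustment (`gamma` 0.99 instead of 0.95).

The open-loop wrapper replaces every commanded action with a draw from a
private seeded uniform stream, leaving reward and termination rules
untouched -- the analysis-side model of the decoupled-joystick condition.

## A2C: objective, estimation, optimization

The actor head emits 65 logits; the critic head a scalar value. Shared
architectures feed both heads from one trunk of 1-4 rectified hidden
layers (64 units each by default; width is a free architecture choice
and is recorded in every result object); separate architectures use
two trunks. The actor's output bias is initialized so the initial policy
gives probability 0.75 to the no-movement action, reproducing the
dominant stillness of early behavior on the rig.

Advantages use generalized advantage estimation:
`delta_t = r_t + gamma V(s_{t+1})(1 - done) - V(s_t)` and
`A_t = sum_k (gamma lambda)^k delta_{t+k}` with `lambda = 0.95`,
accumulated over `n_steps` rollout windows (1, 4 or 8) across 16
synchronous workers. The total loss is

```
L = beta_critic * mean((V - y)^2) + beta_actor * (-mean(log pi(a|s) A))
    - beta_entropy * mean(H(pi(.|s)))
```

with `y = A + V` and the advantage treated as a constant in the actor
term. Two conventions are worth stating explicitly. First, the entropy
term enters with a negative sign (an exploration *bonus*): minimizing `L`
raises entropy, the standard A2C form. Second, every term is a batch
*mean* rather than a sum, so the loss scale does not depend on the batch
layout; the coefficients absorb the constant. Optimization is RMSprop
(rate 1e-4, alpha 0.99, epsilon 1e-5) with the global gradient norm
clipped at 0.5. The forward/backward pass is written directly in matrix
algebra; a finite-difference check (relative error < 1e-4) is part of the
test suite. Dropout, when configured, is active only in the update's
forward pass -- action selection, evaluation and probing run with it off.

The hyperparameter grid crosses shared/separate, depth 1-4, dropout
location (none, a layer index, all) and fraction (0, 0.2, 0.4), critic
coefficient (0, 0.1, 0.2), entropy coefficient (0, 0.2, 0.4) and rollout
length (1, 4, 8); after collapsing no-dropout duplicates and the
one-layer "all" alias the grid has 1620 distinct configurations, trained
with 4 seeds each in the full design (6480 runs).

**The selected configuration.** Model selection ranks agents by the sum
of min-max-normalized state-value fraction, policy fraction and
sparseness. In this implementation's environment the score is maximized
by the shared 3-layer network with deep-layer dropout (0.2), critic
coefficient 0.2 and rollout 8 -- and entropy coefficient 0: at the
training budgets used here, entropy 0.2 leaves the policy too soft for
value or policy coding to emerge, while entropy 0 lets it commit.
`selected_config()` records this choice and exposes the coefficient.

Evaluation runs 300 trials by default, sampling from the policy (greedy
selection is available but sampling is the default, matching the
training-time behavior). Both the hit rate (equal to the undiscounted
mean return in the unit-reward task) and the mean discounted return are
reported.

## Decision-variable maps

**State value.** The empirical state value of a spatial bin is the mean
over visits of `R_T * gamma_a^(T - t)` (terminal reward times discounted
time-to-end); miss trials contribute 0, reward-zone bins are fixed at 1,
and unvisited bins are `NA`, never 0. The analysis discount `gamma_a` is
a property of the *map*, not of the agent: it should make
`gamma_a^(trial duration)` span a useful range. For 10-ms mouse-like
trajectories the conventional value is 0.99 (a 2-s trial then discounts
to ~0.13); for expert agents whose trials last a handful of steps the
package analyses use `gamma_a = 0.9`, which plays the same role at the
agent's duration scale. With the agent's training discount (0.95 per
step) and very short trials the map compresses into a narrow band near 1
and single long exploratory trials dominate the visited-bin averages --
an instability we observed directly and avoided by this choice. For the
two-reward variant the terminal rewards 1 / 0.1 enter scaled as
1.25 / 0.125, matching the relative water volumes of the original
two-reward design.

**Policy.** The policy map is the per-bin resultant (vector sum) of all
movement vectors originating in the bin, reported as preferred direction
and magnitude, with unit vectors for display. Movement vectors are one
step for agents and a 100-ms window for 10-ms mouse-like data.

**Diverse density.** A bin scores high when successful trajectories pass
near it and unsuccessful ones avoid it: per-point proximities
`p = exp(-d^2)` combine into per-trial joint probabilities
(`1 - prod(1 - p)` for hits, `prod(1 - p)` for misses) whose product over
trials is the DD, returned as a log (sums of `log1p(-p)` terms avoid
underflow; a naive triple-loop oracle verifies the vectorized
implementation to 1e-10). Distances are measured in units of the spatial
bin size, the convention of the original diverse-density subgoal work.
This is load-bearing: with arena-normalized distances the kernel spans
the whole arena, the miss-side product dominates, and the argmax
degenerates to the corner farthest from the unsuccessful mass (we
verified this empirically); cell-scale kernels localize the score and
recover bottleneck structure. `discover_subgoal()` additionally restricts
candidate bins to visited bins outside a margin (default 0.8 units)
around extrinsic reward zones, since every successful trajectory
terminates at the goal and the goal funnel otherwise always wins -- the
same exclusion the subgoal-discovery literature applies.

**Efficiency.** The per-trial efficiency ratio divides path length
(sampled at a coarser stride, 100 ms for mouse-like data) by the
straight-line distance from the start to the nearest point of the reward
zone. Surrogate "shuffled" trajectories resample observed movement
vectors (excluding edge-clipped ones) cumulatively from real start
points, clamping at edges step by step.

## Tuning, classification, and population statistics

Hidden-unit spatial tuning is probed with uniform random states (default
100,000; position uniform over the arena, velocity uniform over the
achievable per-step range) on a 40 x 40 grid; a unit is *active* if any
probe elicits a strictly positive response (exact zero is meaningful
under rectifying activations, which is why the package fixes ReLU).
Probes are drawn up front so results are independent of batch
partitioning. Trajectory-aligned tuning (`agent_samples()`,
`activity_samples()`) is the occupancy-normalized mean per visited bin
and is the basis of all classifications, because the permutation null --
a per-point permutation of the samples' spatial bin labels -- must be
computed on the same footing as the observed statistic. The alternative
readings of "shuffling the spatial bins of trajectories" (coherent map
rotations, block permutations) were considered; per-point label
permutation is the strictest exchangeable null and is what we implement,
seeded.

Classification against a reference map (state value, occupancy, or log
DD) uses the Pearson correlation over visited bins, one-tailed
permutation p-values with the `+1` floor, and Benjamini-Hochberg control
at `q = 0.05` within each call (one family per target and population).
Constant tunings are excluded with a reason code rather than scored.
Policy classification follows the conjunctive recipe: a unit's 8-bin
direction tuning is correlated with the agent's movement-direction
distribution in the unit's top-5% most active spatial bins (weighted by
normalized activity; the threshold is a strict quantile with at least one
bin guaranteed), with direction-label permutations as the null. The
velocity test is two-stage -- one-way ANOVA across the 8 direction bins,
then a correlation between binned speed and activity at the preferred
direction -- both at `P < 0.05`.

One subtlety of direction statistics deserves emphasis. Movements clamped
at the arena boundary carry inward-distorted directions, and merely
excluding the clamped movements selects against outward movements near
edges -- either way, position and movement direction become coupled, and
spatially tuned units then acquire spurious "policy" correlations (most
visibly, they survive the open-loop control). Direction statistics
therefore use only samples farther from every edge than the largest
observed displacement (capped at 20% of the smaller arena dimension),
a direction-independent criterion under which no clamping can occur.

Spatial coherence is the correlation between each bin and the mean of its
up-to-8 available neighbors (constant maps are defined as coherence 0).
The border index contrasts the maximal fractional border coverage of the
z > 1 activity field with the mean bin-distance of field bins to their
nearest border (border-adjacent bins count as distance 0), normalized by
the larger arena dimension.

Chance-level classified fractions are estimated by running the same
pipeline on the spatial raised-cosine basis maps (place-field proxies
tiling the arena). Peak-location statistics (quadrant enrichment,
two-reward side preference) break ties to the first bin in row-major
order. Retention analysis cross-tabulates stage-1 categories against
stage-2 activity and category membership for identical unit sets. Region
scoring assigns ranks 1 (worst) to R (best) per variable with ties
sharing the mean rank; variables with missing cells are dropped for all
regions.

## The Poisson encoding model

Task variables -- trial onset/offset flags, reward onsets, object and
joystick velocity (8 direction channels carrying movement magnitude), and
object position -- live on the imaging frame clock (5.67 Hz), with
native-rate channels down-sampled by within-frame averaging. Temporal
variables are convolved with evenly spaced raised-cosine bases
(onset/offset: 6 over +-2 s; velocity: 6 per direction; reward: 9 over
-2..+4 s; half-width equal to the center spacing, unit-sum normalized);
position is expanded onto 100 separable raised-cosine bumps (10 x 10,
peak 1) evaluated at the frame's coordinates. The default design has
exactly 217 columns, z-scored (constant columns are left at zero).

Fitting is a Poisson GLM with elastic-net penalty (`alpha = 0.9`) over a
path of up to 100 lambdas via `glmnet`, with 5-fold cross-validation on
*contiguous* folds of a *contiguous* leading 70% training block -- both
choices respect temporal autocorrelation; random-frame splits would leak.
The lambda minimizing mean CV deviance is chosen (a 1-SE rule was the
other candidate; minimum-deviance is fixed and recorded). Performance is
the pseudo-explained variance `1 - D(yhat) / D(ybar)` on the held-out 30%
block, with `D` the Poisson deviance from the saturated model and the
null model the training-block mean.

Task-relatedness compares the observed pseudo-E.V. against refits on
block-permuted predictors (2-s blocks, `ceiling(2 * frame_rate)` = 12
frames at 5.67 Hz, permuted as whole blocks so within-block structure
survives; refits reuse the chosen lambda). Variable contributions refit
the model without one predictor group (a fresh lambda search, i.e. a true
partial model, not weight-zeroing) and test the pseudo-E.V. drop against
group-column block shuffles, BH-corrected across the six variables.
Response profiles exponentiate a group's weighted basis combination over
its domain with the other groups factored out; a zero-weight group gives
a flat profile of 1.

## Synthetic sessions and populations

`gen_trajectory()` simulates the object path on a 10-ms grid: speeds
resampled every 300 ms from the 1.4-21.3 cm/s range used for velocity
binning, headings drifting toward the target (reward zone, or first a
corner waypoint) with Gaussian noise, or a persistent random walk in the
open-loop-like random mode; the per-direction bias weights scale
displacement. Waypoint-mode paths steer around the reward zone until the
waypoint has been visited, so at least 80% of hit trials pass within the
stated radius. Trials are separated by a 4-s reward period and 2-s
intertrial interval during which the object is stationary; the trial cap
defaults to 30 s (the task maximum of 5 min is accepted but makes miss
trials needlessly long). Behavior channels are rendered at 2000 Hz by
linear interpolation (joystick = object velocity + noise when coupled; an
independent random process in random mode); the rate is configurable and
analyses at 200-500 Hz are statistically indistinguishable, which the
test suite exploits for speed.

`gen_units()` draws archetype parameters -- place (2D Gaussian), border,
velocity (von Mises direction x linear speed), value-coding (rate
proportional to the session's state-value map), policy-coding
(conjunctive space x direction), mixed, and null -- with
signal-to-noise ratio `snr` scaling peak modulation over the baseline
rate (defaults 3 and 0.5 events/s). `render_activity()` draws per-frame
Poisson counts with mean `rate / frame_rate`: calcium dynamics and
deconvolution are deliberately not simulated; the counts stand in for
deconvolved event signals directly. Every generator is a pure function of
its seed.

What passing tests on these data do and do not show: the generator
emulates trial structure, movement bias, waypoint behavior and planted
tuning, but not calcium-indicator dynamics, slow drifts, correlated
population noise, or behavioral idiosyncrasies of real mice -- so
recovery results certify the pipeline's statistical machinery, not its
performance on raw imaging data.

## Scaled experiment protocols

Two composite experiments are packaged with fixed desk-scale protocols
(sizes chosen once; the full-scale designs simply raise the same knobs):

* `staged_training()` trains the selected configuration on the base task
  and reads out, at the naive (1.6e3 steps), intermediate (1.6e4) and
  expert (default 4e5) checkpoints: evaluation statistics, the
  active-unit fraction, and the state-value- and policy-classified
  fractions (200 evaluation trials, 200 permutations, 2e4 probe states by
  default; the full design uses 300 trials, 1000 permutations, 1e5
  probes).
* `subgoal_experiment()` runs the two-room comparison: one exploration
  agent (6e4 steps, entropy 0.2 so the policy stays mobile), DD subgoal
  discovery from 40 trials at a 3000-step cap, then paired continuation
  arms (default 8 seeds x 2e5 steps, entropy 0.05 -- large enough to
  prevent the occasional collapse of a fully greedy policy, small enough
  to let the intrinsic-reward gradient commit) with the intrinsic reward
  at the discovered zone versus an extrinsic reward doubled to 2. The
  sample-efficiency metric is the mean undiscounted episode return over
  the continuation phase (the area under the learning curve at a matched
  budget). The discovered zone defaults to 0.4 x 0.6 around the DD peak,
  covering the post-door funnel that all successful trajectories
  traverse.

## Known limitations

* **Distributed value coding.** The critic's spatial value surface
  converges slowly at the 1e-4 learning rate and, across every
  regime we probed (speed scales, widths 16-64, dropout on/off, budgets
  to 1.5e6 steps, analysis discounts 0.9-0.99), individual hidden units
  never correlate with the empirical value map beyond `|r| ~ 0.35`, even
  when the critic output itself tracks it: the value readout stays
  distributed across weakly tuned, near-planar units. Unit-level
  state-value classification of agent networks therefore returns
  chance-level fractions here, and learning signatures that depend on it
  are reported as computed rather than assumed. Planted value-coding
  units in synthetic populations are recovered with high sensitivity, so
  this is a property of the trained networks, not of the classifier.
* **Power ceiling of the policy test.** The policy classification
  correlates two 8-point vectors and permutes direction labels for its
  null; with 8 points the null correlation spread is ~0.38 regardless of
  sample size, so permutation p-values bottom out near 5e-3 and BH
  control over small families sits on a cliff. Measured sensitivity for
  planted conjunctive units at SNR 3 is ~0.5 (with zero false positives);
  this bounds the method, not the implementation.
* The interleaved-reward retention analysis is provided as a recipe
  (trial-subset GLM fits composed with `retention_analysis()`), not a
  dedicated operation.
* Training at the full grid scale (6480 runs) is supported but not
  packaged as a single call; `hyper_grid()` plus `train_agent()` compose
  it.
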