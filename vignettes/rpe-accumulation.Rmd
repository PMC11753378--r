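---
title: "Temporally accumulated reward prediction errors: models and analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporally accumulated reward prediction errors: models and analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

In a goal-directed object-manipulation task, a mouse moves an object with a
joystick toward a central reward zone. Individual movements ("strokes") that
approach but fail to reach the zone are *errors*: each one violates a reward
expectation, generating a negative reward prediction error (RPE). When several
errors occur within one trial, a learner with a multi-step eligibility horizon
can accumulate them — the n-th error within a trial is an *n-step error*.
`rpeacc` provides the full computational apparatus to study this idea in three
coupled settings:

1. **Artificial agents** (`arena_config()`, `ppo_config()`, `train_agent()`):
   a PPO actor-critic navigating a 2D arena with a custom non-bootstrapped RPE
   and n-step advantage accumulation.
2. **Behavior** (`detect_strokes()`, `detect_errors()`, `peri_event_lick()`,
   `empirical_state_value()`): extraction of strokes, toward/away errors,
   n-step accumulation onsets, anticipatory licking, and an empirical spatial
   state-value map from 10-ms trajectories.
3. **Neural encoding** (`build_design_matrix()`, `fit_glm()`,
   `classify_error_neuron()`, plus the population statistics in
   `sequential_slope()`, `classify_rpe_sign()`, `region_code_summary()`):
   Poisson elastic-net encoding models of deconvolved calcium traces with
   raised-cosine temporal bases, and permutation/bootstrap population tests.

Because no public recording accession exists for the mouse data this package
was designed around, a synthetic-data generator (`generate_session()`,
`generate_neurons()`) provides ground-truth inputs for every analysis stage;
all quantitative validation is recovery of planted structure.

# The reinforcement-learning model

## Environment

The arena is the closed square $[-1,1]^2$ with a centered $0.4 \times 0.4$
reward zone. The action space has 256 discrete actions: 192 no-ops (75%,
mirroring how often mice leave the object stationary) and 64 movements, 8
directions $\times$ 8 speeds. Step sizes carry a diagonal bias (cardinal
directions 0.216–0.720, the 45°/225° diagonals 0.072–0.240, the 135°/315°
diagonals 0.360–1.200 a.u.); only each range is fixed, so the 8 speed levels
are evenly spaced between each range's endpoints — the simplest scheme
consistent with movement at varying speeds. Trials start from a
uniform random position outside the zone (rejection sampling) and end on zone
entry or after 60 steps. Three reward schedules: *standard* (1.0 on entry),
*interleaved* (1.0 on a random 50% of trials), and *split* (0.125 on the left
zone half, 1.25 on the right).

Each realized movement is classified geometrically: `goal` (zone entered,
closed boundary), `away` (Euclidean distance to the zone center did not
decrease — reinitialization), `toward_short` (distance decreased and the
infinite ray along the displacement meets the zone square, but the step
stopped short), `lateral_miss` (distance decreased but the ray misses the
square). The ray test is the minimal operationalization of the two error
scenarios — not far enough vs. too lateral — and introduces no free
parameters. Moves clamped at the walls are classified by their realized
displacement.

## The single-step RPE and its accumulation

Because a single stroke could in principle reach the goal, the agent treats
every included step as potentially terminal: the RPE is

$$\delta_t = r_t - V(s_t),$$

*without* the bootstrapped $\gamma V(s_{t+1})$ of the canonical TD error.
Away-movements are reinitializations and carry no RPE; zero-displacement steps
are likewise excluded from the RPE sequence, so the $\delta$ sequence contains
exactly the reward-expectation events (approach errors and goal entries),
mirroring the stroke-based behavioral analysis. The n-step advantage is

$$\hat A_t(n) = \sum_{k=0}^{n-1} (\gamma\lambda)^k\, \delta_{t+k},
\qquad \gamma = \lambda = 0.95,$$

truncated at trial end (`accumulate_advantage()`). Advantages are computed
over consecutive windows of $n$ included steps and each window is followed by
10 PPO epochs on that window.

## Training and the critic target

The network is a shared 4-layer, 256-unit rectifier MLP with a softmax policy
head over the 256 actions and a scalar value head, trained with Adam at
$10^{-5}$, a clipped surrogate (ratio clip 0.2), value-loss coefficient 0.2,
entropy coefficient 0.02, and global gradient-norm clip 0.4, for 4000 episodes
at full scale. Expert summaries average the final 10% of episodes; naive
summaries come from evaluation rollouts taken before the first gradient step.
Action selection is stochastic (sampled from the softmax) at training and
evaluation alike.

The non-bootstrapped $\delta$ leaves the critic's regression target open. Two
options are implemented (`ppo_config(value_target = ...)`):

* `"gae"` (default): the advantage-corrected rollout value
  $V(s_t) + \hat A_t$, the return construction used by standard PPO
  implementations.
* `"return"`: the within-trial discounted empirical return over included
  steps.

The default matters. With `"return"`, failure episodes (return 0 everywhere)
drag $V$ toward zero session-wide while any early growth of $V$ makes every
approach movement's RPE negative; empirically the policy collapses into
inaction (success 0.28 naive → 0.04 after 4000 episodes at $n=8$). With
`"gae"`, states whose approaches are persistently punished relax toward zero
value instead of being pinned there by failures, positive goal RPEs propagate
backward over the $n$-step window, and learning proceeds (0.31 → ~0.78
success at $n=8$; $n=1$ learns far less). All shipped analyses use the
default.

## What the agent reproduces

At a reduced scale (1500 episodes; 3 seeds for the n-contrast, 2 per
alternative schedule — the package's test scale, chosen so the full suite
runs within half an hour on one core) the qualitative results are:

* final steps-to-goal decrease with the accumulation horizon ($n=8$ better
  than $n=1$);
* reward-evoked RPEs shrink from naive to expert (reward expectation grows)
  while pre-goal error RPEs become more negative;
* under intermittent reward, expert reward-evoked RPEs stay large, and at
  omissions the RPE equals $-V$ at the goal-entering state exactly;
* under the split schedule, expert state values are higher on the
  high-reward (right) half of the arena, and reward-evoked RPEs are larger on
  the high side.

# Behavioral feature extraction

Trajectories are consumed at 10-ms resolution, positions in mm in a
100 × 100 mm arena with a centered 40 × 40 mm zone. A *stroke* is a movement
whose speed exceeds 60 mm/s, with at least 200 ms separation between peaks
(`pracma::findpeaks`, mirroring the MATLAB function). Errors are peaks of the
differenced distance-to-center series at the same threshold and separation:
distance decreasing → `toward` (unless the movement enters the zone, which
ends the trial), increasing → `away`. Peaks are detected on each signed
direction separately, so the 200-ms separation is enforced within class; the
threshold is applied to peak height (prominence would be an alternative; on
ballistic strokes with stationary pauses the two coincide). Trials shorter
than 200 ms are skipped.

The n-th toward error of a trial (n = 1..6) is the onset of the n-step
accumulation $\delta_t(n)$; accumulation resets at the inter-trial interval.
Error latency is the time from the $(n-1)$-th to the $n$-th error; for $n=1$,
from trial start (the first error has no predecessor). Peri-event lick
histograms use a ±2-s window (matching the GLM basis span), 100-ms bins,
baseline-subtracted at the −50-ms bin, with a comparison scalar equal to the
sum of the five bins after the event; the published normalization modes are
all "divide by the maximum of a reference histogram", so normalization takes
a caller-supplied reference value.

The empirical state value of a spatial bin is the mean of
$R\,\gamma^{T-t}$ over 10-ms visits during rewarded trials ($\gamma = 0.99$
per step, $T$ the rewarded trial end, $R$ the relative reward size, 1.25/0.125
under the split schedule). Unrewarded trials are excluded: the value is
defined through rewarded terminations only.

# The encoding model

Predictors: n-step error onsets (single-frame impulses; the behavioral boxcar
form is used only on the behavior side — the two published definitions
differ, and the GLM-side impulse form is the one used for fitting), object
and joystick velocity (angle discretized into 8 bins carrying speed), and
within-trial frame count. Each series is convolved with 6 raised-cosine
bumps tiling ±2 s: with unit peaks, even spacing 4/9 s, half-width 8/9 s, the
outermost supports end exactly at ±2 s and coverage has no gaps. Columns are
z-scored across the session. Column counts are structural invariants:
138 standard (36 + 48 + 48 + 6), 138 away-control, 114 modified-reward
(two single-step error types × 6 + 96 + 6), 108 modified-reward control.

Traces are nonnegative deconvolved activity; the model predicts activity by
exponentiating the weighted predictor sum, fixing the log link, and the
Poisson deviance is its standard companion — used both in fitting (`glmnet`,
$\alpha = 0.9$ elastic net, 5-fold blocked CV on a contiguous 70% training
block; penalty = CV-deviance minimum along a 30-step path) and in the
held-out pseudo explained variance

$$\text{pseudo-E.V.} = 1 - \frac{D(\hat y)}{D(\bar y)},$$

with $\bar y$ the mean-activity null. The contiguous train/test split avoids
leakage through the ±2-s basis.

Significance is assessed against circular rotations of the predictors by
random multiples of a 2-s block (1000 shuffles), which preserve
autocorrelation; the fitted coefficients are applied to the rotated
predictors, and a variable *contributes* when its own contribution has
positive pseudo-E.V. and the full model beats the 95th percentile of the
rotate-that-variable null (the concrete reading of "removal significantly
reduces performance"). A task-related neuron has positive held-out
pseudo-E.V., beats the all-predictor rotation null at P < 0.05, and has at
least one contributing variable. An error neuron additionally requires: the
error contribution significant; the error-coefficient summary above the
object- and joystick-velocity summaries (the published comparison does not
fix a summary; each group is summarized kernel-wise — per n for errors, per
direction for velocities — by the sum of positive coefficients over the
kernel's 6 basis columns, taking the strongest kernel, which is symmetric
between the 6-column error kernels and the 6-column direction kernels and
empirically rejects velocity-tuned cells that a max-coefficient summary
confuses); error coefficients above the away-control
coefficients from a separate control fit; and excitatory model-derived
response at the assigned n. `assigned_n` is the argmax over n of the per-n
summary. These criteria are deliberately strict; as in the original analysis
they undercount error neurons rather than admit false positives.

# Population statistics

*Sequential activity*: per-trial activity onsets are the first frames where
session-z-scored activity exceeds 2. Neurons are ordered by mean onset in a
random half of trials and the trial-averaged onset rank on the held-out half
is regressed on that order, both normalized to [0, 1] so that slope 1 means
perfectly conserved order. The null shuffles onsets across neurons within
each held-out trial (1000 permutations). Ranks are computed among the neurons
active in that trial, ties broken by frame index.

*RPE sign at trial offset* (interleaved sessions): positive neurons must show
reward-epoch (0–2 s) activity above baseline (−4 to −3.5 s), rewarded above
omission trials, and a post-offset peak above the pre-offset (−2 to 0 s)
peak, each by a one-tailed trial-resampling bootstrap at P < 0.01 (1000
resamples, matching the published procedure's other bootstrap counts);
negative neurons satisfy the mirrored conditions on omission trials.

*Controls and summaries*: reward-evoked responses are baseline-subtracted
(−4 s) means over 0–0.5 s post delivery; the long-trial control compares
error neurons' trial-averaged activity between long trials with and without
errors on a log10 scale; region summaries report per-n fractions of error
neurons normalized to the across-region maximum (regions need more than 5
task-related cells), cross-environment n-bins 1–2 / 3–4 / 5–6 min-max
normalized to [0, 1] (the published bin list "1-2, 3-4, 4-6" once overlaps at
4 — read as the 5–6 typo), and session bootstrap (1000 resamples with
replacement).

# The synthetic-data generator

`generate_session()` emulates the task, not any particular animal: trials are
sequences of ballistic strokes with triangular speed profiles (peak > 60
mm/s; the sharp apex keeps the planted peak sample identifiable under
positional jitter), toward-errors stopping 3–11 mm outside the zone along a
±8°-jittered ray to the center, away reinitializations between approaches,
and a final goal stroke on completed trials. Defaults follow the task
conditions: 60 trials per session (120 interleaved), expert-like profiles
with ~1 toward error per trial and 95% completion versus naive-like with ~3
and 60%, anticipatory lick bursts 100–400 ms after toward errors with
probability equal to the reward-expectation parameter (0.9 expert, 0.5
intermittent, 0.2 naive), and positional jitter of 0.05 mm s.d. — the scale
of LED-tracking noise after 10-ms subsampling. Ground truth records each
planted event's pre-noise radial-speed peak sample.

`generate_neurons()` draws activity from exactly the generative family the
encoding model assumes: scaled Poisson counts with rate
$\exp(\beta_0 + X\beta)$ on the session's z-scored design matrix, with causal
raised-cosine kernels planted on one predictor group per neuron
(default population 500: 180 error-tuned spread over n = 1..6, 95 + 95
velocity-tuned, 60 time-ramp, 60 reward-locked, and flat-noise cells), plus
reward/omission neurons with rate bumps after the relevant trial offsets. The
trace scale (gain 10 on Poisson draws from baseline rate 0.5) puts active
cells above the deconvolved-activity inclusion threshold of 20.

What passing recovery tests does *not* show: the generator has no slow
calcium-indicator kinetics, no correlated population noise, no behavioral
covariates beyond those in the design, and its errors follow planted
Poisson counts rather than a closed-loop policy. Recovery rates on this
generator bound the pipeline's correctness, not its performance on real
recordings.

# Numerical choices and problem sizes

* Training is single-threaded C++ (RcppArmadillo) driven by R's RNG, so runs
  are bit-reproducible from the seed.
* Network initialization is the standard uniform fan-in scheme
  $U(\pm 1/\sqrt{\text{fan-in}})$; Adam uses default moments
  (0.9, 0.999, $\epsilon = 10^{-8}$).
* The test suite trains at a reduced scale — 1500 episodes, 5 seeds for the
  $n \in \{1, 8\}$ contrast, 2 seeds for the interleaved/split schedules —
  the smallest sizes at which the contrasts above are stable across seeds.
* Degenerate inputs are signalled, not silently patched: all-zero traces,
  constant activity (undefined pseudo-E.V.), single-condition sessions for
  RPE-sign classification, sessions in which no neuron crosses the onset
  threshold.
* Ties in onset ranks break by frame index; distance ties in movement
  classification (distance unchanged) count as `away`.

# Known limitations

* The critic-target choice (`"gae"`) is a reconstruction; the source
  description does not pin it down, and the `"return"` alternative is kept
  for comparison.
* Of the loss-ablation properties, only the value-loss one is asserted
  (setting the value-loss coefficient to zero abolishes the learning
  improvement). The entropy-bonus ablation is not asserted: with stochastic
  softmax action selection at evaluation, this implementation does not need
  the entropy term to keep exploring at the scales tested.
* The exact bijection from the 64 movement actions to (direction, speed)
  pairs is unspecified upstream; any consistent mapping is equivalent for
  the analyses here.
* Mouse-level quantitative results (correct rates, neuron fractions, regional
  contrasts) are not reproducible without the original recordings; the
  package validates those pipelines by synthetic recovery only.
* `classify_rpe_sign` needs both rewarded and omission trials, i.e. the
  interleaved schedule.
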