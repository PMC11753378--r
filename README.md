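# rpeacc

Tools for studying **temporally accumulated reward prediction errors (RPEs)**
in a goal-directed object-manipulation task — for computational
neuroscientists who want to simulate the underlying reinforcement-learning
account, extract error events from behavior, and test neural encoding of
accumulated errors, all with a ground-truth synthetic data path.

When a movement approaches a reward zone but stops short, a learner that
expected reward after the movement experiences a negative RPE

    δ = r − V(s)

— deliberately *without* the bootstrapped `γV(s′)` of the canonical TD error,
because a single movement could have reached the goal. The n-th such error
within a trial is an *n-step error*, and a multi-step learner accumulates
them with the generalized-advantage weights

    Â_t(n) = δ_t + (γλ)δ_{t+1} + … + (γλ)^{n−1} δ_{t+n−1},   γ = λ = 0.95.

The package implements, as separate but interoperating stages:

* **`rl_env` / `rl_agent`** — a 2D arena (256 discrete actions, 75% no-ops,
  diagonally biased speeds; standard / intermittent / split reward schedules)
  and a PPO actor-critic (shared 4×256 rectifier MLP, clipped surrogate,
  entropy bonus, Adam) trained on n-step accumulations of the RPE above.
  Training is single-threaded C++ and bit-reproducible from a seed.
  `summarize_rpes()`, `value_map()` and `unit_tuning()` probe trained agents.
* **`behavior`** — stroke detection (> 60 mm/s, 200-ms separation),
  toward/away error detection on the differenced distance-to-center signal,
  n-step accumulation onsets δ_t(n), peri-error lick histograms, correct
  rate, and the empirical spatial state value E[γ^(T−t)] (γ = 0.99 per 10 ms).
* **`encoding_glm`** — raised-cosine temporal bases (6 bumps tiling ±2 s),
  design matrices with exact column structure (138 standard / 138 control /
  114 modified-reward / 108 modified-control), elastic-net Poisson GLMs
  (`glmnet`, α = 0.9, blocked 70/30 split, 5-fold CV), held-out pseudo
  explained variance `1 − D(ŷ)/D(ȳ)`, and strict error-neuron classification
  with per-n assignment.
* **`population_analysis`** — sequential-activity slope with a permutation
  null, positive/negative RPE-sign classification at trial offset,
  reward-evoked activity changes, the long-trial control, and region-level
  n-step code summaries with session bootstraps.
* **`synthetic_data`** — session and neuron generators with planted ground
  truth for every stage.

## Worked example

Generate a naive-like session, detect errors, and fit an encoding model to a
synthetic neuron tuned to the 3-step error:

```r
library(rpeacc)
g  <- generate_session(synth_config(profile = "naive", n_trials = 20L, seed = 7L))
g$session
#> trajectory session: 20 trials (standard schedule), 16896 samples, 172 licks
#>   correct rate: 0.600

ev <- detect_errors(g$session)
ev
#> error events: 75 toward, 61 away over 20 trials
round(error_statistics(ev)$mean_freq, 3)
#>   n1   n2   n3   n4   n5   n6
#> 1.00 0.95 0.65 0.60 0.40 0.15

dm <- build_design_matrix(ev, g$session)
dm
#> design matrix (standard): 1445 frames x 138 predictors

nr  <- generate_neurons(g$session, ev, types = c(error = 6, noise = 2),
                        design = dm, seed = 2L)
fit <- fit_glm(nr$activity[3, ], dm)
fit
#> Poisson elastic-net encoding fit: 138 predictors, 32 nonzero,
#> held-out pseudo-E.V. 0.9590

fit  <- classify_task_related(fit, dm, nr$activity[3, ])
ctrl <- fit_glm(nr$activity[3, ], build_design_matrix(ev, g$session,
                                                      variant = "control"))
fit  <- classify_error_neuron(fit, ctrl)
fit$error_related; fit$assigned_n
#> TRUE
#> 3        # the planted n
```

The per-trial error frequencies fall off with n (errors accumulate to high n
only in long, error-rich trials), the held-out pseudo-E.V. near 1 reflects
the high planted signal, and the classifier recovers the planted 3-step
tuning while rejecting velocity and control accounts.

Train an agent with an 8-step horizon at reduced scale and summarize its RPE
dynamics:

```r
rec <- train_agent(arena_config("standard"),
                   ppo_config(n_step = 8L, episodes = 1500L, seed = 1L))
summary(rec)
#> Naive -> expert summaries
#>   success rate: 0.303 -> 0.687
#>   steps-to-goal: 26.68 -> 26.16
#>   reward-evoked RPE: 1.030 -> 0.412
#>   pre-goal RPE: 0.029 -> -0.185
```

The success rate more than doubles while reward-evoked RPEs shrink (the
critic learns to expect reward) and approach errors acquire negative RPEs —
the learning signature the n-step accumulation account predicts. (Naive
steps-to-goal averages only the rare lucky successes, so the success rate is
the better naive-performance measure.)

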