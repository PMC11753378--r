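# memoized fixtures shared across test files (built once per test run)
.fx <- new.env(parent = emptyenv())

# small naive-like session with detected events and design matrices
fx_small <- function() {
  if (is.null(.fx$small)) {
    g <- generate_session(synth_config(profile = "naive", n_trials = 15L,
                                       seed = 101L))
    ev <- detect_errors(g$session)
    .fx$small <- list(
      g = g, session = g$session, ev = ev,
      dm = build_design_matrix(ev, g$session),
      dmc = build_design_matrix(ev, g$session, variant = "control"))
  }
  .fx$small
}

# a handful of synthetic neurons on the small session
fx_neurons <- function() {
  if (is.null(.fx$neurons)) {
    fx <- fx_small()
    .fx$neurons <- generate_neurons(
      fx$session, fx$ev,
      types = c(error = 6, objvel = 2, joyvel = 2, time = 1, noise = 3),
      design = fx$dm, seed = 7L)
  }
  .fx$neurons
}

# reduced-scale training runs shared by the agent-level acceptance checks:
# 3 seeds x n in {1, 8} on the standard schedule, 1200 episodes each
fx_rl_standard <- function() {
  if (is.null(.fx$rl_std)) {
    arena <- arena_config("standard")
    runs <- list()
    for (n in c(1L, 8L)) {
      for (sd in 1:3) {
        key <- sprintf("n%d_s%d", n, sd)
        runs[[key]] <- train_agent(arena, ppo_config(
          n_step = n, episodes = 1200L, naive_episodes = 200L, seed = sd))
      }
    }
    .fx$rl_std <- runs
  }
  .fx$rl_std
}

fx_rl_sched <- function(schedule, seeds = 1:2) {
  key <- paste0("rl_", schedule)
  if (is.null(.fx[[key]])) {
    arena <- arena_config(schedule)
    .fx[[key]] <- lapply(seeds, function(sd)
      train_agent(arena, ppo_config(n_step = 8L, episodes = 1200L,
                                    naive_episodes = 200L, seed = sd)))
  }
  .fx[[key]]
}

expert_steps_to_goal <- function(rec) {
  ex <- rpeacc:::expert_slice(rec)
  # failures count at the full step budget, so the mean is defined even for
  # poor learners
  mean(ex$steps)
}

# hand-built single-trial session: positions (mm) on the 10-ms grid
manual_session <- function(x, y, completed = TRUE, rewarded = completed,
                           reward_size = 1, licks = numeric(),
                           schedule = "standard") {
  n <- length(x)
  t <- (seq_len(n) - 1L) * 0.01
  trajectory_session(
    trajectory = data.frame(trial = 1L, t = t, x = x, y = y),
    trials = data.frame(trial = 1L, t_start = 0, t_end = t[n],
                        completed = completed, rewarded = rewarded,
                        reward_size = reward_size),
    licks = licks, schedule = schedule)
}

# build a population with a planted activation order: neuron j fires a burst
# j seconds after each trial start (plus optional jitter), on a 5.67-Hz grid
planted_sequence <- function(n_neurons = 10L, n_trials = 12L, jitter = 0,
                             seed = 1L) {
  set.seed(seed)
  rate <- 5.67
  trial_len <- n_neurons + 4
  starts <- (seq_len(n_trials) - 1L) * (trial_len + 2)
  frame_times <- seq(0, max(starts) + trial_len + 1, by = 1 / rate)
  act <- matrix(0, n_neurons, length(frame_times))
  for (i in seq_len(n_trials)) {
    for (j in seq_len(n_neurons)) {
      t0 <- starts[i] + j + stats::rnorm(1, 0, jitter)
      sel <- frame_times >= t0 & frame_times <= t0 + 0.4
      act[j, sel] <- 10
    }
  }
  act <- act + matrix(abs(stats::rnorm(length(act), 0, 0.05)), nrow(act))
  trials <- data.frame(trial = seq_len(n_trials), t_start = starts,
                       t_end = starts + trial_len,
                       completed = TRUE, rewarded = TRUE, reward_size = 1)
  list(activity = act, frame_times = frame_times, trials = trials)
}

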