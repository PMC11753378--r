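#' Configuration of the PPO actor-critic
#'
#' The agent is a multilayer perceptron shared between the actor and the
#' critic (four hidden layers of 256 rectified-linear units by default) with a
#' softmax policy head over the 256 discrete actions and a scalar value head.
#' It is trained with a clipped-surrogate PPO objective whose advantages are
#' n-step accumulations of a non-bootstrapped single-step RPE,
#' \eqn{\delta_t = r_t - V(s_t)}: because a single movement could in principle
#' reach the goal, the discounted value of the next state is not subtracted as
#' it would be in the canonical TD error. Steps on which the agent moves away
#' from the reward zone carry no RPE.
#'
#' @param n_step horizon of the advantage accumulation (1, 2, 4, 6 or 8 in the
#'   sweep; any integer >= 1 is accepted).
#' @param episodes training episodes (default 4000).
#' @param naive_episodes evaluation rollouts of the untrained agent used for
#'   the naive summaries (taken before the first gradient step).
#' @param hidden integer vector of hidden-layer widths.
#' @param learning_rate Adam learning rate (default 1e-5).
#' @param gamma,lambda discount and accumulation-decay factors (defaults 0.95).
#' @param clip_eps PPO probability-ratio clip (default 0.2).
#' @param max_grad_norm global gradient-norm clip (default 0.4).
#' @param value_coef,entropy_coef loss coefficients for the critic and the
#'   entropy bonus (defaults 0.2 and 0.02; the policy-loss coefficient is 1).
#' @param update_epochs PPO epochs per n-step window (default 10).
#' @param expert_window fraction of final episodes averaged for the expert
#'   summaries (default 0.1, i.e. episodes 3600-4000 of a 4000-episode run).
#' @param value_target critic regression target: `"gae"` (advantage-corrected
#'   rollout value, the standard PPO return; default) or `"return"` (the
#'   within-trial discounted empirical return).
#' @param seed integer seed; the whole run is bit-reproducible given the seed.
#' @return an object of class `"ppo_config"`.
#' @export
ppo_config <- function(n_step = 1L, episodes = 4000L, naive_episodes = 300L,
                       hidden = c(256L, 256L, 256L, 256L),
                       learning_rate = 1e-5, gamma = 0.95, lambda = 0.95,
                       clip_eps = 0.2, max_grad_norm = 0.4,
                       value_coef = 0.2, entropy_coef = 0.02,
                       update_epochs = 10L, expert_window = 0.1,
                       value_target = c("gae", "return"), seed = 1L) {
  value_target <- match.arg(value_target)
  stopifnot(n_step >= 1L, episodes >= 1L, clip_eps > 0, clip_eps < 1,
            gamma >= 0, lambda >= 0, value_coef >= 0, entropy_coef >= 0,
            max_grad_norm >= 0, learning_rate > 0, update_epochs >= 1L,
            expert_window > 0, expert_window <= 1)
  structure(list(n_step = as.integer(n_step), episodes = as.integer(episodes),
                 naive_episodes = as.integer(naive_episodes),
                 hidden = as.integer(hidden), learning_rate = learning_rate,
                 gamma = gamma, lambda = lambda, clip_eps = clip_eps,
                 max_grad_norm = max_grad_norm, value_coef = value_coef,
                 entropy_coef = entropy_coef,
                 update_epochs = as.integer(update_epochs),
                 expert_window = expert_window, value_target = value_target,
                 seed = as.integer(seed)),
            class = "ppo_config")
}

#' Single-step reward prediction error
#'
#' \eqn{\delta = r - V(s)} for movements that approach the reward zone
#' (`toward_short`, `lateral_miss`) or reach it (`goal`). Movements away from
#' the zone are treated as reinitialization and carry no RPE (`NA` is
#' returned); zero-displacement steps likewise contribute no RPE event.
#'
#' @param reward realized reward at the step.
#' @param value critic estimate \eqn{V(s)} of the current state.
#' @param movement_class one of `"none"`, `"toward_short"`, `"lateral_miss"`,
#'   `"away"`, `"goal"`.
#' @return the scalar RPE, or `NA_real_` for excluded classes.
#' @export
single_step_rpe <- function(reward, value, movement_class) {
  stopifnot(is.finite(value))
  if (movement_class %in% c("toward_short", "lateral_miss", "goal"))
    reward - value
  else
    NA_real_
}

#' Accumulate single-step RPEs into n-step advantages
#'
#' Computes \eqn{\hat A_t(n) = \sum_{k=0}^{n-1} (\gamma\lambda)^k
#' \delta_{t+k}} for every position of an RPE trace, truncating the sum at the
#' end of the trace (trial end). With \eqn{n = 1} or \eqn{\lambda = 0} this
#' reduces to \eqn{\hat A_t = \delta_t}.
#'
#' @param delta numeric vector of single-step RPEs from the included steps of
#'   one trial.
#' @param n accumulation horizon (>= 1).
#' @param gamma,lambda discount and decay factors.
#' @return numeric vector of advantages, same length as `delta`.
#' @export
accumulate_advantage <- function(delta, n, gamma = 0.95, lambda = 0.95) {
  if (length(delta) == 0) stop("`delta` must be nonempty")
  if (n < 1) stop("`n` must be >= 1")
  gl <- gamma * lambda
  m <- length(delta)
  out <- numeric(m)
  for (t in seq_len(m)) {
    kmax <- min(n - 1, m - t)
    out[t] <- sum(gl^(0:kmax) * delta[t + 0:kmax])
  }
  out
}

.schedule_code <- function(schedule) {
  match(schedule, c("standard", "interleaved", "split")) - 1L
}

#' Train a PPO agent in the arena
#'
#' Runs the full training loop: stochastic rollouts, single-step RPEs at
#' included steps (away-movements excluded), n-step advantage accumulation
#' over consecutive windows of included steps, and clipped-surrogate PPO
#' updates (Adam, 10 epochs per window). The critic regresses onto the
#' within-trial discounted empirical return. Naive evaluation rollouts are
#' taken before the first gradient step.
#'
#' @param arena an [arena_config()].
#' @param config a [ppo_config()].
#' @return an object of class `"training_record"`: a list with `episodes` and
#'   `naive_episodes` data frames (per-episode steps, success, rewards, RPE
#'   summaries), `params` (expert parameters), `naive_params`, and the two
#'   configurations.
#' @export
train_agent <- function(arena, config) {
  stopifnot(inherits(arena, "arena_config"), inherits(config, "ppo_config"))
  set.seed(config$seed)
  res <- cpp_train_ppo(
    schedule = .schedule_code(arena$schedule), n_step = config$n_step,
    episodes = config$episodes, naive_episodes = config$naive_episodes,
    hidden = config$hidden, lr = config$learning_rate, gamma = config$gamma,
    lambda = config$lambda, clip_eps = config$clip_eps,
    max_grad_norm = config$max_grad_norm, value_coef = config$value_coef,
    entropy_coef = config$entropy_coef, update_epochs = config$update_epochs,
    max_steps = arena$max_steps, reward_standard = arena$reward_standard,
    reward_split_low = arena$reward_split_low,
    reward_split_high = arena$reward_split_high,
    reward_interleaved_prob = arena$reward_interleaved_prob,
    value_target = match(config$value_target, c("gae", "return")) - 1L)
  structure(list(episodes = res$episodes,
                 naive_episodes = res$naive_episodes,
                 params = res$params, naive_params = res$naive_params,
                 arena = arena, config = config),
            class = "training_record")
}

expert_slice <- function(record) {
  ep <- record$episodes
  e0 <- floor(nrow(ep) * (1 - record$config$expert_window)) + 1L
  ep[ep$episode >= e0, , drop = FALSE]
}

#' @method print training_record
#' @export
print.training_record <- function(x, ...) {
  ex <- expert_slice(x)
  cat("PPO training record\n")
  cat(sprintf("  schedule: %s, n-step: %d, episodes: %d, seed: %d\n",
              x$arena$schedule, x$config$n_step, nrow(x$episodes),
              x$config$seed))
  cat(sprintf("  naive success rate: %.3f (%d eval episodes)\n",
              mean(x$naive_episodes$success), nrow(x$naive_episodes)))
  cat(sprintf("  expert success rate: %.3f, expert mean steps-to-goal: %.2f\n",
              mean(ex$success),
              mean(ex$steps[ex$success == 1])))
  invisible(x)
}

#' @method summary training_record
#' @export
summary.training_record <- function(object, ...) {
  out <- summarize_rpes(object)
  ex <- expert_slice(object)
  out$expert_success <- mean(ex$success)
  out$expert_steps <- mean(ex$steps[ex$success == 1])
  out$naive_success <- mean(object$naive_episodes$success)
  out$naive_steps <- mean(object$naive_episodes$steps[
    object$naive_episodes$success == 1])
  class(out) <- "summary.training_record"
  out
}

#' @method print summary.training_record
#' @export
print.summary.training_record <- function(x, ...) {
  cat("Naive -> expert summaries\n")
  cat(sprintf("  success rate: %.3f -> %.3f\n", x$naive_success,
              x$expert_success))
  cat(sprintf("  steps-to-goal: %.2f -> %.2f\n", x$naive_steps,
              x$expert_steps))
  cat(sprintf("  reward-evoked RPE: %.3f -> %.3f\n",
              x$naive$reward_evoked, x$expert$reward_evoked))
  cat(sprintf("  pre-goal RPE: %.3f -> %.3f\n",
              x$naive$pregoal, x$expert$pregoal))
  invisible(x)
}

#' @method plot training_record
#' @export
plot.training_record <- function(x, span = 101L, ...) {
  ep <- x$episodes
  s <- stats::filter(ep$steps, rep(1 / span, span), sides = 2)
  plot(ep$episode, ep$steps, col = "grey80", pch = 16, cex = 0.3,
       xlab = "episode", ylab = "steps to trial end", ...)
  graphics::lines(ep$episode, s, lwd = 2)
  invisible(x)
}

rpe_block_summary <- function(ep, schedule) {
  goal <- ep[ep$success == 1, , drop = FALSE]
  rewarded_goal <- goal[goal$reward > 0, , drop = FALSE]
  out <- list(
    reward_evoked = if (nrow(rewarded_goal)) mean(rewarded_goal$rpe_goal) else NA_real_,
    reward_evoked_rpes = rewarded_goal$rpe_goal,
    pregoal = if (any(!is.na(ep$pregoal_rpe_mean)))
      mean(ep$pregoal_rpe_mean, na.rm = TRUE) else NA_real_,
    pregoal_rpes = ep$pregoal_rpe_mean[!is.na(ep$pregoal_rpe_mean)])
  if (schedule == "interleaved") {
    om <- goal[goal$rewarded == 0, , drop = FALSE]
    out$omission = if (nrow(om)) mean(om$rpe_goal) else NA_real_
    out$omission_rpes <- om$rpe_goal
    out$omission_v_goal <- om$v_goal
  }
  if (schedule == "split") {
    hi <- goal[goal$goal_side > 0, , drop = FALSE]
    lo <- goal[goal$goal_side < 0, , drop = FALSE]
    out$reward_evoked_high <- if (nrow(hi)) mean(hi$rpe_goal) else NA_real_
    out$reward_evoked_low <- if (nrow(lo)) mean(lo$rpe_goal) else NA_real_
    out$high_rpes <- hi$rpe_goal
    out$low_rpes <- lo$rpe_goal
  }
  out
}

#' Naive and expert RPE summaries of a training run
#'
#' Extracts reward-evoked RPEs (at goal attainment) and pre-goal RPEs (at
#' toward-type errors, where \eqn{\delta = -V}) for the naive agent (before
#' the first update) and the expert agent (final-window episodes). Under the
#' interleaved schedule omission RPEs are reported separately (at an omitted
#' reward \eqn{\delta = -V(s)} at the goal-entering state); under the split
#' schedule reward-evoked RPEs are stratified by arena half (high/low side).
#'
#' @param record a `"training_record"` from [train_agent()].
#' @return a list with elements `naive` and `expert`, each carrying the
#'   summary means and the per-episode RPE vectors.
#' @export
summarize_rpes <- function(record) {
  stopifnot(inherits(record, "training_record"))
  schedule <- record$arena$schedule
  if (!any(record$episodes$success == 1))
    warning("no goal events in training episodes; expert summary undefined")
  list(naive = rpe_block_summary(record$naive_episodes, schedule),
       expert = rpe_block_summary(expert_slice(record), schedule),
       schedule = schedule)
}

#' Map of the critic's state-value estimates
#'
#' Evaluates the critic on uniformly sampled states and averages the outputs
#' in a 40 x 40 grid over the arena.
#'
#' @param params a parameter list from a `"training_record"` (`$params` or
#'   `$naive_params`).
#' @param n_samples number of random states (default 100000).
#' @param bins grid resolution per axis.
#' @return an object of class `"value_map"`: list with `value` (bins x bins
#'   matrix, `NA` for empty bins), `count`, and bin `breaks`.
#' @export
value_map <- function(params, n_samples = 100000L, bins = 40L) {
  X <- matrix(stats::runif(2L * n_samples, -1, 1), ncol = 2L)
  v <- cpp_forward(params, X)$value
  breaks <- seq(-1, 1, length.out = bins + 1L)
  ix <- findInterval(X[, 1], breaks, rightmost.closed = TRUE)
  iy <- findInterval(X[, 2], breaks, rightmost.closed = TRUE)
  idx <- (iy - 1L) * bins + ix
  sums <- rowsum(v, idx)
  cnts <- rowsum(rep(1L, n_samples), idx)
  value <- matrix(NA_real_, bins, bins)
  count <- matrix(0L, bins, bins)
  pos <- as.integer(rownames(sums))
  value[pos] <- sums / cnts
  count[pos] <- cnts
  structure(list(value = value, count = count, breaks = breaks),
            class = "value_map")
}

#' @method print value_map
#' @export
print.value_map <- function(x, ...) {
  cat(sprintf("state-value map: %d x %d bins, mean value %.4f\n",
              nrow(x$value), ncol(x$value), mean(x$value, na.rm = TRUE)))
  invisible(x)
}

#' Mean critic value inside a region of a value map
#'
#' @param map a [value_map()].
#' @param xlim,ylim region limits in arena units.
#' @return mean of the non-empty bins whose centers fall in the region.
#' @export
map_region_mean <- function(map, xlim = c(-0.2, 0.2), ylim = c(-0.2, 0.2)) {
  ctr <- (map$breaks[-1] + map$breaks[-length(map$breaks)]) / 2
  sel_x <- ctr >= xlim[1] & ctr <= xlim[2]
  sel_y <- ctr >= ylim[1] & ctr <= ylim[2]
  mean(map$value[sel_x, sel_y], na.rm = TRUE)
}

#' Spatial and direction tuning of final-hidden-layer units
#'
#' For each unit of the last hidden layer, computes a spatial activity map
#' (mean activation over states in each spatial bin) and an 8-direction
#' profile: the unit's mean activity associated with each movement direction,
#' weighted by the policy's probability mass on that direction in each state.
#'
#' @param params a parameter list from a `"training_record"`.
#' @param n_samples number of probe states.
#' @param bins spatial grid resolution.
#' @return list with `spatial` (bins x bins x units array) and `direction`
#'   (units x 8 matrix; columns are directions 0, 45, ..., 315 degrees).
#' @export
unit_tuning <- function(params, n_samples = 20000L, bins = 40L) {
  X <- matrix(stats::runif(2L * n_samples, -1, 1), ncol = 2L)
  fw <- cpp_forward(params, X)
  H <- fw$hidden                      # n x units
  tab <- build_action_table()
  move <- !is.na(tab$direction_deg)
  dir_of <- tab$direction_deg[move] / 45
  P <- fw$probs[, move, drop = FALSE] # n x 64
  n_units <- ncol(H)
  direction <- matrix(0, n_units, 8L)
  for (d in 0:7) {
    w <- rowSums(P[, dir_of == d, drop = FALSE])
    direction[, d + 1L] <- colSums(H * w) / sum(w)
  }
  breaks <- seq(-1, 1, length.out = bins + 1L)
  ix <- findInterval(X[, 1], breaks, rightmost.closed = TRUE)
  iy <- findInterval(X[, 2], breaks, rightmost.closed = TRUE)
  idx <- (iy - 1L) * bins + ix
  cnts <- rowsum(rep(1L, n_samples), idx)
  sums <- rowsum(H, idx)
  spatial <- array(NA_real_, c(bins, bins, n_units))
  pos <- as.integer(rownames(sums))
  for (u in seq_len(n_units)) {
    m <- matrix(NA_real_, bins, bins)
    m[pos] <- sums[, u] / cnts
    spatial[, , u] <- m
  }
  list(spatial = spatial, direction = direction)
}

#' Evaluate frozen agent parameters
#'
#' Rolls out episodes with the stored (stochastic) policy without any
#' learning, returning the same per-episode record as training.
#'
#' @param record a `"training_record"`.
#' @param which `"expert"` or `"naive"` parameters.
#' @param episodes number of evaluation episodes.
#' @param seed RNG seed for the evaluation rollouts.
#' @return per-episode data frame.
#' @export
evaluate_agent <- function(record, which = c("expert", "naive"),
                           episodes = 200L, seed = 1L) {
  which <- match.arg(which)
  params <- if (which == "expert") record$params else record$naive_params
  arena <- record$arena
  set.seed(seed)
  cpp_evaluate_policy(params, .schedule_code(arena$schedule), episodes,
                      arena$max_steps, arena$reward_standard,
                      arena$reward_split_low, arena$reward_split_high,
                      arena$reward_interleaved_prob)
}
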