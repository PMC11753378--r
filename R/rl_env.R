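#' Arena configuration for the reinforcement-learning task
#'
#' Builds the configuration of the 2D navigation arena in which agents move an
#' object from a random start position into a central reward zone. The arena is
#' the closed square \[-1, 1\] x \[-1, 1\] (arbitrary units) with a centered
#' 0.4 x 0.4 reward zone. Three reward schedules are supported:
#' \describe{
#'   \item{standard}{reaching the zone delivers a reward of 1.0 on every trial.}
#'   \item{interleaved}{a reward of 1.0 is delivered on a randomly interleaved
#'     50\% of trials; on the remaining trials reaching the zone ends the trial
#'     without reward (reward omission).}
#'   \item{split}{the zone is split into halves: entering the left half yields
#'     a low reward (0.125), the right half a high reward (1.25).}
#' }
#'
#' @param schedule one of `"standard"`, `"interleaved"`, `"split"`.
#' @param max_steps maximum number of steps per trial (default 60).
#' @param reward_standard reward on goal under the standard schedule.
#' @param reward_interleaved_prob probability a trial is rewarded under the
#'   interleaved schedule.
#' @param reward_split_low,reward_split_high rewards for the left (low) and
#'   right (high) halves of the zone under the split schedule.
#' @return an object of class `"arena_config"`.
#' @export
arena_config <- function(schedule = c("standard", "interleaved", "split"),
                         max_steps = 60L,
                         reward_standard = 1.0,
                         reward_interleaved_prob = 0.5,
                         reward_split_low = 0.125,
                         reward_split_high = 1.25) {
  schedule <- match.arg(schedule)
  stopifnot(max_steps >= 1L,
            reward_standard >= 0, reward_split_low >= 0, reward_split_high >= 0,
            reward_interleaved_prob >= 0, reward_interleaved_prob <= 1)
  structure(list(
    bound = 1.0,
    zone_half = 0.2,
    schedule = schedule,
    max_steps = as.integer(max_steps),
    reward_standard = reward_standard,
    reward_interleaved_prob = reward_interleaved_prob,
    reward_split_low = reward_split_low,
    reward_split_high = reward_split_high
  ), class = "arena_config")
}

#' Discrete action table with a diagonal speed bias
#'
#' The action space has 256 entries. The first 192 (75\%) produce no movement,
#' mimicking the large fraction of time mice spend not moving the object. The
#' remaining 64 map onto 8 directions (0, 45, ..., 315 degrees) x 8 speed
#' levels. Step magnitudes are direction dependent (diagonal bias): cardinal
#' directions span 0.216-0.720 a.u., the 45/225-degree diagonals span
#' 0.072-0.240, and the 135/315-degree diagonals span 0.360-1.200. The eight
#' speed levels are evenly spaced from each direction's minimum to its maximum.
#'
#' @return a data frame with one row per action id (0-255) and columns
#'   `action`, `dx`, `dy`, `direction_deg` (NA for no-movement actions),
#'   `speed_level`, `magnitude`.
#' @export
build_action_table <- function() {
  n_noop <- 192L
  dirs <- seq(0, 315, by = 45)
  speed_range <- function(deg) {
    if (deg %% 90 == 0) c(0.216, 0.720)
    else if (deg %in% c(45, 225)) c(0.072, 0.240)
    else c(0.360, 1.200)           # 135, 315
  }
  rows <- vector("list", 64L)
  k <- 1L
  for (d in dirs) {
    rng <- speed_range(d)
    mags <- seq(rng[1], rng[2], length.out = 8L)
    for (s in seq_len(8L)) {
      theta <- d * pi / 180
      rows[[k]] <- data.frame(
        action = n_noop + k - 1L,
        dx = mags[s] * cos(theta),
        dy = mags[s] * sin(theta),
        direction_deg = d,
        speed_level = s,
        magnitude = mags[s]
      )
      k <- k + 1L
    }
  }
  noop <- data.frame(action = seq_len(n_noop) - 1L, dx = 0, dy = 0,
                     direction_deg = NA_real_, speed_level = NA_integer_,
                     magnitude = 0)
  out <- rbind(noop, do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

in_zone <- function(pos, zone_half) {
  abs(pos[1]) <= zone_half && abs(pos[2]) <= zone_half
}

# Infinite-ray / axis-aligned-square intersection (slab method). The ray
# starts at p and runs along d; returns TRUE if it meets the closed square
# [-h, h]^2 at any t >= 0.
ray_hits_zone <- function(p, d, h) {
  tmin <- -Inf; tmax <- Inf
  for (ax in 1:2) {
    if (abs(d[ax]) < 1e-15) {
      if (p[ax] < -h || p[ax] > h) return(FALSE)
    } else {
      t1 <- (-h - p[ax]) / d[ax]
      t2 <- ( h - p[ax]) / d[ax]
      tmin <- max(tmin, min(t1, t2))
      tmax <- min(tmax, max(t1, t2))
    }
  }
  tmax >= max(tmin, 0)
}

#' Reset the arena to a new trial
#'
#' Draws a uniform start position over the arena excluding the reward zone
#' (rejection sampling) and initializes per-trial state. Under the interleaved
#' schedule the trial's rewarded flag is drawn here.
#'
#' @param config an [arena_config()].
#' @return a list with elements `pos` (length-2 numeric), `step` (0), and
#'   `rewarded` (logical; `TRUE` except on unrewarded interleaved trials).
#' @export
arena_reset <- function(config) {
  stopifnot(inherits(config, "arena_config"))
  repeat {
    pos <- stats::runif(2, -config$bound, config$bound)
    if (!in_zone(pos, config$zone_half)) break
  }
  rewarded <- if (config$schedule == "interleaved")
    stats::runif(1) < config$reward_interleaved_prob else TRUE
  list(pos = pos, step = 0L, rewarded = rewarded)
}

#' Advance the arena by one action
#'
#' Applies the displacement of `action_id`, clamps the next position to the
#' arena bounds, classifies the realized movement, and assigns reward and
#' termination. Movement classes:
#' \describe{
#'   \item{none}{zero displacement.}
#'   \item{goal}{the movement enters the reward zone (closed boundary).}
#'   \item{away}{distance to the zone center did not decrease
#'     (reinitialization; carries no single-step RPE downstream).}
#'   \item{toward_short}{distance decreased and the heading ray intersects the
#'     zone, but the step stopped short of it.}
#'   \item{lateral_miss}{distance decreased but the heading ray misses the
#'     zone (aimed too laterally).}
#' }
#' A clamped move is classified by its realized displacement. Termination
#' occurs on goal entry or when the step budget is exhausted.
#'
#' @param pos current position (length-2 numeric, within bounds).
#' @param action_id integer in 0-255.
#' @param config an [arena_config()].
#' @param trial_state the list returned by [arena_reset()] (fields `step`,
#'   `rewarded`), updated across calls by the caller.
#' @param action_table the table from [build_action_table()]; pass it in to
#'   avoid rebuilding per step.
#' @return a list (`transition`): `prev_pos`, `next_pos`, `action`, `reward`,
#'   `terminal`, `movement_class`, and the updated `trial_state`.
#' @export
arena_step <- function(pos, action_id, config, trial_state,
                       action_table = build_action_table()) {
  if (!is.numeric(action_id) || length(action_id) != 1L ||
      is.na(action_id) || action_id < 0 || action_id > 255)
    stop("action_id must be a single integer in [0, 255]")
  d <- c(action_table$dx[action_id + 1L], action_table$dy[action_id + 1L])
  nxt <- pmin(pmax(pos + d, -config$bound), config$bound)
  realized <- nxt - pos
  trial_state$step <- trial_state$step + 1L

  h <- config$zone_half
  if (all(realized == 0)) {
    cls <- "none"
  } else if (in_zone(nxt, h)) {
    cls <- "goal"
  } else {
    d_prev <- sqrt(sum(pos^2))
    d_next <- sqrt(sum(nxt^2))
    if (d_next >= d_prev) {
      cls <- "away"
    } else if (ray_hits_zone(pos, realized, h)) {
      cls <- "toward_short"
    } else {
      cls <- "lateral_miss"
    }
  }

  reward <- 0
  if (cls == "goal") {
    reward <- switch(config$schedule,
      standard = config$reward_standard,
      interleaved = if (trial_state$rewarded) config$reward_standard else 0,
      split = if (nxt[1] < 0) config$reward_split_low else config$reward_split_high)
  }
  terminal <- cls == "goal" || trial_state$step >= config$max_steps

  list(prev_pos = pos, next_pos = nxt, action = as.integer(action_id),
       reward = reward, terminal = terminal, movement_class = cls,
       trial_state = trial_state)
}

#' Roll out one episode with a supplied policy
#'
#' Convenience driver used in tests and examples: repeatedly samples an action
#' id from `policy(pos)` and advances the arena until the trial terminates.
#'
#' @param config an [arena_config()].
#' @param policy function taking the current position and returning an action
#'   id; defaults to uniform random actions.
#' @return a data frame with one row per step: `step`, `x`, `y`, `action`,
#'   `reward`, `class`, `terminal`.
#' @export
run_episode <- function(config, policy = function(pos) sample(0:255, 1L)) {
  tab <- build_action_table()
  st <- arena_reset(config)
  pos <- st$pos
  rows <- list()
  repeat {
    a <- policy(pos)
    tr <- arena_step(pos, a, config, st, tab)
    st <- tr$trial_state
    rows[[length(rows) + 1L]] <- data.frame(
      step = st$step, x = tr$next_pos[1], y = tr$next_pos[2],
      action = tr$action, reward = tr$reward, class = tr$movement_class,
      terminal = tr$terminal)
    pos <- tr$next_pos
    if (tr$terminal) break
  }
  do.call(rbind, rows)
}
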