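#' Configuration of the synthetic session generator
#'
#' The generator emulates the object-manipulation task: trial-structured 2D
#' trajectories built from ballistic strokes (raised-cosine speed profiles
#' whose peaks exceed the 60 mm/s stroke threshold), toward-type errors that
#' stop short of the reward zone, away-type reinitialization movements,
#' anticipatory lick bursts locked 100-400 ms after toward errors with a
#' probability set by the reward-expectation parameter, and reward schedules
#' matching the arena task (standard / interleaved / split).
#'
#' @param schedule reward schedule.
#' @param profile `"expert"` (few errors, high reward expectation), `"naive"`
#'   (many errors, low expectation) or `"ir"` (expert-like errors, interleaved
#'   schedule, intermediate expectation).
#' @param n_trials trials per session; defaults to 60, or 120 under the
#'   interleaved schedule.
#' @param error_rate mean toward errors per trial (Poisson, capped at 6);
#'   defaults 1 (expert/ir) or 3 (naive).
#' @param away_rate mean extra away movements per trial beyond the structural
#'   reinitialization after each non-final error.
#' @param p_correct probability a trial reaches the reward zone; defaults
#'   0.95 (expert/ir) or 0.6 (naive).
#' @param reward_expectation probability of an anticipatory lick burst after
#'   a toward error; defaults 0.9 (expert), 0.5 (ir), 0.2 (naive).
#' @param noise_mm positional jitter s.d. (mm) added to every 10-ms sample.
#' @param frame_rate imaging frame rate (Hz) used downstream.
#' @param seed integer seed; output is bit-reproducible given the seed.
#' @return an object of class `"synth_config"`.
#' @export
synth_config <- function(schedule = c("standard", "interleaved", "split"),
                         profile = c("expert", "naive", "ir"),
                         n_trials = NULL, error_rate = NULL, away_rate = 0.3,
                         p_correct = NULL, reward_expectation = NULL,
                         noise_mm = 0.05, frame_rate = 5.67, seed = 1L) {
  profile <- match.arg(profile)
  schedule <- if (profile == "ir" && missing(schedule)) "interleaved"
    else match.arg(schedule)
  naive <- profile == "naive"
  if (is.null(n_trials))
    n_trials <- if (schedule == "interleaved") 120L else 60L
  if (is.null(error_rate)) error_rate <- if (naive) 3 else 1
  if (is.null(p_correct)) p_correct <- if (naive) 0.6 else 0.95
  if (is.null(reward_expectation))
    reward_expectation <- switch(profile, expert = 0.9, ir = 0.5, naive = 0.2)
  stopifnot(n_trials >= 1, error_rate >= 0, p_correct > 0, p_correct <= 1,
            reward_expectation >= 0, reward_expectation <= 1, noise_mm >= 0)
  structure(list(schedule = schedule, profile = profile,
                 n_trials = as.integer(n_trials), error_rate = error_rate,
                 away_rate = away_rate, p_correct = p_correct,
                 reward_expectation = reward_expectation,
                 noise_mm = noise_mm, frame_rate = frame_rate,
                 dt = 0.01, arena_mm = 100, zone_mm = 40,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# ballistic position ramp from p0 to p1 over dur seconds on the 10-ms grid;
# triangular speed profile (quadratic ease-in/out), so the speed peak at the
# stroke midpoint is sharp and survives positional jitter
stroke_samples <- function(p0, p1, dur, dt) {
  n <- max(5L, round(dur / dt))
  if (n %% 2L == 0L) n <- n + 1L   # odd count: unique central speed maximum
  u <- seq_len(n) / n
  s <- ifelse(u <= 0.5, 2 * u^2, 1 - 2 * (1 - u)^2)
  cbind(p0[1] + (p1[1] - p0[1]) * s, p0[2] + (p1[2] - p0[2]) * s)
}

chebyshev <- function(p) max(abs(p))

# target of an approach stroke: walk along the (jittered) ray toward the
# center, stopping at a random point between 12 mm of travel and the point
# where the Chebyshev radius reaches `r_stop` (just outside the zone);
# NULL if no approach of at least 12 mm is feasible from `from`
toward_target <- function(from, r_stop, jitter_deg = 8) {
  th <- atan2(-from[2], -from[1]) +
    stats::runif(1, -jitter_deg, jitter_deg) * pi / 180
  d <- c(cos(th), sin(th))
  t_close <- max(0, -sum(from * d))   # distance to closest approach
  f <- function(t) chebyshev(from + t * d)
  if (f(t_close) > r_stop) return(NULL)
  lo <- 0; hi <- t_close
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    if (f(mid) > r_stop) lo <- mid else hi <- mid
  }
  if (hi < 13) return(NULL)
  from + stats::runif(1, max(12, 0.35 * hi), hi) * d
}

#' Generate a synthetic behavioral session with ground truth
#'
#' @param config a [synth_config()].
#' @return list with `session` (a [trajectory_session()]), and `truth`: a
#'   data frame of planted movement events (`trial`, `time` of the
#'   radial-speed peak on the pre-noise 10-ms grid, `class`, `side`), the
#'   per-trial toward-error counts, and the planted lick-burst times.
#' @export
generate_session <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  if (config$n_trials < 1) stop("infeasible config: no trials")
  set.seed(config$seed)
  dt <- config$dt
  half <- config$arena_mm / 2
  zone_half <- config$zone_mm / 2
  clamp_arena <- function(p) pmin(pmax(p, -half + 1), half - 1)

  traj <- list(); licks <- numeric(); trials <- list(); truth <- list()
  t_glob <- 0
  for (tr in seq_len(config$n_trials)) {
    completed <- runif(1) < config$p_correct
    k_tow <- min(rpois(1, config$error_rate), 6L)
    if (!completed && k_tow == 0) k_tow <- 1L  # failed trials still move
    k_extra_away <- rpois(1, config$away_rate)

    # start outside the zone, biased outward so approaches have room
    repeat {
      pos <- runif(2, -half + 2, half - 2)
      if (chebyshev(pos) > zone_half + 15) break
    }
    t0 <- t_glob
    xy <- matrix(pos, 1, 2)
    tt <- t0
    ev <- list()
    pause <- function(len) {
      n <- round(len / dt)
      xy <<- rbind(xy, matrix(rep(xy[nrow(xy), ], n), n, 2, byrow = TRUE))
    }
    do_stroke <- function(target, cls, side_ok = TRUE) {
      dur <- runif(1, 0.16, 0.30)
      seg <- stroke_samples(xy[nrow(xy), ], target, dur, dt)
      i0 <- nrow(xy)
      xy <<- rbind(xy, seg)
      if (cls %in% c("toward", "away")) {
        d <- sqrt(rowSums(xy[i0:nrow(xy), , drop = FALSE]^2))
        rv <- diff(d) / dt
        pk <- if (cls == "toward") which.min(rv) else which.max(rv)
        ev[[length(ev) + 1L]] <<- data.frame(
          trial = tr, sample = i0 + pk, class = cls,
          side = if (xy[i0 + pk, 1] >= 0) "high" else "low")
      }
    }
    pause(runif(1, 0.4, 0.8))
    extra_slots <- if (k_tow + 1 > 0)
      sort(sample.int(k_tow + 1L, min(k_extra_away, k_tow + 1L))) else integer()
    reinit <- function() {
      cur <- xy[nrow(xy), ]
      out_target <- clamp_arena(cur * runif(1, 1.6, 2.2) +
                                  stats::rnorm(2, 0, 4))
      if (chebyshev(out_target) < zone_half + 18)
        out_target <- clamp_arena(out_target * 2.5)
      do_stroke(out_target, "away")
      pause(runif(1, 0.6, 1.2))
    }
    for (e in seq_len(k_tow)) {
      tgt <- toward_target(xy[nrow(xy), ], zone_half + 3)
      if (is.null(tgt)) {
        # reposition outward first so the approach can exceed the threshold
        reinit()
        tgt <- toward_target(xy[nrow(xy), ], zone_half + 3)
        if (is.null(tgt)) next
      }
      do_stroke(tgt, "toward")
      pause(runif(1, 0.6, 1.2))
      if (e %in% extra_slots) reinit()
    }
    if (completed) {
      if (chebyshev(xy[nrow(xy), ]) < zone_half + 10) {
        reinit()
      }
      goal <- runif(2, -zone_half + 8, zone_half - 8)
      if (config$schedule == "split")
        goal[1] <- abs(goal[1]) * sample(c(-1, 1), 1)
      do_stroke(goal, "goal")
      pause(runif(1, 0.2, 0.4))
    } else {
      pause(runif(1, 0.5, 1.0))
    }

    n_samp <- nrow(xy)
    times <- t0 + (seq_len(n_samp) - 1L) * dt
    ev_df <- if (length(ev)) do.call(rbind, ev) else NULL
    if (!is.null(ev_df)) ev_df$time <- times[ev_df$sample]

    # anticipatory lick bursts after toward errors; rare after away moves
    if (!is.null(ev_df)) {
      for (k in seq_len(nrow(ev_df))) {
        p_burst <- if (ev_df$class[k] == "toward")
          config$reward_expectation else 0.05
        if (runif(1) < p_burst) {
          b0 <- ev_df$time[k] + runif(1, 0.10, 0.18)
          licks <- c(licks, b0 + (0:3) * 0.07)
        }
      }
    }
    rewarded <- completed && (config$schedule != "interleaved" ||
                                runif(1) < 0.5)
    reward_size <- if (!rewarded) 0 else switch(config$schedule,
      standard = 1, interleaved = 1,
      split = if (xy[n_samp, 1] >= 0) 1.25 else 0.125)
    if (rewarded)
      licks <- c(licks, times[n_samp] + 0.1 + (0:9) * 0.125)

    traj[[tr]] <- data.frame(trial = tr, t = times, x = xy[, 1], y = xy[, 2])
    trials[[tr]] <- data.frame(trial = tr, t_start = times[1],
                               t_end = times[n_samp], completed = completed,
                               rewarded = rewarded, reward_size = reward_size)
    if (!is.null(ev_df)) truth[[length(truth) + 1L]] <- ev_df
    t_glob <- times[n_samp] + if (completed) 6 else 2
  }

  trajectory <- do.call(rbind, traj)
  trajectory$x <- pmin(pmax(trajectory$x +
                              rnorm(nrow(trajectory), 0, config$noise_mm),
                            -half), half)
  trajectory$y <- pmin(pmax(trajectory$y +
                              rnorm(nrow(trajectory), 0, config$noise_mm),
                            -half), half)
  joystick <- trajectory
  joystick$x <- pmin(pmax(joystick$x + rnorm(nrow(joystick), 0, 0.08), -half),
                     half)
  joystick$y <- pmin(pmax(joystick$y + rnorm(nrow(joystick), 0, 0.08), -half),
                     half)
  truth_df <- if (length(truth)) do.call(rbind, truth) else
    data.frame(trial = integer(), sample = integer(), class = character(),
               side = character(), time = numeric())
  rownames(truth_df) <- NULL
  counts <- vapply(seq_len(config$n_trials), function(tr)
    sum(truth_df$class == "toward" & truth_df$trial == tr), integer(1))
  session <- trajectory_session(trajectory, do.call(rbind, trials),
                                licks = sort(licks), joystick = joystick,
                                schedule = config$schedule,
                                arena_mm = config$arena_mm,
                                zone_mm = config$zone_mm)
  list(session = session, truth = truth_df, error_counts = counts,
       config = config)
}

default_neuron_types <- function(n_neurons = 500L) {
  n_err <- round(n_neurons * 0.36)
  n_err <- n_err - n_err %% 6
  rest <- n_neurons - n_err
  c(error = n_err, objvel = round(rest * 0.19), joyvel = round(rest * 0.19),
    time = round(rest * 0.12), reward = round(rest * 0.12),
    noise = rest - round(rest * 0.19) * 2 - round(rest * 0.12) * 2)
}

#' Generate synthetic neurons from the GLM generative form
#'
#' Draws per-frame activity for a population of neurons with known ground
#' truth. GLM-type neurons (n-step error, object velocity, joystick velocity,
#' time ramp) have rate \eqn{\exp(\beta_0 + X\beta)} with \eqn{X} the
#' z-scored design matrix built from the session, \eqn{\beta} supported on
#' the planted group with a causal raised-cosine kernel. Reward/omission
#' neurons carry a multiplicative rate bump 0-2 s after the relevant trial
#' offsets. Traces are Poisson draws scaled by `gain` so that active neurons
#' exceed the deconvolved-activity inclusion threshold.
#'
#' @param session a [trajectory_session()].
#' @param events an [detect_errors()] result for the session.
#' @param types named integer vector of neuron counts (`error`, `objvel`,
#'   `joyvel`, `time`, `reward`, `omission`, `noise`); error counts are split
#'   evenly across n = 1..6.
#' @param design optional pre-built standard design matrix.
#' @param kernel_weight peak planted coefficient magnitude.
#' @param baseline log baseline rate before scaling.
#' @param gain multiplicative trace scale applied to the Poisson draws.
#' @param regions optional per-neuron region labels; defaults to uniform
#'   draws from M1, M2, S1, PPC, RSC.
#' @param seed RNG seed.
#' @return list with `activity` (neurons x frames), `truth` (data frame:
#'   neuron, type, n, region), `design`, `frame_times`.
#' @export
generate_neurons <- function(session, events,
                             types = default_neuron_types(),
                             design = NULL, kernel_weight = 3,
                             baseline = log(0.5), gain = 10,
                             regions = NULL, seed = 1L) {
  stopifnot(inherits(session, "trajectory_session"),
            inherits(events, "error_events"))
  set.seed(seed)
  if (is.null(design))
    design <- build_design_matrix(events, session, variant = "standard")
  X <- design$X
  nf <- nrow(X)
  groups <- design$groups
  n_basis <- ncol(design$basis$B)
  # causal response kernel: weight on the post-event basis bumps
  causal <- c(0, 0, 0.15, 1, 0.55, 0.15)[seq_len(n_basis)]
  causal <- causal / max(causal) * kernel_weight

  type_list <- rep(names(types), types)
  n_neurons <- length(type_list)
  if (is.null(regions))
    regions <- sample(c("M1", "M2", "S1", "PPC", "RSC"), n_neurons,
                      replace = TRUE)
  err_ns <- rep_len(1:6, sum(type_list == "error"))

  offsets <- session$trials$t_end
  rewarded <- session$trials$rewarded
  frame_times <- design$frame_times

  activity <- matrix(0L, n_neurons, nf)
  truth <- data.frame(neuron = seq_len(n_neurons), type = type_list,
                      n = NA_integer_, region = regions)
  ei <- 0L
  for (i in seq_len(n_neurons)) {
    ty <- type_list[i]
    eta <- rep(baseline, nf)
    if (ty == "error") {
      ei <- ei + 1L
      nn <- err_ns[ei]
      truth$n[i] <- nn
      sel <- groups == paste0("err", nn)
      eta <- eta + as.numeric(X[, sel, drop = FALSE] %*% causal)
    } else if (ty %in% c("objvel", "joyvel")) {
      g <- if (ty == "objvel") "objvel" else "joyvel"
      cols <- which(groups == g)
      dir <- sample.int(8L, 1L)
      sel <- cols[((dir - 1L) * n_basis + 1L):(dir * n_basis)]
      eta <- eta + as.numeric(X[, sel, drop = FALSE] %*% (causal * 0.6))
    } else if (ty == "time") {
      sel <- groups == "time"
      w <- rep(kernel_weight / n_basis, n_basis)
      eta <- eta + as.numeric(X[, sel, drop = FALSE] %*% w)
    } else if (ty %in% c("reward", "omission")) {
      want <- if (ty == "reward") rewarded else !rewarded
      offs <- offsets[session$trials$completed & want]
      for (o in offs) {
        sel <- frame_times >= o & frame_times <= o + 2
        eta[sel] <- eta[sel] + kernel_weight *
          exp(-(frame_times[sel] - o - 0.3)^2 / (2 * 0.4^2))
      }
    }
    eta <- pmin(eta, baseline + 1.6 * kernel_weight)  # guard against blow-ups
    activity[i, ] <- gain * rpois(nf, exp(eta))
  }
  list(activity = activity, truth = truth, design = design,
       frame_times = frame_times)
}

#' Small canonical fixture suite
#'
#' Deterministic miniature sessions (8 trials each) for unit tests: one per
#' reward schedule plus a naive-like session, regenerated bit-identically
#' from the stored seed.
#'
#' @param seed integer seed.
#' @return named list of [generate_session()] results: `expert` (standard),
#'   `naive` (standard), `ir` (interleaved), `split`.
#' @export
make_fixture_suite <- function(seed = 42L) {
  list(
    expert = generate_session(synth_config(profile = "expert", n_trials = 8L,
                                           seed = seed)),
    naive = generate_session(synth_config(profile = "naive", n_trials = 8L,
                                          seed = seed + 1L)),
    ir = generate_session(synth_config(schedule = "interleaved",
                                       profile = "ir", n_trials = 8L,
                                       seed = seed + 2L)),
    split = generate_session(synth_config(schedule = "split",
                                          profile = "expert", n_trials = 8L,
                                          seed = seed + 3L)))
}
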