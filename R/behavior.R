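#' Trial-structured behavioral session
#'
#' Bundles the 10-ms object trajectory, the joystick trajectory, lick event
#' times and the trial table of one object-manipulation session. The arena is
#' a 100 x 100 mm square with a centered 40 x 40 mm reward zone; positions are
#' in mm relative to the arena center, times in seconds.
#'
#' @param trajectory data frame with columns `trial`, `t` (s, 10-ms steps),
#'   `x`, `y` (object position, mm).
#' @param trials data frame with columns `trial`, `t_start`, `t_end`,
#'   `completed` (logical: object reached the reward zone), `rewarded`
#'   (logical) and `reward_size` (relative scale; 1 standard, 1.25/0.125 for
#'   the high/low halves under the split schedule).
#' @param licks numeric vector of lick event times (s).
#' @param joystick optional data frame like `trajectory` for the joystick.
#' @param schedule `"standard"`, `"interleaved"` or `"split"`.
#' @param arena_mm,zone_mm arena and reward-zone side lengths.
#' @param center arena center in the trajectory's coordinates.
#' @return an object of class `"trajectory_session"`.
#' @export
trajectory_session <- function(trajectory, trials, licks = numeric(),
                               joystick = NULL,
                               schedule = c("standard", "interleaved", "split"),
                               arena_mm = 100, zone_mm = 40,
                               center = c(0, 0)) {
  schedule <- match.arg(schedule)
  stopifnot(all(c("trial", "t", "x", "y") %in% names(trajectory)),
            all(c("trial", "t_start", "t_end", "completed", "rewarded",
                  "reward_size") %in% names(trials)))
  for (tr in split(trajectory$t, trajectory$trial))
    if (is.unsorted(tr, strictly = TRUE))
      stop("timestamps must be strictly increasing within each trial")
  half <- arena_mm / 2
  if (any(abs(trajectory$x - center[1]) > half + 1e-9) ||
      any(abs(trajectory$y - center[2]) > half + 1e-9))
    stop("positions outside the arena")
  structure(list(trajectory = trajectory, trials = trials, licks = licks,
                 joystick = joystick, schedule = schedule,
                 arena_mm = arena_mm, zone_mm = zone_mm, center = center,
                 dt = 0.01),
            class = "trajectory_session")
}

#' @method print trajectory_session
#' @export
print.trajectory_session <- function(x, ...) {
  cat(sprintf("trajectory session: %d trials (%s schedule), %d samples, %d licks\n",
              nrow(x$trials), x$schedule, nrow(x$trajectory),
              length(x$licks)))
  cat(sprintf("  correct rate: %.3f\n", correct_rate(x)))
  invisible(x)
}

in_zone_mm <- function(x, y, session) {
  h <- session$zone_mm / 2
  abs(x - session$center[1]) <= h & abs(y - session$center[2]) <= h
}

# peak detection mirroring MATLAB findpeaks with a height threshold and a
# minimum peak separation (larger peaks suppress smaller ones within range)
find_speed_peaks <- function(v, min_height, min_dist) {
  p <- pracma::findpeaks(v, minpeakheight = min_height, sortstr = TRUE)
  if (is.null(p)) return(integer())
  idx <- p[, 2]
  keep <- logical(0)
  kept <- integer(0)
  for (i in idx) {
    if (all(abs(kept - i) >= min_dist)) kept <- c(kept, i)
  }
  sort(kept)
}

#' Detect strokes in a session
#'
#' A stroke is an object movement whose speed exceeds 60 mm/s, separated by at
#' least 200 ms from any previous movement. Speed is the 10-ms displacement
#' divided by the sampling step.
#'
#' @param session a [trajectory_session()].
#' @param min_speed threshold (mm/s).
#' @param min_separation minimum separation between strokes (s).
#' @return data frame with columns `trial`, `time`, `peak_speed`.
#' @export
detect_strokes <- function(session, min_speed = 60, min_separation = 0.2) {
  stopifnot(inherits(session, "trajectory_session"))
  dt <- session$dt
  out <- lapply(split(session$trajectory, session$trajectory$trial), function(tr) {
    if (nrow(tr) < 2) return(NULL)
    sp <- sqrt(diff(tr$x)^2 + diff(tr$y)^2) / dt
    idx <- find_speed_peaks(sp, min_speed, round(min_separation / dt))
    if (!length(idx)) return(NULL)
    data.frame(trial = tr$trial[1], time = tr$t[idx + 1L],
               peak_speed = sp[idx])
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame(trial = integer(), time = numeric(),
                                      peak_speed = numeric())
  rownames(out) <- NULL
  out
}

#' Detect toward/away errors and n-step accumulation onsets
#'
#' Computes the object's distance to the arena center at each 10-ms sample,
#' differences adjacent time points (radial velocity), and finds peaks of its
#' magnitude exceeding 60 mm/s with at least 200 ms separation (enforced
#' within each class). A peak with decreasing distance is a `toward` error
#' unless that movement carries the object into the reward zone; a peak with
#' increasing distance is an `away` movement (reinitialization, not an error).
#' For each trial the n-th toward error (n = 1..6) defines the onset of the
#' n-step error accumulation \eqn{\delta_t(n)}; accumulation resets between
#' trials. Trials shorter than 200 ms are skipped. Under the split schedule
#' each error is labelled by arena half (`x >= center`: high, else low).
#'
#' @param session a [trajectory_session()].
#' @param min_speed radial-speed threshold (mm/s).
#' @param min_separation minimum separation between same-class peaks (s).
#' @param n_max largest accumulation step tracked.
#' @return an object of class `"error_events"`: list with `events` (data
#'   frame: `trial`, `time`, `frame`, `class`, `side`) and `onsets` (data
#'   frame: `trial`, `n`, `time` of each n-step onset), plus the session's
#'   trial count.
#' @export
detect_errors <- function(session, min_speed = 60, min_separation = 0.2,
                          n_max = 6L) {
  stopifnot(inherits(session, "trajectory_session"))
  dt <- session$dt
  min_dist <- round(min_separation / dt)
  ev <- list(); on <- list()
  for (tr in split(session$trajectory, session$trajectory$trial)) {
    if (nrow(tr) < 2 || (tr$t[nrow(tr)] - tr$t[1]) < 0.2) next
    d <- sqrt((tr$x - session$center[1])^2 + (tr$y - session$center[2])^2)
    rv <- diff(d) / dt          # signed radial velocity, mm/s; < 0 approaches
    toward_idx <- find_speed_peaks(-rv, min_speed, min_dist)
    away_idx <- find_speed_peaks(rv, min_speed, min_dist)
    if (length(toward_idx)) {
      # a movement that enters the zone terminates the approach: not an error
      entered <- vapply(toward_idx, function(i) {
        j <- i:min(i + min_dist, nrow(tr) - 1L) + 1L
        any(in_zone_mm(tr$x[j], tr$y[j], session))
      }, logical(1))
      toward_idx <- toward_idx[!entered]
    }
    idx <- c(toward_idx, away_idx)
    if (!length(idx)) next
    cls <- rep(c("toward", "away"), c(length(toward_idx), length(away_idx)))
    o <- order(idx)
    idx <- idx[o]; cls <- cls[o]
    side <- ifelse(tr$x[idx + 1L] >= session$center[1], "high", "low")
    ev[[length(ev) + 1L]] <- data.frame(
      trial = tr$trial[1], time = tr$t[idx + 1L], frame = idx + 1L,
      class = cls, side = side)
    tw <- which(cls == "toward")
    if (length(tw)) {
      nn <- seq_len(min(length(tw), n_max))
      on[[length(on) + 1L]] <- data.frame(
        trial = tr$trial[1], n = nn, time = tr$t[idx[tw[nn]] + 1L])
    }
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(trial = integer(), time = numeric(), frame = integer(),
               class = character(), side = character())
  onsets <- if (length(on)) do.call(rbind, on) else
    data.frame(trial = integer(), n = integer(), time = numeric())
  rownames(events) <- rownames(onsets) <- NULL
  structure(list(events = events, onsets = onsets, n_max = n_max,
                 n_trials = nrow(session$trials)),
            class = "error_events")
}

#' @method print error_events
#' @export
print.error_events <- function(x, ...) {
  tw <- sum(x$events$class == "toward")
  cat(sprintf("error events: %d toward, %d away over %d trials\n",
              tw, nrow(x$events) - tw, x$n_trials))
  invisible(x)
}

#' Per-n error frequencies and latencies
#'
#' @param events an [detect_errors()] result.
#' @return list with `freq` (trials x n matrix of 0/1 onset indicators for
#'   the trials carrying at least one event), `mean_freq` (per-n mean over
#'   those trials), and `latency` (data frame `trial`, `n`, `latency`:
#'   time from the (n-1)-th to the n-th error; for n = 1, from trial start,
#'   approximated by the first trajectory time of the trial).
#' @param session the session the events came from (for trial start times).
#' @export
error_statistics <- function(events, session = NULL) {
  stopifnot(inherits(events, "error_events"))
  trials <- sort(unique(events$onsets$trial))
  n_max <- events$n_max
  freq <- matrix(0L, length(trials), n_max,
                 dimnames = list(trials, paste0("n", seq_len(n_max))))
  lat <- list()
  for (ti in seq_along(trials)) {
    o <- events$onsets[events$onsets$trial == trials[ti], ]
    freq[ti, o$n] <- 1L
    t0 <- if (!is.null(session))
      session$trials$t_start[session$trials$trial == trials[ti]] else NA_real_
    prev <- c(t0, o$time[-nrow(o)])
    lat[[ti]] <- data.frame(trial = trials[ti], n = o$n,
                            latency = o$time - prev)
  }
  list(freq = freq, mean_freq = colMeans(freq),
       latency = if (length(lat)) do.call(rbind, lat) else
         data.frame(trial = integer(), n = integer(), latency = numeric()))
}

#' Peri-event lick histogram
#'
#' Subsamples lick events onto the 10-ms grid, averages a window around each
#' event, bins the average every 100 ms, and subtracts the baseline bin at
#' -50 ms relative to the event. The lick-frequency comparison scalar is the
#' sum of the first five post-event bins. Normalization divides the
#' baseline-subtracted histogram by a caller-supplied reference value, which
#' is how the session-level modes are expressed (normalize to the maximum of
#' the single-step toward histogram of expert sessions, of the one-step
#' histogram, of the first session quarter, or of the high-reward side).
#'
#' @param session a [trajectory_session()].
#' @param event_times numeric vector of event times (s).
#' @param window window around the event (s).
#' @param bin_width histogram bin (s).
#' @param normalize_to positive scalar used as the normalization reference
#'   (e.g. `max(other_histogram$values)`), or `NULL` for none.
#' @return an object of class `"lick_histogram"`: list with `mids` (bin
#'   centers, s), `values`, and `scalar` (sum of the five bins after the
#'   event).
#' @export
peri_event_lick <- function(session, event_times, window = c(-2, 2),
                            bin_width = 0.1, normalize_to = NULL) {
  stopifnot(inherits(session, "trajectory_session"))
  if (!length(event_times)) stop("no events supplied")
  dt <- session$dt
  offs <- seq(window[1], window[2] - dt, by = dt)
  licks <- sort(session$licks)
  # mean lick count per 10-ms sample at each offset across events
  prof <- numeric(length(offs))
  for (e in event_times) {
    rel <- licks - e
    rel <- rel[rel >= window[1] & rel < window[2]]
    if (length(rel))
      prof <- prof + tabulate(floor((rel - window[1]) / dt) + 1L,
                              nbins = length(offs))
  }
  prof <- prof / length(event_times)
  per_bin <- round(bin_width / dt)
  nb <- floor(length(prof) / per_bin)
  vals <- colMeans(matrix(prof[seq_len(nb * per_bin)], nrow = per_bin))
  mids <- window[1] + (seq_len(nb) - 0.5) * bin_width
  base_bin <- which.min(abs(mids - (-bin_width / 2)))  # bin covering -50 ms
  vals <- vals - vals[base_bin]
  if (!is.null(normalize_to)) {
    stopifnot(is.numeric(normalize_to), normalize_to > 0)
    vals <- vals / normalize_to
  }
  post <- which(mids > 0)[seq_len(5)]
  structure(list(mids = mids, values = vals,
                 scalar = sum(vals[post], na.rm = TRUE)),
            class = "lick_histogram")
}

#' @method print lick_histogram
#' @export
print.lick_histogram <- function(x, ...) {
  cat(sprintf("peri-event lick histogram: %d bins, comparison scalar %.4f\n",
              length(x$values), x$scalar))
  invisible(x)
}

#' Fraction of completed trials
#'
#' The number of trials in which the object was successfully guided to the
#' reward zone divided by the total number of trials; under the interleaved
#' schedule completion is counted regardless of reward delivery, and under
#' the split schedule regardless of reward magnitude.
#'
#' @param session a [trajectory_session()].
#' @return fraction in \[0, 1\].
#' @export
correct_rate <- function(session) {
  stopifnot(inherits(session, "trajectory_session"), nrow(session$trials) >= 1)
  mean(session$trials$completed)
}

#' Empirical spatial state-value map
#'
#' The state value of a spatial bin is the mean of \eqn{R\,\gamma^{T-t}} over
#' all 10-ms visits to that bin during rewarded trials, where \eqn{T} is the
#' rewarded trial end, \eqn{t} the visit time (in samples) and \eqn{R} the
#' relative reward size (1 for the standard reward, 1.25/0.125 for the
#' high/low halves under the split schedule). Trials that do not end in
#' reward contribute nothing.
#'
#' @param sessions a [trajectory_session()] or list of them.
#' @param gamma discount factor per 10-ms step (default 0.99).
#' @param bins spatial bins per axis.
#' @return list with `value` (bins x bins matrix, `NA` where unvisited),
#'   `count`, and `breaks` (mm).
#' @export
empirical_state_value <- function(sessions, gamma = 0.99, bins = 10L) {
  if (inherits(sessions, "trajectory_session")) sessions <- list(sessions)
  s1 <- sessions[[1]]
  half <- s1$arena_mm / 2
  breaks <- seq(-half, half, length.out = bins + 1L)
  sums <- matrix(0, bins, bins)
  cnts <- matrix(0L, bins, bins)
  for (session in sessions) {
    tr_tab <- session$trials
    for (tr in split(session$trajectory, session$trajectory$trial)) {
      row <- tr_tab[tr_tab$trial == tr$trial[1], ]
      if (!nrow(row) || !row$completed || !row$rewarded || row$reward_size <= 0)
        next
      Tn <- nrow(tr)
      w <- row$reward_size * gamma^((Tn - seq_len(Tn)))
      ix <- findInterval(tr$x - session$center[1], breaks,
                         rightmost.closed = TRUE, all.inside = TRUE)
      iy <- findInterval(tr$y - session$center[2], breaks,
                         rightmost.closed = TRUE, all.inside = TRUE)
      for (k in seq_len(Tn)) {
        sums[ix[k], iy[k]] <- sums[ix[k], iy[k]] + w[k]
        cnts[ix[k], iy[k]] <- cnts[ix[k], iy[k]] + 1L
      }
    }
  }
  value <- ifelse(cnts > 0, sums / cnts, NA_real_)
  list(value = value, count = cnts, breaks = breaks)
}

#' Write / read a behavioral session as CSV files
#'
#' Serializes the trajectory, trial table and licks to `<prefix>_trajectory.csv`,
#' `<prefix>_trials.csv`, `<prefix>_licks.csv` (and `<prefix>_joystick.csv` if
#' present), with times in seconds and positions in mm.
#'
#' @param session a [trajectory_session()].
#' @param prefix path prefix for the CSV files.
#' @return `write_session` the file paths invisibly; `read_session` the
#'   reconstructed session.
#' @export
write_session <- function(session, prefix) {
  stopifnot(inherits(session, "trajectory_session"))
  paths <- c(trajectory = paste0(prefix, "_trajectory.csv"),
             trials = paste0(prefix, "_trials.csv"),
             licks = paste0(prefix, "_licks.csv"))
  write.csv(session$trajectory, paths["trajectory"], row.names = FALSE)
  write.csv(session$trials, paths["trials"], row.names = FALSE)
  write.csv(data.frame(t = session$licks), paths["licks"], row.names = FALSE)
  if (!is.null(session$joystick)) {
    paths <- c(paths, joystick = paste0(prefix, "_joystick.csv"))
    write.csv(session$joystick, paths["joystick"], row.names = FALSE)
  }
  meta <- paste0(prefix, "_meta.csv")
  write.csv(data.frame(schedule = session$schedule,
                       arena_mm = session$arena_mm, zone_mm = session$zone_mm,
                       center_x = session$center[1],
                       center_y = session$center[2]),
            meta, row.names = FALSE)
  invisible(c(paths, meta = meta))
}

#' @rdname write_session
#' @export
read_session <- function(prefix) {
  meta <- read.csv(paste0(prefix, "_meta.csv"))
  joy_path <- paste0(prefix, "_joystick.csv")
  trajectory_session(
    trajectory = read.csv(paste0(prefix, "_trajectory.csv")),
    trials = read.csv(paste0(prefix, "_trials.csv")),
    licks = read.csv(paste0(prefix, "_licks.csv"))$t,
    joystick = if (file.exists(joy_path)) read.csv(joy_path) else NULL,
    schedule = meta$schedule, arena_mm = meta$arena_mm,
    zone_mm = meta$zone_mm, center = c(meta$center_x, meta$center_y))
}
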