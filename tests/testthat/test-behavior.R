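# straight movement of `len` mm over `dur` s with a triangular speed profile,
# embedded between stationary stretches
burst_xy <- function(n_pre, n_move, n_post, x0 = 40, step_dir = c(-1, 0),
                     len = 20) {
  u <- seq_len(n_move) / n_move
  s <- ifelse(u <= 0.5, 2 * u^2, 1 - 2 * (1 - u)^2)
  x <- c(rep(x0, n_pre), x0 + step_dir[1] * len * s,
         rep(x0 + step_dir[1] * len, n_post))
  y <- c(rep(0, n_pre), step_dir[2] * len * s, rep(step_dir[2] * len, n_post))
  list(x = x, y = y)
}

test_that("stroke detection honors the speed threshold and separation", {
  # one 20-mm movement in 0.25 s: peak speed 160 mm/s -> one stroke
  b <- burst_xy(30, 25, 30)
  s <- manual_session(b$x, b$y)
  st <- detect_strokes(s)
  expect_equal(nrow(st), 1L)
  expect_gt(st$peak_speed, 60)

  # constant 50 mm/s drift never crosses the threshold
  x <- 45 - 0.5 * seq_len(80)           # 0.5 mm per 10 ms
  s <- manual_session(x, rep(30, 80))
  expect_equal(nrow(detect_strokes(s)), 0L)

  # two bursts whose speed peaks are ~150 ms apart merge into one stroke
  ramp <- function(n) ifelse(seq_len(n) / n <= 0.5, 2 * (seq_len(n) / n)^2,
                             1 - 2 * (1 - seq_len(n) / n)^2)
  x <- c(rep(45, 20), 45 - 15 * ramp(11), rep(30, 4), 30 - 15 * ramp(11),
         rep(15, 20))
  s <- manual_session(x, rep(0, length(x)), completed = FALSE,
                      rewarded = FALSE, reward_size = 0)
  expect_equal(nrow(detect_strokes(s)), 1L)
})

test_that("error detection separates toward errors from reinitializations", {
  # approach from x = 45 stopping at x = 25 (10 mm outside the zone wall at
  # 160 mm/s peak): one toward error, no away event
  b <- burst_xy(30, 25, 40, x0 = 45, len = 20)
  s <- manual_session(b$x, b$y)
  ev <- detect_errors(s)
  expect_equal(sum(ev$events$class == "toward"), 1L)
  expect_equal(sum(ev$events$class == "away"), 0L)

  # outward movement is a reinitialization, not an error
  b <- burst_xy(30, 25, 40, x0 = 25, step_dir = c(1, 0), len = 20)
  s <- manual_session(b$x, b$y)
  ev <- detect_errors(s)
  expect_equal(sum(ev$events$class == "toward"), 0L)
  expect_equal(sum(ev$events$class == "away"), 1L)

  # a movement that carries the object into the zone is not an error
  b <- burst_xy(30, 25, 40, x0 = 35, len = 20)   # ends at x = 15, inside
  s <- manual_session(b$x, b$y)
  ev <- detect_errors(s)
  expect_equal(sum(ev$events$class == "toward"), 0L)
})

test_that("n-step onsets accumulate within a trial and order correctly", {
  fx <- fx_small()
  ev <- fx$ev
  # each trial's n-th onset follows its (n-1)-th
  for (tr in unique(ev$onsets$trial)) {
    o <- ev$onsets[ev$onsets$trial == tr, ]
    expect_equal(o$n, seq_len(nrow(o)))
    expect_true(all(diff(o$time) > 0))
  }
  # a trial with exactly five toward errors has one delta(5) onset at the
  # fifth error and none beyond
  k5 <- which(fx$g$error_counts == 5)
  if (length(k5)) {
    tr <- k5[1]
    o <- ev$onsets[ev$onsets$trial == tr, ]
    expect_equal(max(o$n), 5L)
    tw <- sort(ev$events$time[ev$events$trial == tr &
                                ev$events$class == "toward"])
    expect_equal(o$time[o$n == 5], tw[5])
  }
})

test_that("error detection is invariant to translating the coordinate frame", {
  b <- burst_xy(30, 25, 40, x0 = 45, len = 20)
  s1 <- manual_session(b$x, b$y)
  s2 <- trajectory_session(
    trajectory = data.frame(trial = 1L, t = s1$trajectory$t,
                            x = b$x + 4, y = b$y - 3),
    trials = s1$trials, center = c(4, -3))
  e1 <- detect_errors(s1); e2 <- detect_errors(s2)
  expect_equal(e1$events$time, e2$events$time)
  expect_equal(e1$events$class, e2$events$class)
})

test_that("error statistics report per-n frequency and latency", {
  # synthetic onsets: three errors at 1.0, 2.5, 4.0 s
  ev <- structure(list(
    events = data.frame(trial = 1L, time = c(1, 2.5, 4), frame = c(100, 250, 400),
                        class = "toward", side = "high"),
    onsets = data.frame(trial = 1L, n = 1:3, time = c(1, 2.5, 4)),
    n_max = 6L, n_trials = 1L), class = "error_events")
  st <- error_statistics(ev)
  expect_equal(unname(st$mean_freq), c(1, 1, 1, 0, 0, 0))
  expect_equal(st$latency$latency[st$latency$n == 2], 1.5)
  expect_equal(st$latency$latency[st$latency$n == 3], 1.5)
})

test_that("expert-like sessions have fewer errors than naive-like ones", {
  ge <- generate_session(synth_config(profile = "expert", n_trials = 20L,
                                      seed = 21L))
  gn <- generate_session(synth_config(profile = "naive", n_trials = 20L,
                                      seed = 21L))
  se <- error_statistics(detect_errors(ge$session))
  sn <- error_statistics(detect_errors(gn$session))
  expect_lt(mean(ge$error_counts), mean(gn$error_counts))
  expect_lt(sum(se$mean_freq[3:6]), sum(sn$mean_freq[3:6]))
})

test_that("peri-event lick histograms are baseline-subtracted and scored", {
  b <- burst_xy(50, 25, 150, x0 = 45, len = 20)
  # event peak lands mid-burst (~0.62 s); licks 150-350 ms later
  s <- manual_session(b$x, b$y, licks = 0.62 + c(0.15, 0.22, 0.29, 0.36))
  ev <- detect_errors(s)
  h <- peri_event_lick(s, ev$events$time)
  base_bin <- which.min(abs(h$mids + 0.05))
  expect_equal(h$values[base_bin], 0)
  expect_gt(h$scalar, 0)

  s0 <- manual_session(b$x, b$y)          # no licks at all
  h0 <- peri_event_lick(s0, ev$events$time)
  expect_equal(unname(h0$values), rep(0, length(h0$values)))
  expect_equal(h0$scalar, 0)

  hn <- peri_event_lick(s, ev$events$time, normalize_to = max(h$values))
  expect_equal(max(hn$values), 1)
})

test_that("anticipatory licking follows toward errors, not reinitializations", {
  g <- generate_session(synth_config(profile = "expert", n_trials = 40L,
                                     seed = 33L))
  ev <- detect_errors(g$session)
  tw <- ev$events$time[ev$events$class == "toward"]
  aw <- ev$events$time[ev$events$class == "away"]
  ht <- peri_event_lick(g$session, tw)
  ha <- peri_event_lick(g$session, aw)
  expect_gt(ht$scalar, ha$scalar)
})

test_that("lick scalar rises with the reward-expectation parameter", {
  scal <- vapply(c(0.1, 0.9), function(re) {
    g <- generate_session(synth_config(profile = "naive", n_trials = 30L,
                                       reward_expectation = re, seed = 44L))
    ev <- detect_errors(g$session)
    peri_event_lick(g$session,
                    ev$events$time[ev$events$class == "toward"])$scalar
  }, numeric(1))
  expect_gt(scal[2], scal[1])
})

test_that("correct rate counts completed trials regardless of reward", {
  g <- make_fixture_suite(5L)
  s <- g$expert$session
  expect_equal(correct_rate(s), mean(s$trials$completed))
  s_ir <- g$ir$session
  # interleaved: completion counts even when the reward was omitted
  expect_equal(correct_rate(s_ir), mean(s_ir$trials$completed))
  expect_true(any(s_ir$trials$completed & !s_ir$trials$rewarded) ||
                all(s_ir$trials$rewarded))
  tr <- s$trials; tr$completed <- rep(c(TRUE, FALSE), 4)
  s2 <- trajectory_session(s$trajectory, tr, schedule = s$schedule)
  expect_equal(correct_rate(s2), 0.5)
})

test_that("empirical state value matches the closed-form discounting", {
  # a straight rewarded run: each bin visited at a known number of steps
  # before the reward
  n <- 100
  x <- seq(-45, 15, length.out = n)
  s <- manual_session(x, rep(0, n))
  v <- empirical_state_value(s, bins = 10L)
  # value at the terminal bin (visited at reward time among others) and a
  # bin visited exactly 69 steps (0.69 s) before reward
  k <- n - 69
  ix <- findInterval(x[k], v$breaks, rightmost.closed = TRUE)
  iy <- findInterval(0, v$breaks, rightmost.closed = TRUE)
  visits <- which(findInterval(x, v$breaks, rightmost.closed = TRUE) == ix)
  expect_equal(v$value[ix, iy], mean(0.99^(n - visits)), tolerance = 1e-12)
  one_step <- manual_session(c(25, 0), c(0, 0))
  v1 <- empirical_state_value(one_step, bins = 10L)
  izx <- findInterval(0, v1$breaks, rightmost.closed = TRUE)
  expect_equal(v1$value[izx, izx], 1)   # gamma^0 at the reward itself

  # the same geometry scores 10x more on the high-reward side
  hi <- manual_session(x, rep(0, n), reward_size = 1.25, schedule = "split")
  lo <- manual_session(x, rep(0, n), reward_size = 0.125, schedule = "split")
  vh <- empirical_state_value(hi, bins = 10L)
  vl <- empirical_state_value(lo, bins = 10L)
  sel <- !is.na(vh$value)
  expect_equal(vh$value[sel], 10 * vl$value[sel], tolerance = 1e-12)

  # failed trials contribute nothing
  s_fail <- manual_session(x, rep(0, n), completed = FALSE, rewarded = FALSE,
                           reward_size = 0)
  expect_true(all(is.na(empirical_state_value(s_fail, bins = 10L)$value)))
})

test_that("sessions round-trip through CSV serialization", {
  g <- make_fixture_suite(8L)
  s <- g$split$session
  prefix <- file.path(tempdir(), "sess_rt")
  write_session(s, prefix)
  s2 <- read_session(prefix)
  expect_equal(s2$trajectory$x, s$trajectory$x, tolerance = 1e-9)
  expect_equal(s2$trials$completed, s$trials$completed)
  expect_equal(s2$schedule, s$schedule)
  e1 <- detect_errors(s); e2 <- detect_errors(s2)
  expect_equal(e1$events$time, e2$events$time)
})
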