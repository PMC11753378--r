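test_that("activity onsets use the session-wide z-score threshold", {
  p <- planted_sequence(4L, 3L)
  on <- activity_onsets(p$activity, p$frame_times, p$trials)
  expect_equal(dim(on), c(3L, 4L))
  expect_false(any(is.na(on)))
  # onsets follow the planted order in every trial
  for (i in 1:3) expect_true(all(diff(on[i, ]) > 0))
  # a flat neuron never crosses the threshold
  p$activity[2, ] <- 1
  on2 <- activity_onsets(p$activity, p$frame_times, p$trials)
  expect_true(all(is.na(on2[, 2])))
})

test_that("sequential slope is ~1 for planted order and collapses on shuffles", {
  p <- planted_sequence(10L, 12L, jitter = 0.2, seed = 3L)
  set.seed(4)
  r <- sequential_slope(p$activity, p$frame_times, p$trials, n_perm = 300L)
  expect_gt(r$slope, 0.8)
  expect_lt(r$p, 0.01)
  expect_gt(r$slope, stats::quantile(r$null, 0.95, na.rm = TRUE))
  expect_lt(abs(mean(r$null, na.rm = TRUE)), 0.15)

  # destroying the order across trials gives a null-consistent slope
  set.seed(5)
  shuffled <- p$activity[, sample(ncol(p$activity))]
  # shuffle onset structure by permuting neurons independently per trial:
  # rebuild activity with random per-trial order
  q <- planted_sequence(10L, 12L, seed = 6L)
  for (i in seq_len(nrow(q$trials))) {
    fr <- which(q$frame_times >= q$trials$t_start[i] &
                  q$frame_times <= q$trials$t_end[i])
    q$activity[, fr] <- q$activity[sample(nrow(q$activity)), fr]
  }
  r0 <- sequential_slope(q$activity, q$frame_times, q$trials, n_perm = 300L)
  expect_gt(r0$p, 0.01)
})

test_that("RPE-sign classification detects planted reward and omission cells", {
  set.seed(7)
  rate <- 5.67
  lags <- seq(-4, 4, by = 1 / rate)
  n_tr <- 40L
  rewarded <- rep(c(TRUE, FALSE), n_tr / 2)
  mk_peri <- function(kind) {
    m <- matrix(abs(rnorm(n_tr * length(lags), 0, 0.3)), n_tr)
    attr(m, "lags") <- lags
    bump <- which(lags >= 0.2 & lags <= 1.5)
    if (kind == "pos") m[rewarded, bump] <- m[rewarded, bump] + 5
    if (kind == "neg") m[!rewarded, bump] <- m[!rewarded, bump] + 5
    m
  }
  expect_equal(classify_rpe_sign(mk_peri("pos"), rewarded)$label, "positive")
  expect_equal(classify_rpe_sign(mk_peri("neg"), rewarded)$label, "negative")
  expect_equal(classify_rpe_sign(mk_peri("flat"), rewarded)$label, "none")
  expect_error(classify_rpe_sign(mk_peri("pos"), rep(TRUE, n_tr)),
               "omission")
})

test_that("reward-evoked responses are baseline subtracted and compared", {
  rate <- 5.67
  frame_times <- seq(0, 400, by = 1 / rate)
  rewards <- seq(20, 380, by = 20)
  mk <- function(amp) {
    a <- matrix(0, 1, length(frame_times))
    for (r in rewards) {
      sel <- frame_times >= r & frame_times <= r + 0.5
      a[1, sel] <- amp
    }
    a
  }
  expect_equal(reward_evoked_response(mk(0), frame_times, rewards), 0)
  hi <- reward_evoked_response(mk(5), frame_times, rewards)
  lo <- reward_evoked_response(mk(1), frame_times, rewards)
  expect_gt(hi, lo)
  # shrinking response amplitude across learning is detected
  set.seed(8)
  naive <- rnorm(40, 5, 0.5); expert <- rnorm(40, 2, 0.5)
  expect_lt(bootstrap_greater(naive, expert, 500L), 0.01)
})

test_that("long-trial control separates error-driven from time-driven activity", {
  rate <- 5.67
  n_tr <- 20L
  starts <- (seq_len(n_tr) - 1L) * 30
  dur <- rep(c(10, 25), n_tr / 2)          # half the trials are long
  trials <- data.frame(trial = seq_len(n_tr), t_start = starts,
                       t_end = starts + dur)
  has_error <- rep(c(TRUE, TRUE, FALSE, FALSE), length.out = n_tr)
  frame_times <- seq(0, max(trials$t_end) + 1, by = 1 / rate)
  set.seed(9)
  act <- matrix(abs(rnorm(3 * length(frame_times), 0, 0.05)), 3)
  for (i in which(has_error)) {   # error neurons fire only in error trials
    sel <- frame_times >= trials$t_start[i] & frame_times <= trials$t_end[i]
    act[1:2, sel] <- act[1:2, sel] + 4
  }
  r <- long_trial_control(act[1:2, , drop = FALSE], frame_times, trials,
                          has_error)
  expect_true(all(r$diff > 1))            # about 10x and more on log10 scale
  expect_lt(r$p, 0.05)
  # identical activity in both groups: zero difference
  flat <- matrix(1, 1, length(frame_times))
  r0 <- long_trial_control(flat, frame_times, trials, has_error)
  expect_equal(r0$diff, 0, tolerance = 1e-12)
})

test_that("region summaries normalize fractions and respect the cell minimum", {
  set.seed(10)
  tab <- data.frame(
    region = rep(c("M1", "RSC"), each = 60),
    session = rep(1:6, 20),
    task_related = TRUE,
    error_related = rep(c(TRUE, FALSE), 60),
    assigned_n = NA_integer_)
  # M1 dominated by low n, RSC by high n
  tab$assigned_n[tab$error_related & tab$region == "M1"] <-
    sample(1:2, 30, replace = TRUE)
  tab$assigned_n[tab$error_related & tab$region == "RSC"] <-
    sample(5:6, 30, replace = TRUE)
  rs <- region_code_summary(tab, n_boot = 100L)
  populated <- colSums(rs$fractions, na.rm = TRUE) > 0
  expect_true(all(apply(rs$norm_fractions[, populated], 2, max,
                        na.rm = TRUE) == 1))
  expect_gt(sum(rs$fractions["RSC", 5:6]), sum(rs$fractions["M1", 5:6]))
  expect_gt(sum(rs$fractions["M1", 1:2]), sum(rs$fractions["RSC", 1:2]))

  # single region: every defined normalized fraction is 1
  rs1 <- region_code_summary(tab[tab$region == "M1", ], n_boot = 50L)
  nf <- rs1$norm_fractions["M1", ]
  expect_true(all(nf[is.finite(nf)] == 1))

  # a region with too few task-related cells is omitted
  tab2 <- tab
  tab2$task_related[tab2$region == "RSC"][-(1:4)] <- FALSE
  rs2 <- region_code_summary(tab2, n_boot = 50L)
  expect_true(all(is.na(rs2$fractions["RSC", ])))

  # two environments: min-max normalization attains exactly 0 and 1
  tab$environment <- rep(c("original", "ir"), length.out = nrow(tab))
  rs3 <- region_code_summary(tab, n_boot = 50L)
  expect_equal(min(rs3$env_bins, na.rm = TRUE), 0)
  expect_equal(max(rs3$env_bins, na.rm = TRUE), 1)

  # normalized quantities are invariant to duplicating every neuron
  tabx <- rbind(tab, tab)
  rs4 <- region_code_summary(tabx, n_boot = 50L)
  expect_equal(rs4$norm_fractions, rs$norm_fractions)
})
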