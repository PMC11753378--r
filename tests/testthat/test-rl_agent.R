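test_that("single-step RPE is r - V for approach and goal, excluded for away", {
  expect_equal(single_step_rpe(1.0, 0.4, "goal"), 0.6)
  expect_equal(single_step_rpe(0, 0.8, "toward_short"), -0.8)
  expect_equal(single_step_rpe(0, 0.3, "lateral_miss"), -0.3)
  expect_true(is.na(single_step_rpe(0, 0.8, "away")))
  expect_true(is.na(single_step_rpe(0, 0.8, "none")))
})

test_that("advantage accumulation follows the discounted n-step sum", {
  # n = 1 is the identity
  d <- c(0.3, -0.2, 0.7)
  expect_equal(accumulate_advantage(d, 1), d)
  # two-step worked value: 1 - 0.95 * 0.95 = 0.0975
  expect_equal(accumulate_advantage(c(1, -1), 2)[1], 1 - 0.9025,
               tolerance = 1e-12)
  # lambda = 0 collapses every horizon to the single-step RPE
  for (n in c(1, 4, 8))
    expect_equal(accumulate_advantage(d, n, lambda = 0), d)
  expect_error(accumulate_advantage(d, 0), ">= 1")
  expect_error(accumulate_advantage(numeric(), 2), "nonempty")
})

test_that("advantage accumulation matches a brute-force oracle", {
  brute <- function(delta, n, gl) {
    vapply(seq_along(delta), function(t) {
      s <- 0
      for (k in 0:(n - 1))
        if (t + k <= length(delta)) s <- s + gl^k * delta[t + k]
      s
    }, numeric(1))
  }
  set.seed(5)
  for (i in 1:50) {
    delta <- rnorm(sample(1:20, 1))
    n <- sample(1:8, 1)
    g <- runif(1); l <- runif(1)
    expect_equal(accumulate_advantage(delta, n, g, l),
                 brute(delta, n, g * l), tolerance = 1e-10)
  }
})

test_that("training is bit-reproducible under a fixed seed", {
  arena <- arena_config("standard")
  cfg <- ppo_config(n_step = 2L, episodes = 25L, naive_episodes = 10L,
                    hidden = c(16L, 16L), seed = 7L)
  a <- train_agent(arena, cfg)
  b <- train_agent(arena, cfg)
  expect_identical(a$episodes, b$episodes)
  expect_identical(a$params, b$params)
})

test_that("naive parameters precede any update and differ from trained ones", {
  arena <- arena_config("standard")
  rec <- train_agent(arena, ppo_config(n_step = 2L, episodes = 40L,
                                       naive_episodes = 5L,
                                       hidden = c(16L, 16L), seed = 3L))
  # naive params equal a freshly initialized net under the same seed
  rec0 <- train_agent(arena, ppo_config(n_step = 2L, episodes = 1L,
                                        naive_episodes = 5L,
                                        hidden = c(16L, 16L), seed = 3L))
  expect_identical(rec$naive_params$W[[1]], rec0$naive_params$W[[1]])
  expect_false(identical(rec$params$Wv, rec$naive_params$Wv))
})

test_that("value map averages the critic on a 40 x 40 grid", {
  rec <- train_agent(arena_config("standard"),
                     ppo_config(n_step = 1L, episodes = 2L,
                                naive_episodes = 2L, hidden = c(16L, 16L),
                                seed = 1L))
  params <- rec$naive_params
  # zero value head makes the map exactly zero everywhere
  params$Wv[] <- 0; params$bv[] <- 0
  set.seed(2)
  vm <- value_map(params, n_samples = 5000L)
  expect_equal(dim(vm$value), c(40L, 40L))
  filled <- !is.na(vm$value)
  expect_equal(unname(vm$value[filled]), rep(0, sum(filled)))
  expect_true(all(vm$count[!filled] == 0))
})

test_that("unit tuning yields spatial maps and 8-direction profiles", {
  rec <- train_agent(arena_config("standard"),
                     ppo_config(n_step = 1L, episodes = 2L,
                                naive_episodes = 2L, hidden = c(16L, 8L),
                                seed = 1L))
  set.seed(3)
  tun <- unit_tuning(rec$params, n_samples = 4000L)
  expect_equal(dim(tun$direction), c(8L, 8L))  # last layer has 8 units
  expect_equal(dim(tun$spatial), c(40L, 40L, 8L))
  # a unit with zero incoming weights is flat in both probes
  params <- rec$params
  params$W[[2]][1, ] <- 0; params$b[[2]][1] <- 0
  set.seed(3)
  tun0 <- unit_tuning(params, n_samples = 2000L)
  expect_equal(unname(tun0$direction[1, ]), rep(0, 8))
  expect_equal(stats::var(as.vector(tun0$spatial[, , 1]), na.rm = TRUE), 0)
})

test_that("RPE summaries expose omission identities and split sides", {
  arena <- arena_config("interleaved")
  rec <- train_agent(arena, ppo_config(n_step = 2L, episodes = 120L,
                                       naive_episodes = 120L,
                                       hidden = c(32L, 32L), seed = 5L))
  s <- summarize_rpes(rec)
  # omission RPE at the goal state equals -V exactly (r = 0)
  expect_true(length(s$naive$omission_rpes) > 0)
  expect_equal(s$naive$omission_rpes, -s$naive$omission_v_goal,
               tolerance = 1e-12)
  # every goal RPE is the realized reward minus the critic estimate
  ep <- rec$naive_episodes[rec$naive_episodes$success == 1, ]
  expect_equal(ep$rpe_goal, ep$reward - ep$v_goal, tolerance = 1e-12)
})

test_that("learning requires the critic: zero value loss abolishes improvement", {
  rec <- train_agent(arena_config("standard"),
                     ppo_config(n_step = 8L, episodes = 1000L,
                                naive_episodes = 150L, value_coef = 0,
                                seed = 3L))
  ex <- rpeacc:::expert_slice(rec)
  expect_lte(mean(ex$success), mean(rec$naive_episodes$success) + 0.1)
})

test_that("evaluation of frozen parameters is seeded and update-free", {
  rec <- train_agent(arena_config("standard"),
                     ppo_config(n_step = 1L, episodes = 10L,
                                naive_episodes = 5L, hidden = c(16L, 16L),
                                seed = 2L))
  a <- evaluate_agent(rec, "naive", episodes = 30L, seed = 9L)
  b <- evaluate_agent(rec, "naive", episodes = 30L, seed = 9L)
  expect_identical(a, b)
  expect_equal(nrow(a), 30L)
})
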