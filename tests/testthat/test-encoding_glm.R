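test_that("raised-cosine basis tiles the window without gaps", {
  b <- raised_cosine_basis()
  expect_equal(ncol(b$B), 6L)
  expect_true(all(b$B >= 0))
  expect_gt(max(b$B), 0.99)                 # unit peaks (up to grid sampling)
  expect_true(all(abs(b$tau) <= 2 + 1e-9))
  # compact support: zero beyond each bump's half-width, and the outermost
  # supports end exactly at the window edges
  expect_true(all(b$B[abs(outer(b$tau, b$centers, "-")) > b$width] == 0))
  expect_equal(b$centers[1] - b$width, -2, tolerance = 1e-12)
  expect_equal(b$centers[6] + b$width, 2, tolerance = 1e-12)
  # no coverage gap strictly inside the window
  interior <- abs(b$tau) < 2 - 1 / b$frame_rate
  expect_true(all(rowSums(b$B[interior, ]) > 0))
  # centers evenly spaced
  expect_equal(diff(b$centers), rep(diff(b$centers)[1], 5), tolerance = 1e-12)
})

test_that("basis convolution aligns the kernel with the event frame", {
  b <- raised_cosine_basis()
  x <- numeric(101); x[51] <- 1
  conv <- rpeacc:::convolve_basis(x, b)
  half <- (nrow(b$B) - 1) / 2
  for (j in 1:6)
    expect_equal(conv[51 + (-half:half), j], b$B[, j], tolerance = 1e-9)
})

test_that("design variants have the exact column counts", {
  fx <- fx_small()
  expect_equal(ncol(fx$dm$X), 138L)
  expect_equal(ncol(fx$dmc$X), 138L)
  dmm <- build_design_matrix(fx$ev, fx$session, variant = "modified_reward")
  dmmc <- build_design_matrix(fx$ev, fx$session, variant = "modified_control")
  expect_equal(ncol(dmm$X), 114L)
  expect_equal(ncol(dmmc$X), 108L)
  expect_equal(unname(table(fx$dm$groups)[c("objvel", "joyvel", "time")]),
               c(48L, 48L, 6L), ignore_attr = TRUE)
  # predictors are z-scored across the session
  live <- apply(fx$dm$X, 2, stats::sd) > 0
  expect_equal(colMeans(fx$dm$X[, live]), rep(0, sum(live)),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(apply(fx$dm$X[, live], 2, stats::sd), rep(1, sum(live)),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("pseudo explained variance matches a hand-coded deviance oracle", {
  # worked Poisson example
  expect_equal(pseudo_ev(c(2, 0, 1), c(2, 0.5, 0.5)), 0.5, tolerance = 1e-12)
  set.seed(8)
  y <- rpois(200, 2)
  expect_equal(pseudo_ev(y, rep(mean(y), 200)), 0)    # null prediction
  expect_equal(pseudo_ev(y + 0.5, y + 0.5), 1)        # perfect prediction
  expect_error(pseudo_ev(rep(3, 10), rep(2, 10)), "constant")

  hand_dev <- function(y, mu) {
    s <- 0
    for (i in seq_along(y)) {
      s <- s + (if (y[i] > 0) y[i] * log(y[i] / mu[i]) else 0) - (y[i] - mu[i])
    }
    2 * s
  }
  for (i in 1:20) {
    y <- rpois(50, 3); mu <- runif(50, 0.2, 6)
    expect_equal(pseudo_ev(y, mu), 1 - hand_dev(y, mu) / hand_dev(y, rep(mean(y), 50)),
                 tolerance = 1e-10)
    # invariant to reordering the (y, yhat) pairs
    o <- sample(50)
    expect_equal(pseudo_ev(y[o], mu[o]), pseudo_ev(y, mu), tolerance = 1e-12)
  }
})

test_that("planted-support neurons are recovered by the elastic-net fit", {
  fx <- fx_small()
  nr <- fx_neurons()
  i3 <- which(nr$truth$type == "error" & nr$truth$n == 3)[1]
  set.seed(31)
  fit <- fit_glm(nr$activity[i3, ], fx$dm)
  expect_s3_class(fit, "neuron_fit")
  expect_gt(fit$pseudo_ev, 0.2)
  by_grp <- tapply(abs(fit$beta), fx$dm$groups, max)
  expect_equal(names(which.max(by_grp[startsWith(names(by_grp), "err")])),
               "err3")
  expect_gt(by_grp["err3"], max(by_grp[c("objvel", "joyvel")]))
  expect_error(fit_glm(rep(0, nrow(fx$dm$X)), fx$dm), "all-zero")
})

test_that("the train/test split is contiguous and sized 70/30", {
  fx <- fx_small()
  nr <- fx_neurons()
  set.seed(55)
  fit <- fit_glm(nr$activity[1, ], fx$dm)
  n <- nrow(fx$dm$X)
  expect_equal(length(fit$split$test), round(0.3 * n))
  expect_equal(fit$split$test, seq(min(fit$split$test), max(fit$split$test)))
  expect_setequal(c(fit$split$train, fit$split$test), seq_len(n))
})

test_that("marginal responses factorize the model prediction", {
  fx <- fx_small()
  nr <- fx_neurons()
  set.seed(12)
  fit <- fit_glm(nr$activity[2, ], fx$dm)
  # product of per-variable contributions times the intercept equals the
  # full prediction (exp of a sum)
  vars <- rpeacc:::variable_groups(fit$groups)
  pred <- exp(fit$intercept) * Reduce(`*`, lapply(unique(vars), function(v) {
    sel <- vars == v
    exp(as.numeric(fx$dm$X[, sel, drop = FALSE] %*% fit$beta[sel]))
  }))
  expect_equal(pred, predict(fit, fx$dm), tolerance = 1e-9)

  # all-zero coefficients give a flat profile of 1
  fit0 <- fit
  fit0$beta[] <- 0
  mr <- marginal_response(fit0, "err1")
  expect_equal(mr$response, rep(1, nrow(mr)))

  # a planted error neuron's kernel is recovered up to scale
  i2 <- which(nr$truth$type == "error" & nr$truth$n == 2)[1]
  set.seed(13)
  f2 <- fit_glm(nr$activity[i2, ], fx$dm)
  mr2 <- marginal_response(f2, "err2")
  b <- raised_cosine_basis()
  causal <- c(0, 0, 0.15, 1, 0.55, 0.15); causal <- causal / max(causal) * 3
  planted <- as.numeric(b$B %*% causal)
  cosim <- sum(log(mr2$response) * planted) /
    sqrt(sum(log(mr2$response)^2) * sum(planted^2))
  expect_gt(cosim, 0.9)
})

test_that("task-related and error classifications behave on planted neurons", {
  fx <- fx_small()
  nr <- fx_neurons()
  cfg <- glm_config(n_shuffles = 200L)
  i1 <- which(nr$truth$type == "error" & nr$truth$n == 1)[1]
  set.seed(21)
  f <- classify_task_related(fit_glm(nr$activity[i1, ], fx$dm, cfg), fx$dm,
                             nr$activity[i1, ])
  expect_true(f$task_related)
  expect_true(f$contributions$contributing[f$contributions$variable == "error"])
  ctrl <- fit_glm(nr$activity[i1, ], fx$dmc, cfg)
  f <- classify_error_neuron(f, ctrl)
  expect_true(f$error_related)
  expect_equal(f$assigned_n, 1L)

  # a velocity-tuned neuron is task related but not error related
  iv <- which(nr$truth$type == "objvel")[1]
  set.seed(22)
  fv <- classify_task_related(fit_glm(nr$activity[iv, ], fx$dm, cfg), fx$dm,
                              nr$activity[iv, ])
  if (fv$task_related) {
    ctrlv <- fit_glm(nr$activity[iv, ], fx$dmc, cfg)
    fv <- classify_error_neuron(fv, ctrlv)
    expect_false(fv$error_related)
  }
})
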