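#' Raised-cosine temporal basis
#'
#' Six evenly spaced raised-cosine bumps tiling a window extending 2 s forward
#' and backward in time, sampled on the imaging frame grid. Each function is
#' \eqn{b_j(\tau) = (1 + \cos(\pi (\tau - c_j)/w))/2} on
#' \eqn{|\tau - c_j| \le w} and 0 outside, with unit peak. Centers and
#' half-width are chosen so that the outermost supports end exactly at
#' \eqn{\pm 2} s and the bumps overlap with no coverage gap: with 6 centers,
#' spacing is 4/9 s and the half-width 8/9 s.
#'
#' @param frame_rate imaging frame rate in Hz (default 5.67).
#' @param span half-window in seconds (default 2).
#' @param n_basis number of bumps (default 6).
#' @return an object of class `"basis_set"`: list with `tau` (lag grid, s),
#'   `B` (length(tau) x n_basis matrix), `centers`, `width`.
#' @export
raised_cosine_basis <- function(frame_rate = 5.67, span = 2, n_basis = 6L) {
  stopifnot(frame_rate > 0, span > 0, n_basis >= 2L)
  # supports must stay inside [-span, span]: c_1 - w = -span, c_n + w = span,
  # with w = 2 * spacing
  spacing <- 2 * span / (n_basis + 3)
  w <- 2 * spacing
  centers <- seq(-span + w, span - w, length.out = n_basis)
  half_taps <- floor(span * frame_rate)
  tau <- (-half_taps:half_taps) / frame_rate
  B <- vapply(centers, function(cj) {
    v <- 0.5 * (1 + cos(pi * (tau - cj) / w))
    v[abs(tau - cj) > w] <- 0
    v
  }, numeric(length(tau)))
  structure(list(tau = tau, B = B, centers = centers, width = w,
                 frame_rate = frame_rate),
            class = "basis_set")
}

# centered convolution of a frame series with each basis column; the value at
# lag 0 aligns with the event frame, positive lags follow it
convolve_basis <- function(x, basis) {
  n <- length(x)
  L <- nrow(basis$B)
  half <- (L - 1L) / 2L
  xp <- c(rep(0, half), x, rep(0, half))
  out <- matrix(0, n, ncol(basis$B))
  for (j in seq_len(ncol(basis$B))) {
    # stats::filter with sides = 2 cross-correlates the centered kernel,
    # which for our symmetric lag grid places b(tau) at event time + tau
    y <- stats::filter(xp, basis$B[, j], method = "convolution", sides = 2)
    out[, j] <- y[(half + 1L):(half + n)]
  }
  out
}

#' Imaging frame grid of a session
#'
#' @param session a [trajectory_session()].
#' @param frame_rate frames per second (default 5.67).
#' @return numeric vector of frame times spanning the session.
#' @export
frame_grid <- function(session, frame_rate = 5.67) {
  t_end <- max(session$trajectory$t, session$trials$t_end)
  seq(0, t_end, by = 1 / frame_rate)
}

impulse_series <- function(times, frame_times) {
  x <- numeric(length(frame_times))
  if (length(times)) {
    idx <- vapply(times, function(tt) which.min(abs(frame_times - tt)),
                  integer(1))
    for (i in idx) x[i] <- x[i] + 1
  }
  x
}

# per-frame mean velocity (mm/s) of a 10-ms trajectory; zero outside trials
frame_velocity <- function(traj, frame_times, dt) {
  n <- length(frame_times)
  vx_s <- c(0, diff(traj$x)) / dt
  vy_s <- c(0, diff(traj$y)) / dt
  # zero across trial boundaries
  new_trial <- c(TRUE, diff(traj$trial) != 0)
  vx_s[new_trial] <- 0; vy_s[new_trial] <- 0
  frame_of <- findInterval(traj$t, frame_times)
  ok <- frame_of >= 1 & frame_of <= n
  vx <- numeric(n); vy <- numeric(n); cnt <- numeric(n)
  sx <- rowsum(vx_s[ok], frame_of[ok])
  sy <- rowsum(vy_s[ok], frame_of[ok])
  cc <- rowsum(rep(1, sum(ok)), frame_of[ok])
  pos <- as.integer(rownames(sx))
  vx[pos] <- sx / cc; vy[pos] <- sy / cc
  cbind(vx, vy)
}

velocity_bins <- function(v) {
  speed <- sqrt(rowSums(v^2))
  ang <- atan2(v[, 2], v[, 1]) * 180 / pi
  ang[ang < 0] <- ang[ang < 0] + 360
  bin <- (round(ang / 45) %% 8) + 1L     # nearest of 0, 45, ..., 315 degrees
  out <- matrix(0, nrow(v), 8L)
  nz <- speed > 0
  out[cbind(which(nz), bin[nz])] <- speed[nz]
  out
}

zscore_cols <- function(X) {
  for (j in seq_len(ncol(X))) {
    s <- stats::sd(X[, j])
    X[, j] <- if (s > 0) (X[, j] - mean(X[, j])) / s else 0
  }
  X
}

away_onsets <- function(events, n_max) {
  ev <- events$events[events$events$class == "away", , drop = FALSE]
  out <- list()
  for (tr in split(ev, ev$trial)) {
    nn <- seq_len(min(nrow(tr), n_max))
    out[[length(out) + 1L]] <- data.frame(trial = tr$trial[1], n = nn,
                                          time = sort(tr$time)[nn])
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(trial = integer(), n = integer(), time = numeric())
}

#' Build a GLM design matrix from a behavioral session
#'
#' Event predictors (single-frame impulses at the n-step accumulation onsets),
#' object- and joystick-velocity predictors (velocity angle discretized into 8
#' bins carrying movement amplitude), and the passage of time (frame count
#' within each trial) are each convolved with the raised-cosine basis and
#' z-scored across the session. Variants:
#' \describe{
#'   \item{standard}{n-step toward-error onsets, n = 1..6 (36 columns) +
#'     object velocity (48) + joystick velocity (48) + time (6) = 138.}
#'   \item{control}{away-movement accumulation onsets replace the error
#'     predictors; 138 columns.}
#'   \item{modified_reward}{single-step (n = 1) error onsets split by
#'     high/low reward side (12) + velocities (96) + time (6) = 114.}
#'   \item{modified_control}{single-step away onsets (6) + velocities (96) +
#'     time (6) = 108.}
#' }
#'
#' @param events an [detect_errors()] result for the session.
#' @param session the [trajectory_session()].
#' @param frame_times frame grid (default [frame_grid()] at 5.67 Hz).
#' @param variant design variant, see above.
#' @param basis a [raised_cosine_basis()].
#' @return an object of class `"design_matrix"`: list with `X` (frames x
#'   columns, z-scored), `groups` (column group labels), `frame_times`,
#'   `basis`, `variant`.
#' @export
build_design_matrix <- function(events, session,
                                frame_times = frame_grid(session),
                                variant = c("standard", "control",
                                            "modified_reward",
                                            "modified_control"),
                                basis = raised_cosine_basis()) {
  variant <- match.arg(variant)
  stopifnot(inherits(events, "error_events"),
            inherits(session, "trajectory_session"))
  n_max <- events$n_max

  event_block <- function(onsets_df, labels_n) {
    cols <- list(); labs <- character()
    for (nn in labels_n) {
      tt <- onsets_df$time[onsets_df$n == nn]
      conv <- convolve_basis(impulse_series(tt, frame_times), basis)
      cols[[length(cols) + 1L]] <- conv
      labs <- c(labs, rep(paste0("err", nn), ncol(conv)))
    }
    list(X = do.call(cbind, cols), labs = labs)
  }

  if (variant == "standard") {
    eb <- event_block(events$onsets, seq_len(n_max))
  } else if (variant == "control") {
    eb <- event_block(away_onsets(events, n_max), seq_len(n_max))
    eb$labs <- sub("^err", "ctrl", eb$labs)
  } else if (variant == "modified_reward") {
    ev1 <- events$onsets[events$onsets$n == 1L, , drop = FALSE]
    if (!nrow(ev1) || is.null(events$events$side))
      stop("modified_reward variant requires side-labelled single-step errors")
    side_of <- function(tt) {
      i <- vapply(tt, function(x)
        which.min(abs(events$events$time - x)), integer(1))
      events$events$side[i]
    }
    sides <- side_of(ev1$time)
    xh <- convolve_basis(impulse_series(ev1$time[sides == "high"],
                                        frame_times), basis)
    xl <- convolve_basis(impulse_series(ev1$time[sides == "low"],
                                        frame_times), basis)
    eb <- list(X = cbind(xh, xl),
               labs = c(rep("err_high", ncol(xh)), rep("err_low", ncol(xl))))
  } else {
    aw <- away_onsets(events, n_max)
    aw1 <- aw[aw$n == 1L, , drop = FALSE]
    x1 <- convolve_basis(impulse_series(aw1$time, frame_times), basis)
    eb <- list(X = x1, labs = rep("ctrl1", ncol(x1)))
  }

  vel_block <- function(traj, tag) {
    vb <- velocity_bins(frame_velocity(traj, frame_times, session$dt))
    cols <- list(); labs <- character()
    for (d in seq_len(8L)) {
      conv <- convolve_basis(vb[, d], basis)
      cols[[length(cols) + 1L]] <- conv
      labs <- c(labs, rep(tag, ncol(conv)))
    }
    list(X = do.call(cbind, cols), labs = labs)
  }
  ob <- vel_block(session$trajectory, "objvel")
  joy <- if (!is.null(session$joystick)) session$joystick else
    session$trajectory
  jb <- vel_block(joy, "joyvel")

  # passage of time: monotonic frame count within each trial, 0 in the ITI
  tcount <- numeric(length(frame_times))
  for (i in seq_len(nrow(session$trials))) {
    sel <- frame_times >= session$trials$t_start[i] &
      frame_times <= session$trials$t_end[i]
    tcount[sel] <- seq_len(sum(sel))
  }
  tb <- convolve_basis(tcount, basis)

  X <- cbind(eb$X, ob$X, jb$X, tb)
  groups <- c(eb$labs, ob$labs, jb$labs, rep("time", ncol(tb)))
  colnames(X) <- paste0(groups, "_b",
                        stats::ave(seq_along(groups), groups, FUN = seq_along))
  structure(list(X = zscore_cols(X), groups = groups,
                 frame_times = frame_times, basis = basis, variant = variant),
            class = "design_matrix")
}

#' @method print design_matrix
#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("design matrix (%s): %d frames x %d predictors\n",
              x$variant, nrow(x$X), ncol(x$X)))
  print(table(x$groups))
  invisible(x)
}

#' Deviance-based pseudo explained variance
#'
#' \eqn{1 - D(\hat y)/D(\bar y)}, where \eqn{D} is the family deviance from
#' the saturated model and \eqn{\bar y} the mean-activity null prediction.
#' For the Poisson family \eqn{D(\hat y) = 2\sum[y \log(y/\hat y) -
#' (y - \hat y)]} with \eqn{y \log y = 0} at \eqn{y = 0}.
#'
#' @param y observed nonnegative activity.
#' @param yhat predicted activity (> 0).
#' @param family deviance family; only `"poisson"` is implemented.
#' @return scalar pseudo-E.V. (1 for a perfect fit, 0 for the null).
#' @export
pseudo_ev <- function(y, yhat, family = "poisson") {
  stopifnot(length(y) == length(yhat), family == "poisson")
  d_null <- poisson_deviance(y, rep(mean(y), length(y)))
  if (d_null == 0) stop("constant activity: null deviance is zero")
  1 - poisson_deviance(y, yhat) / d_null
}

poisson_deviance <- function(y, mu) {
  mu <- pmax(mu, 1e-12)
  term <- ifelse(y > 0, y * log(y / mu), 0)
  2 * sum(term - (y - mu))
}

#' Configuration of the encoding-model fit
#'
#' @param alpha elastic-net mixing (0.9: mostly lasso with a ridge component).
#' @param train_frac fraction of frames in the training set (contiguous
#'   blocks; the held-out 30\% is a contiguous block chosen by seed).
#' @param nfolds cross-validation folds on the training frames.
#' @param n_shuffles circular block-shuffles for the significance tests.
#' @param shuffle_block block length in seconds for the shuffles.
#' @param alpha_level significance threshold.
#' @param activity_threshold inclusion threshold: a neuron enters the analysis
#'   only if its activity exceeds this value at least once.
#' @return an object of class `"glm_config"`.
#' @export
glm_config <- function(alpha = 0.9, train_frac = 0.7, nfolds = 5L,
                       n_shuffles = 1000L, shuffle_block = 2,
                       alpha_level = 0.05, activity_threshold = 20) {
  stopifnot(alpha > 0, alpha <= 1, train_frac > 0, train_frac < 1,
            nfolds >= 2L, n_shuffles >= 1L)
  structure(list(alpha = alpha, train_frac = train_frac,
                 nfolds = as.integer(nfolds),
                 n_shuffles = as.integer(n_shuffles),
                 shuffle_block = shuffle_block, alpha_level = alpha_level,
                 activity_threshold = activity_threshold),
            class = "glm_config")
}

train_test_split <- function(n, train_frac) {
  n_test <- round(n * (1 - train_frac))
  start <- sample.int(n - n_test + 1L, 1L)
  test <- start:(start + n_test - 1L)
  list(train = setdiff(seq_len(n), test), test = test)
}

#' Fit an elastic-net Poisson encoding model to one neuron
#'
#' Fits a log-link Poisson GLM with elastic-net regularization (`glmnet`,
#' alpha = 0.9) on a contiguous 70\% of frames, selecting the penalty by
#' 5-fold blocked cross-validation, and evaluates the pseudo-E.V. on the
#' held-out 30\%.
#'
#' @param activity nonnegative per-frame activity trace.
#' @param design a [build_design_matrix()] result.
#' @param config a [glm_config()].
#' @return an object of class `"neuron_fit"`: intercept, `beta` (named
#'   coefficients), `groups`, `pseudo_ev` (held-out), the train/test split
#'   and the fitted `glmnet` path object.
#' @export
fit_glm <- function(activity, design, config = glm_config()) {
  stopifnot(inherits(design, "design_matrix"),
            length(activity) == nrow(design$X))
  if (all(activity == 0)) stop("degenerate input: all-zero activity trace")
  split <- train_test_split(length(activity), config$train_frac)
  Xtr <- design$X[split$train, , drop = FALSE]
  ytr <- activity[split$train]
  foldid <- as.integer(cut(seq_along(split$train), config$nfolds,
                           labels = FALSE))
  cvfit <- suppressWarnings(glmnet::cv.glmnet(
    Xtr, ytr, family = "poisson", alpha = config$alpha,
    foldid = foldid, nlambda = 25, lambda.min.ratio = 1e-3, thresh = 1e-4,
    dfmax = 80, standardize = FALSE))
  beta <- as.numeric(coef(cvfit, s = "lambda.min"))
  names(beta) <- c("(Intercept)", colnames(design$X))
  eta_test <- beta[1] + as.numeric(design$X[split$test, , drop = FALSE] %*%
                                     beta[-1])
  ev <- pseudo_ev(activity[split$test], exp(eta_test))
  structure(list(intercept = beta[1], beta = beta[-1],
                 groups = design$groups, pseudo_ev = ev, split = split,
                 cvfit = cvfit, config = config),
            class = "neuron_fit")
}

#' @method print neuron_fit
#' @export
print.neuron_fit <- function(x, ...) {
  cat(sprintf("Poisson elastic-net encoding fit: %d predictors, %d nonzero, held-out pseudo-E.V. %.4f\n",
              length(x$beta), sum(x$beta != 0), x$pseudo_ev))
  invisible(x)
}

#' @method coef neuron_fit
#' @export
coef.neuron_fit <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$beta)
}

#' @method predict neuron_fit
#' @export
predict.neuron_fit <- function(object, design, type = c("response", "link"),
                               ...) {
  type <- match.arg(type)
  eta <- object$intercept + as.numeric(design$X %*% object$beta)
  if (type == "response") exp(eta) else eta
}

# top-level task variables used for the contribution tests
variable_groups <- function(groups) {
  g <- groups
  g[startsWith(g, "err")] <- "error"
  g[startsWith(g, "ctrl")] <- "error"
  g
}

# circular row rotation by whole blocks, the shuffle that preserves
# within-block autocorrelation
block_shifts <- function(n_frames, block_frames, n_shuffles) {
  n_blocks <- max(2L, floor(n_frames / block_frames))
  sample.int(n_blocks - 1L, n_shuffles, replace = TRUE) * block_frames
}

rotate_vec <- function(x, k) {
  n <- length(x)
  k <- k %% n
  if (k == 0) x else c(x[(n - k + 1L):n], x[seq_len(n - k)])
}

#' Task-relatedness of a fitted neuron
#'
#' A neuron is task related if its held-out pseudo-E.V. is positive and
#' exceeds the null distribution obtained by circularly rotating the task
#' predictors in 2-s blocks (1000 shuffles, P < 0.05), and at least one task
#' variable (n-step errors, object velocity, joystick velocity, time)
#' contributes: the variable's own contribution has positive pseudo-E.V. and
#' rotating that variable alone significantly reduces the model's pseudo-E.V.
#'
#' @param fit a [fit_glm()] result.
#' @param design the design matrix used for the fit.
#' @param activity the neuron's activity trace.
#' @return the fit with fields `task_related`, `p_task`, and `contributions`
#'   (per-variable data frame) added.
#' @export
classify_task_related <- function(fit, design, activity) {
  stopifnot(inherits(fit, "neuron_fit"))
  cfg <- fit$config
  test <- fit$split$test
  y <- activity[test]
  n <- nrow(design$X)
  frame_rate <- design$basis$frame_rate
  block <- max(1L, round(cfg$shuffle_block * frame_rate))
  shifts <- block_shifts(n, block, cfg$n_shuffles)

  # fast held-out pseudo-E.V. from a linear predictor: the Poisson deviance
  # is C + 2*sum(mu - y*log mu) with C depending on y only, so C cancels
  # against the null deviance computed once
  C0 <- 2 * sum(ifelse(y > 0, y * log(y), 0) - y)
  d_null <- C0 + 2 * sum(mean(y) - y * log(mean(y)))
  if (d_null == 0) stop("constant activity: null deviance is zero")
  ev_of <- function(eta) 1 - (C0 + 2 * sum(exp(eta) - y * eta)) / d_null

  contrib_all <- as.numeric(design$X %*% fit$beta)
  ev_obs <- ev_of(fit$intercept + contrib_all[test])

  ev_null <- vapply(shifts, function(k)
    ev_of(fit$intercept + rotate_vec(contrib_all, k)[test]), numeric(1))
  p_task <- (1 + sum(ev_null >= ev_obs)) / (length(shifts) + 1)

  vars <- variable_groups(fit$groups)
  rows <- lapply(unique(vars), function(v) {
    sel <- vars == v
    c_v <- as.numeric(design$X[, sel, drop = FALSE] %*% fit$beta[sel])
    c_rest <- (fit$intercept + contrib_all - c_v)[test]
    ev_alone <- ev_of(fit$intercept + c_v[test])
    ev_removed <- ev_of(c_rest)
    ev_rot <- vapply(shifts, function(k)
      ev_of(c_rest + rotate_vec(c_v, k)[test]), numeric(1))
    p_v <- (1 + sum(ev_rot >= ev_obs)) / (length(shifts) + 1)
    data.frame(variable = v, ev_alone = ev_alone, ev_removed = ev_removed,
               drop = ev_obs - ev_removed, p = p_v,
               contributing = ev_alone > 0 & p_v < cfg$alpha_level)
  })
  fit$contributions <- do.call(rbind, rows)
  fit$p_task <- p_task
  fit$task_related <- ev_obs > 0 && p_task < cfg$alpha_level &&
    any(fit$contributions$contributing)
  fit
}

# coefficient strength of a predictor group: the group's columns are split
# into kernels of n_basis consecutive columns (one per n for errors, one per
# direction for velocities) and each kernel is summarized by the sum of its
# positive coefficients; the group's strength is the strongest kernel
group_strength <- function(fit, prefix, n_basis = 6L) {
  sel <- which(startsWith(fit$groups, prefix))
  if (!length(sel)) return(-Inf)
  chunks <- split(sel, ceiling(seq_along(sel) / n_basis))
  max(vapply(chunks, function(s) sum(pmax(fit$beta[s], 0)), numeric(1)))
}

#' Model-derived marginal response profile of one variable group
#'
#' The Poisson GLM predicts activity as the exponentiated weighted sum of the
#' task predictors, so the prediction factorizes into per-variable
#' multiplicative contributions. The marginal response of a group to a single
#' event is \eqn{\exp(\sum_j \beta_j b_j(\tau))} over the basis lag grid,
#' with all other variables at their session mean (contribution 1).
#'
#' @param fit a [fit_glm()] result.
#' @param group group label (e.g. `"err3"`, `"objvel"`).
#' @param basis the basis used in the design (defaults to the standard one).
#' @return data frame with `tau` (s) and `response` (multiplicative gain).
#' @export
marginal_response <- function(fit, group, basis = raised_cosine_basis()) {
  sel <- fit$groups == group
  if (!any(sel)) stop("unknown group: ", group)
  k <- as.numeric(basis$B %*% fit$beta[sel])
  data.frame(tau = basis$tau, response = exp(k))
}

#' Classify an error-encoding neuron and assign its n
#'
#' A task-related neuron is error encoding if (i) rotating the error
#' predictors significantly deteriorates held-out performance, (ii) the error
#' coefficients exceed the object- and joystick-velocity coefficients, (iii)
#' they exceed the coefficients obtained for the away-movement control
#' predictors in a separate control fit, and (iv) the model-derived response
#' at the assigned n is excitatory. Each group's coefficients are summarized
#' kernel-wise (per n for errors, per direction for velocities) by the sum of
#' positive coefficients across the kernel's basis columns, taking the
#' strongest kernel; `assigned_n` is the argmax across n of the per-n summary.
#'
#' @param fit a classified [classify_task_related()] fit on the standard
#'   design.
#' @param control_fit a [fit_glm()] on the away-control design.
#' @param basis basis for the excitatory-modulation check.
#' @return the fit with `error_related`, `assigned_n` and the comparison
#'   summaries added.
#' @export
classify_error_neuron <- function(fit, control_fit,
                                  basis = raised_cosine_basis()) {
  stopifnot(inherits(fit, "neuron_fit"), !is.null(fit$task_related))
  err_p <- fit$contributions$p[fit$contributions$variable == "error"]
  err_contributes <- length(err_p) == 1 && err_p < fit$config$alpha_level

  n_vals <- sort(unique(as.integer(sub("^err", "",
    grep("^err[0-9]+$", unique(fit$groups), value = TRUE)))))
  per_n <- vapply(n_vals, function(nn) group_strength(fit, paste0("err", nn)),
                  numeric(1))
  err_max <- max(per_n)
  obj_max <- group_strength(fit, "objvel")
  joy_max <- group_strength(fit, "joyvel")
  ctrl_max <- group_strength(control_fit, "ctrl")

  assigned <- n_vals[which.max(per_n)]
  resp <- marginal_response(fit, paste0("err", assigned), basis)
  excitatory <- max(resp$response) > 1

  fit$error_summary <- list(per_n = stats::setNames(per_n, paste0("n", n_vals)),
                            obj_max = obj_max, joy_max = joy_max,
                            ctrl_max = ctrl_max)
  fit$error_related <- isTRUE(fit$task_related) && err_contributes &&
    err_max > obj_max && err_max > joy_max && err_max > ctrl_max && excitatory
  fit$assigned_n <- if (fit$error_related) assigned else NA_integer_
  fit
}

# do the control-free error conditions hold? (error variable contributes,
# error coefficients dominate both velocity groups)
error_precheck <- function(fit) {
  err_p <- fit$contributions$p[fit$contributions$variable == "error"]
  if (length(err_p) != 1 || err_p >= fit$config$alpha_level) return(FALSE)
  err_max <- group_strength(fit, "err")
  err_max > group_strength(fit, "objvel") &&
    err_max > group_strength(fit, "joyvel")
}

#' Fit and classify a population of neurons
#'
#' Applies the inclusion threshold, fits the standard and control designs,
#' runs the task-related and error-neuron classifications, and returns a
#' per-neuron table.
#'
#' @param activity neurons x frames matrix of nonnegative traces.
#' @param design standard-variant design matrix.
#' @param control_design away-control design matrix.
#' @param config a [glm_config()].
#' @param regions optional per-neuron region labels.
#' @param progress print progress every so many neurons (0 = silent).
#' @return list with `table` (data frame: neuron, region, included,
#'   task_related, error_related, assigned_n, pseudo_ev) and `fits` (list of
#'   classified fits, `NULL` for excluded neurons).
#' @export
fit_population <- function(activity, design, control_design,
                           config = glm_config(), regions = NULL,
                           progress = 0L) {
  n_neurons <- nrow(activity)
  if (is.null(regions)) regions <- rep(NA_character_, n_neurons)
  fits <- vector("list", n_neurons)
  tab <- data.frame(neuron = seq_len(n_neurons), region = regions,
                    included = FALSE, task_related = FALSE,
                    error_related = FALSE, assigned_n = NA_integer_,
                    pseudo_ev = NA_real_)
  for (i in seq_len(n_neurons)) {
    y <- activity[i, ]
    if (max(y) < config$activity_threshold || all(y == 0)) next
    tab$included[i] <- TRUE
    fit <- classify_task_related(fit_glm(y, design, config), design, y)
    tab$pseudo_ev[i] <- fit$pseudo_ev
    tab$task_related[i] <- fit$task_related
    if (fit$task_related) {
      # the control fit only matters when the cheap coefficient comparisons
      # already favor the error predictors
      if (error_precheck(fit)) {
        ctrl <- fit_glm(y, control_design, config)
        fit <- classify_error_neuron(fit, ctrl)
      } else {
        fit$error_related <- FALSE
        fit$assigned_n <- NA_integer_
      }
      tab$error_related[i] <- fit$error_related
      tab$assigned_n[i] <- fit$assigned_n
    }
    fits[[i]] <- fit
    if (progress > 0 && i %% progress == 0)
      message(sprintf("fit %d / %d neurons", i, n_neurons))
  }
  list(table = tab, fits = fits)
}
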