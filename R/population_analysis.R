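#' Per-trial activity onsets
#'
#' The onset of a neuron in a trial is the first frame of that trial at which
#' its activity, z-scored over the entire session, exceeds 2.
#'
#' @param activity neurons x frames matrix.
#' @param frame_times frame time stamps (s).
#' @param trials trial table with `t_start`, `t_end`.
#' @param z_threshold onset threshold (default 2).
#' @return trials x neurons matrix of onset frame indices (`NA` if the neuron
#'   never crosses the threshold in that trial).
#' @export
activity_onsets <- function(activity, frame_times, trials, z_threshold = 2) {
  z <- t(scale(t(activity)))
  n_tr <- nrow(trials)
  out <- matrix(NA_integer_, n_tr, nrow(activity))
  for (i in seq_len(n_tr)) {
    fr <- which(frame_times >= trials$t_start[i] &
                  frame_times <= trials$t_end[i])
    if (!length(fr)) next
    for (j in seq_len(nrow(activity))) {
      k <- which(z[j, fr] > z_threshold)
      if (length(k)) out[i, j] <- fr[k[1]]
    }
  }
  out
}

slope_from_onsets <- function(train_idx, test_idx, onsets) {
  train_mean <- colMeans(onsets[train_idx, , drop = FALSE], na.rm = TRUE)
  active <- which(!is.nan(train_mean))
  if (length(active) < 2) return(NA_real_)
  sort_index <- rank(train_mean[active], ties.method = "first")
  x <- (sort_index - 1) / (length(active) - 1)
  # trial-averaged normalized rank on the held-out trials
  ranks <- matrix(NA_real_, length(test_idx), length(active))
  for (k in seq_along(test_idx)) {
    o <- onsets[test_idx[k], active]
    a <- which(!is.na(o))
    if (length(a) < 2) next
    ranks[k, a] <- (rank(o[a], ties.method = "first") - 1) / (length(a) - 1)
  }
  y <- colMeans(ranks, na.rm = TRUE)
  ok <- !is.nan(y)
  if (sum(ok) < 2) return(NA_real_)
  unname(stats::coef(stats::lm(y[ok] ~ x[ok]))[2])
}

#' Sequential-activity slope with a permutation null
#'
#' Neurons are sorted by their mean activity-onset order in a random half of
#' the trials (training set); on the other half the trial-averaged onset rank
#' is regressed on the sorting index (both normalized to \[0, 1\]). A slope of
#' 1 indicates perfectly consistent sequential activation across trials; a
#' slope of 0, no consistency. The null distribution is obtained by shuffling
#' onsets across neurons within each held-out trial.
#'
#' @param activity neurons x frames matrix.
#' @param frame_times frame times (s).
#' @param trials trial table with `t_start`, `t_end`.
#' @param n_perm permutation count (default 1000).
#' @return an object of class `"sequential_slope"`: list with `slope`,
#'   `null` (permutation slopes), `p`, and the train/test trial split.
#' @export
sequential_slope <- function(activity, frame_times, trials, n_perm = 1000L) {
  onsets <- activity_onsets(activity, frame_times, trials)
  usable <- which(rowSums(!is.na(onsets)) >= 2)
  if (length(usable) < 2)
    stop("fewer than two trials with at least two active neurons")
  if (all(is.na(onsets))) stop("no neuron crosses the onset threshold")
  half <- sample(usable, floor(length(usable) / 2))
  train_idx <- sort(half)
  test_idx <- setdiff(usable, half)
  obs <- slope_from_onsets(train_idx, test_idx, onsets)
  null <- vapply(seq_len(n_perm), function(s) {
    shuf <- onsets
    for (i in test_idx) {
      a <- which(!is.na(shuf[i, ]))
      shuf[i, a] <- shuf[i, sample(a)]
    }
    slope_from_onsets(train_idx, test_idx, shuf)
  }, numeric(1))
  p <- (1 + sum(null >= obs, na.rm = TRUE)) / (n_perm + 1)
  structure(list(slope = obs, null = null, p = p, train = train_idx,
                 test = test_idx),
            class = "sequential_slope")
}

#' @method print sequential_slope
#' @export
print.sequential_slope <- function(x, ...) {
  cat(sprintf("sequential-activity slope: %.3f (permutation p = %.4g, %d shuffles)\n",
              x$slope, x$p, length(x$null)))
  invisible(x)
}

#' Peri-event activity matrix
#'
#' @param trace one neuron's per-frame activity.
#' @param frame_times frame times (s).
#' @param event_times event times (s).
#' @param window window around the event (s).
#' @return events x frames matrix; column lags in `attr(, "lags")`.
#' @export
peri_event_activity <- function(trace, frame_times, event_times,
                                window = c(-4, 4)) {
  dt <- stats::median(diff(frame_times))
  lags <- seq(window[1], window[2], by = dt)
  out <- matrix(NA_real_, length(event_times), length(lags))
  for (i in seq_along(event_times)) {
    idx <- round((event_times[i] + lags - frame_times[1]) / dt) + 1L
    ok <- idx >= 1 & idx <= length(trace)
    out[i, ok] <- trace[idx[ok]]
  }
  attr(out, "lags") <- lags
  out
}

boot_p_greater <- function(stat_fn, n_boot) {
  stats_b <- vapply(seq_len(n_boot), function(i) stat_fn(), numeric(1))
  (1 + sum(stats_b <= 0, na.rm = TRUE)) / (n_boot + 1)
}

epoch_mean <- function(peri, lags, lo, hi) {
  sel <- lags >= lo & lags <= hi
  rowMeans(peri[, sel, drop = FALSE], na.rm = TRUE)
}

#' Classify a neuron's RPE sign at trial offset (interleaved schedule)
#'
#' Using peri-trial-offset activity from rewarded and omission trials, a
#' neuron carries a positive RPE signal if, on rewarded trials, its
#' reward-epoch mean (0-2 s) exceeds baseline (-4 to -3.5 s), exceeds the
#' omission-trial reward-epoch mean, and its post-offset peak exceeds the
#' pre-offset (-2 to 0 s) peak -- each by a one-tailed trial bootstrap at
#' P < 0.01. A negative RPE signal satisfies the mirrored conditions on
#' omission trials. Otherwise the label is `"none"`.
#'
#' @param peri events x frames matrix from [peri_event_activity()] around
#'   trial offsets (window must cover -4 to 2 s).
#' @param rewarded logical flag per trial (row of `peri`).
#' @param n_boot bootstrap resamples.
#' @param alpha significance threshold (default 0.01).
#' @return an object of class `"rpe_class"`: list with `label`, and the three
#'   p-values for each candidate sign.
#' @export
classify_rpe_sign <- function(peri, rewarded, n_boot = 1000L, alpha = 0.01) {
  lags <- attr(peri, "lags")
  if (!any(rewarded) || all(rewarded))
    stop("both rewarded and omission trials are required")
  base <- epoch_mean(peri, lags, -4, -3.5)
  rew <- epoch_mean(peri, lags, 0, 2)
  test_sign <- function(target) {
    sel <- if (target == "positive") rewarded else !rewarded
    oth <- !sel
    idx <- which(sel); idx_o <- which(oth)
    post_sel <- lags >= 0 & lags <= 2
    pre_sel <- lags >= -2 & lags <= 0
    p1 <- boot_p_greater(function() {
      i <- sample(idx, replace = TRUE)
      mean(rew[i] - base[i], na.rm = TRUE)
    }, n_boot)
    p2 <- boot_p_greater(function() {
      i <- sample(idx, replace = TRUE); j <- sample(idx_o, replace = TRUE)
      mean(rew[i], na.rm = TRUE) - mean(rew[j], na.rm = TRUE)
    }, n_boot)
    p3 <- boot_p_greater(function() {
      i <- sample(idx, replace = TRUE)
      m <- colMeans(peri[i, , drop = FALSE], na.rm = TRUE)
      max(m[post_sel]) - max(m[pre_sel])
    }, n_boot)
    c(p1, p2, p3)
  }
  p_pos <- test_sign("positive")
  p_neg <- test_sign("negative")
  label <- if (all(p_pos < alpha)) "positive"
    else if (all(p_neg < alpha)) "negative" else "none"
  structure(list(label = label, p_positive = p_pos, p_negative = p_neg),
            class = "rpe_class")
}

#' @method print rpe_class
#' @export
print.rpe_class <- function(x, ...) {
  cat(sprintf("RPE-sign class: %s\n", x$label))
  invisible(x)
}

#' Baseline-subtracted reward-evoked responses
#'
#' Per neuron, the mean activity 0-0.5 s after reward delivery minus the
#' baseline activity at -4 s relative to delivery, averaged over reward
#' events. The group comparison (e.g. naive vs expert populations) is a
#' one-tailed bootstrap over neurons.
#'
#' @param activity neurons x frames matrix.
#' @param frame_times frame times (s).
#' @param reward_times reward delivery times (s).
#' @param window response window (s).
#' @param baseline_at baseline lag (s).
#' @return numeric vector of per-neuron responses.
#' @export
reward_evoked_response <- function(activity, frame_times, reward_times,
                                   window = c(0, 0.5), baseline_at = -4) {
  vapply(seq_len(nrow(activity)), function(i) {
    peri <- peri_event_activity(activity[i, ], frame_times, reward_times,
                                window = c(baseline_at, window[2]))
    lags <- attr(peri, "lags")
    resp <- epoch_mean(peri, lags, window[1], window[2])
    base <- peri[, which.min(abs(lags - baseline_at))]
    mean(resp - base, na.rm = TRUE)
  }, numeric(1))
}

#' One-tailed bootstrap comparison of two groups
#'
#' @param x,y numeric vectors; tests mean(x) > mean(y).
#' @param n_boot resamples.
#' @return p-value.
#' @export
bootstrap_greater <- function(x, y, n_boot = 1000L) {
  boot_p_greater(function()
    mean(sample(x, replace = TRUE)) - mean(sample(y, replace = TRUE)), n_boot)
}

#' Long-trial control for error neurons
#'
#' Long trials (duration above the mean across all supplied trials) are split
#' by whether they contain toward errors; each neuron's trial-averaged
#' activity is compared between the two groups on a log10 scale, ruling out
#' a pure passage-of-time account of error responses.
#'
#' @param activity neurons x frames matrix (error neurons).
#' @param frame_times frame times (s).
#' @param trials trial table with `t_start`, `t_end`.
#' @param has_error logical per trial: contains at least one toward error.
#' @param eps floor added before the log for zero-activity trials.
#' @return list with `log_with`, `log_without` (per-neuron log10 mean
#'   activity in the two groups), `diff`, and `p` (one-tailed bootstrap over
#'   neurons for with > without).
#' @export
long_trial_control <- function(activity, frame_times, trials, has_error,
                               eps = 1e-3) {
  dur <- trials$t_end - trials$t_start
  long <- dur > mean(dur)
  g_with <- which(long & has_error)
  g_without <- which(long & !has_error)
  if (!length(g_with) || !length(g_without))
    stop("need long trials both with and without errors")
  trial_mean <- function(i, grp) {
    v <- vapply(grp, function(k) {
      fr <- frame_times >= trials$t_start[k] & frame_times <= trials$t_end[k]
      mean(activity[i, fr])
    }, numeric(1))
    mean(v, na.rm = TRUE)
  }
  n <- nrow(activity)
  w <- vapply(seq_len(n), trial_mean, numeric(1), grp = g_with)
  wo <- vapply(seq_len(n), trial_mean, numeric(1), grp = g_without)
  lw <- log10(w + eps); lwo <- log10(wo + eps)
  list(log_with = lw, log_without = lwo, diff = lw - lwo,
       p = bootstrap_greater(lw, lwo))
}

#' Region-level summary of the n-step error code
#'
#' For each cortical region, computes the fraction of n-step error neurons
#' (among error neurons) for each n, normalized to the maximum across regions
#' per n; regions contribute only where they have more than `min_cells`
#' task-related cells. When two environments are supplied the fractions are
#' pooled into n-bins (1-2, 3-4, 5-6) and min-max normalized to \[0, 1\]
#' across all regions and both environments. Uncertainty comes from
#' resampling sessions with replacement.
#'
#' @param table per-neuron data frame with columns `region`, `session`,
#'   `task_related`, `error_related`, `assigned_n`, and optionally
#'   `environment`.
#' @param n_max largest n.
#' @param min_cells minimum task-related cells for a region to be reported.
#' @param n_boot session resamples (default 1000).
#' @return an object of class `"region_summary"`: list with `fractions`
#'   (region x n, among error neurons), `norm_fractions` (per-n max-normalized),
#'   `env_bins` (region x bin x environment, min-max normalized; `NULL` with
#'   one environment), `boot_sd`, and the per-region cell counts.
#' @export
region_code_summary <- function(table, n_max = 6L, min_cells = 5L,
                                n_boot = 1000L) {
  stopifnot(all(c("region", "session", "task_related", "error_related",
                  "assigned_n") %in% names(table)))
  if (is.null(table$environment)) table$environment <- "env1"
  regions <- sort(unique(table$region))
  envs <- sort(unique(table$environment))

  frac_matrix <- function(tab, denom = c("error", "task")) {
    denom <- match.arg(denom)
    out <- matrix(NA_real_, length(regions), n_max,
                  dimnames = list(regions, paste0("n", seq_len(n_max))))
    for (r in regions) {
      sel <- tab$region == r
      if (sum(sel & tab$task_related) <= min_cells) next
      d <- if (denom == "error") sum(sel & tab$error_related) else
        sum(sel & tab$task_related)
      if (d == 0) next
      for (nn in seq_len(n_max))
        out[r, nn] <- sum(sel & tab$error_related &
                            tab$assigned_n == nn, na.rm = TRUE) / d
    }
    out
  }
  fr <- frac_matrix(table)
  colmax <- suppressWarnings(apply(fr, 2, max, na.rm = TRUE))
  colmax[!is.finite(colmax) | colmax == 0] <- NA_real_  # no neurons at this n
  norm_fr <- sweep(fr, 2, colmax, "/")

  env_bins <- NULL
  if (length(envs) > 1) {
    bins <- list(`1-2` = 1:2, `3-4` = 3:4, `5-6` = 5:6)
    raw <- array(NA_real_, c(length(regions), length(bins), length(envs)),
                 dimnames = list(regions, names(bins), envs))
    for (e in seq_along(envs)) {
      fe <- frac_matrix(table[table$environment == envs[e], , drop = FALSE],
                        denom = "task")
      for (b in seq_along(bins))
        raw[, b, e] <- rowSums(fe[, bins[[b]], drop = FALSE], na.rm = TRUE)
    }
    rng <- range(raw, na.rm = TRUE)
    env_bins <- (raw - rng[1]) / (rng[2] - rng[1])
  }

  sessions <- unique(table$session)
  boot <- array(NA_real_, c(length(regions), n_max, n_boot))
  for (b in seq_len(n_boot)) {
    pick <- sample(sessions, replace = TRUE)
    tab_b <- do.call(rbind, lapply(pick, function(s)
      table[table$session == s, , drop = FALSE]))
    boot[, , b] <- frac_matrix(tab_b)
  }
  boot_sd <- apply(boot, c(1, 2), stats::sd, na.rm = TRUE)
  dimnames(boot_sd) <- dimnames(fr)

  counts <- t(vapply(regions, function(r)
    c(analyzed = sum(table$region == r),
      task_related = sum(table$region == r & table$task_related),
      error = sum(table$region == r & table$error_related)),
    numeric(3)))
  structure(list(fractions = fr, norm_fractions = norm_fr,
                 env_bins = env_bins, boot_sd = boot_sd, counts = counts),
            class = "region_summary")
}

#' @method print region_summary
#' @export
print.region_summary <- function(x, ...) {
  cat("region-level n-step error code (fractions among error neurons)\n")
  print(round(x$fractions, 3))
  invisible(x)
}
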