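#' Bin spike times into an activity dataset
#'
#' Bins per-unit spike times into non-overlapping bins whose centers run
#' from 1 s before stimulus onset to 0.7 s after stimulus end at the
#' defaults (151 bins of 20 ms for a 1.3-s stimulus).
#'
#' @param spikes A tibble with columns `trial_id`, `unit`, `time` (seconds
#'   relative to stimulus onset).
#' @param trials The matching trials tibble (with choices).
#' @param bin_width Bin width in seconds (default 0.02).
#' @param window `c(first_center, last_center)` in seconds
#'   (default `c(-1, 2)`).
#' @return An `activity_dataset`: `activity` (units x bins x trials),
#'   `bin_centers`, `bin_width`, `units`, `trials`.
#' @export
bin_activity <- function(spikes, trials, bin_width = 0.02, window = c(-1, 2)) {
  centers <- seq(window[1], window[2], by = bin_width)
  units <- sort(unique(spikes$unit))
  trial_ids <- trials$trial_id
  bi <- floor((spikes$time - (window[1] - bin_width / 2)) / bin_width) + 1L
  ok <- bi >= 1L & bi <= length(centers)
  a <- array(0, dim = c(length(units), length(centers), length(trial_ids)))
  ui <- match(spikes$unit, units)
  ki <- match(spikes$trial_id, trial_ids)
  keep <- ok & !is.na(ki)
  idx <- cbind(ui[keep], bi[keep], ki[keep])
  for (r in seq_len(nrow(idx))) {
    a[idx[r, 1], idx[r, 2], idx[r, 3]] <- a[idx[r, 1], idx[r, 2], idx[r, 3]] + 1
  }
  structure(
    list(activity = a, bin_centers = centers, bin_width = bin_width,
         units = units, trials = trials),
    class = "activity_dataset"
  )
}

#' Simulate network activity as an activity dataset
#'
#' Integrates the network over an analysis window bracketing the stimulus
#' (context input on throughout, evidence only during the stimulus) and
#' samples the unit states at the activity bin centers. Choices are
#' attached from the readout sign at stimulus end.
#'
#' @param params An `rnn_params`.
#' @param trials A trials tibble.
#' @param bin_width Bin width in seconds (default 0.02).
#' @param window `c(first_center, last_center)` (default `c(-1, 2)`).
#' @param tau Time constant override.
#' @return An `activity_dataset` whose units are the network state
#'   variables.
#' @export
simulate_activity <- function(params, trials, bin_width = 0.02,
                              window = c(-1, 2), tau = params$tau) {
  centers <- seq(window[1], window[2], by = bin_width)
  dt <- params$dt
  sim_window <- c(centers[1], centers[length(centers)])
  fw <- rnn_forward_trials(params, trials, tau = tau, window = sim_window,
                           keep_bins = centers)
  trials$z <- fw$z
  trials$choice <- ifelse(fw$z > 0, "R", "L")
  if (!"correct_side" %in% names(trials)) {
    trials$correct_side <- correct_side(trials$loc_strength,
                                        trials$frq_strength, trials$context)
  }
  trials$correct <- trials$choice == trials$correct_side
  structure(
    list(activity = fw$activity, bin_centers = centers,
         bin_width = bin_width, units = seq_len(params$N), trials = trials),
    class = "activity_dataset"
  )
}

#' @export
print.activity_dataset <- function(x, ...) {
  d <- dim(x$activity)
  cat(sprintf("Activity dataset: %d units x %d bins x %d trials (bin %g s)\n",
              d[1], d[2], d[3], x$bin_width))
  invisible(x)
}

# Signed pulse counts per activity bin: a trials-list of (bin, value) pairs
# per feature, restricted to an optional pulse time window.
signed_pulse_bins <- function(trials, centers, bin_width, pulse_window = NULL) {
  first_edge <- centers[1] - bin_width / 2
  n_bins <- length(centers)
  per_feature <- function(label_col) {
    ks <- integer(0); bs <- integer(0); vs <- numeric(0)
    for (k in seq_len(nrow(trials))) {
      tt <- trials$pulse_times[[k]]
      sg <- trials[[label_col]][[k]]
      if (!is.null(pulse_window)) {
        keep <- tt >= pulse_window[1] & tt < pulse_window[2]
        tt <- tt[keep]; sg <- sg[keep]
      }
      if (length(tt) == 0) next
      bi <- floor((tt - first_edge) / bin_width) + 1L
      ok <- bi >= 1L & bi <= n_bins
      if (!any(ok)) next
      cnt <- tapply(sg[ok], bi[ok], sum)
      nz <- cnt != 0
      if (!any(nz)) next
      ks <- c(ks, rep(k, sum(nz)))
      bs <- c(bs, as.integer(names(cnt))[nz])
      vs <- c(vs, unname(cnt[nz]))
    }
    list(k = ks, bin = bs, value = vs)
  }
  list(loc = per_feature("side_labels"), frq = per_feature("freq_labels"))
}

# Sparse design matrix for the pulse-based regression. Row order is
# trial-major: row = (k - 1) * T + t. Column blocks: choice (T), context
# (T), time (T), then 4 pulse streams x n_lags in the order
# loc_locctx, loc_frqctx, frq_locctx, frq_frqctx.
pulse_design <- function(trials, centers, bin_width, n_lags,
                         pulse_window = NULL) {
  if (is.null(trials$choice) || anyNA(trials$choice)) {
    abort("Trials must carry choices to build the pulse regression design.")
  }
  T_ <- length(centers)
  K <- nrow(trials)
  ch <- ifelse(trials$choice == "R", 0.5, -0.5)
  cx <- ifelse(trials$context == "LOC", 0.5, -0.5)
  is_loc <- trials$context == "LOC"

  kk <- rep(seq_len(K), each = T_)
  tt <- rep(seq_len(T_), times = K)
  rows0 <- seq_len(K * T_)
  i_idx <- c(rows0, rows0, rows0)
  j_idx <- c(tt, T_ + tt, 2L * T_ + tt)
  x_val <- c(ch[kk], cx[kk], rep(1, K * T_))

  pb <- signed_pulse_bins(trials, centers, bin_width, pulse_window)
  add_stream <- function(feat, ctx_loc, offset) {
    p <- pb[[feat]]
    sel <- if (ctx_loc) is_loc[p$k] else !is_loc[p$k]
    k <- p$k[sel]; b <- p$bin[sel]; v <- p$value[sel]
    if (length(k) == 0) return(NULL)
    n <- length(k)
    lag <- rep(0:(n_lags - 1L), times = n)
    k2 <- rep(k, each = n_lags)
    t2 <- rep(b, each = n_lags) + lag
    v2 <- rep(v, each = n_lags)
    ok <- t2 <= T_
    list(i = (k2[ok] - 1L) * T_ + t2[ok],
         j = offset + lag[ok] + 1L,
         x = v2[ok])
  }
  off0 <- 3L * T_
  streams <- list(
    add_stream("loc", TRUE, off0),
    add_stream("loc", FALSE, off0 + n_lags),
    add_stream("frq", TRUE, off0 + 2L * n_lags),
    add_stream("frq", FALSE, off0 + 3L * n_lags)
  )
  for (s in streams) {
    if (is.null(s)) next
    i_idx <- c(i_idx, s$i); j_idx <- c(j_idx, s$j); x_val <- c(x_val, s$x)
  }
  Matrix::sparseMatrix(i = i_idx, j = j_idx, x = x_val,
                       dims = c(K * T_, off0 + 4L * n_lags))
}

# Second-difference roughness penalty for one kernel block of length m.
second_diff_penalty <- function(m) {
  if (m < 3) return(matrix(0, m, m))
  D <- diff(diag(m), differences = 2)
  crossprod(D)
}

# Block-diagonal smoothness penalty over the 3 time kernels and 4 lag
# kernels.
smoothness_penalty <- function(T_, n_lags) {
  blocks <- c(rep(list(second_diff_penalty(T_)), 3),
              rep(list(second_diff_penalty(n_lags)), 4))
  as.matrix(Matrix::bdiag(blocks))
}

#' Fit pulse-based kernels to unit activity
#'
#' Linear regression of each unit's binned activity on choice, context and
#' time (one coefficient per activity bin each) plus four signed
#' pulse-count streams (location/frequency evidence in the LOC/FRQ
#' context), each convolved with a causal kernel over `n_lags` bins.
#' Regularised by a ridge penalty on all coefficients and a squared
#' second-difference smoothness penalty along each kernel's time/lag axis.
#' All units share the design, so the fit is a single multi-response
#' penalised solve. When `cv_grid` is given, penalty strengths are chosen
#' by cross-validated prediction error over trials.
#'
#' @param data An `activity_dataset`.
#' @param ridge_strength Ridge penalty (default 1).
#' @param smoothness_strength Smoothness penalty (default 10).
#' @param n_lags Pulse-kernel length in bins (default 33; 0 to 640 ms at
#'   20-ms bins).
#' @param pulse_window Optional `c(start, end)` restricting which pulses
#'   enter the pulse regressors (e.g. the first half of the stimulus).
#' @param cv_grid Optional data frame with columns `ridge` and `smooth` of
#'   candidate penalty pairs.
#' @param cv_folds Folds for the penalty search (default 3).
#' @param seed Seed for fold assignment.
#' @return A `pulse_kernel_fit` with `choice_kernels`, `context_kernels`,
#'   `time_kernels` (units x bins), `pulse_kernels` (named list of four
#'   units x lags matrices), `lags`, `bin_centers`, `units`, penalty
#'   strengths and the coding metadata.
#' @export
fit_pulse_kernels <- function(data, ridge_strength = 1,
                              smoothness_strength = 10, n_lags = 33,
                              pulse_window = NULL, cv_grid = NULL,
                              cv_folds = 3, seed = NULL) {
  stopifnot(inherits(data, "activity_dataset"))
  centers <- data$bin_centers
  T_ <- length(centers)
  K <- nrow(data$trials)
  n_units <- dim(data$activity)[1]
  X <- pulse_design(data$trials, centers, data$bin_width, n_lags, pulse_window)
  Y <- matrix(aperm(data$activity, c(2, 3, 1)), nrow = T_ * K, ncol = n_units)
  p <- ncol(X)
  S <- smoothness_penalty(T_, n_lags)
  solve_for <- function(XtX, XtY, lr, ls) {
    A <- XtX + diag(lr, p) + ls * S
    solve(A, XtY)
  }
  XtX <- as.matrix(Matrix::crossprod(X))
  XtY <- as.matrix(Matrix::crossprod(X, Y))

  if (!is.null(cv_grid)) {
    foldid <- with_seed(seed, sample(rep_len(seq_len(cv_folds), K)))
    row_fold <- rep(foldid, each = T_)
    fold_XtX <- list(); fold_XtY <- list()
    for (f in seq_len(cv_folds)) {
      Xf <- X[row_fold == f, , drop = FALSE]
      Yf <- Y[row_fold == f, , drop = FALSE]
      fold_XtX[[f]] <- as.matrix(Matrix::crossprod(Xf))
      fold_XtY[[f]] <- as.matrix(Matrix::crossprod(Xf, Yf))
    }
    score <- numeric(nrow(cv_grid))
    for (g in seq_len(nrow(cv_grid))) {
      sse <- 0
      for (f in seq_len(cv_folds)) {
        B <- solve_for(XtX - fold_XtX[[f]], XtY - fold_XtY[[f]],
                       cv_grid$ridge[g], cv_grid$smooth[g])
        resid <- Y[row_fold == f, , drop = FALSE] -
          as.matrix(X[row_fold == f, , drop = FALSE] %*% B)
        sse <- sse + sum(resid^2)
      }
      score[g] <- sse
    }
    best <- which.min(score)
    ridge_strength <- cv_grid$ridge[best]
    smoothness_strength <- cv_grid$smooth[best]
  }

  B <- solve_for(XtX, XtY, ridge_strength, smoothness_strength)
  # rows of B: T choice, T context, T time, 4 x n_lags pulse kernels
  slice <- function(from, len) t(B[from + seq_len(len), , drop = FALSE])
  off0 <- 3L * T_
  structure(
    list(
      choice_kernels = slice(0L, T_),
      context_kernels = slice(T_, T_),
      time_kernels = slice(2L * T_, T_),
      pulse_kernels = list(
        loc_locctx = slice(off0, n_lags),
        loc_frqctx = slice(off0 + n_lags, n_lags),
        frq_locctx = slice(off0 + 2L * n_lags, n_lags),
        frq_frqctx = slice(off0 + 3L * n_lags, n_lags)
      ),
      lags = (seq_len(n_lags) - 1L) * data$bin_width,
      bin_centers = centers,
      units = data$units,
      ridge_strength = ridge_strength,
      smoothness_strength = smoothness_strength,
      pulse_window = pulse_window,
      coding = list(choice = "right = +0.5, left = -0.5",
                    context = "LOC = +0.5, FRQ = -0.5")
    ),
    class = "pulse_kernel_fit"
  )
}

#' @export
print.pulse_kernel_fit <- function(x, ...) {
  cat(sprintf(
    "Pulse kernel fit: %d units, %d time bins, %d lags (ridge %.3g, smooth %.3g)\n",
    nrow(x$choice_kernels), length(x$bin_centers), length(x$lags),
    x$ridge_strength, x$smoothness_strength
  ))
  invisible(x)
}

#' Estimate the choice axis from choice kernels
#'
#' Stacks the per-unit choice kernels over the stimulus window into a
#' units x bins matrix, subtracts each unit's mean, and takes the first
#' left singular vector as the choice axis. The sign is fixed so that the
#' mean go-right kernel projects positively.
#'
#' @param fit A `pulse_kernel_fit`.
#' @param window Time window in seconds (default `c(0, 1.3)`).
#' @param context_tag Label recorded on the axis (`"pooled"` by default;
#'   fit on a context subset of trials to obtain per-context axes).
#' @return A `choice_axis` with unit-norm `direction`, `variance_explained`
#'   and `context_tag`.
#' @export
estimate_choice_axis <- function(fit, window = c(0, 1.3),
                                 context_tag = "pooled") {
  stopifnot(inherits(fit, "pulse_kernel_fit"))
  if (nrow(fit$choice_kernels) < 2) abort("Need at least 2 units.")
  keep <- fit$bin_centers >= window[1] & fit$bin_centers <= window[2]
  M <- fit$choice_kernels[, keep, drop = FALSE]
  Mc <- M - rowMeans(M)
  if (all(Mc == 0)) abort("Choice-kernel matrix has rank 0.")
  sv <- svd(Mc)
  axis <- sv$u[, 1]
  if (sum(axis * rowMeans(M)) < 0) axis <- -axis
  structure(
    list(direction = axis,
         variance_explained = sv$d[1]^2 / sum(sv$d^2),
         context_tag = context_tag,
         window = window),
    class = "choice_axis"
  )
}

#' @export
print.choice_axis <- function(x, ...) {
  cat(sprintf("Choice axis (%s): %d units, %.1f%% variance explained\n",
              x$context_tag, length(x$direction),
              100 * x$variance_explained))
  invisible(x)
}

#' Permutation test for context dependence of the choice axis
#'
#' Estimates the choice axis separately per context and compares the angle
#' between the two axes against the null distribution obtained by
#' shuffling the trials' context labels.
#'
#' @param data An `activity_dataset` containing both contexts.
#' @param n_permutations Number of label shuffles (must be >= 1).
#' @param seed Optional integer seed.
#' @param ... Passed to [fit_pulse_kernels()] (e.g. penalty strengths).
#' @return A list with `angle_degrees` (observed), `p_value` (fraction of
#'   null angles at least as large) and `null_angles`.
#' @export
choice_axis_context_test <- function(data, n_permutations = 200,
                                     seed = NULL, ...) {
  stopifnot(inherits(data, "activity_dataset"))
  if (n_permutations < 1) abort("`n_permutations` must be at least 1.")
  if (length(unique(data$trials$context)) < 2) {
    abort("Both contexts must be present.")
  }
  axis_angle <- function(ctx_labels) {
    one_axis <- function(ctx) {
      keep <- ctx_labels == ctx
      sub <- data
      sub$activity <- data$activity[, , keep, drop = FALSE]
      sub$trials <- data$trials[keep, ]
      sub$trials$context <- ctx_labels[keep]
      fit <- fit_pulse_kernels(sub, ...)
      estimate_choice_axis(fit, context_tag = ctx)$direction
    }
    a <- one_axis("LOC"); b <- one_axis("FRQ")
    acos(pmin(abs(sum(a * b)), 1)) * 180 / pi
  }
  obs <- axis_angle(data$trials$context)
  with_seed(seed, {
    null_angles <- replicate(n_permutations,
                             axis_angle(sample(data$trials$context)))
    list(angle_degrees = obs,
         p_value = mean(null_angles >= obs),
         null_angles = null_angles)
  })
}

#' Estimated differential pulse response
#'
#' Projects the population pulse kernels onto the choice axis, per lag and
#' per context, and returns the relevant-context minus irrelevant-context
#' projection (location: LOC minus FRQ context; frequency: FRQ minus LOC).
#'
#' @param fit A `pulse_kernel_fit`.
#' @param axis A `choice_axis` over the same units.
#' @param feature `"loc"` or `"frq"`.
#' @return A `differential_pulse_response` with `times` (lags), `values`
#'   and a `slope_index` fit.
#' @export
differential_pulse_response_estimate <- function(fit, axis,
                                                 feature = c("loc", "frq")) {
  feature <- match.arg(feature)
  if (length(axis$direction) != nrow(fit$choice_kernels)) {
    abort("Choice axis and kernel fit cover different unit sets.")
  }
  rel <- if (feature == "loc") fit$pulse_kernels$loc_locctx else fit$pulse_kernels$frq_frqctx
  irr <- if (feature == "loc") fit$pulse_kernels$loc_frqctx else fit$pulse_kernels$frq_locctx
  values <- drop(crossprod(rel, axis$direction)) -
    drop(crossprod(irr, axis$direction))
  structure(
    list(feature = feature, times = fit$lags, values = values,
         slope_index = slope_index(values, fit$lags),
         source = "estimated"),
    class = "differential_pulse_response"
  )
}
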