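#' Initialise a tanh recurrent network
#'
#' Weights are drawn from scaled standard normals: input weights (context
#' columns and both evidence vectors) as eta / sqrt(U) with U = 4 inputs,
#' recurrent weights as 0.8 eta / sqrt(N), output weights as eta / sqrt(N).
#' All biases start at 0 and every element of the learned initial condition
#' starts at 0.1.
#'
#' @param seed Optional integer seed.
#' @param N Number of hidden units (default 100).
#' @param tau Time constant in seconds used in analyses (default 0.1; note
#'   that training uses its own, typically faster, time constant).
#' @param dt Euler integration step in seconds (default 0.01).
#' @return An `rnn_params` list with `W` (N x N), `W_c` (N x 2, columns LOC
#'   and FRQ), `b`, `w_loc`, `w_frq`, `w_O`, `k_O`, `x0`, `N`, `tau`, `dt`.
#' @export
init_network <- function(seed = NULL, N = 100, tau = 0.1, dt = 0.01) {
  stopifnot(N >= 2)
  n_inputs <- 4
  with_seed(seed, {
    structure(
      list(
        W = matrix(rnorm(N * N) * 0.8 / sqrt(N), N, N),
        W_c = matrix(rnorm(N * 2) / sqrt(n_inputs), N, 2),
        b = rep(0, N),
        w_loc = rnorm(N) / sqrt(n_inputs),
        w_frq = rnorm(N) / sqrt(n_inputs),
        w_O = rnorm(N) / sqrt(N),
        k_O = 0,
        x0 = rep(0.1, N),
        N = N, tau = tau, dt = dt
      ),
      class = "rnn_params"
    )
  })
}

#' @export
print.rnn_params <- function(x, ...) {
  cat(sprintf("Recurrent network: N = %d units, tau = %g s, dt = %g s\n",
              x$N, x$tau, x$dt))
  invisible(x)
}

#' Encode trials as momentary network inputs
#'
#' Each pulse contributes a signed impulse (+ for right/high, - for
#' left/low) to the integration step containing its time; multiple pulses
#' in a step sum. The impulse height is `pulse_area / dt`, i.e. each pulse
#' carries a fixed time-integrated input of `pulse_area` seconds regardless
#' of the step size. The default area of 0.01 s makes the momentary
#' evidence +/-1 on a 10-ms step, which keeps single pulses within the
#' quasi-linear range of the tanh nonlinearity.
#'
#' @param trials A trials tibble.
#' @param dt Step size in seconds.
#' @param pulse_area Time-integrated input per pulse, in seconds
#'   (default 0.01).
#' @param pulse_amplitude Impulse height (default `pulse_area / dt`).
#' @param window `c(start, end)` of the simulated interval in seconds
#'   relative to stimulus onset (default the stimulus itself).
#' @return A list with matrices `i_loc`, `i_frq` (steps x trials), integer
#'   `ctx` (0 = LOC, 1 = FRQ), `steps`, and the window.
#' @export
encode_trials <- function(trials, dt = 0.01, pulse_area = 0.01,
                          pulse_amplitude = pulse_area / dt,
                          window = NULL) {
  duration <- trials$duration[1]
  window <- window %||% c(0, duration)
  steps <- round((window[2] - window[1]) / dt)
  B <- nrow(trials)
  i_loc <- matrix(0, steps, B)
  i_frq <- matrix(0, steps, B)
  for (k in seq_len(B)) {
    tt <- trials$pulse_times[[k]]
    if (length(tt) == 0) next
    step <- floor((tt - window[1]) / dt) + 1L
    ok <- step >= 1L & step <= steps
    for (j in which(ok)) {
      i_loc[step[j], k] <- i_loc[step[j], k] +
        pulse_amplitude * trials$side_labels[[k]][j]
      i_frq[step[j], k] <- i_frq[step[j], k] +
        pulse_amplitude * trials$freq_labels[[k]][j]
    }
  }
  list(i_loc = i_loc, i_frq = i_frq,
       ctx = as.integer(trials$context == "FRQ"),
       steps = steps, window = window, dt = dt)
}

#' Simulate a single trial
#'
#' Euler integration of the network on one trial's inputs, returning the
#' full state trajectory and the readout time course.
#'
#' @param params An `rnn_params`.
#' @param inputs An encoding from [encode_trials()] (one trial), or a trials
#'   tibble with one row.
#' @param tau Time constant override (defaults to `params$tau`).
#' @return A list with `trajectory` (N x (steps + 1) states, including the
#'   initial state), `z` (readout per state) and `times`.
#' @export
simulate_trial <- function(params, inputs, tau = params$tau) {
  if (is.data.frame(inputs)) inputs <- encode_trials(inputs, dt = params$dt)
  steps <- inputs$steps
  out <- cpp_rnn_forward(
    params$W, params$W_c, params$b, params$w_loc, params$w_frq,
    params$w_O, params$k_O, params$x0,
    inputs$i_loc[, 1, drop = FALSE], inputs$i_frq[, 1, drop = FALSE],
    inputs$ctx[1], params$dt / tau, 0:steps
  )
  traj <- matrix(out$activity, nrow = params$N)
  list(trajectory = traj, z = drop(out$z_t),
       times = inputs$window[1] + (0:steps) * inputs$dt)
}

# Fast path for training: draws a minibatch of encoded trials directly as
# matrices (no tibble construction). Tie trials (relevant strength 0) are
# dropped. Uses the current RNG stream.
training_batch <- function(batch_size, grid, duration, total_rate, dt,
                           pulse_amplitude = 0.01 / dt) {
  steps <- round(duration / dt)
  cond <- sample.int(nrow(grid), batch_size, replace = TRUE)
  ctx <- rbinom(batch_size, 1, 0.5)  # 0 = LOC, 1 = FRQ
  counts <- rpois(batch_size, total_rate * duration)
  k_rep <- rep(seq_len(batch_size), counts)
  total <- length(k_rep)
  step <- floor(runif(total, 0, duration) / dt) + 1L
  side <- 2L * rbinom(total, 1, grid$p_right[cond][k_rep]) - 1L
  freq <- 2L * rbinom(total, 1, grid$p_high[cond][k_rep]) - 1L
  i_loc <- matrix(0, steps, batch_size)
  i_frq <- matrix(0, steps, batch_size)
  lin <- (k_rep - 1L) * steps + step
  acc_l <- rowsum(as.numeric(side), lin)
  i_loc[as.integer(rownames(acc_l))] <- acc_l * pulse_amplitude
  acc_f <- rowsum(as.numeric(freq), lin)
  i_frq[as.integer(rownames(acc_f))] <- acc_f * pulse_amplitude
  strength_of <- function(sg) {
    s <- numeric(batch_size)
    agg <- rowsum(as.numeric(sg), k_rep)
    s[as.integer(rownames(agg))] <- agg
    s
  }
  rel <- ifelse(ctx == 0L, strength_of(side), strength_of(freq))
  keep <- rel != 0
  list(i_loc = i_loc[, keep, drop = FALSE],
       i_frq = i_frq[, keep, drop = FALSE],
       ctx = as.integer(ctx[keep]),
       targets = sign(rel[keep]))
}

# Batched forward over a trials tibble; returns z at the end of the
# stimulus and optionally activity snapshots at bin centers.
rnn_forward_trials <- function(params, trials, tau = params$tau,
                               window = NULL, keep_bins = NULL,
                               batch_size = 1024) {
  duration <- trials$duration[1]
  window <- window %||% c(0, duration)
  dt <- params$dt
  steps <- round((window[2] - window[1]) / dt)
  z_end_step <- round((duration - window[1]) / dt)
  keep_steps <- if (is.null(keep_bins)) integer(0) else {
    pmin(pmax(round((keep_bins - window[1]) / dt), 0L), steps)
  }
  n <- nrow(trials)
  z <- numeric(n)
  act <- if (!is.null(keep_bins)) {
    array(NA_real_, dim = c(params$N, length(keep_bins), n))
  }
  starts <- seq(1, n, by = batch_size)
  for (s in starts) {
    idx <- s:min(s + batch_size - 1, n)
    enc <- encode_trials(trials[idx, ], dt = dt, window = window)
    out <- cpp_rnn_forward(
      params$W, params$W_c, params$b, params$w_loc, params$w_frq,
      params$w_O, params$k_O, params$x0,
      enc$i_loc, enc$i_frq, enc$ctx, dt / tau, as.integer(keep_steps)
    )
    z[idx] <- out$z_t[z_end_step + 1, ]
    if (!is.null(keep_bins)) act[, , idx] <- aperm(out$activity, c(1, 3, 2))
  }
  list(z = z, activity = act)
}

#' Network choices on a set of trials
#'
#' Simulates the network on each trial; the choice is the sign of the
#' readout at the end of the stimulus (right for positive).
#'
#' @param params An `rnn_params`.
#' @param trials A trials tibble.
#' @param tau Time constant override.
#' @return The trials tibble with `z`, `choice` and `correct` added.
#' @export
network_choices <- function(params, trials, tau = params$tau) {
  fw <- rnn_forward_trials(params, trials, tau = tau)
  trials$z <- fw$z
  trials$choice <- ifelse(fw$z > 0, "R", "L")
  if (!"correct_side" %in% names(trials)) {
    trials$correct_side <- correct_side(trials$loc_strength,
                                        trials$frq_strength, trials$context)
  }
  trials$correct <- trials$choice == trials$correct_side
  trials
}

#' Training configuration
#'
#' Adam hyperparameters and schedule for backpropagation-through-time
#' training. The defaults are a desk-scale schedule; the full schedule used
#' for large network populations is `n_batches = 120000`,
#' `batch_size = 256`, `step_size = 0.002`, `decay = 0.99998`.
#'
#' @param n_batches Number of minibatches (default 5000).
#' @param batch_size Trials per minibatch (default 64).
#' @param step_size Initial Adam step size (default 0.005).
#' @param decay Per-batch exponential decay of the step size.
#' @param b1,b2,epsilon Adam moment decay rates and damping (large-epsilon
#'   style).
#' @param tau_train Time constant during training in seconds (default 0.01;
#'   analyses then typically use a slower constant).
#' @param loss_window Number of trailing integration steps over which the
#'   readout is penalised (default 1: only the final step). Penalising a
#'   short trailing window encourages the readout to be held stably at the
#'   end of the trial.
#' @param seed Integer seed for batch sampling.
#' @return A `train_config` list.
#' @export
train_config <- function(n_batches = 5000, batch_size = 64,
                         step_size = 0.005, decay = 0.9995,
                         b1 = 0.9, b2 = 0.999, epsilon = 0.1,
                         tau_train = 0.01, loss_window = 1, seed = 1) {
  stopifnot(step_size > 0, decay > 0, decay <= 1, loss_window >= 1)
  structure(
    list(n_batches = n_batches, batch_size = batch_size,
         step_size = step_size, decay = decay, b1 = b1, b2 = b2,
         epsilon = epsilon, tau_train = tau_train,
         loss_window = loss_window, seed = seed),
    class = "train_config"
  )
}

#' Train the network by backpropagation through time
#'
#' Minimises the squared error between the final readout and a +/-1 target
#' (the sign of the contextually relevant evidence) over random minibatches
#' of freshly generated trials, with the Adam optimizer; a logistic
#' (cross-entropy on the readout sign) loss is available as an alternative.
#' Tie trials (relevant strength 0) are dropped from a batch. All weights,
#' biases and the initial condition are trained.
#'
#' @param params An `rnn_params` (typically from [init_network()]).
#' @param config A [train_config()].
#' @param grid Condition grid to sample stimuli from.
#' @param duration,total_rate Stimulus parameters.
#' @param loss `"squared"` (default) or `"logistic"` (cross-entropy on the
#'   sign of the readout).
#' @return The trained `rnn_params`, with a `learning_curve` tibble
#'   (batch, loss) attached as attribute.
#' @export
train_network <- function(params, config = train_config(),
                          grid = condition_grid(), duration = 1.3,
                          total_rate = 40, loss = c("squared", "logistic")) {
  loss <- match.arg(loss)
  if (config$n_batches == 0) return(params)
  dt <- params$dt
  alpha <- dt / config$tau_train
  names_p <- c("W", "W_c", "b", "w_loc", "w_frq", "w_O", "k_O", "x0")
  m <- lapply(params[names_p], function(p) p * 0)
  v <- m
  losses <- numeric(config$n_batches)
  with_seed(config$seed, {
    lr <- config$step_size
    for (bt in seq_len(config$n_batches)) {
      enc <- training_batch(config$batch_size, grid, duration, total_rate, dt)
      g <- cpp_rnn_grad(params$W, params$W_c, params$b, params$w_loc,
                        params$w_frq, params$w_O, params$k_O, params$x0,
                        enc$i_loc, enc$i_frq, enc$ctx, alpha, enc$targets,
                        if (loss == "squared") 0L else 1L,
                        as.integer(config$loss_window %||% 1L))
      if (!is.finite(g$loss)) {
        abort(sprintf("Training diverged (non-finite loss) at batch %d.", bt))
      }
      losses[bt] <- g$loss
      gl <- list(g$gW, g$gWc, g$gb, g$gw_loc, g$gw_frq, g$gw_O, g$gk_O, g$gx0)
      for (j in seq_along(names_p)) {
        nm <- names_p[j]
        m[[nm]] <- config$b1 * m[[nm]] + (1 - config$b1) * gl[[j]]
        v[[nm]] <- config$b2 * v[[nm]] + (1 - config$b2) * gl[[j]]^2
        mh <- m[[nm]] / (1 - config$b1^bt)
        vh <- v[[nm]] / (1 - config$b2^bt)
        params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + config$epsilon)
      }
      lr <- lr * config$decay
    }
  })
  attr(params, "learning_curve") <- tibble::tibble(
    batch = seq_len(config$n_batches), loss = losses
  )
  params
}

#' Evaluate task performance of a network
#'
#' Simulates trials from the grid in both contexts and summarises accuracy
#' per condition, overall, and on the easiest conditions (extreme levels of
#' the relevant feature).
#'
#' @param params An `rnn_params`.
#' @param grid Condition grid.
#' @param n_trials Number of evaluation trials.
#' @param seed Optional integer seed.
#' @param tau Time constant override.
#' @return A list with `trials` (choices attached), `by_condition`
#'   (fraction right and accuracy per condition and context), `accuracy`,
#'   and `easiest_accuracy`.
#' @export
evaluate_performance <- function(params, grid = condition_grid(),
                                 n_trials = 2000, seed = NULL,
                                 tau = params$tau) {
  trials <- simulate_trials(n_trials, grid, context = "both", seed = seed)
  trials <- network_choices(params, trials, tau = tau)
  lv <- sort(unique(grid$p_right))
  trials$level_loc <- match(trials$p_right, lv)
  trials$level_frq <- match(trials$p_high, lv)
  n_levels <- length(lv)
  by_condition <- trials |>
    dplyr::summarise(
      n = dplyr::n(),
      frac_right = mean(.data$choice == "R"),
      accuracy = mean(.data$correct),
      .by = c("context", "level_loc", "level_frq")
    )
  rel_level <- ifelse(trials$context == "LOC", trials$level_loc,
                      trials$level_frq)
  easiest <- rel_level %in% c(1L, n_levels)
  list(
    trials = trials,
    by_condition = by_condition,
    accuracy = mean(trials$correct),
    easiest_accuracy = mean(trials$correct[easiest])
  )
}
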