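#' Stimulus condition grid
#'
#' Builds the grid of generative stimulus conditions for the two-feature
#' pulse task. Each condition is defined by the probability that a pulse is
#' labelled "right" (`p_right`, the location feature) and the probability
#' that it is labelled "high frequency" (`p_high`, the frequency feature).
#' Levels are equally spaced in log-odds between `p_min` and `p_max`, so the
#' default 6-level grid is symmetric about p = 0.5 and yields 36 conditions.
#'
#' @param n_levels Number of levels per feature (default 6).
#' @param p_min,p_max Extreme per-pulse probabilities (defaults 0.2 and 0.8).
#' @return A tibble with columns `level_loc`, `level_frq`, `p_right`,
#'   `p_high`; one row per condition (`n_levels^2` rows).
#' @examples
#' condition_grid()        # 36 conditions
#' condition_grid(2, 0, 1) # the four corner conditions
#' @export
condition_grid <- function(n_levels = 6, p_min = 0.2, p_max = 0.8) {
  if (!is.numeric(n_levels) || n_levels < 2) abort("`n_levels` must be >= 2.")
  assert_prob(p_min, "p_min")
  assert_prob(p_max, "p_max")
  if (p_min >= p_max) abort("`p_min` must be strictly below `p_max`.")
  if ((p_min == 0 || p_max == 1) && n_levels > 2) {
    abort("Log-odds spacing requires 0 < p_min and p_max < 1 for n_levels > 2.")
  }
  p <- if (n_levels == 2) {
    c(p_min, p_max)
  } else {
    plogis(seq(qlogis(p_min), qlogis(p_max), length.out = n_levels))
  }
  tidyr::crossing(level_loc = seq_len(n_levels), level_frq = seq_len(n_levels)) |>
    dplyr::mutate(p_right = p[.data$level_loc], p_high = p[.data$level_frq])
}

#' Generate one Poisson pulse train
#'
#' Pulse times follow a homogeneous Poisson process at `total_rate` over
#' `[0, duration)`; each pulse independently receives a side label
#' (right with probability `p_right`) and a frequency label (high with
#' probability `p_high`). The total rate does not depend on the condition;
#' only the relative rates of the labels vary.
#'
#' @param p_right,p_high Per-pulse label probabilities.
#' @param duration Stimulus duration in seconds (default 1.3).
#' @param total_rate Total pulse rate in Hz (default 40).
#' @param seed Optional integer seed.
#' @return A `pulse_train` list with `pulse_times` (sorted, seconds),
#'   `side_labels` and `freq_labels` (+1 for right/high, -1 for left/low),
#'   `duration` and `total_rate`.
#' @export
generate_pulse_train <- function(p_right, p_high, duration = 1.3,
                                 total_rate = 40, seed = NULL) {
  assert_prob(p_right, "p_right")
  assert_prob(p_high, "p_high")
  assert_scalar_pos(duration, "duration")
  assert_scalar_pos(total_rate, "total_rate")
  with_seed(seed, {
    n <- rpois(1, total_rate * duration)
    times <- sort(runif(n, 0, duration))
    structure(
      list(
        pulse_times = times,
        side_labels = ifelse(rbinom(n, 1, p_right) == 1, 1L, -1L),
        freq_labels = ifelse(rbinom(n, 1, p_high) == 1, 1L, -1L),
        duration = duration,
        total_rate = total_rate
      ),
      class = "pulse_train"
    )
  })
}

#' Evidence strengths of pulse trains
#'
#' The location strength of a trial is the number of right pulses minus the
#' number of left pulses; the frequency strength is the number of
#' high-frequency minus low-frequency pulses.
#'
#' @param x A trials tibble (with list-columns `side_labels`, `freq_labels`)
#'   or a single `pulse_train`.
#' @return For a tibble, the tibble with columns `loc_strength` and
#'   `frq_strength` added; for a `pulse_train`, a named numeric vector.
#' @export
evidence_strengths <- function(x) UseMethod("evidence_strengths")

#' @export
evidence_strengths.pulse_train <- function(x) {
  c(loc_strength = sum(x$side_labels), frq_strength = sum(x$freq_labels))
}

#' @export
evidence_strengths.data.frame <- function(x) {
  dplyr::mutate(
    x,
    loc_strength = purrr::map_dbl(.data$side_labels, sum),
    frq_strength = purrr::map_dbl(.data$freq_labels, sum)
  )
}

#' Time-binned log-ratio evidence
#'
#' Partitions the stimulus window into `n_bins` equal half-open bins and
#' computes, per bin, the natural log of the ratio of right to left pulse
#' counts (location) and of high to low counts (frequency). A pseudo-count
#' is added to numerator and denominator so that empty bins give 0.
#'
#' @param train A `pulse_train`.
#' @param n_bins Number of bins (default 26, i.e. 50-ms bins for a 1.3-s
#'   stimulus).
#' @param pseudo_count Positive pseudo-count (default 1).
#' @return A list with numeric vectors `loc` and `frq` (length `n_bins`) and
#'   `times` (bin centers in seconds).
#' @export
bin_log_ratio_evidence <- function(train, n_bins = 26, pseudo_count = 1) {
  stopifnot(inherits(train, "pulse_train"))
  if (n_bins < 1) abort("`n_bins` must be >= 1.")
  assert_scalar_pos(pseudo_count, "pseudo_count")
  width <- train$duration / n_bins
  idx <- pmin(floor(train$pulse_times / width) + 1L, n_bins)
  count_signed <- function(labels, sign) {
    tabulate(idx[labels == sign], nbins = n_bins)
  }
  loc <- log((count_signed(train$side_labels, 1L) + pseudo_count) /
               (count_signed(train$side_labels, -1L) + pseudo_count))
  frq <- log((count_signed(train$freq_labels, 1L) + pseudo_count) /
               (count_signed(train$freq_labels, -1L) + pseudo_count))
  list(loc = loc, frq = frq, times = bin_centers(train$duration, n_bins))
}

# Design matrices of binned log-ratio evidence for a trials tibble:
# an N x n_bins matrix per feature, plus bin centers.
kernel_design <- function(trials, n_bins = 26, pseudo_count = 1) {
  duration <- trials$duration[1]
  width <- duration / n_bins
  n <- nrow(trials)
  X_loc <- matrix(0, n, n_bins)
  X_frq <- matrix(0, n, n_bins)
  for (k in seq_len(n)) {
    idx <- pmin(floor(trials$pulse_times[[k]] / width) + 1L, n_bins)
    sl <- trials$side_labels[[k]]
    fl <- trials$freq_labels[[k]]
    X_loc[k, ] <- log((tabulate(idx[sl == 1L], n_bins) + pseudo_count) /
                        (tabulate(idx[sl == -1L], n_bins) + pseudo_count))
    X_frq[k, ] <- log((tabulate(idx[fl == 1L], n_bins) + pseudo_count) /
                        (tabulate(idx[fl == -1L], n_bins) + pseudo_count))
  }
  list(loc = X_loc, frq = X_frq, times = bin_centers(duration, n_bins))
}

#' Parametric choice agent
#'
#' A ground-truth agent for closed-loop testing: in each context it weighs
#' the binned log-ratio evidence of both features with known temporal
#' kernels, adds a bias, and chooses through a logistic link. With
#' probability `lapse_rate` the choice is replaced by a fair coin.
#'
#' @param w_loc_in_loc,w_frq_in_loc Kernels (scalar or length `n_bins`)
#'   applied to location and frequency evidence in the LOC context.
#' @param w_loc_in_frq,w_frq_in_frq Same, in the FRQ context.
#' @param bias_loc,bias_frq Per-context biases.
#' @param decision_noise Logistic scale; 0 gives deterministic sign choices.
#' @param lapse_rate Probability of a random choice.
#' @param n_bins Number of stimulus time bins the kernels refer to.
#' @return An object of class `agent_spec`.
#' @export
agent_spec <- function(w_loc_in_loc = 1, w_frq_in_loc = 0,
                       w_loc_in_frq = 0, w_frq_in_frq = 1,
                       bias_loc = 0, bias_frq = 0,
                       decision_noise = 0, lapse_rate = 0, n_bins = 26) {
  assert_prob(lapse_rate, "lapse_rate")
  if (decision_noise < 0) abort("`decision_noise` must be >= 0.")
  expand <- function(w, name) {
    if (length(w) == 1L) w <- rep(w, n_bins)
    if (length(w) != n_bins) {
      abort(sprintf("`%s` must have length 1 or n_bins (%d).", name, n_bins))
    }
    w
  }
  structure(
    list(
      w_loc_in_loc = expand(w_loc_in_loc, "w_loc_in_loc"),
      w_frq_in_loc = expand(w_frq_in_loc, "w_frq_in_loc"),
      w_loc_in_frq = expand(w_loc_in_frq, "w_loc_in_frq"),
      w_frq_in_frq = expand(w_frq_in_frq, "w_frq_in_frq"),
      bias_loc = bias_loc, bias_frq = bias_frq,
      decision_noise = decision_noise, lapse_rate = lapse_rate,
      n_bins = n_bins
    ),
    class = "agent_spec"
  )
}

# Decision variable of the agent on binned evidence (vectors or matrices
# with trials in rows).
agent_decision_value <- function(agent, loc_bins, frq_bins, context) {
  if (is.matrix(loc_bins)) {
    if (context == "LOC") {
      drop(loc_bins %*% agent$w_loc_in_loc + frq_bins %*% agent$w_frq_in_loc) +
        agent$bias_loc
    } else {
      drop(loc_bins %*% agent$w_loc_in_frq + frq_bins %*% agent$w_frq_in_frq) +
        agent$bias_frq
    }
  } else {
    agent_decision_value(agent, matrix(loc_bins, 1), matrix(frq_bins, 1), context)
  }
}

#' Agent choice on a single trial
#'
#' @param agent An [agent_spec()].
#' @param train A `pulse_train`.
#' @param context `"LOC"` or `"FRQ"`.
#' @param pseudo_count Pseudo-count for the evidence binning.
#' @param seed Optional integer seed.
#' @return `"R"` or `"L"`.
#' @export
agent_choice <- function(agent, train, context, pseudo_count = 1, seed = NULL) {
  stopifnot(inherits(agent, "agent_spec"))
  ev <- bin_log_ratio_evidence(train, agent$n_bins, pseudo_count)
  dv <- agent_decision_value(agent, ev$loc, ev$frq, context)
  with_seed(seed, draw_choices(agent, dv))
}

# Vectorised stochastic choice from decision values (uses current RNG).
draw_choices <- function(agent, dv) {
  p <- if (agent$decision_noise == 0) {
    (dv > 0) + 0.5 * (dv == 0)
  } else {
    plogis(dv / agent$decision_noise)
  }
  ch <- ifelse(rbinom(length(dv), 1, p) == 1, "R", "L")
  if (agent$lapse_rate > 0) {
    lapse <- rbinom(length(dv), 1, agent$lapse_rate) == 1
    ch[lapse] <- ifelse(rbinom(sum(lapse), 1, 0.5) == 1, "R", "L")
  }
  ch
}

# Internal: build a trials tibble from drawn conditions/contexts.
build_trials <- function(p_right, p_high, context, duration, total_rate) {
  n <- length(p_right)
  counts <- rpois(n, total_rate * duration)
  tibble::tibble(
    trial_id = seq_len(n),
    context = context,
    p_right = p_right,
    p_high = p_high,
    duration = duration,
    total_rate = total_rate,
    pulse_times = purrr::map(counts, ~sort(runif(.x, 0, duration))),
    side_labels = purrr::map2(counts, p_right,
                              ~ifelse(rbinom(.x, 1, .y) == 1, 1L, -1L)),
    freq_labels = purrr::map2(counts, p_high,
                              ~ifelse(rbinom(.x, 1, .y) == 1, 1L, -1L))
  )
}

# Correct side given strengths and context; ties resolved by fair coin
# (uses current RNG). Returns "R"/"L".
correct_side <- function(loc_strength, frq_strength, context) {
  s <- ifelse(context == "LOC", loc_strength, frq_strength)
  out <- ifelse(s > 0, "R", "L")
  ties <- s == 0
  if (any(ties)) {
    out[ties] <- ifelse(rbinom(sum(ties), 1, 0.5) == 1, "R", "L")
  }
  out
}

#' Simulate unstructured trials
#'
#' Draws `n_trials` conditions uniformly from `grid` in a fixed or random
#' context, without session block structure. Used for network training,
#' evaluation and kernel estimation.
#'
#' @param n_trials Number of trials.
#' @param grid A condition grid from [condition_grid()].
#' @param context `"LOC"`, `"FRQ"`, or `"both"` (random per trial).
#' @param duration,total_rate Stimulus parameters.
#' @param seed Optional integer seed.
#' @return A trials tibble with pulse list-columns and evidence strengths.
#' @export
simulate_trials <- function(n_trials, grid = condition_grid(),
                            context = "both", duration = 1.3,
                            total_rate = 40, seed = NULL) {
  with_seed(seed, {
    idx <- sample.int(nrow(grid), n_trials, replace = TRUE)
    ctx <- switch(context,
      both = ifelse(rbinom(n_trials, 1, 0.5) == 1, "LOC", "FRQ"),
      LOC = rep("LOC", n_trials),
      FRQ = rep("FRQ", n_trials),
      abort("`context` must be 'LOC', 'FRQ' or 'both'.")
    )
    trials <- build_trials(grid$p_right[idx], grid$p_high[idx], ctx,
                           duration, total_rate)
    trials <- evidence_strengths(trials)
    trials$correct_side <- correct_side(trials$loc_strength,
                                        trials$frq_strength, trials$context)
    trials
  })
}

#' Simulate a blocked behavioural session
#'
#' Contexts alternate in blocks. A context switch is allowed only once the
#' current block has at least `min_block_length` trials and the running
#' accuracy over the last `switch_window` trials reaches
#' `switch_threshold`; switches are also withheld near the end of the
#' session so that every block, including the last, reaches the minimum
#' length. Conditions are drawn uniformly from the grid and choices are
#' produced by the agent.
#'
#' @param n_trials Session length.
#' @param agent An [agent_spec()].
#' @param grid Condition grid.
#' @param min_block_length Minimum trials per context block (default 30).
#' @param switch_window Trials in the causal performance window (default 20).
#' @param switch_threshold Accuracy required to allow a switch (default 0.8).
#' @param start_context First block's context (default `"LOC"`).
#' @param duration,total_rate,pseudo_count Stimulus and binning parameters.
#' @param session_id Integer identifier stored in the output.
#' @param seed Optional integer seed.
#' @return A trials tibble with columns `block_id`, `context`, pulse
#'   list-columns, `choice`, `correct_side`, `correct`.
#' @export
generate_session <- function(n_trials, agent = agent_spec(),
                             grid = condition_grid(),
                             min_block_length = 30, switch_window = 20,
                             switch_threshold = 0.8, start_context = "LOC",
                             duration = 1.3, total_rate = 40,
                             pseudo_count = 1, session_id = 1L, seed = NULL) {
  stopifnot(n_trials >= 1)
  with_seed(seed, {
    idx <- sample.int(nrow(grid), n_trials, replace = TRUE)
    trials <- build_trials(grid$p_right[idx], grid$p_high[idx],
                           rep(start_context, n_trials), duration, total_rate)
    trials <- evidence_strengths(trials)
    design <- kernel_design(trials, agent$n_bins, pseudo_count)

    context <- character(n_trials)
    block_id <- integer(n_trials)
    choice <- character(n_trials)
    corr_side <- character(n_trials)
    correct <- logical(n_trials)
    cur_ctx <- start_context
    cur_block <- 1L
    block_len <- 0L
    for (k in seq_len(n_trials)) {
      context[k] <- cur_ctx
      block_id[k] <- cur_block
      dv <- agent_decision_value(agent, design$loc[k, ], design$frq[k, ], cur_ctx)
      choice[k] <- draw_choices(agent, dv)
      corr_side[k] <- correct_side(trials$loc_strength[k],
                                   trials$frq_strength[k], cur_ctx)
      correct[k] <- choice[k] == corr_side[k]
      block_len <- block_len + 1L
      # a switch is disallowed if the new block could not reach the minimum
      # length before the session ends
      if (block_len >= min_block_length && k >= switch_window &&
          n_trials - k >= min_block_length) {
        recent <- correct[(k - switch_window + 1L):k]
        if (mean(recent) >= switch_threshold) {
          cur_ctx <- if (cur_ctx == "LOC") "FRQ" else "LOC"
          cur_block <- cur_block + 1L
          block_len <- 0L
        }
      }
    }
    trials$context <- context
    trials$block_id <- block_id
    trials$choice <- choice
    trials$correct_side <- corr_side
    trials$correct <- correct
    trials$session_id <- session_id
    trials
  })
}

#' Maximal context-run lengths of a session
#'
#' @param session A trials tibble with a `context` column in trial order.
#' @return Integer vector of lengths of maximal constant-context runs.
#' @export
block_lengths <- function(session) {
  rle(session$context)$lengths
}

#' Write / read a trial table
#'
#' Serialises a trials tibble to the plain-text interchange format: one row
#' per trial with pulse times semicolon-joined (6 decimals) and labels as
#' strings of `L`/`R` and `l`/`h`.
#'
#' @param trials A trials tibble.
#' @param path File path.
#' @return `write_trials` returns `path` invisibly; `read_trials` returns a
#'   trials tibble.
#' @export
write_trials <- function(trials, path) {
  flat <- tibble::tibble(
    trial_id = trials$trial_id,
    session_id = trials$session_id %||% 1L,
    block_id = trials$block_id %||% 1L,
    context = trials$context,
    p_right = trials$p_right,
    p_high = trials$p_high,
    duration = trials$duration,
    total_rate = trials$total_rate,
    pulse_times = purrr::map_chr(trials$pulse_times,
                                 ~paste(sprintf("%.6f", .x), collapse = ";")),
    side_labels = purrr::map_chr(trials$side_labels,
                                 ~paste(ifelse(.x == 1L, "R", "L"), collapse = "")),
    freq_labels = purrr::map_chr(trials$freq_labels,
                                 ~paste(ifelse(.x == 1L, "h", "l"), collapse = "")),
    choice = trials$choice %||% NA_character_,
    correct = as.integer(trials$correct %||% NA)
  )
  utils::write.csv(flat, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  flat <- utils::read.csv(path, stringsAsFactors = FALSE)
  split1 <- function(s) if (is.na(s) || s == "") numeric(0) else as.numeric(strsplit(s, ";")[[1]])
  to_sign <- function(s, pos) {
    if (is.na(s) || s == "") return(integer(0))
    ifelse(strsplit(s, "")[[1]] == pos, 1L, -1L)
  }
  out <- tibble::tibble(
    trial_id = flat$trial_id,
    session_id = flat$session_id,
    block_id = flat$block_id,
    context = flat$context,
    p_right = flat$p_right,
    p_high = flat$p_high,
    duration = flat$duration,
    total_rate = flat$total_rate,
    pulse_times = purrr::map(flat$pulse_times, split1),
    side_labels = purrr::map_chr(flat$side_labels, identity) |>
      purrr::map(to_sign, pos = "R"),
    freq_labels = purrr::map_chr(flat$freq_labels, identity) |>
      purrr::map(to_sign, pos = "h"),
    choice = flat$choice,
    correct = as.logical(flat$correct)
  )
  evidence_strengths(out)
}
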