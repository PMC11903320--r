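# Independent forward constructor for pulse-regression test data: builds
# unit activity directly from known kernels by explicit per-trial loops
# (deliberately naive; the package's sparse design matrix is never used).
synthesize_activity <- function(trials, centers, bin_width,
                                choice_k, context_k, time_k,
                                pulse_k, noise_sd = 0.1, seed = 1) {
  # choice_k/context_k/time_k: units x bins; pulse_k: named list of four
  # units x lags matrices (loc_locctx, loc_frqctx, frq_locctx, frq_frqctx)
  set.seed(seed)
  n_units <- nrow(choice_k)
  T_ <- length(centers)
  K <- nrow(trials)
  n_lags <- ncol(pulse_k[[1]])
  first_edge <- centers[1] - bin_width / 2
  a <- array(0, dim = c(n_units, T_, K))
  for (k in seq_len(K)) {
    ch <- if (trials$choice[k] == "R") 0.5 else -0.5
    cx <- if (trials$context[k] == "LOC") 0.5 else -0.5
    base <- choice_k * ch + context_k * cx + time_k
    counts_loc <- rep(0, T_); counts_frq <- rep(0, T_)
    tt <- trials$pulse_times[[k]]
    bi <- floor((tt - first_edge) / bin_width) + 1L
    ok <- bi >= 1 & bi <= T_
    for (j in which(ok)) {
      counts_loc[bi[j]] <- counts_loc[bi[j]] + trials$side_labels[[k]][j]
      counts_frq[bi[j]] <- counts_frq[bi[j]] + trials$freq_labels[[k]][j]
    }
    kern_loc <- if (trials$context[k] == "LOC") pulse_k$loc_locctx else pulse_k$loc_frqctx
    kern_frq <- if (trials$context[k] == "LOC") pulse_k$frq_locctx else pulse_k$frq_frqctx
    conv <- matrix(0, n_units, T_)
    for (t in seq_len(T_)) {
      for (l in seq_len(n_lags)) {
        src <- t - l + 1L
        if (src >= 1) {
          conv[, t] <- conv[, t] + kern_loc[, l] * counts_loc[src] +
            kern_frq[, l] * counts_frq[src]
        }
      }
    }
    a[, , k] <- base + conv + matrix(rnorm(n_units * T_, sd = noise_sd),
                                     n_units, T_)
  }
  structure(
    list(activity = a, bin_centers = centers, bin_width = bin_width,
         units = seq_len(n_units), trials = trials),
    class = "activity_dataset"
  )
}

# Smooth random kernels for synthesis.
smooth_kernels <- function(n_units, len, scale = 1, seed = 1) {
  set.seed(seed)
  t(sapply(seq_len(n_units), function(u) {
    raw <- rnorm(len)
    as.numeric(stats::filter(raw, rep(1 / 5, 5), circular = TRUE)) * scale
  }))
}

# Trials with random choices for synthesis (choices need not follow the
# stimulus for regression recovery).
synthetic_trials <- function(n, seed = 1) {
  trials <- simulate_trials(n, context = "both", seed = seed)
  set.seed(seed + 1)
  trials$choice <- ifelse(rbinom(n, 1, 0.5) == 1, "R", "L")
  trials
}
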