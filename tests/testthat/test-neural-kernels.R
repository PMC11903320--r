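test_that("binning spike times matches the configured window", {
  trials <- simulate_trials(3, seed = 1)
  spikes <- tibble::tibble(
    trial_id = c(1L, 1L, 2L, 3L),
    unit = c(1L, 2L, 1L, 1L),
    time = c(-0.5, 0.01, 1.95, 0.655)
  )
  ds <- bin_activity(spikes, trials)
  expect_equal(length(ds$bin_centers), 151)
  expect_equal(ds$bin_centers[1], -1)
  expect_equal(ds$bin_centers[151], 2)
  # all in-window spikes preserved
  expect_equal(sum(ds$activity), 4)
  # the spike at 0.655 falls in the bin centred at 0.66
  expect_equal(ds$activity[1, which(abs(ds$bin_centers - 0.66) < 1e-9), 3], 1)
})

test_that("pulse kernels are recovered from synthesised activity", {
  centers <- seq(-0.2, 1.5, by = 0.02)
  n_units <- 10; n_lags <- 20
  trials <- synthetic_trials(2500, seed = 21)
  truth <- list(
    choice_k = smooth_kernels(n_units, length(centers), 0.5, seed = 1),
    context_k = smooth_kernels(n_units, length(centers), 0.3, seed = 2),
    time_k = smooth_kernels(n_units, length(centers), 0.5, seed = 3),
    pulse_k = list(
      loc_locctx = smooth_kernels(n_units, n_lags, 0.4, seed = 4),
      loc_frqctx = smooth_kernels(n_units, n_lags, 0.2, seed = 5),
      frq_locctx = smooth_kernels(n_units, n_lags, 0.2, seed = 6),
      frq_frqctx = smooth_kernels(n_units, n_lags, 0.4, seed = 7)
    )
  )
  ds <- synthesize_activity(trials, centers, 0.02, truth$choice_k,
                            truth$context_k, truth$time_k, truth$pulse_k,
                            noise_sd = 0.2, seed = 22)
  fit <- fit_pulse_kernels(ds, ridge_strength = 1e-3,
                           smoothness_strength = 1e-3, n_lags = n_lags)
  for (nm in names(truth$pulse_k)) {
    r <- cor(as.numeric(fit$pulse_kernels[[nm]]),
             as.numeric(truth$pulse_k[[nm]]))
    expect_gt(r, 0.9)
  }
  expect_gt(cor(as.numeric(fit$choice_kernels), as.numeric(truth$choice_k)),
            0.95)
})

test_that("pulse-independent activity yields near-zero pulse kernels", {
  centers <- seq(-0.2, 1.0, by = 0.02)
  n_units <- 6; n_lags <- 15
  trials <- synthetic_trials(1200, seed = 31)
  zero_pk <- replicate(4, matrix(0, n_units, n_lags), simplify = FALSE)
  names(zero_pk) <- c("loc_locctx", "loc_frqctx", "frq_locctx", "frq_frqctx")
  ds <- synthesize_activity(
    trials, centers, 0.02,
    smooth_kernels(n_units, length(centers), 1, seed = 8),
    smooth_kernels(n_units, length(centers), 0.3, seed = 9),
    smooth_kernels(n_units, length(centers), 0.5, seed = 10),
    zero_pk, noise_sd = 0.2, seed = 32
  )
  fit <- fit_pulse_kernels(ds, ridge_strength = 1e-3,
                           smoothness_strength = 1e-3, n_lags = n_lags)
  pk_norm <- sqrt(sum(unlist(fit$pulse_kernels)^2))
  ck_norm <- sqrt(sum(fit$choice_kernels^2))
  expect_lt(pk_norm, 0.05 * ck_norm)
})

test_that("an overwhelming smoothness penalty drives kernels to straight lines", {
  centers <- seq(-0.1, 0.7, by = 0.02)
  n_units <- 4; n_lags <- 12
  trials <- synthetic_trials(600, seed = 41)
  pk <- list(
    loc_locctx = smooth_kernels(n_units, n_lags, 0.6, seed = 11),
    loc_frqctx = smooth_kernels(n_units, n_lags, 0.6, seed = 12),
    frq_locctx = smooth_kernels(n_units, n_lags, 0.6, seed = 13),
    frq_frqctx = smooth_kernels(n_units, n_lags, 0.6, seed = 14)
  )
  ds <- synthesize_activity(
    trials, centers, 0.02,
    smooth_kernels(n_units, length(centers), 0.5, seed = 15),
    smooth_kernels(n_units, length(centers), 0.3, seed = 16),
    smooth_kernels(n_units, length(centers), 0.5, seed = 17),
    pk, noise_sd = 0.1, seed = 42
  )
  fit <- fit_pulse_kernels(ds, ridge_strength = 1e-6,
                           smoothness_strength = 1e9, n_lags = n_lags)
  k <- fit$pulse_kernels$loc_locctx[1, ]
  second_diffs <- diff(k, differences = 2)
  expect_lt(max(abs(second_diffs)), 1e-3 * max(abs(k)))
})

test_that("the choice axis finds the informative unit and is duplication-stable", {
  centers <- seq(-0.2, 1.5, by = 0.02)
  n_units <- 8; n_lags <- 10
  trials <- synthetic_trials(800, seed = 51)
  choice_k <- matrix(0, n_units, length(centers))
  ramp <- pmax(centers, 0)
  choice_k[3, ] <- ramp   # one informative unit among silent ones
  zero_pk <- replicate(4, matrix(0, n_units, n_lags), simplify = FALSE)
  names(zero_pk) <- c("loc_locctx", "loc_frqctx", "frq_locctx", "frq_frqctx")
  ds <- synthesize_activity(trials, centers, 0.02, choice_k,
                            matrix(0, n_units, length(centers)),
                            matrix(0, n_units, length(centers)),
                            zero_pk, noise_sd = 0.02, seed = 52)
  fit <- fit_pulse_kernels(ds, ridge_strength = 1e-4,
                           smoothness_strength = 1e-4, n_lags = n_lags)
  axis <- estimate_choice_axis(fit)
  expect_equal(sqrt(sum(axis$direction^2)), 1, tolerance = 1e-10)
  expect_gt(abs(axis$direction[3]), 0.98)
  expect_gt(axis$direction[3], 0)   # sign: go-right projects positively

  # duplicating every unit leaves projections proportional
  fit2 <- fit
  fit2$choice_kernels <- rbind(fit$choice_kernels, fit$choice_kernels)
  for (nm in names(fit2$pulse_kernels)) {
    fit2$pulse_kernels[[nm]] <- rbind(fit$pulse_kernels[[nm]],
                                      fit$pulse_kernels[[nm]])
  }
  axis2 <- estimate_choice_axis(fit2)
  d1 <- differential_pulse_response_estimate(fit, axis, "loc")
  d2 <- differential_pulse_response_estimate(fit2, axis2, "loc")
  expect_equal(d2$values, d1$values * sqrt(2), tolerance = 1e-6)
})

test_that("context permutation test detects orthogonal per-context axes", {
  centers <- seq(-0.1, 1.4, by = 0.05)
  n_units <- 6; n_lags <- 5
  trials <- synthetic_trials(400, seed = 61)
  # choice encoding lives on unit 1 in LOC trials, unit 2 in FRQ trials
  T_ <- length(centers)
  a <- array(0, dim = c(n_units, T_, nrow(trials)))
  ramp <- seq(0, 1, length.out = T_)
  set.seed(62)
  for (k in seq_len(nrow(trials))) {
    ch <- if (trials$choice[k] == "R") 0.5 else -0.5
    u <- if (trials$context[k] == "LOC") 1 else 2
    a[u, , k] <- ch * ramp
    a[, , k] <- a[, , k] + matrix(rnorm(n_units * T_, sd = 0.02), n_units, T_)
  }
  ds <- structure(
    list(activity = a, bin_centers = centers, bin_width = 0.05,
         units = seq_len(n_units), trials = trials),
    class = "activity_dataset"
  )
  out <- choice_axis_context_test(ds, n_permutations = 49, seed = 63,
                                  ridge_strength = 1e-3,
                                  smoothness_strength = 1e-3, n_lags = n_lags)
  expect_gt(out$angle_degrees, 80)
  expect_lt(out$p_value, 0.05)
  expect_error(choice_axis_context_test(ds, n_permutations = 0),
               "at least 1")
})

test_that("identical kernels across contexts give a zero differential response", {
  fit <- list(
    choice_kernels = matrix(rnorm(40), 4, 10),
    pulse_kernels = list(
      loc_locctx = matrix(1, 4, 6), loc_frqctx = matrix(1, 4, 6),
      frq_locctx = matrix(0.5, 4, 6), frq_frqctx = matrix(0.5, 4, 6)
    ),
    lags = (0:5) * 0.02,
    bin_centers = seq(0, 0.18, by = 0.02)
  )
  class(fit) <- "pulse_kernel_fit"
  axis <- structure(list(direction = rep(0.5, 4), context_tag = "pooled"),
                    class = "choice_axis")
  d <- differential_pulse_response_estimate(fit, axis, "loc")
  expect_true(all(d$values == 0))
  bad_axis <- structure(list(direction = rep(0.5, 5)), class = "choice_axis")
  expect_error(differential_pulse_response_estimate(fit, bad_axis, "loc"),
               "different unit sets")
})
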