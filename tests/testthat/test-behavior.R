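# Simulate choices directly from a known four-parameter logistic curve.
simulate_psychometric_trials <- function(n, y0, a, x0, b, seed) {
  set.seed(seed)
  trials <- simulate_trials(n, context = "LOC", seed = seed)
  p <- y0 + a / (1 + exp(-(trials$loc_strength - x0) / b))
  trials$choice <- ifelse(rbinom(n, 1, p) == 1, "R", "L")
  trials
}

test_that("psychometric parameters are recovered from simulated choices", {
  truth <- c(y0 = 0.02, a = 0.96, x0 = 0, b = 2)
  trials <- simulate_psychometric_trials(20000, truth["y0"], truth["a"],
                                         truth["x0"], truth["b"], seed = 1)
  fit <- fit_psychometric(trials, "loc")
  # bootstrap SEs from refits on resampled trials
  bs <- bootstrap_se(trials, function(d) {
    f <- fit_psychometric(d, "loc")
    c(f$y0, f$a, f$x0, f$b)
  }, n_boot = 20, seed = 2)
  est <- c(fit$y0, fit$a, fit$x0, fit$b)
  expect_true(all(abs(est - truth) < 3 * bs$se + 1e-8))
  # least-squares variant agrees closely
  fit_ls <- fit_psychometric(trials, "loc", method = "ls")
  expect_equal(fit_ls$x0, fit$x0, tolerance = 0.3)
})

test_that("a symmetric generator yields a centred psychometric curve", {
  trials <- simulate_psychometric_trials(20000, 0, 1, 0, 2, seed = 3)
  fit <- fit_psychometric(trials, "loc")
  expect_lt(abs(fit$x0), 0.5)
})

test_that("a fully biased chooser gives a degenerate flat fit", {
  trials <- simulate_trials(200, context = "LOC", seed = 4)
  trials$choice <- "R"
  expect_warning(fit <- fit_psychometric(trials, "loc"), "degenerate")
  expect_equal(fit$status, "degenerate")
  expect_equal(fit$y0 + fit$a, 1, tolerance = 1e-6)
})

test_that("FSI separates context-using, context-blind and single-feature agents", {
  # relevant feature only in each context -> FSI ~ 1
  fsi1 <- feature_selection_index(agent_trials(ideal_agent(), seed = 11))
  expect_gt(fsi1$fsi, 0.93)
  # both features equally in both contexts -> FSI ~ 0.5
  blind <- agent_spec(w_loc_in_loc = 2, w_frq_in_loc = 2,
                      w_loc_in_frq = 2, w_frq_in_frq = 2,
                      decision_noise = 0.5)
  fsi2 <- feature_selection_index(agent_trials(blind, seed = 12))
  expect_equal(fsi2$fsi, 0.5, tolerance = 0.05)
  # location only in both contexts -> 1 in LOC, 0 in FRQ -> FSI ~ 0.5
  loconly <- agent_spec(w_loc_in_loc = 2, w_frq_in_loc = 0,
                        w_loc_in_frq = 2, w_frq_in_frq = 0,
                        decision_noise = 0.5)
  fsi3 <- feature_selection_index(agent_trials(loconly, seed = 13))
  expect_equal(fsi3$fsi, 0.5, tolerance = 0.05)
  expect_gt(fsi3$relative_weight_location, 0.9)
  expect_lt(fsi3$relative_weight_frequency, 0.1)
  # single-context input errors
  expect_error(
    feature_selection_index(simulate_trials(100, context = "LOC", seed = 1)),
    "Both contexts"
  )
})

test_that("session filtering applies all three criteria", {
  good <- generate_session(150, ideal_agent(noise = 0.2), session_id = 1,
                           seed = 41)
  bad <- generate_session(150, chance_agent(), session_id = 2, seed = 42)
  short <- generate_session(99, ideal_agent(noise = 0.2), session_id = 3,
                            seed = 43)
  out <- session_filter(dplyr::bind_rows(good, bad, short))
  expect_equal(sort(unique(out$trials$session_id)), 1)
  rep_bad <- out$report[out$report$session_id == 2, ]
  expect_match(rep_bad$reasons, "low_accuracy")
  expect_match(rep_bad$reasons, "low_fsi")
  rep_short <- out$report[out$report$session_id == 3, ]
  expect_match(rep_short$reasons, "too_few_trials")
})

test_that("behavioural kernels recover a known temporal weighting", {
  # agent with a flat kernel on the relevant feature, zero on the other
  agent <- agent_spec(w_loc_in_loc = 1.5, decision_noise = 1)
  trials <- simulate_trials(8000, context = "LOC", seed = 51)
  design <- pulsedyn:::kernel_design(trials, 26, 1)
  set.seed(52)
  dv <- pulsedyn:::agent_decision_value(agent, design$loc, design$frq, "LOC")
  trials$choice <- pulsedyn:::draw_choices(agent, dv)
  fit <- fit_behavioral_kernels(trials, seed = 53)
  expect_length(fit$w_loc, 26)
  expect_true(all(fit$w_loc > 0))
  # relevant weights approximately flat: spread small relative to mean
  expect_lt(sd(fit$w_loc) / mean(fit$w_loc), 0.35)
  # irrelevant weights near zero relative to relevant ones
  expect_lt(max(abs(fit$w_frq)), 0.35 * mean(fit$w_loc))
  # CV ridge choice is deterministic under the seed
  fit2 <- fit_behavioral_kernels(trials, seed = 53)
  expect_identical(fit$ridge_strength, fit2$ridge_strength)
  expect_identical(fit$w_loc, fit2$w_loc)
})

test_that("stimulus-independent choices shrink to zero under the ridge", {
  trials <- simulate_trials(2000, context = "LOC", seed = 61)
  set.seed(62)
  trials$choice <- ifelse(rbinom(2000, 1, 0.5) == 1, "R", "L")
  fit <- fit_behavioral_kernels(trials, seed = 63)
  expect_lt(max(abs(c(fit$w_loc, fit$w_frq))), 0.05)
})

test_that("differential kernels difference the contexts and attach slopes", {
  trials <- simulate_trials(3000, context = "LOC", seed = 71)
  agent <- ideal_agent()
  design <- pulsedyn:::kernel_design(trials, 26, 1)
  set.seed(72)
  dv <- pulsedyn:::agent_decision_value(agent, design$loc, design$frq, "LOC")
  trials$choice <- pulsedyn:::draw_choices(agent, dv)
  fit <- fit_behavioral_kernels(trials, seed = 73)

  # identical fits -> zero kernel, zero slope
  d0 <- differential_behavioral_kernel(fit, fit, "loc")
  expect_true(all(d0$values == 0))
  expect_equal(d0$slope_index$slope, 0)

  # constant offset -> flat kernel at the offset, zero slope
  fit_shift <- fit
  fit_shift$w_loc <- fit$w_loc + 0.4
  d1 <- differential_behavioral_kernel(fit_shift, fit, "loc")
  expect_equal(unique(round(d1$values, 10)), 0.4)
  expect_equal(d1$slope_index$slope, 0, tolerance = 1e-8)

  fit_bad <- fit
  fit_bad$times <- fit$times + 1
  expect_error(differential_behavioral_kernel(fit_bad, fit, "loc"),
               "mismatched")
})

test_that("an agent whose relative weighting converges in time yields a negative slope", {
  # relevant-context weights drop linearly; irrelevant-context weights for
  # the same feature are constant -> differential kernel decreases
  w_rel <- seq(2.2, 0.6, length.out = 26)
  agent_rel <- agent_spec(w_loc_in_loc = w_rel, decision_noise = 0.8)
  agent_irr <- agent_spec(w_loc_in_frq = 0.6, w_frq_in_frq = 2,
                          decision_noise = 0.8)
  fit_ctx <- function(agent, ctx, seed) {
    trials <- simulate_trials(12000, context = ctx, seed = seed)
    design <- pulsedyn:::kernel_design(trials, 26, 1)
    set.seed(seed + 1)
    dv <- pulsedyn:::agent_decision_value(agent, design$loc, design$frq, ctx)
    trials$choice <- pulsedyn:::draw_choices(agent, dv)
    fit_behavioral_kernels(trials, seed = seed + 2)
  }
  f_rel <- fit_ctx(agent_rel, "LOC", 81)
  f_irr <- fit_ctx(agent_irr, "FRQ", 84)
  dk <- differential_behavioral_kernel(f_rel, f_irr, "loc")
  expect_lt(dk$slope_index$slope, 0)
})
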