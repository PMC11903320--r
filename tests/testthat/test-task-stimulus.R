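test_that("condition grid has the expected size, spacing and symmetry", {
  g <- condition_grid()
  expect_equal(nrow(g), 36)
  # log-odds spacing is even
  lo <- sort(unique(qlogis(g$p_right)))
  expect_equal(diff(lo), rep(diff(lo)[1], 5))
  # for every condition (p, q) the mirrored condition (1-p, 1-q) exists
  key <- paste(round(g$p_right, 10), round(g$p_high, 10))
  mirrored <- paste(round(1 - g$p_right, 10), round(1 - g$p_high, 10))
  expect_setequal(key, mirrored)

  g2 <- condition_grid(2, 0, 1)
  expect_equal(nrow(g2), 4)
  expect_setequal(g2$p_right, c(0, 1))
  expect_error(condition_grid(6, 0.8, 0.2), "strictly below")
})

test_that("pulse trains are Poisson at the configured rate with Bernoulli labels", {
  tr <- generate_pulse_train(1.0, 0.5, seed = 1)
  expect_true(all(tr$side_labels == 1L))
  expect_true(all(tr$pulse_times >= 0 & tr$pulse_times < 1.3))
  expect_true(all(diff(tr$pulse_times) >= 0))
  expect_equal(length(tr$side_labels), length(tr$pulse_times))

  # determinism
  tr2 <- generate_pulse_train(1.0, 0.5, seed = 1)
  expect_identical(tr, tr2)

  # empirical mean rate within 2 Monte-Carlo SE of 40 Hz, and Fano factor
  # of the counts within 3 SE of 1 (Poisson count law)
  n_reps <- 3000
  counts <- sapply(seq_len(n_reps), function(s) {
    length(generate_pulse_train(0.5, 0.5, seed = s)$pulse_times)
  })
  rate <- mean(counts) / 1.3
  se_rate <- sqrt(40 / 1.3 / n_reps)
  expect_lt(abs(rate - 40), 2 * se_rate)
  fano <- var(counts) / mean(counts)
  se_fano <- sqrt(2 / (n_reps - 1))
  expect_lt(abs(fano - 1), 3 * se_fano)
})

test_that("label symmetry: relabelling sides mirrors the generator", {
  # p_right -> 1 - p_right with flipped labels gives the same distribution
  # of location strengths (checked on summary moments)
  s1 <- sapply(1:800, function(s)
    sum(generate_pulse_train(0.7, 0.5, seed = s)$side_labels))
  s2 <- sapply(1:800, function(s)
    -sum(generate_pulse_train(0.3, 0.5, seed = 1000 + s)$side_labels))
  expect_lt(abs(mean(s1) - mean(s2)), 3 * sqrt(var(s1) / 800 + var(s2) / 800))
})

test_that("evidence strengths count pulses correctly", {
  tr <- structure(
    list(pulse_times = c(0.1, 0.2, 0.3, 0.4),
         side_labels = c(1L, 1L, 1L, -1L),
         freq_labels = c(1L, 1L, -1L, -1L),
         duration = 1.3, total_rate = 40),
    class = "pulse_train"
  )
  expect_equal(unname(evidence_strengths(tr)), c(2, 0))
  empty <- structure(
    list(pulse_times = numeric(0), side_labels = integer(0),
         freq_labels = integer(0), duration = 1.3, total_rate = 40),
    class = "pulse_train"
  )
  expect_equal(unname(evidence_strengths(empty)), c(0, 0))
  # identity: loc_strength + 2 * #left = total pulses
  tr2 <- generate_pulse_train(0.3, 0.6, seed = 9)
  st <- evidence_strengths(tr2)
  expect_equal(unname(st["loc_strength"]) + 2 * sum(tr2$side_labels == -1L),
               length(tr2$pulse_times))
})

test_that("binned log-ratio evidence follows the pseudo-count definition", {
  tr <- structure(
    list(pulse_times = c(0.01, 0.02), side_labels = c(1L, 1L),
         freq_labels = c(1L, -1L), duration = 1.3, total_rate = 40),
    class = "pulse_train"
  )
  ev <- bin_log_ratio_evidence(tr, n_bins = 26, pseudo_count = 1)
  expect_length(ev$loc, 26)
  expect_equal(ev$loc[1], log(3))   # 2 right, 0 left -> ln((2+1)/(0+1))
  expect_equal(ev$loc[2], 0)        # empty bin -> ln(1/1)
  expect_equal(ev$frq[1], 0)        # 1 high, 1 low -> ln(2/2)
  expect_equal(ev$times[1], 0.025)
})

test_that("sessions respect block structure and the switch rule", {
  sess <- generate_session(200, ideal_agent(noise = 0.2), seed = 21)
  expect_true(all(block_lengths(sess) >= 30))
  expect_gt(mean(sess$correct), 0.8)

  # unreachable threshold -> a single block
  sess1 <- generate_session(120, ideal_agent(), switch_threshold = 1.01,
                            seed = 22)
  expect_equal(length(block_lengths(sess1)), 1L)

  # determinism
  sess2 <- generate_session(200, ideal_agent(noise = 0.2), seed = 21)
  expect_identical(sess$choice, sess2$choice)
  expect_identical(sess$pulse_times, sess2$pulse_times)

  # a chance agent switches far less often than a near-ideal agent
  n_blocks <- function(agent, seeds) {
    sapply(seeds, function(s)
      length(block_lengths(generate_session(300, agent, seed = s))))
  }
  b_good <- n_blocks(ideal_agent(noise = 0.2), 1:5)
  b_chance <- n_blocks(chance_agent(), 1:5)
  expect_gt(mean(b_good), 2 * mean(b_chance))
})

test_that("agent choices follow the deterministic sign limit and lapse at chance", {
  tr <- generate_pulse_train(0.9, 0.5, seed = 5)
  ag <- agent_spec(w_loc_in_loc = 1, decision_noise = 0)
  expect_equal(agent_choice(ag, tr, "LOC", seed = 1), "R")

  lapser <- chance_agent()
  trials <- simulate_trials(600, context = "LOC", seed = 6)
  design <- pulsedyn:::kernel_design(trials, 26, 1)
  dv <- pulsedyn:::agent_decision_value(lapser, design$loc, design$frq, "LOC")
  set.seed(7)
  ch <- pulsedyn:::draw_choices(lapser, dv)
  acc <- mean(ch == trials$correct_side)
  expect_lt(abs(acc - 0.5), 3 * sqrt(0.25 / 600))
})

test_that("trial tables round-trip through the CSV interchange format", {
  sess <- generate_session(40, ideal_agent(), min_block_length = 10, seed = 31)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials(sess, path)
  back <- read_trials(path)
  expect_equal(nrow(back), nrow(sess))
  expect_equal(back$context, sess$context)
  expect_equal(back$choice, sess$choice)
  expect_equal(back$side_labels, sess$side_labels)
  expect_equal(back$loc_strength, sess$loc_strength)
  expect_equal(back$pulse_times[[3]], sess$pulse_times[[3]], tolerance = 1e-5)
})
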