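# Reference agents used across tests. Decision noise is kept small but
# positive so logistic fits stay well-conditioned.
ideal_agent <- function(noise = 0.5) {
  agent_spec(w_loc_in_loc = 3, w_frq_in_frq = 3, decision_noise = noise)
}

chance_agent <- function() {
  agent_spec(lapse_rate = 1)
}

# Balanced two-context trial sets with agent choices drawn from the
# agent's own decision rule.
agent_trials <- function(agent, n = 4000, seed = 1) {
  t_loc <- simulate_trials(n / 2, context = "LOC", seed = seed)
  t_frq <- simulate_trials(n / 2, context = "FRQ", seed = seed + 1)
  trials <- dplyr::bind_rows(t_loc, t_frq)
  design <- pulsedyn:::kernel_design(trials, agent$n_bins, 1)
  set.seed(seed + 2)
  ch <- character(nrow(trials))
  for (ctx in c("LOC", "FRQ")) {
    k <- trials$context == ctx
    dv <- pulsedyn:::agent_decision_value(
      agent, design$loc[k, , drop = FALSE], design$frq[k, , drop = FALSE], ctx
    )
    ch[k] <- pulsedyn:::draw_choices(agent, dv)
  }
  trials$choice <- ch
  trials$correct <- trials$choice == trials$correct_side
  trials
}
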