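# Shared trained-network fixture. Training is the most expensive step in
# the suite, so the base network is trained once per test run and reused
# by the dynamics, engineering and linking tests.
.network_cache <- new.env(parent = emptyenv())

# Desk-scale schedule for the shared base network (see the methods
# vignette for the rationale behind these sizes).
base_train_config <- function(seed = 42) {
  train_config(n_batches = 2500, batch_size = 64, step_size = 0.005,
               decay = 0.9995, tau_train = 0.03, loss_window = 30,
               seed = seed)
}

get_base_network <- function() {
  if (is.null(.network_cache$base)) {
    .network_cache$base <- train_network(init_network(seed = 42, N = 100),
                                         base_train_config())
  }
  .network_cache$base
}

# Linearisations of the base network in both contexts (computed once).
get_base_lins <- function() {
  if (is.null(.network_cache$lins)) {
    net <- get_base_network()
    .network_cache$lins <- list(
      LOC = linearize(net, find_fixed_points(net, "LOC", n_seeds = 40,
                                             seed = 1)[1, ]),
      FRQ = linearize(net, find_fixed_points(net, "FRQ", n_seeds = 40,
                                             seed = 2)[1, ])
    )
  }
  .network_cache$lins
}
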