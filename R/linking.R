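#' Map a population of trained networks in barycentric coordinates
#'
#' Trains `n_networks` networks from independent initialisations,
#' decomposes each per feature, and reports barycentric positions and
#' nearest-vertex assignment counts (nearest vertex = largest component
#' percentage; ties assigned to SVM).
#'
#' @param n_networks Number of networks (>= 5 recommended).
#' @param config A [train_config()].
#' @param grid Condition grid.
#' @param N Hidden units per network.
#' @param seed Integer seed; network `j` trains with seed `seed + j`.
#' @param features Which features to decompose (default both).
#' @return A list with `summary` (one row per network x feature: component
#'   percentages, barycentric `x`/`y`, nearest vertex, accuracy) and
#'   `vertex_counts`; failed trainings are excluded and counted in
#'   `n_failed`.
#' @export
trained_population_map <- function(n_networks, config = train_config(),
                                   grid = condition_grid(), N = 100,
                                   seed = 1, features = c("loc", "frq")) {
  rows <- list()
  n_failed <- 0L
  for (j in seq_len(n_networks)) {
    sj <- seed + j
    res <- tryCatch({
      cfg <- config
      cfg$seed <- sj
      net <- train_network(init_network(seed = sj, N = N), cfg, grid)
      perf <- evaluate_performance(net, grid, n_trials = 1000, seed = sj)
      lins <- list(
        LOC = linearize_first(net, find_fixed_points(net, "LOC", n_seeds = 50,
                                                     seed = sj)),
        FRQ = linearize_first(net, find_fixed_points(net, "FRQ", n_seeds = 50,
                                                     seed = sj))
      )
      purrr::map_dfr(features, function(f) {
        rel <- if (f == "loc") "LOC" else "FRQ"
        irr <- if (f == "loc") "FRQ" else "LOC"
        dec <- decompose_components(lins[[rel]], lins[[irr]], f)
        bc <- barycentric_point(dec)
        pc <- dec$percentages
        nearest <- c("svm", "dim", "iim")[which.max(c(pc["svm"], pc["dim"],
                                                      pc["iim"]))]
        tibble::tibble(
          network_id = j, feature = f,
          svm_pct = pc[["svm"]], dim_pct = pc[["dim"]], iim_pct = pc[["iim"]],
          total = dec$total, x = bc$x, y = bc$y,
          nearest_vertex = nearest,
          accuracy = perf$accuracy,
          easiest_accuracy = perf$easiest_accuracy
        )
      })
    }, error = function(e) NULL)
    if (is.null(res)) n_failed <- n_failed + 1L else rows[[length(rows) + 1]] <- res
  }
  summary <- dplyr::bind_rows(rows)
  list(
    summary = summary,
    vertex_counts = table(factor(summary$nearest_vertex,
                                 levels = c("svm", "dim", "iim"))),
    n_failed = n_failed
  )
}

# Differential behavioural kernel of a network's own choices: simulates
# trials per context, fits behavioural kernels, differences them.
network_behavioral_slope <- function(params, feature, n_trials,
                                     slope_window = NULL, seed = NULL) {
  half <- floor(n_trials / 2)
  fit_ctx <- function(ctx, s) {
    trials <- simulate_trials(half, context = ctx, seed = s)
    trials <- network_choices(params, trials)
    fit_behavioral_kernels(trials, seed = s)
  }
  f_loc <- fit_ctx("LOC", seed)
  f_frq <- fit_ctx("FRQ", seed + 1L)
  if (feature == "loc") {
    differential_behavioral_kernel(f_loc, f_frq, "loc",
                                   slope_window = slope_window)
  } else {
    differential_behavioral_kernel(f_frq, f_loc, "frq",
                                   slope_window = slope_window)
  }
}

# Estimated neural differential pulse response of a network from its own
# simulated activity.
network_neural_slope <- function(params, feature, n_trials,
                                 pulse_window = NULL, rho = NULL,
                                 window = c(-0.2, 1.5), seed = NULL,
                                 ridge_strength = 1e-3,
                                 smoothness_strength = 1e-2) {
  trials <- simulate_trials(n_trials, context = "both", seed = seed)
  act <- simulate_activity(params, trials, window = window)
  fit <- fit_pulse_kernels(act, ridge_strength = ridge_strength,
                           smoothness_strength = smoothness_strength,
                           pulse_window = pulse_window)
  axis <- estimate_choice_axis(fit)
  list(response = differential_pulse_response_estimate(fit, axis, feature),
       axis = axis, fit = fit)
}

#' Sweep engineered networks along the DIM axis
#'
#' Engineers the base network to a list of mixtures, and for each computes
#' both sides of the neural-behavioural link: the estimated neural
#' differential pulse response (from activity simulated on `n_trials_neural`
#' trials) and the differential behavioural kernel (from choices on
#' `n_trials_behavior` trials), with their slope indices. In split mode the
#' neural regression uses only pulses from the first half of the stimulus,
#' while the behavioural slope index is computed over the second-half bins
#' of the differential kernel, so the pulses driving the two slope measures
#' do not overlap.
#'
#' @param base_params A trained `rnn_params`.
#' @param mixtures A list of length-3 mixtures, or a numeric vector of DIM
#'   fractions (the SVM/IIM remainder split at the base network's own
#'   SVM:IIM ratio). Default 11 mixtures spanning 0 to 100% DIM.
#' @param feature `"loc"` or `"frq"`.
#' @param n_trials_behavior Behavioural trials per network (default 30000).
#' @param n_trials_neural Neural-fit trials per network (default 2000).
#' @param split_halves Use first-half pulses for the neural measure and
#'   the second-half kernel bins for the behavioural slope (default TRUE).
#' @param seed Integer seed.
#' @return A list with `summary` (one row per mixture: dim fraction,
#'   measured percentages, both slope indices, accuracy, fsi) and
#'   `n_skipped` (engineering failures).
#' @export
engineered_sweep <- function(base_params, mixtures = seq(0, 1, length.out = 11),
                             feature = "loc", n_trials_behavior = 30000,
                             n_trials_neural = 2000, split_halves = TRUE,
                             seed = 1) {
  duration <- 1.3
  lins <- list(
    LOC = linearize(base_params,
                    find_fixed_points(base_params, "LOC", n_seeds = 50,
                                      seed = seed)[1, ]),
    FRQ = linearize(base_params,
                    find_fixed_points(base_params, "FRQ", n_seeds = 50,
                                      seed = seed)[1, ])
  )
  if (is.numeric(mixtures)) {
    rel <- if (feature == "loc") "LOC" else "FRQ"
    irr <- if (feature == "loc") "FRQ" else "LOC"
    dec0 <- decompose_components(lins[[rel]], lins[[irr]], feature)
    side <- c(dec0$svm, dec0$iim)
    side <- if (any(side > 0)) pmax(side, 0) / sum(pmax(side, 0)) else c(0.5, 0.5)
    mixtures <- lapply(mixtures, function(d) {
      c(side[1] * (1 - d), d, side[2] * (1 - d))
    })
  }
  first_half <- c(0, duration / 2)
  second_half <- c(duration / 2, duration)
  rows <- list()
  n_skipped <- 0L
  rho_bar <- unit_vector((lins$LOC$rho + lins$FRQ$rho) / 2)
  for (j in seq_along(mixtures)) {
    mix <- mixtures[[j]]
    sj <- seed + 13L * j
    res <- tryCatch({
      net <- engineer_input_weights(base_params, feature, mix, lins = lins)
      # engineering preserves fixed points, so the base linearisations stay
      # valid; only the engineered feature's effective input changes
      eff_name <- if (feature == "loc") "i_loc_eff" else "i_frq_eff"
      w_new <- if (feature == "loc") net$w_loc else net$w_frq
      lin_rel_new <- lins[[if (feature == "loc") "LOC" else "FRQ"]]
      lin_irr_new <- lins[[if (feature == "loc") "FRQ" else "LOC"]]
      lin_rel_new[[eff_name]] <- w_new * lin_rel_new$sat
      lin_irr_new[[eff_name]] <- w_new * lin_irr_new$sat
      dec_new <- decompose_components(lin_rel_new, lin_irr_new, feature)
      beh <- network_behavioral_slope(
        net, feature, n_trials_behavior,
        slope_window = if (split_halves) second_half else NULL,
        seed = sj
      )
      neu <- network_neural_slope(
        net, feature, n_trials_neural,
        pulse_window = if (split_halves) first_half else NULL,
        seed = sj + 1L
      )
      perf <- evaluate_performance(net, n_trials = 1000, seed = sj + 2L)
      fsi <- feature_selection_index(perf$trials)$fsi
      tibble::tibble(
        mixture_id = j,
        svm_target = mix[1], dim_target = mix[2], iim_target = mix[3],
        dim_pct = dec_new$percentages[["dim"]],
        behavioral_slope = beh$slope_index$slope,
        neural_slope = neu$response$slope_index$slope,
        axis_alignment = abs(sum(neu$axis$direction * rho_bar)),
        accuracy = perf$accuracy,
        easiest_accuracy = perf$easiest_accuracy,
        fsi = fsi
      )
    }, error = function(e) NULL)
    if (is.null(res)) {
      n_skipped <- n_skipped + 1L
      next
    }
    rows[[length(rows) + 1]] <- res
  }
  list(summary = dplyr::bind_rows(rows), n_skipped = n_skipped)
}

#' Link neural and behavioural slope indices
#'
#' Pearson correlation (with permutation p-value) between the neural and
#' behavioural slope indices across networks or subjects.
#'
#' @param summaries A data frame with columns `neural_slope` and
#'   `behavioral_slope` (e.g. from [engineered_sweep()]).
#' @param n_permutations Permutations for the p-value (default 1000).
#' @param seed Optional integer seed.
#' @return A list with `r`, `p_value` and the input `table`.
#' @export
link_slopes <- function(summaries, n_permutations = 1000, seed = NULL) {
  ok <- stats::complete.cases(summaries[, c("neural_slope", "behavioral_slope")])
  d <- summaries[ok, ]
  if (nrow(d) < 3) abort("Need at least 3 entries with both slopes.")
  ct <- correlation_with_permutation(d$neural_slope, d$behavioral_slope,
                                     n_permutations, seed)
  list(r = ct$r, p_value = ct$p_value, table = d)
}
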