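#' Saturation factors at the context fixed points
#'
#' Elementwise derivative of the tanh nonlinearity at each context's fixed
#' point; the diagonal gain that converts raw weights into effective
#' linearised quantities.
#'
#' @param params An `rnn_params`.
#' @param fp_loc,fp_frq Fixed points (one-row `fixed_points` slices or bare
#'   state vectors) for the LOC and FRQ contexts.
#' @return A list with `sat_loc` and `sat_frq` (N-vectors in (0, 1\]).
#' @export
saturation_factors <- function(params, fp_loc, fp_frq) {
  one <- function(fp, context) {
    r <- if (is.data.frame(fp)) fp$r[[1]] else fp
    i0 <- params$b + params$W_c[, if (context == "LOC") 1 else 2]
    1 - tanh(drop(params$W %*% r + i0))^2
  }
  list(sat_loc = one(fp_loc, "LOC"), sat_frq = one(fp_frq, "FRQ"))
}

#' Constraint basis for input-weight engineering
#'
#' The four N-vectors against which candidate input weights are measured:
#' `v_svm = ds * sat_bar` (selection vector modulation), `v_dim = dsat *
#' rho_bar` (direct input modulation), `v_iim = dsat * s_bar_perp`
#' (indirect input modulation) and `v_leak = sat_irr * s_irr` (accumulation
#' of the pulse in the irrelevant context). Differences and means are taken
#' relevant-minus/with-irrelevant for the given feature. Because the
#' decomposition convention computes DIM through the component of the input
#' difference parallel to the unit mean attractor direction and scales it
#' by `s_bar . rho_bar`, the basis stores that factor in `dim_gain` so the
#' measured components are exactly linear in the input weights.
#'
#' @param lin_loc,lin_frq Linearisations of the same base network in the
#'   LOC and FRQ contexts.
#' @param feature `"loc"` or `"frq"`.
#' @return A `constraint_basis` list with `v_svm`, `v_dim`, `v_iim`,
#'   `v_leak`, `dim_gain` and a `degenerate` flag per vector.
#' @export
build_constraint_basis <- function(lin_loc, lin_frq, feature = c("loc", "frq")) {
  feature <- match.arg(feature)
  lin_rel <- if (feature == "loc") lin_loc else lin_frq
  lin_irr <- if (feature == "loc") lin_frq else lin_loc
  sat_rel <- lin_rel$sat; sat_irr <- lin_irr$sat
  s_rel <- lin_rel$s; s_irr <- lin_irr$s
  rho_rel <- lin_rel$rho; rho_irr <- lin_irr$rho
  if (sum(rho_rel * rho_irr) < 0) rho_irr <- -rho_irr
  rho_bar <- unit_vector((rho_rel + rho_irr) / 2)
  s_bar <- (s_rel + s_irr) / 2
  s_bar_perp <- s_bar - sum(s_bar * rho_bar) * rho_bar
  v <- list(
    v_svm = (s_rel - s_irr) * (sat_rel + sat_irr) / 2,
    v_dim = (sat_rel - sat_irr) * rho_bar,
    v_iim = (sat_rel - sat_irr) * s_bar_perp,
    v_leak = sat_irr * s_irr
  )
  norms <- vapply(v, function(x) sqrt(sum(x^2)), numeric(1))
  structure(
    c(v, list(
      dim_gain = sum(s_bar * rho_bar),
      feature = feature,
      degenerate = norms < 1e-10 * max(norms)
    )),
    class = "constraint_basis"
  )
}

# Orthogonalise v against the columns of M (Gram-Schmidt with
# orthonormalised constraint set).
project_out <- function(v, M) {
  if (length(M) == 0 || ncol(M) == 0) return(v)
  qr_m <- qr(M)
  Q <- qr.Q(qr_m)[, seq_len(qr_m$rank), drop = FALSE]
  drop(v - Q %*% crossprod(Q, v))
}

#' Engineer input weights to a target component mixture
#'
#' Replaces one feature's input weight vector so the network's measured
#' decomposition hits an arbitrary target mixture of SVM/DIM/IIM while the
#' pulse has no net effect along the attractor in the irrelevant context.
#' For each pure component, a solution is built by Gram-Schmidt: the
#' component's basis vector orthogonalised against the other two
#' zero-target constraint vectors and the irrelevant-context leak vector.
#' Mixtures are linear combinations of the three pure solutions, and the
#' result is rescaled so the relevant-context pulse efficacy
#' `s_REL . i_REL` equals `gain_match` times its pre-engineering value.
#' Recurrent weights, context weights and readout are untouched, so the
#' fixed points and linearised dynamics are preserved.
#'
#' @param params A trained `rnn_params`.
#' @param feature `"loc"` or `"frq"` - which input vector to replace.
#' @param mix Length-3 nonnegative mixture `(svm, dim, iim)` summing to 1.
#' @param gain_match Positive rescaling of pulse efficacy (default 1).
#' @param lins Optional named list `list(LOC = , FRQ = )` of linearisations
#'   of `params`; computed (one fixed point per context) if missing.
#' @param seed Seed for the fixed-point search when it has to run.
#' @return The engineered `rnn_params`; the target and the constraint
#'   basis are attached as attribute `engineering`.
#' @export
engineer_input_weights <- function(params, feature = c("loc", "frq"),
                                   mix, gain_match = 1, lins = NULL,
                                   seed = NULL) {
  feature <- match.arg(feature)
  if (length(mix) != 3 || any(mix < -1e-12) || abs(sum(mix) - 1) > 1e-9) {
    abort("`mix` must be three nonnegative fractions (svm, dim, iim) summing to 1.")
  }
  mix <- pmax(mix, 0)
  if (is.null(lins)) {
    lins <- list(
      LOC = linearize(params, find_fixed_points(params, "LOC", n_seeds = 50,
                                                seed = seed)[1, ]),
      FRQ = linearize(params, find_fixed_points(params, "FRQ", n_seeds = 50,
                                                seed = seed)[1, ])
    )
  }
  basis <- build_constraint_basis(lins$LOC, lins$FRQ, feature)
  if (any(basis$degenerate[c("v_svm", "v_dim", "v_iim")] & mix > 0)) {
    abort("Requested mixture needs a degenerate (near-zero) basis vector; engineering unattainable.")
  }
  # measured components are w . u_k with u_dim carrying the dim_gain factor
  u <- list(svm = basis$v_svm,
            dim = basis$v_dim * basis$dim_gain,
            iim = basis$v_iim)
  pure <- vector("list", 3)
  for (k in 1:3) {
    others <- do.call(cbind, c(u[-k], list(basis$v_leak)))
    wk <- project_out(u[[k]], others)
    ck <- sum(wk * u[[k]])
    if (mix[k] > 0 && abs(ck) < 1e-12 * sum(u[[k]]^2)) {
      abort(sprintf(
        "Infeasible orthogonality: constraint vectors are collinear with the %s component.",
        c("svm", "dim", "iim")[k]
      ))
    }
    pure[[k]] <- if (abs(ck) > 0) wk / ck else wk * 0
  }
  w_new <- mix[1] * pure[[1]] + mix[2] * pure[[2]] + mix[3] * pure[[3]]

  lin_rel <- if (feature == "loc") lins$LOC else lins$FRQ
  sat_s_rel <- lin_rel$sat * lin_rel$s
  w_old <- if (feature == "loc") params$w_loc else params$w_frq
  target_eff <- gain_match * abs(sum(w_old * sat_s_rel))
  current_eff <- sum(w_new * sat_s_rel)
  if (abs(current_eff) < 1e-14) abort("Engineered weights have zero relevant-context efficacy.")
  w_new <- w_new * target_eff / current_eff

  out <- params
  if (feature == "loc") out$w_loc <- w_new else out$w_frq <- w_new
  attr(out, "engineering") <- list(feature = feature, mix = mix,
                                   gain_match = gain_match, basis = basis)
  out
}

#' Verify an engineered network
#'
#' Recomputes fixed points, linearisations and the component decomposition
#' of an engineered network, and evaluates task behaviour.
#'
#' @param params_engineered The engineered `rnn_params`.
#' @param target Length-3 target mixture `(svm, dim, iim)`.
#' @param feature `"loc"` or `"frq"`.
#' @param n_trials Evaluation trials (default 2000).
#' @param seed Optional integer seed.
#' @return A list with `decomposition`, `measured_mix`, `mixture_error`
#'   (max absolute error in percentage points), `irr_leak_ratio`,
#'   `accuracy`, `easiest_accuracy`, `fsi` and `flagged_low_accuracy`.
#' @export
verify_engineering <- function(params_engineered, target,
                               feature = c("loc", "frq"),
                               n_trials = 2000, seed = NULL) {
  feature <- match.arg(feature)
  lins <- list(
    LOC = linearize(params_engineered,
                    find_fixed_points(params_engineered, "LOC", n_seeds = 50,
                                      seed = seed)[1, ]),
    FRQ = linearize(params_engineered,
                    find_fixed_points(params_engineered, "FRQ", n_seeds = 50,
                                      seed = seed)[1, ])
  )
  rel <- if (feature == "loc") "LOC" else "FRQ"
  irr <- if (feature == "loc") "FRQ" else "LOC"
  dec <- decompose_components(lins[[rel]], lins[[irr]], feature)
  measured <- unname(dec$percentages) / 100
  perf <- evaluate_performance(params_engineered, n_trials = n_trials,
                               seed = seed)
  fsi <- feature_selection_index(perf$trials)$fsi
  list(
    decomposition = dec,
    measured_mix = measured,
    mixture_error = max(abs(measured - target)) * 100,
    irr_leak_ratio = abs(dec$irr_leak) / abs(dec$total),
    accuracy = perf$accuracy,
    easiest_accuracy = perf$easiest_accuracy,
    fsi = fsi,
    flagged_low_accuracy = perf$easiest_accuracy < 0.85
  )
}
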