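# Autonomous drift of the network in one context (evidence inputs zero):
# F(r) = (-r + tanh(W r + i0)) / tau, with i0 = b + W_c c.
context_drift <- function(params, context, tau = params$tau) {
  i0 <- params$b + params$W_c[, if (context == "LOC") 1 else 2]
  list(
    F = function(r) (-r + tanh(params$W %*% r + i0)) / tau,
    i0 = i0
  )
}

#' Find fixed points of the autonomous dynamics
#'
#' Minimises the squared speed q = 1/2 |dr/dt|^2 from many initial states
#' sampled from simulated trajectories (context input clamped, evidence
#' zero), polishes candidate minima with Newton steps, keeps points whose
#' speed falls below `tol`, deduplicates within `dedup_radius` and sorts by
#' absolute readout |z|.
#'
#' @param params An `rnn_params`.
#' @param context `"LOC"` or `"FRQ"`.
#' @param n_seeds Number of optimisation starts (default 200).
#' @param tol Maximum accepted speed |dr/dt| (default 1e-8).
#' @param dedup_radius Euclidean deduplication radius (default 1e-3).
#' @param n_init_trials Simulated trials used to sample initial states.
#' @param seed Optional integer seed.
#' @param tau Time constant override.
#' @return A `fixed_points` tibble with list-column `r` and columns `z`,
#'   `residual`, `context`, sorted by `abs(z)`; zero rows (with a warning)
#'   if no minimum reaches `tol`.
#' @export
find_fixed_points <- function(params, context, n_seeds = 200, tol = 1e-8,
                              dedup_radius = 1e-3, n_init_trials = 20,
                              seed = NULL, tau = params$tau) {
  drift <- context_drift(params, context, tau)
  N <- params$N
  with_seed(seed, {
    # candidate starting states: points visited during task trials
    trials <- simulate_trials(n_init_trials, context = context)
    n_keep_per <- max(2L, ceiling(n_seeds / n_init_trials))
    states <- matrix(0, N, 0)
    for (k in seq_len(nrow(trials))) {
      sim <- simulate_trial(params, trials[k, ], tau = tau)
      cols <- sample(ncol(sim$trajectory), n_keep_per)
      states <- cbind(states, sim$trajectory[, cols, drop = FALSE])
    }
    starts <- states[, sample(ncol(states), min(n_seeds, ncol(states))),
                     drop = FALSE]

    q_fun <- function(r) 0.5 * sum(drift$F(r)^2)
    q_grad <- function(r) {
      f <- drift$F(r)
      d <- drop(1 - tanh(params$W %*% r + drift$i0)^2)
      J <- (-diag(N) + d * params$W) / tau
      drop(crossprod(J, f))
    }
    newton_polish <- function(r) {
      for (it in 1:50) {
        f <- drift$F(r)
        if (sqrt(sum(f^2)) < tol / 10) break
        d <- drop(1 - tanh(params$W %*% r + drift$i0)^2)
        J <- (-diag(N) + d * params$W) / tau
        step <- tryCatch(solve(J, -f), error = function(e) NULL)
        if (is.null(step)) break
        if (sqrt(sum(step^2)) > 1) step <- step / sqrt(sum(step^2))
        r <- r + step
      }
      r
    }

    found <- list()
    for (j in seq_len(ncol(starts))) {
      opt <- optim(starts[, j], q_fun, q_grad, method = "BFGS",
                   control = list(maxit = 200, reltol = 1e-14))
      r <- newton_polish(opt$par)
      res <- sqrt(sum(drift$F(r)^2))
      if (res < tol) found[[length(found) + 1]] <- list(r = r, residual = res)
    }
    if (length(found) == 0) {
      warn("No fixed point reached the speed tolerance.")
      return(structure(
        tibble::tibble(r = list(), z = numeric(0), residual = numeric(0),
                       context = character(0)),
        class = c("fixed_points", "tbl_df", "tbl", "data.frame")
      ))
    }
    pts <- do.call(cbind, lapply(found, `[[`, "r"))
    res <- vapply(found, `[[`, numeric(1), "residual")
    keep <- integer(0)
    for (j in seq_len(ncol(pts))) {
      if (length(keep) == 0 ||
          min(sqrt(colSums((pts[, keep, drop = FALSE] - pts[, j])^2))) >
            dedup_radius) {
        keep <- c(keep, j)
      }
    }
    z <- drop(crossprod(params$w_O, pts[, keep, drop = FALSE])) + params$k_O
    out <- tibble::tibble(
      r = lapply(keep, function(j) pts[, j]),
      z = z,
      residual = res[keep],
      context = context
    )
    out <- out[order(abs(out$z)), ]
    class(out) <- c("fixed_points", class(out))
    out
  })
}

#' Linearise the dynamics around a fixed point
#'
#' First-order expansion of the firing-rate dynamics at the fixed point:
#' the gain matrix D has diagonal elements g'(x0_j) (the saturation
#' factors), the Jacobian is (-I + D W)/tau, the line-attractor direction
#' rho is the unit-norm right eigenvector of the largest-real-part
#' eigenvalue (sign fixed so the readout weights project positively onto
#' it), and the selection vector s is the matching left eigenvector scaled
#' so s . rho = 1. Effective inputs are the elementwise products of the
#' input weight vectors with the saturation factors.
#'
#' @param params An `rnn_params`.
#' @param fp A one-row `fixed_points` slice, or a numeric state vector.
#' @param context Required if `fp` is a bare vector.
#' @param tau Time constant override.
#' @param im_tol Tolerance on the attractor eigenvalue's imaginary part,
#'   in units of 1/tau (default 1e-6); a complex attractor mode is an
#'   error because it violates the line-attractor premise.
#' @return A `linearized_dynamics` list with `context`, `r_star`, `sat`
#'   (gain diagonal), `J`, `eigenvalues`, `rho`, `s`, `i_loc_eff`,
#'   `i_frq_eff`, `lambda0` and `eigen_gap`.
#' @export
linearize <- function(params, fp, context = NULL, tau = params$tau,
                      im_tol = 1e-6) {
  if (is.data.frame(fp)) {
    context <- fp$context[1]
    r_star <- fp$r[[1]]
  } else {
    r_star <- fp
    if (is.null(context)) abort("`context` is required for a bare state vector.")
  }
  i0 <- params$b + params$W_c[, if (context == "LOC") 1 else 2]
  x0 <- drop(params$W %*% r_star + i0)
  sat <- 1 - tanh(x0)^2
  J <- (-diag(params$N) + sat * params$W) / tau
  eg <- eigen(J)
  j0 <- which.max(Re(eg$values))
  lambda0 <- eg$values[j0]
  if (abs(Im(lambda0)) > im_tol / tau) {
    abort(sprintf(
      "Attractor eigenvalue is complex (Im = %.3g); line-attractor premise violated.",
      Im(lambda0)
    ))
  }
  rho <- Re(eg$vectors[, j0])
  rho <- unit_vector(rho)
  if (sum(params$w_O * rho) < 0) rho <- -rho
  # left eigenvector: right eigenvector of t(J) with the same eigenvalue
  egl <- eigen(t(J))
  jl <- which.min(abs(egl$values - lambda0))
  s <- Re(egl$vectors[, jl])
  s <- s / sum(s * rho)
  others <- Re(eg$values[-j0])
  structure(
    list(
      context = context, r_star = r_star, sat = sat, J = J,
      eigenvalues = eg$values, lambda0 = lambda0,
      eigen_gap = Re(lambda0) - max(others),
      rho = rho, s = s,
      i_loc_eff = params$w_loc * sat,
      i_frq_eff = params$w_frq * sat
    ),
    class = "linearized_dynamics"
  )
}

#' @export
print.linearized_dynamics <- function(x, ...) {
  cat(sprintf(
    "Linearised dynamics (%s): lambda0 = %.4g, eigen gap = %.4g\n",
    x$context, Re(x$lambda0), x$eigen_gap
  ))
  invisible(x)
}

#' Linearise at the first analysable fixed point
#'
#' Tries the fixed points of a context in order of increasing |z| and
#' returns the first whose leading mode is real (a complex leading pair is
#' skipped: it violates the line-attractor premise at that point, and
#' linearised structure is typically similar across a network's fixed
#' points).
#'
#' @param params An `rnn_params`.
#' @param fps A `fixed_points` tibble (ordered by |z|).
#' @param ... Passed to [linearize()].
#' @return A `linearized_dynamics`, or an error if no fixed point is
#'   analysable.
#' @export
linearize_first <- function(params, fps, ...) {
  if (nrow(fps) == 0) abort("No fixed points to linearise.")
  last_err <- NULL
  for (k in seq_len(nrow(fps))) {
    out <- tryCatch(linearize(params, fps[k, ], ...),
                    error = function(e) { last_err <<- e; NULL })
    if (!is.null(out)) return(out)
  }
  stop(last_err)
}

#' Net motion along the line attractor caused by a pulse
#'
#' Under linearised line-attractor dynamics the asymptotic displacement
#' along the attractor caused by an input pulse `i` is the dot product of
#' the selection vector with the input.
#'
#' @param s Selection vector.
#' @param i Input vector (same length).
#' @return A scalar.
#' @export
pulse_effect <- function(s, i) {
  if (length(s) != length(i)) abort("`s` and `i` must have the same length.")
  sum(s * i)
}

#' Decompose context-dependent evidence selection into three components
#'
#' The across-context difference in a feature's pulse efficacy,
#' `total = s_REL . i_REL - s_IRR . i_IRR`, is written exactly as the sum
#' of selection vector modulation (SVM, `ds . i_bar`), direct input
#' modulation (DIM, the part of `s_bar . di` carried by the component of
#' `di` parallel to the mean attractor direction) and indirect input
#' modulation (IIM, the remaining, orthogonal part).
#'
#' @param lin_rel Linearisation in the feature's relevant context.
#' @param lin_irr Linearisation in the irrelevant context.
#' @param feature `"loc"` or `"frq"`; selects which effective input enters.
#' @return A `component_decomposition` with `svm`, `dim`, `iim`, `total`,
#'   `percentages`, `irr_leak` and `feature`. A non-positive total carries
#'   a warning (the network does not prefer relevant evidence).
#' @export
decompose_components <- function(lin_rel, lin_irr, feature = c("loc", "frq")) {
  feature <- match.arg(feature)
  pick <- function(lin) if (feature == "loc") lin$i_loc_eff else lin$i_frq_eff
  i_rel <- pick(lin_rel); i_irr <- pick(lin_irr)
  s_rel <- lin_rel$s; s_irr <- lin_irr$s
  rho_rel <- lin_rel$rho; rho_irr <- lin_irr$rho
  if (sum(rho_rel * rho_irr) < 0) rho_irr <- -rho_irr
  rho_bar <- unit_vector((rho_rel + rho_irr) / 2)
  ds <- s_rel - s_irr
  di <- i_rel - i_irr
  s_bar <- (s_rel + s_irr) / 2
  i_bar <- (i_rel + i_irr) / 2
  svm <- sum(ds * i_bar)
  dim_c <- sum(di * rho_bar) * sum(s_bar * rho_bar)
  iim <- sum(s_bar * di) - dim_c
  total <- sum(s_rel * i_rel) - sum(s_irr * i_irr)
  if (total <= 0) {
    warn("Total differential efficacy is non-positive; the network does not prefer relevant evidence.")
  }
  structure(
    list(
      feature = feature, svm = svm, dim = dim_c, iim = iim, total = total,
      percentages = c(svm = svm, dim = dim_c, iim = iim) / total * 100,
      irr_leak = sum(s_irr * i_irr)
    ),
    class = "component_decomposition"
  )
}

#' @export
print.component_decomposition <- function(x, ...) {
  cat(sprintf(
    "Decomposition (%s): SVM %.1f%%, DIM %.1f%%, IIM %.1f%% (total %.4g, leak %.3g)\n",
    x$feature, x$percentages["svm"], x$percentages["dim"],
    x$percentages["iim"], x$total, x$irr_leak
  ))
  invisible(x)
}

#' @export
tidy.component_decomposition <- function(x, ...) {
  tibble::tibble(
    component = c("svm", "dim", "iim"),
    value = c(x$svm, x$dim, x$iim),
    percentage = unname(x$percentages)
  )
}

#' Barycentric coordinates of a decomposition
#'
#' Maps the three component percentages to a point in the reference
#' triangle with the SVM vertex at the bottom left (0, 0), IIM at the
#' bottom right (1, 0) and DIM at the top (1/2, sqrt(3)/2).
#'
#' @param dec A `component_decomposition`, or a length-3 numeric vector of
#'   fractions (svm, dim, iim) summing to 1.
#' @return A tibble with `x`, `y`.
#' @export
barycentric_point <- function(dec) {
  f <- if (inherits(dec, "component_decomposition")) {
    if (dec$total <= 0) abort("Barycentric mapping requires a positive total.")
    c(dec$svm, dec$dim, dec$iim) / dec$total
  } else {
    as.numeric(dec)
  }
  vertices <- rbind(svm = c(0, 0), dim = c(0.5, sqrt(3) / 2), iim = c(1, 0))
  xy <- drop(f %*% vertices)
  tibble::tibble(x = xy[1], y = xy[2])
}

#' Directly measured differential pulse response
#'
#' For each context the network is initialised at that context's fixed
#' point, a single signed pulse of the feature is injected at time zero,
#' and the full nonlinear dynamics are integrated; the displacement from
#' the fixed point is projected onto the choice axis. The differential
#' response is the relevant-context minus irrelevant-context projection
#' over time.
#'
#' @param params An `rnn_params`.
#' @param choice_axis Unit-norm N-vector (e.g. the attractor direction).
#' @param feature `"loc"` or `"frq"`.
#' @param fixed_points Optional named list with elements `LOC` and `FRQ`
#'   (one-row `fixed_points` slices); computed if missing.
#' @param window Response window in seconds (default 0.65).
#' @param pulse_amplitude Impulse height (default `0.01/dt`, matching the
#'   fixed pulse area of the trial encoding).
#' @param tau Time constant override.
#' @param seed Seed for the fixed-point search when it has to run.
#' @return A `differential_pulse_response` with `times`, `values`,
#'   `by_context` (per-context projections) and a `slope_index` fit.
#' @export
measure_differential_pulse_response <- function(params, choice_axis,
                                                feature = c("loc", "frq"),
                                                fixed_points = NULL,
                                                window = 0.65,
                                                pulse_amplitude = 0.01 / params$dt,
                                                tau = params$tau,
                                                seed = NULL) {
  feature <- match.arg(feature)
  if (is.null(fixed_points)) {
    fixed_points <- list(
      LOC = find_fixed_points(params, "LOC", n_seeds = 50, seed = seed),
      FRQ = find_fixed_points(params, "FRQ", n_seeds = 50, seed = seed)
    )
  }
  dt <- params$dt
  steps <- round(window / dt)
  project_one <- function(context) {
    fp <- fixed_points[[context]]
    r0 <- if (is.data.frame(fp)) fp$r[[1]] else fp
    i_loc <- matrix(0, steps, 1)
    i_frq <- matrix(0, steps, 1)
    if (feature == "loc") i_loc[1, 1] <- pulse_amplitude else i_frq[1, 1] <- pulse_amplitude
    out <- cpp_rnn_forward(
      params$W, params$W_c, params$b, params$w_loc, params$w_frq,
      params$w_O, params$k_O, r0, i_loc, i_frq,
      as.integer(context == "FRQ"), dt / tau, 0:steps
    )
    traj <- matrix(out$activity, nrow = params$N)
    drop(crossprod(choice_axis, traj - r0))
  }
  rel <- if (feature == "loc") "LOC" else "FRQ"
  irr <- if (feature == "loc") "FRQ" else "LOC"
  values <- project_one(rel) - project_one(irr)
  times <- (0:steps) * dt
  # drop the pre-pulse sample: the response starts at the first post-pulse step
  values <- values[-1]
  times <- times[-1]
  structure(
    list(
      feature = feature, times = times, values = values,
      slope_index = slope_index(values, times),
      source = "measured"
    ),
    class = "differential_pulse_response"
  )
}

#' @export
print.differential_pulse_response <- function(x, ...) {
  cat(sprintf(
    "Differential pulse response (%s, %s): slope index = %.4g /s\n",
    x$feature, x$source, x$slope_index$slope
  ))
  invisible(x)
}
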