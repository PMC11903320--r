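# Minimal rnn_params for hand-built linear-regime toys (tanh at 0 has unit
# gain, so around the origin the dynamics are J = (-I + W)/tau).
toy_params <- function(W, tau = 0.1, w_O = NULL) {
  N <- nrow(W)
  structure(
    list(W = W, W_c = matrix(0, N, 2), b = rep(0, N),
         w_loc = rep(0, N), w_frq = rep(0, N),
         w_O = w_O %||% c(1, rep(0, N - 1)), k_O = 0,
         x0 = rep(0, N), N = N, tau = tau, dt = 0.01),
    class = "rnn_params"
  )
}

test_that("the pure-decay system has a unique fixed point at the origin", {
  p <- toy_params(matrix(0, 6, 6))
  fps <- find_fixed_points(p, "LOC", n_seeds = 20, seed = 1)
  expect_equal(nrow(fps), 1)
  expect_lt(max(abs(fps$r[[1]])), 1e-6)
  expect_lt(fps$residual[1], 1e-8)
})

test_that("every returned fixed point is stationary under re-simulation", {
  p <- toy_params(diag(c(1, rep(0.5, 4))))
  fps <- find_fixed_points(p, "LOC", n_seeds = 20, seed = 2)
  for (k in seq_len(nrow(fps))) {
    r0 <- fps$r[[k]]
    steps <- round(10 * p$tau / p$dt)
    out <- pulsedyn:::cpp_rnn_forward(
      p$W, p$W_c, p$b, p$w_loc, p$w_frq, p$w_O, p$k_O, r0,
      matrix(0, steps, 1), matrix(0, steps, 1), 0L, p$dt / p$tau,
      as.integer(steps)
    )
    moved <- sqrt(sum((out$r_final - r0)^2))
    expect_lt(moved, 1e-3)
  }
})

test_that("linearisation of a diagonal toy gives the textbook eigenstructure", {
  # W = diag(1, 0): modes (0, -1)/tau at the origin; rho = s = e1
  p <- toy_params(diag(c(1, 0)))
  lin <- linearize(p, rep(0, 2), context = "LOC")
  expect_equal(Re(lin$lambda0), 0, tolerance = 1e-12)
  expect_equal(abs(lin$rho), c(1, 0), tolerance = 1e-12)
  expect_equal(lin$s, lin$rho * sign(lin$rho[1]) * sign(lin$s[1]),
               tolerance = 1e-12)
  expect_equal(sum(lin$s * lin$rho), 1, tolerance = 1e-12)
  # tanh gain at zero input is exactly 1
  expect_equal(lin$sat, c(1, 1))
  # effective inputs are gain-modulated raw weights
  p2 <- p; p2$w_loc <- c(0.3, -0.2)
  lin2 <- linearize(p2, rep(0, 2), context = "LOC")
  expect_equal(lin2$i_loc_eff, p2$w_loc * lin2$sat)
})

test_that("complex attractor modes are rejected", {
  # rotation block on top of decay: leading pair is complex
  W <- rbind(c(1, -2), c(2, 1))
  p <- toy_params(W)
  expect_error(linearize(p, rep(0, 2), context = "LOC"), "complex")
})

test_that("pulse effect is the selection-vector dot product", {
  s <- c(0.5, -1, 2)
  expect_equal(pulse_effect(s, c(2, 1, 0)), 0)
  rho <- c(1, 0, 0); s2 <- c(1, 0.3, -0.2)  # s2 . rho = 1
  expect_equal(pulse_effect(s2, rho), 1)
  expect_error(pulse_effect(s, 1:2), "same length")
})

test_that("direct integration of linear line-attractor systems matches s . i", {
  # Box-1 oracle: for dr/dt = M r with one zero mode, the asymptotic
  # projection of the relaxed state onto the attractor direction equals
  # s . i for a pulse displacement i.
  set.seed(42)
  n_sys <- 100
  worst <- 0
  for (k in seq_len(n_sys)) {
    N <- 8
    repeat {
      V <- matrix(rnorm(N * N), N, N)
      if (rcond(V) > 1e-3) break
    }
    lambda <- c(0, -runif(N - 1, 0.5, 3))
    M <- V %*% diag(lambda) %*% solve(V)
    rho <- V[, 1] / sqrt(sum(V[, 1]^2))
    s <- solve(V)[1, ] * sqrt(sum(V[, 1]^2))   # rescaled so s . rho = 1
    i <- rnorm(N)
    # direct Euler integration for 10 times the slowest relaxation
    t_end <- 10 / min(abs(lambda[-1]))
    dt <- min(0.01 / max(abs(lambda)), t_end / 1000)
    r <- i
    for (tt in seq(0, t_end, by = dt)) r <- r + dt * (M %*% r)
    displacement <- sum(rho * r)
    expected <- pulse_effect(s, i)
    err <- abs(displacement - expected) / max(abs(expected), 1e-3)
    worst <- max(worst, err)
  }
  expect_lt(worst, 0.01)
})

# Hand-built linearisations for decomposition tests.
fake_lin <- function(s, rho, i_loc, i_frq = i_loc, context = "LOC") {
  structure(
    list(context = context, s = s, rho = rho,
         i_loc_eff = i_loc, i_frq_eff = i_frq,
         sat = rep(1, length(s))),
    class = "linearized_dynamics"
  )
}

test_that("decomposition components match brute-force evaluation", {
  set.seed(9)
  for (rep in 1:25) {
    N <- 50
    rho <- rnorm(N); rho <- rho / sqrt(sum(rho^2))
    make_s <- function() { s <- rnorm(N); s / sum(s * rho) }
    s_rel <- make_s(); s_irr <- make_s()
    i_rel <- rnorm(N); i_irr <- rnorm(N)
    dec <- decompose_components(fake_lin(s_rel, rho, i_rel),
                                fake_lin(s_irr, rho, i_irr, context = "FRQ"),
                                "loc")
    # independent brute-force: plain dot products of the defining formulas
    ds <- s_rel - s_irr; di <- i_rel - i_irr
    sbar <- (s_rel + s_irr) / 2; ibar <- (i_rel + i_irr) / 2
    svm_bf <- sum(ds * ibar)
    di_par <- sum(di * rho) * rho
    dim_bf <- sum(sbar * di_par)
    iim_bf <- sum(sbar * (di - di_par))
    expect_equal(dec$svm, svm_bf, tolerance = 1e-12)
    expect_equal(dec$dim, dim_bf, tolerance = 1e-12)
    expect_equal(dec$iim, iim_bf, tolerance = 1e-12)
    # the left- and right-hand sides of the component identity agree
    lhs <- sum(s_rel * i_rel) - sum(s_irr * i_irr)
    expect_equal(dec$svm + dec$dim + dec$iim, lhs, tolerance = 1e-12)
  }
})

test_that("degenerate decompositions behave as expected", {
  N <- 20
  set.seed(10)
  rho <- rnorm(N); rho <- rho / sqrt(sum(rho^2))
  s <- rnorm(N); s <- s / sum(s * rho)
  i <- rnorm(N)
  # identical contexts: all components vanish (and a warning: total = 0)
  expect_warning(
    dec0 <- decompose_components(fake_lin(s, rho, i),
                                 fake_lin(s, rho, i, context = "FRQ"), "loc"),
    "non-positive"
  )
  expect_equal(dec0$svm, 0, tolerance = 1e-12)
  expect_equal(dec0$dim, 0, tolerance = 1e-12)
  expect_equal(dec0$iim, 0, tolerance = 1e-12)

  # input difference parallel to the attractor with shared s -> pure DIM
  i_rel <- i + 0.7 * rho
  dec1 <- decompose_components(fake_lin(s, rho, i_rel),
                               fake_lin(s, rho, i, context = "FRQ"), "loc")
  expect_equal(unname(dec1$percentages["dim"]), 100, tolerance = 1e-8)
  expect_equal(unname(dec1$percentages["svm"]), 0, tolerance = 1e-8)
})

test_that("percentages are invariant to joint input rescaling", {
  set.seed(11)
  N <- 30
  rho <- rnorm(N); rho <- rho / sqrt(sum(rho^2))
  make_s <- function() { s <- rnorm(N); s / sum(s * rho) }
  s_rel <- make_s(); s_irr <- make_s()
  i_rel <- rnorm(N); i_irr <- rnorm(N)
  d1 <- decompose_components(fake_lin(s_rel, rho, i_rel),
                             fake_lin(s_irr, rho, i_irr, context = "FRQ"),
                             "loc")
  d2 <- decompose_components(fake_lin(s_rel, rho, 3.7 * i_rel),
                             fake_lin(s_irr, rho, 3.7 * i_irr,
                                      context = "FRQ"), "loc")
  expect_equal(d1$percentages, d2$percentages, tolerance = 1e-10)
})

test_that("barycentric mapping sends pure and mixed solutions where expected", {
  expect_equal(as.numeric(barycentric_point(c(1, 0, 0))), c(0, 0))
  expect_equal(as.numeric(barycentric_point(c(0, 1, 0))), c(0.5, sqrt(3) / 2))
  expect_equal(as.numeric(barycentric_point(c(0, 0, 1))), c(1, 0))
  expect_equal(as.numeric(barycentric_point(c(1, 1, 1) / 3)),
               c(0.5, sqrt(3) / 6), tolerance = 1e-12)
  # 50% DIM / 50% SVM -> midpoint of the left edge
  expect_equal(as.numeric(barycentric_point(c(0.5, 0.5, 0))),
               c(0.25, sqrt(3) / 4))
})
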