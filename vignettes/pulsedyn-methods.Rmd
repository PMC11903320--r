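---
title: "Models and methods behind pulsedyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pulsedyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

pulsedyn implements a complete simulation-and-analysis loop for
context-dependent accumulation of pulsed evidence: a task generator, a
recurrent network model, a linearised-dynamics decomposition of how the
network selects the contextually relevant feature, closed-form engineering
of networks at arbitrary points of that solution space, and the behavioural
and neural kernel estimators that link the two. This vignette documents the
models, the tunable parameters, and the design choices a maintainer should
know about.

## The task

On each trial a 1.3-s train of auditory pulses is presented. Pulse times
follow a homogeneous Poisson process with a constant total rate of 40 Hz;
each pulse independently carries a side label (left/right, with per-pulse
probability `p_right`) and a frequency label (low/high, probability
`p_high`). In the LOC context the correct response is the side with more
pulses; in the FRQ context it is right if high-frequency pulses outnumber
low-frequency ones. Contexts alternate in blocks of at least 30 trials,
with a switch permitted only once running accuracy over the last 20 trials
reaches 80%.

Design choices where the protocol leaves room:

* **Generative grid.** The published stimulus set is shown graphically, not
  numerically, so `condition_grid()` defaults to 6 levels per feature
  equally spaced in log-odds between p = 0.2 and p = 0.8, symmetric about
  0.5 (36 conditions). All of this is configurable.
* **Pulse generation.** One 40-Hz Poisson process with independent
  Bernoulli labels per pulse. The alternative — four independent labelled
  processes — was rejected because the total pulse rate would then
  fluctuate with the condition, and the task holds it constant.
* **Ties.** When the relevant counts are equal the rewarded side is a fair
  coin; the tie is recorded.
* **Switch rule.** The "local estimate of performance" is a causal window
  of 20 trials; switches are also withheld when fewer than 30 trials
  remain, so every block in a generated session, including the final one,
  respects the minimum length.
* **Evidence binning.** Behavioural kernels use 26 bins of 50 ms. Per-bin
  evidence is the log-ratio of right to left (or high to low) counts with
  a pseudo-count of 1 in numerator and denominator, so empty bins
  contribute 0. Bins are half-open `[t, t + 50 ms)` with t = 0 at stimulus
  onset.

## The recurrent network

The model is a vanilla tanh network with N = 100 units,
`tau * dr/dt = -r + tanh(W r + i)`, where the input collects a constant
bias, a one-hot context input through `W_c`, and two scalar evidence
streams through input vectors `w_loc` and `w_frq`. A linear readout
`z = w_O . r + k_O` gives the choice as the sign of z at the end of the
stimulus. Integration is Euler with 10-ms steps.

Each pulse is encoded as a signed impulse with a fixed time-integrated
area of 0.01 s (momentary evidence of magnitude 1 on a 10-ms step). The
fixed-area convention makes the effect of a pulse independent of the
integration step in the quasi-linear regime, which is also the regime the
linearised analysis assumes; impulse heights much larger than 1 would
saturate the tanh nonlinearity and decouple the simulated pulse responses
from the linearised theory.

Training minimises the squared error between the readout and a target of
±1 (the sign of the contextually relevant count difference) by
backpropagation through time with Adam (b1 = 0.9, b2 = 0.999,
epsilon = 0.1). A logistic loss on the readout sign is available as an
alternative. Tie trials are dropped from training batches. Two schedule
choices deserve comment:

* **Time constants.** Following the convention of training fast and
  analysing slow, the time constant used in analyses (100 ms) is ten times
  the training default of 10 ms. Because the linearised eigenvalues scale
  as `1/tau`, a network whose slow mode is adequate for task performance
  at the training constant has a proportionally slower — hence more
  line-attractor-like — slow mode at the analysis constant. The desk-scale
  schedule used by the package's own tests trains at 30 ms, a compromise
  that keeps gradients well conditioned over the 130-step trial (training
  at 10 ms needs roughly an order of magnitude more batches to reach the
  same attractor quality) while still leaving the analysed slow mode
  within a fraction of `1/tau` of zero.
* **Loss window.** The readout target can be enforced on the final step
  only, or held over a trailing window of steps (`loss_window`).
  Penalising a short trailing window (300 ms by default in the desk-scale
  schedule used by the test suite) asks the network to *hold* its decision
  variable stably, which speeds up the formation of slow, attractor-like
  dynamics under short schedules. With long schedules both choices
  converge to similar solutions; the package exposes both.
* **Problem sizes.** The full published-style schedule (120,000 batches of
  256) is available through `train_config()`, but the package's own tests
  and examples use desk-scale schedules (thousands of batches of 64),
  which reach high accuracy and clean linearised structure on a single
  CPU in minutes. The test suite trains one shared base network and
  reuses it across analyses.

## Fixed points, linearisation and the three-component decomposition

For each context (context input clamped one-hot, evidence zero),
`find_fixed_points()` minimises the squared speed from many states sampled
off simulated trajectories, polishes candidates with Newton steps, keeps
minima with speed below `1e-8`, deduplicates within `1e-3`, and orders the
result by |z|. Analyses default to the fixed point with the smallest
absolute readout — the point closest to the decision boundary.

`linearize()` expands the dynamics in firing-rate space: the gain matrix D
is the elementwise tanh slope at the fixed point (the *saturation
factors*), the Jacobian is `(-I + D W)/tau`, the line-attractor direction
`rho` is the unit-norm right eigenvector of the slowest mode (sign fixed so
the readout projects positively), and the selection vector `s` is the
corresponding left eigenvector normalised so `s . rho = 1`. The effective
input of a pulse is the input weight vector gain-modulated elementwise,
`i = w * sat`. Firing-rate-space linearisation is load-bearing: linearising
in activation space would make the effective input identical across
contexts by construction and hide input-vector modulation entirely.

The across-context difference in a feature's pulse efficacy,
`total = s_REL . i_REL − s_IRR . i_IRR`, decomposes exactly into

* **SVM** (selection vector modulation): `Δs . ī`,
* **DIM** (direct input modulation): the part of `s̄ . Δi` carried by the
  component of `Δi` parallel to the mean attractor direction,
* **IIM** (indirect input modulation): the remaining, orthogonal part,

where Δ is the relevant-minus-irrelevant difference and the bar the
across-context mean. Two conventions pin down the split: the reference
direction is the *mean* attractor direction across contexts (renormalised;
the two are nearly parallel in well-trained networks), and DIM is computed
through the parallel component of `Δi` so that SVM + DIM + IIM equals the
total *identically* — the package enforces this conservation identity to
1e-8 relative error on every decomposition. Percentages of the total map a
network into barycentric coordinates in the SVM/DIM/IIM triangle.

If the slowest eigenvalue is complex beyond tolerance (|Im| above
`1e-6/tau`), the linearisation refuses to produce an attractor direction:
the premise of a one-dimensional slow manifold is violated, as happens in
undertrained networks whose decision dynamics are still rotational.

## Engineering networks at arbitrary mixtures

Because the three components are linear functionals of the input weight
vector (with everything else frozen), a network can be placed anywhere in
the triangle in closed form. For each component the package builds the
basis vector of that functional (elementwise products of Δs, Δsat, the
mean saturation, the mean attractor direction and the orthogonalised mean
selection vector), then finds, by Gram-Schmidt, the input vector maximally
aligned with the desired component and orthogonal to the other two *and*
to the irrelevant-context leak functional `s_IRR * sat_IRR` — so the pulse
has no net effect along the attractor in the irrelevant context. Mixtures
are linear combinations of the three pure solutions. The engineered vector
is rescaled so the relevant-context efficacy `s_REL . i_REL` matches the
base network's (`gain_match = 1`); nothing else is retrained, so the fixed
points, saturation factors and selection vectors of the base network are
preserved exactly, and the engineering for one feature leaves the other
feature's mechanism untouched.

## Kernel estimators

**Behavioural kernels.** Choice is regressed on the 26 + 26 binned
log-ratio evidence regressors plus a bias, with an L2 (ridge) penalty
selected by 5-fold cross-validated deviance over a log-spaced grid
(glmnet; the bias is never penalised). The differential kernel of a
feature is the relevant-context minus irrelevant-context weights; its
slope index is the OLS slope against bin centers.

**Neural pulse kernels.** Unit activity binned at 20 ms (bin centers from
1 s before stimulus onset to 0.7 s after its end at the defaults, 151
bins) is regressed on choice, context and time (one coefficient per bin
each) plus four signed pulse-count streams — location and frequency
evidence, separately per context — convolved with causal 33-lag kernels
(0 to 640 ms). The regression is regularised by a ridge penalty and a
squared second-difference smoothness penalty along each kernel's time/lag
axis; both strengths can be chosen by cross-validated prediction error
over trials. All units share one design matrix, so the fit is a single
sparse multi-response solve. The choice axis is the first left singular
vector of the row-centred units-by-bins choice-kernel matrix over the
stimulus window, and both correct and error trials enter the estimation
(withholding error trials is an explicit option, not the default).
Projecting the four population pulse kernels on the choice axis and
differencing contexts gives the estimated differential pulse response; the
directly measured counterpart integrates the full nonlinear network from
each context's fixed point after a single pulse and projects the
displacement on the same axis.

For network data the "units" are the N state variables; an optional
Poisson spiking layer is deliberately not applied by default, so estimator
validation isolates estimation error from spiking noise.

**Slope indices and statistics.** All slope indices are closed-form OLS
slopes. Bootstrap standard errors resample trials with replacement
(default 100 iterations). Permutation p-values are two-sided with add-one
smoothing, except the choice-axis context test, which reports the plain
fraction of null angles at least as large as the observed one.

## The linking analysis

For a population of engineered networks spanning 0-100% DIM, the package
computes, per network, the estimated neural differential pulse response
(rising slowly from zero for SVM/IIM solutions, immediate and flat for
DIM) and the differential behavioural kernel (flat for DIM, converging —
negative slope — for SVM/IIM). Theory predicts the two slope indices are
anti-correlated across networks; `link_slopes()` reports the Pearson
correlation with a permutation p-value. To keep the two measures
statistically independent, split mode computes the neural measure from
first-half pulses only and the behavioural measure from second-half pulses
only. Sweep defaults (11 mixtures, 8,000 behavioural and 2,000 neural-fit
trials per network) are sized for single-CPU desk runs; the slopes of
engineered extremes are stable well below these counts.

## What the synthetic generators do and do not emulate

The task generator reproduces the pulse statistics, context blocks and
switch rule of the behavioural protocol, and parametric agents provide
ground-truth kernels for estimator validation. It does not emulate
sensory transduction, reaction times, training curricula, session-to-session
nonstationarity, or history effects, and network "units" are noiseless
rate variables rather than spiking neurons. Passing recovery tests on
these generators therefore demonstrates correctness of the estimators
under the model's assumptions, not robustness to every property of real
recordings (spiking noise, non-Poisson firing, electrode drift).

## Numerical notes

* Fixed-point candidates come from states visited during task trials, so
  the search explores the region of state space the network actually
  uses; BFGS is polished by damped Newton steps, reaching speeds near
  machine precision.
* Eigenvector sign conventions: `rho` is flipped so `w_O . rho > 0`;
  per-context attractor directions are sign-aligned before averaging.
* The barycentric map uses vertices SVM = (0,0), IIM = (1,0),
  DIM = (1/2, sqrt(3)/2); nearest-vertex assignment is by largest
  component percentage with ties resolved toward SVM.
* Degenerate inputs: empty pulse trains give zero evidence everywhere;
  all-identical choices give a flagged degenerate psychometric fit;
  logistic separation falls back to a lightly ridge-penalised fit and is
  flagged; a non-positive decomposition total carries a warning rather
  than an error.
* Seeds: every stochastic entry point takes a `seed` argument and
  restores the caller's RNG state, so seeded pipelines are reproducible
  end-to-end and independent of call order.
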