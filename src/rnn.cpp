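// Core numerics for the tanh recurrent network: batched Euler forward
// simulation and backpropagation-through-time gradients.
//
// Dynamics: tau * dr/dt = -r + tanh(W r + i),
//   i = b + W_c c + w_loc * i_loc(t) + w_frq * i_frq(t)
// integrated with Euler steps of size dt (alpha = dt / tau):
//   r_{t+1} = (1 - alpha) r_t + alpha tanh(W r_t + i_t)
// Readout: z = w_O' r + k_O; the choice is the sign of z at the last step.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static mat context_input(const arma::mat& Wc, const arma::ivec& ctx) {
  // ctx: 0 = LOC (first column of W_c), 1 = FRQ (second column)
  mat C(Wc.n_rows, ctx.n_elem);
  for (uword k = 0; k < ctx.n_elem; ++k) C.col(k) = Wc.col(ctx(k));
  return C;
}

// Batched forward pass. i_loc / i_frq: steps x B matrices of momentary
// evidence. keep_steps: 0-based state indices (0 = initial state) at which
// to record the full state; empty -> record nothing.
// [[Rcpp::export]]
Rcpp::List cpp_rnn_forward(const arma::mat& W, const arma::mat& Wc, const arma::vec& b,
                           const arma::vec& w_loc, const arma::vec& w_frq,
                           const arma::vec& w_O, double k_O, const arma::vec& x0,
                           const arma::mat& i_loc, const arma::mat& i_frq,
                           const arma::ivec& ctx, double alpha,
                           const arma::ivec& keep_steps) {
  const uword steps = i_loc.n_rows, B = i_loc.n_cols, N = W.n_rows;
  mat R = repmat(x0, 1, B);
  mat Cin = context_input(Wc, ctx);
  Cin.each_col() += b;

  std::vector<uword> keep(keep_steps.begin(), keep_steps.end());
  cube A;
  if (!keep.empty()) A.set_size(N, B, keep.size());
  uword ki = 0;
  if (!keep.empty() && keep[0] == 0) { A.slice(0) = R; ki = 1; }

  mat zt(steps + 1, B);
  zt.row(0) = w_O.t() * R + k_O;

  for (uword t = 0; t < steps; ++t) {
    mat X = W * R + Cin;
    X += w_loc * i_loc.row(t);
    X += w_frq * i_frq.row(t);
    R = (1.0 - alpha) * R + alpha * tanh(X);
    if (!R.is_finite())
      Rcpp::stop("Non-finite network state at step %d.", (int)(t + 1));
    zt.row(t + 1) = w_O.t() * R + k_O;
    if (ki < keep.size() && keep[ki] == t + 1) { A.slice(ki) = R; ++ki; }
  }

  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("z") = zt.row(steps).t(),
    Rcpp::Named("z_t") = zt,
    Rcpp::Named("r_final") = R);
  if (!keep.empty()) out["activity"] = A;
  return out;
}

// Squared-error loss on the final readout and its gradients via BPTT.
// targets: length-B vector of +/-1.
// [[Rcpp::export]]
Rcpp::List cpp_rnn_grad(const arma::mat& W, const arma::mat& Wc, const arma::vec& b,
                        const arma::vec& w_loc, const arma::vec& w_frq,
                        const arma::vec& w_O, double k_O, const arma::vec& x0,
                        const arma::mat& i_loc, const arma::mat& i_frq,
                        const arma::ivec& ctx, double alpha, const arma::vec& targets,
                        int loss_type = 0, int loss_window = 1) {
  const uword steps = i_loc.n_rows, B = i_loc.n_cols, N = W.n_rows;
  mat Cin = context_input(Wc, ctx);
  Cin.each_col() += b;
  mat Onehot(B, 2, fill::zeros);
  for (uword k = 0; k < B; ++k) Onehot(k, ctx(k)) = 1.0;

  cube Rs(N, B, steps + 1);   // states
  cube Hs(N, B, steps);       // tanh activations
  Rs.slice(0) = repmat(x0, 1, B);
  for (uword t = 0; t < steps; ++t) {
    mat X = W * Rs.slice(t) + Cin;
    X += w_loc * i_loc.row(t);
    X += w_frq * i_frq.row(t);
    Hs.slice(t) = tanh(X);
    Rs.slice(t + 1) = (1.0 - alpha) * Rs.slice(t) + alpha * Hs.slice(t);
  }
  if (!Rs.slice(steps).is_finite()) Rcpp::stop("Non-finite state in forward pass.");

  // loss applied to the readout at the last `loss_window` states,
  // averaged; loss_window = 1 penalises only the final step
  if (loss_window < 1) loss_window = 1;
  if ((uword)loss_window > steps) loss_window = steps;
  const double wnorm = 1.0 / (double)loss_window;

  // dz at state index st (0..steps); returns the loss contribution
  mat dzs(loss_window, B);
  double loss = 0.0;
  rowvec zfin;
  for (int j = 0; j < loss_window; ++j) {
    uword st = steps - j;
    rowvec zj = w_O.t() * Rs.slice(st) + k_O;
    if (j == 0) zfin = zj;
    rowvec dzj;
    if (loss_type == 0) {      // squared error
      dzj = 2.0 * (zj - targets.t()) / (double)B * wnorm;
      loss += accu(square(zj - targets.t())) / (double)B * wnorm;
    } else {                   // logistic loss on the readout sign
      rowvec m = -targets.t() % zj;
      loss += accu(log1p(exp(m))) / (double)B * wnorm;
      dzj = (-targets.t() % (1.0 / (1.0 + exp(-m)))) / (double)B * wnorm;
    }
    dzs.row(j) = dzj;
  }
  rowvec z = zfin;

  mat G = w_O * dzs.row(0);            // dL/dr at the final state
  mat gW(N, N, fill::zeros), gWc(N, 2, fill::zeros);
  vec gb(N, fill::zeros), gwloc(N, fill::zeros), gwfrq(N, fill::zeros);
  vec gwO = Rs.slice(steps) * dzs.row(0).t();
  double gkO = accu(dzs.row(0));

  for (uword t = steps; t-- > 0;) {
    mat Hl = Hs.slice(t);
    mat Ht = alpha * (1.0 - square(Hl)) % G;   // dL/dx_t
    gW += Ht * Rs.slice(t).t();
    gb += sum(Ht, 1);
    gWc += Ht * Onehot;
    gwloc += Ht * i_loc.row(t).t();
    gwfrq += Ht * i_frq.row(t).t();
    G = (1.0 - alpha) * G + W.t() * Ht;
    long j = (long)steps - (long)t;    // state t has loss index j
    if (j < (long)loss_window) {
      G += w_O * dzs.row(j);
      gwO += Rs.slice(t) * dzs.row(j).t();
      gkO += accu(dzs.row(j));
    }
  }
  vec gx0 = sum(G, 1);

  return Rcpp::List::create(
    Rcpp::Named("loss") = loss,
    Rcpp::Named("z") = vec(z.t()),
    Rcpp::Named("gW") = gW, Rcpp::Named("gWc") = gWc,
    Rcpp::Named("gb") = gb,
    Rcpp::Named("gw_loc") = gwloc, Rcpp::Named("gw_frq") = gwfrq,
    Rcpp::Named("gw_O") = gwO, Rcpp::Named("gk_O") = gkO,
    Rcpp::Named("gx0") = gx0);
}
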