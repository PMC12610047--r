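// Batched LSTM and GRU cell loops (forward and backward-through-time).
// Activations are cubes with dimensions (batch, units, time); the gate
// conventions match the R-level documentation: LSTM blocks ordered
// input/forget/cell/output, GRU blocks reset/update/candidate with the
// reset gate applied to the recurrent term of the candidate.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// [[Rcpp::export]]
Rcpp::List lstm_cell_forward(const arma::cube& x, const arma::mat& W,
                             const arma::mat& U, const arma::vec& b) {
  const uword n = x.n_rows, t_len = x.n_slices, h = U.n_rows;
  cube I(n, h, t_len), F(n, h, t_len), G(n, h, t_len), O(n, h, t_len),
      C(n, h, t_len), TC(n, h, t_len), H(n, h, t_len);
  mat hp(n, h, fill::zeros), cp(n, h, fill::zeros);
  rowvec br = b.t();
  for (uword t = 0; t < t_len; ++t) {
    mat a = x.slice(t) * W + hp * U;
    a.each_row() += br;
    mat i = sigm(a.cols(0, h - 1));
    mat f = sigm(a.cols(h, 2 * h - 1));
    mat g = tanh(a.cols(2 * h, 3 * h - 1));
    mat o = sigm(a.cols(3 * h, 4 * h - 1));
    cp = f % cp + i % g;
    mat tc = tanh(cp);
    hp = o % tc;
    I.slice(t) = i; F.slice(t) = f; G.slice(t) = g; O.slice(t) = o;
    C.slice(t) = cp; TC.slice(t) = tc; H.slice(t) = hp;
  }
  return Rcpp::List::create(
      Rcpp::Named("H") = H, Rcpp::Named("I") = I, Rcpp::Named("F") = F,
      Rcpp::Named("G") = G, Rcpp::Named("O") = O, Rcpp::Named("C") = C,
      Rcpp::Named("TC") = TC);
}

// [[Rcpp::export]]
Rcpp::List lstm_cell_backward(const arma::cube& dh_all, const arma::cube& x,
                              const arma::mat& W, const arma::mat& U,
                              const arma::cube& I, const arma::cube& F,
                              const arma::cube& G, const arma::cube& O,
                              const arma::cube& C, const arma::cube& TC,
                              const arma::cube& H) {
  const uword n = x.n_rows, d = x.n_cols, t_len = x.n_slices, h = U.n_rows;
  cube dx(n, d, t_len);
  mat dW(d, 4 * h, fill::zeros), dU(h, 4 * h, fill::zeros);
  rowvec db(4 * h, fill::zeros);
  mat dc(n, h, fill::zeros), dh_next(n, h, fill::zeros);
  for (uword tt = t_len; tt-- > 0;) {
    mat dh = dh_all.slice(tt) + dh_next;
    const mat& i = I.slice(tt); const mat& f = F.slice(tt);
    const mat& g = G.slice(tt); const mat& o = O.slice(tt);
    const mat& tc = TC.slice(tt);
    dc += dh % o % (1.0 - tc % tc);
    mat cprev = (tt > 0) ? C.slice(tt - 1) : mat(n, h, fill::zeros);
    mat da(n, 4 * h);
    da.cols(0, h - 1) = (dc % g) % i % (1.0 - i);
    da.cols(h, 2 * h - 1) = (dc % cprev) % f % (1.0 - f);
    da.cols(2 * h, 3 * h - 1) = (dc % i) % (1.0 - g % g);
    da.cols(3 * h, 4 * h - 1) = (dh % tc) % o % (1.0 - o);
    dW += x.slice(tt).t() * da;
    mat hprev = (tt > 0) ? H.slice(tt - 1) : mat(n, h, fill::zeros);
    dU += hprev.t() * da;
    db += sum(da, 0);
    dx.slice(tt) = da * W.t();
    dh_next = da * U.t();
    dc = dc % f;
  }
  return Rcpp::List::create(
      Rcpp::Named("dx") = dx, Rcpp::Named("dW") = dW,
      Rcpp::Named("dU") = dU,
      Rcpp::Named("db") = Rcpp::wrap(conv_to<vec>::from(db)));
}

// [[Rcpp::export]]
Rcpp::List gru_cell_forward(const arma::cube& x, const arma::mat& W,
                            const arma::mat& U, const arma::vec& b) {
  const uword n = x.n_rows, t_len = x.n_slices, h = U.n_rows;
  cube R(n, h, t_len), Z(n, h, t_len), N(n, h, t_len), HUn(n, h, t_len),
      H(n, h, t_len);
  mat hp(n, h, fill::zeros);
  rowvec br = b.t();
  for (uword t = 0; t < t_len; ++t) {
    mat hu = hp * U;
    mat a = x.slice(t) * W;
    a.each_row() += br;
    mat r = sigm(a.cols(0, h - 1) + hu.cols(0, h - 1));
    mat z = sigm(a.cols(h, 2 * h - 1) + hu.cols(h, 2 * h - 1));
    mat hun = hu.cols(2 * h, 3 * h - 1);
    mat nn = tanh(a.cols(2 * h, 3 * h - 1) + r % hun);
    hp = (1.0 - z) % nn + z % hp;
    R.slice(t) = r; Z.slice(t) = z; N.slice(t) = nn; HUn.slice(t) = hun;
    H.slice(t) = hp;
  }
  return Rcpp::List::create(
      Rcpp::Named("H") = H, Rcpp::Named("R") = R, Rcpp::Named("Z") = Z,
      Rcpp::Named("N") = N, Rcpp::Named("HUn") = HUn);
}

// [[Rcpp::export]]
Rcpp::List gru_cell_backward(const arma::cube& dh_all, const arma::cube& x,
                             const arma::mat& W, const arma::mat& U,
                             const arma::cube& R, const arma::cube& Z,
                             const arma::cube& N, const arma::cube& HUn,
                             const arma::cube& H) {
  const uword n = x.n_rows, d = x.n_cols, t_len = x.n_slices, h = U.n_rows;
  cube dx(n, d, t_len);
  mat dW(d, 3 * h, fill::zeros), dU(h, 3 * h, fill::zeros);
  rowvec db(3 * h, fill::zeros);
  mat dh_next(n, h, fill::zeros);
  for (uword tt = t_len; tt-- > 0;) {
    mat dh = dh_all.slice(tt) + dh_next;
    const mat& r = R.slice(tt); const mat& z = Z.slice(tt);
    const mat& nn = N.slice(tt); const mat& hun = HUn.slice(tt);
    mat hprev = (tt > 0) ? H.slice(tt - 1) : mat(n, h, fill::zeros);
    mat dz = dh % (hprev - nn);
    mat dn = dh % (1.0 - z);
    mat dan = dn % (1.0 - nn % nn);
    mat dr = dan % hun;
    mat dar = dr % r % (1.0 - r);
    mat daz = dz % z % (1.0 - z);
    mat da(n, 3 * h);                       // pre-activation grads (x path)
    da.cols(0, h - 1) = dar;
    da.cols(h, 2 * h - 1) = daz;
    da.cols(2 * h, 3 * h - 1) = dan;
    mat dg = da;                            // recurrent-product grads
    dg.cols(2 * h, 3 * h - 1) = dan % r;
    dW += x.slice(tt).t() * da;
    dU += hprev.t() * dg;
    db += sum(da, 0);
    dx.slice(tt) = da * W.t();
    dh_next = dh % z + dg * U.t();
  }
  return Rcpp::List::create(
      Rcpp::Named("dx") = dx, Rcpp::Named("dW") = dW,
      Rcpp::Named("dU") = dU,
      Rcpp::Named("db") = Rcpp::wrap(conv_to<vec>::from(db)));
}
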