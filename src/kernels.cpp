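#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Rolling (Horner) k-mer counter. `digits` holds one base per position,
// A=0, C=1, G=2, T=3, any non-canonical base = -1. A window contributes
// only when all k of its bases are canonical; the index of the next window
// is derived from the previous one in constant time by dropping the most
// significant base-4 digit and appending the new base.
// [[Rcpp::export(name = ".kmer_count_horner")]]
NumericVector kmer_count_horner(IntegerVector digits, int k) {
  const long long l = (long long)std::pow(4.0, k);
  NumericVector counts((R_xlen_t)l);
  const long long msd = l / 4;  // 4^(k-1)
  long long idx = 0;
  int run = 0;  // length of the current run of canonical bases
  const R_xlen_t n = digits.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    const int d = digits[i];
    if (d < 0) { run = 0; idx = 0; continue; }
    idx = (idx % msd) * 4 + d;
    if (++run >= k) counts[(R_xlen_t)idx] += 1.0;
  }
  return counts;
}

static inline arma::mat sigmoid(const arma::mat& x) {
  return 1.0 / (1.0 + arma::exp(-x));
}

// GRU forward pass over a batch.
//   X: cube (batch, input_dim, T)
// Gates: z_t = sigmoid(W_z x_t + U_z h_{t-1} + b_z)
//        r_t = sigmoid(W_r x_t + U_r h_{t-1} + b_r)
//        h'_t = tanh(W_h x_t + r_t .* (U_h h_{t-1}) + b_h)
//        h_t = (1 - z_t) .* h'_t + z_t .* h_{t-1}
// Returns the hidden sequence plus the per-step caches backprop needs.
// [[Rcpp::export(name = ".gru_forward")]]
List gru_forward(const arma::cube& X,
                 const arma::mat& Wz, const arma::mat& Uz, const arma::rowvec& bz,
                 const arma::mat& Wr, const arma::mat& Ur, const arma::rowvec& br,
                 const arma::mat& Wh, const arma::mat& Uh, const arma::rowvec& bh) {
  const arma::uword B = X.n_rows, T = X.n_slices, H = Wz.n_cols;
  arma::cube Hs(B, H, T), Zs(B, H, T), Rs(B, H, T), Hc(B, H, T), UhH(B, H, T);
  arma::mat hprev(B, H, arma::fill::zeros);
  for (arma::uword t = 0; t < T; ++t) {
    const arma::mat xt = X.slice(t);
    arma::mat z = sigmoid(xt * Wz + hprev * Uz + arma::repmat(bz, B, 1));
    arma::mat r = sigmoid(xt * Wr + hprev * Ur + arma::repmat(br, B, 1));
    arma::mat uhh = hprev * Uh;
    arma::mat hc = arma::tanh(xt * Wh + r % uhh + arma::repmat(bh, B, 1));
    arma::mat h = (1.0 - z) % hc + z % hprev;
    Zs.slice(t) = z; Rs.slice(t) = r; Hc.slice(t) = hc;
    UhH.slice(t) = uhh; Hs.slice(t) = h;
    hprev = h;
  }
  return List::create(_["H"] = Hs, _["Z"] = Zs, _["R"] = Rs,
                      _["Hc"] = Hc, _["UhH"] = UhH);
}

// Backpropagation through time for the GRU above. dH is the gradient of the
// loss w.r.t. every hidden state (zero slices where the layer output is
// unused). Returns gradients for the input sequence and all parameters.
// [[Rcpp::export(name = ".gru_backward")]]
List gru_backward(const arma::cube& X, const arma::cube& Hs, const arma::cube& Zs,
                  const arma::cube& Rs, const arma::cube& Hc, const arma::cube& UhH,
                  const arma::mat& Wz, const arma::mat& Uz,
                  const arma::mat& Wr, const arma::mat& Ur,
                  const arma::mat& Wh, const arma::mat& Uh,
                  const arma::cube& dH) {
  const arma::uword B = X.n_rows, D = X.n_cols, T = X.n_slices, H = Wz.n_cols;
  arma::cube dX(B, D, T, arma::fill::zeros);
  arma::mat dWz(D, H, arma::fill::zeros), dUz(H, H, arma::fill::zeros);
  arma::mat dWr(D, H, arma::fill::zeros), dUr(H, H, arma::fill::zeros);
  arma::mat dWh(D, H, arma::fill::zeros), dUh(H, H, arma::fill::zeros);
  arma::rowvec dbz(H, arma::fill::zeros), dbr(H, arma::fill::zeros), dbh(H, arma::fill::zeros);
  arma::mat carry(B, H, arma::fill::zeros);
  for (arma::uword ti = T; ti-- > 0;) {
    const arma::mat xt = X.slice(ti);
    const arma::mat hprev = (ti == 0) ? arma::mat(B, H, arma::fill::zeros)
                                      : arma::mat(Hs.slice(ti - 1));
    const arma::mat z = Zs.slice(ti), r = Rs.slice(ti), hc = Hc.slice(ti),
                    uhh = UhH.slice(ti);
    arma::mat dh = dH.slice(ti) + carry;
    arma::mat dz = dh % (hprev - hc);
    arma::mat dhc = dh % (1.0 - z);
    arma::mat dprev = dh % z;
    arma::mat dah = dhc % (1.0 - hc % hc);
    arma::mat duhh = dah % r;
    arma::mat dr = dah % uhh;
    arma::mat daz = dz % z % (1.0 - z);
    arma::mat dar = dr % r % (1.0 - r);
    dWh += xt.t() * dah;  dbh += arma::sum(dah, 0);
    dUh += hprev.t() * duhh;  dprev += duhh * Uh.t();
    dWz += xt.t() * daz;  dbz += arma::sum(daz, 0);
    dUz += hprev.t() * daz;  dprev += daz * Uz.t();
    dWr += xt.t() * dar;  dbr += arma::sum(dar, 0);
    dUr += hprev.t() * dar;  dprev += dar * Ur.t();
    dX.slice(ti) = daz * Wz.t() + dar * Wr.t() + dah * Wh.t();
    carry = dprev;
  }
  return List::create(
    _["dX"] = dX,
    _["dWz"] = dWz, _["dUz"] = dUz, _["dbz"] = dbz,
    _["dWr"] = dWr, _["dUr"] = dUr, _["dbr"] = dbr,
    _["dWh"] = dWh, _["dUh"] = dUh, _["dbh"] = dbh);
}
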