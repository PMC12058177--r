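// Multi-head scaled-dot-product self-attention kernels. One call handles a
// whole padded batch: state matrices are (B*L) x hidden with element (b,l)
// at row b + B*l (0-based), matching the R-side layout. PAD positions are
// excluded by construction because each sequence only contributes its first
// lens[b] rows. Attention probabilities are returned in a flat buffer
// (per sequence, per head, column-major L x L blocks) for the backward pass.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static uvec seq_rows(int b, int L, int B) {
  uvec r(L);
  for (int l = 0; l < L; ++l) r[l] = (uword)b + (uword)B * l;
  return r;
}

// [[Rcpp::export]]
Rcpp::List attn_forward_cpp(const arma::mat& Q, const arma::mat& K, const arma::mat& V,
                            const arma::ivec& lens, int nh) {
  const int B = lens.n_elem;
  const int h = Q.n_cols;
  const int dh = h / nh;
  const double scale = 1.0 / std::sqrt((double)dh);
  mat O(Q.n_rows, h, fill::zeros);
  uword tot = 0;
  for (int b = 0; b < B; ++b) tot += (uword)nh * lens[b] * lens[b];
  vec att(tot);
  uword off = 0;
  for (int b = 0; b < B; ++b) {
    const int L = lens[b];
    uvec r = seq_rows(b, L, B);
    for (int k = 0; k < nh; ++k) {
      uvec cols = regspace<uvec>((uword)k * dh, (uword)(k + 1) * dh - 1);
      mat Qb = Q.submat(r, cols);
      mat Kb = K.submat(r, cols);
      mat S = Qb * Kb.t() * scale;
      vec mx = max(S, 1);
      S.each_col() -= mx;
      S = exp(S);
      vec rs = sum(S, 1);
      S.each_col() /= rs;
      O.submat(r, cols) = S * V.submat(r, cols);
      std::memcpy(att.memptr() + off, S.memptr(), sizeof(double) * (uword)L * L);
      off += (uword)L * L;
    }
  }
  return Rcpp::List::create(Rcpp::_["O"] = O, Rcpp::_["att"] = att);
}

// [[Rcpp::export]]
Rcpp::List attn_backward_cpp(const arma::mat& Q, const arma::mat& K, const arma::mat& V,
                             const arma::vec& att, const arma::mat& dO,
                             const arma::ivec& lens, int nh) {
  const int B = lens.n_elem;
  const int h = Q.n_cols;
  const int dh = h / nh;
  const double scale = 1.0 / std::sqrt((double)dh);
  mat dQ(Q.n_rows, h, fill::zeros), dK(Q.n_rows, h, fill::zeros), dV(Q.n_rows, h, fill::zeros);
  uword off = 0;
  for (int b = 0; b < B; ++b) {
    const int L = lens[b];
    uvec r = seq_rows(b, L, B);
    for (int k = 0; k < nh; ++k) {
      uvec cols = regspace<uvec>((uword)k * dh, (uword)(k + 1) * dh - 1);
      mat S(const_cast<double*>(att.memptr()) + off, L, L, false, true);
      off += (uword)L * L;
      mat dOb = dO.submat(r, cols);
      mat Vb = V.submat(r, cols);
      mat dA = dOb * Vb.t();
      dV.submat(r, cols) = S.t() * dOb;
      vec rowdot = sum(dA % S, 1);
      dA.each_col() -= rowdot;       // dA - rowSums(dA*S)
      mat dS = (S % dA) * scale;     // softmax backward + 1/sqrt(dh)
      dQ.submat(r, cols) = dS * K.submat(r, cols);
      dK.submat(r, cols) = dS.t() * Q.submat(r, cols);
    }
  }
  return Rcpp::List::create(Rcpp::_["dQ"] = dQ, Rcpp::_["dK"] = dK, Rcpp::_["dV"] = dV);
}
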