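// Batched scaled-dot-product attention, forward and backward.
//
// Activations for a batch are held as cubes of dimension (T, C, B): slice b
// is the T x C matrix of sample b.  For multi-head attention the C columns
// are split into h contiguous blocks of width C/h; single-head axial
// attention passes h = 1.
//
// Internally the score matrix is kept transposed (column q holds the
// scores of query q against all keys) so that the softmax reductions run
// down contiguous columns.  The cached attention cube A stores these
// transposed maps: A(k, q, slice) is the weight of key k for query q of
// sample-head slice b*h + hd.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export(name = ".attn_forward")]]
List attn_forward_cpp(const arma::cube& Q, const arma::cube& K,
                      const arma::cube& V, int h, double scale) {
  const arma::uword T = Q.n_rows, C = Q.n_cols, B = Q.n_slices;
  if (C % h != 0) stop("attention: feature width not divisible by head count");
  const arma::uword dk = C / h;
  arma::cube O(T, C, B, arma::fill::none);
  arma::cube A(T, T, B * h, arma::fill::none);
  for (arma::uword b = 0; b < B; ++b) {
    for (int hd = 0; hd < h; ++hd) {
      const arma::uword c0 = hd * dk, c1 = (hd + 1) * dk - 1;
      arma::mat& St = A.slice(b * h + hd);
      // St(k, q) = <key_k, query_q> * scale
      St = K.slice(b).cols(c0, c1) * Q.slice(b).cols(c0, c1).t() * scale;
      arma::rowvec mx = arma::max(St, 0);
      St.each_row() -= mx;
      St = arma::exp(St);
      arma::rowvec cs = arma::sum(St, 0);
      St.each_row() /= cs;
      O.slice(b).cols(c0, c1) = St.t() * V.slice(b).cols(c0, c1);
    }
  }
  return List::create(Named("O") = O, Named("A") = A);
}

// Flat-layout variants: activations as (B*T) x C matrices whose rows are
// sample-major (rows b*T .. (b+1)*T - 1 belong to sample b), avoiding the
// cube reshuffle on the R side.

// [[Rcpp::export(name = ".attn_forward_flat")]]
List attn_forward_flat_cpp(const arma::mat& Q, const arma::mat& K,
                           const arma::mat& V, int T, int h, double scale) {
  const arma::uword C = Q.n_cols, B = Q.n_rows / T;
  if (C % h != 0) stop("attention: feature width not divisible by head count");
  const arma::uword dk = C / h;
  arma::mat O(Q.n_rows, C, arma::fill::none);
  arma::cube A(T, T, B * h, arma::fill::none);
  for (arma::uword b = 0; b < B; ++b) {
    const arma::uword r0 = b * T, r1 = (b + 1) * T - 1;
    for (int hd = 0; hd < h; ++hd) {
      const arma::uword c0 = hd * dk, c1 = (hd + 1) * dk - 1;
      arma::mat Qb = Q.submat(r0, c0, r1, c1);
      arma::mat Kb = K.submat(r0, c0, r1, c1);
      arma::mat& St = A.slice(b * h + hd);
      St = Kb * Qb.t() * scale;
      arma::rowvec mx = arma::max(St, 0);
      St.each_row() -= mx;
      St = arma::exp(St);
      arma::rowvec cs = arma::sum(St, 0);
      St.each_row() /= cs;
      O.submat(r0, c0, r1, c1) = St.t() * V.submat(r0, c0, r1, c1);
    }
  }
  return List::create(Named("O") = O, Named("A") = A);
}

// [[Rcpp::export(name = ".attn_backward_flat")]]
List attn_backward_flat_cpp(const arma::mat& dO, const arma::mat& Q,
                            const arma::mat& K, const arma::mat& V,
                            const arma::cube& A, int T, int h, double scale) {
  const arma::uword C = Q.n_cols, B = Q.n_rows / T;
  const arma::uword dk = C / h;
  arma::mat dQ(Q.n_rows, C, arma::fill::none);
  arma::mat dK(Q.n_rows, C, arma::fill::none);
  arma::mat dV(Q.n_rows, C, arma::fill::none);
  arma::mat dAt(T, T);
  for (arma::uword b = 0; b < B; ++b) {
    const arma::uword r0 = b * T, r1 = (b + 1) * T - 1;
    for (int hd = 0; hd < h; ++hd) {
      const arma::uword c0 = hd * dk, c1 = (hd + 1) * dk - 1;
      const arma::mat& At = A.slice(b * h + hd);
      arma::mat dOb = dO.submat(r0, c0, r1, c1);
      dAt = V.submat(r0, c0, r1, c1) * dOb.t();
      arma::rowvec cs = arma::sum(dAt % At, 0);
      dAt.each_row() -= cs;
      dAt %= At;
      dQ.submat(r0, c0, r1, c1) = dAt.t() * K.submat(r0, c0, r1, c1) * scale;
      dK.submat(r0, c0, r1, c1) = dAt * Q.submat(r0, c0, r1, c1) * scale;
      dV.submat(r0, c0, r1, c1) = At * dOb;
    }
  }
  return List::create(Named("dQ") = dQ, Named("dK") = dK, Named("dV") = dV);
}

// [[Rcpp::export(name = ".attn_backward")]]
List attn_backward_cpp(const arma::cube& dO, const arma::cube& Q,
                       const arma::cube& K, const arma::cube& V,
                       const arma::cube& A, int h, double scale) {
  const arma::uword T = Q.n_rows, C = Q.n_cols, B = Q.n_slices;
  const arma::uword dk = C / h;
  arma::cube dQ(T, C, B, arma::fill::none);
  arma::cube dK(T, C, B, arma::fill::none);
  arma::cube dV(T, C, B, arma::fill::none);
  arma::mat dAt(T, T);
  for (arma::uword b = 0; b < B; ++b) {
    for (int hd = 0; hd < h; ++hd) {
      const arma::uword c0 = hd * dk, c1 = (hd + 1) * dk - 1;
      const arma::mat& At = A.slice(b * h + hd);
      arma::mat dOb = dO.slice(b).cols(c0, c1);
      dAt = V.slice(b).cols(c0, c1) * dOb.t();
      // softmax backward down each (contiguous) query column
      arma::rowvec cs = arma::sum(dAt % At, 0);
      dAt.each_row() -= cs;
      dAt %= At;
      dQ.slice(b).cols(c0, c1) = dAt.t() * K.slice(b).cols(c0, c1) * scale;
      dK.slice(b).cols(c0, c1) = dAt * Q.slice(b).cols(c0, c1) * scale;
      dV.slice(b).cols(c0, c1) = At * dOb;
    }
  }
  return List::create(Named("dQ") = dQ, Named("dK") = dK, Named("dV") = dV);
}
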