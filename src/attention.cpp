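// Multi-head self-attention forward/backward.  Tokens arrive as a
// (B*T) x 3D matrix of stacked Q|K|V projections, sample-major; the
// per-(sample, head) softmax(Q K^T / sqrt(dh)) V products are the only
// part of the encoder that does not reduce to one large BLAS call, so
// they live here.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static void softmax_rows_inplace(mat &s) {
  vec m = max(s, 1);
  s.each_col() -= m;
  s = exp(s);
  s.each_col() /= sum(s, 1);
}

// [[Rcpp::export]]
Rcpp::List attn_fwd_cpp(const arma::mat &qkv, int B, int T, int H) {
  const int D = qkv.n_cols / 3;
  const int dh = D / H;
  const double sc = 1.0 / std::sqrt((double)dh);
  mat O(qkv.n_rows, D, fill::zeros);
  cube A(T, T, (uword)H * B);
  for (int b = 0; b < B; ++b) {
    const uword r0 = (uword)b * T, r1 = r0 + T - 1;
    for (int h = 0; h < H; ++h) {
      const uword c0 = (uword)h * dh, c1 = c0 + dh - 1;
      mat Q = qkv.submat(r0, c0, r1, c1);
      mat K = qkv.submat(r0, D + c0, r1, D + c1);
      mat V = qkv.submat(r0, 2 * D + c0, r1, 2 * D + c1);
      mat S = Q * K.t() * sc;
      softmax_rows_inplace(S);
      O.submat(r0, c0, r1, c1) = S * V;
      A.slice((uword)b * H + h) = S;
    }
  }
  return Rcpp::List::create(Rcpp::Named("O") = O, Rcpp::Named("A") = A);
}

// [[Rcpp::export]]
arma::mat attn_bwd_cpp(const arma::mat &dO, const arma::mat &qkv,
                       const arma::cube &A, int B, int T, int H) {
  const int D = qkv.n_cols / 3;
  const int dh = D / H;
  const double sc = 1.0 / std::sqrt((double)dh);
  mat dqkv(qkv.n_rows, qkv.n_cols, fill::zeros);
  for (int b = 0; b < B; ++b) {
    const uword r0 = (uword)b * T, r1 = r0 + T - 1;
    for (int h = 0; h < H; ++h) {
      const uword c0 = (uword)h * dh, c1 = c0 + dh - 1;
      mat Q = qkv.submat(r0, c0, r1, c1);
      mat K = qkv.submat(r0, D + c0, r1, D + c1);
      mat V = qkv.submat(r0, 2 * D + c0, r1, 2 * D + c1);
      const mat &Ah = A.slice((uword)b * H + h);
      mat dOh = dO.submat(r0, c0, r1, c1);
      mat dA = dOh * V.t();
      vec r = sum(dA % Ah, 1);
      dA.each_col() -= r;
      mat dS = Ah % dA;
      dqkv.submat(r0, c0, r1, c1) = dS * K * sc;
      dqkv.submat(r0, D + c0, r1, D + c1) = dS.t() * Q * sc;
      dqkv.submat(r0, 2 * D + c0, r1, 2 * D + c1) = Ah.t() * dOh;
    }
  }
  return dqkv;
}
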