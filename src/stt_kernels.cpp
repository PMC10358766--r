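// Compiled kernels for the encoder hot path: row-wise layer normalization,
// exact (Gaussian-CDF) GELU, row softmax, and per-group multi-head scaled
// dot-product attention. Each mirrors the reference R implementation in
// R/nn.R one for one; the test suite cross-checks the two.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double LN_EPS = 1e-5;

// softmax over the rows of s, in place
static void softmax_rows_inplace(mat &s) {
  vec m = max(s, 1);
  s.each_col() -= m;
  s = exp(s);
  s.each_col() /= sum(s, 1);
}

// [[Rcpp::export(name = "cpp_layernorm_fwd")]]
Rcpp::List cpp_layernorm_fwd(const arma::mat &x, const arma::rowvec &g, const arma::rowvec &b) {
  vec mu = mean(x, 1);
  mat xc = x.each_col() - mu;
  vec invstd = 1.0 / sqrt(mean(square(xc), 1) + LN_EPS);
  mat xhat = xc.each_col() % invstd;
  mat y = xhat.each_row() % g;
  y.each_row() += b;
  return Rcpp::List::create(Rcpp::Named("y") = y,
                            Rcpp::Named("xhat") = xhat,
                            Rcpp::Named("invstd") = invstd);
}

// [[Rcpp::export(name = "cpp_layernorm_bwd")]]
Rcpp::List cpp_layernorm_bwd(const arma::mat &xhat, const arma::vec &invstd,
                             const arma::rowvec &g, const arma::mat &dy) {
  mat dxhat = dy.each_row() % g;
  vec m1 = mean(dxhat, 1);
  vec m2 = mean(dxhat % xhat, 1);
  mat dx = dxhat;
  dx.each_col() -= m1;
  dx -= xhat.each_col() % m2;
  dx.each_col() %= invstd;
  rowvec dg = sum(dy % xhat, 0);
  rowvec db = sum(dy, 0);
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dg") = dg,
                            Rcpp::Named("db") = db);
}

// [[Rcpp::export(name = "cpp_gelu_fwd")]]
Rcpp::List cpp_gelu_fwd(const arma::mat &x) {
  mat phi = normcdf(x);
  return Rcpp::List::create(Rcpp::Named("y") = x % phi,
                            Rcpp::Named("phi") = phi);
}

// [[Rcpp::export(name = "cpp_gelu_bwd")]]
arma::mat cpp_gelu_bwd(const arma::mat &x, const arma::mat &phi, const arma::mat &dy) {
  const double inv_sqrt2pi = 0.3989422804014327;
  mat pdf = inv_sqrt2pi * exp(-0.5 * square(x));
  return dy % (phi + x % pdf);
}

// [[Rcpp::export(name = "cpp_softmax_rows")]]
arma::mat cpp_softmax_rows(arma::mat s) {
  softmax_rows_inplace(s);
  return s;
}

// [[Rcpp::export(name = "cpp_attention_fwd")]]
Rcpp::List cpp_attention_fwd(const arma::mat &q, const arma::mat &k, const arma::mat &v,
                             const int B, const int T, const int n_heads) {
  const int D = q.n_cols;
  const int dh = D / n_heads;
  const double scale = 1.0 / std::sqrt((double) dh);
  mat out(q.n_rows, D, fill::zeros);
  cube A(T, T, (size_t) B * n_heads);
  for (int h = 0; h < n_heads; ++h) {
    const uword c0 = h * dh, c1 = (h + 1) * dh - 1;
    for (int b = 0; b < B; ++b) {
      const uword r0 = (uword) b * T, r1 = r0 + T - 1;
      mat s = scale * (q.submat(r0, c0, r1, c1) *
                       k.submat(r0, c0, r1, c1).t());
      softmax_rows_inplace(s);
      A.slice((size_t) b * n_heads + h) = s;
      out.submat(r0, c0, r1, c1) = s * v.submat(r0, c0, r1, c1);
    }
  }
  return Rcpp::List::create(Rcpp::Named("out") = out,
                            Rcpp::Named("A") = A);
}

// [[Rcpp::export(name = "cpp_attention_bwd")]]
Rcpp::List cpp_attention_bwd(const arma::cube &A, const arma::mat &q, const arma::mat &k,
                             const arma::mat &v, const arma::mat &dout, const int B,
                             const int T, const int n_heads) {
  const int D = q.n_cols;
  const int dh = D / n_heads;
  const double scale = 1.0 / std::sqrt((double) dh);
  mat dq(q.n_rows, D, fill::zeros), dk(q.n_rows, D, fill::zeros),
      dv(q.n_rows, D, fill::zeros);
  for (int h = 0; h < n_heads; ++h) {
    const uword c0 = h * dh, c1 = (h + 1) * dh - 1;
    for (int b = 0; b < B; ++b) {
      const uword r0 = (uword) b * T, r1 = r0 + T - 1;
      const mat &a = A.slice((size_t) b * n_heads + h);
      mat doh = dout.submat(r0, c0, r1, c1);
      mat da = doh * v.submat(r0, c0, r1, c1).t();
      dv.submat(r0, c0, r1, c1) = a.t() * doh;
      vec rs = sum(da % a, 1);                // softmax Jacobian, row-wise
      da.each_col() -= rs;
      mat ds = a % da;
      dq.submat(r0, c0, r1, c1) = scale * (ds * k.submat(r0, c0, r1, c1));
      dk.submat(r0, c0, r1, c1) = scale * (ds.t() * q.submat(r0, c0, r1, c1));
    }
  }
  return Rcpp::List::create(Rcpp::Named("dq") = dq,
                            Rcpp::Named("dk") = dk,
                            Rcpp::Named("dv") = dv);
}
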