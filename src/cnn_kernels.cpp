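// Fast path for the 3D-CNN forward/backward passes.
//
// Tensors use the (channel, x, y, z, batch) layout, column-major, matching
// the R reference implementation; convolution weights arrive as
// (Cin * k^3, Cout) matrices whose row order is channel-within-offset with
// offsets enumerated dx fastest (the conv_wmat() layout).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Dims3 {
  int a, b, c;
  int vox() const { return a * b * c; }
};

inline void elu_inplace(mat &m) {
  for (uword i = 0; i < m.n_elem; ++i) {
    if (m[i] < 0) m[i] = std::exp(m[i]) - 1.0;
  }
}

// derivative of ELU expressed through the activation value
inline mat elu_grad(const mat &a) {
  mat g(a.n_rows, a.n_cols);
  for (uword i = 0; i < a.n_elem; ++i) g[i] = a[i] > 0 ? 1.0 : a[i] + 1.0;
  return g;
}

// average pooling (size = stride = pool) of (C, in, B) into (C, out, B)
vec avgpool(const double *x, int C, Dims3 in, Dims3 out, int pool, int B) {
  vec res(static_cast<uword>(C) * out.vox() * B, fill::zeros);
  double inv = 1.0 / (pool * pool * pool);
  for (int b = 0; b < B; ++b) {
    for (int oz = 0; oz < out.c; ++oz)
      for (int oy = 0; oy < out.b; ++oy)
        for (int ox = 0; ox < out.a; ++ox) {
          size_t dst = (((static_cast<size_t>(b) * out.c + oz) * out.b + oy) *
                            out.a + ox) * C;
          for (int dz = 0; dz < pool; ++dz)
            for (int dy = 0; dy < pool; ++dy)
              for (int dx = 0; dx < pool; ++dx) {
                size_t src = (((static_cast<size_t>(b) * in.c +
                                (oz * pool + dz)) * in.b +
                               (oy * pool + dy)) * in.a +
                              (ox * pool + dx)) * C;
                for (int c = 0; c < C; ++c) res[dst + c] += x[src + c];
              }
          for (int c = 0; c < C; ++c) res[dst + c] *= inv;
        }
  }
  return res;
}

// im2col: (C * k^3, out.vox() * B) from an input of dims (C, in, B)
mat im2col(const double *x, int C, Dims3 in, Dims3 out, int k, int B) {
  int k3 = k * k * k;
  mat cols(static_cast<uword>(C) * k3, static_cast<uword>(out.vox()) * B);
  for (int b = 0; b < B; ++b) {
    for (int oz = 0; oz < out.c; ++oz)
      for (int oy = 0; oy < out.b; ++oy)
        for (int ox = 0; ox < out.a; ++ox) {
          uword col = ((static_cast<uword>(b) * out.c + oz) * out.b + oy) *
                          out.a + ox;
          double *dst = cols.colptr(col);
          int o = 0;
          for (int dz = 0; dz < k; ++dz)
            for (int dy = 0; dy < k; ++dy)
              for (int dx = 0; dx < k; ++dx, ++o) {
                size_t src = (((static_cast<size_t>(b) * in.c + (oz + dz)) *
                                   in.b + (oy + dy)) * in.a + (ox + dx)) * C;
                std::memcpy(dst + static_cast<size_t>(o) * C, x + src,
                            C * sizeof(double));
              }
        }
  }
  return cols;
}

// col2im: scatter-add the transpose of im2col
void col2im_add(const mat &dcols, double *dxp, int C, Dims3 in, Dims3 out,
                int k, int B) {
  for (int b = 0; b < B; ++b) {
    for (int oz = 0; oz < out.c; ++oz)
      for (int oy = 0; oy < out.b; ++oy)
        for (int ox = 0; ox < out.a; ++ox) {
          uword col = ((static_cast<uword>(b) * out.c + oz) * out.b + oy) *
                          out.a + ox;
          const double *src = dcols.colptr(col);
          int o = 0;
          for (int dz = 0; dz < k; ++dz)
            for (int dy = 0; dy < k; ++dy)
              for (int dx = 0; dx < k; ++dx, ++o) {
                size_t dst = (((static_cast<size_t>(b) * in.c + (oz + dz)) *
                                   in.b + (oy + dy)) * in.a + (ox + dx)) * C;
                const double *s = src + static_cast<size_t>(o) * C;
                for (int c = 0; c < C; ++c) dxp[dst + c] += s[c];
              }
        }
  }
}

struct Forward {
  vec p1;
  mat cols1, a1, cols2, a2;
  vec mp;
  uvec argi;
  mat fmat, h;
  rowvec z, p;
};

Forward run_forward(const double *x, int C, Dims3 d0, int B,
                    const mat &Wm1, const vec &b1, const mat &Wm2,
                    const vec &b2, const mat &Wf1, const vec &bf1,
                    const vec &Wf2, double bf2, int k, int pool,
                    bool keep) {
  Forward f;
  Dims3 d1{d0.a / pool, d0.b / pool, d0.c / pool};
  Dims3 d2{d1.a - k + 1, d1.b - k + 1, d1.c - k + 1};
  Dims3 d3{d2.a - k + 1, d2.b - k + 1, d2.c - k + 1};
  Dims3 d4{d3.a / pool, d3.b / pool, d3.c / pool};
  int C1 = Wm1.n_cols, C2 = Wm2.n_cols;

  f.p1 = avgpool(x, C, d0, d1, pool, B);
  f.cols1 = im2col(f.p1.memptr(), C, d1, d2, k, B);
  f.a1 = Wm1.t() * f.cols1;
  f.a1.each_col() += b1;
  elu_inplace(f.a1);
  if (!keep) f.cols1.reset();

  f.cols2 = im2col(f.a1.memptr(), C1, d2, d3, k, B);
  f.a2 = Wm2.t() * f.cols2;
  f.a2.each_col() += b2;
  elu_inplace(f.a2);
  if (!keep) f.cols2.reset();

  // max pooling with argmax bookkeeping (indices into a2's memory)
  uword nmp = static_cast<uword>(C2) * d4.vox() * B;
  f.mp.set_size(nmp);
  f.argi.set_size(nmp);
  const double *a2p = f.a2.memptr();
  for (int b = 0; b < B; ++b) {
    for (int oz = 0; oz < d4.c; ++oz)
      for (int oy = 0; oy < d4.b; ++oy)
        for (int ox = 0; ox < d4.a; ++ox) {
          size_t dst = (((static_cast<size_t>(b) * d4.c + oz) * d4.b + oy) *
                            d4.a + ox) * C2;
          for (int c = 0; c < C2; ++c) {
            double best = -datum::inf;
            size_t besti = 0;
            for (int dz = 0; dz < pool; ++dz)
              for (int dy = 0; dy < pool; ++dy)
                for (int dx = 0; dx < pool; ++dx) {
                  size_t src = (((static_cast<size_t>(b) * d3.c +
                                  (oz * pool + dz)) * d3.b +
                                 (oy * pool + dy)) * d3.a +
                                (ox * pool + dx)) * C2 + c;
                  if (a2p[src] > best) { best = a2p[src]; besti = src; }
                }
            f.mp[dst + c] = best;
            f.argi[dst + c] = besti;
          }
        }
  }

  int F = C2 * d4.vox();
  f.fmat = mat(f.mp.memptr(), F, B);  // copies, fine
  f.h = Wf1.t() * f.fmat;
  f.h.each_col() += bf1;
  elu_inplace(f.h);
  f.z = Wf2.t() * f.h + bf2;
  f.p = 1.0 / (1.0 + exp(-f.z));
  return f;
}

} // namespace

// Forward pass only: returns the sigmoid scores
// [[Rcpp::export]]
arma::rowvec cnn_fwd_cpp(const arma::vec &x, const Rcpp::IntegerVector &xdim,
                         const arma::mat &Wm1, const arma::vec &b1,
                         const arma::mat &Wm2, const arma::vec &b2,
                         const arma::mat &Wf1, const arma::vec &bf1,
                         const arma::vec &Wf2, double bf2, int k, int pool) {
  int C = xdim[0], B = xdim[4];
  Dims3 d0{xdim[1], xdim[2], xdim[3]};
  Forward f = run_forward(x.memptr(), C, d0, B, Wm1, b1, Wm2, b2, Wf1, bf1,
                          Wf2, bf2, k, pool, false);
  return f.p;
}

// Forward plus gradients of the mean binary cross-entropy
// [[Rcpp::export]]
Rcpp::List cnn_fwdbwd_cpp(const arma::vec &x, const Rcpp::IntegerVector &xdim,
                          const arma::mat &Wm1, const arma::vec &b1,
                          const arma::mat &Wm2, const arma::vec &b2,
                          const arma::mat &Wf1, const arma::vec &bf1,
                          const arma::vec &Wf2, double bf2, int k, int pool,
                          const arma::rowvec &y) {
  int C = xdim[0], B = xdim[4];
  Dims3 d0{xdim[1], xdim[2], xdim[3]};
  Dims3 d1{d0.a / pool, d0.b / pool, d0.c / pool};
  Dims3 d2{d1.a - k + 1, d1.b - k + 1, d1.c - k + 1};
  Dims3 d3{d2.a - k + 1, d2.b - k + 1, d2.c - k + 1};
  int C1 = Wm1.n_cols, C2 = Wm2.n_cols;

  Forward f = run_forward(x.memptr(), C, d0, B, Wm1, b1, Wm2, b2, Wf1, bf1,
                          Wf2, bf2, k, pool, true);

  rowvec dz = (f.p - y) / B;
  vec dWf2 = f.h * dz.t();
  double dbf2 = accu(dz);
  mat dh = (Wf2 * dz) % elu_grad(f.h);
  mat dWf1 = f.fmat * dh.t();
  vec dbf1 = sum(dh, 1);
  mat df = Wf1 * dh;                     // F x B

  // max-pool backward through the stored argmax indices
  mat da2(C2, f.a2.n_cols, fill::zeros);
  double *da2p = da2.memptr();
  const double *dfp = df.memptr();
  for (uword i = 0; i < f.argi.n_elem; ++i) da2p[f.argi[i]] += dfp[i];

  mat dz2 = da2 % elu_grad(f.a2);
  mat dWm2 = f.cols2 * dz2.t();
  vec db2 = sum(dz2, 1);
  mat dcols2 = Wm2 * dz2;

  mat da1(C1, f.a1.n_cols, fill::zeros);
  col2im_add(dcols2, da1.memptr(), C1, d2, d3, k, B);
  mat dz1 = da1 % elu_grad(f.a1);
  mat dWm1 = f.cols1 * dz1.t();
  vec db1 = sum(dz1, 1);

  double eps = 1e-12, loss = 0;
  for (uword i = 0; i < f.p.n_elem; ++i) {
    double pi = std::min(std::max(static_cast<double>(f.p[i]), eps), 1 - eps);
    loss += -(y[i] * std::log(pi) + (1 - y[i]) * std::log(1 - pi));
  }
  loss /= B;

  return Rcpp::List::create(
      Rcpp::Named("p") = f.p, Rcpp::Named("loss") = loss,
      Rcpp::Named("dWm1") = dWm1, Rcpp::Named("db1") = db1,
      Rcpp::Named("dWm2") = dWm2, Rcpp::Named("db2") = db2,
      Rcpp::Named("dWf1") = dWf1, Rcpp::Named("dbf1") = dbf1,
      Rcpp::Named("dWf2") = dWf2, Rcpp::Named("dbf2") = dbf2);
}
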