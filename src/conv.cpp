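// Batched 3x3 "same" convolution primitives for the registration network.
// Activations are H x W x N x C arrays (column-major; N = batch of frames),
// weights are (9*cin) x cout with im2col columns ordered offset-major
// (dc slowest, then dr, then input channel), offsets in {-1, 0, 1}.
// im2col matrices are built in grow-only workspace buffers so the training
// loop performs no large allocations per step.

#include <RcppArmadillo.h>
#ifdef __GLIBC__
#include <malloc.h>
#endif
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// keep large transient blocks on the heap instead of mmap-ing them anew on
// every step (glibc only; a measurable win for the per-iteration GEMMs)
static const int malloc_tuned = [] {
#ifdef __GLIBC__
  mallopt(M_MMAP_THRESHOLD, 256 * 1024 * 1024);
  mallopt(M_TRIM_THRESHOLD, 256 * 1024 * 1024);
#endif
  return 0;
}();

static std::vector<double>& ws(int which) {
  static std::vector<double> buf[2];
  return buf[which];
}

static void get_dims4(const Rcpp::NumericVector& x, int* d) {
  Rcpp::IntegerVector dim = x.attr("dim");
  if (dim.size() != 4) Rcpp::stop("expected a 4-dimensional array");
  for (int i = 0; i < 4; ++i) d[i] = dim[i];
}

// im2col over the batch into a workspace-backed matrix:
// rows ordered (i, j, n), columns (dc, dr, ch)
static mat im2col3b(const double* x, int h, int w, int n, int cin) {
  const uword hw = static_cast<uword>(h) * w;
  const uword hwn = hw * n;
  std::vector<double>& buf = ws(0);
  if (buf.size() < hwn * 9 * cin) buf.resize(hwn * 9 * cin);
  mat out(buf.data(), hwn, 9 * static_cast<uword>(cin), false, true);
  uword col = 0;
  for (int dc = -1; dc <= 1; ++dc)
    for (int dr = -1; dr <= 1; ++dr)
      for (int ch = 0; ch < cin; ++ch, ++col) {
        double* o = out.colptr(col);
        const double* xc = x + static_cast<uword>(ch) * hwn;
        const int i0 = std::max(0, -dr), i1 = std::min(h, h - dr);
        for (int b = 0; b < n; ++b) {
          const double* xb = xc + static_cast<uword>(b) * hw;
          double* ob = o + static_cast<uword>(b) * hw;
          for (int j = 0; j < w; ++j) {
            double* oc = ob + static_cast<uword>(j) * h;
            const int js = j + dc;
            if (js < 0 || js >= w) { std::fill(oc, oc + h, 0.0); continue; }
            const double* s = xb + static_cast<uword>(js) * h;
            if (i0 > 0) std::fill(oc, oc + i0, 0.0);
            if (i1 > i0) std::copy(s + i0 + dr, s + i1 + dr, oc + i0);
            if (i1 < h) std::fill(oc + std::max(i1, i0), oc + h, 0.0);
          }
        }
      }
  return out;
}

// [[Rcpp::export(name = ".conv3_fwd_cpp")]]
Rcpp::NumericVector conv3_fwd_cpp(const Rcpp::NumericVector& x,
                                  const arma::mat& W, const arma::vec& b) {
  int d[4];
  get_dims4(x, d);
  mat xc = im2col3b(x.begin(), d[0], d[1], d[2], d[3]);
  Rcpp::NumericVector out(xc.n_rows * W.n_cols);
  mat y(out.begin(), xc.n_rows, W.n_cols, false, true);
  y = xc * W;
  y.each_row() += b.t();
  out.attr("dim") = Rcpp::IntegerVector::create(
      d[0], d[1], d[2], static_cast<int>(W.n_cols));
  return out;
}

// [[Rcpp::export(name = ".conv3_bwd_cpp")]]
Rcpp::List conv3_bwd_cpp(const Rcpp::NumericVector& x, const arma::mat& W,
                         const Rcpp::NumericVector& dout) {
  int d[4], dd[4];
  get_dims4(x, d);
  get_dims4(dout, dd);
  const int h = d[0], w = d[1], n = d[2], cin = d[3];
  const uword hw = static_cast<uword>(h) * w;
  const uword hwn = hw * n;
  const mat do_m(const_cast<double*>(dout.begin()), hwn, dd[3], false, true);
  mat xc = im2col3b(x.begin(), h, w, n, cin);
  mat dW = xc.t() * do_m;
  vec db = sum(do_m, 0).t();
  std::vector<double>& buf = ws(1);
  if (buf.size() < hwn * 9 * cin) buf.resize(hwn * 9 * cin);
  mat dxc(buf.data(), hwn, 9 * static_cast<uword>(cin), false, true);
  dxc = do_m * W.t();
  Rcpp::NumericVector dx(hwn * static_cast<uword>(cin));
  dx.attr("dim") = Rcpp::IntegerVector::create(h, w, n, cin);
  double* dxp = dx.begin();
  uword col = 0;
  for (int dc = -1; dc <= 1; ++dc)
    for (int dr = -1; dr <= 1; ++dr)
      for (int ch = 0; ch < cin; ++ch, ++col) {
        const double* g = dxc.colptr(col);
        double* xch = dxp + static_cast<uword>(ch) * hwn;
        const int i0 = std::max(0, -dr), i1 = std::min(h, h - dr);
        for (int b = 0; b < n; ++b) {
          double* xb = xch + static_cast<uword>(b) * hw;
          const double* gb = g + static_cast<uword>(b) * hw;
          for (int j = 0; j < w; ++j) {
            const int js = j + dc;
            if (js < 0 || js >= w) continue;
            double* s = xb + static_cast<uword>(js) * h;
            const double* gc = gb + static_cast<uword>(j) * h;
            for (int i = i0; i < i1; ++i) s[i + dr] += gc[i];
          }
        }
      }
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// ---- light layer primitives ----------------------------------------------

// [[Rcpp::export(name = ".conv1_fwd_cpp")]]
Rcpp::NumericVector conv1_fwd_cpp(const Rcpp::NumericVector& x,
                                  const arma::mat& W, const arma::vec& b) {
  int d[4];
  get_dims4(x, d);
  const uword rows = static_cast<uword>(d[0]) * d[1] * d[2];
  const mat xm(const_cast<double*>(x.begin()), rows, d[3], false, true);
  Rcpp::NumericVector out(rows * W.n_cols);
  mat y(out.begin(), rows, W.n_cols, false, true);
  y = xm * W;
  y.each_row() += b.t();
  out.attr("dim") = Rcpp::IntegerVector::create(
      d[0], d[1], d[2], static_cast<int>(W.n_cols));
  return out;
}

// [[Rcpp::export(name = ".conv1_bwd_cpp")]]
Rcpp::List conv1_bwd_cpp(const Rcpp::NumericVector& x, const arma::mat& W,
                         const Rcpp::NumericVector& dout) {
  int d[4], dd[4];
  get_dims4(x, d);
  get_dims4(dout, dd);
  const uword rows = static_cast<uword>(d[0]) * d[1] * d[2];
  const mat xm(const_cast<double*>(x.begin()), rows, d[3], false, true);
  const mat dm(const_cast<double*>(dout.begin()), rows, dd[3], false, true);
  mat dW = xm.t() * dm;
  vec db = sum(dm, 0).t();
  Rcpp::NumericVector dxo(rows * static_cast<uword>(d[3]));
  mat dx(dxo.begin(), rows, d[3], false, true);
  dx = dm * W.t();
  dxo.attr("dim") = Rcpp::IntegerVector::create(d[0], d[1], d[2], d[3]);
  return Rcpp::List::create(Rcpp::Named("dx") = dxo,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// [[Rcpp::export(name = ".lrelu_fwd_cpp")]]
Rcpp::List lrelu_fwd_cpp(const Rcpp::NumericVector& x, const double slope) {
  const R_xlen_t m = x.size();
  Rcpp::NumericVector y(m), fac(m);
  const double* xp = x.begin();
  double* yp = y.begin();
  double* fp = fac.begin();
  for (R_xlen_t i = 0; i < m; ++i) {
    const double v = xp[i];
    if (v < 0) { yp[i] = slope * v; fp[i] = slope; }
    else { yp[i] = v; fp[i] = 1.0; }
  }
  y.attr("dim") = x.attr("dim");
  fac.attr("dim") = x.attr("dim");
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("fac") = fac);
}

// [[Rcpp::export(name = ".pool2_fwd_cpp")]]
Rcpp::List pool2_fwd_cpp(const Rcpp::NumericVector& x) {
  int d[4];
  get_dims4(x, d);
  const int h = d[0], w = d[1], nc = d[2] * d[3];
  const int ho = h / 2, wo = w / 2;
  Rcpp::NumericVector y(static_cast<R_xlen_t>(ho) * wo * nc);
  Rcpp::IntegerVector which(y.size());
  const double* xp = x.begin();
  double* yp = y.begin();
  int* wp = which.begin();
  for (int s = 0; s < nc; ++s) {
    const double* xs = xp + static_cast<uword>(s) * h * w;
    double* ys = yp + static_cast<uword>(s) * ho * wo;
    int* ws_ = wp + static_cast<uword>(s) * ho * wo;
    for (int j = 0; j < wo; ++j) {
      const double* c0 = xs + static_cast<uword>(2 * j) * h;
      const double* c1 = c0 + h;
      double* yc = ys + static_cast<uword>(j) * ho;
      int* wc = ws_ + static_cast<uword>(j) * ho;
      for (int i = 0; i < ho; ++i) {
        const double v[4] = {c0[2 * i], c0[2 * i + 1],
                             c1[2 * i], c1[2 * i + 1]};
        int k = 0;
        for (int t = 1; t < 4; ++t) if (v[t] > v[k]) k = t;
        yc[i] = v[k];
        wc[i] = k;
      }
    }
  }
  y.attr("dim") = Rcpp::IntegerVector::create(ho, wo, d[2], d[3]);
  return Rcpp::List::create(Rcpp::Named("y") = y,
                            Rcpp::Named("which") = which);
}

// [[Rcpp::export(name = ".pool2_bwd_cpp")]]
Rcpp::NumericVector pool2_bwd_cpp(const Rcpp::NumericVector& dout,
                                  const Rcpp::IntegerVector& which) {
  int d[4];
  get_dims4(dout, d);
  const int ho = d[0], wo = d[1], nc = d[2] * d[3];
  const int h = 2 * ho, w = 2 * wo;
  Rcpp::NumericVector dx(static_cast<R_xlen_t>(h) * w * nc);
  const double* gp = dout.begin();
  const int* wp = which.begin();
  double* dp = dx.begin();
  for (int s = 0; s < nc; ++s) {
    const double* gs = gp + static_cast<uword>(s) * ho * wo;
    const int* ws_ = wp + static_cast<uword>(s) * ho * wo;
    double* ds = dp + static_cast<uword>(s) * h * w;
    for (int j = 0; j < wo; ++j) {
      double* c0 = ds + static_cast<uword>(2 * j) * h;
      double* c1 = c0 + h;
      const double* gc = gs + static_cast<uword>(j) * ho;
      const int* wc = ws_ + static_cast<uword>(j) * ho;
      for (int i = 0; i < ho; ++i) {
        double* tgt[4] = {c0 + 2 * i, c0 + 2 * i + 1,
                          c1 + 2 * i, c1 + 2 * i + 1};
        *tgt[wc[i]] = gc[i];
      }
    }
  }
  dx.attr("dim") = Rcpp::IntegerVector::create(h, w, d[2], d[3]);
  return dx;
}

// [[Rcpp::export(name = ".upsample2_fwd_cpp")]]
Rcpp::NumericVector upsample2_fwd_cpp(const Rcpp::NumericVector& x) {
  int d[4];
  get_dims4(x, d);
  const int h = d[0], w = d[1], nc = d[2] * d[3];
  const int ho = 2 * h, wo = 2 * w;
  Rcpp::NumericVector y(static_cast<R_xlen_t>(ho) * wo * nc);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int s = 0; s < nc; ++s) {
    const double* xs = xp + static_cast<uword>(s) * h * w;
    double* ys = yp + static_cast<uword>(s) * ho * wo;
    for (int j = 0; j < w; ++j) {
      const double* xc = xs + static_cast<uword>(j) * h;
      double* y0 = ys + static_cast<uword>(2 * j) * ho;
      double* y1 = y0 + ho;
      for (int i = 0; i < h; ++i) {
        const double v = xc[i];
        y0[2 * i] = v; y0[2 * i + 1] = v;
        y1[2 * i] = v; y1[2 * i + 1] = v;
      }
    }
  }
  y.attr("dim") = Rcpp::IntegerVector::create(ho, wo, d[2], d[3]);
  return y;
}

// [[Rcpp::export(name = ".upsample2_bwd_cpp")]]
Rcpp::NumericVector upsample2_bwd_cpp(const Rcpp::NumericVector& dout) {
  int d[4];
  get_dims4(dout, d);
  const int ho = d[0], wo = d[1], nc = d[2] * d[3];
  const int h = ho / 2, w = wo / 2;
  Rcpp::NumericVector dx(static_cast<R_xlen_t>(h) * w * nc);
  const double* gp = dout.begin();
  double* dp = dx.begin();
  for (int s = 0; s < nc; ++s) {
    const double* gs = gp + static_cast<uword>(s) * ho * wo;
    double* ds = dp + static_cast<uword>(s) * h * w;
    for (int j = 0; j < w; ++j) {
      const double* g0 = gs + static_cast<uword>(2 * j) * ho;
      const double* g1 = g0 + ho;
      double* dc = ds + static_cast<uword>(j) * h;
      for (int i = 0; i < h; ++i)
        dc[i] = g0[2 * i] + g0[2 * i + 1] + g1[2 * i] + g1[2 * i + 1];
    }
  }
  dx.attr("dim") = Rcpp::IntegerVector::create(h, w, d[2], d[3]);
  return dx;
}
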