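// Low-level numeric kernels for the hybrid classifier: im2col convolution
// (forward/backward), pooling, and separable antialiased bilinear resize.
// Arrays follow R's column-major layout: images are (H, W, C) and activation
// batches are (H, W, C, N); convolution weights are (k, k, Cin, Cout).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Unfold x (H,W,C,N) into a (k*k*C) x (Ho*Wo*N) matrix whose row order
// matches the flattened (k,k,Cin) leading dims of the weight array.
static arma::mat im2col(const double* x, int H, int W, int C, int N,
                        int k, int stride, int pad, int Ho, int Wo) {
  arma::mat cols((arma::uword)k * k * C, (arma::uword)Ho * Wo * N,
                 arma::fill::zeros);
  const size_t plane = (size_t)H * W;
  for (int n = 0; n < N; ++n) {
    const double* xn = x + plane * C * n;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        double* dst = cols.colptr((size_t)ho + (size_t)Ho * wo +
                                  (size_t)Ho * Wo * n);
        for (int c = 0; c < C; ++c) {
          const double* xc = xn + plane * c;
          for (int dw = 0; dw < k; ++dw) {
            const int w = wo * stride - pad + dw;
            double* d2 = dst + k * (dw + k * c);
            if (w < 0 || w >= W) continue;  // stays zero
            const double* xcol = xc + (size_t)H * w;
            for (int dh = 0; dh < k; ++dh) {
              const int h = ho * stride - pad + dh;
              if (h >= 0 && h < H) d2[dh] = xcol[h];
            }
          }
        }
      }
    }
  }
  return cols;
}

static inline void out_dims(int H, int W, int k, int stride, int pad,
                            int& Ho, int& Wo) {
  Ho = (H + 2 * pad - k) / stride + 1;
  Wo = (W + 2 * pad - k) / stride + 1;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_forward(NumericVector x, NumericVector w,
                                 int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  if (wd[2] != C) stop("conv2d: channel mismatch");
  int Ho, Wo; out_dims(H, W, k, stride, pad, Ho, Wo);
  if (Ho < 1 || Wo < 1) stop("conv2d: input smaller than kernel");
  arma::mat cols = im2col(x.begin(), H, W, C, N, k, stride, pad, Ho, Wo);
  arma::mat Wm(w.begin(), (arma::uword)k * k * C, Cout, false);
  arma::mat Y = Wm.t() * cols;  // Cout x (Ho*Wo*N)
  NumericVector out((R_xlen_t)Ho * Wo * Cout * N);
  double* o = out.begin();
  const size_t sp = (size_t)Ho * Wo;
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      double* on = o + sp * (co + (size_t)Cout * n);
      for (size_t q = 0; q < sp; ++q) on[q] = Y(co, q + sp * n);
    }
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(NumericVector x, NumericVector w, NumericVector dy,
                         int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  int Ho, Wo; out_dims(H, W, k, stride, pad, Ho, Wo);
  const size_t sp = (size_t)Ho * Wo;
  arma::mat dY(Cout, sp * N);
  const double* dyp = dy.begin();
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      const double* dn = dyp + sp * (co + (size_t)Cout * n);
      for (size_t q = 0; q < sp; ++q) dY(co, q + sp * n) = dn[q];
    }
  arma::mat cols = im2col(x.begin(), H, W, C, N, k, stride, pad, Ho, Wo);
  arma::mat dWm = cols * dY.t();                       // K x Cout
  arma::mat Wm(const_cast<double*>(w.begin()), (arma::uword)k * k * C, Cout,
               false);
  arma::mat dcols = Wm * dY;                           // K x (Ho*Wo*N)
  NumericVector dx((R_xlen_t)H * W * C * N);           // zero-initialised
  double* dxp = dx.begin();
  const size_t plane = (size_t)H * W;
  for (int n = 0; n < N; ++n) {
    double* xn = dxp + plane * C * n;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        const double* src = dcols.colptr((size_t)ho + (size_t)Ho * wo +
                                         (size_t)Ho * Wo * n);
        for (int c = 0; c < C; ++c) {
          double* xc = xn + plane * c;
          for (int dw = 0; dw < k; ++dw) {
            const int wpos = wo * stride - pad + dw;
            if (wpos < 0 || wpos >= W) continue;
            const double* s2 = src + k * (dw + k * c);
            double* xcol = xc + (size_t)H * wpos;
            for (int dh = 0; dh < k; ++dh) {
              const int h = ho * stride - pad + dh;
              if (h >= 0 && h < H) xcol[h] += s2[dh];
            }
          }
        }
      }
  }
  dx.attr("dim") = xd;
  NumericVector dw(dWm.begin(), dWm.end());
  dw.attr("dim") = wd;
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// Average pooling; padded positions count in the divisor (k*k).
// [[Rcpp::export]]
NumericVector cpp_avgpool_forward(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho, Wo; out_dims(H, W, k, stride, pad, Ho, Wo);
  NumericVector out((R_xlen_t)Ho * Wo * C * N);
  const double inv = 1.0 / (k * k);
  const double* xp = x.begin();
  double* o = out.begin();
  const size_t plane = (size_t)H * W, oplane = (size_t)Ho * Wo;
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double* xc = xp + plane * cn;
    double* oc = o + oplane * cn;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        double s = 0.0;
        for (int dw = 0; dw < k; ++dw) {
          const int w = wo * stride - pad + dw;
          if (w < 0 || w >= W) continue;
          for (int dh = 0; dh < k; ++dh) {
            const int h = ho * stride - pad + dh;
            if (h >= 0 && h < H) s += xc[h + (size_t)H * w];
          }
        }
        oc[ho + (size_t)Ho * wo] = s * inv;
      }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool_backward(NumericVector dy, IntegerVector xdim,
                                   int k, int stride, int pad) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  int Ho, Wo; out_dims(H, W, k, stride, pad, Ho, Wo);
  NumericVector dx((R_xlen_t)H * W * C * N);
  const double inv = 1.0 / (k * k);
  const double* dyp = dy.begin();
  double* dxp = dx.begin();
  const size_t plane = (size_t)H * W, oplane = (size_t)Ho * Wo;
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double* dc = dyp + oplane * cn;
    double* xc = dxp + plane * cn;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        const double g = dc[ho + (size_t)Ho * wo] * inv;
        for (int dw = 0; dw < k; ++dw) {
          const int w = wo * stride - pad + dw;
          if (w < 0 || w >= W) continue;
          for (int dh = 0; dh < k; ++dh) {
            const int h = ho * stride - pad + dh;
            if (h >= 0 && h < H) xc[h + (size_t)H * w] += g;
          }
        }
      }
  }
  dx.attr("dim") = xdim;
  return dx;
}

// Max pooling; returns the pooled values and 1-based linear argmax indices
// into x so the backward pass is a scatter.
// [[Rcpp::export]]
List cpp_maxpool_forward(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho, Wo; out_dims(H, W, k, stride, pad, Ho, Wo);
  NumericVector out((R_xlen_t)Ho * Wo * C * N);
  NumericVector idx((R_xlen_t)Ho * Wo * C * N);  // double: may exceed int
  const double* xp = x.begin();
  double* o = out.begin();
  double* ip = idx.begin();
  const size_t plane = (size_t)H * W, oplane = (size_t)Ho * Wo;
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double* xc = xp + plane * cn;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        double best = -std::numeric_limits<double>::infinity();
        size_t bi = 0;
        for (int dw = 0; dw < k; ++dw) {
          const int w = wo * stride - pad + dw;
          if (w < 0 || w >= W) continue;
          for (int dh = 0; dh < k; ++dh) {
            const int h = ho * stride - pad + dh;
            if (h < 0 || h >= H) continue;
            const double v = xc[h + (size_t)H * w];
            if (v > best) { best = v; bi = plane * cn + h + (size_t)H * w; }
          }
        }
        const size_t q = oplane * cn + ho + (size_t)Ho * wo;
        o[q] = best;
        ip[q] = (double)(bi + 1);
      }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["y"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_backward(NumericVector dy, NumericVector idx,
                                   IntegerVector xdim) {
  NumericVector dx((R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  double* dxp = dx.begin();
  const double* dyp = dy.begin();
  const double* ip = idx.begin();
  const R_xlen_t n = dy.size();
  for (R_xlen_t q = 0; q < n; ++q) dxp[(size_t)ip[q] - 1] += dyp[q];
  dx.attr("dim") = xdim;
  return dx;
}

// Separable bilinear resize with triangle-filter antialiasing on downscale
// (support widened by the scale ratio). img is (H, W, C).
static void resize_axis(const double* src, double* dst, int n_in, int n_out,
                        int inner, int outer, size_t in_stride,
                        size_t out_stride, size_t in_outer_stride,
                        size_t out_outer_stride) {
  const double ratio = (double)n_in / n_out;
  const double support = ratio > 1.0 ? ratio : 1.0;
  std::vector<std::vector<double>> wts(n_out);
  std::vector<int> lo(n_out);
  for (int i = 0; i < n_out; ++i) {
    const double center = (i + 0.5) * ratio - 0.5;
    int jlo = (int)std::ceil(center - support);
    int jhi = (int)std::floor(center + support);
    if (jlo < 0) jlo = 0;
    if (jhi > n_in - 1) jhi = n_in - 1;
    if (jhi < jlo) { jlo = std::min(std::max((int)std::round(center), 0),
                                    n_in - 1); jhi = jlo; }
    lo[i] = jlo;
    double tot = 0.0;
    std::vector<double> w(jhi - jlo + 1);
    for (int j = jlo; j <= jhi; ++j) {
      double t = 1.0 - std::fabs(j - center) / support;
      if (t < 0) t = 0;
      w[j - jlo] = t;
      tot += t;
    }
    if (tot <= 0) { w.assign(w.size(), 1.0 / w.size()); tot = 1.0; }
    else for (double& v : w) v /= tot;
    wts[i] = w;
  }
  for (int u = 0; u < outer; ++u)
    for (int v = 0; v < inner; ++v) {
      const double* s = src + in_outer_stride * u + v;
      double* d = dst + out_outer_stride * u + v;
      for (int i = 0; i < n_out; ++i) {
        double acc = 0.0;
        const std::vector<double>& w = wts[i];
        for (size_t j = 0; j < w.size(); ++j)
          acc += w[j] * s[in_stride * (lo[i] + j)];
        d[out_stride * i] = acc;
      }
    }
}

// [[Rcpp::export]]
NumericVector cpp_resize_bilinear(NumericVector img, int out_h, int out_w) {
  IntegerVector d = img.attr("dim");
  const int H = d[0], W = d[1], C = d.size() > 2 ? d[2] : 1;
  if (out_h < 1 || out_w < 1) stop("resize: output dims must be positive");
  // pass 1: rows H -> out_h  (column-major: row stride 1, column stride H)
  std::vector<double> tmp((size_t)out_h * W * C);
  for (int c = 0; c < C; ++c)
    resize_axis(img.begin() + (size_t)H * W * c,
                tmp.data() + (size_t)out_h * W * c,
                H, out_h, /*inner*/ 1, /*outer*/ W,
                /*in_stride*/ 1, /*out_stride*/ 1,
                /*in_outer*/ H, /*out_outer*/ out_h);
  // pass 2: cols W -> out_w
  NumericVector out((R_xlen_t)out_h * out_w * C);
  for (int c = 0; c < C; ++c)
    resize_axis(tmp.data() + (size_t)out_h * W * c,
                out.begin() + (size_t)out_h * out_w * c,
                W, out_w, /*inner*/ out_h, /*outer*/ 1,
                /*in_stride*/ out_h, /*out_stride*/ out_h,
                /*in_outer*/ 0, /*out_outer*/ 0);
  if (d.size() > 2)
    out.attr("dim") = IntegerVector::create(out_h, out_w, C);
  else
    out.attr("dim") = IntegerVector::create(out_h, out_w);
  return out;
}

// Batch normalization over (H, W, N) per channel, training mode.
// [[Rcpp::export]]
List cpp_bn2d_train(NumericVector x, NumericVector g, NumericVector b) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const size_t plane = (size_t)H * W;
  const double m = (double)plane * N;
  NumericVector mu(C), var(C), istd(C);
  NumericVector xhat((R_xlen_t)x.size()), y((R_xlen_t)x.size());
  const double* xp = x.begin();
  for (int c = 0; c < C; ++c) {
    double s = 0.0, s2 = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* p = xp + plane * (c + (size_t)C * n);
      for (size_t q = 0; q < plane; ++q) { s += p[q]; s2 += p[q] * p[q]; }
    }
    const double mc = s / m;
    double vc = s2 / m - mc * mc;
    if (vc < 0) vc = 0;
    mu[c] = mc; var[c] = vc;
    istd[c] = 1.0 / std::sqrt(vc + 1e-5);
    const double gc = g[c], bc = b[c], ic = istd[c];
    for (int n = 0; n < N; ++n) {
      const size_t off = plane * (c + (size_t)C * n);
      const double* p = xp + off;
      double* xh = xhat.begin() + off;
      double* yy = y.begin() + off;
      for (size_t q = 0; q < plane; ++q) {
        const double h = (p[q] - mc) * ic;
        xh[q] = h;
        yy[q] = h * gc + bc;
      }
    }
  }
  xhat.attr("dim") = xd;
  y.attr("dim") = xd;
  return List::create(_["y"] = y, _["xhat"] = xhat, _["istd"] = istd,
                      _["mu"] = mu, _["var"] = var);
}

// [[Rcpp::export]]
List cpp_bn2d_train_backward(NumericVector dy, NumericVector xhat,
                             NumericVector istd, NumericVector g) {
  IntegerVector xd = dy.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const size_t plane = (size_t)H * W;
  const double m = (double)plane * N;
  NumericVector dg(C), db(C);
  NumericVector dx((R_xlen_t)dy.size());
  const double* dyp = dy.begin();
  const double* xh = xhat.begin();
  for (int c = 0; c < C; ++c) {
    double sg = 0.0, sb = 0.0;
    for (int n = 0; n < N; ++n) {
      const size_t off = plane * (c + (size_t)C * n);
      const double* d = dyp + off;
      const double* h = xh + off;
      for (size_t q = 0; q < plane; ++q) { sg += d[q] * h[q]; sb += d[q]; }
    }
    dg[c] = sg; db[c] = sb;
    const double gc = g[c], ic = istd[c];
    const double t1 = sb / m, t2 = sg / m;
    for (int n = 0; n < N; ++n) {
      const size_t off = plane * (c + (size_t)C * n);
      const double* d = dyp + off;
      const double* h = xh + off;
      double* o = dx.begin() + off;
      for (size_t q = 0; q < plane; ++q)
        o[q] = (d[q] - t1 - h[q] * t2) * gc * ic;
    }
  }
  dx.attr("dim") = xd;
  return List::create(_["dx"] = dx, _["dg"] = dg, _["db"] = db);
}

// Evaluation-mode per-channel affine transform: y = x * a[c] + off[c].
// [[Rcpp::export]]
NumericVector cpp_scale_channels(NumericVector x, NumericVector a,
                                 NumericVector off) {
  IntegerVector xd = x.attr("dim");
  const int C = xd[2], N = xd[3];
  const size_t plane = (size_t)xd[0] * xd[1];
  NumericVector y((R_xlen_t)x.size());
  const double* xp = x.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t o2 = plane * (c + (size_t)C * n);
      const double* p = xp + o2;
      double* yy = y.begin() + o2;
      const double ac = a[c], oc = off[c];
      for (size_t q = 0; q < plane; ++q) yy[q] = p[q] * ac + oc;
    }
  y.attr("dim") = xd;
  return y;
}

// Single-pass exponential moment update: m' = phi1*m + (1-phi1)*g,
// v' = phi2*v + (1-phi2)*g^2. One allocation per moment array.
// [[Rcpp::export]]
List cpp_moment_update(NumericVector m, NumericVector v, NumericVector g,
                       double phi1, double phi2) {
  const R_xlen_t n = m.size();
  NumericVector m2(n), v2(n);
  const double* mp = m.begin();
  const double* vp = v.begin();
  const double* gp = g.begin();
  double* m2p = m2.begin();
  double* v2p = v2.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    m2p[i] = phi1 * mp[i] + (1.0 - phi1) * gp[i];
    v2p[i] = phi2 * vp[i] + (1.0 - phi2) * gp[i] * gp[i];
  }
  m2.attr("dim") = m.attr("dim");
  v2.attr("dim") = v.attr("dim");
  return List::create(_["m"] = m2, _["v"] = v2);
}

// Single-pass moment-based step. literal: p - lr * m / (eps + v);
// otherwise p - lr * (m/c1) / (sqrt(v/c2) + eps).
// [[Rcpp::export]]
NumericVector cpp_apply_step(NumericVector p, NumericVector m,
                             NumericVector v, double lr, double c1,
                             double c2, double eps, bool literal) {
  const R_xlen_t n = p.size();
  NumericVector out(n);
  const double* pp = p.begin();
  const double* mp = m.begin();
  const double* vp = v.begin();
  double* op = out.begin();
  if (literal) {
    for (R_xlen_t i = 0; i < n; ++i)
      op[i] = pp[i] - lr * mp[i] / (eps + vp[i]);
  } else {
    const double isq = 1.0 / std::sqrt(c2);
    for (R_xlen_t i = 0; i < n; ++i)
      op[i] = pp[i] - lr * (mp[i] / c1) / (std::sqrt(vp[i]) * isq + eps);
  }
  out.attr("dim") = p.attr("dim");
  return out;
}
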