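// Low-level tensor kernels for the autodiff tape.
// Feature maps are arma::cube with (rows, cols, slices) = (H, W, C).
// Conv weights are matrices of shape (k*k*Cin/groups) x Cout; column g*Cout/G + j
// holds the filter for output channel j of group g, rows ordered (dy, dx, c_in)
// with c_in fastest — im2col below must use the same ordering.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// im2col for one group: channels [c0, c0+cg) of x.
// Result: (k*k*cg) x (Ho*Wo), column index = y*Wo + x (row-major over output).
static arma::mat im2col_group(const arma::cube& x, int c0, int cg,
                              int k, int stride, int pad, int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols;
  arma::mat cols(k * k * cg, (size_t)Ho * Wo, arma::fill::zeros);
  for (int oy = 0; oy < Ho; ++oy) {
    for (int ox = 0; ox < Wo; ++ox) {
      const size_t col = (size_t)oy * Wo + ox;
      double* dst = cols.colptr(col);
      for (int dy = 0; dy < k; ++dy) {
        const int iy = oy * stride - pad + dy;
        for (int dx = 0; dx < k; ++dx) {
          const int ix = ox * stride - pad + dx;
          const size_t base = (size_t)(dy * k + dx) * cg;
          if (iy >= 0 && iy < H && ix >= 0 && ix < W) {
            for (int c = 0; c < cg; ++c)
              dst[base + c] = x(iy, ix, c0 + c);
          }
        }
      }
    }
  }
  return cols;
}

// scatter-add of column gradients back to the input (inverse of im2col_group)
static void col2im_group(arma::cube& gx, const arma::mat& gcols, int c0, int cg,
                         int k, int stride, int pad, int Ho, int Wo) {
  const int H = gx.n_rows, W = gx.n_cols;
  for (int oy = 0; oy < Ho; ++oy) {
    for (int ox = 0; ox < Wo; ++ox) {
      const size_t col = (size_t)oy * Wo + ox;
      const double* src = gcols.colptr(col);
      for (int dy = 0; dy < k; ++dy) {
        const int iy = oy * stride - pad + dy;
        if (iy < 0 || iy >= H) continue;
        for (int dx = 0; dx < k; ++dx) {
          const int ix = ox * stride - pad + dx;
          if (ix < 0 || ix >= W) continue;
          const size_t base = (size_t)(dy * k + dx) * cg;
          for (int c = 0; c < cg; ++c)
            gx(iy, ix, c0 + c) += src[base + c];
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::cube conv2d_fwd(const arma::cube& x, const arma::mat& w,
                      const arma::vec& bias, bool has_bias,
                      int k, int stride, int pad, int groups) {
  const int Cin = x.n_slices;
  const int Cout = w.n_cols;
  const int cg = Cin / groups;
  const int og = Cout / groups;
  const int Ho = out_size(x.n_rows, k, stride, pad);
  const int Wo = out_size(x.n_cols, k, stride, pad);
  arma::cube out(Ho, Wo, Cout);
  for (int g = 0; g < groups; ++g) {
    arma::mat cols = im2col_group(x, g * cg, cg, k, stride, pad, Ho, Wo);
    arma::mat wg = w.cols(g * og, (g + 1) * og - 1);   // (k*k*cg) x og
    arma::mat res = wg.t() * cols;                     // og x (Ho*Wo)
    for (int j = 0; j < og; ++j) {
      arma::mat plane(res.row(j).t());
      plane.reshape(Wo, Ho);                           // col index = y*Wo + x
      out.slice(g * og + j) = plane.t();
      if (has_bias) out.slice(g * og + j) += bias(g * og + j);
    }
  }
  return out;
}

// [[Rcpp::export]]
List conv2d_bwd(const arma::cube& x, const arma::mat& w, const arma::cube& gout,
                int k, int stride, int pad, int groups, bool has_bias) {
  const int Cin = x.n_slices;
  const int Cout = w.n_cols;
  const int cg = Cin / groups;
  const int og = Cout / groups;
  const int Ho = gout.n_rows, Wo = gout.n_cols;
  arma::cube gx(x.n_rows, x.n_cols, Cin, arma::fill::zeros);
  arma::mat gw(w.n_rows, w.n_cols, arma::fill::zeros);
  arma::vec gb(Cout, arma::fill::zeros);
  for (int g = 0; g < groups; ++g) {
    arma::mat gres(og, (size_t)Ho * Wo);
    for (int j = 0; j < og; ++j) {
      arma::mat plane = gout.slice(g * og + j).t();    // Wo x Ho
      plane.reshape(1, (size_t)Ho * Wo);
      gres.row(j) = plane;
      if (has_bias) gb(g * og + j) = arma::accu(gout.slice(g * og + j));
    }
    arma::mat cols = im2col_group(x, g * cg, cg, k, stride, pad, Ho, Wo);
    gw.cols(g * og, (g + 1) * og - 1) = cols * gres.t();
    arma::mat wg = w.cols(g * og, (g + 1) * og - 1);
    arma::mat gcols = wg * gres;                       // (k*k*cg) x (Ho*Wo)
    col2im_group(gx, gcols, g * cg, cg, k, stride, pad, Ho, Wo);
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
List maxpool2d_fwd(const arma::cube& x, int k, int stride, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);
  arma::cube out(Ho, Wo, C);
  arma::ucube arg(Ho, Wo, C);  // linear index into the H*W plane
  for (int c = 0; c < C; ++c) {
    for (int oy = 0; oy < Ho; ++oy) {
      for (int ox = 0; ox < Wo; ++ox) {
        double best = -arma::datum::inf;
        size_t best_idx = 0;
        for (int dy = 0; dy < k; ++dy) {
          const int iy = oy * stride - pad + dy;
          if (iy < 0 || iy >= H) continue;
          for (int dx = 0; dx < k; ++dx) {
            const int ix = ox * stride - pad + dx;
            if (ix < 0 || ix >= W) continue;
            const double v = x(iy, ix, c);
            if (v > best) { best = v; best_idx = (size_t)ix * H + iy; }
          }
        }
        out(oy, ox, c) = best;
        arg(oy, ox, c) = best_idx;
      }
    }
  }
  return List::create(_["out"] = out, _["arg"] = arg);
}

// [[Rcpp::export]]
arma::cube maxpool2d_bwd(const arma::ucube& arg, const arma::cube& gout,
                         int H, int W) {
  const int Ho = gout.n_rows, Wo = gout.n_cols, C = gout.n_slices;
  arma::cube gx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int oy = 0; oy < Ho; ++oy)
      for (int ox = 0; ox < Wo; ++ox) {
        const size_t idx = arg(oy, ox, c);
        gx(idx % H, idx / H, c) += gout(oy, ox, c);
      }
  return gx;
}

// nearest-neighbour resize to (Ho, Wo); source index floor(i * H / Ho)
// [[Rcpp::export]]
arma::cube upsample_nearest_fwd(const arma::cube& x, int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube out(Ho, Wo, C);
  for (int oy = 0; oy < Ho; ++oy) {
    const int iy = std::min((int)((long long)oy * H / Ho), H - 1);
    for (int ox = 0; ox < Wo; ++ox) {
      const int ix = std::min((int)((long long)ox * W / Wo), W - 1);
      for (int c = 0; c < C; ++c) out(oy, ox, c) = x(iy, ix, c);
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::cube upsample_nearest_bwd(const arma::cube& gout, int H, int W) {
  const int Ho = gout.n_rows, Wo = gout.n_cols, C = gout.n_slices;
  arma::cube gx(H, W, C, arma::fill::zeros);
  for (int oy = 0; oy < Ho; ++oy) {
    const int iy = std::min((int)((long long)oy * H / Ho), H - 1);
    for (int ox = 0; ox < Wo; ++ox) {
      const int ix = std::min((int)((long long)ox * W / Wo), W - 1);
      for (int c = 0; c < C; ++c) gx(iy, ix, c) += gout(oy, ox, c);
    }
  }
  return gx;
}
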