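// Low-level tensor ops for the segmentation network.
//
// Feature maps are H x W x C arma::cube (double), matching R arrays with
// dim = c(H, W, C).  Convolution weights are (k*k*Cin) x Cout matrices with
// column index layout ci*k*k + di*k + dj (channel-major, then kernel row,
// then kernel column); the layout only has to be consistent between the
// forward and backward passes.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// im2col for 'same' convolution with zero padding `pad` and stride 1.
// Output: (H*W) x (k*k*Cin); spatial rows are column-major (i + j*H), the
// same linearisation R uses for matrix elements.
static arma::mat im2col(const arma::cube& x, const int k, const int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat cols(H * W, k * k * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const arma::mat& plane = x.slice(c);
    for (int di = 0; di < k; ++di) {
      for (int dj = 0; dj < k; ++dj) {
        const int col = c * k * k + di * k + dj;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj - pad;
          if (sj < 0 || sj >= W) continue;
          const int i0 = std::max(0, pad - di);
          const int i1 = std::min(H, H + pad - di);
          if (i0 >= i1) continue;
          // rows i0..i1-1 read source rows i0+di-pad ..
          std::memcpy(cols.colptr(col) + (j * H + i0),
                      plane.colptr(sj) + (i0 + di - pad),
                      sizeof(double) * (i1 - i0));
        }
      }
    }
  }
  return cols;
}

// Adjoint of im2col: scatter-add columns back into an H x W x C cube.
static arma::cube col2im(const arma::mat& cols, const int H, const int W,
                         const int C, const int k, const int pad) {
  arma::cube x(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    arma::mat& plane = x.slice(c);
    for (int di = 0; di < k; ++di) {
      for (int dj = 0; dj < k; ++dj) {
        const int col = c * k * k + di * k + dj;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj - pad;
          if (sj < 0 || sj >= W) continue;
          const int i0 = std::max(0, pad - di);
          const int i1 = std::min(H, H + pad - di);
          for (int i = i0; i < i1; ++i) {
            plane(i + di - pad, sj) += cols(j * H + i, col);
          }
        }
      }
    }
  }
  return x;
}

// [[Rcpp::export]]
arma::cube conv2d_fwd(const arma::cube& x, const arma::mat& W,
                      const arma::vec& b, const int k, const int pad) {
  const int H = x.n_rows, Wd = x.n_cols;
  const int Cout = W.n_cols;
  arma::mat y;
  if (k == 1 && pad == 0) {
    // fast path: pure channel mixing
    arma::mat xm(const_cast<double*>(x.memptr()), H * Wd, x.n_slices, false);
    y = xm * W;
  } else {
    y = im2col(x, k, pad) * W;
  }
  y.each_row() += b.t();
  arma::cube out(y.memptr(), H, Wd, Cout);
  return out;
}

// [[Rcpp::export]]
List conv2d_bwd(const arma::cube& x, const arma::mat& W, const int k,
                const int pad, const arma::cube& dy) {
  const int H = x.n_rows, Wd = x.n_cols, Cin = x.n_slices;
  const int Cout = dy.n_slices;
  arma::mat dym(const_cast<double*>(dy.memptr()), H * Wd, Cout, false);
  arma::mat dW;
  arma::cube dx;
  if (k == 1 && pad == 0) {
    arma::mat xm(const_cast<double*>(x.memptr()), H * Wd, Cin, false);
    dW = xm.t() * dym;
    arma::mat dxm = dym * W.t();
    dx = arma::cube(dxm.memptr(), H, Wd, Cin);
  } else {
    arma::mat cols = im2col(x, k, pad);
    dW = cols.t() * dym;
    arma::mat dcols = dym * W.t();
    dx = col2im(dcols, H, Wd, Cin, k, pad);
  }
  arma::vec db = arma::sum(dym, 0).t();
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// 2x2 max pooling, stride 2.  Returns pooled map and, per pooled element,
// the 0-based linear index (i + j*H) of the argmax within its input plane.
// Ties resolve to the first element in column-major window scan order.
// [[Rcpp::export]]
List maxpool2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  if (H % 2 || W % 2) stop("maxpool2_fwd: spatial dims must be even");
  const int h = H / 2, w = W / 2;
  arma::cube y(h, w, C);
  IntegerVector idx(h * w * C);
  int p = 0;
  for (int c = 0; c < C; ++c) {
    const arma::mat& plane = x.slice(c);
    for (int j = 0; j < w; ++j) {
      for (int i = 0; i < h; ++i) {
        double best = plane(2 * i, 2 * j);
        int bi = 2 * i, bj = 2 * j;
        const int ii[4] = {2 * i, 2 * i + 1, 2 * i, 2 * i + 1};
        const int jj[4] = {2 * j, 2 * j, 2 * j + 1, 2 * j + 1};
        for (int t = 1; t < 4; ++t) {
          const double v = plane(ii[t], jj[t]);
          if (v > best) { best = v; bi = ii[t]; bj = jj[t]; }
        }
        y(i, j, c) = best;
        idx[p++] = bi + bj * H;
      }
    }
  }
  idx.attr("dim") = IntegerVector::create(h, w, C);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// Scatter pooled values (or gradients) into an H x W x C cube at the stored
// argmax positions; zeros elsewhere.  This is both the unpooling forward op
// and the max-pooling backward op.
// [[Rcpp::export]]
arma::cube unpool_scatter(const arma::cube& v, const IntegerVector& idx,
                          const int H, const int W) {
  const int h = v.n_rows, w = v.n_cols, C = v.n_slices;
  if (idx.size() != (R_xlen_t)(h * w * C))
    stop("unpool_scatter: index/value shape mismatch");
  arma::cube out(H, W, C, arma::fill::zeros);
  int p = 0;
  for (int c = 0; c < C; ++c) {
    double* plane = out.slice(c).memptr();
    const double* vp = v.slice(c).memptr();
    for (int q = 0; q < h * w; ++q) {
      const int lin = idx[p++];
      if (lin < 0 || lin >= H * W) stop("unpool_scatter: index out of range");
      plane[lin] += vp[q];
    }
  }
  return out;
}

// Gather from an H x W x C cube at stored argmax positions: the unpooling
// backward op (and an alternative view of pooling itself).
// [[Rcpp::export]]
arma::cube unpool_gather(const arma::cube& big, const IntegerVector& idx,
                         const int h, const int w) {
  const int H = big.n_rows, W = big.n_cols, C = big.n_slices;
  if (idx.size() != (R_xlen_t)(h * w * C))
    stop("unpool_gather: index/value shape mismatch");
  arma::cube out(h, w, C);
  int p = 0;
  for (int c = 0; c < C; ++c) {
    const double* plane = big.slice(c).memptr();
    double* vp = out.slice(c).memptr();
    for (int q = 0; q < h * w; ++q) {
      const int lin = idx[p++];
      if (lin < 0 || lin >= H * W) stop("unpool_gather: index out of range");
      vp[q] = plane[lin];
    }
  }
  return out;
}

// Fused fire-module forward: squeeze (1x1) + ReLU, then parallel expand
// 1x1 and 3x3 ('same') convolutions + ReLU written into one output cube.
// Returns the output and, when `want_cache`, the squeeze activation.
// [[Rcpp::export]]
List fire_fwd_cpp(const arma::cube& x, const arma::mat& Ws,
                  const arma::vec& bs, const arma::mat& W1,
                  const arma::vec& b1, const arma::mat& W3,
                  const arma::vec& b3, const bool want_cache) {
  const int H = x.n_rows, W = x.n_cols;
  const int Cs = Ws.n_cols, C1 = W1.n_cols, C3 = W3.n_cols;
  arma::mat xm(const_cast<double*>(x.memptr()), H * W, x.n_slices, false);
  arma::mat sm = xm * Ws;
  sm.each_row() += bs.t();
  sm.clamp(0.0, arma::datum::inf);
  arma::cube s(sm.memptr(), H, W, Cs);
  arma::cube out(H, W, C1 + C3);
  arma::mat outm(out.memptr(), H * W, C1 + C3, false, true);
  outm.cols(0, C1 - 1) = sm * W1;
  outm.cols(C1, C1 + C3 - 1) = im2col(s, 3, 1) * W3;
  for (int c = 0; c < C1; ++c) outm.col(c) += b1[c];
  for (int c = 0; c < C3; ++c) outm.col(C1 + c) += b3[c];
  out.clamp(0.0, arma::datum::inf);
  if (want_cache) return List::create(_["out"] = out, _["s"] = s);
  return List::create(_["out"] = out);
}

// Fused fire-module backward.  `s` and `out` are the cached (activated)
// squeeze and module outputs; ReLU masks come from them.
// [[Rcpp::export]]
List fire_bwd_cpp(const arma::cube& x, const arma::cube& s,
                  const arma::cube& out, const arma::mat& Ws,
                  const arma::mat& W1, const arma::mat& W3,
                  const arma::cube& dout) {
  const int H = x.n_rows, W = x.n_cols;
  const int Cs = s.n_slices, C1 = W1.n_cols, C3 = W3.n_cols;
  const int HW = H * W;
  arma::mat dom(const_cast<double*>(dout.memptr()), HW, C1 + C3, false);
  arma::mat om(const_cast<double*>(out.memptr()), HW, C1 + C3, false);
  arma::mat de = dom;
  de.elem(arma::find(om <= 0)).zeros();        // ReLU mask
  arma::mat de1 = de.cols(0, C1 - 1);
  arma::mat de3 = de.cols(C1, C1 + C3 - 1);
  arma::mat sm(const_cast<double*>(s.memptr()), HW, Cs, false);
  arma::mat dW1 = sm.t() * de1;
  arma::vec db1 = arma::sum(de1, 0).t();
  arma::mat cols3 = im2col(s, 3, 1);
  arma::mat dW3 = cols3.t() * de3;
  arma::vec db3 = arma::sum(de3, 0).t();
  arma::mat dsm = de1 * W1.t();
  arma::cube ds3 = col2im(de3 * W3.t(), H, W, Cs, 3, 1);
  arma::mat ds3m(ds3.memptr(), HW, Cs, false);
  dsm += ds3m;
  dsm.elem(arma::find(sm <= 0)).zeros();
  arma::mat xm(const_cast<double*>(x.memptr()), HW, x.n_slices, false);
  arma::mat dWs = xm.t() * dsm;
  arma::vec dbs = arma::sum(dsm, 0).t();
  arma::mat dxm = dsm * Ws.t();
  arma::cube dx(dxm.memptr(), H, W, x.n_slices);
  return List::create(_["dx"] = dx, _["dWs"] = dWs, _["dbs"] = dbs,
                      _["dW1"] = dW1, _["db1"] = db1,
                      _["dW3"] = dW3, _["db3"] = db3);
}

// Symmetric Hausdorff distance between two point sets (rows = points).
// [[Rcpp::export]]
double hausdorff_cpp(const arma::mat& A, const arma::mat& B) {
  if (A.n_rows == 0 || B.n_rows == 0)
    stop("hausdorff_cpp: empty point set");
  double hAB = 0.0, hBA = 0.0;
  arma::vec minB(B.n_rows);
  minB.fill(arma::datum::inf);
  for (arma::uword i = 0; i < A.n_rows; ++i) {
    double m = arma::datum::inf;
    for (arma::uword j = 0; j < B.n_rows; ++j) {
      double d = 0.0;
      for (arma::uword k = 0; k < A.n_cols; ++k) {
        const double t = A(i, k) - B(j, k);
        d += t * t;
      }
      if (d < m) m = d;
      if (d < minB[j]) minB[j] = d;
    }
    if (m > hAB) hAB = m;
  }
  hBA = minB.max();
  return std::sqrt(std::max(hAB, hBA));
}
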