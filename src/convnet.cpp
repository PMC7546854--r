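// Fixed-weight multiscale convolutional feature extractor for the similarity
// network, with an exact backward pass to the input region. Each level is a
// zero-padded 3x3(x3) convolution (no bias) + ReLU + 2x max-pooling; the
// global mean of every pooled map is concatenated across levels into the
// region's feature vector.
//
// Activations are (npix x channels) matrices over a column-major spatial
// block of dims (d1, d2, d3); linear pixel index = i1 + d1*(i2 + d2*i3).
// Convolution weights for level l are (K*Cin x Cout) with row index
// k*Cin + cin, where k enumerates the neighbourhood offsets.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

struct LevelCache {
  arma::mat Y;        // post-ReLU conv output (npix x C)
  arma::umat amax;    // argmax pixel index per (pooled pixel, channel)
  int d1, d2, d3;     // input spatial dims of this level's conv
  int p1, p2, p3;     // pooled dims
};

static inline int nOffsets(bool is3d) { return is3d ? 27 : 9; }

static void offsetK(int k, bool is3d, int &o1, int &o2, int &o3) {
  o1 = k % 3 - 1;
  o2 = (k / 3) % 3 - 1;
  o3 = is3d ? (k / 9 - 1) : 0;
}

static arma::mat im2col(const arma::mat &A, int d1, int d2, int d3, bool is3d) {
  const int K = nOffsets(is3d);
  const int Cin = A.n_cols;
  const arma::uword npix = A.n_rows;
  arma::mat cols(npix, (arma::uword)K * Cin, arma::fill::zeros);
  for (int k = 0; k < K; ++k) {
    int o1, o2, o3;
    offsetK(k, is3d, o1, o2, o3);
    for (int c = 0; c < Cin; ++c) {
      const arma::uword outcol = (arma::uword)k * Cin + c;
      for (int i3 = 0; i3 < d3; ++i3) {
        const int j3 = i3 + o3;
        if (j3 < 0 || j3 >= d3) continue;
        for (int i2 = 0; i2 < d2; ++i2) {
          const int j2 = i2 + o2;
          if (j2 < 0 || j2 >= d2) continue;
          const int i1lo = std::max(0, -o1), i1hi = std::min(d1, d1 - o1);
          const arma::uword dst0 = (arma::uword)d1 * (i2 + (arma::uword)d2 * i3);
          const arma::uword src0 = (arma::uword)d1 * (j2 + (arma::uword)d2 * j3);
          for (int i1 = i1lo; i1 < i1hi; ++i1)
            cols(dst0 + i1, outcol) = A(src0 + i1 + o1, c);
        }
      }
    }
  }
  return cols;
}

// adjoint of im2col: scatter-add column gradients back to input pixels
static arma::mat col2im(const arma::mat &G, int d1, int d2, int d3, bool is3d,
                        int Cin) {
  const int K = nOffsets(is3d);
  arma::mat dA((arma::uword)d1 * d2 * d3, Cin, arma::fill::zeros);
  for (int k = 0; k < K; ++k) {
    int o1, o2, o3;
    offsetK(k, is3d, o1, o2, o3);
    for (int c = 0; c < Cin; ++c) {
      const arma::uword gc = (arma::uword)k * Cin + c;
      for (int i3 = 0; i3 < d3; ++i3) {
        const int j3 = i3 + o3;
        if (j3 < 0 || j3 >= d3) continue;
        for (int i2 = 0; i2 < d2; ++i2) {
          const int j2 = i2 + o2;
          if (j2 < 0 || j2 >= d2) continue;
          const int i1lo = std::max(0, -o1), i1hi = std::min(d1, d1 - o1);
          const arma::uword dst0 = (arma::uword)d1 * (i2 + (arma::uword)d2 * i3);
          const arma::uword src0 = (arma::uword)d1 * (j2 + (arma::uword)d2 * j3);
          for (int i1 = i1lo; i1 < i1hi; ++i1)
            dA(src0 + i1 + o1, c) += G(dst0 + i1, gc);
        }
      }
    }
  }
  return dA;
}

static void maxpool(const arma::mat &Y, int d1, int d2, int d3, bool is3d,
                    arma::mat &P, arma::umat &amax, int &p1, int &p2, int &p3) {
  p1 = std::max(1, d1 / 2);
  p2 = std::max(1, d2 / 2);
  p3 = is3d ? std::max(1, d3 / 2) : d3;
  const int C = Y.n_cols;
  P.set_size((arma::uword)p1 * p2 * p3, C);
  amax.set_size((arma::uword)p1 * p2 * p3, C);
  const int w3 = is3d ? 2 : 1;
  for (int c = 0; c < C; ++c) {
    for (int i3 = 0; i3 < p3; ++i3) {
      for (int i2 = 0; i2 < p2; ++i2) {
        for (int i1 = 0; i1 < p1; ++i1) {
          double best = -std::numeric_limits<double>::infinity();
          arma::uword bidx = 0;
          for (int u3 = 0; u3 < w3; ++u3) {
            const int j3 = (is3d ? 2 * i3 : i3) + u3;
            if (j3 >= d3) continue;
            for (int u2 = 0; u2 < 2; ++u2) {
              const int j2 = 2 * i2 + u2;
              if (j2 >= d2) continue;
              for (int u1 = 0; u1 < 2; ++u1) {
                const int j1 = 2 * i1 + u1;
                if (j1 >= d1) continue;
                const arma::uword j =
                    j1 + (arma::uword)d1 * (j2 + (arma::uword)d2 * j3);
                if (Y(j, c) > best) { best = Y(j, c); bidx = j; }
              }
            }
          }
          const arma::uword i =
              i1 + (arma::uword)p1 * (i2 + (arma::uword)p2 * i3);
          P(i, c) = best;
          amax(i, c) = bidx;
        }
      }
    }
  }
}

// Forward pass; if caches != nullptr, retain what the backward pass needs.
static arma::vec forwardStack(const arma::mat &region0, int d1, int d2, int d3,
                              const List &weights, bool is3d,
                              std::vector<LevelCache> *caches,
                              std::vector<arma::uword> &featOffsets) {
  const int L = weights.size();
  arma::mat A = region0;
  int a1 = d1, a2 = d2, a3 = d3;
  std::vector<arma::vec> feats(L);
  featOffsets.assign(L + 1, 0);
  for (int l = 0; l < L; ++l) {
    const arma::mat W = as<arma::mat>(weights[l]);
    arma::mat cols = im2col(A, a1, a2, a3, is3d);
    arma::mat Y = cols * W;
    Y.for_each([](double &v) { if (v < 0.0) v = 0.0; });
    arma::mat P;
    arma::umat amax;
    int p1, p2, p3;
    maxpool(Y, a1, a2, a3, is3d, P, amax, p1, p2, p3);
    feats[l] = arma::conv_to<arma::vec>::from(arma::mean(P, 0));
    if (caches) {
      LevelCache lc;
      lc.Y = Y;
      lc.amax = amax;
      lc.d1 = a1; lc.d2 = a2; lc.d3 = a3;
      lc.p1 = p1; lc.p2 = p2; lc.p3 = p3;
      caches->push_back(std::move(lc));
    }
    A = std::move(P);
    a1 = p1; a2 = p2; a3 = p3;
  }
  arma::uword tot = 0;
  for (int l = 0; l < L; ++l) { featOffsets[l] = tot; tot += feats[l].n_elem; }
  featOffsets[L] = tot;
  arma::vec f(tot);
  for (int l = 0; l < L; ++l)
    f.subvec(featOffsets[l], featOffsets[l + 1] - 1) = feats[l];
  return f;
}

// [[Rcpp::export]]
NumericVector cppRegionFeatures(NumericVector region, IntegerVector rdims,
                                List weights, bool is3d) {
  const int d1 = rdims[0], d2 = rdims[1], d3 = rdims[2];
  arma::mat A(const_cast<double *>(&region[0]), (arma::uword)d1 * d2 * d3, 1,
              true);
  std::vector<arma::uword> off;
  arma::vec f = forwardStack(A, d1, d2, d3, weights, is3d, nullptr, off);
  return wrap(f);
}

// Forward + cosine-similarity loss against a fixed feature vector fa, and
// backward all the way to the input region. Returns the loss contribution
// (-cosine), the region gradient, the region's own feature vector, and a
// degeneracy flag (zero-norm features on either side).
// [[Rcpp::export]]
List cppRegionLossGrad(NumericVector region, IntegerVector rdims, List weights,
                       NumericVector fa, bool is3d) {
  const int d1 = rdims[0], d2 = rdims[1], d3 = rdims[2];
  const int L = weights.size();
  arma::mat A0(const_cast<double *>(&region[0]), (arma::uword)d1 * d2 * d3, 1,
               true);
  std::vector<LevelCache> caches;
  std::vector<arma::uword> off;
  arma::vec fw = forwardStack(A0, d1, d2, d3, weights, is3d, &caches, off);
  arma::vec a(const_cast<double *>(&fa[0]), fa.size(), true);

  const double nw = arma::norm(fw), na = arma::norm(a);
  if (nw < 1e-12 || na < 1e-12) {
    NumericVector zg((R_xlen_t)d1 * d2 * d3);
    zg.attr("dim") = rdims;
    return List::create(_["loss"] = 0.0, _["grad"] = zg, _["fw"] = wrap(fw),
                        _["degenerate"] = true);
  }
  const double dot = arma::dot(fw, a);
  const double loss = -dot / (nw * na);
  // d loss / d fw
  arma::vec dfw = -(a / (nw * na) - dot * fw / (nw * nw * nw * na));

  // backward through the stack
  arma::mat dA;  // gradient wrt the pooled output of the current level
  for (int l = L - 1; l >= 0; --l) {
    const LevelCache &lc = caches[l];
    const int C = lc.Y.n_cols;
    const arma::uword np = lc.amax.n_rows;
    // gradient wrt pooled map: global-mean term + downstream term
    arma::mat dP(np, C, arma::fill::zeros);
    for (int c = 0; c < C; ++c) {
      const double gm = dfw(off[l] + c) / (double)np;
      dP.col(c).fill(gm);
    }
    if (l < L - 1 && !dA.empty()) dP += dA;
    // unpool to conv output
    arma::mat dY(lc.Y.n_rows, C, arma::fill::zeros);
    for (int c = 0; c < C; ++c)
      for (arma::uword i = 0; i < np; ++i)
        dY(lc.amax(i, c), c) += dP(i, c);
    // ReLU
    dY.elem(arma::find(lc.Y <= 0.0)).zeros();
    // conv backward to this level's input
    const arma::mat W = as<arma::mat>(weights[l]);
    arma::mat G = dY * W.t();
    const int Cin = (l == 0) ? 1 : as<arma::mat>(weights[l - 1]).n_cols;
    dA = col2im(G, lc.d1, lc.d2, lc.d3, is3d, Cin);
  }
  NumericVector grad(wrap(arma::vec(dA.col(0))));
  grad.attr("dim") = rdims;
  return List::create(_["loss"] = loss, _["grad"] = grad, _["fw"] = wrap(fw),
                      _["degenerate"] = false);
}
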