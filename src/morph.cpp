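#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Grayscale erosion/dilation with an arbitrary (possibly non-flat)
// structuring element. `se` is a (2*rh+1) x (2*rw+1) matrix of heights;
// NA marks cells outside the support. Borders are handled by nearest-border
// replication (index clamping).
// [[Rcpp::export]]
NumericMatrix grey_morph(NumericMatrix img, NumericMatrix se, bool dilate) {
  const int H = img.nrow(), W = img.ncol();
  const int kh = se.nrow(), kw = se.ncol();
  const int rh = kh / 2, rw = kw / 2;

  // flatten the SE support into offset/height triples
  std::vector<int> odr, odc;
  std::vector<double> oh;
  for (int dc = -rw; dc <= rw; ++dc)
    for (int dr = -rh; dr <= rh; ++dr) {
      const double h = se(dr + rh, dc + rw);
      if (!ISNAN(h)) {
        odr.push_back(dr);
        odc.push_back(dc);
        oh.push_back(dilate ? h : -h);
      }
    }
  const int K = (int)odr.size();
  const double *ip = &img(0, 0);
  NumericMatrix out(H, W);

  for (int c = 0; c < W; ++c) {
    const bool cedge = (c < rw) || (c >= W - rw);
    for (int r = 0; r < H; ++r) {
      double best = dilate ? R_NegInf : R_PosInf;
      if (!cedge && r >= rh && r < H - rh) {
        const double *base = ip + (size_t)c * H + r;
        if (dilate) {
          for (int k = 0; k < K; ++k) {
            const double t = base[(size_t)odc[k] * H + odr[k]] + oh[k];
            if (t > best) best = t;
          }
        } else {
          for (int k = 0; k < K; ++k) {
            const double t = base[(size_t)odc[k] * H + odr[k]] + oh[k];
            if (t < best) best = t;
          }
        }
      } else {
        for (int k = 0; k < K; ++k) {
          const double v =
              ip[(size_t)clampi(c + odc[k], 0, W - 1) * H + clampi(r + odr[k], 0, H - 1)];
          const double t = v + oh[k];
          if (dilate ? (t > best) : (t < best)) best = t;
        }
      }
      out(r, c) = best;
    }
  }
  return out;
}
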