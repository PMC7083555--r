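#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Threshold-free cluster enhancement of a non-negative 3D map.
//
// For thresholds h = dh, 2*dh, ..., up to max(x), every voxel v with
// x[v] >= h receives an increment e(h,v)^E * h^H * dh, where e(h,v) is the
// size (voxel count) of the suprathreshold connected component containing v.
// Connectivity is 6 (faces), 18 (faces+edges) or 26 (full neighbourhood).
// Signed maps are handled in R by enhancing the positive and the negated
// map separately.
// [[Rcpp::export(name = ".tfce_cpp")]]
NumericVector tfce_cpp(NumericVector x, IntegerVector dim,
                       double H, double E, double dh, int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (x.size() != n) stop("map length does not match dim");
  if (dh <= 0) stop("dh must be > 0");
  if (!(connectivity == 6 || connectivity == 18 || connectivity == 26))
    stop("connectivity must be 6, 18 or 26");

  // neighbour offsets
  std::vector<int> dxs, dys, dzs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh > 1) continue;
        if (connectivity == 18 && manh > 2) continue;
        dxs.push_back(dx); dys.push_back(dy); dzs.push_back(dz);
      }
  const int nnb = (int)dxs.size();

  double mx = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (ISNAN(x[i])) stop("non-finite values in map");
    if (x[i] > mx) mx = x[i];
  }
  NumericVector out(n);
  if (mx <= 0.0) return out;

  std::vector<int> label(n), stack;
  std::vector<R_xlen_t> members;
  stack.reserve(1024); members.reserve(1024);

  for (double h = dh; h <= mx + 1e-12; h += dh) {
    std::fill(label.begin(), label.end(), 0);
    int cur = 0;
    for (R_xlen_t s = 0; s < n; ++s) {
      if (x[s] < h || label[s] != 0) continue;
      ++cur;
      members.clear();
      stack.clear();
      stack.push_back((int)s);
      label[s] = cur;
      while (!stack.empty()) {
        int v = stack.back(); stack.pop_back();
        members.push_back(v);
        int zi = v / (nx * ny), rem = v % (nx * ny);
        int yi = rem / nx, xi = rem % nx;
        for (int k = 0; k < nnb; ++k) {
          int xn = xi + dxs[k], yn = yi + dys[k], zn = zi + dzs[k];
          if (xn < 0 || xn >= nx || yn < 0 || yn >= ny || zn < 0 || zn >= nz)
            continue;
          R_xlen_t w = (R_xlen_t)zn * nx * ny + (R_xlen_t)yn * nx + xn;
          if (x[w] >= h && label[w] == 0) {
            label[w] = cur;
            stack.push_back((int)w);
          }
        }
      }
      double inc = std::pow((double)members.size(), E) * std::pow(h, H) * dh;
      for (size_t m = 0; m < members.size(); ++m) out[members[m]] += inc;
    }
  }
  return out;
}
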