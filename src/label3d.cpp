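#include <Rcpp.h>
#include <vector>
#include <array>
#include <cstdlib>

using namespace Rcpp;

// 3D connected-component labeling of a logical lattice by iterative
// depth-first search. Labels are assigned in column-major scan order of the
// first voxel of each component, so the output is deterministic and labels
// are contiguous 1..K. connectivity: 6 (face), 18 (face+edge) or 26
// (face+edge+vertex).
// [[Rcpp::export]]
IntegerVector label_components3d_cpp(LogicalVector mask, IntegerVector dims,
                                     int connectivity) {
  if (dims.size() != 3)
    stop("dims must have length 3");
  const R_xlen_t nx = dims[0], ny = dims[1], nz = dims[2];
  if (nx * ny * nz != mask.size())
    stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");

  std::vector<std::array<int, 3> > offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int s = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (s == 0) continue;
        if (connectivity == 6 && s > 1) continue;
        if (connectivity == 18 && s > 2) continue;
        offs.push_back({{dx, dy, dz}});
      }

  IntegerVector lab(mask.size(), 0);
  std::vector<R_xlen_t> stack;
  int cur = 0;
  for (R_xlen_t i = 0; i < mask.size(); ++i) {
    if (mask[i] != TRUE || lab[i] != 0) continue;
    ++cur;
    lab[i] = cur;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      R_xlen_t x = v % nx;
      R_xlen_t y = (v / nx) % ny;
      R_xlen_t z = v / (nx * ny);
      for (size_t o = 0; o < offs.size(); ++o) {
        R_xlen_t xx = x + offs[o][0];
        R_xlen_t yy = y + offs[o][1];
        R_xlen_t zz = z + offs[o][2];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
          continue;
        R_xlen_t u = xx + nx * (yy + ny * zz);
        if (mask[u] == TRUE && lab[u] == 0) {
          lab[u] = cur;
          stack.push_back(u);
        }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}
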