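#include <RcppArmadillo.h>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Voxel layout everywhere: column-major R array dim = (nz, nx, ny),
// linear index i = z + nz * (x + nx * y), all 0-based here.

// ---------------------------------------------------------------------------
// 26-connected component labelling (BFS)
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(IntegerVector bin, IntegerVector dims) {
  const int nz = dims[0], nx = dims[1], ny = dims[2];
  const R_xlen_t n = bin.size();
  IntegerVector lab(n, 0);
  std::vector<int> queue;
  queue.reserve(1024);
  int cur = 0;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (bin[start] == 0 || lab[start] != 0) continue;
    ++cur;
    lab[start] = cur;
    queue.clear();
    queue.push_back((int)start);
    while (!queue.empty()) {
      int i = queue.back();
      queue.pop_back();
      int z = i % nz, x = (i / nz) % nx, y = i / (nz * nx);
      for (int dy = -1; dy <= 1; ++dy) {
        int yy = y + dy;
        if (yy < 0 || yy >= ny) continue;
        for (int dx = -1; dx <= 1; ++dx) {
          int xx = x + dx;
          if (xx < 0 || xx >= nx) continue;
          for (int dz = -1; dz <= 1; ++dz) {
            int zz = z + dz;
            if (zz < 0 || zz >= nz) continue;
            int j = zz + nz * (xx + nx * yy);
            if (bin[j] != 0 && lab[j] == 0) {
              lab[j] = cur;
              queue.push_back(j);
            }
          }
        }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// ---------------------------------------------------------------------------
// (26, 6) simple-point test on a 3x3x3 neighbourhood.
// nb[] indexed by (dz+1) + 3*(dx+1) + 9*(dy+1); centre = 13.
// ---------------------------------------------------------------------------

static inline int off_dz(int p) { return p % 3 - 1; }
static inline int off_dx(int p) { return (p / 3) % 3 - 1; }
static inline int off_dy(int p) { return p / 9 - 1; }

// number of 26-connected components of object voxels among the 26 neighbours
static int object_components26(const bool nb[27]) {
  bool seen[27] = {false};
  int ncomp = 0;
  int stack[27];
  for (int s = 0; s < 27; ++s) {
    if (s == 13 || !nb[s] || seen[s]) continue;
    ++ncomp;
    int top = 0;
    stack[top++] = s;
    seen[s] = true;
    while (top > 0) {
      int p = stack[--top];
      int pz = off_dz(p), px = off_dx(p), py = off_dy(p);
      for (int q = 0; q < 27; ++q) {
        if (q == 13 || q == p || !nb[q] || seen[q]) continue;
        if (std::abs(off_dz(q) - pz) <= 1 && std::abs(off_dx(q) - px) <= 1 &&
            std::abs(off_dy(q) - py) <= 1) {
          seen[q] = true;
          stack[top++] = q;
        }
      }
    }
  }
  return ncomp;
}

// number of 6-connected components of background voxels within the
// 18-neighbourhood that contain at least one face neighbour of the centre
static int background_components6(const bool nb[27]) {
  bool inN18[27], seen[27] = {false};
  for (int p = 0; p < 27; ++p) {
    int a = std::abs(off_dz(p)) + std::abs(off_dx(p)) + std::abs(off_dy(p));
    inN18[p] = (p != 13) && (a <= 2);
  }
  int ncomp = 0;
  int stack[27];
  for (int s = 0; s < 27; ++s) {
    // seeds: background face neighbours
    int a = std::abs(off_dz(s)) + std::abs(off_dx(s)) + std::abs(off_dy(s));
    if (a != 1 || nb[s] || seen[s]) continue;
    ++ncomp;
    int top = 0;
    stack[top++] = s;
    seen[s] = true;
    while (top > 0) {
      int p = stack[--top];
      int pz = off_dz(p), px = off_dx(p), py = off_dy(p);
      for (int q = 0; q < 27; ++q) {
        if (!inN18[q] || nb[q] || seen[q]) continue;
        int d = std::abs(off_dz(q) - pz) + std::abs(off_dx(q) - px) +
                std::abs(off_dy(q) - py);
        if (d == 1) {
          seen[q] = true;
          stack[top++] = q;
        }
      }
    }
  }
  return ncomp;
}

static inline void fill_neighbourhood(const std::vector<unsigned char> &v,
                                      int nz, int nx, int ny, int z, int x,
                                      int y, bool nb[27]) {
  for (int dy = -1; dy <= 1; ++dy)
    for (int dx = -1; dx <= 1; ++dx)
      for (int dz = -1; dz <= 1; ++dz) {
        int p = (dz + 1) + 3 * (dx + 1) + 9 * (dy + 1);
        int zz = z + dz, xx = x + dx, yy = y + dy;
        if (zz < 0 || zz >= nz || xx < 0 || xx >= nx || yy < 0 || yy >= ny)
          nb[p] = false;  // outside the array is background
        else
          nb[p] = v[zz + (size_t)nz * (xx + (size_t)nx * yy)] != 0;
      }
}

static inline bool is_simple(const bool nb[27]) {
  return object_components26(nb) == 1 && background_components6(nb) == 1;
}

static inline int n_object_neighbours(const bool nb[27]) {
  int c = 0;
  for (int p = 0; p < 27; ++p)
    if (p != 13 && nb[p]) ++c;
  return c;
}

// ---------------------------------------------------------------------------
// Topology-preserving 3D thinning: 6 directional sub-iterations per cycle,
// sequential deletion of simple, non-endpoint border voxels until stable.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".skeletonize3d_cpp")]]
IntegerVector skeletonize3d_cpp(IntegerVector bin, IntegerVector dims) {
  const int nz = dims[0], nx = dims[1], ny = dims[2];
  std::vector<unsigned char> v(bin.size());
  for (R_xlen_t i = 0; i < bin.size(); ++i) v[i] = bin[i] != 0;

  const int dirs[6][3] = {{-1, 0, 0}, {1, 0, 0}, {0, -1, 0},
                          {0, 1, 0},  {0, 0, -1}, {0, 0, 1}};
  bool nb[27];
  std::vector<int> cand;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      cand.clear();
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x)
          for (int z = 0; z < nz; ++z) {
            size_t i = z + (size_t)nz * (x + (size_t)nx * y);
            if (!v[i]) continue;
            int zz = z + dirs[d][0], xx = x + dirs[d][1], yy = y + dirs[d][2];
            bool border =
                (zz < 0 || zz >= nz || xx < 0 || xx >= nx || yy < 0 ||
                 yy >= ny) ||
                !v[zz + (size_t)nz * (xx + (size_t)nx * yy)];
            if (!border) continue;
            fill_neighbourhood(v, nz, nx, ny, z, x, y, nb);
            if (n_object_neighbours(nb) <= 1) continue;  // endpoint
            if (is_simple(nb)) cand.push_back((int)i);
          }
      // delete sequentially, re-checking so topology is preserved exactly
      for (size_t c = 0; c < cand.size(); ++c) {
        int i = cand[c];
        int z = i % nz, x = (i / nz) % nx, y = i / (nz * nx);
        fill_neighbourhood(v, nz, nx, ny, z, x, y, nb);
        if (n_object_neighbours(nb) <= 1) continue;
        if (is_simple(nb)) {
          v[i] = 0;
          changed = true;
        }
      }
    }
  }
  IntegerVector out(bin.size());
  for (R_xlen_t i = 0; i < bin.size(); ++i) out[i] = v[i];
  out.attr("dim") = dims;
  return out;
}

// ---------------------------------------------------------------------------
// Per-voxel sorted eigenvalues of a symmetric 3x3 matrix field.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".eig_sym3_cpp")]]
List eig_sym3_cpp(NumericVector q11, NumericVector q12, NumericVector q13,
                  NumericVector q22, NumericVector q23, NumericVector q33) {
  const R_xlen_t n = q11.size();
  NumericVector l1(n), l2(n), l3(n);
  arma::mat33 Q;
  arma::vec3 ev;
  for (R_xlen_t i = 0; i < n; ++i) {
    Q(0, 0) = q11[i]; Q(0, 1) = q12[i]; Q(0, 2) = q13[i];
    Q(1, 0) = q12[i]; Q(1, 1) = q22[i]; Q(1, 2) = q23[i];
    Q(2, 0) = q13[i]; Q(2, 1) = q23[i]; Q(2, 2) = q33[i];
    arma::eig_sym(ev, Q);  // ascending
    l1[i] = ev(0); l2[i] = ev(1); l3[i] = ev(2);
  }
  return List::create(_["l1"] = l1, _["l2"] = l2, _["l3"] = l3);
}
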