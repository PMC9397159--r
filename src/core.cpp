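#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Mirror-reflect an index into [0, n). scipy-style 'reflect':
// (d c b a | a b c d | d c b a)
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    else i = 2 * n - i - 1;
  }
  return i;
}

static std::vector<double> gauss_kernel(double sigma, bool peak_norm) {
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> w(2 * r + 1);
  double s = 0.0;
  for (int k = -r; k <= r; ++k) {
    w[k + r] = std::exp(-0.5 * (double)k * (double)k / (sigma * sigma));
    s += w[k + r];
  }
  if (!peak_norm) for (double &x : w) x /= s;
  return w;
}

// Separable Gaussian smoothing of a 3D array (column-major, dim = nx,ny,nz)
// with mirror boundaries. sigma == 0 skips that axis. When peak_norm_z is
// true the z kernel keeps a central weight of 1 (a one-slice-thick sheet
// retains density 1 at its own slice instead of being diluted by the axial
// spread); x and y kernels are always sum-normalized.
// [[Rcpp::export]]
NumericVector cpp_gauss3d(NumericVector arr, IntegerVector dim,
                          double sx, double sy, double sz,
                          bool peak_norm_z = false) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> cur(arr.begin(), arr.end());
  std::vector<double> nxt(n);

  // one 1D pass along an axis with the given stride; lines are gathered into
  // a contiguous buffer so the hot loop is stride-1 with an interior fast
  // path free of boundary handling
  auto pass = [&](double sigma, bool peak_norm, int len, R_xlen_t stride,
                  R_xlen_t n_lines, auto line_base) {
    std::vector<double> w = gauss_kernel(sigma, peak_norm);
    int r = ((int)w.size() - 1) / 2;
    std::vector<double> line(len);
    for (R_xlen_t li = 0; li < n_lines; ++li) {
      R_xlen_t base = line_base(li);
      for (int i = 0; i < len; ++i) line[i] = cur[base + stride * i];
      int lo = std::min(r, len);
      int hi = std::max(lo, len - r);
      for (int i = 0; i < lo; ++i) {
        double acc = 0.0;
        for (int k = -r; k <= r; ++k)
          acc += w[k + r] * line[reflect_idx(i + k, len)];
        nxt[base + stride * i] = acc;
      }
      for (int i = lo; i < hi; ++i) {
        double acc = 0.0;
        const double *p = line.data() + i - r;
        for (int k = 0; k <= 2 * r; ++k) acc += w[k] * p[k];
        nxt[base + stride * i] = acc;
      }
      for (int i = hi; i < len; ++i) {
        double acc = 0.0;
        for (int k = -r; k <= r; ++k)
          acc += w[k + r] * line[reflect_idx(i + k, len)];
        nxt[base + stride * i] = acc;
      }
    }
    std::swap(cur, nxt);
  };

  const R_xlen_t plane = (R_xlen_t)nx * ny;
  if (sx > 0)
    pass(sx, false, nx, 1, (R_xlen_t)ny * nz,
         [&](R_xlen_t li) { return (R_xlen_t)nx * li; });
  if (sy > 0)
    pass(sy, false, ny, nx, (R_xlen_t)nx * nz,
         [&](R_xlen_t li) { return (li % nx) + plane * (li / nx); });
  if (sz > 0)
    pass(sz, peak_norm_z, nz, plane, plane,
         [&](R_xlen_t li) { return li; });

  NumericVector out(n);
  std::copy(cur.begin(), cur.end(), out.begin());
  out.attr("dim") = dim;
  return out;
}

// Axial local maxima with amplitudes. For every (x,y) column, a maximal run
// of equal values [a,b] is a maximum iff it rises on the left (I[a-1] < I[a])
// and drops on the right (I[b+1] < I[b]); the run contributes its first index
// a (so boundary slices are never maxima). The amplitude is
// min(I(p) - I(p1), I(p) - I(p2)) where p1/p2 are the nearest local minima on
// each side, walking while values keep non-increasing; the stack boundary
// counts as a minimum at the boundary value.
// Returns a 5-column matrix: x, y, z (0-based), intensity, amplitude.
// [[Rcpp::export]]
NumericMatrix cpp_z_maxima(NumericVector arr, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t plane = (R_xlen_t)nx * ny;
  std::vector<double> col(nz);
  std::vector<double> rx, ry, rz, ri, ra;

  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = x + (R_xlen_t)nx * y;
      for (int z = 0; z < nz; ++z) col[z] = arr[base + plane * z];
      int a = 0;
      while (a < nz) {
        int b = a;
        while (b + 1 < nz && col[b + 1] == col[a]) ++b;
        bool rises = (a > 0) && (col[a - 1] < col[a]);
        bool drops = (b < nz - 1) && (col[b + 1] < col[b]);
        if (rises && drops) {
          // nearest local minima on each side
          int j = a;
          while (j > 0 && col[j - 1] <= col[j]) --j;
          double leftmin = col[j];
          j = b;
          while (j < nz - 1 && col[j + 1] <= col[j]) ++j;
          double rightmin = col[j];
          double amp = std::min(col[a] - leftmin, col[b] - rightmin);
          rx.push_back((double)x);
          ry.push_back((double)y);
          rz.push_back((double)a);
          ri.push_back(col[a]);
          ra.push_back(amp);
        }
        a = b + 1;
      }
    }

  NumericMatrix out((int)rx.size(), 5);
  for (int i = 0; i < (int)rx.size(); ++i) {
    out(i, 0) = rx[i]; out(i, 1) = ry[i]; out(i, 2) = rz[i];
    out(i, 3) = ri[i]; out(i, 4) = ra[i];
  }
  colnames(out) = CharacterVector::create("x", "y", "z", "intensity", "amplitude");
  return out;
}

// 26-connected component labelling of a 3D logical mask (column-major).
// Returns an integer array of labels (0 = background), labelled in scan order.
// [[Rcpp::export]]
IntegerVector cpp_label26(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;

  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || labels[i] != 0) continue;
    ++next;
    labels[i] = next;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back(); stack.pop_back();
      int x = (int)(cur % nx);
      int y = (int)((cur / nx) % ny);
      int z = (int)(cur / ((R_xlen_t)nx * ny));
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            int xx = x + dx, yy = y + dy, zz = z + dz;
            if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
              continue;
            R_xlen_t j = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
            if (mask[j] && labels[j] == 0) {
              labels[j] = next;
              stack.push_back(j);
            }
          }
    }
  }
  labels.attr("dim") = dim;
  return labels;
}

struct Chain { int id; int last_u; int last_z; };

// Orthogonal surface elements within one section. mask is (nu x nzz),
// rows = in-plane coordinate u, cols = z. Chains are grown column by column:
// a pixel (u,z) continues a chain ending at (u-1, z') when |z - z'| <= 1
// (section 6-connectivity); ambiguous continuations (forks) are resolved
// greedily by smallest |dz|, then smallest pixel z, then smallest chain z;
// a single missing column is bridged only when the flanking pixels share the
// same z. Every pixel joins exactly one chain. Returns an integer label
// matrix (0 = no pixel), labels ordered by chain creation.
// [[Rcpp::export]]
IntegerMatrix cpp_build_oses(LogicalMatrix mask) {
  const int nu = mask.nrow(), nzz = mask.ncol();
  IntegerMatrix labels(nu, nzz);
  std::vector<Chain> chains;   // all chains ever created
  std::vector<int> active;     // indices of chains with last_u >= u-2
  int next_id = 0;

  struct Edge { int dz; int pz; int cz; int ci; int pi; };

  std::vector<int> pix;      // z of pixels in current column
  std::vector<int> pix_chain; // assigned chain index or -1

  for (int u = 0; u < nu; ++u) {
    pix.clear();
    for (int z = 0; z < nzz; ++z) if (mask(u, z)) pix.push_back(z);
    pix_chain.assign(pix.size(), -1);
    std::vector<bool> extended(chains.size(), false);

    if (!pix.empty() && !active.empty()) {
      // direct continuation from column u-1
      std::vector<Edge> edges;
      for (int ci : active) {
        if (chains[ci].last_u != u - 1) continue;
        for (int pi = 0; pi < (int)pix.size(); ++pi) {
          int dz = std::abs(pix[pi] - chains[ci].last_z);
          if (dz <= 1) edges.push_back({dz, pix[pi], chains[ci].last_z, ci, pi});
        }
      }
      std::sort(edges.begin(), edges.end(), [](const Edge &a, const Edge &b) {
        if (a.dz != b.dz) return a.dz < b.dz;
        if (a.pz != b.pz) return a.pz < b.pz;
        return a.cz < b.cz;
      });
      for (const Edge &e : edges) {
        if (extended[e.ci] || pix_chain[e.pi] != -1) continue;
        extended[e.ci] = true;
        pix_chain[e.pi] = e.ci;
        chains[e.ci].last_u = u;
        chains[e.ci].last_z = pix[e.pi];
      }
      // single straight gap from column u-2 (same z required)
      for (int ci : active) {
        if (chains[ci].last_u != u - 2) continue;
        for (int pi = 0; pi < (int)pix.size(); ++pi) {
          if (pix_chain[pi] == -1 && pix[pi] == chains[ci].last_z) {
            pix_chain[pi] = ci;
            chains[ci].last_u = u;
            chains[ci].last_z = pix[pi];
            break;
          }
        }
      }
    }

    // leftovers start new chains (in increasing z for determinism)
    for (int pi = 0; pi < (int)pix.size(); ++pi) {
      if (pix_chain[pi] == -1) {
        chains.push_back({next_id++, u, pix[pi]});
        pix_chain[pi] = (int)chains.size() - 1;
      }
      labels(u, pix[pi]) = chains[pix_chain[pi]].id + 1;
    }

    // refresh active list: chains reachable from column u+1
    active.clear();
    for (int ci = 0; ci < (int)chains.size(); ++ci)
      if (chains[ci].last_u >= u - 1) active.push_back(ci);
  }
  return labels;
}
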