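// 3D image-analysis primitives for anisotropic confocal stacks.
// Arrays are R column-major with dim = (nz, ny, nx); linear index
// i = z + nz*(y + ny*x). All distances are in physical units (um)
// via the per-axis `spacing` arguments. All algorithms visit voxels
// in a fixed scan order so results are reproducible run to run.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <map>
#include <cmath>
#include <limits>
#include <cstdint>

using namespace Rcpp;

static inline int64_t vidx(int z, int y, int x, int nz, int ny) {
  return (int64_t)z + (int64_t)nz * ((int64_t)y + (int64_t)ny * x);
}

// ---------------------------------------------------------------------------
// Separable Gaussian blur, reflecting boundary. sigma given in voxels per axis.
// [[Rcpp::export]]
NumericVector blur3d_cpp(NumericVector img, IntegerVector dim,
                         NumericVector sigma_vox) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int64_t n = (int64_t)nz * ny * nx;
  std::vector<double> src(img.begin(), img.end());
  std::vector<double> dst(n);

  const int cnt[3] = {nz, ny, nx};
  const int64_t strides[3] = {1, (int64_t)nz, (int64_t)nz * ny};

  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma_vox[ax];
    if (s <= 1e-8 || cnt[ax] == 1) continue;
    int rad = (int)std::ceil(3.0 * s);
    std::vector<double> k(2 * rad + 1);
    double ksum = 0.0;
    for (int i = -rad; i <= rad; ++i) {
      k[i + rad] = std::exp(-0.5 * (double)i * i / (s * s));
      ksum += k[i + rad];
    }
    for (double& v : k) v /= ksum;

    const int64_t st = strides[ax];
    const int m = cnt[ax];
    // iterate over all lines along axis `ax`
    const int oax1 = (ax == 0) ? 1 : 0;
    const int oax2 = (ax == 2) ? 1 : 2;
    const int m1 = cnt[oax1], m2 = cnt[oax2];
    const int64_t st1 = strides[oax1], st2 = strides[oax2];
    for (int b = 0; b < m2; ++b) {
      for (int a = 0; a < m1; ++a) {
        const int64_t base = (int64_t)a * st1 + (int64_t)b * st2;
        for (int i = 0; i < m; ++i) {
          double acc = 0.0;
          for (int j = -rad; j <= rad; ++j) {
            int p = i + j;
            if (p < 0) p = -p - 1;            // reflect
            if (p >= m) p = 2 * m - p - 1;
            acc += k[j + rad] * src[base + (int64_t)p * st];
          }
          dst[base + (int64_t)i * st] = acc;
        }
      }
    }
    std::swap(src, dst);
  }
  NumericVector out(src.begin(), src.end());
  out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------------------------------
// Connected-component labelling of a binary mask (connectivity 6 or 26),
// labels assigned in scan order (deterministic).
// [[Rcpp::export]]
IntegerVector cc_label3d_cpp(LogicalVector mask, IntegerVector dim,
                             int connectivity) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int64_t n = (int64_t)nz * ny * nx;
  IntegerVector out(n, 0);
  out.attr("dim") = dim;

  std::vector<int> dz, dy, dx;
  for (int cz = -1; cz <= 1; ++cz)
    for (int cy = -1; cy <= 1; ++cy)
      for (int cx = -1; cx <= 1; ++cx) {
        int ad = std::abs(cz) + std::abs(cy) + std::abs(cx);
        if (ad == 0) continue;
        if (connectivity == 6 && ad != 1) continue;
        dz.push_back(cz); dy.push_back(cy); dx.push_back(cx);
      }
  const int nn = (int)dz.size();

  int lab = 0;
  std::vector<int64_t> stack;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        int64_t i = vidx(z, y, x, nz, ny);
        if (!mask[i] || out[i] != 0) continue;
        ++lab;
        out[i] = lab;
        stack.clear();
        stack.push_back(i);
        while (!stack.empty()) {
          int64_t c = stack.back(); stack.pop_back();
          int cz = (int)(c % nz);
          int64_t r = c / nz;
          int cy = (int)(r % ny);
          int cx = (int)(r / ny);
          for (int q = 0; q < nn; ++q) {
            int pz = cz + dz[q], py = cy + dy[q], px = cx + dx[q];
            if (pz < 0 || pz >= nz || py < 0 || py >= ny || px < 0 || px >= nx)
              continue;
            int64_t j = vidx(pz, py, px, nz, ny);
            if (mask[j] && out[j] == 0) { out[j] = lab; stack.push_back(j); }
          }
        }
      }
  return out;
}

// ---------------------------------------------------------------------------
// Exact Euclidean distance transform (Felzenszwalb-Huttenlocher, separable),
// anisotropic spacing. Returns, for every voxel, the distance in physical
// units to the nearest TRUE voxel of `features`. If no feature exists the
// result is Inf everywhere.
static void dt1d(std::vector<double>& f, int m, double w,
                 std::vector<int>& v, std::vector<double>& zb,
                 std::vector<double>& d) {
  const double INF = std::numeric_limits<double>::infinity();
  int kk = 0;
  v[0] = 0;
  zb[0] = -INF;
  zb[1] = INF;
  for (int q = 1; q < m; ++q) {
    if (f[q] == INF) continue;
    if (f[v[kk]] == INF) { v[kk] = q; continue; }
    double s;
    while (true) {
      double xq = q * w, xv = v[kk] * w;
      s = ((f[q] + xq * xq) - (f[v[kk]] + xv * xv)) / (2 * xq - 2 * xv);
      if (s <= zb[kk]) { --kk; } else break;
    }
    ++kk;
    v[kk] = q;
    zb[kk] = s;
    zb[kk + 1] = INF;
  }
  if (f[v[0]] == INF) { for (int q = 0; q < m; ++q) d[q] = INF; return; }
  int k2 = 0;
  for (int q = 0; q < m; ++q) {
    double xq = q * w;
    while (zb[k2 + 1] < xq) ++k2;
    double dxv = xq - v[k2] * w;
    d[q] = dxv * dxv + f[v[k2]];
  }
}

// [[Rcpp::export]]
NumericVector edt3d_cpp(LogicalVector features, IntegerVector dim,
                        NumericVector spacing) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int64_t n = (int64_t)nz * ny * nx;
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> g(n);
  for (int64_t i = 0; i < n; ++i) g[i] = features[i] ? 0.0 : INF;

  const int cnt[3] = {nz, ny, nx};
  const int64_t strides[3] = {1, (int64_t)nz, (int64_t)nz * ny};
  int mmax = std::max(nz, std::max(ny, nx));
  std::vector<double> f(mmax), d(mmax), zb(mmax + 1);
  std::vector<int> v(mmax);

  for (int ax = 0; ax < 3; ++ax) {
    const int m = cnt[ax];
    if (m == 1) continue;
    const double w = spacing[ax];
    const int oax1 = (ax == 0) ? 1 : 0;
    const int oax2 = (ax == 2) ? 1 : 2;
    const int m1 = cnt[oax1], m2 = cnt[oax2];
    const int64_t st = strides[ax], st1 = strides[oax1], st2 = strides[oax2];
    for (int b = 0; b < m2; ++b)
      for (int a = 0; a < m1; ++a) {
        const int64_t base = (int64_t)a * st1 + (int64_t)b * st2;
        for (int i = 0; i < m; ++i) f[i] = g[base + (int64_t)i * st];
        dt1d(f, m, w, v, zb, d);
        for (int i = 0; i < m; ++i) g[base + (int64_t)i * st] = d[i];
      }
  }
  NumericVector out(n);
  for (int64_t i = 0; i < n; ++i)
    out[i] = std::isinf(g[i]) ? g[i] : std::sqrt(g[i]);
  out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------------------------------
// Grayscale reconstruction by dilation (Vincent's hybrid algorithm),
// 6-connectivity. marker must be <= mask everywhere (clamped here).
// [[Rcpp::export]]
NumericVector grey_reconstruct3d_cpp(NumericVector marker, NumericVector mask,
                                     IntegerVector dim) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int64_t n = (int64_t)nz * ny * nx;
  std::vector<double> J(n);
  for (int64_t i = 0; i < n; ++i) J[i] = std::min(marker[i], mask[i]);

  // forward raster scan: neighbours preceding in scan order (z-1, y-1, x-1)
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        int64_t i = vidx(z, y, x, nz, ny);
        double m = J[i];
        if (z > 0) m = std::max(m, J[i - 1]);
        if (y > 0) m = std::max(m, J[i - nz]);
        if (x > 0) m = std::max(m, J[i - (int64_t)nz * ny]);
        J[i] = std::min(m, mask[i]);
      }
  // backward raster scan + queue seeding
  std::queue<int64_t> fifo;
  for (int x = nx - 1; x >= 0; --x)
    for (int y = ny - 1; y >= 0; --y)
      for (int z = nz - 1; z >= 0; --z) {
        int64_t i = vidx(z, y, x, nz, ny);
        double m = J[i];
        if (z < nz - 1) m = std::max(m, J[i + 1]);
        if (y < ny - 1) m = std::max(m, J[i + nz]);
        if (x < nx - 1) m = std::max(m, J[i + (int64_t)nz * ny]);
        J[i] = std::min(m, mask[i]);
        // enqueue if a succeeding neighbour could still be raised
        bool enq = false;
        if (z < nz - 1 && J[i + 1] < J[i] && J[i + 1] < mask[i + 1]) enq = true;
        if (!enq && y < ny - 1 && J[i + nz] < J[i] && J[i + nz] < mask[i + nz]) enq = true;
        if (!enq && x < nx - 1) {
          int64_t j = i + (int64_t)nz * ny;
          if (J[j] < J[i] && J[j] < mask[j]) enq = true;
        }
        if (enq) fifo.push(i);
      }
  const int dz6[6] = {-1, 1, 0, 0, 0, 0};
  const int dy6[6] = {0, 0, -1, 1, 0, 0};
  const int dx6[6] = {0, 0, 0, 0, -1, 1};
  while (!fifo.empty()) {
    int64_t i = fifo.front(); fifo.pop();
    int z = (int)(i % nz);
    int64_t r = i / nz;
    int y = (int)(r % ny);
    int x = (int)(r / ny);
    for (int q = 0; q < 6; ++q) {
      int pz = z + dz6[q], py = y + dy6[q], px = x + dx6[q];
      if (pz < 0 || pz >= nz || py < 0 || py >= ny || px < 0 || px >= nx)
        continue;
      int64_t j = vidx(pz, py, px, nz, ny);
      if (J[j] < J[i] && mask[j] != J[j]) {
        J[j] = std::min(J[i], mask[j]);
        fifo.push(j);
      }
    }
  }
  NumericVector out(J.begin(), J.end());
  out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------------------------------
// Marker-controlled watershed by priority flooding (6-connectivity).
// Seeds grow over `mask` in order of increasing `elev`; FIFO tie-break on
// insertion order makes the result deterministic.
struct WsItem {
  double prio;
  uint64_t order;
  int64_t idx;
  int label;
};
struct WsCmp {
  bool operator()(const WsItem& a, const WsItem& b) const {
    if (a.prio != b.prio) return a.prio > b.prio;
    return a.order > b.order;
  }
};

// [[Rcpp::export]]
IntegerVector watershed3d_cpp(NumericVector elev, IntegerVector seeds,
                              LogicalVector mask, IntegerVector dim) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int64_t n = (int64_t)nz * ny * nx;
  IntegerVector out(n);
  out.attr("dim") = dim;
  for (int64_t i = 0; i < n; ++i) out[i] = seeds[i];

  std::priority_queue<WsItem, std::vector<WsItem>, WsCmp> pq;
  uint64_t counter = 0;
  const int dz6[6] = {-1, 1, 0, 0, 0, 0};
  const int dy6[6] = {0, 0, -1, 1, 0, 0};
  const int dx6[6] = {0, 0, 0, 0, -1, 1};

  auto push_nbrs = [&](int64_t i, int label) {
    int z = (int)(i % nz);
    int64_t r = i / nz;
    int y = (int)(r % ny);
    int x = (int)(r / ny);
    for (int q = 0; q < 6; ++q) {
      int pz = z + dz6[q], py = y + dy6[q], px = x + dx6[q];
      if (pz < 0 || pz >= nz || py < 0 || py >= ny || px < 0 || px >= nx)
        continue;
      int64_t j = vidx(pz, py, px, nz, ny);
      if (mask[j] && out[j] == 0)
        pq.push({elev[j], counter++, j, label});
    }
  };

  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        int64_t i = vidx(z, y, x, nz, ny);
        if (seeds[i] > 0) push_nbrs(i, seeds[i]);
      }

  while (!pq.empty()) {
    WsItem it = pq.top(); pq.pop();
    if (out[it.idx] != 0) continue;
    out[it.idx] = it.label;
    push_nbrs(it.idx, it.label);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Mean intensity over shared interfaces of adjacent label pairs
// (6-connectivity faces; intensity of a face = mean of its two voxels).
// [[Rcpp::export]]
DataFrame interface_means3d_cpp(IntegerVector labels, NumericVector intensity,
                                IntegerVector dim) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  std::map<std::pair<int, int>, std::pair<int64_t, double>> acc;
  auto note = [&](int64_t i, int64_t j) {
    int a = labels[i], b = labels[j];
    if (a <= 0 || b <= 0 || a == b) return;
    if (a > b) std::swap(a, b);
    auto& e = acc[{a, b}];
    e.first += 1;
    e.second += 0.5 * (intensity[i] + intensity[j]);
  };
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        int64_t i = vidx(z, y, x, nz, ny);
        if (labels[i] <= 0) continue;
        if (z + 1 < nz) note(i, i + 1);
        if (y + 1 < ny) note(i, i + nz);
        if (x + 1 < nx) note(i, i + (int64_t)nz * ny);
      }
  int m = (int)acc.size();
  IntegerVector a(m), b(m), cntv(m);
  NumericVector mn(m);
  int k = 0;
  for (auto& kv : acc) {
    a[k] = kv.first.first;
    b[k] = kv.first.second;
    cntv[k] = (int)kv.second.first;
    mn[k] = kv.second.second / kv.second.first;
    ++k;
  }
  return DataFrame::create(_["a"] = a, _["b"] = b, _["n_faces"] = cntv,
                           _["mean_intensity"] = mn);
}

// ---------------------------------------------------------------------------
// Per-label surface accounting: for every boundary face of a label (neighbour
// missing, background, or different label), whether the facing voxel carries
// above-threshold membrane signal. Faces on the stack border count as
// uncovered. Returns one row per label id present.
// [[Rcpp::export]]
DataFrame surface_coverage3d_cpp(IntegerVector labels, LogicalVector covered,
                                 IntegerVector dim, int max_label) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<int64_t> total(max_label + 1, 0), cov(max_label + 1, 0);
  const int dz6[6] = {-1, 1, 0, 0, 0, 0};
  const int dy6[6] = {0, 0, -1, 1, 0, 0};
  const int dx6[6] = {0, 0, 0, 0, -1, 1};
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        int64_t i = vidx(z, y, x, nz, ny);
        int lab = labels[i];
        if (lab <= 0 || lab > max_label) continue;
        for (int q = 0; q < 6; ++q) {
          int pz = z + dz6[q], py = y + dy6[q], px = x + dx6[q];
          if (pz < 0 || pz >= nz || py < 0 || py >= ny || px < 0 || px >= nx) {
            total[lab]++;
            continue;
          }
          int64_t j = vidx(pz, py, px, nz, ny);
          if (labels[j] == lab) continue;
          total[lab]++;
          if (covered[j]) cov[lab]++;
        }
      }
  IntegerVector id(max_label);
  NumericVector tt(max_label), cc(max_label);
  for (int l = 1; l <= max_label; ++l) {
    id[l - 1] = l;
    tt[l - 1] = (double)total[l];
    cc[l - 1] = (double)cov[l];
  }
  return DataFrame::create(_["id"] = id, _["boundary_faces"] = tt,
                           _["covered_faces"] = cc);
}

// ---------------------------------------------------------------------------
// For each nucleus label: count voxels of its 1-voxel (6-connectivity)
// dilation shell, and how many of those lie in a given cell label.
// own_cell is 1-indexed by nucleus id (0 = no owner).
// [[Rcpp::export]]
DataFrame nucleus_shell_counts_cpp(IntegerVector nuc, IntegerVector cells,
                                   IntegerVector dim, IntegerVector own_cell) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int max_n = own_cell.size();
  std::vector<int64_t> shell(max_n + 1, 0), inside(max_n + 1, 0);
  const int dz6[6] = {-1, 1, 0, 0, 0, 0};
  const int dy6[6] = {0, 0, -1, 1, 0, 0};
  const int dx6[6] = {0, 0, 0, 0, -1, 1};
  // a shell voxel of nucleus n: not labelled n, 6-adjacent to a voxel of n;
  // counted once per distinct adjacent nucleus.
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        int64_t i = vidx(z, y, x, nz, ny);
        int here = nuc[i];
        int seen[6]; int nseen = 0;
        for (int q = 0; q < 6; ++q) {
          int pz = z + dz6[q], py = y + dy6[q], px = x + dx6[q];
          if (pz < 0 || pz >= nz || py < 0 || py >= ny || px < 0 || px >= nx)
            continue;
          int64_t j = vidx(pz, py, px, nz, ny);
          int lab = nuc[j];
          if (lab <= 0 || lab == here || lab > max_n) continue;
          bool dup = false;
          for (int t = 0; t < nseen; ++t) if (seen[t] == lab) { dup = true; break; }
          if (dup) continue;
          seen[nseen++] = lab;
          shell[lab]++;
          if (own_cell[lab - 1] > 0 && cells[i] == own_cell[lab - 1]) inside[lab]++;
        }
      }
  IntegerVector id(max_n);
  NumericVector sh(max_n), in(max_n);
  for (int l = 1; l <= max_n; ++l) {
    id[l - 1] = l;
    sh[l - 1] = (double)shell[l];
    in[l - 1] = (double)inside[l];
  }
  return DataFrame::create(_["id"] = id, _["shell_voxels"] = sh,
                           _["shell_in_cell"] = in);
}
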