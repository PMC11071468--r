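#include "lattice.h"
using namespace Rcpp;

// Connectivity within a <= 27-voxel patch uses Moore adjacency: two member
// voxels are adjacent iff they differ by <= 1 on every axis.
static int patch_components(const std::vector<int> &vox, const Grid &g) {
  int m = (int)vox.size();
  if (m == 0) return 0;
  std::vector<int> comp(m, -1);
  int ncomp = 0;
  std::vector<int> stack;
  std::vector<long> cx(m), cy(m), cz(m);
  for (int i = 0; i < m; ++i) {
    int x, y, z; g.coords(vox[i], x, y, z);
    cx[i] = x; cy[i] = y; cz[i] = z;
  }
  for (int i = 0; i < m; ++i) {
    if (comp[i] >= 0) continue;
    comp[i] = ncomp;
    stack.push_back(i);
    while (!stack.empty()) {
      int a = stack.back(); stack.pop_back();
      for (int b = 0; b < m; ++b) {
        if (comp[b] >= 0) continue;
        if (std::labs(cx[a] - cx[b]) <= 1 && std::labs(cy[a] - cy[b]) <= 1 &&
            std::labs(cz[a] - cz[b]) <= 1) {
          comp[b] = ncomp;
          stack.push_back(b);
        }
      }
    }
    ++ncomp;
  }
  return ncomp;
}

bool local_articulation(const int *state, const Grid &g, int j, int label) {
  int buf[26];
  int k = g.moore_neighbors(j, buf);
  std::vector<int> members;
  members.reserve(27);
  for (int t = 0; t < k; ++t)
    if (state[buf[t]] == label) members.push_back(buf[t]);
  int without_j = patch_components(members, g);
  members.push_back(j);
  int with_j = patch_components(members, g);
  return with_j != without_j;
}

// [[Rcpp::export(name = ".is_articulation_cpp")]]
bool is_articulation_cpp(IntegerVector state, IntegerVector dims, int j, int label) {
  Grid g(dims[0], dims[1], dims[2]);
  if (j < 0 || j >= g.n()) stop("voxel index out of bounds");
  if (label <= 0) stop("label must be a positive cell id");
  return local_articulation(INTEGER(state), g, j, label);
}

// Moore-connected component count for every cell id in 1..n (global flood fill).
// [[Rcpp::export(name = ".cell_component_counts_cpp")]]
IntegerVector cell_component_counts_cpp(IntegerVector state, IntegerVector dims, int n) {
  Grid g(dims[0], dims[1], dims[2]);
  int N = g.n();
  const int *s = INTEGER(state);
  IntegerVector out(n);
  std::vector<char> seen(N, 0);
  std::vector<int> stack;
  int buf[26];
  for (int v = 0; v < N; ++v) {
    int c = s[v];
    if (c <= 0 || seen[v]) continue;
    out[c - 1] += 1;
    seen[v] = 1;
    stack.push_back(v);
    while (!stack.empty()) {
      int a = stack.back(); stack.pop_back();
      int k = g.moore_neighbors(a, buf);
      for (int t = 0; t < k; ++t) {
        int u = buf[t];
        if (!seen[u] && s[u] == c) { seen[u] = 1; stack.push_back(u); }
      }
    }
  }
  return out;
}

// Keep only the largest Moore-connected component of each cell; the rest of
// that cell's voxels become unassigned (0).  Ties go to the component whose
// smallest voxel index is smallest (deterministic).
// [[Rcpp::export(name = ".largest_component_filter_cpp")]]
IntegerVector largest_component_filter_cpp(IntegerVector state, IntegerVector dims, int n) {
  Grid g(dims[0], dims[1], dims[2]);
  int N = g.n();
  IntegerVector out = clone(state);
  int *s = INTEGER(out);
  std::vector<int> compid(N, -1);
  std::vector<int> compsize, compcell, compmin;
  std::vector<int> stack;
  int buf[26];
  int ncomp = 0;
  for (int v = 0; v < N; ++v) {
    int c = s[v];
    if (c <= 0 || compid[v] >= 0) continue;
    int sz = 0, mn = v;
    compid[v] = ncomp;
    stack.push_back(v);
    while (!stack.empty()) {
      int a = stack.back(); stack.pop_back();
      ++sz;
      int k = g.moore_neighbors(a, buf);
      for (int t = 0; t < k; ++t) {
        int u = buf[t];
        if (compid[u] < 0 && s[u] == c) { compid[u] = ncomp; stack.push_back(u); }
      }
    }
    compsize.push_back(sz);
    compcell.push_back(c);
    compmin.push_back(mn);
    ++ncomp;
  }
  // best component per cell
  std::vector<int> best(n, -1);
  for (int i = 0; i < ncomp; ++i) {
    int c = compcell[i] - 1;
    if (best[c] < 0 || compsize[i] > compsize[best[c]] ||
        (compsize[i] == compsize[best[c]] && compmin[i] < compmin[best[c]]))
      best[c] = i;
  }
  for (int v = 0; v < N; ++v)
    if (s[v] > 0 && compid[v] != best[s[v] - 1]) s[v] = 0;
  return out;
}

// Ordered mismatched von Neumann pairs (i, j), 0-based, as a 2-column matrix.
// [[Rcpp::export(name = ".edge_pool_cpp")]]
IntegerMatrix edge_pool_cpp(IntegerVector state, IntegerVector dims) {
  Grid g(dims[0], dims[1], dims[2]);
  int N = g.n();
  const int *s = INTEGER(state);
  std::vector<int> from, to;
  int buf[6];
  for (int v = 0; v < N; ++v) {
    int k = g.vn_neighbors(v, buf);
    for (int t = 0; t < k; ++t)
      if (s[v] != s[buf[t]]) { from.push_back(v); to.push_back(buf[t]); }
  }
  IntegerMatrix out(from.size(), 2);
  for (size_t i = 0; i < from.size(); ++i) { out(i, 0) = from[i]; out(i, 1) = to[i]; }
  return out;
}

// Per-cell, per-z-layer voxel counts and raw perimeter tallies.
// Raw perimeter of (c, z) = sum over voxels of c in layer z of the number of
// in-plane Moore neighbors not belonging to c (in-bounds neighbors only).
// [[Rcpp::export(name = ".layer_tallies_cpp")]]
List layer_tallies_cpp(IntegerVector state, IntegerVector dims, int n) {
  Grid g(dims[0], dims[1], dims[2]);
  int N = g.n();
  const int *s = INTEGER(state);
  IntegerMatrix vol(n, g.nz), per(n, g.nz);
  int buf[8];
  for (int v = 0; v < N; ++v) {
    int c = s[v];
    if (c <= 0) continue;
    int x, y, z; g.coords(v, x, y, z);
    vol(c - 1, z) += 1;
    int k = g.inplane_neighbors(v, buf);
    int mism = 0;
    for (int t = 0; t < k; ++t)
      if (s[buf[t]] != c) ++mism;
    per(c - 1, z) += mism;
  }
  return List::create(_["layer_volume"] = vol, _["layer_perimeter_raw"] = per);
}
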