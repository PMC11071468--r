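#include "lattice.h"
#include <unordered_map>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Edge pool: every ordered von-Neumann pair (a, b) with state[a] != state[b].
// O(1) insert/remove/uniform-draw via swap-with-last + hash position map.
// ---------------------------------------------------------------------------
struct EdgePool {
  std::vector<long long> edges;
  std::unordered_map<long long, int> pos;
  long long N;
  explicit EdgePool(long long N_) : N(N_) {}
  inline long long key(int a, int b) const { return (long long)a * N + b; }
  inline void decode(long long k, int &a, int &b) const { a = (int)(k / N); b = (int)(k % N); }
  inline bool has(int a, int b) const { return pos.count(key(a, b)) > 0; }
  void add(int a, int b) {
    long long k = key(a, b);
    if (pos.count(k)) return;
    pos[k] = (int)edges.size();
    edges.push_back(k);
  }
  void remove(int a, int b) {
    long long k = key(a, b);
    auto it = pos.find(k);
    if (it == pos.end()) return;
    int i = it->second;
    long long last = edges.back();
    edges[i] = last;
    pos[last] = i;
    edges.pop_back();
    pos.erase(it);
  }
  inline int size() const { return (int)edges.size(); }
};

static inline double ln_lognormal(double v, double mu, double prec) {
  double d = std::log(v) - mu;
  return -std::log(v) + 0.5 * std::log(prec) - 0.5 * prec * d * d;
}

// ---------------------------------------------------------------------------
// Metropolis-Hastings boundary sampling.
//
// state       voxel states (0 = unassigned), modified copy returned
// tvox/tgene/tnuc  per-transcript voxel (0-based), gene (0-based),
//                  nuclear label (0 = none)
// tau         m x n cell rate matrix (transcripts / um^3)
// taubg       m background rates
// cell_z, mu_vol, prec_vol  volume-model terms (log-normal by component)
// bin_size    checkerboard bin edge in voxels (0 disables phase cycling)
// phase_len   proposals evaluated per phase before advancing
// record_base if > 0, tally visited states encoded in base (n_cells + 1)
//             (requires record_base^N to fit the tally vector; tiny toys only)
// ---------------------------------------------------------------------------
// [[Rcpp::export(name = ".run_sweeps_cpp")]]
List run_sweeps_cpp(IntegerVector state_in, IntegerVector dims,
                    NumericVector voxel_size, int n_cells,
                    IntegerVector tvox, IntegerVector tgene, IntegerVector tnuc,
                    NumericMatrix tau, NumericVector taubg,
                    IntegerVector cell_z, NumericVector mu_vol, NumericVector prec_vol,
                    bool use_volume_prior,
                    double p_nuc, double bubble_prob, double b_factor, double xi,
                    int n_proposals,
                    int bin_size, int phase_len,
                    bool use_qratio, bool use_articulation, bool check_perimeter,
                    bool record_states) {
  Grid g(dims[0], dims[1], dims[2]);
  const int N = g.n();
  IntegerVector state_out = clone(state_in);
  int *state = INTEGER(state_out);
  const int m = tau.nrow();
  const double vx = voxel_size[0], vy = voxel_size[1], vz = voxel_size[2];
  const double bvol = vx * vy * vz;
  const double unit = std::sqrt(vx * vy);     // in-plane voxel edge (um)
  const double area1 = vx * vy;               // in-plane voxel area (um^2)

  // per-cell voxel counts
  std::vector<long> cellvox(n_cells, 0);
  for (int v = 0; v < N; ++v)
    if (state[v] > 0) cellvox[state[v] - 1] += 1;

  // per-cell per-layer volume and raw perimeter tallies
  std::vector<long> lvol((size_t)n_cells * g.nz, 0), lper((size_t)n_cells * g.nz, 0);
  {
    int buf[8];
    for (int v = 0; v < N; ++v) {
      int c = state[v];
      if (c <= 0) continue;
      int x, y, z; g.coords(v, x, y, z);
      lvol[(size_t)(c - 1) * g.nz + z] += 1;
      int k = g.inplane_neighbors(v, buf), mism = 0;
      for (int t = 0; t < k; ++t) if (state[buf[t]] != c) ++mism;
      lper[(size_t)(c - 1) * g.nz + z] += mism;
    }
  }

  // rate column sums (index 0 = unassigned = 0)
  std::vector<double> tau_colsum(n_cells + 1, 0.0);
  for (int c = 0; c < n_cells; ++c) {
    double s = 0.0;
    for (int gidx = 0; gidx < m; ++gidx) s += tau(gidx, c);
    tau_colsum[c + 1] = s;
  }

  // transcripts bucketed by voxel (CSR)
  const int M = tvox.size();
  std::vector<int> bstart(N + 1, 0), bitems(M);
  for (int t = 0; t < M; ++t) bstart[tvox[t] + 1] += 1;
  for (int v = 0; v < N; ++v) bstart[v + 1] += bstart[v];
  {
    std::vector<int> cur(bstart.begin(), bstart.end() - 1);
    for (int t = 0; t < M; ++t) bitems[cur[tvox[t]]++] = t;
  }

  // edge pool
  EdgePool pool((long long)N);
  {
    int buf[6];
    for (int v = 0; v < N; ++v) {
      int k = g.vn_neighbors(v, buf);
      for (int t = 0; t < k; ++t)
        if (state[v] != state[buf[t]]) pool.add(v, buf[t]);
    }
  }

  // checkerboard phases: phase of voxel = (x / bin) %% 2 + 2 * ((y / bin) %% 2)
  const bool phase_on = bin_size > 0;
  auto phase_of = [&](int v) {
    int x, y, z; g.coords(v, x, y, z);
    return (x / bin_size) % 2 + 2 * ((y / bin_size) % 2);
  };
  int cur_phase = 0, in_phase = 0, phase_seq = 1;
  long eligible = 0;
  auto recount_eligible = [&]() {
    eligible = 0;
    for (auto k : pool.edges) {
      int a, b; pool.decode(k, a, b);
      if (phase_of(b) == cur_phase) ++eligible;
    }
  };
  if (phase_on) recount_eligible();
  std::vector<int> cellstamp(n_cells, 0);
  long conflicts = 0;

  // state-visit tallies (tiny enumerable toys only)
  NumericVector visits(0);
  long long code_n = 0;
  const long long base = n_cells + 1;
  if (record_states) {
    double total = 1.0;
    for (int v = 0; v < N; ++v) total *= (double)base;
    if (total > 2e7) stop("state space too large to record visits");
    code_n = (long long)total;
    visits = NumericVector((R_xlen_t)code_n);
  }
  auto encode = [&]() {
    long long c = 0;
    for (int v = N - 1; v >= 0; --v) c = c * base + state[v];
    return c;
  };

  long accepted = 0, done = 0;
  int nb[6];

  for (int it = 0; it < n_proposals; ++it) {
    if (pool.size() == 0) break;
    if (phase_on) {
      int guard = 0;
      while (eligible == 0 && guard < 4) {
        cur_phase = (cur_phase + 1) % 4; ++phase_seq; in_phase = 0;
        recount_eligible(); ++guard;
      }
      if (eligible == 0) break;
      if (in_phase >= phase_len) {
        cur_phase = (cur_phase + 1) % 4; ++phase_seq; in_phase = 0;
        recount_eligible();
        continue;  // re-enter with fresh phase
      }
      ++in_phase;
    }
    ++done;

    // select edge (uniform over pool, or over in-phase targets)
    int a = -1, b = -1;
    for (;;) {
      int idx = (int)(unif_rand() * pool.size());
      if (idx >= pool.size()) idx = pool.size() - 1;
      pool.decode(pool.edges[idx], a, b);
      if (!phase_on || phase_of(b) == cur_phase) break;
    }

    bool bubble = unif_rand() < bubble_prob;
    int s_old = state[b];
    int s_new = bubble ? 0 : state[a];
    if (record_states && s_new == s_old) { visits[encode()] += 1; continue; }
    if (s_new == s_old) continue;  // bubble onto an already-unassigned voxel

    // conflict tracking: proposals within one phase touching the same cell
    if (phase_on) {
      if (s_old > 0) {
        if (cellstamp[s_old - 1] == phase_seq) ++conflicts;
        cellstamp[s_old - 1] = phase_seq;
      }
      if (s_new > 0) {
        if (cellstamp[s_new - 1] == phase_seq) ++conflicts;
        cellstamp[s_new - 1] = phase_seq;
      }
    }

    bool reject = false;

    // annihilation prohibition: never empty a cell
    if (s_old > 0 && cellvox[s_old - 1] == 1) reject = true;

    // local-connectivity (articulation) pre-rejection for non-empty labels
    if (!reject && use_articulation) {
      if (s_old > 0 && local_articulation(state, g, b, s_old)) reject = true;
      if (!reject && s_new > 0 && local_articulation(state, g, b, s_new)) reject = true;
    }

    int x, y, z; g.coords(b, x, y, z);
    int ip[8];
    int kip = g.inplane_neighbors(b, ip);
    int same_old = 0, same_new = 0;
    for (int t = 0; t < kip; ++t) {
      if (state[ip[t]] == s_old) ++same_old;
      if (state[ip[t]] == s_new) ++same_new;
    }
    long dper_old = -(kip - same_old) + same_old;  // if s_old loses b
    long dper_new = (kip - same_new) - same_new;   // if s_new gains b

    // hard perimeter-to-volume constraint on the resulting state.  A state
    // can start slightly over the bound after a resolution doubling (the
    // mismatch tally of a rough boundary is not exactly scale-invariant);
    // moves that strictly reduce the excess are allowed so cells relax back
    // under the bound, which leaves the valid set closed and its sampling
    // unchanged.
    if (!reject && check_perimeter) {
      auto excess = [&](long nv, long np) {
        if (nv <= 0) return -1.0;
        return xi * (double)np * unit -
               b_factor * 2.0 * std::sqrt(M_PI * nv * area1);
      };
      if (s_old > 0) {
        size_t o = (size_t)(s_old - 1) * g.nz + z;
        double enew = excess(lvol[o] - 1, lper[o] + dper_old);
        if (enew > 0 && enew >= excess(lvol[o], lper[o])) reject = true;
      }
      if (!reject && s_new > 0) {
        size_t o = (size_t)(s_new - 1) * g.nz + z;
        double enew = excess(lvol[o] + 1, lper[o] + dper_new);
        if (enew > 0 && enew >= excess(lvol[o], lper[o])) reject = true;
      }
    }

    double logr = 0.0;
    if (!reject) {
      // exposure terms (background exposure is constant in sigma)
      logr += bvol * (tau_colsum[s_old] - tau_colsum[s_new]);
      // point terms + nuclear prior for transcripts in voxel b
      for (int q = bstart[b]; q < bstart[b + 1]; ++q) {
        int t = bitems[q], gi = tgene[t];
        double rn = taubg[gi] + (s_new > 0 ? tau(gi, s_new - 1) : 0.0);
        double ro = taubg[gi] + (s_old > 0 ? tau(gi, s_old - 1) : 0.0);
        logr += std::log(rn) - std::log(ro);
        int L = tnuc[t];
        if (L > 0) {
          double pn = (s_new == L) ? p_nuc : 1.0 - p_nuc;
          double po = (s_old == L) ? p_nuc : 1.0 - p_nuc;
          logr += std::log(pn) - std::log(po);
        }
      }
      // per-component log-normal volume prior
      if (use_volume_prior) {
        if (s_old > 0) {
          int t = cell_z[s_old - 1] - 1;
          double v = cellvox[s_old - 1] * bvol;
          logr += ln_lognormal(v - bvol, mu_vol[t], prec_vol[t]) -
                  ln_lognormal(v, mu_vol[t], prec_vol[t]);
        }
        if (s_new > 0) {
          int t = cell_z[s_new - 1] - 1;
          double v = cellvox[s_new - 1] * bvol;
          logr += ln_lognormal(v + bvol, mu_vol[t], prec_vol[t]) -
                  ln_lognormal(v, mu_vol[t], prec_vol[t]);
        }
      }

      // proposal-density ratio q(sigma | sigma') / q(sigma' | sigma)
      int kvn = g.vn_neighbors(b, nb);
      int deg_old = 0, deg_new = 0, ncopy_new = 0, ncopy_old = 0;
      long delig = 0;
      bool bphase = !phase_on || true;  // b is always in the current phase when drawn
      (void)bphase;
      for (int t = 0; t < kvn; ++t) {
        int su = state[nb[t]];
        if (su != s_old) ++deg_old;
        if (su != s_new) ++deg_new;
        if (su == s_new) ++ncopy_new;
        if (su == s_old) ++ncopy_old;
        if (phase_on) {
          int before = (su != s_old), after = (su != s_new);
          int d = after - before;
          if (d != 0) {
            int w = 1 + (phase_of(nb[t]) == cur_phase ? 1 : 0);
            delig += d * w;
          }
        }
      }
      double num_fwd = (1.0 - bubble_prob) * ncopy_new +
                       (s_new == 0 ? bubble_prob * deg_old : 0.0);
      double num_rev = (1.0 - bubble_prob) * ncopy_old +
                       (s_old == 0 ? bubble_prob * deg_new : 0.0);
      if (use_qratio) {
        if (num_rev <= 0.0) {
          reject = true;  // irreversible move
        } else {
          double E_fwd = phase_on ? (double)eligible : (double)pool.size();
          double E_rev = phase_on ? (double)(eligible + delig)
                                  : (double)(pool.size() + 2 * (deg_new - deg_old));
          logr += std::log(num_rev) - std::log(num_fwd) + std::log(E_fwd) - std::log(E_rev);
        }
      }
    }

    if (!reject && (logr >= 0.0 || std::log(unif_rand()) < logr)) {
      // apply flip
      state[b] = s_new;
      if (s_old > 0) {
        cellvox[s_old - 1] -= 1;
        size_t o = (size_t)(s_old - 1) * g.nz + z;
        lvol[o] -= 1; lper[o] += dper_old;
      }
      if (s_new > 0) {
        cellvox[s_new - 1] += 1;
        size_t o = (size_t)(s_new - 1) * g.nz + z;
        lvol[o] += 1; lper[o] += dper_new;
      }
      int kvn = g.vn_neighbors(b, nb);
      for (int t = 0; t < kvn; ++t) {
        int u = nb[t], su = state[u];
        bool before = (su != s_old), after = (su != s_new);
        if (before && !after) {
          pool.remove(b, u); pool.remove(u, b);
          if (phase_on) {
            if (phase_of(u) == cur_phase) --eligible;
            --eligible;  // edge (u, b): target b is in the current phase
          }
        } else if (!before && after) {
          pool.add(b, u); pool.add(u, b);
          if (phase_on) {
            if (phase_of(u) == cur_phase) ++eligible;
            ++eligible;
          }
        }
      }
      ++accepted;
    }
    if (record_states) visits[encode()] += 1;
  }

  IntegerMatrix lvol_out(n_cells, g.nz), lper_out(n_cells, g.nz);
  for (int c = 0; c < n_cells; ++c)
    for (int zz = 0; zz < g.nz; ++zz) {
      lvol_out(c, zz) = (int)lvol[(size_t)c * g.nz + zz];
      lper_out(c, zz) = (int)lper[(size_t)c * g.nz + zz];
    }
  IntegerVector cv(n_cells);
  for (int c = 0; c < n_cells; ++c) cv[c] = (int)cellvox[c];

  return List::create(
      _["state"] = state_out, _["accepted"] = (double)accepted,
      _["proposed"] = (double)done, _["conflicts"] = (double)conflicts,
      _["cell_voxels"] = cv, _["layer_volume"] = lvol_out,
      _["layer_perimeter_raw"] = lper_out,
      _["visits"] = record_states ? (SEXP)visits : R_NilValue);
}

// ---------------------------------------------------------------------------
// Transcript repositioning sweep.  Symmetric Gaussian random-walk proposal on
// the latent position; accepted with the Normal-mixture diffusion prior ratio
// times the Poisson point-term ratio.  Proposals leaving the lattice are
// rejected.  Returns updated positions and voxel assignments.
// ---------------------------------------------------------------------------
// [[Rcpp::export(name = ".reposition_sweep_cpp")]]
List reposition_sweep_cpp(NumericMatrix pos_in, NumericMatrix obs,
                          IntegerVector tgene, IntegerVector tvox_in,
                          IntegerVector state, IntegerVector dims,
                          NumericVector origin, NumericVector voxel_size,
                          NumericMatrix tau, NumericVector taubg,
                          double rho, double sig_a, double sig_b,
                          double sd_xy, double sd_z) {
  Grid g(dims[0], dims[1], dims[2]);
  NumericMatrix pos = clone(pos_in);
  IntegerVector tvox = clone(tvox_in);
  const int M = pos.nrow();
  const int *st = INTEGER(state);
  const double hx = origin[0] + dims[0] * voxel_size[0];
  const double hy = origin[1] + dims[1] * voxel_size[1];
  const double hz = origin[2] + dims[2] * voxel_size[2];

  // flat data (no z proposals) lives in 2 dimensions; the Gaussian
  // normalization must match or the mixture weights are distorted
  const double half_dim = (sd_z > 0) ? 1.5 : 1.0;
  auto mix_logdens = [&](double dx, double dy, double dz) {
    double r2 = dx * dx + dy * dy + dz * dz;
    double la = -half_dim * std::log(2.0 * M_PI * sig_a * sig_a) - r2 / (2.0 * sig_a * sig_a);
    double lb = -half_dim * std::log(2.0 * M_PI * sig_b * sig_b) - r2 / (2.0 * sig_b * sig_b);
    double mx = std::max(la, lb);
    return mx + std::log(rho * std::exp(la - mx) + (1.0 - rho) * std::exp(lb - mx));
  };
  auto voxel_at = [&](double px, double py, double pz) {
    int ix = (int)std::floor((px - origin[0]) / voxel_size[0]);
    int iy = (int)std::floor((py - origin[1]) / voxel_size[1]);
    int iz = (int)std::floor((pz - origin[2]) / voxel_size[2]);
    if (ix == dims[0]) --ix;
    if (iy == dims[1]) --iy;
    if (iz == dims[2]) --iz;
    return g.idx(ix, iy, iz);
  };

  long accepted = 0;
  for (int t = 0; t < M; ++t) {
    double nx = pos(t, 0) + sd_xy * norm_rand();
    double ny = pos(t, 1) + sd_xy * norm_rand();
    double nz = pos(t, 2) + (sd_z > 0 ? sd_z * norm_rand() : 0.0);
    if (nx < origin[0] || nx > hx || ny < origin[1] || ny > hy ||
        nz < origin[2] || nz > hz)
      continue;
    int vnew = voxel_at(nx, ny, nz);
    int vold = tvox[t];
    int gi = tgene[t];
    double logr = mix_logdens(nx - obs(t, 0), ny - obs(t, 1), nz - obs(t, 2)) -
                  mix_logdens(pos(t, 0) - obs(t, 0), pos(t, 1) - obs(t, 1),
                              pos(t, 2) - obs(t, 2));
    if (vnew != vold) {
      double rn = taubg[gi] + (st[vnew] > 0 ? tau(gi, st[vnew] - 1) : 0.0);
      double ro = taubg[gi] + (st[vold] > 0 ? tau(gi, st[vold] - 1) : 0.0);
      logr += std::log(rn) - std::log(ro);
    }
    if (logr >= 0.0 || std::log(unif_rand()) < logr) {
      pos(t, 0) = nx; pos(t, 1) = ny; pos(t, 2) = nz;
      tvox[t] = vnew;
      ++accepted;
    }
  }
  return List::create(_["pos"] = pos, _["tvox"] = tvox,
                      _["accepted"] = (double)accepted);
}
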