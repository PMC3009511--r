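// Compiled core: exhaustive enumeration on the FCC lattice.
//
// All search here is deterministic: candidate lattice points are visited in
// lexicographic (x, y, z) order, so enumeration order and tie-breaking are
// reproducible across platforms.

#include <Rcpp.h>
#include <unordered_map>
#include <functional>
#include <vector>
#include <algorithm>
#include <cmath>
#include <chrono>
#include <cstdint>

using namespace Rcpp;

namespace {

// The 12 FCC unit steps (permutations of (+-1, +-1, 0)), lexicographic order.
static const int STEPS[12][3] = {
  {-1, -1, 0}, {-1, 0, -1}, {-1, 0, 1}, {-1, 1, 0},
  {0, -1, -1}, {0, -1, 1},  {0, 1, -1}, {0, 1, 1},
  {1, -1, 0},  {1, 0, -1},  {1, 0, 1},  {1, 1, 0}
};

// Offsets at L1 distance exactly 2: the 12 lattice steps plus the 6 axial
// (+-2, 0, 0) permutations.  Residue pairs at any of these offsets are in
// contact under the plain L1 definition; "strict" mode keeps only the 12.
static const int AXIAL[6][3] = {
  {-2, 0, 0}, {0, -2, 0}, {0, 0, -2}, {0, 0, 2}, {0, 2, 0}, {2, 0, 0}
};

struct P3 { int x, y, z; };

inline int64_t pack(int x, int y, int z) {
  const int64_t OFF = 1 << 20;
  return (((int64_t)(x + OFF)) << 42) | (((int64_t)(y + OFF)) << 21) |
         ((int64_t)(z + OFF));
}
inline int64_t pack(const P3& p) { return pack(p.x, p.y, p.z); }

inline bool fcc_ok(int x, int y, int z) { return ((x + y + z) % 2) == 0; }

inline int l1(const P3& a, const P3& b) {
  return std::abs(a.x - b.x) + std::abs(a.y - b.y) + std::abs(a.z - b.z);
}

inline bool adjacent(const P3& a, const P3& b) {
  int dx = std::abs(a.x - b.x), dy = std::abs(a.y - b.y),
      dz = std::abs(a.z - b.z);
  return dx <= 1 && dy <= 1 && dz <= 1 && (dx + dy + dz) == 2;
}

// contact offsets for the requested contact definition
static std::vector<P3> contact_offsets(bool strict) {
  std::vector<P3> off;
  for (int k = 0; k < 12; ++k) off.push_back({STEPS[k][0], STEPS[k][1], STEPS[k][2]});
  if (!strict)
    for (int k = 0; k < 6; ++k) off.push_back({AXIAL[k][0], AXIAL[k][1], AXIAL[k][2]});
  return off;
}

}  // namespace

// ---------------------------------------------------------------------------
// Self-avoiding walk counting (directed walks from a fixed origin)
// ---------------------------------------------------------------------------

static long long saw_dfs(std::vector<P3>& walk, int remaining) {
  if (remaining == 0) return 1;
  long long total = 0;
  const P3 cur = walk.back();
  for (int k = 0; k < 12; ++k) {
    P3 nxt{cur.x + STEPS[k][0], cur.y + STEPS[k][1], cur.z + STEPS[k][2]};
    bool clash = false;
    for (const P3& q : walk)
      if (q.x == nxt.x && q.y == nxt.y && q.z == nxt.z) { clash = true; break; }
    if (clash) continue;
    walk.push_back(nxt);
    total += saw_dfs(walk, remaining - 1);
    walk.pop_back();
  }
  return total;
}

// [[Rcpp::export]]
double cpp_count_saws(int steps) {
  if (steps < 1) stop("steps must be >= 1");
  std::vector<P3> walk;
  walk.reserve(steps + 1);
  walk.push_back({0, 0, 0});
  return (double)saw_dfs(walk, steps);
}

// ---------------------------------------------------------------------------
// Full conformation energy (used internally; the R implementation is the
// user-facing pair scan and the two are cross-checked in the test suite)
// ---------------------------------------------------------------------------

static double full_energy(const std::vector<P3>& pos, const IntegerVector& seq,
                          const NumericMatrix& pot, bool strict) {
  const int n = (int)pos.size();
  std::unordered_map<int64_t, int> occ;
  occ.reserve(n * 2);
  for (int i = 0; i < n; ++i) occ[pack(pos[i])] = i;
  std::vector<P3> off = contact_offsets(strict);
  double e = 0.0;
  for (int i = 0; i < n; ++i) {
    for (const P3& d : off) {
      auto it = occ.find(pack(pos[i].x + d.x, pos[i].y + d.y, pos[i].z + d.z));
      if (it == occ.end()) continue;
      int j = it->second;
      if (j > i && (j - i) > 1) e += pot(seq[i], seq[j]);
    }
  }
  return e;
}

// [[Rcpp::export]]
double cpp_full_energy(IntegerMatrix posm, IntegerVector seq0,
                       NumericMatrix pot, bool strict) {
  const int n = posm.nrow();
  std::vector<P3> pos(n);
  for (int i = 0; i < n; ++i) pos[i] = {posm(i, 0), posm(i, 1), posm(i, 2)};
  return full_energy(pos, seq0, pot, strict);
}

// ---------------------------------------------------------------------------
// Generic finite-domain CSP enumeration (leftmost labeling, lexicographic
// candidates).  Constraint kinds: 0 = chain adjacency (L1 == 2 with the
// per-coordinate <= 1 cap), 1 = L1 == d, 2 = L1 >= d.
// ---------------------------------------------------------------------------

struct Cons { int i, j, d, kind; };

static bool cons_ok(const Cons& c, const P3& a, const P3& b) {
  int dd = l1(a, b);
  switch (c.kind) {
    case 0: return adjacent(a, b);
    case 1: return dd == c.d;
    default: return dd >= c.d;
  }
}

// [[Rcpp::export]]
List cpp_enumerate_csp(IntegerMatrix boxes, LogicalVector ground,
                       IntegerMatrix gpts, IntegerMatrix consm,
                       double max_solutions) {
  const int n = boxes.nrow();
  std::vector<Cons> cons;
  for (int k = 0; k < consm.nrow(); ++k)
    cons.push_back({consm(k, 0) - 1, consm(k, 1) - 1, consm(k, 2), consm(k, 3)});

  std::vector<bool> isg(n);
  std::vector<P3> val(n);
  std::vector<bool> has(n, false);
  std::vector<int> freev;
  for (int i = 0; i < n; ++i) {
    isg[i] = ground[i];
    if (isg[i]) {
      val[i] = {gpts(i, 0), gpts(i, 1), gpts(i, 2)};
      has[i] = true;
    } else {
      freev.push_back(i);
    }
  }

  // ground-ground constraints must already hold
  for (const Cons& c : cons)
    if (has[c.i] && has[c.j] && !cons_ok(c, val[c.i], val[c.j]))
      return List::create(_["count"] = 0.0,
                          _["solutions"] = IntegerMatrix(0, 3 * n));

  // constraints touching each variable
  std::vector<std::vector<int>> byvar(n);
  for (size_t k = 0; k < cons.size(); ++k) {
    byvar[cons[k].i].push_back((int)k);
    byvar[cons[k].j].push_back((int)k);
  }

  std::vector<int> out;  // flattened solutions, 3n per row
  long long count = 0;
  const int nf = (int)freev.size();

  // iterative DFS over free variables in index order
  std::function<void(int)> rec = [&](int lvl) {
    if (lvl == nf) {
      ++count;
      if ((double)count <= max_solutions)
        for (int i = 0; i < n; ++i) {
          out.push_back(val[i].x);
          out.push_back(val[i].y);
          out.push_back(val[i].z);
        }
      return;
    }
    int v = freev[lvl];
    for (int x = boxes(v, 0); x <= boxes(v, 3); ++x)
      for (int y = boxes(v, 1); y <= boxes(v, 4); ++y)
        for (int z = boxes(v, 2); z <= boxes(v, 5); ++z) {
          if (!fcc_ok(x, y, z)) continue;
          P3 p{x, y, z};
          bool ok = true;
          for (int ci : byvar[v]) {
            const Cons& c = cons[ci];
            int other = (c.i == v) ? c.j : c.i;
            if (!has[other]) continue;
            if (!cons_ok(c, (c.i == v) ? p : val[other],
                         (c.i == v) ? val[other] : p)) { ok = false; break; }
          }
          if (!ok) continue;
          val[v] = p;
          has[v] = true;
          rec(lvl + 1);
          has[v] = false;
        }
  };
  rec(0);

  if ((double)count > max_solutions)
    stop("solution count %lld exceeds max_solutions guard", count);

  IntegerMatrix sols((int)count, 3 * n);
  for (long long r = 0; r < count; ++r)
    for (int c = 0; c < 3 * n; ++c) sols((int)r, c) = out[r * 3 * n + c];
  return List::create(_["count"] = (double)count, _["solutions"] = sols);
}

// ---------------------------------------------------------------------------
// Subchain window enumeration: both flanks fixed, window boxes dilated.
// Enumerates every feasible re-placement, tracks the best-energy solution
// (optionally excluding the current one) and the total solution count.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_best_window(IntegerMatrix posm, IntegerVector seq0, NumericMatrix pot,
                     int ws, int wlen, IntegerMatrix wboxes, bool strict,
                     bool include_current, double max_nodes) {
  const int n = posm.nrow();
  if (ws < 1 || ws + wlen - 1 > n) stop("window out of range");
  std::vector<P3> pos(n);
  for (int i = 0; i < n; ++i) pos[i] = {posm(i, 0), posm(i, 1), posm(i, 2)};
  const std::vector<P3> off = contact_offsets(strict);
  const int we = ws + wlen - 1;  // last window index (1-based)

  // fixed residues: everything outside [ws, we]
  std::unordered_map<int64_t, int> occ;  // point -> 0-based index
  occ.reserve(2 * n);
  for (int i = 0; i < n; ++i)
    if (i + 1 < ws || i + 1 > we) occ[pack(pos[i])] = i;

  // energy over pairs with both residues fixed
  double e_fixed = 0.0;
  for (int i = 0; i < n; ++i) {
    if (i + 1 >= ws && i + 1 <= we) continue;
    for (const P3& d : off) {
      auto it = occ.find(pack(pos[i].x + d.x, pos[i].y + d.y, pos[i].z + d.z));
      if (it == occ.end()) continue;
      int j = it->second;
      if (j > i && (j - i) > 1) e_fixed += pot(seq0[i], seq0[j]);
    }
  }

  const bool has_left = ws > 1;
  const bool has_right = we < n;
  const P3 right = has_right ? pos[we] : P3{0, 0, 0};

  std::vector<P3> assign(wlen);
  std::vector<double> de(wlen, 0.0);
  double best_e = R_PosInf;
  std::vector<P3> best(wlen);
  bool have_best = false;
  bool found_current = false;
  double current_e = NA_REAL;
  long long count = 0, nodes = 0;

  std::function<void(int, double)> rec = [&](int t, double acc) {
    if (t == wlen) {
      ++count;
      bool is_cur = true;
      for (int k = 0; k < wlen; ++k) {
        const P3& q = pos[ws - 1 + k];
        if (assign[k].x != q.x || assign[k].y != q.y || assign[k].z != q.z) {
          is_cur = false;
          break;
        }
      }
      double e = e_fixed + acc;
      if (is_cur) { found_current = true; current_e = e; }
      if (is_cur && !include_current) return;
      if (e < best_e) { best_e = e; best = assign; have_best = true; }
      return;
    }
    const int g = ws + t;  // 1-based index of residue being placed
    // candidate generation
    std::vector<P3> cand;
    const P3* prev = nullptr;
    if (t > 0) prev = &assign[t - 1];
    else if (has_left) prev = &pos[ws - 2];
    if (prev) {
      for (int k = 0; k < 12; ++k) {
        P3 p{prev->x + STEPS[k][0], prev->y + STEPS[k][1], prev->z + STEPS[k][2]};
        if (p.x < wboxes(t, 0) || p.x > wboxes(t, 3) || p.y < wboxes(t, 1) ||
            p.y > wboxes(t, 4) || p.z < wboxes(t, 2) || p.z > wboxes(t, 5))
          continue;
        cand.push_back(p);
      }
    } else {
      for (int x = wboxes(t, 0); x <= wboxes(t, 3); ++x)
        for (int y = wboxes(t, 1); y <= wboxes(t, 4); ++y)
          for (int z = wboxes(t, 2); z <= wboxes(t, 5); ++z)
            if (fcc_ok(x, y, z)) cand.push_back({x, y, z});
    }
    for (const P3& p : cand) {
      if (++nodes > (long long)max_nodes)
        stop("enumeration guard exceeded (%0.0f nodes)", max_nodes);
      // self-avoidance (distinct FCC points are automatically at L1 >= 2)
      if (occ.count(pack(p))) continue;
      bool clash = false;
      for (int k = 0; k < t; ++k)
        if (assign[k].x == p.x && assign[k].y == p.y && assign[k].z == p.z) {
          clash = true;
          break;
        }
      if (clash) continue;
      // right-flank reachability / final adjacency
      if (has_right) {
        int steps_left = we + 1 - g;
        if (steps_left == 1) {
          if (!adjacent(p, right)) continue;
        } else if (l1(p, right) > 2 * steps_left) {
          continue;
        }
      }
      // incremental energy: contacts of residue g with fixed residues and
      // with already-placed window residues (each pair counted once)
      double d_e = 0.0;
      for (const P3& d : off) {
        P3 q{p.x + d.x, p.y + d.y, p.z + d.z};
        auto it = occ.find(pack(q));
        if (it != occ.end()) {
          int m = it->second + 1;
          if (std::abs(m - g) > 1) d_e += pot(seq0[g - 1], seq0[m - 1]);
        }
        for (int k = 0; k < t; ++k)
          if (assign[k].x == q.x && assign[k].y == q.y && assign[k].z == q.z) {
            int m = ws + k;
            if (std::abs(m - g) > 1) d_e += pot(seq0[g - 1], seq0[m - 1]);
          }
      }
      assign[t] = p;
      rec(t + 1, acc + d_e);
    }
  };
  rec(0, 0.0);

  IntegerMatrix bm(wlen, 3);
  if (have_best)
    for (int k = 0; k < wlen; ++k) {
      bm(k, 0) = best[k].x;
      bm(k, 1) = best[k].y;
      bm(k, 2) = best[k].z;
    }
  return List::create(
      _["count"] = (double)count, _["have_best"] = have_best,
      _["best_energy"] = best_e, _["best_window"] = bm,
      _["found_current"] = found_current, _["current_energy"] = current_e,
      _["nodes"] = (double)nodes);
}

// ---------------------------------------------------------------------------
// Pure CP search: complete branch-and-bound over anchored self-avoiding
// chains inside a cube of the given half-width.  V1 is anchored at the
// origin and V2 at (1,1,0); every conformation can be mapped onto this
// anchoring by a lattice symmetry, which leaves the energy unchanged.
// ---------------------------------------------------------------------------

namespace {
inline int64_t pack_sym(const P3& p, int variant) {
  // orbit of p under the anchor stabilizer {id, swap xy, negate z, both}
  switch (variant) {
    case 1: return pack(p.y, p.x, p.z);
    case 2: return pack(p.x, p.y, -p.z);
    case 3: return pack(p.y, p.x, -p.z);
    default: return pack(p);
  }
}
}

// [[Rcpp::export]]
List cpp_solve_pure(IntegerVector seq0, NumericMatrix pot, int halfwidth,
                    double time_limit, bool strict) {
  const int n = seq0.size();

  std::vector<P3> pos(n), best(n);
  double best_e = R_PosInf;
  bool complete = true;
  long long nodes = 0;

  if (n >= 1) pos[0] = {0, 0, 0};
  if (n >= 2) pos[1] = {1, 1, 0};
  if (n <= 2) {
    for (int i = 0; i < n; ++i) best[i] = pos[i];
    IntegerMatrix bm(n, 3);
    for (int i = 0; i < n; ++i) {
      bm(i, 0) = best[i].x; bm(i, 1) = best[i].y; bm(i, 2) = best[i].z;
    }
    return List::create(_["energy"] = 0.0, _["positions"] = bm,
                        _["complete"] = true, _["nodes"] = 0.0,
                        _["have"] = true);
  }
  if (halfwidth < 1) stop("box_halfwidth must be >= 1");

  // direct-indexed occupancy grid over the cube [-hw, hw]^3
  const int W = 2 * halfwidth + 1;
  const int NC = W * W * W;
  auto cell = [&](const P3& p) {
    return (p.x + halfwidth) + W * ((p.y + halfwidth) + W * (p.z + halfwidth));
  };
  auto cell_p3 = [&](int c) {
    return P3{c % W - halfwidth, (c / W) % W - halfwidth,
              c / (W * W) - halfwidth};
  };
  std::vector<int> occ(NC, -1);  // cell -> residue index or -1

  // precomputed in-box neighbour and contact cell lists per cell
  const std::vector<P3> off = contact_offsets(strict);
  std::vector<std::vector<int>> nbr(NC), con(NC);
  for (int c = 0; c < NC; ++c) {
    P3 p = cell_p3(c);
    if (!fcc_ok(p.x, p.y, p.z)) continue;
    for (int k = 0; k < 12; ++k) {
      P3 q{p.x + STEPS[k][0], p.y + STEPS[k][1], p.z + STEPS[k][2]};
      if (std::abs(q.x) <= halfwidth && std::abs(q.y) <= halfwidth &&
          std::abs(q.z) <= halfwidth)
        nbr[c].push_back(cell(q));
    }
    for (const P3& d : off) {
      P3 q{p.x + d.x, p.y + d.y, p.z + d.z};
      if (std::abs(q.x) <= halfwidth && std::abs(q.y) <= halfwidth &&
          std::abs(q.z) <= halfwidth)
        con[c].push_back(cell(q));
    }
  }

  // most negative pair energy among residue types present in the sequence
  double emin = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      emin = std::min(emin, pot(seq0[i], seq0[j]));
  // admissible cap on the contacts residue m (1-based) can close when placed
  const int percap = strict ? 11 : 17;
  std::vector<double> suffix(n + 2, 0.0);
  for (int m = n; m >= 1; --m)
    suffix[m] = suffix[m + 1] + std::min(percap, m - 2 > 0 ? m - 2 : 0);

  occ[cell(pos[0])] = 0;
  occ[cell(pos[1])] = 1;

  const auto t0 = std::chrono::steady_clock::now();
  bool timed_out = false;

  std::function<void(int, double)> rec = [&](int i, double acc) {
    // i: 0-based index of residue to place next
    if (timed_out) return;
    if (i == n) {
      if (acc < best_e) {
        best_e = acc;
        best = pos;
      }
      return;
    }
    if ((++nodes & 0xFFF) == 0) {
      double el = std::chrono::duration<double>(
                      std::chrono::steady_clock::now() - t0).count();
      if (el > time_limit) { timed_out = true; complete = false; return; }
    }
    // bound: acc plus the best conceivable remaining contacts
    if (acc + emin * suffix[i + 1] >= best_e) return;

    const int pc = cell(pos[i - 1]);
    struct Cand { int c; double de; };
    Cand cand[12];
    int ncand = 0;
    for (int cc : nbr[pc]) {
      if (occ[cc] >= 0) continue;
      if (i == 2) {
        // symmetry reduction at the first free level: keep the orbit
        // representative under the anchor stabilizer (energy-invariant)
        P3 p = cell_p3(cc);
        int64_t key = pack(p);
        bool rep = true;
        for (int v = 1; v < 4; ++v)
          if (pack_sym(p, v) < key) { rep = false; break; }
        if (!rep) continue;
      }
      double d_e = 0.0;
      for (int qc : con[cc]) {
        int m = occ[qc];
        if (m >= 0 && std::abs(m - i) > 1) d_e += pot(seq0[i], seq0[m]);
      }
      cand[ncand++] = {cc, d_e};
    }
    // explore most promising first (better incumbents earlier => more
    // pruning); ties broken lexicographically in cell order for determinism
    std::stable_sort(cand, cand + ncand, [](const Cand& a, const Cand& b) {
      if (a.de != b.de) return a.de < b.de;
      return a.c < b.c;
    });
    for (int k = 0; k < ncand; ++k) {
      pos[i] = cell_p3(cand[k].c);
      occ[cand[k].c] = i;
      rec(i + 1, acc + cand[k].de);
      occ[cand[k].c] = -1;
      if (timed_out) return;
    }
  };
  rec(2, 0.0);

  IntegerMatrix bm(n, 3);
  bool have = R_finite(best_e);
  if (have)
    for (int i = 0; i < n; ++i) {
      bm(i, 0) = best[i].x; bm(i, 1) = best[i].y; bm(i, 2) = best[i].z;
    }
  return List::create(_["energy"] = have ? best_e : NA_REAL,
                      _["positions"] = bm, _["complete"] = complete,
                      _["nodes"] = (double)nodes, _["have"] = have);
}
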