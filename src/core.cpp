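// Graph-level cheminformatics kernels: ring/aromaticity perception,
// hashed fingerprints (subgraph, circular, torsion) and maximum common
// substructure search. Molecules arrive as flat atom/bond vectors
// (1-based indices from R).

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
#include <unordered_set>
#include <chrono>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// deterministic hashing (no std::hash: must be stable across platforms)

static inline uint64_t splitmix64(uint64_t &x) {
  x += 0x9e3779b97f4a7c15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

static inline uint64_t hash_combine(uint64_t h, uint64_t v) {
  h ^= v + 0x9e3779b97f4a7c15ULL + (h << 6) + (h >> 2);
  uint64_t s = h;
  return splitmix64(s);
}

// ---------------------------------------------------------------------------
// molecular graph

struct Mol {
  int natoms;
  std::vector<int> z;          // atomic number
  std::vector<int> arom_atom;  // 0/1
  std::vector<int> bu, bv;     // bond endpoints, 0-based
  std::vector<int> border;     // bond order 1,2,3 (kekulized input)
  std::vector<int> bring;      // ring membership 0/1
  std::vector<int> barom;      // aromatic bond 0/1
  std::vector<std::vector<int>> adj_bonds;  // atom -> incident bond ids

  int nbonds() const { return (int)bu.size(); }
  int bond_code(int i) const { return barom[i] ? 4 : border[i]; }
  int other(int bi, int a) const { return bu[bi] == a ? bv[bi] : bu[bi]; }
};

static Mol mol_from_args(int natoms, IntegerVector z, IntegerVector arom,
                         IntegerVector bu, IntegerVector bv,
                         IntegerVector border, IntegerVector bring,
                         IntegerVector barom) {
  Mol m;
  m.natoms = natoms;
  m.z.assign(z.begin(), z.end());
  m.arom_atom.assign(arom.begin(), arom.end());
  int nb = bu.size();
  m.bu.resize(nb); m.bv.resize(nb);
  for (int i = 0; i < nb; ++i) { m.bu[i] = bu[i] - 1; m.bv[i] = bv[i] - 1; }
  m.border.assign(border.begin(), border.end());
  m.bring.assign(bring.begin(), bring.end());
  m.barom.assign(barom.begin(), barom.end());
  m.adj_bonds.assign(natoms, {});
  for (int i = 0; i < nb; ++i) {
    m.adj_bonds[m.bu[i]].push_back(i);
    m.adj_bonds[m.bv[i]].push_back(i);
  }
  return m;
}

// ---------------------------------------------------------------------------
// ring perception: a bond is a ring bond iff it is not a bridge (DFS
// bridge-finding); aromaticity by a contained Hueckel-style rule on
// small rings of the cycle basis.

static void find_bridges(const Mol &m, std::vector<int> &is_bridge) {
  int n = m.natoms, nb = m.bu.size();
  is_bridge.assign(nb, 1);
  std::vector<int> disc(n, -1), low(n, 0);
  int timer = 0;
  // iterative DFS
  for (int s = 0; s < n; ++s) {
    if (disc[s] != -1) continue;
    std::vector<std::array<int,3>> stack;  // atom, parent bond, next adj idx
    stack.push_back({s, -1, 0});
    disc[s] = low[s] = timer++;
    while (!stack.empty()) {
      auto &fr = stack.back();
      int a = fr[0], pb = fr[1];
      if (fr[2] < (int)m.adj_bonds[a].size()) {
        int bi = m.adj_bonds[a][fr[2]++];
        if (bi == pb) continue;
        int b = m.other(bi, a);
        if (disc[b] == -1) {
          disc[b] = low[b] = timer++;
          stack.push_back({b, bi, 0});
        } else {
          low[a] = std::min(low[a], disc[b]);
          is_bridge[bi] = 0;  // back edge is in a cycle
        }
      } else {
        stack.pop_back();
        if (!stack.empty()) {
          int p = stack.back()[0];
          low[p] = std::min(low[p], low[a]);
          if (low[a] <= disc[p]) is_bridge[pb] = 0;
        }
      }
    }
  }
}

// smallest ring through a given ring bond (BFS between endpoints,
// avoiding the bond itself); returns atom list or empty
static std::vector<int> smallest_ring(const Mol &m, int bond, int maxsize) {
  int src = m.bu[bond], dst = m.bv[bond];
  std::vector<int> prev_atom(m.natoms, -2), prev_bond(m.natoms, -1);
  std::vector<int> queue{src};
  prev_atom[src] = -1;
  size_t qi = 0;
  while (qi < queue.size()) {
    int a = queue[qi++];
    for (int bi : m.adj_bonds[a]) {
      if (bi == bond) continue;
      int b = m.other(bi, a);
      if (prev_atom[b] != -2) continue;
      prev_atom[b] = a; prev_bond[b] = bi;
      if (b == dst) {
        std::vector<int> ring;
        int cur = dst;
        while (cur != -1) { ring.push_back(cur); cur = prev_atom[cur]; }
        if ((int)ring.size() > maxsize) return {};
        return ring;
      }
      queue.push_back(b);
    }
  }
  return {};
}

// [[Rcpp::export]]
List cpp_perceive(int natoms, IntegerVector z, IntegerVector bu,
                  IntegerVector bv, IntegerVector border) {
  Mol m = mol_from_args(natoms, z, IntegerVector(natoms),
                        bu, bv, border, IntegerVector(bu.size()),
                        IntegerVector(bu.size()));
  int nb = m.nbonds();
  std::vector<int> is_bridge;
  find_bridges(m, is_bridge);
  std::vector<int> ring_bond(nb), arom_bond(nb, 0), arom_atom(natoms, 0);
  for (int i = 0; i < nb; ++i) ring_bond[i] = is_bridge[i] ? 0 : 1;

  // double bond incident to each atom?
  std::vector<int> has_double(natoms, 0);
  for (int i = 0; i < nb; ++i)
    if (m.border[i] >= 2) { has_double[m.bu[i]] = 1; has_double[m.bv[i]] = 1; }

  // candidate aromatic rings: size 5-7, every atom sp2-eligible,
  // pi count == 2 (mod 4)
  std::vector<std::vector<int>> rings;
  for (int i = 0; i < nb; ++i) {
    if (!ring_bond[i]) continue;
    std::vector<int> ring = smallest_ring(m, i, 7);
    if (ring.size() < 5) continue;
    rings.push_back(ring);
  }
  for (auto &ring : rings) {
    std::vector<int> inring(natoms, 0);
    for (int a : ring) inring[a] = 1;
    int pi = 0; bool ok = true;
    for (int a : ring) {
      if (has_double[a]) { pi += 1; continue; }
      // lone-pair donor: N, O, S with only single bonds
      if (m.z[a] == 7 || m.z[a] == 8 || m.z[a] == 16) { pi += 2; continue; }
      ok = false; break;
    }
    if (!ok || pi % 4 != 2) continue;
    for (int a : ring) arom_atom[a] = 1;
  }
  // aromatic bond: ring bond joining two aromatic atoms
  for (int i = 0; i < nb; ++i)
    if (ring_bond[i] && arom_atom[m.bu[i]] && arom_atom[m.bv[i]])
      arom_bond[i] = 1;

  return List::create(_["ring_bond"] = wrap(ring_bond),
                      _["aromatic_bond"] = wrap(arom_bond),
                      _["aromatic_atom"] = wrap(arom_atom));
}

// ---------------------------------------------------------------------------
// Daylight/RDKit-style subgraph-hash fingerprint: enumerate all connected
// bond subgraphs of 1..max_path bonds, hash a canonical-ish invariant
// (sorted multiset of typed-bond codes with within-subgraph degrees) and
// set bits_per_hash bits per subgraph.

struct SubgraphEnum {
  const Mol &m;
  int maxlen;
  std::unordered_set<uint64_t> seen64;
  std::unordered_set<std::string> seenS;
  bool small;
  std::vector<std::vector<int>> out;

  SubgraphEnum(const Mol &mm, int ml) : m(mm), maxlen(ml) {
    small = m.nbonds() <= 64;
  }

  bool mark(const std::vector<int> &cur) {
    if (small) {
      uint64_t key = 0;
      for (int b : cur) key |= (1ULL << b);
      return seen64.insert(key).second;
    }
    std::vector<int> s(cur); std::sort(s.begin(), s.end());
    std::string key((char*)s.data(), s.size() * sizeof(int));
    return seenS.insert(key).second;
  }

  void grow(std::vector<int> &cur) {
    if (!mark(cur)) return;
    out.push_back(cur);
    if ((int)cur.size() == maxlen) return;
    std::vector<char> inset(m.nbonds(), 0), atom_in(m.natoms, 0);
    for (int b : cur) { inset[b] = 1; atom_in[m.bu[b]] = 1; atom_in[m.bv[b]] = 1; }
    std::vector<int> cand;
    for (int a = 0; a < m.natoms; ++a) {
      if (!atom_in[a]) continue;
      for (int bi : m.adj_bonds[a])
        if (!inset[bi]) { cand.push_back(bi); inset[bi] = 2; }
    }
    for (int bi : cand) {
      cur.push_back(bi);
      grow(cur);
      cur.pop_back();
    }
  }

  void run() {
    for (int i = 0; i < m.nbonds(); ++i) {
      std::vector<int> cur{i};
      grow(cur);
    }
  }
};

static uint64_t subgraph_hash(const Mol &m, const std::vector<int> &sg) {
  std::vector<int> deg(m.natoms, 0);
  for (int b : sg) { deg[m.bu[b]]++; deg[m.bv[b]]++; }
  std::vector<std::array<uint64_t,5>> codes;
  for (int b : sg) {
    int u = m.bu[b], v = m.bv[b];
    uint64_t iu = (uint64_t)(m.z[u] + 128 * m.arom_atom[u]);
    uint64_t iv = (uint64_t)(m.z[v] + 128 * m.arom_atom[v]);
    uint64_t du = deg[u], dv = deg[v];
    if (iu > iv || (iu == iv && du > dv)) { std::swap(iu, iv); std::swap(du, dv); }
    codes.push_back({(uint64_t)m.bond_code(b), iu, du, iv, dv});
  }
  std::sort(codes.begin(), codes.end());
  uint64_t h = 1469598103934665603ULL;
  for (auto &c : codes)
    for (uint64_t f : c) h = hash_combine(h, f);
  return h;
}

// [[Rcpp::export]]
LogicalVector cpp_path_fp(int natoms, IntegerVector z, IntegerVector arom,
                          IntegerVector bu, IntegerVector bv,
                          IntegerVector border, IntegerVector bring,
                          IntegerVector barom,
                          int nbits, int max_path, int bits_per_hash) {
  Mol m = mol_from_args(natoms, z, arom, bu, bv, border, bring, barom);
  LogicalVector fp(nbits);
  SubgraphEnum en(m, max_path);
  en.run();
  for (auto &sg : en.out) {
    uint64_t h = subgraph_hash(m, sg);
    uint64_t state = h;
    for (int j = 0; j < bits_per_hash; ++j) {
      uint64_t r = splitmix64(state);
      fp[(int)(r % (uint64_t)nbits)] = true;
    }
  }
  return fp;
}

// ---------------------------------------------------------------------------
// Morgan / circular fingerprint (ECFP-like), radius r, folded

static int implicit_h(const Mol &m, int a) {
  static const int val_c = 4;
  int z = m.z[a], valence;
  switch (z) {
    case 6: valence = val_c; break;
    case 7: valence = 3; break;
    case 8: valence = 2; break;
    case 16: valence = 2; break;
    case 15: valence = 3; break;
    case 5: valence = 3; break;
    case 9: case 17: case 35: case 53: valence = 1; break;
    default: valence = 0;
  }
  double used = 0;
  for (int bi : m.adj_bonds[a]) used += m.barom[bi] ? 1.5 : m.border[bi];
  int h = valence - (int)(used + 0.01);
  return h > 0 ? h : 0;
}

// [[Rcpp::export]]
LogicalVector cpp_morgan_fp(int natoms, IntegerVector z, IntegerVector arom,
                            IntegerVector bu, IntegerVector bv,
                            IntegerVector border, IntegerVector bring,
                            IntegerVector barom, int nbits, int radius) {
  Mol m = mol_from_args(natoms, z, arom, bu, bv, border, bring, barom);
  LogicalVector fp(nbits);
  std::vector<uint64_t> inv(m.natoms), nxt(m.natoms);
  std::vector<char> in_ring_atom(m.natoms, 0);
  for (int i = 0; i < m.nbonds(); ++i)
    if (m.bring[i]) { in_ring_atom[m.bu[i]] = 1; in_ring_atom[m.bv[i]] = 1; }
  for (int a = 0; a < m.natoms; ++a) {
    uint64_t h = 0xcbf29ce484222325ULL;
    h = hash_combine(h, (uint64_t)m.z[a]);
    h = hash_combine(h, (uint64_t)m.adj_bonds[a].size());
    h = hash_combine(h, (uint64_t)implicit_h(m, a));
    h = hash_combine(h, (uint64_t)m.arom_atom[a]);
    h = hash_combine(h, (uint64_t)in_ring_atom[a]);
    inv[a] = h;
    fp[(int)(h % (uint64_t)nbits)] = true;
  }
  for (int r = 1; r <= radius; ++r) {
    for (int a = 0; a < m.natoms; ++a) {
      std::vector<std::pair<uint64_t,uint64_t>> env;
      for (int bi : m.adj_bonds[a])
        env.push_back({(uint64_t)m.bond_code(bi), inv[m.other(bi, a)]});
      std::sort(env.begin(), env.end());
      uint64_t h = 0xcbf29ce484222325ULL;
      h = hash_combine(h, (uint64_t)r);
      h = hash_combine(h, inv[a]);
      for (auto &e : env) { h = hash_combine(h, e.first); h = hash_combine(h, e.second); }
      nxt[a] = h;
      fp[(int)(h % (uint64_t)nbits)] = true;
    }
    inv = nxt;
  }
  return fp;
}

// ---------------------------------------------------------------------------
// topological torsion fingerprint: linear 4-atom paths

// [[Rcpp::export]]
LogicalVector cpp_torsion_fp(int natoms, IntegerVector z, IntegerVector arom,
                             IntegerVector bu, IntegerVector bv,
                             IntegerVector border, IntegerVector bring,
                             IntegerVector barom, int nbits) {
  Mol m = mol_from_args(natoms, z, arom, bu, bv, border, bring, barom);
  LogicalVector fp(nbits);
  auto acode = [&](int a) -> uint64_t {
    return (uint64_t)m.z[a] + 128ULL * m.arom_atom[a] +
           1024ULL * m.adj_bonds[a].size();
  };
  for (int a = 0; a < m.natoms; ++a) {
    for (int b1 : m.adj_bonds[a]) {
      int b = m.other(b1, a);
      for (int b2 : m.adj_bonds[b]) {
        int c = m.other(b2, b);
        if (c == a) continue;
        for (int b3 : m.adj_bonds[c]) {
          int d = m.other(b3, c);
          if (d == b || d == a) continue;
          uint64_t f[4] = {acode(a), acode(b), acode(c), acode(d)};
          bool rev = (f[3] < f[0]) ||
                     (f[3] == f[0] && f[2] < f[1]);
          uint64_t h = 0xcbf29ce484222325ULL;
          if (rev) for (int i = 3; i >= 0; --i) h = hash_combine(h, f[i]);
          else     for (int i = 0; i <  4; ++i) h = hash_combine(h, f[i]);
          fp[(int)(h % (uint64_t)nbits)] = true;
        }
      }
    }
  }
  return fp;
}

// ---------------------------------------------------------------------------
// maximum common substructure.
//
// Common edge subgraph (MCES) semantics: find a pairing of bonds of A with
// bonds of B, consistent with an injective atom mapping, maximizing the
// number of paired bonds (atom count of the solution as tie-break
// information). Disconnected solutions allowed (fragment-tolerant match);
// a connected-only mode restricts growth to bond-adjacent extensions.
// Disconnected search = maximum clique on the bond-compatibility graph
// (Tomita-style branch and bound with greedy coloring); connected search =
// McGregor-style DFS. Both honor a deterministic node budget plus a
// wall-clock timeout and report best-so-far when exhausted.

struct CompatVertex { int ba, bb; int a1, a2, b1, b2; };  // maps a1->b1, a2->b2

struct McsResultC { int bonds = 0, atoms = 0; bool timed_out = false; };

class McsSearch {
public:
  const Mol &A, &B;
  bool ring_match;
  long max_nodes;
  double timeout;
  std::vector<CompatVertex> verts;
  std::vector<std::vector<uint64_t>> adj;  // bitset adjacency
  int nwords = 0;
  long nodes = 0;
  std::chrono::steady_clock::time_point t0;
  McsResultC best;
  std::vector<int> best_clique;

  McsSearch(const Mol &a, const Mol &b, bool rm, long mn, double to)
    : A(a), B(b), ring_match(rm), max_nodes(mn), timeout(to) {}

  bool out_of_budget() {
    if (max_nodes > 0 && nodes > max_nodes) return true;
    if ((nodes & 1023) == 0 && timeout > 0) {
      double el = std::chrono::duration<double>(
          std::chrono::steady_clock::now() - t0).count();
      if (el > timeout) return true;
    }
    return false;
  }

  void build_vertices() {
    for (int i = 0; i < A.nbonds(); ++i) {
      for (int j = 0; j < B.nbonds(); ++j) {
        if (A.bond_code(i) != B.bond_code(j)) continue;
        if (ring_match && A.bring[i] != B.bring[j]) continue;
        int a1 = A.bu[i], a2 = A.bv[i], b1 = B.bu[j], b2 = B.bv[j];
        if (A.z[a1] == B.z[b1] && A.z[a2] == B.z[b2])
          verts.push_back({i, j, a1, a2, b1, b2});
        if (A.z[a1] == B.z[b2] && A.z[a2] == B.z[b1])
          verts.push_back({i, j, a1, a2, b2, b1});
      }
    }
  }

  static bool consistent(const CompatVertex &p, const CompatVertex &q) {
    if (p.ba == q.ba || p.bb == q.bb) return false;
    // union of the two 2-atom maps must be a consistent injection
    int pa[2] = {p.a1, p.a2}, pb[2] = {p.b1, p.b2};
    int qa[2] = {q.a1, q.a2}, qb[2] = {q.b1, q.b2};
    for (int i = 0; i < 2; ++i)
      for (int j = 0; j < 2; ++j) {
        bool same_a = pa[i] == qa[j], same_b = pb[i] == qb[j];
        if (same_a != same_b) return false;
      }
    return true;
  }

  void build_adjacency() {
    int n = verts.size();
    nwords = (n + 63) / 64;
    adj.assign(n, std::vector<uint64_t>(nwords, 0));
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j)
        if (consistent(verts[i], verts[j])) {
          adj[i][j >> 6] |= 1ULL << (j & 63);
          adj[j][i >> 6] |= 1ULL << (i & 63);
        }
  }

  int count_atoms(const std::vector<int> &clique) {
    std::vector<char> seen(A.natoms, 0);
    int n = 0;
    for (int v : clique) {
      if (!seen[verts[v].a1]) { seen[verts[v].a1] = 1; ++n; }
      if (!seen[verts[v].a2]) { seen[verts[v].a2] = 1; ++n; }
    }
    return n;
  }

  void record(const std::vector<int> &clique) {
    int na = count_atoms(clique);
    if ((int)clique.size() > best.bonds ||
        ((int)clique.size() == best.bonds && na > best.atoms)) {
      best.bonds = clique.size();
      best.atoms = na;
      best_clique = clique;
    }
  }

  // greedy coloring bound for candidate set P
  int color_bound(const std::vector<uint64_t> &P) {
    std::vector<uint64_t> un(P);
    int colors = 0;
    while (true) {
      bool any = false;
      std::vector<uint64_t> cls(nwords, 0);
      std::vector<uint64_t> avail(un);
      for (int w = 0; w < nwords; ++w) {
        while (avail[w]) {
          int b = __builtin_ctzll(avail[w]);
          int v = w * 64 + b;
          avail[w] &= avail[w] - 1;
          any = true;
          un[w] &= ~(1ULL << b);
          // remove neighbors of v from avail
          for (int w2 = 0; w2 < nwords; ++w2) avail[w2] &= ~adj[v][w2];
          if (w > 0) { /* avail for earlier words already consumed */ }
        }
      }
      if (!any) break;
      ++colors;
      (void)cls;
    }
    return colors;
  }

  void expand(std::vector<int> &clique, std::vector<uint64_t> &P) {
    ++nodes;
    if (best.timed_out || out_of_budget()) { best.timed_out = true; return; }
    int pc = 0;
    for (int w = 0; w < nwords; ++w) pc += __builtin_popcountll(P[w]);
    if ((int)clique.size() + pc <= best.bonds) return;
    if (pc == 0) { record(clique); return; }
    if ((int)clique.size() + color_bound(P) <= best.bonds) return;
    // iterate candidates (descending index for stable, effective ordering)
    for (int w = nwords - 1; w >= 0; --w) {
      while (P[w]) {
        int b = 63 - __builtin_clzll(P[w]);
        int v = w * 64 + b;
        P[w] &= ~(1ULL << b);
        // bound again with shrunken P
        int pc2 = 1;
        for (int w2 = 0; w2 < nwords; ++w2) pc2 += __builtin_popcountll(P[w2]);
        if ((int)clique.size() + pc2 <= best.bonds) { record(clique); return; }
        clique.push_back(v);
        std::vector<uint64_t> P2(nwords);
        bool nonempty = false;
        for (int w2 = 0; w2 < nwords; ++w2) {
          P2[w2] = P[w2] & adj[v][w2];
          if (P2[w2]) nonempty = true;
        }
        if (!nonempty) record(clique);
        else expand(clique, P2);
        clique.pop_back();
        if (best.timed_out) return;
      }
    }
  }

  // greedy initial solution: repeatedly add the candidate vertex with the
  // largest candidate-neighborhood
  void greedy_seed() {
    int n = verts.size();
    std::vector<uint64_t> P(nwords, 0);
    for (int i = 0; i < n; ++i) P[i >> 6] |= 1ULL << (i & 63);
    std::vector<int> clique;
    while (true) {
      int bestv = -1, bestdeg = -1;
      for (int w = 0; w < nwords; ++w) {
        uint64_t x = P[w];
        while (x) {
          int b = __builtin_ctzll(x); x &= x - 1;
          int v = w * 64 + b, d = 0;
          for (int w2 = 0; w2 < nwords; ++w2)
            d += __builtin_popcountll(P[w2] & adj[v][w2]);
          if (d > bestdeg) { bestdeg = d; bestv = v; }
        }
      }
      if (bestv < 0) break;
      clique.push_back(bestv);
      for (int w2 = 0; w2 < nwords; ++w2) P[w2] &= adj[bestv][w2];
    }
    record(clique);
  }

  McsResultC run_disconnected() {
    t0 = std::chrono::steady_clock::now();
    build_vertices();
    if (verts.empty()) return best;
    build_adjacency();
    greedy_seed();
    std::vector<uint64_t> P(nwords, 0);
    for (int i = 0; i < (int)verts.size(); ++i) P[i >> 6] |= 1ULL << (i & 63);
    std::vector<int> clique;
    expand(clique, P);
    return best;
  }

  // ---- connected (McGregor-style) search ----
  void mcgregor(std::vector<int> &sel, std::vector<char> &usedA,
                std::vector<char> &usedB, std::vector<int> &mapAB) {
    ++nodes;
    if (best.timed_out || out_of_budget()) { best.timed_out = true; return; }
    record(sel);
    // candidates: vertices whose A-bond touches the current A-subgraph and
    // which are consistent with the atom map
    int remA = 0, remB = 0;
    for (int i = 0; i < A.nbonds(); ++i) if (!usedA[i]) ++remA;
    for (int j = 0; j < B.nbonds(); ++j) if (!usedB[j]) ++remB;
    if ((int)sel.size() + std::min(remA, remB) <= best.bonds) return;
    std::vector<char> atom_in_A(A.natoms, 0);
    for (int v : sel) { atom_in_A[verts[v].a1] = 1; atom_in_A[verts[v].a2] = 1; }
    for (int vi = 0; vi < (int)verts.size(); ++vi) {
      const CompatVertex &cv = verts[vi];
      if (usedA[cv.ba] || usedB[cv.bb]) continue;
      if (!sel.empty() && !atom_in_A[cv.a1] && !atom_in_A[cv.a2]) continue;
      // map consistency
      int ma1 = mapAB[cv.a1], ma2 = mapAB[cv.a2];
      if (ma1 != -1 && ma1 != cv.b1) continue;
      if (ma2 != -1 && ma2 != cv.b2) continue;
      bool b1_taken = false, b2_taken = false;
      if (ma1 == -1) for (int x = 0; x < A.natoms; ++x)
        if (mapAB[x] == cv.b1) { b1_taken = true; break; }
      if (ma2 == -1) for (int x = 0; x < A.natoms; ++x)
        if (mapAB[x] == cv.b2) { b2_taken = true; break; }
      if (b1_taken || b2_taken) continue;
      // apply
      int o1 = mapAB[cv.a1], o2 = mapAB[cv.a2];
      mapAB[cv.a1] = cv.b1; mapAB[cv.a2] = cv.b2;
      usedA[cv.ba] = 1; usedB[cv.bb] = 1;
      sel.push_back(vi);
      mcgregor(sel, usedA, usedB, mapAB);
      sel.pop_back();
      usedA[cv.ba] = 0; usedB[cv.bb] = 0;
      mapAB[cv.a1] = o1; mapAB[cv.a2] = o2;
      if (best.timed_out) return;
    }
  }

  McsResultC run_connected() {
    t0 = std::chrono::steady_clock::now();
    build_vertices();
    if (verts.empty()) return best;
    std::vector<int> sel;
    std::vector<char> usedA(A.nbonds(), 0), usedB(B.nbonds(), 0);
    std::vector<int> mapAB(A.natoms, -1);
    mcgregor(sel, usedA, usedB, mapAB);
    return best;
  }
};

// [[Rcpp::export]]
List cpp_mcs(int natomsA, IntegerVector zA, IntegerVector aromA,
             IntegerVector buA, IntegerVector bvA, IntegerVector borderA,
             IntegerVector bringA, IntegerVector baromA,
             int natomsB, IntegerVector zB, IntegerVector aromB,
             IntegerVector buB, IntegerVector bvB, IntegerVector borderB,
             IntegerVector bringB, IntegerVector baromB,
             bool connected, bool ring_matches_ring,
             double max_nodes, double timeout_sec) {
  Mol A = mol_from_args(natomsA, zA, aromA, buA, bvA, borderA, bringA, baromA);
  Mol B = mol_from_args(natomsB, zB, aromB, buB, bvB, borderB, bringB, baromB);

  // degenerate: a molecule without bonds can still share one atom
  if (A.nbonds() == 0 || B.nbonds() == 0) {
    int common = 0;
    for (int i = 0; i < A.natoms && !common; ++i)
      for (int j = 0; j < B.natoms; ++j)
        if (A.z[i] == B.z[j]) { common = 1; break; }
    return List::create(_["n_bonds"] = 0, _["n_atoms"] = common,
                        _["timed_out"] = false);
  }

  McsSearch s(A, B, ring_matches_ring, (long)max_nodes, timeout_sec);
  McsResultC r = connected ? s.run_connected() : s.run_disconnected();
  return List::create(_["n_bonds"] = r.bonds, _["n_atoms"] = r.atoms,
                      _["timed_out"] = r.timed_out);
}
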