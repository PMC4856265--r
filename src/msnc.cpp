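// Exact probability mass of a rooted gene-tree topology given a
// phylogenetic network, its branch lengths (coalescent units) and
// inheritance probabilities, under the multispecies network coalescent.
//
// The computation enumerates, by dynamic programming from the leaves to
// the root, the joint distribution of "configurations": for every open
// branch, the set of gene-tree clades currently alive as lineages at its
// top. Within a branch, lineages may only coalesce in ways compatible
// with the gene tree (two lineages merge iff they are siblings in the
// gene tree); a transition from k to k-j lineages contributes
// g_{k,k-j}(t) * w / prod_i C(k-i+1, 2), where g is the Tavare lineage
// transition probability, w counts the orderings of the j required
// merges, and the product counts all ordered merge sequences. At a
// reticulation node every lineage independently follows the gamma-parent
// with probability gamma. Above the root all remaining lineages must
// coalesce into the gene-tree root.
//
// Gene trees are encoded as a parent vector over nodes 1..2L-1 (leaves
// 1..L first, parent 0 at the root) plus the species index of each leaf.
// Network nodes are 1..N with a species index per leaf node. Masks are
// 32-bit, so up to 16 sampled lineages per locus.

#include <Rcpp.h>
#include <cstdint>
#include <map>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

static double coal_gprob(int u, int v, double t) {
  if (u <= 1 || t == 0.0) return (v == u) ? 1.0 : 0.0;
  if (!R_finite(t)) return (v == 1) ? 1.0 : 0.0;
  if (v < 1 || v > u) return 0.0;
  double sum = 0.0;
  for (int k = v; k <= u; ++k) {
    double term = std::exp(-0.5 * k * (k - 1) * t);
    double prod = 1.0;
    for (int y = 0; y <= k - 1; ++y)
      prod *= (v + y) * (double)(u - y) / (u + y);
    double fact = 1.0;
    for (int y = 2; y <= k - v; ++y) fact *= y;
    double vfact = 1.0;
    for (int y = 2; y <= v; ++y) vfact *= y;
    double c = (2.0 * k - 1.0) / (v + k - 1.0) * prod / (vfact * fact);
    if ((k - v) % 2) c = -c;
    sum += term * c;
  }
  if (sum < 0.0) sum = 0.0;
  if (sum > 1.0) sum = 1.0;
  return sum;
}

// [[Rcpp::export]]
double cpp_coal_prob(int u, int v, double t) { return coal_gprob(u, v, t); }

typedef std::vector<std::pair<uint32_t, double> > TransOut;

static int popcount32(uint32_t x) {
  int c = 0;
  while (x) { x &= x - 1; ++c; }
  return c;
}

// All gene-tree-compatible outcomes of pushing lineage set S through a
// branch of length t.
static void branch_trans(uint32_t S, double t, const std::vector<int>& parent,
                         TransOut& out) {
  out.clear();
  int k = popcount32(S);
  if (k <= 1) { out.push_back(std::make_pair(S, 1.0)); return; }
  std::map<uint32_t, double> cur;
  cur[S] = 1.0;
  double invd = 1.0;
  for (int j = 0;; ++j) {
    int rem = k - j;
    double g = coal_gprob(k, rem, t);
    if (g > 0.0)
      for (std::map<uint32_t, double>::const_iterator it = cur.begin();
           it != cur.end(); ++it)
        out.push_back(std::make_pair(it->first, it->second * g * invd));
    if (rem <= 1) break;
    std::map<uint32_t, double> nxt;
    std::vector<int> bits;
    for (std::map<uint32_t, double>::const_iterator it = cur.begin();
         it != cur.end(); ++it) {
      uint32_t m = it->first;
      bits.clear();
      for (int b = 0; b < 32; ++b) if ((m >> b) & 1u) bits.push_back(b);
      for (size_t i = 0; i < bits.size(); ++i)
        for (size_t j2 = i + 1; j2 < bits.size(); ++j2) {
          int a = bits[i] + 1, b2 = bits[j2] + 1;
          if (parent[a - 1] != 0 && parent[a - 1] == parent[b2 - 1]) {
            uint32_t m2 = m;
            m2 &= ~(1u << bits[i]);
            m2 &= ~(1u << bits[j2]);
            m2 |= 1u << (parent[a - 1] - 1);
            nxt[m2] += it->second;
          }
        }
    }
    if (nxt.empty()) break;
    invd /= rem * (rem - 1) / 2.0;
    cur.swap(nxt);
  }
}

struct NetDesc {
  int nNodes, root, nEdges;
  std::vector<int> etail, ehead;       // 0-based node indices per edge
  std::vector<double> len, gamma;      // per edge; gamma NA -> -1
  std::vector<std::vector<int> > outE, inE;  // edge indices per node
  std::vector<int> topo;               // node indices, children before parents
};

static NetDesc build_net(const IntegerMatrix& edge, const NumericVector& len,
                         const NumericVector& gamma, int nNodes, int root) {
  NetDesc nd;
  nd.nNodes = nNodes;
  nd.root = root - 1;
  nd.nEdges = edge.nrow();
  nd.etail.resize(nd.nEdges);
  nd.ehead.resize(nd.nEdges);
  nd.len.assign(len.begin(), len.end());
  nd.gamma.resize(nd.nEdges);
  nd.outE.assign(nNodes, std::vector<int>());
  nd.inE.assign(nNodes, std::vector<int>());
  for (int i = 0; i < nd.nEdges; ++i) {
    nd.etail[i] = edge(i, 0) - 1;
    nd.ehead[i] = edge(i, 1) - 1;
    nd.gamma[i] = NumericVector::is_na(gamma[i]) ? -1.0 : gamma[i];
    nd.outE[nd.etail[i]].push_back(i);
    nd.inE[nd.ehead[i]].push_back(i);
  }
  // Kahn order, leaves first
  std::vector<int> remaining(nNodes);
  for (int v = 0; v < nNodes; ++v) remaining[v] = (int)nd.outE[v].size();
  std::vector<int> queue;
  for (int v = 0; v < nNodes; ++v) if (remaining[v] == 0) queue.push_back(v);
  while (!queue.empty()) {
    int v = queue.back();
    queue.pop_back();
    nd.topo.push_back(v);
    for (size_t i = 0; i < nd.inE[v].size(); ++i) {
      int p = nd.etail[nd.inE[v][i]];
      if (--remaining[p] == 0) queue.push_back(p);
    }
  }
  if ((int)nd.topo.size() != nNodes)
    stop("network has a directed cycle");
  return nd;
}

typedef std::vector<uint64_t> StateKey;   // sorted (edge<<32 | mask)

struct StateKeyHash {
  size_t operator()(const StateKey& k) const {
    uint64_t h = 1469598103934665603ull;
    for (size_t i = 0; i < k.size(); ++i) {
      h ^= k[i];
      h *= 1099511628211ull;
    }
    return (size_t)h;
  }
};
typedef std::unordered_map<StateKey, double, StateKeyHash> StateMap;

static void state_insert(StateMap& sm, StateKey key, double w) {
  std::sort(key.begin(), key.end());
  sm[key] += w;
}

static double mass_one(const NetDesc& nd, const std::vector<uint32_t>& leafMask,
                       const std::vector<int>& parent, int gtRoot) {
  // per-evaluation cache of branch transitions
  std::unordered_map<uint64_t, TransOut> tcache;
  StateMap states;
  states[StateKey()] = 1.0;
  double total = 0.0;
  TransOut tr1, tr2;

  for (size_t oi = 0; oi < nd.topo.size(); ++oi) {
    int v = nd.topo[oi];
    StateMap nxt;
    nxt.reserve(states.size() * 2 + 8);
    for (StateMap::const_iterator it = states.begin(); it != states.end();
         ++it) {
      const StateKey& key = it->first;
      double w = it->second;
      if (w < 1e-300) continue;
      // split entries into v's out-edges (consumed) and the rest
      uint32_t S = leafMask[v];
      StateKey rest;
      for (size_t i = 0; i < key.size(); ++i) {
        int e = (int)(key[i] >> 32);
        if (nd.etail[e] == v) S |= (uint32_t)(key[i] & 0xffffffffu);
        else rest.push_back(key[i]);
      }
      if (v == nd.root) {
        // all remaining lineages coalesce into the gene-tree root
        branch_trans(S, R_PosInf, parent, tr1);
        uint32_t rootmask = 1u << (gtRoot - 1);
        for (size_t i = 0; i < tr1.size(); ++i)
          if (tr1[i].first == rootmask) total += w * tr1[i].second;
        continue;
      }
      const std::vector<int>& ine = nd.inE[v];
      if (ine.size() == 1) {
        int e = ine[0];
        uint64_t ck = ((uint64_t)e << 32) | S;
        std::unordered_map<uint64_t, TransOut>::iterator cit = tcache.find(ck);
        if (cit == tcache.end()) {
          branch_trans(S, nd.len[e], parent, tr1);
          cit = tcache.insert(std::make_pair(ck, tr1)).first;
        }
        const TransOut& to = cit->second;
        for (size_t i = 0; i < to.size(); ++i) {
          StateKey k2(rest);
          k2.push_back(((uint64_t)e << 32) | to[i].first);
          state_insert(nxt, k2, w * to[i].second);
        }
      } else if (ine.size() == 2) {
        int e1 = ine[0], e2 = ine[1];
        double g1 = nd.gamma[e1] >= 0 ? nd.gamma[e1] : 0.5;
        double g2 = 1.0 - g1;
        // every lineage independently tracks the e1 parent with prob g1
        uint32_t A = S;
        for (;;) {   // iterate all submasks of S, including 0 and S
          uint32_t B = S & ~A;
          double f = 1.0;
          uint32_t x;
          for (x = A; x; x &= x - 1) f *= g1;
          for (x = B; x; x &= x - 1) f *= g2;
          if (f > 0.0) {
            uint64_t c1 = ((uint64_t)e1 << 32) | A;
            std::unordered_map<uint64_t, TransOut>::iterator i1 = tcache.find(c1);
            if (i1 == tcache.end()) {
              branch_trans(A, nd.len[e1], parent, tr1);
              i1 = tcache.insert(std::make_pair(c1, tr1)).first;
            }
            uint64_t c2 = ((uint64_t)e2 << 32) | B;
            std::unordered_map<uint64_t, TransOut>::iterator i2 = tcache.find(c2);
            if (i2 == tcache.end()) {
              branch_trans(B, nd.len[e2], parent, tr2);
              i2 = tcache.insert(std::make_pair(c2, tr2)).first;
            }
            const TransOut& ta = i1->second;
            const TransOut& tb = i2->second;
            for (size_t i = 0; i < ta.size(); ++i)
              for (size_t j = 0; j < tb.size(); ++j) {
                StateKey k2(rest);
                k2.push_back(((uint64_t)e1 << 32) | ta[i].first);
                k2.push_back(((uint64_t)e2 << 32) | tb[j].first);
                state_insert(nxt, k2, w * f * ta[i].second * tb[j].second);
              }
          }
          if (A == 0) break;
          A = (A - 1) & S;
        }
      } else {
        stop("node with in-degree > 2");
      }
    }
    if (v != nd.root) {
      // drop configurations with negligible relative weight; the cutoff
      // sits far below double-precision round-off of the final sum
      double mx = 0.0;
      for (StateMap::const_iterator it = nxt.begin(); it != nxt.end(); ++it)
        if (it->second > mx) mx = it->second;
      double thr = mx * 1e-13;
      for (StateMap::iterator it = nxt.begin(); it != nxt.end();) {
        if (it->second < thr) it = nxt.erase(it);
        else ++it;
      }
      states.swap(nxt);
    }
  }
  return total;
}

// Fast structural validity check used inside the MCMC loop: exactly one
// in-degree-0 node (the root, out-degree 2), every other node a leaf
// (1,0), tree node (1,2) or reticulation (2,1), exactly nLeaf leaves, no
// parallel edges, no directed cycle, branch lengths >= 0, and inheritance
// probabilities in [0,1] present exactly on reticulation in-edges and
// summing to 1 per node. Returns the reticulation count, or -1 when the
// candidate is invalid. Node ids are arbitrary integers.
// [[Rcpp::export]]
int cpp_check_network(IntegerMatrix edge, int root, int nLeaf,
                      NumericVector gamma, NumericVector len) {
  int E = edge.nrow();
  std::vector<int> ids;
  ids.reserve(2 * E);
  for (int i = 0; i < E; ++i) {
    ids.push_back(edge(i, 0));
    ids.push_back(edge(i, 1));
  }
  std::sort(ids.begin(), ids.end());
  ids.erase(std::unique(ids.begin(), ids.end()), ids.end());
  int k = (int)ids.size();
  std::vector<int> indeg(k, 0), outdeg(k, 0), tl(E), hd(E);
  for (int i = 0; i < E; ++i) {
    tl[i] = (int)(std::lower_bound(ids.begin(), ids.end(), edge(i, 0)) -
                  ids.begin());
    hd[i] = (int)(std::lower_bound(ids.begin(), ids.end(), edge(i, 1)) -
                  ids.begin());
    ++outdeg[tl[i]];
    ++indeg[hd[i]];
  }
  int roots = 0, leaves = 0, retics = 0, rootidx = -1;
  for (int v = 0; v < k; ++v) {
    if (indeg[v] == 0) { ++roots; rootidx = v; }
    if (indeg[v] == 1 && outdeg[v] == 0) { ++leaves; continue; }
    if (indeg[v] == 2 && outdeg[v] == 1) { ++retics; continue; }
    bool ok = (indeg[v] == 0 && outdeg[v] == 2) ||
              (indeg[v] == 1 && outdeg[v] == 2);
    if (!ok) return -1;
  }
  if (roots != 1 || ids[rootidx] != root || leaves != nLeaf) return -1;
  // branch lengths and inheritance probabilities
  std::vector<double> gsum(k, 0.0);
  std::vector<int> gcount(k, 0);
  for (int i = 0; i < E; ++i) {
    if (!(len[i] >= 0.0)) return -1;
    bool isretic = (indeg[hd[i]] == 2);
    bool hasg = !NumericVector::is_na(gamma[i]);
    if (isretic != hasg) return -1;
    if (hasg) {
      if (gamma[i] < 0.0 || gamma[i] > 1.0) return -1;
      gsum[hd[i]] += gamma[i];
      ++gcount[hd[i]];
    }
  }
  for (int v = 0; v < k; ++v)
    if (gcount[v] == 2 && std::abs(gsum[v] - 1.0) > 1e-9) return -1;
  // parallel edges
  std::vector<int64_t> pairs(E);
  for (int i = 0; i < E; ++i) pairs[i] = ((int64_t)tl[i] << 32) | hd[i];
  std::sort(pairs.begin(), pairs.end());
  for (int i = 1; i < E; ++i) if (pairs[i] == pairs[i - 1]) return -1;
  // acyclicity (Kahn from leaves up)
  std::vector<std::vector<int> > inE(k);
  for (int i = 0; i < E; ++i) inE[hd[i]].push_back(tl[i]);
  std::vector<int> rem(outdeg), stack2;
  int seen = 0;
  for (int v = 0; v < k; ++v) if (rem[v] == 0) stack2.push_back(v);
  while (!stack2.empty()) {
    int v = stack2.back();
    stack2.pop_back();
    ++seen;
    for (size_t i = 0; i < inE[v].size(); ++i)
      if (--rem[inE[v][i]] == 0) stack2.push_back(inE[v][i]);
  }
  return seen == k ? retics : -1;
}

// Gene-tree mass for each encoded topology in `topos` given one network.
//
// The network arrives with arbitrary integer node ids (as used by the
// proposal moves); ids are compacted here. leafIds/leafSpecies give the
// species index of each leaf node; topos is a list of
// list(parent=, leafSpecies=) encodings.
// [[Rcpp::export]]
NumericVector cpp_msnc_masses(IntegerMatrix edge, NumericVector len,
                              NumericVector gamma, IntegerVector leafIds,
                              IntegerVector leafSpecies, int root,
                              List topos) {
  int E = edge.nrow();
  std::vector<int> ids;
  ids.reserve(2 * E);
  for (int i = 0; i < E; ++i) {
    ids.push_back(edge(i, 0));
    ids.push_back(edge(i, 1));
  }
  std::sort(ids.begin(), ids.end());
  ids.erase(std::unique(ids.begin(), ids.end()), ids.end());
  int nNodes = (int)ids.size();
  IntegerMatrix cedge(E, 2);
  for (int i = 0; i < E; ++i) {
    cedge(i, 0) = 1 + (int)(std::lower_bound(ids.begin(), ids.end(),
                                             edge(i, 0)) - ids.begin());
    cedge(i, 1) = 1 + (int)(std::lower_bound(ids.begin(), ids.end(),
                                             edge(i, 1)) - ids.begin());
  }
  IntegerVector nodeSpecies(nNodes);
  for (int l = 0; l < leafIds.size(); ++l) {
    int idx = (int)(std::lower_bound(ids.begin(), ids.end(), leafIds[l]) -
                    ids.begin());
    if (idx >= nNodes || ids[idx] != leafIds[l])
      stop("leaf id absent from the edge matrix");
    nodeSpecies[idx] = leafSpecies[l];
  }
  int croot = 1 + (int)(std::lower_bound(ids.begin(), ids.end(), root) -
                        ids.begin());
  NetDesc nd = build_net(cedge, len, gamma, nNodes, croot);
  NumericVector out(topos.size());
  for (int ti = 0; ti < topos.size(); ++ti) {
    List tp = topos[ti];
    IntegerVector par = tp["parent"];
    IntegerVector lsp = tp["leafSpecies"];
    int ngt = par.size();
    if (ngt > 31) stop("more than 16 sampled lineages per locus");
    std::vector<int> parent(par.begin(), par.end());
    int gtRoot = 0;
    for (int i = 0; i < ngt; ++i) if (parent[i] == 0) gtRoot = i + 1;
    std::vector<uint32_t> leafMask(nNodes, 0u);
    for (int v = 0; v < nNodes; ++v) {
      if (nodeSpecies[v] > 0)
        for (int l = 0; l < lsp.size(); ++l)
          if (lsp[l] == nodeSpecies[v]) leafMask[v] |= 1u << l;
    }
    out[ti] = mass_one(nd, leafMask, parent, gtRoot);
  }
  return out;
}
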