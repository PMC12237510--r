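// Local de Bruijn graph: k-mer counting, unitig compaction, diploid-aware
// simplification, and tip-aware greedy path extension.
//
// k-mers are 2-bit packed into unsigned __int128 (k <= 63). Nodes are
// canonical k-mers; an edge exists where the joining (k+1)-mer was observed
// and both endpoint k-mers are solid. The exported graph is canonicalised
// (unitig orientation = lexicographic min of seq/revcomp, unitigs sorted by
// sequence) so it is byte-identical under input read reordering.

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

typedef unsigned __int128 u128;

struct H128 {
  size_t operator()(const u128& x) const {
    uint64_t lo = (uint64_t)x, hi = (uint64_t)(x >> 64);
    uint64_t h = lo * 0x9E3779B97F4A7C15ULL;
    h ^= hi + 0x9E3779B97F4A7C15ULL + (h << 6) + (h >> 2);
    h ^= h >> 33; h *= 0xff51afd7ed558ccdULL; h ^= h >> 33;
    return (size_t)h;
  }
};

static inline int base2bit(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
  }
  return -1;
}
static const char BIT2BASE[4] = {'A', 'C', 'G', 'T'};

struct Cnt { uint32_t s = 0, l = 0; };

// open-addressing map keyed by packed k-mers; the hot store for counting
// and for graph-walk lookups (lower constant factors than unordered_map)
struct KMap {
  std::vector<u128> keys;
  std::vector<Cnt> vals;
  std::vector<uint8_t> used;
  size_t mask = 0, n = 0;
  void init(size_t expected) {
    size_t cap = 64;
    while (cap < expected * 2 + 16) cap <<= 1;
    keys.assign(cap, 0); vals.assign(cap, Cnt()); used.assign(cap, 0);
    mask = cap - 1; n = 0;
  }
  Cnt& operator[](u128 k) {
    size_t i = H128{}(k) & mask;
    while (used[i] && keys[i] != k) i = (i + 1) & mask;
    if (!used[i]) { used[i] = 1; keys[i] = k; ++n; }
    return vals[i];
  }
  const Cnt* find_ptr(u128 k) const {
    size_t i = H128{}(k) & mask;
    while (used[i]) {
      if (keys[i] == k) return &vals[i];
      i = (i + 1) & mask;
    }
    return nullptr;
  }
  bool contains(u128 k) const { return find_ptr(k) != nullptr; }
};

static void count_kmers(const std::string& s, int K, bool is_long, KMap& m) {
  if ((int)s.size() < K) return;
  const u128 one = 1;
  const u128 mask = (one << (2 * K)) - 1;
  const int shift = 2 * (K - 1);
  u128 f = 0, r = 0;
  int len = 0;
  for (char c : s) {
    int b = base2bit(c);
    if (b < 0) { len = 0; f = 0; r = 0; continue; }
    f = ((f << 2) | (u128)b) & mask;
    r = (r >> 2) | ((u128)(3 - b) << shift);
    if (++len >= K) {
      u128 can = f < r ? f : r;
      Cnt& e = m[can];
      if (is_long) e.l++; else e.s++;
    }
  }
}

static std::string decode(u128 x, int K) {
  std::string s(K, 'A');
  for (int i = K - 1; i >= 0; --i) { s[i] = BIT2BASE[(int)(x & 3)]; x >>= 2; }
  return s;
}

struct Orient { u128 f, r; };  // a k-mer with its reverse complement

// Graph-construction context
struct Ctx {
  int K;
  u128 mask;
  int shift;
  const KMap* nodes;  // solid canonical k-mers with counts
  const KMap* edges;  // observed canonical (k+1)-mers
  int eshift;         // 2*K : position for the complement base in rc of (k+1)-mer

  bool has_edge(const Orient& x, int b, Orient& y, uint32_t* ecov = nullptr) const {
    u128 ef = (x.f << 2) | (u128)b;                       // (k+1)-mer forward
    u128 er = ((u128)(3 - b) << eshift) | x.r;            // its revcomp
    u128 ecan = ef < er ? ef : er;
    const Cnt* it = edges->find_ptr(ecan);
    if (!it) return false;
    y.f = ((x.f << 2) | (u128)b) & mask;
    y.r = (x.r >> 2) | ((u128)(3 - b) << shift);
    u128 ycan = y.f < y.r ? y.f : y.r;
    if (!nodes->contains(ycan)) return false;
    if (ecov) *ecov = it->s + it->l;
    return true;
  }
  int outdeg(const Orient& x) const {
    Orient y; int d = 0;
    for (int b = 0; b < 4; ++b) if (has_edge(x, b, y)) ++d;
    return d;
  }
  // indegree of y == outdegree of rc(y)
  int indeg(const Orient& y) const { Orient ry{y.r, y.f}; return outdeg(ry); }
};

struct Unitig {
  std::string seq;
  double cov = 0;
  int nk = 0;
};

struct LinkRec { int u, ue, v, ve; double cov; };

// Build unitigs + links from counted maps. Returns via out-params.
static void build_unitigs(const Ctx& ctx, const KMap& nodemap,
                          std::vector<Unitig>& unis, std::vector<LinkRec>& links) {
  const int K = ctx.K;
  std::unordered_set<u128, H128> visited;
  visited.reserve(nodemap.n * 2);

  // deterministic iteration: collect and sort canonical k-mers
  std::vector<u128> keys;
  keys.reserve(nodemap.n);
  for (size_t i = 0; i <= nodemap.mask; ++i)
    if (nodemap.used[i]) keys.push_back(nodemap.keys[i]);
  std::sort(keys.begin(), keys.end());

  struct Walk { std::vector<u128> canon; std::string seq; double covsum; Orient first, last; };
  std::vector<Walk> walks;

  for (u128 c : keys) {
    if (visited.count(c)) continue;
    Orient start{c, 0};
    start.r = 0;
    { // compute rc of c
      u128 x = c; u128 r = 0;
      for (int i = 0; i < K; ++i) { r = (r << 2) | (u128)(3 - (int)(x & 3)); x >>= 2; }
      start.r = r;
    }
    // walk backward (successors of reverse orientation) to the unitig start
    Orient cur{start.r, start.f};
    size_t guard = nodemap.n + 2;
    while (guard--) {
      if (ctx.outdeg(cur) != 1) break;
      Orient y; int bfound = -1;
      for (int b = 0; b < 4; ++b) if (ctx.has_edge(cur, b, y)) { bfound = b; break; }
      (void)bfound;
      if (ctx.indeg(y) != 1) break;
      u128 ycan = y.f < y.r ? y.f : y.r;
      if (ycan == c) break;  // circular
      cur = y;
    }
    Orient first{cur.r, cur.f};  // flip back to forward orientation

    Walk w;
    w.first = first;
    w.seq = decode(first.f, K);
    Orient x = first;
    u128 xcan = x.f < x.r ? x.f : x.r;
    const Cnt* it0 = nodemap.find_ptr(xcan);
    w.covsum = it0 ? (double)(it0->s + it0->l) : 0.0;
    w.canon.push_back(xcan);
    visited.insert(xcan);
    guard = nodemap.n + 2;
    while (guard--) {
      if (ctx.outdeg(x) != 1) break;
      Orient y; int bstep = -1;
      for (int b = 0; b < 4; ++b) if (ctx.has_edge(x, b, y)) { bstep = b; break; }
      if (ctx.indeg(y) != 1) break;
      u128 ycan = y.f < y.r ? y.f : y.r;
      if (visited.count(ycan)) break;  // circular component closes
      w.seq.push_back(BIT2BASE[bstep]);
      const Cnt* it = nodemap.find_ptr(ycan);
      w.covsum += it ? (double)(it->s + it->l) : 0.0;
      w.canon.push_back(ycan);
      visited.insert(ycan);
      x = y;
    }
    w.last = x;
    walks.push_back(std::move(w));
  }

  // entry map: oriented k-mer value -> (unitig, end)
  // entering at end0 means reading the stored sequence forward.
  std::unordered_map<u128, std::pair<int,int>, H128> entry;
  entry.reserve(walks.size() * 4);
  for (size_t i = 0; i < walks.size(); ++i) {
    entry[walks[i].first.f] = {(int)i, 0};
    entry[walks[i].last.r]  = {(int)i, 1};  // rc of last k-mer: entering from the right
  }

  unis.resize(walks.size());
  for (size_t i = 0; i < walks.size(); ++i) {
    unis[i].seq = walks[i].seq;
    unis[i].nk  = (int)walks[i].canon.size();
    unis[i].cov = walks[i].covsum / std::max(1, unis[i].nk);
  }

  std::vector<LinkRec> raw;
  for (size_t i = 0; i < walks.size(); ++i) {
    // exits: end1 = forward continuation from last k-mer; end0 = continuation
    // from rc of first k-mer.
    for (int end = 0; end < 2; ++end) {
      Orient ex = end == 1 ? walks[i].last
                           : Orient{walks[i].first.r, walks[i].first.f};
      Orient y; uint32_t ec;
      for (int b = 0; b < 4; ++b) {
        if (!ctx.has_edge(ex, b, y, &ec)) continue;
        auto it = entry.find(y.f);
        if (it == entry.end()) continue;  // target swallowed into a cycle walk
        raw.push_back({(int)i, end, it->second.first, it->second.second, (double)ec});
      }
    }
  }
  // each link appears once from each endpoint; dedupe by canonical key
  for (auto& L : raw) {
    long a = (long)L.u * 2 + L.ue, b = (long)L.v * 2 + L.ve;
    if (a <= b) links.push_back(L);
  }
}

// Canonicalise: orient each unitig to min(seq, rc), sort by sequence, remap links.
static void canonicalise(std::vector<Unitig>& unis, std::vector<LinkRec>& links) {
  size_t n = unis.size();
  std::vector<int> flipped(n, 0);
  for (size_t i = 0; i < n; ++i) {
    std::string rc(unis[i].seq.rbegin(), unis[i].seq.rend());
    for (char& c : rc) c = BIT2BASE[3 - base2bit(c)];
    if (rc < unis[i].seq) { unis[i].seq = rc; flipped[i] = 1; }
  }
  for (auto& L : links) {
    if (flipped[L.u]) L.ue = 1 - L.ue;
    if (flipped[L.v]) L.ve = 1 - L.ve;
  }
  std::vector<int> ord(n);
  for (size_t i = 0; i < n; ++i) ord[i] = (int)i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (unis[a].seq.size() != unis[b].seq.size()) return unis[a].seq.size() > unis[b].seq.size();
    return unis[a].seq < unis[b].seq;
  });
  std::vector<int> rank(n);
  for (size_t i = 0; i < n; ++i) rank[ord[i]] = (int)i;
  std::vector<Unitig> u2(n);
  for (size_t i = 0; i < n; ++i) u2[rank[i]] = unis[i];
  unis.swap(u2);
  for (auto& L : links) { L.u = rank[L.u]; L.v = rank[L.v]; }
  for (auto& L : links) {
    long a = (long)L.u * 2 + L.ue, b = (long)L.v * 2 + L.ve;
    if (a > b) { std::swap(L.u, L.v); std::swap(L.ue, L.ve); }
  }
  std::sort(links.begin(), links.end(), [](const LinkRec& a, const LinkRec& b) {
    if (a.u != b.u) return a.u < b.u;
    if (a.ue != b.ue) return a.ue < b.ue;
    if (a.v != b.v) return a.v < b.v;
    return a.ve < b.ve;
  });
  links.erase(std::unique(links.begin(), links.end(), [](const LinkRec& a, const LinkRec& b) {
    return a.u == b.u && a.ue == b.ue && a.v == b.v && a.ve == b.ve;
  }), links.end());
}

static List export_graph(int K, const std::vector<Unitig>& unis,
                         const std::vector<LinkRec>& links) {
  size_t n = unis.size();
  CharacterVector seqs(n);
  NumericVector cov(n);
  IntegerVector nk(n);
  for (size_t i = 0; i < n; ++i) {
    seqs[i] = unis[i].seq; cov[i] = unis[i].cov; nk[i] = unis[i].nk;
  }
  IntegerMatrix lm(links.size(), 4);
  NumericVector lcov(links.size());
  for (size_t i = 0; i < links.size(); ++i) {
    lm(i, 0) = links[i].u + 1; lm(i, 1) = links[i].ue;
    lm(i, 2) = links[i].v + 1; lm(i, 3) = links[i].ve;
    lcov[i] = links[i].cov;
  }
  colnames(lm) = CharacterVector::create("u", "ue", "v", "ve");
  return List::create(_["k"] = K, _["unitigs"] = seqs, _["cov"] = cov,
                      _["n_kmers"] = nk, _["links"] = lm, _["link_cov"] = lcov);
}

// [[Rcpp::export(name = ".cpp_dbg_build")]]
List cpp_dbg_build(CharacterVector short_reads, CharacterVector long_reads,
                   int k, int short_solid_min, int long_solid_min) {
  if (k < 15 || k % 2 == 0 || k > 63) stop("k must be odd, in [15, 63]");
  KMap counts, edges;
  {
    size_t tot = 0;
    for (R_xlen_t i = 0; i < short_reads.size(); ++i) tot += LENGTH(STRING_ELT(short_reads, i));
    for (R_xlen_t i = 0; i < long_reads.size(); ++i) tot += LENGTH(STRING_ELT(long_reads, i));
    counts.init(tot + 16);
    edges.init(tot + 16);
  }
  for (R_xlen_t i = 0; i < short_reads.size(); ++i)
    count_kmers(std::string(short_reads[i]), k, false, counts);
  for (R_xlen_t i = 0; i < long_reads.size(); ++i)
    count_kmers(std::string(long_reads[i]), k, true, counts);
  for (R_xlen_t i = 0; i < short_reads.size(); ++i)
    count_kmers(std::string(short_reads[i]), k + 1, false, edges);
  for (R_xlen_t i = 0; i < long_reads.size(); ++i)
    count_kmers(std::string(long_reads[i]), k + 1, true, edges);

  // solid filter: short count >= threshold, or a long-read k-mer corroborated
  // by >=1 short occurrence or >= long_solid_min long reads
  KMap solid;
  solid.init(counts.n + 16);
  for (size_t i = 0; i <= counts.mask; ++i) {
    if (!counts.used[i]) continue;
    uint32_t s = counts.vals[i].s, l = counts.vals[i].l;
    bool ok = (s >= (uint32_t)short_solid_min) ||
              (l >= 1 && s >= 1) ||
              (l >= (uint32_t)long_solid_min);
    if (ok) solid[counts.keys[i]] = counts.vals[i];
  }

  Ctx ctx;
  ctx.K = k;
  ctx.mask = (((u128)1) << (2 * k)) - 1;
  ctx.shift = 2 * (k - 1);
  ctx.eshift = 2 * k;
  ctx.nodes = &solid;
  ctx.edges = &edges;

  std::vector<Unitig> unis;
  std::vector<LinkRec> links;
  build_unitigs(ctx, solid, unis, links);
  canonicalise(unis, links);
  return export_graph(k, unis, links);
}

// ---------------------------------------------------------------------------
// Unitig-level graph for simplification and path extension

struct UGraph {
  int K;
  std::vector<Unitig> unis;
  std::vector<std::array<std::vector<std::pair<int,int>>, 2>> adj;  // adj[u][end] -> (v, vend)
  std::vector<LinkRec> links;
  std::vector<char> alive;

  void index() {
    adj.assign(unis.size(), {});
    for (auto& L : links) {
      if (!alive[L.u] || !alive[L.v]) continue;
      adj[L.u][L.ue].push_back({L.v, L.ve});
      if (!(L.u == L.v && L.ue == L.ve))
        adj[L.v][L.ve].push_back({L.u, L.ue});
    }
    for (auto& a : adj) {
      for (int e = 0; e < 2; ++e)
        std::sort(a[e].begin(), a[e].end());
    }
  }
  int deg(int u, int end) const { return (int)adj[u][end].size(); }
  bool dead_end(int u) const {
    if (!alive[u]) return false;
    int d0 = deg(u, 0), d1 = deg(u, 1);
    return (d0 == 0) != (d1 == 0);
  }
};

static UGraph from_list(List g) {
  UGraph ug;
  ug.K = as<int>(g["k"]);
  CharacterVector seqs = g["unitigs"];
  NumericVector cov = g["cov"];
  IntegerVector nk = g["n_kmers"];
  IntegerMatrix lm = g["links"];
  NumericVector lcov = g["link_cov"];
  ug.unis.resize(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    ug.unis[i].seq = std::string(seqs[i]);
    ug.unis[i].cov = cov[i];
    ug.unis[i].nk = nk[i];
  }
  for (int i = 0; i < lm.nrow(); ++i)
    ug.links.push_back({lm(i,0)-1, lm(i,1), lm(i,2)-1, lm(i,3), lcov[i]});
  ug.alive.assign(ug.unis.size(), 1);
  ug.index();
  return ug;
}

static std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (char& c : r) c = BIT2BASE[3 - base2bit(c)];
  return r;
}

// merge maximal linear chains after removals, then re-export
static List recompact_and_export(UGraph& ug) {
  // rebuild link list from alive unitigs
  std::vector<LinkRec> L2;
  for (auto& L : ug.links)
    if (ug.alive[L.u] && ug.alive[L.v]) L2.push_back(L);
  ug.links.swap(L2);
  ug.index();

  size_t n = ug.unis.size();
  std::vector<char> used(n, 0);
  std::vector<Unitig> out;
  std::vector<LinkRec> outlinks;

  // a junction endpoint (u,end): deg != 1, or partner's entry side deg != 1
  auto mergeable = [&](int u, int end) {
    if (ug.deg(u, end) != 1) return false;
    auto pr = ug.adj[u][end][0];
    if (pr.first == u) return false;               // self-loop: keep as junction
    if (ug.deg(pr.first, pr.second) != 1) return false;
    return true;
  };

  // map old (u,end) -> new (unitig,end) for surviving chain endpoints
  std::unordered_map<long, std::pair<int,int>> endmap;

  for (size_t s = 0; s < n; ++s) {
    if (!ug.alive[s] || used[s]) continue;
    // find chain start: walk left from s via end0 while mergeable
    int u = (int)s, ent = 0;  // entering at end0 = reading forward
    size_t guard = n + 2;
    bool circular = false;
    while (guard--) {
      // predecessor side is the entry side 'ent'
      if (!mergeable(u, ent)) break;
      auto pr = ug.adj[u][ent][0];
      if (pr.first == (int)s && (int)pr.second == 1) { circular = true; break; }
      // step to predecessor: we entered it at pr.second; its entry side for
      // forward reading is the other end
      u = pr.first; ent = 1 - pr.second;
      if (u == (int)s) { circular = true; break; }
    }
    if (circular) { u = (int)s; ent = 0; }
    // walk forward collecting the chain
    Unitig merged;
    int cur = u, inend = ent;  // entering cur at side inend
    double covsum = 0; int nksum = 0;
    int firstU = cur, firstIn = inend;
    int lastU = cur, lastOut;
    guard = n + 2;
    while (guard--) {
      used[cur] = 1;
      std::string sq = ug.unis[cur].seq;
      if (inend == 1) sq = revcomp_str(sq);
      if (merged.seq.empty()) merged.seq = sq;
      else merged.seq += sq.substr(ug.K - 1);
      covsum += ug.unis[cur].cov * ug.unis[cur].nk;
      nksum += ug.unis[cur].nk;
      int outend = 1 - inend;
      lastU = cur; lastOut = outend;
      if (!mergeable(cur, outend)) break;
      auto pr = ug.adj[cur][outend][0];
      if (used[pr.first]) break;  // circular closure
      cur = pr.first; inend = pr.second;
    }
    merged.nk = nksum;
    merged.cov = nksum > 0 ? covsum / nksum : 0;
    int id = (int)out.size();
    out.push_back(merged);
    endmap[(long)firstU * 2 + firstIn] = {id, 0};
    endmap[(long)lastU * 2 + lastOut] = {id, 1};
  }

  // remap surviving junction links
  for (auto& L : ug.links) {
    auto a = endmap.find((long)L.u * 2 + L.ue);
    auto b = endmap.find((long)L.v * 2 + L.ve);
    if (a == endmap.end() || b == endmap.end()) continue;  // merged-away internal link
    outlinks.push_back({a->second.first, a->second.second,
                        b->second.first, b->second.second, L.cov});
  }
  canonicalise(out, outlinks);
  return export_graph(ug.K, out, outlinks);
}

// [[Rcpp::export(name = ".cpp_dbg_simplify")]]
List cpp_dbg_simplify(List g, double tip_max_cov, double bulge_floor_frac) {
  UGraph ug = from_list(g);
  int K = ug.K;
  size_t n = ug.unis.size();

  // length-weighted median coverage over unitigs
  std::vector<std::pair<double,double>> wc;
  double wtot = 0;
  for (size_t i = 0; i < n; ++i) {
    wc.push_back({ug.unis[i].cov, (double)ug.unis[i].seq.size()});
    wtot += ug.unis[i].seq.size();
  }
  std::sort(wc.begin(), wc.end());
  double acc = 0, med = 0;
  for (auto& p : wc) { acc += p.second; if (acc >= wtot / 2) { med = p.first; break; } }
  double floor_cov = bulge_floor_frac * med;

  bool changed = true;
  int rounds = 0;
  while (changed && rounds++ < 20) {
    changed = false;
    // (1) short low-coverage dead-end tips (sequencing errors); long tips
    //     (>= 2k) are retained regardless of coverage.
    for (size_t u = 0; u < n; ++u) {
      if (!ug.alive[u] || !ug.dead_end((int)u)) continue;
      if ((int)ug.unis[u].seq.size() >= K + 10) continue;
      if (ug.unis[u].cov > tip_max_cov) continue;
      ug.alive[u] = 0;
      changed = true;
    }
    if (changed) { ug.index(); continue; }

    // (2) exact-duplicate parallel unitigs, and (3) error bulge branches:
    // simple parallel branches sharing both endpoints where one branch falls
    // below the heterozygous-coverage floor while the other does not.
    for (size_t u = 0; u < n && !changed; ++u) {
      if (!ug.alive[u]) continue;
      if (ug.deg((int)u, 0) != 1 || ug.deg((int)u, 1) != 1) continue;
      auto a = ug.adj[u][0][0], b = ug.adj[u][1][0];
      for (size_t v = u + 1; v < n; ++v) {
        if (!ug.alive[v]) continue;
        if (ug.deg((int)v, 0) != 1 || ug.deg((int)v, 1) != 1) continue;
        auto a2 = ug.adj[v][0][0], b2 = ug.adj[v][1][0];
        bool same = (a == a2 && b == b2) || (a == b2 && b == a2);
        if (!same) continue;
        const std::string &su = ug.unis[u].seq, &sv = ug.unis[v].seq;
        if (su == sv || su == revcomp_str(sv)) {
          ug.alive[v] = 0; changed = true; break;
        }
        double cu = ug.unis[u].cov, cvv = ug.unis[v].cov;
        double lo = std::min(cu, cvv), hi = std::max(cu, cvv);
        if (lo < floor_cov && hi >= floor_cov) {
          ug.alive[cu < cvv ? u : v] = 0; changed = true; break;
        }
      }
    }
    if (changed) ug.index();
  }
  return recompact_and_export(ug);
}

// ---------------------------------------------------------------------------
// Path extension

struct Path {
  std::vector<std::pair<int,int>> steps;  // (unitig, entry end): 0 = forward
  std::unordered_map<int,int> usage;
  bool tip_left = false, tip_right = false;
};

// is w a long dead-end tip?
static bool is_long_tip(const UGraph& ug, int w, int tip_len) {
  return ug.dead_end(w) && (int)ug.unis[w].seq.size() >= tip_len;
}

// Extend path at its right end. Returns list of resulting paths (forks).
static void extend_right(const UGraph& ug, Path p, bool tip_rule, int tip_len,
                         int usage_cap, int max_paths, std::vector<Path>& done) {
  std::vector<Path> active{std::move(p)};
  std::vector<Path> finished;
  size_t guard = ug.unis.size() * 4 + 16;
  while (!active.empty() && guard--) {
    Path cur = std::move(active.back());
    active.pop_back();
    bool extended = true;
    while (extended && guard--) {
      extended = false;
      auto [u, ent] = cur.steps.back();
      int outend = 1 - ent;
      std::vector<std::pair<int,int>> cands;
      for (auto& pr : ug.adj[u][outend]) {
        auto it = cur.usage.find(pr.first);
        if (it != cur.usage.end() && it->second >= usage_cap) continue;
        cands.push_back(pr);
      }
      if (cands.empty()) break;
      if (cands.size() == 1) {
        int v = cands[0].first, vent = cands[0].second;
        if (tip_rule) {
          // vicinity: unitigs incident to the junction (other entrants at v's
          // entry side) and v's immediate far-side neighbours; u and v excluded
          bool blocked = false;
          auto check = [&](const std::vector<std::pair<int,int>>& lst) {
            for (auto& pr : lst) {
              if (pr.first == u || pr.first == v) continue;
              if (is_long_tip(ug, pr.first, tip_len)) { blocked = true; return; }
            }
          };
          check(ug.adj[v][vent]);
          if (!blocked) check(ug.adj[v][1 - vent]);
          if (!blocked) check(ug.adj[u][outend]);
          if (blocked) { cur.tip_right = true; break; }
        }
        cur.steps.push_back({v, vent});
        cur.usage[v]++;
        extended = true;
      } else {
        // a long tip among the alternatives signals a coverage drop bridged
        // by a repeat: forking would spell a chimeric (false-deletion) path
        if (tip_rule) {
          bool blocked = false;
          for (auto& pr : ug.adj[u][outend]) {
            if (pr.first != u && is_long_tip(ug, pr.first, tip_len)) { blocked = true; break; }
          }
          if (blocked) { cur.tip_right = true; break; }
        }
        // fork: spell every branch (relaxed deduplication keeps both alleles)
        for (auto& pr : cands) {
          if ((int)(active.size() + finished.size()) >= max_paths) break;
          Path br = cur;
          br.steps.push_back({pr.first, pr.second});
          br.usage[pr.first]++;
          active.push_back(std::move(br));
        }
        cur.steps.clear();  // superseded by branches
        break;
      }
    }
    if (!cur.steps.empty()) finished.push_back(std::move(cur));
  }
  for (auto& f : finished) done.push_back(std::move(f));
  for (auto& f : active) if (!f.steps.empty()) done.push_back(std::move(f));
}

static Path reverse_path(const Path& p) {
  Path r;
  r.usage = p.usage;
  r.tip_right = p.tip_left;
  r.tip_left = p.tip_right;
  for (auto it = p.steps.rbegin(); it != p.steps.rend(); ++it)
    r.steps.push_back({it->first, 1 - it->second});
  return r;
}

static std::string spell(const UGraph& ug, const Path& p) {
  std::string s;
  for (auto& [u, ent] : p.steps) {
    std::string sq = ug.unis[u].seq;
    if (ent == 1) sq = revcomp_str(sq);
    if (s.empty()) s = sq;
    else s += sq.substr(ug.K - 1);
  }
  return s;
}

// [[Rcpp::export(name = ".cpp_dbg_extend")]]
List cpp_dbg_extend(List g, bool tip_rule, int tip_len, int usage_cap,
                    int max_paths) {
  UGraph ug = from_list(g);
  size_t n = ug.unis.size();
  std::vector<int> order(n);
  for (size_t i = 0; i < n; ++i) order[i] = (int)i;
  std::sort(order.begin(), order.end(), [&](int a, int b) {
    if (ug.unis[a].seq.size() != ug.unis[b].seq.size())
      return ug.unis[a].seq.size() > ug.unis[b].seq.size();
    return ug.unis[a].seq < ug.unis[b].seq;
  });

  std::vector<int> global_used(n, 0);
  std::vector<std::string> contigs;
  std::vector<bool> tipped;
  std::vector<double> pcov;

  for (int seed : order) {
    if (global_used[seed] > 0) continue;
    Path p0;
    p0.steps.push_back({seed, 0});
    p0.usage[seed] = 1;
    std::vector<Path> rightDone;
    extend_right(ug, p0, tip_rule, tip_len, usage_cap, max_paths, rightDone);
    std::vector<Path> full;
    for (auto& rp : rightDone) {
      Path rev = reverse_path(rp);
      std::vector<Path> leftDone;
      extend_right(ug, rev, tip_rule, tip_len, usage_cap, max_paths, leftDone);
      for (auto& lp : leftDone) full.push_back(reverse_path(lp));
      if ((int)full.size() >= max_paths) break;
    }
    std::unordered_set<std::string> seen;
    for (auto& f : full) {
      std::string s = spell(ug, f);
      std::string key = std::min(s, revcomp_str(s));
      if (seen.count(key)) continue;
      seen.insert(key);
      double cs = 0; int nk = 0;
      for (auto& [u, e] : f.steps) { cs += ug.unis[u].cov * ug.unis[u].nk; nk += ug.unis[u].nk; }
      contigs.push_back(s);
      tipped.push_back(f.tip_left || f.tip_right);
      pcov.push_back(nk > 0 ? cs / nk : 0);
      for (auto& [u, e] : f.steps) global_used[u]++;
    }
  }
  return List::create(_["contigs"] = wrap(contigs),
                      _["terminated_by_tip_rule"] = wrap(tipped),
                      _["mean_cov"] = wrap(pcov));
}
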