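// Glocal contig-to-window alignment: global in the query, local in the
// reference. Small problems get exact affine-gap (Gotoh) DP with traceback;
// large contigs are aligned by exact-match seeding on window-unique k-mers,
// collinear chaining, and banded affine DP between adjacent chain anchors.
//
// Scoring: match +1, mismatch -mm, gap of length g costs -(open + g*ext).

#include <Rcpp.h>
#include <vector>
#include <string>
#include <unordered_map>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

static const int NEG = -100000000;

struct Op { char op; int len; };
typedef std::vector<Op> Ops;

static void push_op(Ops& ops, char op, int len) {
  if (len <= 0) return;
  if (!ops.empty() && ops.back().op == op) ops.back().len += len;
  else ops.push_back({op, len});
}
static void append_ops(Ops& dst, const Ops& src) {
  for (auto& o : src) push_op(dst, o.op, o.len);
}

// ---------------------------------------------------------------------------
// Exact affine DP. free_start: alignment may begin at any ref position
// (H[0][j] = 0); free_end: score taken as max over last row. Query is always
// global. Returns score; fills ops and ref_start/ref_end (0-based, half-open).
static int affine_dp(const std::string& q, const std::string& r,
                     int mm, int open, int ext,
                     bool free_start, bool free_end,
                     Ops& ops, int& ref_start, int& ref_end) {
  const int n = (int)q.size(), m = (int)r.size();
  ops.clear();
  if (n == 0) {
    if (free_start || free_end || m == 0) { ref_start = free_start ? m : 0; ref_end = ref_start; return 0; }
    push_op(ops, 'D', m); ref_start = 0; ref_end = m; return -(open + ext * m);
  }
  if (m == 0) {
    push_op(ops, 'I', n); ref_start = 0; ref_end = 0; return -(open + ext * n);
  }
  std::vector<int> H(m + 1), Hprev(m + 1);
  // trace matrices: tH in {0 diag, 1 from E, 2 from F, 3 start}; tE, tF in {0 open, 1 continue}
  std::vector<uint8_t> tH((size_t)(n + 1) * (m + 1)), tE((size_t)(n + 1) * (m + 1)),
      tF((size_t)(n + 1) * (m + 1));
  auto idx = [m](int i, int j) { return (size_t)i * (m + 1) + j; };

  for (int j = 0; j <= m; ++j) {
    if (free_start) {
      Hprev[j] = 0;
      tH[idx(0, j)] = 3;
    } else {
      Hprev[j] = j == 0 ? 0 : -(open + ext * j);
      tH[idx(0, j)] = j == 0 ? 3 : 1;
      tE[idx(0, j)] = 1;
    }
  }
  std::vector<int> Fcol(m + 1, NEG);
  for (int i = 1; i <= n; ++i) {
    // j = 0 column: only insertions
    int fo = Hprev[0] - open - ext, fc = Fcol[0] - ext;
    Fcol[0] = std::max(fo, fc);
    tF[idx(i, 0)] = fc > fo ? 1 : 0;
    H[0] = Fcol[0];
    tH[idx(i, 0)] = 2;
    int Ecur = NEG;
    for (int j = 1; j <= m; ++j) {
      int eo = H[j - 1] - open - ext, ec = Ecur > NEG / 2 ? Ecur - ext : NEG;
      Ecur = std::max(eo, ec);
      tE[idx(i, j)] = ec > eo ? 1 : 0;
      int fo2 = Hprev[j] > NEG / 2 ? Hprev[j] - open - ext : NEG;
      int fc2 = Fcol[j] > NEG / 2 ? Fcol[j] - ext : NEG;
      Fcol[j] = std::max(fo2, fc2);
      tF[idx(i, j)] = fc2 > fo2 ? 1 : 0;
      int sub = Hprev[j - 1] > NEG / 2 ? Hprev[j - 1] + (q[i - 1] == r[j - 1] ? 1 : -mm) : NEG;
      int best = sub; uint8_t tb = 0;
      if (Ecur > best) { best = Ecur; tb = 1; }
      if (Fcol[j] > best) { best = Fcol[j]; tb = 2; }
      H[j] = best;
      tH[idx(i, j)] = tb;
    }
    std::swap(H, Hprev);
  }
  // Hprev now holds row n
  int bestj = m, best = Hprev[m];
  if (free_end) {
    for (int j = 0; j <= m; ++j)
      if (Hprev[j] > best) { best = Hprev[j]; bestj = j; }
  }
  // traceback
  Ops rev;
  int i = n, j = bestj, state = 0;  // 0=H, 1=E, 2=F
  while (i > 0 || (!free_start && j > 0)) {
    if (state == 0) {
      uint8_t t = tH[idx(i, j)];
      if (t == 3) break;  // free start row
      if (t == 0) { push_op(rev, 'M', 1); --i; --j; }
      else state = t;  // move into gap state
    } else if (state == 1) {
      uint8_t t = tE[idx(i, j)];
      push_op(rev, 'D', 1); --j;
      if (t == 0) state = 0;
    } else {
      uint8_t t = tF[idx(i, j)];
      push_op(rev, 'I', 1); --i;
      if (t == 0) state = 0;
    }
    if (i == 0 && state == 0 && free_start) break;
  }
  ref_start = j;
  ref_end = bestj;
  ops.clear();
  for (auto it = rev.rbegin(); it != rev.rend(); ++it) push_op(ops, it->op, it->len);
  return best;
}

// Banded fixed-end global affine DP (both sequences fully consumed).
// Band follows the main diagonal, widened by the expected indel size.
static int banded_global(const std::string& q, const std::string& r,
                         int mm, int open, int ext, Ops& ops) {
  const int n = (int)q.size(), m = (int)r.size();
  ops.clear();
  if (n == 0) { push_op(ops, 'D', m); return m == 0 ? 0 : -(open + ext * m); }
  if (m == 0) { push_op(ops, 'I', n); return -(open + ext * n); }
  if ((double)n * m <= 4e6) {
    int rs, re;
    return affine_dp(q, r, mm, open, ext, false, false, ops, rs, re);
  }
  int d = m - n;
  int w = 50 + (int)(0.1 * std::abs(d)) + 50;  // half-width each side of the diagonal corridor
  int dmin = std::min(0, d) - w, dmax = std::max(0, d) + w;
  int W = dmax - dmin + 1;
  if ((double)(n + 1) * W > 6.4e7) {  // degenerate gap between anchors: crude join
    push_op(ops, 'I', n);
    push_op(ops, 'D', m);
    return -(2 * open + ext * (n + m));
  }
  auto jlo = [&](int i) { return std::max(0, i + dmin); };
  auto jhi = [&](int i) { return std::min(m, i + dmax); };
  std::vector<int> H(W, NEG), E(W, NEG), F(W, NEG), Hp(W, NEG), Fp(W, NEG);
  std::vector<uint8_t> tH((size_t)(n + 1) * W), tE((size_t)(n + 1) * W), tF((size_t)(n + 1) * W);
  auto off = [&](int i, int j) { return j - (i + dmin); };  // not used: band indexed by j-dmin-i
  (void)off;
  auto idx = [&](int i, int j) { return (size_t)i * W + (j - i - dmin); };
  // row 0
  for (int j = jlo(0); j <= jhi(0); ++j) {
    int o = j - dmin;
    H[o] = j == 0 ? 0 : -(open + ext * j);
    E[o] = j == 0 ? NEG : H[o];
    tH[idx(0, j)] = j == 0 ? 3 : 1;
    tE[idx(0, j)] = 1;
  }
  Hp = H; Fp = F;
  for (int i = 1; i <= n; ++i) {
    std::fill(H.begin(), H.end(), NEG);
    std::fill(E.begin(), E.end(), NEG);
    std::fill(F.begin(), F.end(), NEG);
    int lo = jlo(i), hi = jhi(i);
    int Ecur = NEG;
    for (int j = lo; j <= hi; ++j) {
      int o = j - i - dmin;         // this row's band offset
      int op_ = j - (i - 1) - dmin; // previous row's offset for same j
      int Hdiag = NEG, Hup = NEG, Fup = NEG;
      if (j - 1 >= jlo(i - 1) && j - 1 <= jhi(i - 1)) Hdiag = Hp[op_ - 1];
      if (j >= jlo(i - 1) && j <= jhi(i - 1)) { Hup = Hp[op_]; Fup = Fp[op_]; }
      int Hleft = (j - 1 >= lo) ? H[o - 1] : NEG;
      int eo = Hleft > NEG / 2 ? Hleft - open - ext : NEG;
      int ec = (j - 1 >= lo && Ecur > NEG / 2) ? Ecur - ext : NEG;
      Ecur = std::max(eo, ec);
      tE[idx(i, j)] = (ec > eo) ? 1 : 0;
      int fo = Hup > NEG / 2 ? Hup - open - ext : NEG;
      int fc = Fup > NEG / 2 ? Fup - ext : NEG;
      int Fcur = std::max(fo, fc);
      tF[idx(i, j)] = (fc > fo) ? 1 : 0;
      int sub = (j >= 1 && Hdiag > NEG / 2) ? Hdiag + (q[i - 1] == r[j - 1] ? 1 : -mm) : NEG;
      int best = sub; uint8_t tb = 0;
      if (Ecur > best) { best = Ecur; tb = 1; }
      if (Fcur > best) { best = Fcur; tb = 2; }
      H[o] = best; E[o] = Ecur; F[o] = Fcur;
      tH[idx(i, j)] = tb;
    }
    std::swap(H, Hp);
    std::swap(F, Fp);
  }
  int score = Hp[m - n - dmin];
  // traceback
  Ops rev;
  int i = n, j = m, state = 0;
  size_t guard = (size_t)(n + m) * 2 + 8;
  while ((i > 0 || j > 0) && guard--) {
    if (state == 0) {
      uint8_t t = tH[idx(i, j)];
      if (t == 3) break;
      if (t == 0) { push_op(rev, 'M', 1); --i; --j; }
      else state = t;
    } else if (state == 1) {
      uint8_t t = tE[idx(i, j)];
      push_op(rev, 'D', 1); --j;
      if (t == 0) state = 0;
    } else {
      uint8_t t = tF[idx(i, j)];
      push_op(rev, 'I', 1); --i;
      if (t == 0) state = 0;
    }
  }
  for (auto it = rev.rbegin(); it != rev.rend(); ++it) push_op(ops, it->op, it->len);
  return score;
}

// ---------------------------------------------------------------------------
// Seeding and chaining

struct Block { int qs, rs, len; };  // len in bases

typedef std::unordered_map<uint64_t, int> SeedIndex;  // kmer -> pos, -2 = repeated

static inline int b2(char c) {
  switch (c) { case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3; }
  return -1;
}

static SeedIndex build_seed_index(const std::string& r, int seed) {
  SeedIndex pos;
  if ((int)r.size() < seed) return pos;
  pos.reserve(r.size());
  uint64_t mask = seed >= 32 ? ~0ULL : ((1ULL << (2 * seed)) - 1);
  uint64_t h = 0; int len = 0;
  for (int i = 0; i < (int)r.size(); ++i) {
    int b = b2(r[i]);
    if (b < 0) { len = 0; h = 0; continue; }
    h = ((h << 2) | (uint64_t)b) & mask;
    if (++len >= seed) {
      auto it = pos.find(h);
      if (it == pos.end()) pos[h] = i - seed + 1;
      else it->second = -2;
    }
  }
  return pos;
}

static std::vector<Block> collect_blocks_idx(const std::string& q,
                                             const SeedIndex& pos, int seed) {
  if ((int)q.size() < seed) return {};
  uint64_t mask = seed >= 32 ? ~0ULL : ((1ULL << (2 * seed)) - 1);
  std::vector<std::pair<int,int>> anchors;  // (qpos, rpos)
  uint64_t h = 0; int len = 0;
  for (int i = 0; i < (int)q.size(); ++i) {
    int b = b2(q[i]);
    if (b < 0) { len = 0; h = 0; continue; }
    h = ((h << 2) | (uint64_t)b) & mask;
    if (++len >= seed) {
      auto it = pos.find(h);
      if (it != pos.end() && it->second >= 0)
        anchors.push_back({i - seed + 1, it->second});
    }
  }
  std::sort(anchors.begin(), anchors.end());
  // merge runs on the same diagonal with consecutive positions into blocks
  std::vector<Block> blocks;
  for (auto& a : anchors) {
    if (!blocks.empty()) {
      Block& b = blocks.back();
      if (a.first == b.qs + b.len - seed + 1 && a.second == b.rs + b.len - seed + 1) {
        b.len += 1;
        continue;
      }
    }
    blocks.push_back({a.first, a.second, seed});
  }
  return blocks;
}

static std::vector<Block> collect_blocks(const std::string& q, const std::string& r,
                                         int seed) {
  return collect_blocks_idx(q, build_seed_index(r, seed), seed);
}

static std::vector<Block> chain_blocks(std::vector<Block> blocks) {
  if (blocks.empty()) return blocks;
  if (blocks.size() > 5000) {
    std::sort(blocks.begin(), blocks.end(), [](const Block& a, const Block& b) { return a.len > b.len; });
    blocks.resize(5000);
  }
  std::sort(blocks.begin(), blocks.end(), [](const Block& a, const Block& b) { return a.qs < b.qs; });
  int nb = (int)blocks.size();
  std::vector<double> sc(nb);
  std::vector<int> prev(nb, -1);
  double best = -1e18; int besti = 0;
  for (int i = 0; i < nb; ++i) {
    sc[i] = blocks[i].len;
    for (int j = 0; j < nb; ++j) {
      if (j == i) continue;
      int dq = blocks[i].qs - (blocks[j].qs + blocks[j].len);
      int dr = blocks[i].rs - (blocks[j].rs + blocks[j].len);
      if (dq < -blocks[i].len / 2 || dr < -blocks[i].len / 2) continue;
      if (blocks[j].qs >= blocks[i].qs) continue;
      // SV-scale gaps get a capped (concave-like) penalty so true flank
      // blocks across a large indel stay in the chain
      double pen = std::min(0.05 * std::abs(dq - dr), 200.0) +
                   0.01 * std::min(std::abs(dq), std::abs(dr)) + 1;
      double s = sc[j] + blocks[i].len - pen;
      if (s > sc[i]) { sc[i] = s; prev[i] = j; }
    }
    if (sc[i] > best) { best = sc[i]; besti = i; }
  }
  std::vector<Block> chain;
  for (int i = besti; i >= 0; i = prev[i]) chain.push_back(blocks[i]);
  std::reverse(chain.begin(), chain.end());
  // trim overlaps between adjacent blocks
  std::vector<Block> out;
  for (auto b : chain) {
    if (!out.empty()) {
      Block& p = out.back();
      int dq = b.qs - (p.qs + p.len), dr = b.rs - (p.rs + p.len);
      int trim = std::max(0, -std::min(dq, dr));
      b.qs += trim; b.rs += trim; b.len -= trim;
      if (b.len <= 0) continue;
    }
    out.push_back(b);
  }
  return out;
}

// ---------------------------------------------------------------------------

struct OpStats {
  long score = 0, nmatch = 0, nmism = 0, ngapopen = 0, ngapbases = 0;
  int ref_end = 0;
  double identity_gc() const {
    double d = (double)(nmatch + nmism + ngapopen);
    return d > 0 ? nmatch / d : 0.0;
  }
};

static OpStats score_ops(const std::string& q, const std::string& r,
                         int ref_start, const Ops& ops, int mm, int open, int ext) {
  OpStats st;
  int qi = 0, rj = ref_start;
  for (auto& o : ops) {
    if (o.op == 'M') {
      for (int t = 0; t < o.len; ++t) {
        if (q[qi + t] == r[rj + t]) { ++st.nmatch; st.score += 1; }
        else { ++st.nmism; st.score -= mm; }
      }
      qi += o.len; rj += o.len;
    } else if (o.op == 'I') {
      st.score -= open + (long)ext * o.len; ++st.ngapopen; st.ngapbases += o.len; qi += o.len;
    } else if (o.op == 'D') {
      st.score -= open + (long)ext * o.len; ++st.ngapopen; st.ngapbases += o.len; rj += o.len;
    }
  }
  st.ref_end = rj;
  return st;
}

static List finish(const std::string& q, const std::string& r, int ref_start,
                   const Ops& ops, int mm, int open, int ext) {
  OpStats st = score_ops(q, r, ref_start, ops, mm, open, ext);
  std::string cig;
  for (auto& o : ops) { cig += std::to_string(o.len); cig += o.op; }
  return List::create(_["found"] = true, _["score"] = (double)st.score,
                      _["ref_start"] = ref_start, _["ref_end"] = st.ref_end,
                      _["cigar"] = cig, _["n_match"] = (double)st.nmatch,
                      _["n_mismatch"] = (double)st.nmism,
                      _["n_gap_open"] = (double)st.ngapopen,
                      _["n_gap_bases"] = (double)st.ngapbases,
                      _["identity_gc"] = st.identity_gc());
}

// chain the given blocks and stitch a full query-global alignment; returns
// false when no blocks are available
static bool chain_and_stitch(const std::string& q, const std::string& r,
                             std::vector<Block> blocks, int mm, int open,
                             int ext, Ops& ops, int& ref_start) {
  std::vector<Block> chain = chain_blocks(std::move(blocks));
  if (chain.empty()) return false;
  ops.clear();
  ref_start = -1;
  // head: query prefix before the first block, ref end fixed at chain start
  {
    Block& b0 = chain[0];
    int qh = b0.qs;
    if (qh > 0) {
      int span = (int)(1.2 * qh + 200);
      int r0 = std::max(0, b0.rs - span);
      if ((double)qh * (b0.rs - r0) > 1.6e7) {  // unanchorable head: clip it
        ref_start = b0.rs;
        push_op(ops, 'I', qh);
      } else {
        Ops hops; int hrs, hre;
        affine_dp(q.substr(0, qh), r.substr(r0, b0.rs - r0), mm, open, ext,
                  true, false, hops, hrs, hre);
        ref_start = r0 + hrs;
        append_ops(ops, hops);
      }
    } else {
      ref_start = b0.rs;
    }
  }
  for (size_t i = 0; i < chain.size(); ++i) {
    if (i > 0) {
      Block& p = chain[i - 1];
      Block& b = chain[i];
      int q0 = p.qs + p.len, q1 = b.qs;
      int r0 = p.rs + p.len, r1 = b.rs;
      Ops gops;
      banded_global(q.substr(q0, q1 - q0), r.substr(r0, r1 - r0), mm, open, ext, gops);
      append_ops(ops, gops);
    }
    push_op(ops, 'M', chain[i].len);
  }
  // tail: query suffix after the last block, ref start fixed
  {
    Block& bl = chain.back();
    int q0 = bl.qs + bl.len, r0 = bl.rs + bl.len;
    int qt = (int)q.size() - q0;
    if (qt > 0) {
      int span = std::min((int)r.size() - r0, (int)(1.2 * qt + 200));
      if ((double)qt * span > 1.6e7) {
        push_op(ops, 'I', qt);
      } else {
        Ops tops; int trs, tre;
        affine_dp(q.substr(q0, qt), r.substr(r0, span), mm, open, ext,
                  false, true, tops, trs, tre);
        append_ops(ops, tops);
      }
    }
  }
  return true;
}

// [[Rcpp::export(name = ".cpp_align")]]
List cpp_align(std::string q, std::string r, int mm, int open, int ext,
               int seed, double full_limit) {
  if (q.empty() || r.empty())
    return List::create(_["found"] = false);
  if ((double)q.size() * (double)r.size() <= full_limit) {
    Ops ops; int rs, re;
    affine_dp(q, r, mm, open, ext, true, true, ops, rs, re);
    return finish(q, r, rs, ops, mm, open, ext);
  }
  Ops ops; int ref_start;
  if (!chain_and_stitch(q, r, collect_blocks(q, r, seed), mm, open, ext,
                        ops, ref_start))
    return List::create(_["found"] = false);
  return finish(q, r, ref_start, ops, mm, open, ext);
}

// Anchor many flank sequences inside one long read: the read's seed index
// is built once. Returns per flank: found, ref_start, ref_end, identity
// (gap-compressed), aligned M-columns.
// [[Rcpp::export(name = ".cpp_anchor_in_read")]]
NumericMatrix cpp_anchor_in_read(CharacterVector flanks, std::string read,
                                 int mm, int open, int ext, int seed) {
  SeedIndex idx = build_seed_index(read, seed);
  NumericMatrix out(flanks.size(), 5);
  colnames(out) = CharacterVector::create("found", "ref_start", "ref_end",
                                          "identity", "aligned");
  for (R_xlen_t i = 0; i < flanks.size(); ++i) {
    std::string q = std::string(flanks[i]);
    Ops ops; int rs;
    if (!chain_and_stitch(q, read, collect_blocks_idx(q, idx, seed),
                          mm, open, ext, ops, rs)) {
      out(i, 0) = 0;
      continue;
    }
    OpStats st = score_ops(q, read, rs, ops, mm, open, ext);
    out(i, 0) = 1; out(i, 1) = rs; out(i, 2) = st.ref_end;
    out(i, 3) = st.identity_gc(); out(i, 4) = st.nmatch + st.nmism;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Small helpers shared by the R layer

// [[Rcpp::export(name = ".cpp_cigar_stats")]]
NumericMatrix cpp_cigar_stats(CharacterVector cigars) {
  // per CIGAR: reference span, query (stored-sequence) length, soft-clipped bases
  NumericMatrix out(cigars.size(), 3);
  colnames(out) = CharacterVector::create("ref_width", "query_width", "soft_clipped");
  for (R_xlen_t i = 0; i < cigars.size(); ++i) {
    if (cigars[i] == NA_STRING) { out(i, 0) = NA_REAL; out(i, 1) = NA_REAL; out(i, 2) = NA_REAL; continue; }
    std::string c = std::string(cigars[i]);
    long rw = 0, qw = 0, sc = 0, len = 0;
    for (char ch : c) {
      if (ch >= '0' && ch <= '9') { len = len * 10 + (ch - '0'); continue; }
      switch (ch) {
        case 'M': case '=': case 'X': rw += len; qw += len; break;
        case 'D': case 'N': rw += len; break;
        case 'I': qw += len; break;
        case 'S': qw += len; sc += len; break;
        default: break;  // H, P consume nothing stored
      }
      len = 0;
    }
    out(i, 0) = rw; out(i, 1) = qw; out(i, 2) = sc;
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_min_phred")]]
IntegerVector cpp_min_phred(CharacterVector quals, int offset) {
  IntegerVector out(quals.size());
  for (R_xlen_t i = 0; i < quals.size(); ++i) {
    if (quals[i] == NA_STRING) { out[i] = NA_INTEGER; continue; }
    std::string s = std::string(quals[i]);
    if (s.empty() || s == "*") { out[i] = NA_INTEGER; continue; }
    int mn = 1000;
    for (char c : s) mn = std::min(mn, (int)c - offset);
    out[i] = mn;
  }
  return out;
}
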