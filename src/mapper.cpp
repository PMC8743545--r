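#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <string>

using namespace Rcpp;

// Exact k-mer seed + ungapped-extend mapper. References are indexed at
// every position; circular references are indexed over the first copy of a
// doubled sequence so alignments may run across the origin and are then
// reported modulo n (split at the origin to keep 1-based closed intervals
// inside [1, n]).
//
// Scoring is +1 match / -3 mismatch. Per (replicon, strand, diagonal)
// candidate the best-scoring ungapped block is found by a max-subarray scan
// of the whole diagonal, so substitution errors shorten nothing and chimeric
// queries (junction-spanning reads/contigs) fall apart into one block per
// locus, which is exactly the split evidence junction calling consumes.

static inline int code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
  }
  return -1;
}

static inline char comp(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
  }
  return 'N';
}

struct Cand {
  int ref;        // 0-based replicon index
  int strand;     // 0 = '+', 1 = '-'
  int qs, qe;     // 0-based inclusive, ORIGINAL read orientation
  long rs, re;    // 0-based inclusive on reference (already mod n)
  int mism;
  long score;
};

struct Hit { int minq, maxq; };

// [[Rcpp::export]]
List cpp_map_queries(CharacterVector ref_seqs, LogicalVector circular,
                     CharacterVector queries, int k, int min_anchor,
                     double max_mismatch_rate, int max_segments = 10,
                     int seed_stride = 10) {
  // the reference is indexed at every position, so probing query k-mers at
  // a stride still guarantees a seed inside any exact stretch of length
  // >= k + seed_stride - 1; with k = 31 and stride 10 that is 40 bp, below
  // the 50 bp minimum anchor, so no reportable segment is missed
  if (seed_stride < 1) seed_stride = 1;
  const int nref = ref_seqs.size();
  if (k < 4 || k > 31) stop("k must be between 4 and 31");
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);

  // working sequences (doubled for circular) and true lengths
  std::vector<std::string> work(nref);
  std::vector<long> truelen(nref);
  for (int i = 0; i < nref; ++i) {
    std::string s = as<std::string>(ref_seqs[i]);
    truelen[i] = (long)s.size();
    if (circular[i]) s += s;  // allow origin-crossing alignment
    work[i] = s;
  }

  // index: k-mer -> packed (ref, pos); only positions < truelen are indexed
  std::unordered_map<uint64_t, std::vector<uint64_t>> index;
  index.reserve(1 << 20);
  for (int i = 0; i < nref; ++i) {
    const std::string &s = work[i];
    long lim = std::min((long)s.size() - k, truelen[i] - 1);
    uint64_t h = 0;
    int run = 0;
    for (long p = 0; p < (long)s.size() && p <= lim + k - 1; ++p) {
      int c = code(s[p]);
      if (c < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)c) & mask;
      if (++run >= k) {
        long start = p - k + 1;
        if (start <= lim)
          index[h].push_back(((uint64_t)i << 40) | (uint64_t)start);
      }
    }
  }

  std::vector<int> o_qidx, o_qs, o_qe, o_qlen, o_ref, o_strand, o_mism, o_role;
  std::vector<long> o_rs, o_re;
  std::vector<int> o_ambig;

  const int nq = queries.size();
  for (int qi = 0; qi < nq; ++qi) {
    std::string q = as<std::string>(queries[qi]);
    const int qlen = (int)q.size();
    if (qlen < k) stop("query %d is shorter than k = %d", qi + 1, k);
    std::string qr(qlen, 'N');
    for (int j = 0; j < qlen; ++j) qr[j] = comp(q[qlen - 1 - j]);

    std::vector<Cand> cands;
    for (int strand = 0; strand < 2; ++strand) {
      const std::string &qq = (strand == 0) ? q : qr;
      // collect seed hits grouped by (ref, diagonal)
      std::unordered_map<uint64_t, Hit> groups;
      uint64_t h = 0;
      int run = 0;
      for (int p = 0; p < qlen; ++p) {
        int c = code(qq[p]);
        if (c < 0) { run = 0; h = 0; continue; }
        h = ((h << 2) | (uint64_t)c) & mask;
        if (++run < k) continue;
        int qp = p - k + 1;
        if (qp % seed_stride != 0 && qp != qlen - k) continue;
        auto it = index.find(h);
        if (it == index.end()) continue;
        for (uint64_t packed : it->second) {
          int ref = (int)(packed >> 40);
          long rpos = (long)(packed & 0xFFFFFFFFFFULL);
          long diag = rpos - qp;
          uint64_t key = ((uint64_t)ref << 34) |
                         (uint64_t)(diag + (1LL << 32));
          auto g = groups.find(key);
          if (g == groups.end()) groups.emplace(key, Hit{qp, qp});
          else {
            if (qp < g->second.minq) g->second.minq = qp;
            if (qp > g->second.maxq) g->second.maxq = qp;
          }
        }
      }
      // one Kadane pass per diagonal -> best ungapped block
      for (auto &kv : groups) {
        int ref = (int)(kv.first >> 34);
        long diag = (long)(kv.first & ((1ULL << 34) - 1)) - (1LL << 32);
        const std::string &w = work[ref];
        long qlo = std::max(0L, -diag);
        long qhi = std::min((long)qlen, (long)w.size() - diag);
        long best = 0, bqs = -1, bqe = -1;
        long cur = 0, cqs = qlo;
        for (long qp = qlo; qp < qhi; ++qp) {
          long sc = (qq[qp] == w[qp + diag]) ? 1 : -3;
          if (cur <= 0) { cur = sc; cqs = qp; }
          else cur += sc;
          if (cur > best) { best = cur; bqs = cqs; bqe = qp; }
        }
        if (bqs < 0) continue;
        long len = bqe - bqs + 1;
        if (len < min_anchor || len < k) continue;
        int mism = 0;
        for (long qp = bqs; qp <= bqe; ++qp)
          if (qq[qp] != w[qp + diag]) ++mism;
        if (mism > max_mismatch_rate * len) continue;
        long rs = bqs + diag, re = bqe + diag;
        // emit (splitting at the origin for circular refs)
        long n = truelen[ref];
        std::vector<std::array<long, 2>> pieces;
        if (re < n) pieces.push_back({bqs, bqe});
        else if (rs >= n) pieces.push_back({bqs, bqe});  // fully in 2nd copy
        else {
          pieces.push_back({bqs, n - 1 - diag});
          pieces.push_back({n - diag, bqe});
        }
        for (auto &pc : pieces) {
          long pqs = pc[0], pqe = pc[1];
          if (pqe - pqs + 1 < std::max(min_anchor, k)) continue;
          int pm = 0;
          for (long qp = pqs; qp <= pqe; ++qp)
            if (qq[qp] != w[qp + diag]) ++pm;
          long prs = (pqs + diag) % n, pre = (pqe + diag) % n;
          Cand cd;
          cd.ref = ref; cd.strand = strand;
          cd.rs = prs; cd.re = pre; cd.mism = pm;
          cd.score = (pqe - pqs + 1) - 4L * pm;
          if (strand == 0) { cd.qs = (int)pqs; cd.qe = (int)pqe; }
          else { cd.qs = qlen - 1 - (int)pqe; cd.qe = qlen - 1 - (int)pqs; }
          cands.push_back(cd);
        }
      }
    }
    if (cands.empty()) continue;
    std::sort(cands.begin(), cands.end(), [](const Cand &a, const Cand &b) {
      if (a.score != b.score) return a.score > b.score;
      if (a.ref != b.ref) return a.ref < b.ref;
      if (a.rs != b.rs) return a.rs < b.rs;
      return a.strand < b.strand;
    });
    // greedy selection: primary = best; later candidates kept as
    // supplementary only if they cover a mostly-new part of the query
    std::vector<int> kept;
    bool ambiguous = false;
    for (size_t ci = 0; ci < cands.size(); ++ci) {
      const Cand &c = cands[ci];
      long clen = c.qe - c.qs + 1;
      long maxov = 0;
      for (int kj : kept) {
        const Cand &kc = cands[kj];
        long ov = std::min((long)c.qe, (long)kc.qe) -
                  std::max((long)c.qs, (long)kc.qs) + 1;
        if (ov > maxov) maxov = ov;
      }
      if (kept.empty()) { kept.push_back((int)ci); continue; }
      if (maxov <= 0.25 * clen && (int)kept.size() < max_segments) {
        kept.push_back((int)ci);
      } else if (!ambiguous && c.score == cands[kept[0]].score &&
                 maxov >= 0.9 * clen &&
                 (c.ref != cands[kept[0]].ref || c.rs != cands[kept[0]].rs ||
                  c.strand != cands[kept[0]].strand)) {
        // equal-scoring alternative placement of the same query stretch
        ambiguous = true;
      }
    }
    for (size_t r = 0; r < kept.size(); ++r) {
      const Cand &c = cands[kept[r]];
      o_qidx.push_back(qi + 1);
      o_qs.push_back(c.qs + 1);
      o_qe.push_back(c.qe + 1);
      o_qlen.push_back(qlen);
      o_ref.push_back(c.ref + 1);
      o_rs.push_back(c.rs + 1);
      o_re.push_back(c.re + 1);
      o_strand.push_back(c.strand);
      o_mism.push_back(c.mism);
      o_role.push_back(r == 0 ? 1 : 2);
      o_ambig.push_back(r == 0 ? (ambiguous ? 1 : 0) : 0);
    }
  }

  return List::create(
    _["qidx"] = wrap(o_qidx), _["qstart"] = wrap(o_qs),
    _["qend"] = wrap(o_qe), _["qlen"] = wrap(o_qlen),
    _["ref"] = wrap(o_ref),
    _["rstart"] = IntegerVector(o_rs.begin(), o_rs.end()),
    _["rend"] = IntegerVector(o_re.begin(), o_re.end()),
    _["strand"] = wrap(o_strand), _["mism"] = wrap(o_mism),
    _["role"] = wrap(o_role), _["ambiguous"] = wrap(o_ambig));
}
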