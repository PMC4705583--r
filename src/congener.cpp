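// Low-level sequence kernels: k-mer indexing, seed-and-extend read mapping
// with X-drop clipping and one-sided tail rescue (indel observations),
// pileup accumulation, unique-successor k-mer walks for gap filling, and
// unique-k-mer anchor seeding for genome-vs-genome alignment.
//
// All coordinates are 0-based half-open. Sequences are uppercase A/C/G/T/N;
// any non-ACGT base breaks a k-mer window.

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <algorithm>
#include <climits>
#include <cstdint>
#include <string>
#include <vector>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
  }
  return -1;
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
  }
  return 'N';
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = comp_base(r[i]);
  return r;
}

// Enumerate valid k-mer windows of s; calls fn(pos, kmer_code).
template <typename F>
static void each_kmer(const std::string& s, int k, F fn) {
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  uint64_t cur = 0;
  int run = 0;  // number of consecutive valid bases ending here
  for (size_t i = 0; i < s.size(); ++i) {
    int c = base_code(s[i]);
    if (c < 0) { run = 0; cur = 0; continue; }
    cur = ((cur << 2) | (uint64_t)c) & mask;
    if (++run >= k) fn((long)(i + 1 - k), cur);
  }
}

// ---------------------------------------------------------------------------
// Read mapping
// ---------------------------------------------------------------------------

struct MapHit {
  int read;        // 1-based read index
  int target;      // 1-based target index
  long tstart, tend;
  int qstart, qend;  // on the oriented read
  char strand;
  int nmis;
  int max_exact;
  int score;
  int tail_len;    // rescued tail length (0 = none)
  int tail_shift;  // +d deletion of d ref bases at junction, -d insertion
  int tail_mis;
  int tail_trim;   // bases trimmed from the tail start for clean flanks
};

struct Extension {
  int qs, qe;      // clipped aligned query window (clean-flank trimmed)
  int qs_raw, qe_raw;  // X-drop window before trimming
  int nmis, score, max_exact;
  bool ok;
};

// Ungapped X-drop extension around an exact seed on one diagonal.
static Extension extend_seed(const std::string& q, const std::string& t,
                             long diag, int seed_off, int k,
                             int mismatch_pen, int xdrop) {
  Extension ex; ex.ok = false;
  const long tlen = (long)t.size();
  // right
  int best_qe = seed_off + k; int sc = 0, best = 0;
  for (int i = seed_off + k; i < (int)q.size(); ++i) {
    long tp = diag + i;
    if (tp < 0 || tp >= tlen) break;
    sc += (q[i] == t[tp]) ? 1 : -mismatch_pen;
    if (sc > best) { best = sc; best_qe = i + 1; }
    if (sc <= best - xdrop) break;
  }
  // left
  int best_qs = seed_off; sc = 0; best = 0;
  for (int i = seed_off - 1; i >= 0; --i) {
    long tp = diag + i;
    if (tp < 0 || tp >= tlen) break;
    sc += (q[i] == t[tp]) ? 1 : -mismatch_pen;
    if (sc > best) { best = sc; best_qs = i; }
    if (sc <= best - xdrop) break;
  }
  if (diag + best_qs < 0 || diag + best_qe > tlen) return ex;
  const int raw_qs = best_qs, raw_qe = best_qe;
  // require clean flanks: trim each end until its terminal 8 bases match
  // exactly (junction artifacts otherwise leak mismatches into the pileup)
  const int FL = 8;
  auto mism = [&](int i) { return q[i] != t[diag + i]; };
  while (best_qe - best_qs >= FL) {
    bool bad = false;
    for (int i = best_qe - FL; i < best_qe; ++i)
      if (mism(i)) { bad = true; break; }
    if (!bad) break;
    --best_qe;
  }
  while (best_qe - best_qs >= FL) {
    bool bad = false;
    for (int i = best_qs; i < best_qs + FL; ++i)
      if (mism(i)) { bad = true; break; }
    if (!bad) break;
    ++best_qs;
  }
  if (best_qe - best_qs < FL) return ex;
  int nmis = 0, run = 0, max_run = 0;
  for (int i = best_qs; i < best_qe; ++i) {
    if (q[i] == t[diag + i]) { if (++run > max_run) max_run = run; }
    else { ++nmis; run = 0; }
  }
  ex.qs = best_qs; ex.qe = best_qe;
  ex.qs_raw = raw_qs; ex.qe_raw = raw_qe;
  ex.nmis = nmis;
  ex.score = (best_qe - best_qs) - (mismatch_pen + 1) * nmis;
  ex.max_exact = max_run;
  ex.ok = true;
  return ex;
}

// [[Rcpp::export]]
DataFrame cg_map_reads(CharacterVector ref, CharacterVector reads,
                       int k = 25, int nseeds = 5, int max_occ = 200,
                       int mismatch_pen = 3, int xdrop = 12,
                       int ambig_margin = 5, bool tail_rescue = true,
                       int max_shift = 15, int min_tail = 18) {
  const int nref = ref.size();
  std::vector<std::string> T(nref);
  for (int i = 0; i < nref; ++i) T[i] = as<std::string>(ref[i]);

  // index reference k-mers -> packed positions
  std::unordered_map<uint64_t, std::vector<uint64_t>> idx;
  idx.reserve(1 << 20);
  for (int s = 0; s < nref; ++s)
    each_kmer(T[s], k, [&](long p, uint64_t km) {
      idx[km].push_back(((uint64_t)s << 36) | (uint64_t)p);
    });

  std::vector<MapHit> out;
  out.reserve(reads.size());

  const int nreads = reads.size();
  for (int r = 0; r < nreads; ++r) {
    std::string fwd = as<std::string>(reads[r]);
    if ((int)fwd.size() < k) continue;
    std::string rc = revcomp(fwd);

    // candidate diagonals over both orientations: key -> votes
    // key = strand bit | target | diag
    std::unordered_map<uint64_t, int> votes;
    std::unordered_map<uint64_t, int> seed_off_of;  // one seed offset per cand
    for (int ori = 0; ori < 2; ++ori) {
      const std::string& q = (ori == 0) ? fwd : rc;
      int L = (int)q.size();
      int nm = std::max(1, nseeds);
      for (int s = 0; s < nm; ++s) {
        int off = (nm == 1) ? 0 : (int)((long)s * (L - k) / (nm - 1));
        uint64_t km = 0; bool valid = true;
        for (int j = 0; j < k; ++j) {
          int c = base_code(q[off + j]);
          if (c < 0) { valid = false; break; }
          km = (km << 2) | (uint64_t)c;
        }
        if (!valid) continue;
        auto it = idx.find(km);
        if (it == idx.end() || (int)it->second.size() > max_occ) continue;
        for (uint64_t packed : it->second) {
          int tgt = (int)(packed >> 36);
          long tp = (long)(packed & ((1ULL << 36) - 1));
          long diag = tp - off;
          uint64_t key = ((uint64_t)ori << 62) | ((uint64_t)tgt << 40) |
                         (uint64_t)(diag + (1LL << 34));
          ++votes[key];
          if (!seed_off_of.count(key)) seed_off_of[key] = off;
        }
      }
    }
    if (votes.empty()) continue;

    // evaluate candidates (cap at 12, most-voted first)
    std::vector<std::pair<int, uint64_t>> cands;
    cands.reserve(votes.size());
    for (auto& kv : votes) cands.push_back({kv.second, kv.first});
    std::sort(cands.begin(), cands.end(),
              [](const std::pair<int, uint64_t>& a,
                 const std::pair<int, uint64_t>& b) { return a.first > b.first; });
    if (cands.size() > 12) cands.resize(12);

    struct Cand {
      int ori, tgt; long diag; Extension ex;
      int os, oe;  // aligned window in original-read coordinates
    };
    std::vector<Cand> evald;
    const int L = (int)fwd.size();
    for (auto& c : cands) {
      uint64_t key = c.second;
      Cand cd;
      cd.ori = (int)(key >> 62);
      cd.tgt = (int)((key >> 40) & ((1ULL << 22) - 1));
      cd.diag = (long)(key & ((1ULL << 40) - 1)) - (1LL << 34);
      const std::string& q = (cd.ori == 0) ? fwd : rc;
      cd.ex = extend_seed(q, T[cd.tgt], cd.diag, seed_off_of[key], k,
                          mismatch_pen, xdrop);
      if (!cd.ex.ok) continue;
      if (cd.ori == 0) { cd.os = cd.ex.qs; cd.oe = cd.ex.qe; }
      else { cd.os = L - cd.ex.qe; cd.oe = L - cd.ex.qs; }
      evald.push_back(cd);
    }
    if (evald.empty()) continue;
    size_t bi = 0;
    for (size_t i = 1; i < evald.size(); ++i)
      if (evald[i].ex.score > evald[bi].ex.score) bi = i;
    // ambiguity: another placement of (essentially) the same part of the
    // read scoring nearly as well; complementary split parts do not compete
    bool ambig = false;
    for (size_t i = 0; i < evald.size(); ++i) {
      if (i == bi) continue;
      int ov = std::min(evald[i].oe, evald[bi].oe) -
               std::max(evald[i].os, evald[bi].os);
      int mlen = std::min(evald[i].oe - evald[i].os,
                          evald[bi].oe - evald[bi].os);
      if (ov * 2 >= mlen &&
          evald[bi].ex.score - evald[i].ex.score < ambig_margin) {
        ambig = true; break;
      }
    }
    if (ambig) continue;
    MapHit bh;
    const Cand& B = evald[bi];
    bh.read = r + 1; bh.target = B.tgt + 1;
    bh.tstart = B.diag + B.ex.qs; bh.tend = B.diag + B.ex.qe;
    bh.qstart = B.ex.qs; bh.qend = B.ex.qe;
    bh.strand = (B.ori == 0) ? '+' : '-';
    bh.nmis = B.ex.nmis; bh.max_exact = B.ex.max_exact; bh.score = B.ex.score;
    bh.tail_len = 0; bh.tail_shift = 0; bh.tail_mis = 0; bh.tail_trim = 0;
    const std::string& best_q_ref = (B.ori == 0) ? fwd : rc;
    std::string best_q = best_q_ref;
    int best_tgt = B.tgt;

    // Indel rescue. A clipped 3' tail (or 5' head) that re-anchors at a
    // small diagonal shift is evidence of a short indel; on success the
    // junction (split point) is refined to the position minimising total
    // mismatches across the two diagonals and both segments are kept.
    // The hit schema stores the left-in-read segment as the main window
    // and the right-in-read segment as the "tail" at shift sh (sh > 0:
    // deletion of sh target bases at the junction; sh < 0: insertion).
    if (tail_rescue) {
      const std::string& q = best_q;
      const std::string& t = T[best_tgt];
      const long diag = B.diag;
      const int L2 = (int)q.size();
      const long tlen2 = (long)t.size();

      // mismatch indicator on an arbitrary diagonal (out of range counts
      // as mismatch)
      auto mism_on = [&](long dg, int i) {
        long tp = dg + i;
        return !(tp >= 0 && tp < tlen2 && q[i] == t[tp]);
      };
      // exact mismatch count of q[a..b) on diagonal dg
      auto count_mis = [&](long dg, int a, int b) {
        int m = 0;
        for (int i = a; i < b; ++i) if (mism_on(dg, i)) ++m;
        return m;
      };
      // refine split point between diagonals dg1 (left part) and dg2
      // (right part, skipping `skip` inserted read bases). All cost-tied
      // optima are reported as [s_lo, s_hi]: the zone between tied splits
      // is alignment-ambiguous and contributes no pileup evidence.
      struct Split { int s_lo, s_hi, cost; };
      auto refine_split = [&](long dg1, long dg2, int skip, int lo, int hi) {
        Split sp{-1, -1, INT_MAX};
        std::vector<int> A(L2 + 1, 0), Bm(L2 + 1, 0);
        for (int i = 0; i < L2; ++i) {
          A[i + 1] = A[i] + (mism_on(dg1, i) ? 1 : 0);
          Bm[i + 1] = Bm[i] + (mism_on(dg2, i) ? 1 : 0);
        }
        for (int si = lo; si <= hi; ++si) {
          if (si + skip > L2) break;
          int cost = A[si] + (Bm[L2] - Bm[si + skip]);
          if (cost < sp.cost) { sp.cost = cost; sp.s_lo = si; sp.s_hi = si; }
          else if (cost == sp.cost) sp.s_hi = si;
        }
        return sp;
      };

      bool rescued = false;

      // --- 3' tail rescue (read anchored left of the junction)
      int qe_raw = B.ex.qe_raw;
      int tl = L2 - qe_raw;
      if (tl >= min_tail) {
        int best_sh = 0, best_mis = tl + 1, second_mis = tl + 1;
        for (int sh = -max_shift; sh <= max_shift; ++sh) {
          if (sh == 0) continue;
          int qoff = qe_raw + (sh < 0 ? -sh : 0);
          long dg2 = diag + sh;
          int len = L2 - qoff;
          if (len < min_tail) continue;
          if (dg2 + qoff < 0 || dg2 + L2 > tlen2) continue;
          int mis = count_mis(dg2, qoff, L2);
          if (mis < best_mis) { second_mis = best_mis; best_mis = mis; best_sh = sh; }
          else if (mis < second_mis) second_mis = mis;
        }
        int allowed = std::max(1, tl / 20);
        if (best_sh != 0 && best_mis <= allowed && second_mis - best_mis >= 2) {
          int sh = best_sh;
          int skip = (sh < 0) ? -sh : 0;
          int qs = B.ex.qs;
          Split sp = refine_split(diag, diag + sh, skip, qs + k,
                                  L2 - skip - 6);
          if (sp.s_lo > 0 && diag + sp.s_lo <= tlen2 &&
              L2 - (sp.s_hi + skip) > 0) {
            bh.qstart = qs;
            bh.qend = sp.s_lo;
            bh.tstart = diag + qs;
            bh.tend = diag + sp.s_lo;
            bh.nmis = count_mis(diag, qs, sp.s_lo);
            bh.tail_shift = sh;
            bh.tail_trim = sp.s_hi - sp.s_lo;
            bh.tail_len = L2 - (sp.s_hi + skip);
            bh.tail_mis = count_mis(diag + sh, sp.s_hi + skip, L2);
            rescued = true;
          }
        }
      }

      // --- 5' head rescue (read anchored right of the junction)
      int qs_raw = B.ex.qs_raw;
      if (!rescued && qs_raw >= min_tail) {
        int best_sh = 0, best_mis = qs_raw + 1, second_mis = qs_raw + 1;
        for (int sh = -max_shift; sh <= max_shift; ++sh) {
          // head diagonal dg1 = diag + shh; resulting indel shift is -shh
          if (sh == 0) continue;
          long dg1 = diag + sh;
          int hend = qs_raw - (sh > 0 ? sh : 0);  // sh > 0: insertion
          if (hend < min_tail) continue;
          if (dg1 < 0 || dg1 + hend > tlen2) continue;
          int mis = count_mis(dg1, 0, hend);
          if (mis < best_mis) { second_mis = best_mis; best_mis = mis; best_sh = sh; }
          else if (mis < second_mis) second_mis = mis;
        }
        int allowed = std::max(1, qs_raw / 20);
        if (best_sh != 0 && best_mis <= allowed && second_mis - best_mis >= 2) {
          int shh = best_sh;        // head diagonal offset
          int sh2 = -shh;           // indel shift in the output schema
          int skip = (sh2 < 0) ? -sh2 : 0;
          long dg1 = diag + shh;
          int qe2 = B.ex.qe;        // keep the trimmed right end
          Split sp = refine_split(dg1, diag, skip, 6, qe2 - skip - k);
          if (sp.s_lo > 0 && dg1 >= 0 && dg1 + sp.s_lo <= tlen2 &&
              qe2 - (sp.s_hi + skip) > 0) {
            bh.qstart = 0;
            bh.qend = sp.s_lo;
            bh.tstart = dg1;
            bh.tend = dg1 + sp.s_lo;
            bh.nmis = count_mis(dg1, 0, sp.s_lo);
            bh.tail_shift = sh2;
            bh.tail_trim = sp.s_hi - sp.s_lo;
            bh.tail_len = qe2 - (sp.s_hi + skip);
            bh.tail_mis = count_mis(diag, sp.s_hi + skip, qe2);
            rescued = true;
          }
        }
      }
      (void)rescued;
    }
    out.push_back(bh);
  }

  const int n = (int)out.size();
  IntegerVector read(n), target(n), qstart(n), qend(n), nmis(n), max_exact(n),
      score(n), tail_len(n), tail_shift(n), tail_mis(n), tail_trim(n);
  NumericVector tstart(n), tend(n);
  CharacterVector strand(n);
  for (int i = 0; i < n; ++i) {
    const MapHit& h = out[i];
    read[i] = h.read; target[i] = h.target;
    tstart[i] = (double)h.tstart; tend[i] = (double)h.tend;
    qstart[i] = h.qstart; qend[i] = h.qend;
    strand[i] = std::string(1, h.strand);
    nmis[i] = h.nmis; max_exact[i] = h.max_exact; score[i] = h.score;
    tail_len[i] = h.tail_len; tail_shift[i] = h.tail_shift;
    tail_mis[i] = h.tail_mis; tail_trim[i] = h.tail_trim;
  }
  return DataFrame::create(
      _["read"] = read, _["target"] = target, _["tstart"] = tstart,
      _["tend"] = tend, _["qstart"] = qstart, _["qend"] = qend,
      _["strand"] = strand, _["nmis"] = nmis, _["max_exact"] = max_exact,
      _["score"] = score, _["tail_len"] = tail_len,
      _["tail_shift"] = tail_shift, _["tail_mis"] = tail_mis,
      _["tail_trim"] = tail_trim, _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// Pileup
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cg_pileup(CharacterVector ref, CharacterVector reads,
               IntegerVector read_idx, IntegerVector target,
               NumericVector tstart, IntegerVector qstart, IntegerVector qend,
               CharacterVector strand, IntegerVector tail_len,
               IntegerVector tail_shift, IntegerVector tail_trim) {
  const int nref = ref.size();
  std::vector<std::string> T(nref);
  std::vector<IntegerMatrix> counts;
  for (int i = 0; i < nref; ++i) {
    T[i] = as<std::string>(ref[i]);
    counts.push_back(IntegerMatrix(4, (int)T[i].size()));
  }
  const int n = read_idx.size();
  for (int i = 0; i < n; ++i) {
    int tgt = target[i] - 1;
    std::string q = as<std::string>(reads[read_idx[i] - 1]);
    if (as<std::string>(strand[i]) == "-") q = revcomp(q);
    long ts = (long)tstart[i];
    IntegerMatrix& M = counts[tgt];
    long tlen = (long)T[tgt].size();
    for (int j = qstart[i]; j < qend[i]; ++j) {
      long tp = ts + (j - qstart[i]);
      if (tp < 0 || tp >= tlen) continue;
      int c = base_code(q[j]);
      if (c >= 0) ++M(c, (int)tp);
    }
    // rescued tail bases
    int tl = tail_len[i], sh = tail_shift[i];
    if (tl > 0) {
      long tend_main = ts + (qend[i] - qstart[i]);
      int qoff = qend[i] + (sh < 0 ? -sh : 0) + tail_trim[i];
      long toff = tend_main + (sh > 0 ? sh : 0) + tail_trim[i];
      for (int j = 0; j < tl; ++j) {
        long tp = toff + j;
        if (tp < 0 || tp >= tlen) continue;
        int c = base_code(q[qoff + j]);
        if (c >= 0) ++M(c, (int)tp);
      }
    }
  }
  List out(nref);
  for (int i = 0; i < nref; ++i) out[i] = counts[i];
  return out;
}

// ---------------------------------------------------------------------------
// Unique-successor k-mer walk (gap filling)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cg_kmer_walk(std::string left_flank, std::string right_flank,
                  CharacterVector reads, int k = 30, int max_gap = 5000,
                  int max_iterations = 10) {
  std::unordered_set<uint64_t> kmers;
  kmers.reserve(1 << 18);
  for (int i = 0; i < reads.size(); ++i) {
    std::string s = as<std::string>(reads[i]);
    each_kmer(s, k, [&](long, uint64_t km) { kmers.insert(km); });
    std::string r = revcomp(s);
    each_kmer(r, k, [&](long, uint64_t km) { kmers.insert(km); });
  }
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);

  auto encode_tail = [&](const std::string& s, bool from_start) -> long {
    // returns -1 if flank shorter than k or contains non-ACGT in window
    if ((int)s.size() < k) return -1;
    uint64_t km = 0;
    size_t off = from_start ? 0 : s.size() - k;
    for (int j = 0; j < k; ++j) {
      int c = base_code(s[off + j]);
      if (c < 0) return -1;
      km = (km << 2) | (uint64_t)c;
    }
    return (long)km;
  };
  long start = encode_tail(left_flank, false);
  long target = encode_tail(right_flank, true);
  if (start < 0 || target < 0)
    return List::create(_["status"] = "unfilled_no_path", _["fill"] = "",
                        _["steps"] = 0, _["iterations_used"] = 0);

  const char* bases = "ACGT";
  uint64_t cur = (uint64_t)start;
  std::string appended;
  appended.reserve(max_gap + k);
  std::string status = "unfilled_no_path";
  int cap = max_gap + k;
  int chunk = std::max(1, (max_gap + max_iterations - 1) / max_iterations);
  int steps = 0;
  while (true) {
    if (steps >= cap) { status = "unfilled_too_long"; break; }
    int nnext = 0, pick = -1;
    for (int b = 0; b < 4; ++b) {
      uint64_t nxt = ((cur << 2) | (uint64_t)b) & mask;
      if (kmers.count(nxt)) { ++nnext; pick = b; }
    }
    if (nnext == 0) {
      status = (steps > 0) ? "partial" : "unfilled_no_path";
      break;
    }
    if (nnext > 1) { status = "unfilled_ambiguous"; break; }
    cur = ((cur << 2) | (uint64_t)pick) & mask;
    appended.push_back(bases[pick]);
    ++steps;
    if (cur == (uint64_t)target) {
      if (steps >= k) { status = "filled"; }
      else { status = "unfilled_no_path"; }  // negative gap: flanks overlap
      break;
    }
  }
  std::string fill;
  if (status == "filled") fill = appended.substr(0, steps - k);
  else if (status == "partial") fill = appended;
  int iters = (steps + chunk - 1) / chunk;
  if (iters > max_iterations) iters = max_iterations;
  return List::create(_["status"] = status, _["fill"] = fill,
                      _["steps"] = steps, _["iterations_used"] = iters);
}

// ---------------------------------------------------------------------------
// Unique-k-mer anchor seeding (genome vs genome)
// ---------------------------------------------------------------------------

struct Anchor { int query, target; long qstart, tstart; int len; char strand; };

// [[Rcpp::export]]
DataFrame cg_anchor_seeds(CharacterVector ref, CharacterVector query,
                          int k = 20) {
  const int nref = ref.size();
  // kmer -> packed position; repeated k-mers flagged with sentinel
  std::unordered_map<uint64_t, uint64_t> pos;
  pos.reserve(1 << 20);
  const uint64_t REPEAT = ~0ULL;
  for (int s = 0; s < nref; ++s) {
    std::string t = as<std::string>(ref[s]);
    each_kmer(t, k, [&](long p, uint64_t km) {
      auto it = pos.find(km);
      if (it == pos.end()) pos[km] = ((uint64_t)s << 36) | (uint64_t)p;
      else it->second = REPEAT;
    });
  }

  std::vector<Anchor> anchors;
  for (int qi = 0; qi < query.size(); ++qi) {
    std::string qf = as<std::string>(query[qi]);
    for (int ori = 0; ori < 2; ++ori) {
      std::string q = (ori == 0) ? qf : revcomp(qf);
      // open runs keyed by (target, diag): maps to anchor index
      std::unordered_map<uint64_t, size_t> open;
      std::vector<Anchor> runs;
      each_kmer(q, k, [&](long p, uint64_t km) {
        auto it = pos.find(km);
        if (it == pos.end() || it->second == REPEAT) return;
        int tgt = (int)(it->second >> 36);
        long tp = (long)(it->second & ((1ULL << 36) - 1));
        long diag = tp - p;
        uint64_t key = ((uint64_t)tgt << 40) | (uint64_t)(diag + (1LL << 34));
        auto oi = open.find(key);
        if (oi != open.end()) {
          Anchor& a = runs[oi->second];
          if (a.qstart + (a.len - k) + 1 == p) { ++a.len; return; }
          // non-adjacent on same diagonal: close and reopen
        }
        Anchor a; a.query = qi + 1; a.target = tgt + 1;
        a.qstart = p; a.tstart = tp; a.len = k;
        a.strand = (ori == 0) ? '+' : '-';
        runs.push_back(a);
        open[key] = runs.size() - 1;
      });
      for (auto& a : runs) anchors.push_back(a);
    }
  }

  const int n = (int)anchors.size();
  IntegerVector qv(n), tv(n), lv(n);
  NumericVector qs(n), ts(n);
  CharacterVector sv(n);
  for (int i = 0; i < n; ++i) {
    qv[i] = anchors[i].query; tv[i] = anchors[i].target;
    qs[i] = (double)anchors[i].qstart; ts[i] = (double)anchors[i].tstart;
    lv[i] = anchors[i].len; sv[i] = std::string(1, anchors[i].strand);
  }
  return DataFrame::create(_["query"] = qv, _["target"] = tv,
                           _["qstart"] = qs, _["tstart"] = ts,
                           _["len"] = lv, _["strand"] = sv,
                           _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
CharacterVector cg_revcomp(CharacterVector x) {
  CharacterVector out(x.size());
  for (int i = 0; i < x.size(); ++i)
    out[i] = revcomp(as<std::string>(x[i]));
  return out;
}
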