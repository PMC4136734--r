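// Affine-gap local alignment (Smith-Waterman) and k-mer-seeded read mapping.
//
// Conventions:
//  - gap of length L costs gap_open + L * gap_extend (penalties positive)
//  - all coordinates returned 0-based half-open
//  - recurrence tie preference: diagonal > gap-in-query (D) > gap-in-read (I) > stop;
//    best cell = first encountered in row-major order (query outer, target inner)
//  - 'N' (or any non-ACGT) scores as a mismatch and never seeds a k-mer

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <string>
#include <cstdint>

using namespace Rcpp;

namespace {

inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
  }
}

std::vector<int8_t> encode(const std::string& s) {
  std::vector<int8_t> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = (int8_t)base_code(s[i]);
  return v;
}

struct AlnResult {
  int score = 0;
  int qstart = 0, qend = 0;   // 0-based half-open on query
  int tstart = 0, tend = 0;   // 0-based half-open on target
  std::string cigar;          // M/I/D, I = query base unaligned to target
  int n_aligned = 0;          // aligned (M) query bases
  int n_match = 0;            // M positions with identical bases
};

// direction bits per cell
enum : uint8_t {
  H_STOP = 0, H_DIAG = 1, H_FROME = 2, H_FROMF = 3, H_MASK = 3,
  E_EXT = 4,   // E came from E (gap in query extends)
  F_EXT = 8    // F came from F
};

// Full affine-gap SW with traceback over pre-encoded sequences.
AlnResult sw_core(const char* q, int m, const int8_t* qc_v,
                  const char* t, int n, const int8_t* tc_v,
                  int match, int mismatch, int gap_open, int gap_extend) {
  AlnResult res;
  if (m == 0 || n == 0) return res;

  const int NEG = -1000000000;
  std::vector<int> Hprev(n + 1, 0), Hcur(n + 1, 0);
  std::vector<int> Fcol(n + 1, NEG);
  std::vector<uint8_t> dir((size_t)(m + 1) * (n + 1), 0);

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    int E = NEG;
    Hcur[0] = 0;
    const int qc = qc_v[i - 1];
    uint8_t* drow = &dir[(size_t)i * (n + 1)];
    for (int j = 1; j <= n; ++j) {
      uint8_t d = 0;
      // E: gap in query (consumes target), from left
      int e_open = Hcur[j - 1] - gap_open - gap_extend;
      int e_ext  = E - gap_extend;
      if (e_ext > e_open) { E = e_ext; d |= E_EXT; } else { E = e_open; }
      // F: gap in target (consumes query), from above
      int f_open = Hprev[j] - gap_open - gap_extend;
      int f_ext  = Fcol[j] - gap_extend;
      int F;
      if (f_ext > f_open) { F = f_ext; d |= F_EXT; } else { F = f_open; }
      Fcol[j] = F;
      // H
      int sub = (qc >= 0 && qc == tc_v[j - 1]) ? match : -mismatch;
      int diag = Hprev[j - 1] + sub;
      int h = 0; uint8_t src = H_STOP;
      if (diag >= h && diag > 0) { h = diag; src = H_DIAG; }
      if (E > h) { h = E; src = H_FROME; }
      if (F > h) { h = F; src = H_FROMF; }
      Hcur[j] = h;
      drow[j] = d | src;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
  }

  res.score = best;
  if (best == 0) return res;

  // traceback; state: 0 = in H, 1 = in E, 2 = in F
  std::vector<char> ops;
  int i = bi, j = bj;
  int state = 0;
  while (i > 0 && j > 0) {
    uint8_t d = dir[(size_t)i * (n + 1) + j];
    if (state == 0) {
      uint8_t src = d & H_MASK;
      if (src == H_STOP) break;
      if (src == H_DIAG) { ops.push_back('M'); --i; --j; }
      else if (src == H_FROME) state = 1;
      else state = 2;
    } else if (state == 1) {
      ops.push_back('D');           // target base skipped relative to query
      bool ext = (d & E_EXT) != 0;
      --j;
      if (!ext) state = 0;
    } else {
      ops.push_back('I');           // query base unaligned
      bool ext = (d & F_EXT) != 0;
      --i;
      if (!ext) state = 0;
    }
  }
  res.qstart = i; res.qend = bi;
  res.tstart = j; res.tend = bj;
  std::reverse(ops.begin(), ops.end());

  // compact CIGAR + counts
  std::string cig;
  int qi = res.qstart, tj = res.tstart;
  size_t p = 0;
  while (p < ops.size()) {
    size_t r = p;
    while (r < ops.size() && ops[r] == ops[p]) ++r;
    cig += std::to_string(r - p);
    cig += ops[p];
    if (ops[p] == 'M') {
      for (size_t s = p; s < r; ++s) {
        if (q[qi] == t[tj] && qc_v[qi] >= 0) ++res.n_match;
        ++qi; ++tj;
      }
      res.n_aligned += (int)(r - p);
    } else if (ops[p] == 'I') {
      qi += (int)(r - p);
    } else {
      tj += (int)(r - p);
    }
    p = r;
  }
  res.cigar = cig;
  return res;
}

AlnResult sw_core_str(const std::string& q, const std::string& t,
                      int match, int mismatch, int gap_open, int gap_extend) {
  std::vector<int8_t> qc = encode(q), tc = encode(t);
  return sw_core(q.data(), (int)q.size(), qc.data(),
                 t.data(), (int)t.size(), tc.data(),
                 match, mismatch, gap_open, gap_extend);
}

List aln_to_list(const AlnResult& a) {
  return List::create(
    _["score"] = a.score, _["qstart"] = a.qstart, _["qend"] = a.qend,
    _["tstart"] = a.tstart, _["tend"] = a.tend, _["cigar"] = a.cigar,
    _["n_aligned"] = a.n_aligned, _["n_match"] = a.n_match);
}

} // namespace

//' @noRd
// [[Rcpp::export(name = ".cpp_local_align")]]
List cpp_local_align(std::string query, std::string target,
                     int match, int mismatch, int gap_open, int gap_extend) {
  AlnResult a = sw_core_str(query, target, match, mismatch, gap_open, gap_extend);
  return aln_to_list(a);
}

// Map a set of queries against one target string.
// If seed_k > 0: exact k-mer seeding, diagonal clustering, and exact SW
// inside each candidate window. Clusters backed by at least `min_seeds`
// seeds are preferred; if none qualifies the best-supported clusters are
// used anyway (sensitivity fallback for short queries). seed_k == 0 runs a
// single full DP per query.
//' @noRd
// [[Rcpp::export(name = ".cpp_map_to_target")]]
DataFrame cpp_map_to_target(CharacterVector queries, std::string target,
                            int seed_k, int max_windows, int band, int pad,
                            int min_score, int min_seeds, int max_occ,
                            int match, int mismatch, int gap_open, int gap_extend) {
  const int n = (int)target.size();
  std::vector<int8_t> tenc = encode(target);

  // k-mer index of the target (2-bit encoded; k-mers containing non-ACGT skipped)
  std::unordered_map<uint64_t, std::vector<int>> index;
  const int k = seed_k;
  if (k > 0 && n >= k) {
    uint64_t key = 0, mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
    int run = 0;
    index.reserve((size_t)n);
    for (int j = 0; j < n; ++j) {
      int c = tenc[j];
      if (c < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)c) & mask;
      if (++run >= k) index[key].push_back(j - k + 1);
    }
  }

  std::vector<int> out_q;
  std::vector<AlnResult> out_a;

  for (int qi = 0; qi < queries.size(); ++qi) {
    std::string q = as<std::string>(queries[qi]);
    const int m = (int)q.size();
    std::vector<int8_t> qenc = encode(q);
    std::vector<AlnResult> cands;

    if (k <= 0) {
      AlnResult a = sw_core(q.data(), m, qenc.data(), target.data(), n,
                            tenc.data(), match, mismatch, gap_open, gap_extend);
      if (a.score >= min_score) cands.push_back(a);
    } else if (m >= k) {
      // collect seed diagonals
      std::vector<int> diags;
      uint64_t key = 0, mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
      int run = 0;
      for (int p = 0; p < m; ++p) {
        int c = qenc[p];
        if (c < 0) { run = 0; key = 0; continue; }
        key = ((key << 2) | (uint64_t)c) & mask;
        if (++run >= k) {
          auto it = index.find(key);
          // high-frequency k-mers (low-complexity in converted space) are
          // uninformative as seeds and are skipped
          if (it != index.end() && (int)it->second.size() <= max_occ)
            for (int tp : it->second) diags.push_back(tp - (p - k + 1));
        }
      }
      if (!diags.empty()) {
        std::sort(diags.begin(), diags.end());
        struct Clust { int dmin, dmax, count; };
        std::vector<Clust> clusters;
        int s = 0;
        for (int p = 1; p <= (int)diags.size(); ++p) {
          if (p == (int)diags.size() || diags[p] - diags[p - 1] > band) {
            clusters.push_back({diags[s], diags[p - 1], p - s});
            s = p;
          }
        }
        std::stable_sort(clusters.begin(), clusters.end(),
                         [](const Clust& a, const Clust& b) {
                           if (a.count != b.count) return a.count > b.count;
                           return a.dmin < b.dmin;
                         });
        // prefer well-supported clusters; queries too short to expect
        // multiple seeds may fall back to singleton clusters
        int n_good = 0;
        for (const auto& c : clusters) if (c.count >= min_seeds) ++n_good;
        int n_use = n_good;
        if (n_good == 0 && m < 3 * k) n_use = (int)clusters.size();
        int nw = std::min(n_use, max_windows);
        for (int w = 0; w < nw; ++w) {
          int ws = std::max(0, clusters[w].dmin - pad);
          int we = std::min(n, clusters[w].dmax + m + pad);
          if (we - ws < k) continue;
          AlnResult a = sw_core(q.data(), m, qenc.data(),
                                target.data() + ws, we - ws, tenc.data() + ws,
                                match, mismatch, gap_open, gap_extend);
          if (a.score >= min_score) {
            a.tstart += ws; a.tend += ws;
            cands.push_back(a);
          }
        }
        // de-duplicate overlapping windows: keep best score per locus
        std::stable_sort(cands.begin(), cands.end(),
                         [](const AlnResult& a, const AlnResult& b) {
                           if (a.score != b.score) return a.score > b.score;
                           return a.tstart < b.tstart;
                         });
        std::vector<AlnResult> kept;
        for (const auto& a : cands) {
          bool dup = false;
          for (const auto& kpt : kept)
            if (a.tstart < kpt.tend && kpt.tstart < a.tend) { dup = true; break; }
          if (!dup) kept.push_back(a);
        }
        cands = kept;
      }
    }
    for (const auto& a : cands) { out_q.push_back(qi + 1); out_a.push_back(a); }
  }

  const int nr = (int)out_q.size();
  IntegerVector qidx(nr), score(nr), qs(nr), qe(nr), ts(nr), te(nr), nal(nr), nmat(nr);
  CharacterVector cig(nr);
  for (int i = 0; i < nr; ++i) {
    qidx[i] = out_q[i];
    score[i] = out_a[i].score;
    qs[i] = out_a[i].qstart; qe[i] = out_a[i].qend;
    ts[i] = out_a[i].tstart; te[i] = out_a[i].tend;
    nal[i] = out_a[i].n_aligned; nmat[i] = out_a[i].n_match;
    cig[i] = out_a[i].cigar;
  }
  return DataFrame::create(
    _["query"] = qidx, _["score"] = score,
    _["qstart"] = qs, _["qend"] = qe, _["tstart"] = ts, _["tend"] = te,
    _["cigar"] = cig, _["n_aligned"] = nal, _["n_match"] = nmat,
    _["stringsAsFactors"] = false);
}
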