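// Anchor finding and cluster extension for whole-genome alignment.
//
// Anchors are maximal exact matches found by seeding on packed L-mers
// (L = min(min_match, 31)); every maximal match of length >= min_match
// contains an L-mer seed at each offset, and a hit is processed only from
// its leftmost seed so each maximal match is reported exactly once.
// Non-ACGT characters match nothing, so anchors never cross N runs.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static inline bool eq_base(char a, char b) {
  int ca = base_code(a), cb = base_code(b);
  return ca >= 0 && ca == cb;
}

// [[Rcpp::export(name = ".find_anchors_cpp")]]
DataFrame find_anchors_cpp(std::string ref, std::string qry, int min_match,
                           bool unique_ref) {
  int L = min_match < 31 ? min_match : 31;
  if (L < 1) stop("min_match must be positive");
  const uint64_t mask = (1ULL << (2 * L)) - 1;
  int rn = (int)ref.size(), qn = (int)qry.size();

  // index all valid ref L-mers (forward strand)
  std::unordered_map<uint64_t, std::vector<int> > idx;
  {
    uint64_t h = 0;
    int run = 0;
    for (int i = 0; i < rn; ++i) {
      int c = base_code(ref[i]);
      if (c < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)c) & mask;
      if (++run >= L) idx[h].push_back(i + 1 - L);
    }
  }

  std::vector<int> out_r, out_q, out_len;
  uint64_t h = 0;
  int run = 0;
  for (int i = 0; i < qn; ++i) {
    int c = base_code(qry[i]);
    if (c < 0) { run = 0; h = 0; continue; }
    h = ((h << 2) | (uint64_t)c) & mask;
    if (++run < L) continue;
    int q0 = i + 1 - L;
    auto it = idx.find(h);
    if (it == idx.end()) continue;
    for (int r0 : it->second) {
      // leftmost-seed rule: skip if the match extends left of this seed
      if (r0 > 0 && q0 > 0 && eq_base(ref[r0 - 1], qry[q0 - 1])) continue;
      int len = L;
      while (r0 + len < rn && q0 + len < qn &&
             eq_base(ref[r0 + len], qry[q0 + len]))
        ++len;
      if (len < min_match) continue;
      if (unique_ref) {
        // the matched ref substring starts with its own first L-mer, so all
        // of its occurrences are among that seed's positions
        uint64_t h0 = 0;
        for (int j = 0; j < L; ++j)
          h0 = ((h0 << 2) | (uint64_t)base_code(ref[r0 + j])) & mask;
        int occ = 0;
        for (int p : idx[h0]) {
          if (p + len > rn) continue;
          bool same = true;
          for (int j = L; j < len; ++j)
            if (!eq_base(ref[p + j], ref[r0 + j])) { same = false; break; }
          if (same && ++occ > 1) break;
        }
        if (occ > 1) continue;
      }
      out_r.push_back(r0);
      out_q.push_back(q0);
      out_len.push_back(len);
    }
  }
  return DataFrame::create(_["ref_start"] = out_r, _["qry_start"] = out_q,
                           _["length"] = out_len);
}

// Global edit alignment of two gap segments with unit costs, traceback
// preferring match/mismatch, then gap-in-qry, then gap-in-ref.
// Accumulates columns, matches, substitutions and indel run lengths.
static void align_gap(const std::string& a, const std::string& b,
                      long& cols, long& matches, long& subs,
                      std::vector<int>& indels) {
  int n = (int)a.size(), m = (int)b.size();
  if (n == 0 && m == 0) return;
  if (n == 0 || m == 0) {
    int g = n > m ? n : m;
    cols += g;
    indels.push_back(g);
    return;
  }
  std::vector<int> prev(m + 1), cur(m + 1);
  std::vector<unsigned char> tb((size_t)(n + 1) * (m + 1));
  for (int j = 0; j <= m; ++j) { prev[j] = j; tb[j] = 2; }
  tb[0] = 0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    tb[(size_t)i * (m + 1)] = 1;
    for (int j = 1; j <= m; ++j) {
      int cd = prev[j - 1] + (eq_base(a[i - 1], b[j - 1]) ? 0 : 1);
      int cu = prev[j] + 1;      // gap in b (consume a)
      int cl = cur[j - 1] + 1;   // gap in a (consume b)
      int best = cd;
      unsigned char dir = 0;
      if (cu < best) { best = cu; dir = 1; }
      if (cl < best) { best = cl; dir = 2; }
      cur[j] = best;
      tb[(size_t)i * (m + 1) + j] = dir;
    }
    std::swap(prev, cur);
  }
  // traceback
  int i = n, j = m, gaprun = 0;
  while (i > 0 || j > 0) {
    unsigned char d = tb[(size_t)i * (m + 1) + j];
    if (d == 0) {
      if (gaprun) { indels.push_back(gaprun); gaprun = 0; }
      ++cols;
      if (eq_base(a[i - 1], b[j - 1])) ++matches; else ++subs;
      --i; --j;
    } else if (d == 1) {
      ++cols; ++gaprun; --i;
    } else {
      ++cols; ++gaprun; --j;
    }
  }
  if (gaprun) indels.push_back(gaprun);
}

// Greedy end extension: step outward comparing bases one-for-one, keep the
// longest prefix ending on a matching base whose identity stays >= min_ident;
// give up after 20 consecutive mismatches.
static void extend_end(const std::string& ref, const std::string& qry,
                       int rpos, int qpos, int dir, double min_ident,
                       int& best_len, int& best_matches) {
  int t = 0, matches = 0, miss = 0;
  best_len = 0;
  best_matches = 0;
  for (;;) {
    int r = rpos + dir * t, q = qpos + dir * t;
    if (r < 0 || q < 0 || r >= (int)ref.size() || q >= (int)qry.size()) break;
    ++t;
    if (eq_base(ref[r], qry[q])) {
      ++matches;
      miss = 0;
      if ((double)matches / t >= min_ident) { best_len = t; best_matches = matches; }
    } else if (++miss >= 20) break;
  }
}

// Extend each anchor cluster into an alignment block. Anchors must be sorted
// by ref_start within cluster, gaps trimmed to be non-negative on both axes.
// [[Rcpp::export(name = ".extend_clusters_cpp")]]
List extend_clusters_cpp(std::string ref, std::string qry,
                         IntegerVector rs, IntegerVector qs, IntegerVector len,
                         IntegerVector cluster, int small_indel_cutoff,
                         int max_dp_gap, double min_ext_ident) {
  int n = rs.size();
  std::vector<int> b_rs, b_re, b_qs, b_qe, b_cluster;
  std::vector<double> b_cols, b_matches, b_subs;
  std::vector<int> b_small;
  std::vector<int> li_block, li_size;  // large indel events

  int i = 0;
  while (i < n) {
    int cl = cluster[i];
    // block accumulators, seeded from anchor i
    long cols = len[i], matches = len[i], subs = 0;
    std::vector<int> indels;
    int rstart = rs[i], qstart = qs[i];
    int rend = rs[i] + len[i], qend = qs[i] + len[i];
    auto flush = [&](void) {
      // extend both ends
      int el, em;
      extend_end(ref, qry, rstart - 1, qstart - 1, -1, min_ext_ident, el, em);
      rstart -= el; qstart -= el; cols += el; matches += em; subs += el - em;
      extend_end(ref, qry, rend, qend, +1, min_ext_ident, el, em);
      rend += el; qend += el; cols += el; matches += em; subs += el - em;
      int nsmall = 0;
      for (int g : indels) {
        if (g <= small_indel_cutoff) ++nsmall;
        else { li_block.push_back((int)b_rs.size()); li_size.push_back(g); }
      }
      b_rs.push_back(rstart); b_re.push_back(rend);
      b_qs.push_back(qstart); b_qe.push_back(qend);
      b_cluster.push_back(cl);
      b_cols.push_back((double)cols); b_matches.push_back((double)matches);
      b_subs.push_back((double)subs); b_small.push_back(nsmall);
    };
    int j = i + 1;
    for (; j < n && cluster[j] == cl; ++j) {
      int rgap = rs[j] - rend, qgap = qs[j] - qend;
      if (rgap < 0 || qgap < 0 || rgap > max_dp_gap || qgap > max_dp_gap) {
        // band overflow / inconsistent anchor: split the block here
        flush();
        cols = len[j]; matches = len[j]; subs = 0; indels.clear();
        rstart = rs[j]; qstart = qs[j];
        rend = rs[j] + len[j]; qend = qs[j] + len[j];
        continue;
      }
      align_gap(ref.substr(rend, rgap), qry.substr(qend, qgap),
                cols, matches, subs, indels);
      cols += len[j]; matches += len[j];
      rend = rs[j] + len[j]; qend = qs[j] + len[j];
    }
    flush();
    i = j;
  }
  return List::create(
      _["blocks"] = DataFrame::create(
          _["ref_start"] = b_rs, _["ref_end"] = b_re,
          _["qry_start"] = b_qs, _["qry_end"] = b_qe,
          _["cluster"] = b_cluster, _["cols"] = b_cols,
          _["matches"] = b_matches, _["subs"] = b_subs,
          _["small_indels"] = b_small),
      _["large_indels"] = DataFrame::create(_["block"] = li_block,
                                            _["size"] = li_size));
}
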