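// Canonical k-mer counting and coverage profiling.
//
// K-mers are 2-bit packed into 64-bit integers (A=0, C=1, G=2, T=3), which
// caps k at 31. Counting is canonical: each window is unified with its
// reverse complement and the lexicographically smaller encoding is kept.
// Windows containing any non-ACGT character are skipped.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

typedef std::unordered_map<uint64_t, uint32_t> KmerMap;

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static const char CODE_BASE[4] = {'A', 'C', 'G', 'T'};

// Roll over one sequence, calling f(canonical) for every valid window.
template <typename F>
static void for_each_canonical(const char* s, size_t n, int k, F f) {
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  const int shift_rc = 2 * (k - 1);
  uint64_t fwd = 0, rev = 0;
  int run = 0;
  for (size_t i = 0; i < n; ++i) {
    int c = base_code(s[i]);
    if (c < 0) { run = 0; fwd = rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)c) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - c) << shift_rc);
    if (++run >= k) f(i + 1 - k, std::min(fwd, rev));
  }
}

static XPtr<KmerMap> as_db(SEXP db) {
  XPtr<KmerMap> p(db);
  return p;
}

// [[Rcpp::export(name = ".kmer_count_cpp")]]
SEXP kmer_count_cpp(CharacterVector reads, int k) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  KmerMap* m = new KmerMap();
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    const char* s = CHAR(STRING_ELT(reads, r));
    size_t n = LENGTH(STRING_ELT(reads, r));
    if ((int)n < k) continue;
    for_each_canonical(s, n, k, [&](size_t, uint64_t km) { ++(*m)[km]; });
  }
  XPtr<KmerMap> p(m, true);
  p.attr("k") = k;
  return p;
}

// [[Rcpp::export(name = ".kmer_add_cpp")]]
void kmer_add_cpp(SEXP db, CharacterVector reads, int k) {
  XPtr<KmerMap> p = as_db(db);
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    const char* s = CHAR(STRING_ELT(reads, r));
    size_t n = LENGTH(STRING_ELT(reads, r));
    if ((int)n < k) continue;
    for_each_canonical(s, n, k, [&](size_t, uint64_t km) { ++(*p)[km]; });
  }
}

// [[Rcpp::export(name = ".kmer_db_stats_cpp")]]
List kmer_db_stats_cpp(SEXP db) {
  XPtr<KmerMap> p = as_db(db);
  double total = 0;
  for (auto& kv : *p) total += kv.second;
  return List::create(_["n_distinct"] = (double)p->size(), _["total"] = total);
}

// [[Rcpp::export(name = ".kmer_histogram_cpp")]]
DataFrame kmer_histogram_cpp(SEXP db) {
  XPtr<KmerMap> p = as_db(db);
  std::unordered_map<uint32_t, double> h;
  for (auto& kv : *p) h[kv.second] += 1;
  std::vector<uint32_t> mult;
  mult.reserve(h.size());
  for (auto& kv : h) mult.push_back(kv.first);
  std::sort(mult.begin(), mult.end());
  NumericVector m(mult.size()), n(mult.size());
  for (size_t i = 0; i < mult.size(); ++i) {
    m[i] = mult[i];
    n[i] = h[mult[i]];
  }
  return DataFrame::create(_["multiplicity"] = m, _["n_kmers"] = n);
}

// [[Rcpp::export(name = ".coverage_profile_cpp")]]
IntegerVector coverage_profile_cpp(SEXP db, std::string seq, int k) {
  XPtr<KmerMap> p = as_db(db);
  int L = (int)seq.size();
  int np = L - k + 1;
  if (np <= 0) return IntegerVector(0);
  IntegerVector out(np, 0);
  for_each_canonical(seq.c_str(), seq.size(), k, [&](size_t pos, uint64_t km) {
    auto it = p->find(km);
    if (it != p->end()) out[pos] = (int)it->second;
  });
  return out;
}

static std::string decode_kmer(uint64_t km, int k) {
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = CODE_BASE[km & 3ULL];
    km >>= 2;
  }
  return s;
}

// [[Rcpp::export(name = ".kmer_db_dump_cpp")]]
DataFrame kmer_db_dump_cpp(SEXP db, int k) {
  XPtr<KmerMap> p = as_db(db);
  std::vector<std::pair<uint64_t, uint32_t> > v(p->begin(), p->end());
  std::sort(v.begin(), v.end());
  CharacterVector km(v.size());
  NumericVector ct(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    km[i] = decode_kmer(v[i].first, k);
    ct[i] = v[i].second;
  }
  return DataFrame::create(_["kmer"] = km, _["count"] = ct,
                           _["stringsAsFactors"] = false);
}

// [[Rcpp::export(name = ".kmer_db_build_cpp")]]
SEXP kmer_db_build_cpp(CharacterVector kmers, NumericVector counts, int k) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  KmerMap* m = new KmerMap();
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  const int shift_rc = 2 * (k - 1);
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    const char* s = CHAR(STRING_ELT(kmers, i));
    if ((int)LENGTH(STRING_ELT(kmers, i)) != k) stop("k-mer of wrong length");
    uint64_t fwd = 0, rev = 0;
    for (int j = 0; j < k; ++j) {
      int c = base_code(s[j]);
      if (c < 0) stop("non-ACGT character in k-mer");
      fwd = ((fwd << 2) | (uint64_t)c) & mask;
      rev = (rev >> 2) | ((uint64_t)(3 - c) << shift_rc);
    }
    (*m)[std::min(fwd, rev)] += (uint32_t)counts[i];
  }
  XPtr<KmerMap> p(m, true);
  p.attr("k") = k;
  return p;
}

// [[Rcpp::export(name = ".kmer_lookup_cpp")]]
NumericVector kmer_lookup_cpp(SEXP db, CharacterVector kmers, int k) {
  XPtr<KmerMap> p = as_db(db);
  NumericVector out(kmers.size(), 0.0);
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  const int shift_rc = 2 * (k - 1);
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    const char* s = CHAR(STRING_ELT(kmers, i));
    if ((int)LENGTH(STRING_ELT(kmers, i)) != k) { out[i] = NA_REAL; continue; }
    uint64_t fwd = 0, rev = 0;
    bool ok = true;
    for (int j = 0; j < k; ++j) {
      int c = base_code(s[j]);
      if (c < 0) { ok = false; break; }
      fwd = ((fwd << 2) | (uint64_t)c) & mask;
      rev = (rev >> 2) | ((uint64_t)(3 - c) << shift_rc);
    }
    if (!ok) { out[i] = 0; continue; }
    auto it = p->find(std::min(fwd, rev));
    out[i] = (it == p->end()) ? 0 : (double)it->second;
  }
  return out;
}
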