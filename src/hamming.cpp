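#include <Rcpp.h>
using namespace Rcpp;

// Count, for each query k-mer, how many site k-mers lie within Hamming
// distance <= maxMismatches. Early exit once the budget is exceeded keeps
// the scan fast on genome-scale indexes. 'N' never matches anything.

// [[Rcpp::export]]
IntegerVector hamming_count_batch(CharacterVector queries,
                                  CharacterVector sites,
                                  int maxMismatches) {
  const int nq = queries.size();
  const int ns = sites.size();
  IntegerVector out(nq);

  // flatten sites once
  std::vector<const char*> sp(ns);
  int k = 0;
  for (int j = 0; j < ns; ++j) {
    sp[j] = CHAR(STRING_ELT(sites, j));
    if (j == 0) k = LENGTH(STRING_ELT(sites, 0));
  }

  for (int i = 0; i < nq; ++i) {
    const char* q = CHAR(STRING_ELT(queries, i));
    if ((int)strlen(q) != k) stop("query length does not match site length");
    int cnt = 0;
    for (int j = 0; j < ns; ++j) {
      const char* s = sp[j];
      int mm = 0;
      for (int p = 0; p < k; ++p) {
        if (q[p] != s[p] || q[p] == 'N') {
          if (++mm > maxMismatches) break;
        }
      }
      if (mm <= maxMismatches) ++cnt;
    }
    out[i] = cnt;
  }
  return out;
}

// 2-bit packing of 20-mers (A=0,C=1,G=2,T=3) into a uint64 bit-cast into a
// double, and a popcount-based Hamming counter over packed sites. Only
// N-free sequences may be packed (the index excludes them; queries with N
// take the character path).

static inline uint64_t packSeq(const char* s, int k) {
  uint64_t v = 0;
  for (int i = 0; i < k; ++i) {
    uint64_t code;
    switch (s[i]) {
      case 'A': code = 0; break;
      case 'C': code = 1; break;
      case 'G': code = 2; break;
      case 'T': code = 3; break;
      default: stop("cannot pack base '%c'", s[i]);
    }
    v = (v << 2) | code;
  }
  return v;
}

// [[Rcpp::export]]
NumericVector pack_2bit(CharacterVector seqs) {
  const int n = seqs.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    uint64_t v = packSeq(s, (int)strlen(s));
    memcpy(&out[i], &v, sizeof(double));
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector hamming_count_packed(CharacterVector queries,
                                   NumericVector packedSites,
                                   int maxMismatches) {
  const int nq = queries.size();
  const int ns = packedSites.size();
  IntegerVector out(nq);
  const uint64_t odd = 0x5555555555555555ULL;
  std::vector<uint64_t> sp(ns);
  memcpy(sp.data(), &packedSites[0], ns * sizeof(double));
  for (int i = 0; i < nq; ++i) {
    const char* qs = CHAR(STRING_ELT(queries, i));
    uint64_t q = packSeq(qs, (int)strlen(qs));
    int cnt = 0;
    for (int j = 0; j < ns; ++j) {
      uint64_t z = q ^ sp[j];
      z = (z | (z >> 1)) & odd;
      if (__builtin_popcountll(z) <= maxMismatches) ++cnt;
    }
    out[i] = cnt;
  }
  return out;
}

// Pairwise Hamming distance between two equal-length strings ('N' counts
// as a mismatch against anything, including 'N').

// [[Rcpp::export]]
int hamming_distance_cpp(std::string a, std::string b) {
  if (a.size() != b.size()) stop("length mismatch");
  int mm = 0;
  for (size_t i = 0; i < a.size(); ++i)
    if (a[i] != b[i] || a[i] == 'N') ++mm;
  return mm;
}
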