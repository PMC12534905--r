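#include <Rcpp.h>
#include <cstdint>
#include <unordered_set>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Fixed 64-bit mixer (splitmix64 finalizer). Constant across runs and
// platforms; no runtime seeding so sketches are reproducible everywhere.
static inline uint64_t mix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// Hash values handed back to R must be exactly representable as doubles,
// so the 64-bit hash is truncated to its top 53 bits. Retention rule:
// keep h iff h < 2^53 / scaled (FracMinHash over a 2^53 hash space).
static const double HASH_SPACE = 9007199254740992.0; // 2^53

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1; // N or anything else: breaks the k-mer window
  }
}

// Sketch a set of sequences (the contigs of one bin) as one FracMinHash
// k-mer sketch. Canonical k-mer = min(forward, reverse-complement) of the
// 2-bit packed encoding. k-mers containing non-ACGT characters are skipped.
//
// Returns list(hashes = sorted numeric vector of retained 53-bit hashes,
//              genome_kmer_count = number of distinct canonical k-mers).
// [[Rcpp::export(name = ".sketch_sequences")]]
List sketch_sequences(CharacterVector sequences, int k, double scaled) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  if (scaled < 1) stop("scaled must be >= 1");

  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  const int shift_rc = 2 * (k - 1);
  const uint64_t limit = (uint64_t)(HASH_SPACE / scaled);

  std::unordered_set<uint64_t> all_kmers;
  std::unordered_set<uint64_t> retained;

  for (R_xlen_t s = 0; s < sequences.size(); ++s) {
    const char *seq = CHAR(STRING_ELT(sequences, s));
    uint64_t fw = 0, rc = 0;
    int run = 0; // valid bases accumulated since last invalid one
    for (const char *p = seq; *p; ++p) {
      int code = base_code(*p);
      if (code < 0) { run = 0; fw = 0; rc = 0; continue; }
      fw = ((fw << 2) | (uint64_t)code) & mask;
      rc = (rc >> 2) | ((uint64_t)(3 - code) << shift_rc);
      if (++run >= k) {
        uint64_t canon = fw < rc ? fw : rc;
        all_kmers.insert(canon);
        uint64_t h = mix64(canon) >> 11; // top 53 bits
        if (h < limit) retained.insert(h);
      }
    }
  }

  std::vector<double> out(retained.begin(), retained.end());
  std::sort(out.begin(), out.end());
  return List::create(_["hashes"] = NumericVector(out.begin(), out.end()),
                      _["genome_kmer_count"] = (double)all_kmers.size());
}

// Size of the intersection of two sorted numeric hash vectors.
// [[Rcpp::export(name = ".hash_intersection_size")]]
double hash_intersection_size(NumericVector a, NumericVector b) {
  R_xlen_t i = 0, j = 0;
  double n = 0;
  while (i < a.size() && j < b.size()) {
    if (a[i] < b[j]) ++i;
    else if (a[i] > b[j]) ++j;
    else { ++n; ++i; ++j; }
  }
  return n;
}
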